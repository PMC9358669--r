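test_that("the proof-of-concept two-species scan deconvolutes to apo and complex", {
  s <- synthesize_native_scan(c(25232.6, 26195.1), c(7e5, 3e5))
  d <- deconvolve_scan(s)
  expect_equal(nrow(d), 2L)
  expect_equal(d$neutral_mass[1], 25232.6, tolerance = 0.5 / 25232.6)
  expect_equal(diff(d$neutral_mass), 962.5, tolerance = 0.1 / 962.5)
  expect_true(all(d$n_charges >= 3))
})

test_that("degenerate scans are handled without error", {
  empty <- ms_spectrum("e", 1, 1L, numeric(0), numeric(0))
  expect_equal(nrow(deconvolve_scan(empty)), 0L)
  single <- ms_spectrum("s", 1, 1L, mz = 2524.27, intensity = 100)
  expect_equal(nrow(deconvolve_scan(single, min_charge_support = 2L)), 0L)
  expect_error(deconvolve_scan(empty, charge_range = c(10, 5)), "charge range")
  expect_error(deconvolve_scan(empty, charge_range = c(0, 5)), "z_min")
})

test_that("deconvolution recovers random masses from their charge envelopes", {
  # round-trip property: synthesize an envelope, recover the neutral mass
  set.seed(101)
  for (i in 1:100) {
    M <- runif(1, 10e3, 60e3)
    support <- sample(3:8, 1)
    z_lo <- sample(5:(25 - support), 1)
    zs <- z_lo:(z_lo + support - 1L)
    inten <- runif(length(zs), 1e4, 1e5)
    s <- ms_spectrum("r", 1, 1L, mz = mz_from_mass(M, zs), intensity = inten)
    d <- deconvolve_scan(s, charge_range = c(5L, 25L), noise_floor = 0)
    expect_gte(nrow(d), 1L)
    tol <- 2 * max(0.05, 10e-6 * M)
    expect_lt(min(abs(d$neutral_mass - M)), tol)
  }
})

test_that("deconvolution is invariant to peak order and conserves intensity", {
  s <- synthesize_native_scan(c(25232.6, 26195.1), c(7e5, 3e5))
  perm <- sample(seq_along(s$mz))
  s2 <- ms_spectrum(s$scan_id, s$rt, 1L, s$mz[perm], s$intensity[perm])
  expect_equal(deconvolve_scan(s)$neutral_mass, deconvolve_scan(s2)$neutral_mass)
  d <- deconvolve_scan(s)
  for (i in seq_len(nrow(d))) {
    expect_equal(d$total_intensity[i], sum(d$peaks[[i]]$intensity))
  }
  expect_lte(sum(d$total_intensity), sum(s$intensity) + 1e-6)
})

test_that("close but distinct species are not merged", {
  # 3 Da apart at 25 kDa: beyond the 10 ppm intra-series tolerance
  zs <- 7:10
  s <- ms_spectrum("two", 1, 1L,
                   mz = c(mz_from_mass(25000, zs), mz_from_mass(25003, zs)),
                   intensity = rep(1e5, 8))
  d <- deconvolve_scan(s, noise_floor = 0)
  expect_equal(nrow(d), 2L)
  expect_equal(diff(d$neutral_mass), 3, tolerance = 0.05)
})

test_that("mass traces group species across scans and respect min_scans", {
  mk <- function(mass_by_scan) {
    # build a deconv_run-like table from planted per-scan species
    rows <- do.call(rbind, lapply(seq_along(mass_by_scan), function(k) {
      m <- mass_by_scan[[k]]
      if (!length(m)) return(NULL)
      data.frame(neutral_mass = m, total_intensity = 1e5, n_charges = 4L,
                 charges = "7,8,9,10", scan_id = paste0("s", k),
                 rt = k * 0.02, scan_index = k)
    }))
    attr(rows, "scan_rts") <- seq_along(mass_by_scan) * 0.02
    class(rows) <- c("deconv_run", "data.frame")
    rows
  }
  ten <- mk(replicate(10, 25232.6 + rnorm(1, 0, 0.1), simplify = FALSE))
  tr <- build_mass_traces(ten, window = 5, min_scans = 3L)
  expect_length(tr, 1L)
  expect_equal(nrow(tr[[1]]$trace), 10L)
  expect_equal(tr[[1]]$center_mass, 25232.6, tolerance = 0.3 / 25232.6)

  two <- mk(replicate(5, c(25000, 25012), simplify = FALSE))
  expect_length(build_mass_traces(two, window = 5, min_scans = 3L), 2L)

  short <- mk(list(25000, 25000, numeric(0), numeric(0), numeric(0)))
  expect_length(build_mass_traces(short, window = 5, min_scans = 3L), 0L)
})

test_that("deconvoluted XICs are zero-filled and window-faithful", {
  d <- data.frame(neutral_mass = c(25232.6, 25232.6, 26195.1),
                  total_intensity = c(10, 20, 5), n_charges = 4L,
                  charges = "7,8,9,10", scan_id = c("a", "b", "b"),
                  rt = c(0.02, 0.04, 0.04), scan_index = c(1L, 2L, 2L))
  attr(d, "scan_rts") <- c(0.02, 0.04, 0.06)
  class(d) <- c("deconv_run", "data.frame")
  x <- extract_xic(d, 25233, window = 5)
  expect_equal(x$intensity, c(10, 20, 0))
  expect_equal(extract_xic(d, 25232.6, window = 0)$intensity, c(10, 20, 0))
  expect_equal(extract_xic(d, 30000, window = 5)$intensity, c(0, 0, 0))
})

test_that("apo depletion dips are detected at binder retention times", {
  rt <- seq(0, 10, by = 0.02)
  inten <- rep(1e6, length(rt))
  dip <- exp(-(rt - 5.0)^2 / (2 * 0.03^2))
  inten <- inten * (1 - 0.45 * dip)
  dep <- detect_apo_depletion(data.frame(rt = rt, intensity = inten),
                              min_drop = 0.3)
  expect_equal(nrow(dep), 1L)
  expect_equal(dep$rt, 5.0, tolerance = 0.03)
  expect_gte(dep$depth, 0.4)
  flat <- detect_apo_depletion(data.frame(rt = rt, intensity = rep(1e6, length(rt))))
  expect_equal(nrow(flat), 0L)
})
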