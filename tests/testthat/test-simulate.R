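two_binder_scenario <- function(noise = TRUE, seed = 42L) {
  binders <- data.frame(
    id = c("riv1185", "riv1155"),
    ligand_mass = c(1187, 1152), mz = c(1186.6400, 1156.5923),
    rt = c(5.5, 5.1), width = 0.03, ratio = c(0.5, 0.4),
    stoichiometry = 1L, family = "riv", apex_intensity = 2e5,
    stringsAsFactors = FALSE
  )
  if (noise) screen_scenario(apo_mass = 25233, binders = binders,
                             decoys = NULL, seed = seed)
  else noiseless(apo_mass = 25233, binders = binders, decoys = NULL,
                 seed = seed)
}

test_that("simulated runs are deterministic for a fixed seed", {
  sc <- two_binder_scenario()
  r1 <- simulate_native_run(sc)
  r2 <- simulate_native_run(sc)
  expect_identical(r1$run$spectra, r2$run$spectra)
  m1 <- simulate_metabolomics_run(sc)
  m2 <- simulate_metabolomics_run(sc)
  expect_identical(m1$run$spectra, m2$run$spectra)
  # and a different seed perturbs the peaks
  r3 <- simulate_native_run(two_binder_scenario(seed = 43L))
  expect_false(identical(r1$run$spectra, r3$run$spectra))
})

test_that("the molassamide proof-of-concept scenario reproduces its mass shift", {
  sc <- screen_scenario(
    apo_mass = 25232.6,
    binders = data.frame(id = "molassamide", ligand_mass = 962.4749,
                         mz = NA_real_, rt = 5.0, width = 0.03, ratio = 0.5,
                         stoichiometry = 1L, family = "mol",
                         apex_intensity = 2e5, stringsAsFactors = FALSE),
    decoys = NULL, seed = 11L
  )
  nat <- simulate_native_run(sc)
  apex <- which.min(abs(run_rts(nat$run) - 5.0))
  d <- deconvolve_scan(nat$run$spectra[[apex]])
  expect_equal(nrow(d), 2L)
  expect_equal(diff(d$neutral_mass), 962.5, tolerance = 0.1 / 962.5)
  expect_equal(d$neutral_mass[1], 25232.6, tolerance = 0.5 / 25232.6)
})

test_that("a binder-free scenario yields exactly one species per scan", {
  sc <- noiseless(binders = NULL, decoys = default_decoys(2), seed = 3L)
  nat <- simulate_native_run(sc)
  counts <- vapply(nat$run$spectra[seq(1, length(nat$run), by = 50)],
                   function(s) nrow(deconvolve_scan(s)), integer(1))
  expect_true(all(counts == 1L))
})

test_that("envelopes outside the acquisition window raise a named error", {
  expect_error(synthesize_envelope(10000, 1e5, z_range = c(6, 11)),
               "outside m/z")
  # truncation at the window edge keeps only in-window charges
  env <- synthesize_envelope(25232.6, 1e5)
  expect_setequal(env$z, 7:10)
  expect_true(all(env$mz >= 2500 & env$mz <= 4000))
})

test_that("metabolomics simulation places features and family MS/MS correctly", {
  binders <- data.frame(
    id = sprintf("an%02d", 1:3),
    ligand_mass = c(1185.6327, 1155.5850, 1121.6007), mz = NA_real_,
    rt = c(5.5, 5.1, 4.7), width = 0.03, ratio = 0.5, stoichiometry = 1L,
    family = "riv", apex_intensity = 3e5, stringsAsFactors = FALSE
  )
  sc <- noiseless(binders = binders, decoys = default_decoys(1), seed = 21L)
  met <- simulate_metabolomics_run(sc)
  ft <- build_metabolite_features(met$run, min_height = 1e3)
  # the planted rivulariapeptolide-like [M+H]+ appears as an MS1 feature
  hit <- which(abs(ft$mass_value - 1186.6400) / 1186.64 < 1e-5)
  expect_length(hit, 1L)
  expect_equal(ft$rt_apex[hit], 5.5, tolerance = 0.05 / 5.5)
  expect_gte(length(ft$ms2[[hit]]), 1L)

  ms2 <- Filter(function(s) s$ms_level == 2L, met$run$spectra)
  names(ms2) <- vapply(ms2, `[[`, character(1), "scan_id")
  by_prec <- function(mz) {
    cand <- Filter(function(s) abs(s$precursor_mz - mz) < 0.01, ms2)
    cand[[1]]
  }
  fam <- lapply(binders$ligand_mass + PROTON_MASS, by_prec)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(modified_cosine(fam[[i]], fam[[j]])$score, 0.7)
  }
  decoy_mz <- sc$decoys$ligand_mass[1] + PROTON_MASS
  dec <- by_prec(decoy_mz)
  expect_lt(modified_cosine(fam[[1]], dec)$score, 0.7)
})

test_that("titration and dose-response generators honor their models and seeds", {
  s0 <- simulate_titration(kd = 1, rmax = 3, noise = 0)
  expect_equal(s0$ratio, 3 * s0$concentration / (1 + s0$concentration))
  expect_identical(simulate_titration(1, 3, noise = 0.1, seed = 4),
                   simulate_titration(1, 3, noise = 0.1, seed = 4))
  d0 <- simulate_dose_response(ic50 = 10, noise = 0)
  expect_equal(unique(table(d0$concentration)), 3L)
  expect_equal(d0$response[d0$concentration == 10], rep(50, 3))
  expect_identical(simulate_dose_response(10, seed = 8),
                   simulate_dose_response(10, seed = 8))
})
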