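test_that("worked complex/ligand pairs match at the published tolerances", {
  # upper panel: complex 26,420 / apo 25,233 / ligand [M+H]+ 1186.6400 at 5.5 min
  p1 <- make_feature("P1", "protein", 26420, 5.5)
  l1 <- make_feature("M1", "metabolite", 1186.6400, 5.5)
  m1 <- match_complexes(p1, l1, apo_mass = 25233)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$delta_mass, 1187, tolerance = 5 / 1187)
  expect_equal(m1$stoichiometry, 1L)
  expect_equal(m1$mass_error, 1187 - (1186.6400 - PROTON_MASS), tolerance = 1e-6)
  expect_lte(abs(m1$mass_error), 4)

  # lower panel: complex 26,385 / ligand [M+H]+ 1156.5923 at 5.1 min
  m2 <- match_complexes(make_feature("P2", "protein", 26385, 5.1),
                        make_feature("M2", "metabolite", 1156.5923, 5.1),
                        apo_mass = 25233)
  expect_equal(m2$delta_mass, 1152, tolerance = 5 / 1152)

  # 2:1 stoichiometry: shift of two molassamide molecules
  m3 <- match_complexes(make_feature("P3", "protein", 27157.6, 5.0),
                        make_feature("M3", "metabolite", 963.4822, 5.0),
                        apo_mass = 25232.6)
  expect_equal(m3$stoichiometry, 2L)
  expect_true(m3$nonspecific_flag)
  expect_equal(m3$delta_mass, 1925.0, tolerance = 0.1 / 1925)

  # RT gate: apexes 0.3 min apart at rt_tol 0.2
  expect_equal(nrow(match_complexes(make_feature("P4", "protein", 26420, 5.8),
                                    make_feature("M4", "metabolite", 1186.64, 5.5),
                                    apo_mass = 25233)), 0L)
})

test_that("matching rejects invalid inputs and passes through empties", {
  p <- make_feature("P1", "protein", 26420, 5.5)
  l <- make_feature("M1", "metabolite", 1186.64, 5.5)
  expect_error(match_complexes(p, l, apo_mass = -1), "apo_mass")
  expect_equal(nrow(match_complexes(p[0, ], l, apo_mass = 25233)), 0L)
  expect_equal(nrow(match_complexes(p, l[0, ], apo_mass = 25233)), 0L)
})

test_that("matching agrees with a brute-force oracle on random tables", {
  set.seed(202)
  for (trial in 1:100) {
    np <- sample(3:10, 1); nm <- sample(3:15, 1)
    protein <- do.call(bind_features, lapply(seq_len(np), function(i) {
      make_feature(sprintf("P%02d", i), "protein",
                   25233 + runif(1, 300, 3000), runif(1, 1, 9))
    }))
    metabolite <- do.call(bind_features, lapply(seq_len(nm), function(i) {
      make_feature(sprintf("M%02d", i), "metabolite",
                   runif(1, 300, 1500), runif(1, 1, 9))
    }))
    got <- match_complexes(protein, metabolite, apo_mass = 25233)
    keys <- sort(paste(got$protein_feature_id, got$metabolite_feature_id,
                       got$stoichiometry, sep = "|"))
    expect_identical(keys, brute_force_matches(protein, metabolite, 25233))
  }
})

test_that("wider tolerances never remove matches", {
  set.seed(303)
  protein <- do.call(bind_features, lapply(1:8, function(i) {
    make_feature(sprintf("P%02d", i), "protein", 25233 + runif(1, 500, 2000),
                 runif(1, 2, 8))
  }))
  metabolite <- do.call(bind_features, lapply(1:12, function(i) {
    make_feature(sprintf("M%02d", i), "metabolite", runif(1, 400, 1400),
                 runif(1, 2, 8))
  }))
  key <- function(m) paste(m$protein_feature_id, m$metabolite_feature_id,
                           m$stoichiometry, sep = "|")
  narrow <- match_complexes(protein, metabolite, 25233, mass_tol = 4, rt_tol = 0.2)
  wider_mass <- match_complexes(protein, metabolite, 25233, mass_tol = 8, rt_tol = 0.2)
  wider_rt <- match_complexes(protein, metabolite, 25233, mass_tol = 4, rt_tol = 0.5)
  expect_true(all(key(narrow) %in% key(wider_mass)))
  expect_true(all(key(narrow) %in% key(wider_rt)))
})

test_that("apo autodetection picks the spanning, dominant feature", {
  span <- data.frame(rt = seq(0, 10, by = 0.1), intensity = 1e6)
  apo <- make_feature("P1", "protein", 25232.6, 5, trace = span, area = 1e7)
  cplx <- make_feature("P2", "protein", 26420, 5.5, area = 1e4)
  expect_equal(apo_autodetect(bind_features(apo, cplx)), 25232.6)
  expect_equal(apo_autodetect(apo), 25232.6)
  rival <- make_feature("P3", "protein", 27000, 5, trace = span, area = 1e7)
  expect_error(apo_autodetect(bind_features(apo, rival, cplx)), "ambiguous")
})

test_that("binding ratio compares areas over the complex window", {
  apo_trace <- data.frame(rt = seq(5, 6, by = 0.01), intensity = 1e4)
  cplx <- make_feature("C", "protein", 26420, 5.5, sigma = 0.05)
  apo <- make_feature("A", "protein", 25232.6, 5.5, trace = apo_trace)
  r <- binding_ratio(cplx, apo)
  # complex area ~ 1e4 * 0.05 * sqrt(2*pi); apo area over the 0.4-min window
  expect_equal(r, (1e4 * 0.05 * sqrt(2 * pi)) / (1e4 * 0.4), tolerance = 0.02)
  double <- cplx; double$trace[[1]]$intensity <- 2 * double$trace[[1]]$intensity
  expect_equal(binding_ratio(double, apo) / binding_ratio(cplx, apo), 2)
  zero <- apo; zero$trace[[1]]$intensity <- 0
  expect_warning(r0 <- binding_ratio(cplx, zero), "zero")
  expect_true(is.infinite(r0))
})
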