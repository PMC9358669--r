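test_that("modified cosine scores identical, disjoint and shifted spectra correctly", {
  a <- make_ms2("a", c(100, 150, 200, 250), c(5, 10, 20, 5), precursor = 500)
  expect_equal(modified_cosine(a, a, min_matched = 2L)$score, 1.0, tolerance = 1e-9)

  b <- make_ms2("b", c(110, 160, 210, 260), c(5, 10, 20, 5), precursor = 500)
  expect_equal(modified_cosine(a, b, min_matched = 2L)$score, 0)

  # both fragments pair through the precursor-shift channel
  x <- make_ms2("x", c(100, 200), c(1, 1), precursor = 500)
  y <- make_ms2("y", c(110, 210), c(1, 1), precursor = 510)
  got <- modified_cosine(x, y, frag_tol = 0.02, min_matched = 2L)
  expect_equal(got$score, 1.0, tolerance = 1e-9)
  expect_equal(got$n_matched, 2L)

  # empty peak list scores zero without error
  e <- ms_spectrum("e", 5, 2L, numeric(0), numeric(0), precursor_mz = 400)
  expect_equal(modified_cosine(e, a)$score, 0)

  # below min_matched the score is suppressed but the count is kept
  few <- modified_cosine(x, y, min_matched = 6L)
  expect_equal(few$score, 0)
  expect_equal(few$n_matched, 2L)
})

test_that("modified cosine is symmetric and bounded", {
  set.seed(404)
  for (i in 1:25) {
    na <- sample(3:10, 1); nb <- sample(3:10, 1)
    a <- make_ms2("a", sort(runif(na, 100, 900)), runif(na, 1, 100),
                  precursor = runif(1, 900, 1200))
    b <- make_ms2("b", sort(runif(nb, 100, 900)), runif(nb, 1, 100),
                  precursor = runif(1, 900, 1200))
    sab <- modified_cosine(a, b, frag_tol = 5, min_matched = 1L)
    sba <- modified_cosine(b, a, frag_tol = 5, min_matched = 1L)
    expect_identical(sab, sba)
    expect_lte(sab$score, 1 + 1e-9)
    expect_equal(modified_cosine(a, a, min_matched = 1L)$score, 1, tolerance = 1e-9)
  }
})

test_that("greedy pairing is near-optimal and exact mode matches the oracle", {
  set.seed(505)
  for (i in 1:30) {
    n <- sample(3:6, 1)
    a <- make_ms2("a", sort(runif(n, 100, 500)), runif(n, 1, 100),
                  precursor = runif(1, 500, 700))
    b <- make_ms2("b", sort(runif(n, 100, 500)), runif(n, 1, 100),
                  precursor = runif(1, 500, 700))
    cand <- cosine_candidates(a, b, frag_tol = 10)
    if (is.null(cand)) next
    oracle <- oracle_best_pairing(cand)
    greedy <- modified_cosine(a, b, frag_tol = 10, min_matched = 1L)$score
    exact <- modified_cosine(a, b, frag_tol = 10, min_matched = 1L,
                             method = "exact")$score
    expect_equal(exact, min(oracle, 1), tolerance = 1e-9)
    expect_gte(greedy, 0.95 * min(oracle, 1))
  }
})

test_that("network construction thresholds, caps and types edges", {
  # family of three analogs: shared ladder, one residue-shifted member
  base <- c(120.1, 241.2, 362.3, 483.4, 604.5, 725.6)
  fam <- list(
    make_ms2("s1", base, rep(10, 6), precursor = 900.5, rt = 5.0),
    make_ms2("s2", base, rep(10, 6), precursor = 900.5, rt = 5.4),
    make_ms2("s3", c(base[1:3], base[4:6] + 28), rep(10, 6), precursor = 928.5, rt = 5.8)
  )
  lone <- make_ms2("s4", c(77.7, 133.3, 219.9, 301.1, 405.5, 512.2),
                   rep(10, 6), precursor = 950.5, rt = 6.2)
  spectra <- c(fam, list(lone))
  names(spectra) <- vapply(spectra, `[[`, character(1), "scan_id")
  ft <- do.call(bind_features, lapply(seq_along(spectra), function(i) {
    f <- make_feature(sprintf("M%d", i), "metabolite",
                      spectra[[i]]$precursor_mz, spectra[[i]]$rt)
    f$ms2 <- list(names(spectra)[i])
    f
  }))
  matches <- data.frame(
    protein_feature_id = "P1", metabolite_feature_id = c("M1", "M2"),
    apo_mass = 25232.6, delta_mass = c(899.5, 913.5),
    ligand_neutral_mass = c(899.5, 913.5), stoichiometry = 1L,
    mass_error = 0, rt_diff = 0, coelution = 0.99, nonspecific_flag = FALSE,
    stringsAsFactors = FALSE
  )
  net <- build_network(ft, spectra, matches, score_threshold = 0.7,
                       min_matched = 6L)
  expect_s3_class(net, "molecular_network")
  msms <- net$edges[net$edges$type == "msms", ]
  binding <- net$edges[net$edges$type == "binding", ]
  # the three family members are fully connected; the lone spectrum is not
  expect_setequal(unique(c(msms$from, msms$to)), c("M1", "M2", "M3"))
  expect_equal(nrow(msms), 3L)
  expect_equal(nrow(binding), 2L)
  expect_setequal(binding$to, c("M1", "M2"))
  comp <- network_components(net)
  expect_equal(sort(comp$size, decreasing = TRUE)[1], 4L) # family + protein

  # raising the threshold never adds edges
  net2 <- build_network(ft, spectra, matches, score_threshold = 0.95,
                        min_matched = 6L)
  expect_lte(nrow(net2$edges[net2$edges$type == "msms", ]), nrow(msms))

  # top_k = 1 on an equal-score clique keeps at most one edge per node
  net3 <- build_network(ft, spectra, NULL, score_threshold = 0.7,
                        min_matched = 6L, top_k = 1L)
  msms3 <- net3$edges[net3$edges$type == "msms", ]
  for (v in c("M1", "M2", "M3")) {
    expect_lte(sum(msms3$from == v | msms3$to == v), 1L)
  }
  # determinism
  net4 <- build_network(ft, spectra, NULL, score_threshold = 0.7,
                        min_matched = 6L, top_k = 1L)
  expect_identical(msms3, net4$edges[net4$edges$type == "msms", ])
})

test_that("molecular networks reject self-loops and dangling edges", {
  nodes <- data.frame(id = c("a", "b"))
  expect_error(molecular_network(nodes, data.frame(from = "a", to = "a",
                                                   type = "msms", score = 1)),
               "self-loop")
  expect_error(molecular_network(nodes, data.frame(from = "a", to = "c",
                                                   type = "msms", score = 1)),
               "not in nodes")
})
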