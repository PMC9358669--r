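# shared fixture builders and independent oracles

gaussian_trace <- function(apex = 5.5, sigma = 0.05, height = 1e6,
                           from = apex - 1, to = apex + 1, by = 0.01) {
  rt <- seq(from, to, by = by)
  data.frame(rt = rt, intensity = height * exp(-(rt - apex)^2 / (2 * sigma^2)))
}

# minimal feature-table row for matching tests (trace optional)
make_feature <- function(id, kind, mass, rt, sigma = 0.03, area = 1e4,
                         trace = NULL) {
  if (is.null(trace)) trace <- gaussian_trace(apex = rt, sigma = sigma,
                                              height = area, from = rt - 0.2,
                                              to = rt + 0.2, by = 0.01)
  ft <- data.frame(id = id, kind = kind, mass_value = mass, rt_apex = rt,
                   rt_start = min(trace$rt), rt_end = max(trace$rt),
                   apex_intensity = max(trace$intensity), area = area,
                   stringsAsFactors = FALSE)
  ft$trace <- list(trace)
  ft$ms2 <- list(character(0))
  class(ft) <- c("feature_table", "data.frame")
  ft
}

bind_features <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("feature_table", "data.frame")
  out
}

make_ms2 <- function(id, mz, intensity, precursor, rt = 5) {
  ms_spectrum(scan_id = id, rt = rt, ms_level = 2L, mz = mz,
              intensity = intensity, precursor_mz = precursor,
              precursor_charge = 1L)
}

# independent O(n*m*k) enumeration of the delta-mass/RT matching contract
brute_force_matches <- function(protein, metabolite, apo_mass, mass_tol = 4,
                                rt_tol = 0.2, max_stoich = 2L) {
  hits <- character(0)
  for (i in seq_len(nrow(protein))) {
    for (j in seq_len(nrow(metabolite))) {
      for (n in seq_len(max_stoich)) {
        delta <- protein$mass_value[i] - apo_mass
        ligand <- metabolite$mass_value[j] - 1.00727646677
        if (abs(delta - n * ligand) <= mass_tol &&
            abs(protein$rt_apex[i] - metabolite$rt_apex[j]) <= rt_tol) {
          hits <- c(hits, paste(protein$id[i], metabolite$id[j], n, sep = "|"))
        }
      }
    }
  }
  sort(hits)
}

# exact maximum-weight one-to-one pairing by full enumeration over the
# candidate list (independent of the package's branch-search implementation)
oracle_best_pairing <- function(cand) {
  best <- 0
  explore <- function(rows, used_a, used_b, acc) {
    if (acc > best) best <<- acc
    if (!length(rows)) return()
    r <- rows[1]; rest <- rows[-1]
    if (!(cand[r, 1] %in% used_a) && !(cand[r, 2] %in% used_b)) {
      explore(rest, c(used_a, cand[r, 1]), c(used_b, cand[r, 2]),
              acc + cand[r, 3])
    }
    explore(rest, used_a, used_b, acc)
  }
  explore(seq_len(nrow(cand)), numeric(0), numeric(0), 0)
  best
}

# candidate fragment pairs under the modified-cosine matching rule
cosine_candidates <- function(a, b, frag_tol = 0.02) {
  wa <- sqrt(a$intensity); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(b$intensity); wb <- wb / sqrt(sum(wb^2))
  dprec <- a$precursor_mz - b$precursor_mz
  out <- NULL
  for (i in seq_along(a$mz)) {
    for (j in seq_along(b$mz)) {
      d <- a$mz[i] - b$mz[j]
      if (abs(d) <= frag_tol || abs(d - dprec) <= frag_tol) {
        out <- rbind(out, c(i, j, wa[i] * wb[j]))
      }
    }
  }
  out
}

noiseless <- function(...) {
  screen_scenario(..., noise = list(intensity_sd = 0, mz_ppm = 0, floor = 0,
                                    n_noise_peaks = 0L))
}

# recall of planted binders in a match table
planted_recall <- function(matches, protein_features, truth,
                           mass_tol = 4, rt_tol = 0.2) {
  prt <- protein_features$rt_apex[match(matches$protein_feature_id,
                                        protein_features$id)]
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(abs(matches$delta_mass -
              truth$stoichiometry[i] * truth$ligand_mass[i]) <= mass_tol &
          abs(prt - truth$rt[i]) <= rt_tol)
  }, logical(1))
  mean(hit)
}
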