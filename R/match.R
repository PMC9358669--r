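#' Match protein-complex features to ligand features by mass offset and RT
#'
#' The linking step of the native-metabolomics screen: a protein feature at
#' mass P and a metabolite feature with precursor m/z L (assumed [M+H]+) are
#' matched when the complex mass shift `P - apo_mass` equals `n` ligand
#' neutral masses within `mass_tol` Da and the apexes co-elute within
#' `rt_tol` minutes. All qualifying pairs are reported (many-to-many; the
#' mass window is wide by design), ranked by protein retention time and then
#' absolute mass error. Matches with stoichiometry >= 2 are flagged as
#' possible nonspecific binding.
#'
#' @param protein_features,metabolite_features Feature tables
#'   ([build_protein_features()], [build_metabolite_features()]).
#' @param apo_mass Apoprotein neutral mass in Da (e.g. 25234 for
#'   alpha-chymotrypsin).
#' @param mass_tol Mass tolerance in Da (default 4).
#' @param rt_tol Apex-to-apex retention-time tolerance in minutes (default 0.2).
#' @param max_stoichiometry Largest ligand count n considered (default 2).
#' @return `data.frame` with one row per match: feature ids, `apo_mass`,
#'   `delta_mass`, `ligand_neutral_mass`, `stoichiometry`, `mass_error`
#'   (delta minus n x ligand), `rt_diff`, `coelution`, `nonspecific_flag`.
#' @export
match_complexes <- function(protein_features, metabolite_features, apo_mass,
                            mass_tol = 4, rt_tol = 0.2, max_stoichiometry = 2L) {
  if (!is.numeric(apo_mass) || apo_mass <= 0) stop("apo_mass must be > 0")
  empty <- data.frame(
    protein_feature_id = character(0), metabolite_feature_id = character(0),
    apo_mass = numeric(0), delta_mass = numeric(0),
    ligand_neutral_mass = numeric(0), stoichiometry = integer(0),
    mass_error = numeric(0), rt_diff = numeric(0), coelution = numeric(0),
    nonspecific_flag = logical(0), stringsAsFactors = FALSE
  )
  np <- nrow(protein_features); nm <- nrow(metabolite_features)
  if (!np || !nm) return(empty)
  rows <- list()
  for (i in seq_len(np)) {
    delta <- protein_features$mass_value[i] - apo_mass
    for (j in seq_len(nm)) {
      ligand <- metabolite_features$mass_value[j] - PROTON_MASS
      rt_diff <- protein_features$rt_apex[i] - metabolite_features$rt_apex[j]
      if (abs(rt_diff) > rt_tol) next
      for (n in seq_len(max_stoichiometry)) {
        err <- delta - n * ligand
        if (abs(err) > mass_tol) next
        co <- coelution_correlation(protein_features[i, ], metabolite_features[j, ])
        rows[[length(rows) + 1L]] <- data.frame(
          protein_feature_id = protein_features$id[i],
          metabolite_feature_id = metabolite_features$id[j],
          apo_mass = apo_mass, delta_mass = delta,
          ligand_neutral_mass = ligand, stoichiometry = n,
          mass_error = err, rt_diff = rt_diff,
          coelution = if (is.na(co)) 0 else co,
          nonspecific_flag = n >= 2L, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  prt <- protein_features$rt_apex[match(out$protein_feature_id, protein_features$id)]
  out <- out[order(prt, abs(out$mass_error), out$metabolite_feature_id), ]
  rownames(out) <- NULL
  out
}

#' Infer the apoprotein mass from a protein feature table
#'
#' The apoprotein is infused at constant concentration, so among protein
#' features covering most of the gradient the highest-total-area one is taken
#' as apo. A user-supplied apo mass always takes precedence over this
#' heuristic.
#'
#' @param protein_features A protein feature table.
#' @param run_rt_range Optional `c(min, max)` retention-time span of the run;
#'   defaults to the span of the feature traces.
#' @param min_span Minimum fraction of the run span a candidate must cover.
#' @return Apoprotein neutral mass in Da.
#' @export
apo_autodetect <- function(protein_features, run_rt_range = NULL, min_span = 0.8) {
  if (!nrow(protein_features)) stop("no protein features to pick an apo mass from")
  spans <- vapply(seq_len(nrow(protein_features)), function(i) {
    tr <- protein_features$trace[[i]]
    nz <- tr$rt[tr$intensity > 0]
    if (length(nz) < 2L) 0 else diff(range(nz))
  }, numeric(1))
  if (is.null(run_rt_range)) {
    run_rt_range <- range(unlist(lapply(protein_features$trace, `[[`, "rt")))
  }
  total_span <- diff(run_rt_range)
  cand <- which(spans >= min_span * total_span)
  if (length(cand) == 0L) {
    stop("no protein feature spans >= ", round(100 * min_span),
         "% of the run; supply apo_mass explicitly")
  }
  if (length(cand) == 1L) return(protein_features$mass_value[cand])
  areas <- protein_features$area[cand]
  o <- order(-areas)
  if (areas[o[2]] / areas[o[1]] > 0.95) {
    stop("ambiguous apoprotein: two candidates with comparable abundance (",
         round(protein_features$mass_value[cand[o[1]]], 1), " and ",
         round(protein_features$mass_value[cand[o[2]]], 1),
         " Da); supply apo_mass explicitly")
  }
  protein_features$mass_value[cand[o[1]]]
}

#' Bound-to-unbound protein ratio for one complex feature
#'
#' Ratio of the complex feature's area to the apo feature's area integrated
#' over the complex's retention-time window.
#'
#' @param complex_feature,apo_feature Single-row feature-table slices.
#' @return Non-negative ratio; `Inf` (with a warning) when the apo area in
#'   the window is zero.
#' @export
binding_ratio <- function(complex_feature, apo_feature) {
  ctr <- if (is.data.frame(complex_feature$trace)) complex_feature$trace else complex_feature$trace[[1]]
  atr <- if (is.data.frame(apo_feature$trace)) apo_feature$trace else apo_feature$trace[[1]]
  lo <- complex_feature$rt_start[[1]]; hi <- complex_feature$rt_end[[1]]
  sel <- atr$rt >= lo & atr$rt <= hi
  apo_area <- .trapz(atr$rt[sel], atr$intensity[sel])
  complex_area <- .trapz(ctr$rt, ctr$intensity)
  if (apo_area <= 0) {
    warning("apo area is zero in the complex window [", lo, ", ", hi, "] min")
    return(Inf)
  }
  complex_area / apo_area
}
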