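#' Charge-state deconvolution of one native-MS scan
#'
#' Converts a multiply charged MS1 scan into neutral-mass species by
#' charge-series consistency: every (peak, charge) pair above the noise floor
#' proposes a neutral-mass hypothesis; hypotheses agreeing within the
#' intra-series tolerance are clustered; clusters supported by enough distinct,
#' near-consecutive charge states survive; peaks are then assigned greedily to
#' the highest-intensity cluster first so that each centroid supports at most
#' one species. Harmonic artifacts (mass k-fold of a stronger species built on
#' the same peaks, k = 2, 3) are suppressed.
#'
#' @param s An MS1 [ms_spectrum()].
#' @param charge_range Integer vector `c(z_min, z_max)` of charges to consider.
#' @param peak_tol Peak mass tolerance in ppm; the intra-series clustering
#'   tolerance in Da is `max(0.05, peak_tol * 1e-6 * mass)`.
#' @param min_charge_support Minimum number of distinct charge states backing
#'   a species.
#' @param max_charge_gap Largest allowed gap between consecutive supporting
#'   charges. The default 1 requires a contiguous charge ladder, which also
#'   removes k-fold harmonic candidates structurally: the doubled-charge
#'   ladder of a 2M harmonic has gaps of 2 and never reaches
#'   `min_charge_support`.
#' @param noise_floor Absolute intensity floor; default
#'   `min(3 * median(intensity), max(intensity) / 100)`, which removes the
#'   noise carpet of dense centroid scans without discarding sparse scans
#'   whose median peak is itself signal.
#' @return `data.frame` with one row per species: `neutral_mass`,
#'   `total_intensity`, `n_charges`, `charges` (comma-separated), `scan_id`,
#'   `rt`, plus a `peaks` list-column of supporting (mz, z, intensity) rows.
#' @export
deconvolve_scan <- function(s, charge_range = c(5L, 25L), peak_tol = 10,
                            min_charge_support = 3L, max_charge_gap = 1L,
                            noise_floor = NULL) {
  stopifnot(inherits(s, "Spectrum"))
  if (s$ms_level != 1L) stop("deconvolve_scan expects an MS1 spectrum")
  z_min <- as.integer(charge_range[1]); z_max <- as.integer(charge_range[2])
  if (z_min < 1L) stop("z_min must be >= 1")
  if (z_min > z_max) stop("invalid charge range: z_min > z_max")
  empty <- data.frame(neutral_mass = numeric(0), total_intensity = numeric(0),
                      n_charges = integer(0), charges = character(0),
                      scan_id = character(0), rt = numeric(0))
  empty$peaks <- list()
  if (!length(s$mz)) return(empty)

  if (is.null(noise_floor)) {
    # 3 x median suits noise-dominated centroid scans; the cap keeps sparse
    # all-signal scans (few centroids, all real) from being discarded wholesale
    noise_floor <- min(3 * stats::median(s$intensity), max(s$intensity) / 100)
  }
  keep <- s$intensity > noise_floor
  if (!any(keep)) return(empty)
  mz <- s$mz[keep]; inten <- s$intensity[keep]
  np <- length(mz)

  zs <- z_min:z_max
  nz <- length(zs)
  h_peak <- rep(seq_len(np), each = nz)
  h_z <- rep(zs, times = np)
  h_mass <- rep(mz, each = nz) * h_z - h_z * PROTON_MASS
  h_int <- rep(inten, each = nz)
  o <- order(h_mass)
  h_peak <- h_peak[o]; h_z <- h_z[o]; h_mass <- h_mass[o]; h_int <- h_int[o]
  tol_at <- function(m) pmax(0.05, peak_tol * 1e-6 * m)
  nh <- length(h_mass)
  cluster_id <- cumsum(c(TRUE, diff(h_mass) > tol_at(h_mass[-nh])))
  csize <- tabulate(cluster_id)
  rows_by_cluster <- split(seq_len(nh), cluster_id)
  rows_by_cluster <- rows_by_cluster[csize >= min_charge_support]

  candidates <- lapply(rows_by_cluster, function(rows) {
    z <- h_z[rows]
    # restrict to the largest run of near-consecutive charges
    uz <- sort(unique(z))
    if (length(uz) < min_charge_support) return(NULL)
    runs <- cumsum(c(TRUE, diff(uz) > max_charge_gap))
    best_run <- which.max(tabulate(runs))
    zkeep <- uz[runs == best_run]
    if (length(zkeep) < min_charge_support) return(NULL)
    rows <- rows[z %in% zkeep]
    # one hypothesis per peak; a peak backs a species at a single charge
    rows <- rows[!duplicated(h_peak[rows])]
    if (length(unique(h_z[rows])) < min_charge_support) return(NULL)
    w <- h_int[rows]
    list(
      mass = sum(h_mass[rows] * w) / sum(w),
      score = sum(w),
      rows = rows
    )
  })
  candidates <- Filter(Negate(is.null), candidates)
  if (!length(candidates)) return(empty)
  ord <- order(-vapply(candidates, `[[`, numeric(1), "score"),
               vapply(candidates, `[[`, numeric(1), "mass"))
  candidates <- candidates[ord]

  used <- rep(FALSE, np)
  kept <- list()
  for (cand in candidates) {
    rows <- cand$rows[!used[h_peak[cand$rows]]]
    if (length(unique(h_z[rows])) < min_charge_support) next
    w <- h_int[rows]
    mass <- sum(h_mass[rows] * w) / sum(w)
    # harmonic / divisor suppression against stronger accepted species
    harmonic <- FALSE
    for (k in kept) {
      share <- mean(h_peak[cand$rows] %in% h_peak[k$rows])
      if (share < 0.5) next
      for (fac in c(2, 3, 1/2, 1/3)) {
        if (abs(mass - fac * k$mass) <= tol_at(mass)) harmonic <- TRUE
      }
    }
    if (harmonic) next
    used[h_peak[rows]] <- TRUE
    kept[[length(kept) + 1L]] <- list(mass = mass, score = sum(w), rows = rows)
  }
  if (!length(kept)) return(empty)
  out <- data.frame(
    neutral_mass = vapply(kept, `[[`, numeric(1), "mass"),
    total_intensity = vapply(kept, `[[`, numeric(1), "score"),
    n_charges = vapply(kept, function(k) length(unique(h_z[k$rows])), integer(1)),
    charges = vapply(kept, function(k)
      paste(sort(unique(h_z[k$rows])), collapse = ","), character(1)),
    scan_id = s$scan_id, rt = s$rt,
    stringsAsFactors = FALSE
  )
  out$peaks <- lapply(kept, function(k) {
    data.frame(mz = mz[h_peak[k$rows]], z = h_z[k$rows],
               intensity = h_int[k$rows])
  })
  out <- out[order(out$neutral_mass), ]
  rownames(out) <- NULL
  out
}

#' Deconvolve every MS1 scan of a run
#'
#' @param run A [ms_run()].
#' @inheritParams deconvolve_scan
#' @return `data.frame` of species across scans (class `"deconv_run"`), with
#'   the run's MS1 retention-time grid in `attr(, "scan_rts")`.
#' @export
deconvolve_run <- function(run, charge_range = c(5L, 25L), peak_tol = 10,
                           min_charge_support = 3L, max_charge_gap = 1L,
                           noise_floor = NULL) {
  ms1 <- .ms1_spectra(run)
  res <- lapply(ms1, deconvolve_scan, charge_range = charge_range,
                peak_tol = peak_tol, min_charge_support = min_charge_support,
                max_charge_gap = max_charge_gap, noise_floor = noise_floor)
  scan_index <- rep(seq_along(ms1), vapply(res, nrow, integer(1)))
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(neutral_mass = numeric(0), total_intensity = numeric(0),
                      n_charges = integer(0), charges = character(0),
                      scan_id = character(0), rt = numeric(0))
    out$peaks <- list()
  }
  out$scan_index <- scan_index
  attr(out, "scan_rts") <- vapply(ms1, `[[`, numeric(1), "rt")
  class(out) <- c("deconv_run", "data.frame")
  out
}

#' Group deconvoluted species into neutral-mass traces
#'
#' Species within `window` Da of each other across scans form one trace; the
#' per-scan intensity is the species total intensity (zero-filled over the
#' trace's scan span). Traces interrupted by more than `max_gap` consecutive
#' missing scans are split, and traces observed in fewer than `min_scans`
#' scans are discarded.
#'
#' @param deconv A [deconvolve_run()] result.
#' @param window Mass window in Da (the "+/- 5 Da" of a deconvoluted XIC).
#' @param min_scans Minimum scans per trace.
#' @param max_gap Largest tolerated run of missing scans inside a trace.
#' @return List of `mass_trace` objects: `center_mass`, `window`, and a
#'   `trace` data.frame of (rt, intensity).
#' @export
build_mass_traces <- function(deconv, window = 5, min_scans = 3L, max_gap = 2L) {
  scan_rts <- attr(deconv, "scan_rts")
  if (!nrow(deconv)) return(list())
  o <- order(deconv$neutral_mass)
  d <- deconv[o, ]
  grp <- cumsum(c(TRUE, diff(d$neutral_mass) > window))
  traces <- list()
  for (rows in split(seq_len(nrow(d)), grp)) {
    cl <- d[rows, ]
    scans <- sort(unique(cl$scan_index))
    seg_id <- cumsum(c(TRUE, diff(scans) > max_gap + 1L))
    for (seg in split(scans, seg_id)) {
      if (length(seg) < min_scans) next
      sel <- cl[cl$scan_index %in% seg, ]
      span <- seq(min(seg), max(seg))
      inten <- vapply(span, function(i) sum(sel$total_intensity[sel$scan_index == i]),
                      numeric(1))
      traces[[length(traces) + 1L]] <- structure(list(
        center_mass = stats::weighted.mean(sel$neutral_mass, sel$total_intensity),
        window = window,
        trace = data.frame(rt = scan_rts[span], intensity = inten)
      ), class = "mass_trace")
    }
  }
  traces[order(vapply(traces, `[[`, numeric(1), "center_mass"))]
}

#' Extracted ion chromatogram over deconvoluted masses
#'
#' Per-scan summed intensity of all deconvoluted species whose neutral mass
#' lies within `center_mass +/- window`; zero where no species matches.
#'
#' @param deconv A [deconvolve_run()] result.
#' @param center_mass Center of the mass window, Da.
#' @param window Half-width of the window, Da (0 keeps exact matches only).
#' @return `data.frame` of (rt, intensity) over the full MS1 scan grid.
#' @export
extract_xic <- function(deconv, center_mass, window = 5) {
  scan_rts <- attr(deconv, "scan_rts")
  inten <- numeric(length(scan_rts))
  if (nrow(deconv)) {
    hit <- abs(deconv$neutral_mass - center_mass) <= window
    if (any(hit)) {
      agg <- rowsum(deconv$total_intensity[hit], deconv$scan_index[hit])
      inten[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  data.frame(rt = scan_rts, intensity = inten)
}

#' Detect depletion dips in an apo-protein chromatogram
#'
#' Ligand binding converts apoprotein into complexes, so the apo XIC shows
#' negative peaks at binder retention times. The baseline is a rolling median
#' of the trace; contiguous regions dropping below `min_drop` of baseline are
#' reported at their deepest point.
#'
#' @param xic `data.frame` of (rt, intensity), e.g. from [extract_xic()].
#' @param min_drop Minimum fractional drop below baseline (0.3 = 30%).
#' @param baseline_k Rolling-median window length (odd integer, scans).
#' @return `data.frame` of (rt, depth) per depletion event, depth being the
#'   fractional intensity loss at the dip minimum.
#' @export
detect_apo_depletion <- function(xic, min_drop = 0.3, baseline_k = 21L) {
  n <- nrow(xic)
  if (n < 3L) return(data.frame(rt = numeric(0), depth = numeric(0)))
  k <- min(baseline_k, if (n %% 2L == 0L) n - 1L else n)
  if (k %% 2L == 0L) k <- k - 1L
  baseline <- stats::runmed(xic$intensity, k, endrule = "median")
  depth <- ifelse(baseline > 0, 1 - xic$intensity / baseline, 0)
  dip <- depth > min_drop
  if (!any(dip)) return(data.frame(rt = numeric(0), depth = numeric(0)))
  reg <- cumsum(c(dip[1], diff(dip) == 1L))
  out <- lapply(split(which(dip), reg[dip]), function(ix) {
    j <- ix[which.max(depth[ix])]
    data.frame(rt = xic$rt[j], depth = depth[j])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
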