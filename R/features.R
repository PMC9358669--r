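.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

.empty_feature_table <- function() {
  ft <- data.frame(id = character(0), kind = character(0),
                   mass_value = numeric(0), rt_apex = numeric(0),
                   rt_start = numeric(0), rt_end = numeric(0),
                   apex_intensity = numeric(0), area = numeric(0),
                   stringsAsFactors = FALSE)
  ft$trace <- list(); ft$ms2 <- list()
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Detect chromatographic peaks on an intensity trace
#'
#' The trace is moving-average smoothed and cut into segments at baseline
#' (zero-intensity) crossings. Within a segment, local maxima whose
#' surrounding valleys drop by at least `min_prominence` of the apex become
#' peaks, with boundaries at the separating valleys or the baseline crossing.
#' A segment with no prominent internal maximum is reported as a single peak
#' spanning the segment, so a constantly infused species (a flat, noisy
#' profile that never returns to baseline) yields one plateau feature rather
#' than a litter of noise wiggles. The area is the trapezoidal integral of
#' the raw trace between the boundaries.
#'
#' @param trace `data.frame` of (rt, intensity), rt-sorted, minutes.
#' @param min_height Minimum raw apex intensity.
#' @param min_width Minimum peak width (rt_end - rt_start), minutes.
#' @param smoothing Moving-average window, points (odd; 1 disables).
#' @param min_prominence Minimum fractional drop (relative to the apex of the
#'   smoothed trace) of the valleys flanking a local maximum before it is
#'   split out as its own peak.
#' @return `data.frame` with columns `rt_apex`, `rt_start`, `rt_end`,
#'   `apex_intensity`, `area` and a `trace` list-column holding the raw
#'   trace restricted to the peak.
#' @export
detect_peaks <- function(trace, min_height = 0, min_width = 0.05,
                         smoothing = 5L, min_prominence = 0.5) {
  empty <- data.frame(rt_apex = numeric(0), rt_start = numeric(0),
                      rt_end = numeric(0), apex_intensity = numeric(0),
                      area = numeric(0))
  empty$trace <- list()
  n <- nrow(trace)
  if (n < 3L) return(empty)
  rt <- trace$rt; raw <- trace$intensity
  if (is.unsorted(rt)) stop("trace must be rt-sorted")
  y <- raw
  if (smoothing > 1L) {
    k <- min(smoothing, if (n %% 2L == 0L) n - 1L else n)
    if (k %% 2L == 0L) k <- k - 1L
    if (k >= 3L) {
      y <- as.numeric(stats::filter(raw, rep(1 / k, k), sides = 2))
      half <- (k - 1L) %/% 2L
      y[seq_len(half)] <- y[half + 1L]
      y[(n - half + 1L):n] <- y[n - half]
    }
  }
  baseline <- 1e-9 * max(y, 1e-300)
  on <- y > baseline
  if (!any(on)) return(empty)
  seg_id <- cumsum(c(on[1], diff(on) == 1L))
  peaks <- list()
  for (seg in split(which(on), seg_id[on])) {
    # widen to the bracketing baseline points so the peak tails reach zero
    lo0 <- max(1L, min(seg) - 1L); hi0 <- min(n, max(seg) + 1L)
    if (hi0 - lo0 < 2L) next
    ys <- y[lo0:hi0]
    m <- length(ys)
    loc <- which(ys > c(-Inf, ys[-m]) & ys >= c(ys[-1], -Inf))
    loc <- loc[loc > 1L & loc < m]
    # keep maxima prominent against the deepest valley separating them
    splits <- integer(0)
    if (length(loc) > 1L) {
      keep_max <- rep(TRUE, length(loc))
      for (q in seq_len(length(loc) - 1L)) {
        a <- loc[q]; b <- loc[q + 1L]
        valley <- a + which.min(ys[a:b]) - 1L
        depth_a <- 1 - ys[valley] / ys[a]
        depth_b <- 1 - ys[valley] / ys[b]
        if (min(depth_a, depth_b) >= min_prominence) {
          splits <- c(splits, valley)
        }
      }
    }
    bounds <- c(1L, splits, m)
    for (q in seq_len(length(bounds) - 1L)) {
      lo <- lo0 + bounds[q] - 1L
      hi <- lo0 + bounds[q + 1L] - 1L
      if (hi - lo < 2L) next
      sub <- lo:hi
      apex_raw <- sub[which.max(raw[sub])]
      peaks[[length(peaks) + 1L]] <- data.frame(
        rt_apex = rt[apex_raw], rt_start = rt[lo], rt_end = rt[hi],
        apex_intensity = raw[apex_raw],
        area = .trapz(rt[sub], raw[sub]), lo = lo, hi = hi
      )
    }
  }
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks)) return(empty)
  keep <- peaks$apex_intensity >= min_height &
    (peaks$rt_end - peaks$rt_start) >= min_width
  peaks <- peaks[keep, , drop = FALSE]
  if (!nrow(peaks)) return(empty)
  peaks$trace <- lapply(seq_len(nrow(peaks)), function(i) {
    seg <- peaks$lo[i]:peaks$hi[i]
    data.frame(rt = rt[seg], intensity = raw[seg])
  })
  peaks$lo <- NULL; peaks$hi <- NULL
  rownames(peaks) <- NULL
  peaks
}

#' Protein-side feature table from deconvoluted mass traces
#'
#' Runs [detect_peaks()] on each neutral-mass trace; each detected peak
#' becomes a protein feature whose `mass_value` is the trace center mass.
#'
#' @param traces List of `mass_trace` objects ([build_mass_traces()]).
#' @param min_height,min_width,smoothing Passed to [detect_peaks()].
#' @return A `feature_table` with `kind = "protein"`.
#' @export
build_protein_features <- function(traces, min_height = 0, min_width = 0.05,
                                   smoothing = 5L) {
  rows <- list()
  for (tr in traces) {
    pk <- detect_peaks(tr$trace, min_height = min_height,
                       min_width = min_width, smoothing = smoothing)
    if (!nrow(pk)) next
    pk$mass_value <- tr$center_mass
    rows[[length(rows) + 1L]] <- pk
  }
  if (!length(rows)) return(.empty_feature_table())
  ft <- do.call(rbind, rows)
  ft$kind <- "protein"
  ft$id <- sprintf("P%03d", seq_len(nrow(ft)))
  ft$ms2 <- replicate(nrow(ft), character(0), simplify = FALSE)
  ft <- ft[, c("id", "kind", "mass_value", "rt_apex", "rt_start", "rt_end",
               "apex_intensity", "area", "trace", "ms2")]
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Metabolite feature table from an LC-MS/MS run
#'
#' Builds m/z traces by tolerance-linking MS1 centroids across scans, detects
#' chromatographic peaks on each trace, and links each feature to the MS2
#' scans whose precursor m/z falls within `mz_tol` of the feature m/z and
#' whose retention time lies inside the peak boundaries.
#'
#' @param run A [ms_run()] containing MS1 (and optionally MS2) scans.
#' @param mz_tol Precursor/trace linking tolerance in ppm.
#' @param min_height,min_width,smoothing Passed to [detect_peaks()].
#' @return A `feature_table` with `kind = "metabolite"`, `mass_value` the
#'   intensity-weighted precursor m/z and an `ms2` list-column of scan ids.
#' @export
build_metabolite_features <- function(run, mz_tol = 10, min_height = 0,
                                      min_width = 0.05, smoothing = 5L) {
  ms1 <- .ms1_spectra(run)
  if (!length(ms1)) return(.empty_feature_table())
  scan_rts <- vapply(ms1, `[[`, numeric(1), "rt")
  pk <- do.call(rbind, lapply(seq_along(ms1), function(i) {
    s <- ms1[[i]]
    if (!length(s$mz)) return(NULL)
    data.frame(scan = i, mz = s$mz, intensity = s$intensity)
  }))
  if (is.null(pk) || !nrow(pk)) return(.empty_feature_table())
  pk <- pk[order(pk$mz), ]
  grp <- cumsum(c(TRUE, diff(pk$mz) > mz_tol * 1e-6 * pk$mz[-nrow(pk)]))
  ms2 <- .ms2_spectra(run)
  ms2_prec <- vapply(ms2, `[[`, numeric(1), "precursor_mz")
  ms2_rt <- vapply(ms2, `[[`, numeric(1), "rt")
  ms2_id <- vapply(ms2, `[[`, character(1), "scan_id")

  rows <- list()
  for (ix in split(seq_len(nrow(pk)), grp)) {
    cl <- pk[ix, ]
    mz_center <- stats::weighted.mean(cl$mz, cl$intensity)
    inten <- numeric(length(scan_rts))
    agg <- rowsum(cl$intensity, cl$scan)
    inten[as.integer(rownames(agg))] <- agg[, 1]
    feats <- detect_peaks(data.frame(rt = scan_rts, intensity = inten),
                          min_height = min_height, min_width = min_width,
                          smoothing = smoothing)
    if (!nrow(feats)) next
    feats$mass_value <- mz_center
    feats$ms2 <- lapply(seq_len(nrow(feats)), function(i) {
      hit <- abs(ms2_prec - mz_center) <= mz_tol * 1e-6 * mz_center &
        ms2_rt >= feats$rt_start[i] & ms2_rt <= feats$rt_end[i]
      ms2_id[hit]
    })
    rows[[length(rows) + 1L]] <- feats
  }
  if (!length(rows)) return(.empty_feature_table())
  ft <- do.call(rbind, rows)
  ft$kind <- "metabolite"
  ft <- ft[order(ft$mass_value, ft$rt_apex), ]
  ft$id <- sprintf("M%03d", seq_len(nrow(ft)))
  ft <- ft[, c("id", "kind", "mass_value", "rt_apex", "rt_start", "rt_end",
               "apex_intensity", "area", "trace", "ms2")]
  rownames(ft) <- NULL
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Co-elution correlation of two features
#'
#' Pearson correlation of the two elution profiles after linear interpolation
#' onto the union retention-time grid restricted to the overlap of the two
#' peaks. Without overlap (or with a constant profile) the correlation is
#' undefined and `NA` is returned; callers treat that as 0.
#'
#' @param f1,f2 Single-row feature-table slices (or lists with a `trace`
#'   data.frame).
#' @return Correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
coelution_correlation <- function(f1, f2) {
  t1 <- if (is.data.frame(f1$trace)) f1$trace else f1$trace[[1]]
  t2 <- if (is.data.frame(f2$trace)) f2$trace else f2$trace[[1]]
  if (!NROW(t1) || !NROW(t2)) return(NA_real_)
  lo <- max(min(t1$rt), min(t2$rt))
  hi <- min(max(t1$rt), max(t2$rt))
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) return(NA_real_)
  grid <- sort(unique(c(t1$rt[t1$rt >= lo & t1$rt <= hi],
                        t2$rt[t2$rt >= lo & t2$rt <= hi])))
  if (length(grid) < 3L) return(NA_real_)
  y1 <- stats::approx(t1$rt, t1$intensity, xout = grid)$y
  y2 <- stats::approx(t2$rt, t2$intensity, xout = grid)$y
  if (stats::sd(y1) == 0 || stats::sd(y2) == 0) return(NA_real_)
  stats::cor(y1, y2)
}
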