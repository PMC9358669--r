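#' Construct a centroided spectrum
#'
#' In-memory model of one centroided scan. Peaks are stored sorted by m/z;
#' duplicate m/z values are merged by summing intensities so that the m/z
#' vector is strictly increasing.
#'
#' @param scan_id Opaque scan identifier (coerced to character).
#' @param rt Retention time in minutes.
#' @param ms_level 1 or 2. MS2 spectra must carry a precursor m/z.
#' @param mz,intensity Numeric vectors of equal length; intensities >= 0.
#' @param precursor_mz,precursor_charge Optional precursor (required for MS2).
#' @return A list of class `"Spectrum"`.
#' @export
ms_spectrum <- function(scan_id, rt, ms_level, mz, intensity,
                     precursor_mz = NA_real_, precursor_charge = NA_integer_) {
  stopifnot(length(mz) == length(intensity), ms_level %in% c(1L, 2L))
  if (any(intensity < 0)) stop("negative intensity in scan ", scan_id)
  if (ms_level == 2L && is.na(precursor_mz)) {
    stop("MS2 spectrum '", scan_id, "' requires a precursor m/z")
  }
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      agg <- rowsum(intensity, group = mz)
      mz <- as.numeric(rownames(agg))
      intensity <- as.numeric(agg[, 1])
    }
  }
  structure(list(
    scan_id = as.character(scan_id), rt = as.numeric(rt),
    ms_level = as.integer(ms_level),
    mz = as.numeric(mz), intensity = as.numeric(intensity),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge)
  ), class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum %s> MS%d, rt %.3f min, %d peaks",
              x$scan_id, x$ms_level, x$rt, length(x$mz)))
  if (!is.na(x$precursor_mz)) cat(sprintf(", precursor %.4f", x$precursor_mz))
  cat("\n")
  invisible(x)
}

#' Construct an LC-MS run
#'
#' A sequence of [ms_spectrum()] objects ordered by retention time plus run-level
#' metadata (polarity, mass range, free-form description).
#'
#' @param spectra List of `Spectrum` objects.
#' @param metadata Named list; `polarity` defaults to `"positive"`.
#' @return A list of class `"Run"`.
#' @export
ms_run <- function(spectra, metadata = list()) {
  stopifnot(is.list(spectra))
  if (!length(spectra)) stop("empty run: no spectra")
  ok <- vapply(spectra, inherits, logical(1), what = "Spectrum")
  if (!all(ok)) stop("all elements must be Spectrum objects")
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  spectra <- spectra[order(rts)]
  if (is.null(metadata$polarity)) metadata$polarity <- "positive"
  structure(list(spectra = spectra, metadata = metadata), class = "Run")
}

#' @export
print.Run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  rts <- run_rts(x)
  cat(sprintf("<Run> %d spectra (%d MS1, %d MS2), rt %.2f-%.2f min\n",
              length(x$spectra), sum(lv == 1L), sum(lv == 2L),
              min(rts), max(rts)))
  invisible(x)
}

#' @export
length.Run <- function(x) length(x$spectra)

#' Retention times of all scans in a run
#' @param run A `Run`.
#' @param ms_level Optional filter on MS level.
#' @return Numeric vector of retention times (minutes).
#' @export
run_rts <- function(run, ms_level = NULL) {
  sp <- run$spectra
  if (!is.null(ms_level)) {
    sp <- sp[vapply(sp, `[[`, integer(1), "ms_level") == ms_level]
  }
  vapply(sp, `[[`, numeric(1), "rt")
}

.ms1_spectra <- function(run) {
  run$spectra[vapply(run$spectra, `[[`, integer(1), "ms_level") == 1L]
}

.ms2_spectra <- function(run) {
  run$spectra[vapply(run$spectra, `[[`, integer(1), "ms_level") == 2L]
}
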