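#' Read a centroided mzML file
#'
#' Reads every scan into a [ms_spectrum()]; retention times are converted from
#' seconds to minutes on ingest. Profile-mode scans are reduced to centroids
#' by local-maximum picking and a message is emitted.
#'
#' @param path Path to an mzML file.
#' @return A [ms_run()] object.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  if (!nrow(hdr)) stop("empty run: '", path, "' contains no spectra")
  pks <- mzR::peaks(fh)
  if (is.matrix(pks)) pks <- list(pks)
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    message("profile-mode scans detected in '", basename(path),
            "'; centroiding by local-maximum picking")
  }
  spectra <- lapply(seq_len(nrow(hdr)), function(i) {
    p <- pks[[i]]
    mz <- p[, 1]; inten <- p[, 2]
    if (isFALSE(hdr$centroided[i])) {
      keep <- .local_maxima(inten)
      mz <- mz[keep]; inten <- inten[keep]
    }
    lvl <- hdr$msLevel[i]
    ms_spectrum(
      scan_id = if (!is.null(hdr$spectrumId)) hdr$spectrumId[i] else hdr$acquisitionNum[i],
      rt = hdr$retentionTime[i] / 60,
      ms_level = lvl,
      mz = mz, intensity = inten,
      precursor_mz = if (lvl >= 2L && hdr$precursorMZ[i] > 0) hdr$precursorMZ[i] else NA_real_,
      precursor_charge = if (lvl >= 2L && hdr$precursorCharge[i] > 0) hdr$precursorCharge[i] else NA_integer_
    )
  })
  ms_run(spectra, metadata = list(source = path))
}

.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(seq_len(n))
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

#' Write a run to mzML
#'
#' Inverse of [read_mzml()]: peak lists round-trip within floating-point
#' tolerance. Retention times are written in seconds as the format requires.
#'
#' @param run A [ms_run()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  sp <- run$spectra
  n <- length(sp)
  pk <- lapply(sp, function(s) cbind(mz = s$mz, intensity = s$intensity))
  num <- function(f, default = 0) vapply(sp, function(s) {
    v <- f(s); if (length(v) && !is.na(v)) as.numeric(v) else default
  }, numeric(1))
  lvl <- vapply(sp, `[[`, integer(1), "ms_level")
  npk <- vapply(pk, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lvl,
    polarity = rep(1L, n), peaksCount = npk,
    totIonCurrent = vapply(pk, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = num(function(s) s$rt * 60),
    basePeakMZ = vapply(pk, function(p) if (nrow(p)) p[which.max(p[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(p) if (nrow(p)) max(p[, 2]) else 0, numeric(1)),
    collisionEnergy = ifelse(lvl > 1L, 20, 0), ionisationEnergy = rep(0, n),
    lowMZ = vapply(pk, function(p) if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(pk, function(p) if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = rep(0L, n),
    precursorMZ = num(function(s) s$precursor_mz),
    precursorCharge = as.integer(num(function(s) s$precursor_charge)),
    precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = vapply(sp, `[[`, character(1), "scan_id"),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = num(function(s) s$precursor_mz, NA_real_),
    isolationWindowLowerOffset = ifelse(lvl > 1L, 1, NA_real_),
    isolationWindowUpperOffset = ifelse(lvl > 1L, 1, NA_real_),
    scanWindowLowerLimit = rep(NA_real_, n), scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
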