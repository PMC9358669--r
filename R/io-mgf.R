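#' Read an MGF file of MS/MS spectra
#'
#' Parses BEGIN IONS/END IONS blocks. `PEPMASS` becomes the precursor m/z,
#' `CHARGE` the precursor charge and `RTINSECONDS` the retention time
#' (converted to minutes). Every block must carry a PEPMASS.
#'
#' @param path Path to an MGF file.
#' @return List of MS2 [ms_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends)) stop("malformed MGF: unbalanced BEGIN/END IONS")
  idx <- 0L
  lapply(seq_along(starts), function(b) {
    idx <<- idx + 1L
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    kv <- grep("^[A-Z]+=", block, value = TRUE)
    fields <- sub("=.*$", "", kv)
    values <- sub("^[A-Z]+=", "", kv)
    names(values) <- fields
    peak_lines <- block[!grepl("^[A-Z]+=", block) & nzchar(trimws(block))]
    pm <- values["PEPMASS"]
    if (is.na(pm)) stop("MGF block ", idx, " is missing PEPMASS")
    pepmass <- as.numeric(strsplit(trimws(pm), "\\s+")[[1]][1])
    charge <- if (!is.na(values["CHARGE"])) {
      as.integer(sub("\\+$", "", values["CHARGE"]))
    } else NA_integer_
    rt <- if (!is.na(values["RTINSECONDS"])) as.numeric(values["RTINSECONDS"]) / 60 else NA_real_
    title <- if (!is.na(values["TITLE"])) values[["TITLE"]] else paste0("mgf_", idx)
    if (length(peak_lines)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "\\s+"), function(x) {
        as.numeric(x[1:2])
      }))
    } else {
      mat <- matrix(numeric(0), ncol = 2)
    }
    ms_spectrum(scan_id = title, rt = rt, ms_level = 2L,
             mz = mat[, 1], intensity = mat[, 2],
             precursor_mz = pepmass, precursor_charge = charge)
  })
}

#' Write MS/MS spectra to MGF
#'
#' @param spectra List of MS2 [ms_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    if (s$ms_level != 2L) stop("MGF export is for MS2 spectra; got MS", s$ms_level)
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$scan_id), con)
    writeLines(paste0("PEPMASS=", format(s$precursor_mz, digits = 12)), con)
    if (!is.na(s$precursor_charge)) {
      writeLines(paste0("CHARGE=", s$precursor_charge, "+"), con)
    }
    if (!is.na(s$rt)) {
      writeLines(paste0("RTINSECONDS=", format(s$rt * 60, digits = 12)), con)
    }
    if (length(s$mz)) {
      writeLines(paste(format(s$mz, digits = 12, trim = TRUE),
                       format(s$intensity, digits = 12, trim = TRUE)), con)
    }
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}
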