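.NATIVE_FEATURE_COLS <- c("id", "kind", "mass_value", "rt_apex", "rt_start",
                          "rt_end", "apex_intensity", "area")

#' Read a feature table from CSV
#'
#' Two dialects are supported: the package's native dialect (columns
#' `id, kind, mass_value, rt_apex, rt_start, rt_end, apex_intensity, area`)
#' and an MZmine-style export (`row ID`, `row m/z`, `row retention time` and
#' one `... Peak area` column). The dialect is auto-detected from the header
#' unless given; ambiguous or incomplete headers raise an error naming the
#' missing column rather than guessing.
#'
#' @param path CSV path.
#' @param dialect `"auto"`, `"native"` or `"mzmine"`.
#' @param kind Feature kind (`"protein"` or `"metabolite"`) to assign when the
#'   dialect does not carry one (MZmine exports).
#' @param mapping Optional named character vector overriding MZmine column
#'   names, with names `id`, `mz`, `rt`, `area`.
#' @return A feature table `data.frame` (class `"feature_table"`).
#' @export
read_feature_csv <- function(path, dialect = c("auto", "native", "mzmine"),
                             kind = "metabolite", mapping = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("feature CSV not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(df)
  is_native <- all(.NATIVE_FEATURE_COLS %in% hdr)
  is_mzmine <- all(c("row ID", "row m/z", "row retention time") %in% hdr)
  if (dialect == "auto") {
    if (is_native && !is_mzmine) dialect <- "native"
    else if (is_mzmine && !is_native) dialect <- "mzmine"
    else if (is_native && is_mzmine) stop("ambiguous feature CSV header; pass dialect= explicitly")
    else stop("unrecognized feature CSV header in '", path,
              "'; expected native or MZmine-style columns")
  }
  if (dialect == "native") {
    missing <- setdiff(.NATIVE_FEATURE_COLS, hdr)
    if (length(missing)) stop("feature CSV missing required column '", missing[[1]], "'")
    out <- df[, c(.NATIVE_FEATURE_COLS, intersect("provenance", hdr)), drop = FALSE]
  } else {
    map <- c(id = "row ID", mz = "row m/z", rt = "row retention time", area = "")
    if (!is.null(mapping)) map[names(mapping)] <- mapping
    if (!nzchar(map[["area"]])) {
      area_col <- grep("Peak area", hdr, value = TRUE, fixed = TRUE)
      if (!length(area_col)) stop("feature CSV missing required column 'Peak area'")
      map[["area"]] <- area_col[[1]]
    }
    for (col in map) {
      if (!col %in% hdr) stop("feature CSV missing required column '", col, "'")
    }
    area <- if (length(grep("Peak area", hdr, fixed = TRUE)) > 1L && is.null(mapping)) {
      rowSums(df[, grep("Peak area", hdr, fixed = TRUE), drop = FALSE], na.rm = TRUE)
    } else {
      df[[map[["area"]]]]
    }
    out <- data.frame(
      id = as.character(df[[map[["id"]]]]), kind = kind,
      mass_value = df[[map[["mz"]]]], rt_apex = df[[map[["rt"]]]],
      rt_start = NA_real_, rt_end = NA_real_, apex_intensity = NA_real_,
      area = area, stringsAsFactors = FALSE
    )
  }
  out$id <- as.character(out$id)
  if (anyDuplicated(out$id)) stop("duplicate feature ids in '", path, "'")
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write a feature table to CSV
#'
#' @param features A feature table.
#' @param path Output path.
#' @param dialect `"native"` (full schema) or `"mzmine"` (row ID / row m/z /
#'   row retention time / Peak area).
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path, dialect = c("native", "mzmine")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(features)
  if (dialect == "native") {
    keep <- c(.NATIVE_FEATURE_COLS, intersect("provenance", names(df)))
    out <- df[, keep, drop = FALSE]
  } else {
    out <- data.frame(
      `row ID` = df$id, `row m/z` = df$mass_value,
      `row retention time` = df$rt_apex, `Peak area` = df$area,
      check.names = FALSE
    )
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
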