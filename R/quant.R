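.multistart_nls <- function(formula, data, start, lower) {
  # three deterministic perturbed initializations; best residual sum wins
  factors <- c(1, 0.5, 2)
  best <- NULL
  for (f in factors) {
    st <- lapply(start, function(v) v * f)
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  best
}

#' Fit a titration (bound/unbound ratio vs ligand concentration) curve
#'
#' Fits the 1:1 hyperbolic saturation model
#' `ratio(c) = Rmax * c / (Kd + c)` by least squares. The curve passes
#' through the origin and increases monotonically, matching the
#' concentration-dependent rise of the complex-to-apoprotein ratio observed
#' in post-column infusion titrations. The fitted Kd is apparent: gas-phase
#' response factors of apo and complex are not corrected for.
#'
#' @param series `data.frame` with columns `concentration` and `ratio`
#'   (or `bound_area` and `apo_area`, from which the ratio is formed).
#' @return List of class `"binding_fit"`: `kd`, `rmax`, `rss`, `converged`.
#' @export
fit_titration <- function(series) {
  df <- as.data.frame(series)
  if (!"ratio" %in% names(df)) {
    if (!all(c("bound_area", "apo_area") %in% names(df))) {
      stop("series needs a 'ratio' column or 'bound_area'/'apo_area' columns")
    }
    df$ratio <- df$bound_area / df$apo_area
  }
  df <- df[order(df$concentration), ]
  if (length(unique(df$concentration)) < 3L) stop("need >= 3 distinct concentrations")
  if (all(df$ratio <= 0)) stop("no binding signal: all ratios are zero")
  rmax0 <- max(df$ratio)
  kd0 <- df$concentration[which.min(abs(df$ratio - rmax0 / 2))]
  if (kd0 <= 0) kd0 <- stats::median(df$concentration[df$concentration > 0])
  best <- .multistart_nls(ratio ~ rmax * concentration / (kd + concentration),
                          df, start = list(rmax = rmax0, kd = kd0),
                          lower = c(rmax = 1e-12, kd = 1e-12))
  if (is.null(best)) {
    return(structure(list(kd = kd0, rmax = rmax0, rss = NA_real_,
                          converged = FALSE, fit = NULL),
                     class = "binding_fit"))
  }
  cf <- stats::coef(best$fit)
  structure(list(kd = unname(cf["kd"]), rmax = unname(cf["rmax"]),
                 rss = best$rss, converged = TRUE, fit = best$fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> apparent Kd = %.4g, Rmax = %.4g (rss %.3g, %s)\n",
              x$kd, x$rmax, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Summarize a dilution series and bracket the limit of detection
#'
#' A concentration is scored as detected when its complex peak area exceeds
#' the blank mean plus three blank standard deviations. The LOD is reported
#' as a bracket: the largest concentration without signal and the smallest
#' with signal. A linear calibration (area vs concentration) is fitted over
#' the detected range.
#'
#' @param series `data.frame` with columns `concentration` and `area`;
#'   rows with concentration 0 are treated as blanks.
#' @return List of class `"dilution_summary"`: `lod_lower`, `lod_upper`,
#'   `lod_label`, `slope`, `intercept`, `r_squared`, `detected` table.
#' @export
summarize_dilution <- function(series) {
  df <- as.data.frame(series)
  stopifnot(all(c("concentration", "area") %in% names(df)))
  blanks <- df$area[df$concentration == 0]
  blank_mean <- if (length(blanks)) mean(blanks) else 0
  blank_sd <- if (length(blanks) > 1L) stats::sd(blanks) else 0
  threshold <- blank_mean + 3 * blank_sd
  pos <- df[df$concentration > 0, ]
  pos <- pos[order(pos$concentration), ]
  detected <- pos$area > threshold
  lod_lower <- if (any(!detected)) max(pos$concentration[!detected]) else NA_real_
  lod_upper <- if (any(detected)) min(pos$concentration[detected]) else NA_real_
  lod_label <- if (all(detected)) {
    paste0("< ", min(pos$concentration), " (lowest tested)")
  } else if (!any(detected)) {
    paste0("> ", max(pos$concentration), " (highest tested)")
  } else {
    paste0("between ", lod_lower, " and ", lod_upper)
  }
  slope <- intercept <- r_squared <- NA_real_
  if (sum(detected) >= 2L) {
    fit <- stats::lm(area ~ concentration, data = pos[detected, ])
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r_squared <- summary(fit)$r.squared
  }
  structure(list(lod_lower = lod_lower, lod_upper = lod_upper,
                 lod_label = lod_label, slope = slope, intercept = intercept,
                 r_squared = r_squared,
                 detected = data.frame(concentration = pos$concentration,
                                       area = pos$area, detected = detected)),
            class = "dilution_summary")
}

#' Fit a four-parameter logistic (4PL) dose-response curve
#'
#' `y(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)`, the standard
#' sigmoid used for enzyme-inhibition IC50 estimation. The reported IC50 is
#' the curve midpoint (relative IC50). Standard errors come from the local
#' curvature of the least-squares fit.
#'
#' @param d `data.frame` with columns `concentration` and `response`
#'   (optionally `replicate`). At least 4 distinct non-zero concentrations.
#' @param constrain_bottom Fix bottom = 0 instead of fitting it.
#' @return List of class `"ic50_fit"`: `ic50`, `hill`, `top`, `bottom`,
#'   `se` (named vector), `rss`, `converged`, `no_inhibition`.
#' @export
fit_ic50 <- function(d, constrain_bottom = FALSE) {
  df <- as.data.frame(d)
  stopifnot(all(c("concentration", "response") %in% names(df)))
  df <- df[df$concentration > 0, ]
  if (length(unique(df$concentration)) < 4L) {
    stop("need >= 4 distinct non-zero concentrations for a 4PL fit")
  }
  mean_by_c <- tapply(df$response, df$concentration, mean)
  concs <- as.numeric(names(mean_by_c))
  o <- order(concs)
  lowc_resp <- mean_by_c[o][1]; highc_resp <- mean_by_c[o][length(o)]
  span <- max(df$response) - min(df$response)
  no_inhibition <- (lowc_resp - highc_resp) < 0.1 * max(abs(mean_by_c), 1e-12) ||
    span == 0
  top0 <- max(df$response); bottom0 <- min(df$response)
  mid <- (top0 + bottom0) / 2
  ic500 <- concs[which.min(abs(mean_by_c - mid))]
  flagged <- function(converged) {
    structure(list(ic50 = ic500, hill = 1, top = top0, bottom = bottom0,
                   se = c(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_),
                   rss = NA_real_, converged = converged,
                   no_inhibition = no_inhibition, fit = NULL),
              class = "ic50_fit")
  }
  if (no_inhibition) return(flagged(FALSE))
  if (constrain_bottom) {
    best <- .multistart_nls(
      response ~ top / (1 + (concentration / ic50)^hill), df,
      start = list(top = top0, ic50 = ic500, hill = 1),
      lower = c(top = 1e-12, ic50 = 1e-12, hill = 0.1)
    )
  } else {
    best <- .multistart_nls(
      response ~ bottom + (top - bottom) / (1 + (concentration / ic50)^hill), df,
      start = list(top = top0, bottom = max(bottom0, 1e-9), ic50 = ic500, hill = 1),
      lower = c(top = 1e-12, bottom = 0, ic50 = 1e-12, hill = 0.1)
    )
  }
  if (is.null(best)) return(flagged(FALSE))
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  bottom <- if (constrain_bottom) 0 else unname(cf["bottom"])
  structure(list(ic50 = unname(cf["ic50"]), hill = unname(cf["hill"]),
                 top = unname(cf["top"]), bottom = bottom,
                 se = se, rss = best$rss, converged = TRUE,
                 no_inhibition = FALSE, fit = best$fit),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$no_inhibition) {
    cat("<ic50_fit> no inhibition detected\n")
  } else {
    cat(sprintf("<ic50_fit> IC50 = %.4g (hill %.3g, top %.4g, bottom %.4g)%s\n",
                x$ic50, x$hill, x$top, x$bottom,
                if (x$converged) "" else " [NOT converged]"))
  }
  invisible(x)
}

#' Fold change between two IC50 values
#'
#' A "fold increase in potency" is conventionally quoted as the larger IC50
#' over the smaller; this function simply returns `ic50_a / ic50_b` and the
#' caller chooses the order.
#'
#' @param ic50_a,ic50_b Positive IC50 values.
#' @return The ratio `ic50_a / ic50_b`.
#' @export
fold_change <- function(ic50_a, ic50_b) {
  if (any(c(ic50_a, ic50_b) <= 0)) stop("IC50 values must be > 0")
  ic50_a / ic50_b
}
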