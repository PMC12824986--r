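#' Fit a relaxivity calibration line
#'
#' Ordinary least squares of measured R2(1H2O) against concentration:
#' `R2 = R2_0 + r2 * C`.  The slope `r2` is the relaxivity in
#' (mg/mL)^-1 s^-1; `rmsd` is the root-mean-square of measured R2 minus
#' the line, which serves as the per-lab error estimate for outlier bands.
#' When per-point measurement errors are supplied, a measurement-error
#' propagated slope standard error (`slope_se_prop`) is also computed; see
#' [zero_slope_test()].
#'
#' @param concentration Concentrations (mg/mL or particle count); at least
#'   2 distinct values.
#' @param r2 Measured relaxation rates, 1/s.
#' @param se Optional per-point standard errors of `r2`.
#' @param lab_id,sample_class Optional labels carried into the result.
#' @return An object of class `relaxivity_fit` with elements `slope`,
#'   `intercept`, `slope_se` (residual-based OLS; `NA` for 2 points),
#'   `slope_se_prop` (or `NA`), `rmsd`, `n_points`, `lab_id`,
#'   `sample_class`.
#' @export
fit_relaxivity <- function(concentration, r2, se = NULL,
                           lab_id = NA_character_,
                           sample_class = NA_character_) {
  x <- as.numeric(concentration)
  y <- as.numeric(r2)
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("fit_relaxivity: need at least 2 points")
  if (length(unique(x)) < 2L) {
    stop("fit_relaxivity: all concentrations equal, slope is unidentifiable")
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  resid <- stats::residuals(fit)
  rmsd <- sqrt(mean(resid^2))
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope_se <- if (n > 2L) sqrt(sum(resid^2) / (n - 2L) / sxx) else NA_real_
  slope_se_prop <- NA_real_
  if (!is.null(se)) {
    stopifnot(length(se) == length(x))
    slope_se_prop <- sqrt(sum(((x - mean(x)) / sxx)^2 * se^2))
  }
  structure(
    list(lab_id = as.character(lab_id),
         sample_class = as.character(sample_class),
         slope = co[["x"]], intercept = co[["(Intercept)"]],
         slope_se = slope_se, slope_se_prop = slope_se_prop,
         rmsd = rmsd, n_points = n),
    class = "relaxivity_fit"
  )
}

#' @export
print.relaxivity_fit <- function(x, ...) {
  cat(sprintf(
    "<relaxivity_fit> %s/%s: r2 = %.4g, R2_0 = %.4g, rmsd = %.3g (n = %d)\n",
    x$lab_id, x$sample_class, x$slope, x$intercept, x$rmsd, x$n_points))
  invisible(x)
}

#' Span of a set of relaxivities
#'
#' The interlaboratory span, `max - min`, of per-lab relaxivity slopes.
#'
#' @param slopes Non-empty numeric vector of slopes.
#' @return `max(slopes) - min(slopes)`.
#' @export
slope_span <- function(slopes) {
  if (length(slopes) == 0L) stop("slope_span: empty slope set")
  max(slopes) - min(slopes)
}

#' Coefficient of variation of a set of relaxivities
#'
#' `CV = (sigma / mu) * 100 %` across laboratories.  The standard
#' deviation uses the sample (n - 1) convention by default.
#'
#' @param slopes Numeric vector, length >= 2, with nonzero mean.
#' @param population If `TRUE`, use the population (n) standard deviation.
#' @return CV in percent.
#' @seealso [cv_from_stats()] to compute the CV directly from a reported
#'   mean and standard deviation.
#' @export
relaxivity_cv <- function(slopes, population = FALSE) {
  if (length(slopes) < 2L) stop("relaxivity_cv: need at least 2 slopes")
  mu <- mean(slopes)
  if (mu == 0) stop("relaxivity_cv: mean slope is zero, CV undefined")
  sigma <- stats::sd(slopes)
  if (population) sigma <- sigma * sqrt((length(slopes) - 1) / length(slopes))
  (sigma / mu) * 100
}

#' CV from a mean and standard deviation
#'
#' @param mu Mean.
#' @param sigma Standard deviation.
#' @return `(sigma / mu) * 100` percent.
#' @export
cv_from_stats <- function(mu, sigma) {
  if (mu == 0) stop("cv_from_stats: mean is zero, CV undefined")
  (sigma / mu) * 100
}

#' Mean and standard deviation of a set of relaxivities
#'
#' Companion accessor to [relaxivity_cv()] so reported (mu, sigma) pairs
#' can be checked directly.
#'
#' @param slopes Numeric vector.
#' @param population Use population standard deviation if `TRUE`.
#' @return Named vector `c(mu, sigma)`.
#' @export
slope_stats <- function(slopes, population = FALSE) {
  sigma <- stats::sd(slopes)
  if (population) sigma <- sigma * sqrt((length(slopes) - 1) / length(slopes))
  c(mu = mean(slopes), sigma = sigma)
}

#' Percent change in R2 upon freeze/thaw
#'
#' `[1 - R2_frozen / R2_unfrozen] * 100 %`.  Freezing agglomerates
#' aluminum-adjuvant particles and lowers R2, so a positive change is a
#' decrease.
#'
#' @param r2_frozen R2 of the freeze/thaw-stressed sample, 1/s.
#' @param r2_unfrozen R2 of the unstressed mate, 1/s (> 0).
#' @return Percent change (positive = decrease).
#' @export
freeze_thaw_change <- function(r2_frozen, r2_unfrozen) {
  if (any(r2_unfrozen <= 0)) {
    stop("freeze_thaw_change: unfrozen R2 must be > 0")
  }
  (1 - r2_frozen / r2_unfrozen) * 100
}

#' Assess a frozen/unfrozen sample pair for a freeze/thaw outlier
#'
#' Computes the percent R2 change of the stressed vial relative to its
#' unstressed mate and flags it against the larger of the fixed detection
#' threshold (default 10 %) and the lab's own error band.  The band
#' half-width propagates the calibration-line RMSD onto the ratio scale:
#' `100 * rmsd / R2_unfrozen`.
#'
#' @param fit_frozen,fit_unfrozen `fit_result` objects (or bare numeric
#'   rates) for the stressed and unstressed vials.
#' @param calib The lab's [fit_relaxivity()] calibration for the same
#'   sample class (unstressed series).
#' @param threshold Fixed detection threshold in percent (default 10).
#' @param lab_id,sample_class Optional labels; validated against `calib`
#'   when both are present.
#' @return An object of class `outlier_assessment`: `ratio`,
#'   `percent_change`, `band_halfwidth`, `flagged`, `direction`
#'   (`"decrease"`, `"increase"` or `"none"`).
#' @export
assess_outlier <- function(fit_frozen, fit_unfrozen, calib, threshold = 10,
                           lab_id = NA_character_,
                           sample_class = NA_character_) {
  stopifnot(inherits(calib, "relaxivity_fit"))
  a_f <- if (inherits(fit_frozen, "fit_result")) fit_frozen$alpha
         else as.numeric(fit_frozen)
  a_u <- if (inherits(fit_unfrozen, "fit_result")) fit_unfrozen$alpha
         else as.numeric(fit_unfrozen)
  if (!is.na(lab_id) && !is.na(calib$lab_id) && lab_id != calib$lab_id) {
    stop("assess_outlier: lab_id mismatch with calibration (",
         lab_id, " vs ", calib$lab_id, ")")
  }
  if (!is.na(sample_class) && !is.na(calib$sample_class) &&
      sample_class != calib$sample_class) {
    stop("assess_outlier: sample_class mismatch with calibration (",
         sample_class, " vs ", calib$sample_class, ")")
  }
  if (a_u <= 0) stop("assess_outlier: unfrozen R2 must be > 0")
  ratio <- a_f / a_u
  pc <- (1 - ratio) * 100
  band <- 100 * calib$rmsd / a_u
  flagged <- abs(pc) > max(threshold, band)
  direction <- if (!flagged) "none" else if (pc > 0) "decrease" else "increase"
  structure(
    list(lab_id = if (!is.na(lab_id)) lab_id else calib$lab_id,
         sample_class = if (!is.na(sample_class)) sample_class
                        else calib$sample_class,
         ratio = ratio, percent_change = pc, band_halfwidth = band,
         flagged = flagged, direction = direction),
    class = "outlier_assessment"
  )
}

#' Zero-slope negative-control test
#'
#' Tests whether a relaxivity calibration is consistent with a true slope
#' of zero, the expected outcome for ETFE particle suspensions whose
#' magnetic susceptibility matches water.  The verdict is
#' `consistent_with_zero` when `|slope| <= 2 * se`.  When per-point
#' measurement errors were supplied to [fit_relaxivity()], the propagated
#' slope error is used (it is a direct estimate, not a 3-degree-of-freedom
#' residual estimate); otherwise the residual-based OLS error.
#'
#' @param calib A [fit_relaxivity()] result.
#' @param prefer_measurement_se Use `slope_se_prop` when available
#'   (default `TRUE`).
#' @return `"consistent_with_zero"`, `"nonzero"`, or `"indeterminate"`
#'   when no slope standard error is available.
#' @export
zero_slope_test <- function(calib, prefer_measurement_se = TRUE) {
  stopifnot(inherits(calib, "relaxivity_fit"))
  se <- if (prefer_measurement_se && is.finite(calib$slope_se_prop)) {
    calib$slope_se_prop
  } else {
    calib$slope_se
  }
  if (!is.finite(se)) return("indeterminate")
  if (abs(calib$slope) <= 2 * se) "consistent_with_zero" else "nonzero"
}

#' Build the full interlaboratory study report
#'
#' Aggregates per-trace fit results into the complete study analysis:
#' per-lab, per-class relaxivity calibrations (unstressed series only),
#' interlaboratory span and CV per class, freeze/thaw outlier assessments
#' of each stressed vial against its unstressed mate, and zero-slope
#' negative-control outcomes.  Duplicate (lab, sample) submissions are
#' resolved by keeping the last one and recording the anomaly.
#'
#' @param results Data frame with one row per measurement: columns
#'   `lab_id`, `sample_code`, `alpha` and optionally `alpha_se`.
#' @param manifest A `study_manifest` mapping codes to contents.
#' @param threshold Freeze/thaw detection threshold in percent (default 10).
#' @param population_sd Use population SD in the CV (default `FALSE`,
#'   i.e. sample SD).
#' @param provenance Optional list (e.g. seed, config) stored verbatim.
#' @return An object of class `study_report` with elements
#'   `relaxivity_table` (data frame), `dispersion` (per-class span/CV),
#'   `outliers` (data frame), `control_tests` (data frame), `anomalies`
#'   (character), `provenance`.
#' @export
build_report <- function(results, manifest, threshold = 10,
                         population_sd = FALSE, provenance = list()) {
  stopifnot(inherits(manifest, "study_manifest"))
  anomalies <- character(0)
  empty_report <- function() {
    structure(list(relaxivity_table = NULL, dispersion = NULL,
                   outliers = NULL, control_tests = NULL,
                   anomalies = anomalies, provenance = provenance),
              class = "study_report")
  }
  if (is.null(results) || nrow(results) == 0L) return(empty_report())
  stopifnot(all(c("lab_id", "sample_code", "alpha") %in% names(results)))
  if (!"alpha_se" %in% names(results)) results$alpha_se <- NA_real_

  # duplicate submissions: keep the later row, log the anomaly
  key <- paste(results$lab_id, results$sample_code, sep = "/")
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    anomalies <- c(anomalies, paste0(
      "duplicate submission for ", unique(key[dup]),
      "; later measurement used"))
    results <- results[!dup, , drop = FALSE]
  }
  unknown <- setdiff(results$sample_code, manifest$sample_code)
  if (length(unknown)) {
    stop("build_report: sample_code(s) not in manifest: ",
         paste(unknown, collapse = ", "))
  }
  m <- match(results$sample_code, manifest$sample_code)
  results$sample_class <- manifest$sample_class[m]
  results$concentration <- manifest$concentration[m]
  results$stressed <- manifest$stressed[m]

  labs <- unique(results$lab_id)
  fits <- list()
  rows <- list()
  ctrl <- list()
  for (lab in labs) {
    for (cls in unique(results$sample_class)) {
      sub <- results[results$lab_id == lab & results$sample_class == cls &
                       !results$stressed, , drop = FALSE]
      if (nrow(sub) < 2L || length(unique(sub$concentration)) < 2L) next
      se <- if (all(is.finite(sub$alpha_se))) sub$alpha_se else NULL
      rf <- fit_relaxivity(sub$concentration, sub$alpha, se = se,
                           lab_id = lab, sample_class = cls)
      fits[[paste(lab, cls, sep = "/")]] <- rf
      rows[[length(rows) + 1L]] <- data.frame(
        lab_id = lab, sample_class = cls, slope = rf$slope,
        intercept = rf$intercept, slope_se = rf$slope_se,
        slope_se_prop = rf$slope_se_prop, rmsd = rf$rmsd,
        n_points = rf$n_points)
      ctrl[[length(ctrl) + 1L]] <- data.frame(
        lab_id = lab, sample_class = cls, outcome = zero_slope_test(rf))
    }
  }
  relax_tab <- if (length(rows)) do.call(rbind, rows) else NULL
  ctrl_tab <- if (length(ctrl)) do.call(rbind, ctrl) else NULL

  dispersion <- NULL
  if (!is.null(relax_tab)) {
    disp_rows <- lapply(split(relax_tab, relax_tab$sample_class), function(d) {
      data.frame(
        sample_class = d$sample_class[1],
        n_labs = nrow(d),
        mean_slope = mean(d$slope),
        sd_slope = slope_stats(d$slope, population = population_sd)[["sigma"]],
        span = slope_span(d$slope),
        cv = if (nrow(d) >= 2L && mean(d$slope) != 0)
               relaxivity_cv(d$slope, population = population_sd)
             else NA_real_)
    })
    dispersion <- do.call(rbind, disp_rows)
    rownames(dispersion) <- NULL
  }

  # freeze/thaw outlier assessment per stressed vial per lab
  out_rows <- list()
  stressed_codes <- manifest$sample_code[manifest$stressed]
  for (lab in labs) {
    for (sc in stressed_codes) {
      srow <- results[results$lab_id == lab & results$sample_code == sc, ,
                      drop = FALSE]
      if (nrow(srow) == 0L) next
      cls <- srow$sample_class[1]
      conc <- srow$concentration[1]
      mate <- results[results$lab_id == lab &
                        results$sample_class == cls &
                        !results$stressed &
                        results$concentration == conc, , drop = FALSE]
      calib <- fits[[paste(lab, cls, sep = "/")]]
      if (nrow(mate) == 0L || is.null(calib)) {
        anomalies <- c(anomalies, paste0(
          "stressed vial ", sc, " at lab ", lab,
          " has no unstressed mate/calibration; unassessable"))
        next
      }
      oa <- assess_outlier(srow$alpha[1], mate$alpha[1], calib,
                           threshold = threshold,
                           lab_id = lab, sample_class = cls)
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        lab_id = lab, sample_class = cls, sample_code = sc,
        ratio = oa$ratio, percent_change = oa$percent_change,
        band_halfwidth = oa$band_halfwidth, flagged = oa$flagged,
        direction = oa$direction)
    }
  }
  outliers <- if (length(out_rows)) do.call(rbind, out_rows) else NULL

  structure(
    list(relaxivity_table = relax_tab, dispersion = dispersion,
         outliers = outliers, control_tests = ctrl_tab,
         anomalies = anomalies, provenance = provenance),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$dispersion)) {
    cat("  interlab dispersion (slope units):\n")
    d <- x$dispersion
    for (i in seq_len(nrow(d))) {
      cat(sprintf("    %-7s n=%d  mean=%.4g  span=%.4g  CV=%.3g%%\n",
                  d$sample_class[i], d$n_labs[i], d$mean_slope[i],
                  d$span[i], d$cv[i]))
    }
  }
  if (!is.null(x$outliers)) {
    nf <- sum(x$outliers$flagged)
    cat(sprintf("  freeze/thaw assessments: %d, flagged: %d\n",
                nrow(x$outliers), nf))
  }
  if (length(x$anomalies)) {
    cat("  anomalies:\n")
    for (a in x$anomalies) cat("    - ", a, "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
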