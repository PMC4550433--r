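#' Log-transform triglyceride values
#'
#' Base-10 logarithm, the transform under which the additive genetic
#' model is specified and under which the cohort-style log(TG) range
#' (roughly 1.5-2.9 for mg/dL values) is expressed.
#'
#' @param tg_values numeric vector of triglycerides in mg/dL, all > 0.
#' @param ids optional identifiers used in error messages.
#' @return numeric vector of log10 values.
#' @export
log_transform <- function(tg_values, ids = NULL) {
  bad <- which(!is.na(tg_values) & tg_values <= 0)
  if (length(bad)) {
    who <- if (!is.null(ids)) ids[bad[1]] else paste("index", bad[1])
    stop_data("non-positive TG value for individual %s", who)
  }
  log10(tg_values)
}

#' Flag outliers by distance from the mean
#'
#' Single pass: the mean and SD are computed from all input values and
#' individuals beyond `k` SDs are excluded; the rule is not iterated.
#'
#' @param values numeric vector (typically log TG).
#' @param k SD multiplier; default 3.
#' @return logical inclusion mask (`TRUE` = keep).
#' @export
remove_outliers <- function(values, k = 3) {
  if (length(values) < 2) stop_data("need at least 2 values")
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(TRUE, length(values)))
  abs(values - m) <= k * s
}

#' BMI-adjust log(TG) by standardized OLS residuals
#'
#' Ordinary least squares of log(TG) on BMI (intercept + slope); the
#' residuals are divided by their sample SD so the returned trait has
#' mean 0 and SD 1. Standardization absorbs affine rescalings of BMI.
#'
#' @param log_tg,bmi numeric vectors of equal length (>= 3), no NAs.
#' @return standardized residuals (mean 0, SD 1).
#' @export
bmi_adjust <- function(log_tg, bmi) {
  if (length(log_tg) != length(bmi)) stop_data("length mismatch")
  if (length(log_tg) < 3) stop_data("need at least 3 individuals")
  if (stats::sd(bmi) == 0) stop_data("BMI is constant; cannot adjust")
  fit <- stats::lm.fit(cbind(1, bmi), log_tg)
  r <- fit$residuals
  s <- stats::sd(r)
  # a perfect linear fit leaves only rounding noise: zero-SD residuals
  if (s <= 1e-10 * max(stats::sd(log_tg), .Machine$double.eps))
    stop_data("residuals are all zero; cannot standardize")
  r / s
}

#' Ternary case/control/unknown status from TG thresholds
#'
#' TG > 200 mg/dL is a case, TG < 150 mg/dL a control, and the
#' borderline band 150 <= TG <= 200 (boundaries included) is unknown and
#' excluded from the binary analyses.
#'
#' @param tg_values numeric vector, mg/dL.
#' @return character vector in \{"case", "control", "unknown"\}.
#' @export
binarize_tg <- function(tg_values) {
  out <- rep("unknown", length(tg_values))
  out[!is.na(tg_values) & tg_values > 200] <- "case"
  out[!is.na(tg_values) & tg_values < 150] <- "control"
  out[is.na(tg_values)] <- NA_character_
  out
}

#' Prepare analysis phenotypes from raw TG and BMI
#'
#' Applies, in order: log10 transform, single-pass outlier exclusion on
#' log(TG) (> `sd_multiplier` SDs), BMI adjustment by standardized OLS
#' residuals on the surviving individuals, and threshold dichotomization.
#' Excluded individuals keep their raw values but carry
#' `included = FALSE` and an `NA` adjusted trait.
#'
#' @param x data.frame with columns `iid`, `tg`, `bmi` (and optionally
#'   `sex`).
#' @param sd_multiplier outlier rule, default 3.
#' @param adjust compute the BMI-adjusted trait (requires >= 3 included
#'   individuals and non-constant BMI).
#' @return the input with columns `log_tg`, `log_tg_adj`, `status`,
#'   `included` added.
#' @export
prepare_phenotypes <- function(x, sd_multiplier = 3, adjust = TRUE) {
  need <- c("iid", "tg", "bmi")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_data("phenotype table lacks column(s): %s",
              paste(miss, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$iid <- as.character(x$iid)
  x$log_tg <- log_transform(x$tg, x$iid)
  x$included <- if (nrow(x) >= 2) remove_outliers(x$log_tg, sd_multiplier)
                else rep(TRUE, nrow(x))
  x$log_tg_adj <- NA_real_
  if (adjust && nrow(x)) {
    inc <- which(x$included & !is.na(x$bmi))
    x$log_tg_adj[inc] <- bmi_adjust(x$log_tg[inc], x$bmi[inc])
  }
  x$status <- binarize_tg(x$tg)
  x
}
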