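#' Standardized mean difference from arm-level summaries
#'
#' Computes Cohen's d, or Hedges' g when `bias_corrected = TRUE` (the
#' default), together with its large-sample sampling variance. The
#' pooled standard deviation uses the usual (n1 - 1, n2 - 1) weighting;
#' the small-sample correction is J = 1 - 3 / (4 * (n_t + n_c - 2) - 1).
#'
#' @param mean_treated,mean_control Group means (outcome units).
#' @param sd_treated,sd_control Group standard deviations; must be > 0.
#' @param n_treated,n_control Group sizes; must be >= 2.
#' @param bias_corrected Apply the Hedges small-sample correction
#'   (default `TRUE`).
#'
#' @return A one-row data frame of class `"effect_size"` with columns
#'   `smd`, `variance` and `direction_aligned` (always `FALSE` here:
#'   alignment to the expected direction of benefit is a separate,
#'   explicit step; see [align_direction()]).
#'
#' @details The variance is (n_t + n_c) / (n_t * n_c) +
#'   smd^2 / (2 * (n_t + n_c)), evaluated at the returned (possibly
#'   bias-corrected) SMD.
#'
#' @examples
#' compute_smd(10, 2, 10, 8, 2, 10)
#' @export
compute_smd <- function(mean_treated, sd_treated, n_treated,
                        mean_control, sd_control, n_control,
                        bias_corrected = TRUE) {
  stopifnot(is.numeric(mean_treated), is.numeric(mean_control))
  if (any(c(sd_treated, sd_control) <= 0)) {
    stop("standard deviations must be strictly positive")
  }
  if (any(c(n_treated, n_control) < 2)) {
    stop("group sizes must be >= 2")
  }
  n_t <- n_treated
  n_c <- n_control
  df <- n_t + n_c - 2
  sd_pooled <- sqrt(((n_t - 1) * sd_treated^2 + (n_c - 1) * sd_control^2) / df)
  if (any(sd_pooled == 0)) {
    stop("pooled standard deviation is zero: SMD undefined")
  }
  d <- (mean_treated - mean_control) / sd_pooled
  if (bias_corrected) {
    j <- 1 - 3 / (4 * df - 1)
    d <- j * d
  }
  v <- (n_t + n_c) / (n_t * n_c) + d^2 / (2 * (n_t + n_c))
  out <- data.frame(smd = d, variance = v, direction_aligned = FALSE)
  class(out) <- c("effect_size", "data.frame")
  out
}

#' Sampling variance of an SMD from its confidence interval
#'
#' Back-calculates the variance of a reported SMD from a Wald-type
#' normal confidence interval: variance = ((upper - lower) /
#' (2 * z))^2 with z the (1 + level)/2 normal quantile. t-based
#' intervals are not detected; the normal assumption is the caller's.
#'
#' @param smd Reported SMD.
#' @param ci_low,ci_high Interval bounds, `ci_low < ci_high`, with
#'   `smd` inside.
#' @param level Nominal coverage of the interval, in (0, 1).
#'
#' @return A one-row `"effect_size"` data frame (see [compute_smd()]).
#' @export
smd_from_ci <- function(smd, ci_low, ci_high, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (any(ci_low > ci_high)) stop("inverted confidence interval")
  if (any(ci_low == ci_high)) stop("zero-width confidence interval: variance undefined")
  if (any(smd < ci_low | smd > ci_high)) {
    stop("smd outside its own confidence interval")
  }
  z <- stats::qnorm((1 + level) / 2)
  v <- ((ci_high - ci_low) / (2 * z))^2
  out <- data.frame(smd = smd, variance = v, direction_aligned = FALSE)
  class(out) <- c("effect_size", "data.frame")
  out
}

#' Align SMDs with the expected direction of benefit
#'
#' Before meta-regression all SMDs are transformed to be positive when
#' the treatment effect is beneficial (or in the expected direction for
#' pathophysiology models), so that effect sizes are comparable across
#' meta-analyses: `benefit_negative` flips every sign,
#' `benefit_positive` leaves them unchanged.
#'
#' @param smd Numeric vector of SMDs.
#' @param expected_direction One of `"benefit_positive"`,
#'   `"benefit_negative"`, `"unclear"`. An `"unclear"` direction cannot
#'   be aligned here and raises an error; at the pipeline level such
#'   meta-analyses are excluded or aligned by the sign of their pooled
#'   estimate, depending on [run_config()]`$unclear_direction_policy`.
#'
#' @return Numeric vector of aligned SMDs (|smd| and any associated
#'   variance are unchanged).
#' @export
align_direction <- function(smd, expected_direction) {
  expected_direction <- match.arg(expected_direction,
                                  c("benefit_positive", "benefit_negative", "unclear"))
  switch(expected_direction,
         benefit_positive = smd,
         benefit_negative = -smd,
         unclear = stop("expected direction is unclear: cannot align; see run_config()$unclear_direction_policy"))
}

#' Split a shared control group across experimental arms
#'
#' When several experimental arms of one study are compared against a
#' single control group, counting that control repeatedly overstates
#' precision. The standard correction divides the control group: each
#' arm is assigned `floor(n_control / k)` control animals (means and
#' SDs unchanged; remainder animals are dropped).
#'
#' @param n_control Original control group size.
#' @param k Number of experimental arms sharing the control, >= 1.
#'
#' @return The per-arm control group size.
#' @export
split_shared_control <- function(n_control, k) {
  stopifnot(k >= 1, k == floor(k), n_control >= 2)
  n_split <- floor(n_control / k)
  if (any(n_split < 2)) {
    stop("splitting leaves fewer than 2 control animals per arm")
  }
  n_split
}
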