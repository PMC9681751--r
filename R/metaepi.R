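#' Risk-of-bias characteristics
#'
#' The ten study-level risk-of-bias items, adapted from the SYRCLE tool
#' for animal studies, analysed by the meta-epidemiological pipeline.
#' Study-level CSVs carry one rating column per item, named
#' `rob_<characteristic>`.
#'
#' @format Character vector of length 10.
#' @export
rob_characteristics <- c(
  "randomization", "baseline_similarity", "allocation_concealment",
  "random_housing", "blinding_caregivers", "blinding_model",
  "random_outcome_assessment", "blinding_assessors", "attrition",
  "selective_reporting"
)

.rating_levels <- c("low", "high", "unclear", "not_assessed")

#' Dichotomize a risk-of-bias rating
#'
#' High and unclear ratings form the exposed group (following the
#' convention that poor or unreported methodology is the "exposure"
#' whose association with effect size is estimated); low ratings are
#' unexposed; unassessed arms are excluded from the contrast.
#'
#' @param rating Character vector with values `low`, `high`, `unclear`,
#'   `not_assessed` (or `NA`, treated as `not_assessed`).
#'
#' @return Character vector: `"exposed"`, `"unexposed"` or `"excluded"`.
#' @export
dichotomize <- function(rating) {
  rating[is.na(rating)] <- "not_assessed"
  if (!all(rating %in% .rating_levels)) {
    stop("unknown rating value(s): ",
         paste(setdiff(unique(rating), .rating_levels), collapse = ", "))
  }
  out <- rep("excluded", length(rating))
  out[rating %in% c("high", "unclear")] <- "exposed"
  out[rating == "low"] <- "unexposed"
  out
}

#' Pipeline configuration
#'
#' @param min_mas Minimum number of eligible meta-analyses needed to run
#'   the analysis for a characteristic (default 10; below it the
#'   characteristic is reported as skipped).
#' @param min_studies Minimum number of studies for a meta-analysis to
#'   be eligible (default 3).
#' @param tau2_method Heterogeneity estimator, `"REML"` or `"DL"`.
#' @param ci_method Step-2 confidence interval, `"wald"` or
#'   `"knapp_hartung"`.
#' @param robust Robust-variance type for the sensitivity analysis:
#'   `"none"`, `"CR2"`, `"CR1"`, `"CR0"`.
#' @param unclear_direction_policy What to do with meta-analyses whose
#'   expected direction of benefit is unclear: `"exclude"` (default) or
#'   `"pooled_sign"` (align by the sign of the meta-analysis's pooled
#'   random-effects estimate).
#' @param level Confidence level.
#' @param seed Optional integer recorded in run logs; the analysis
#'   pipeline itself is deterministic.
#'
#' @return A list of class `"metaepi_config"`.
#' @export
run_config <- function(min_mas = 10, min_studies = 3,
                       tau2_method = c("REML", "DL"),
                       ci_method = c("wald", "knapp_hartung"),
                       robust = c("none", "CR2", "CR1", "CR0"),
                       unclear_direction_policy = c("exclude", "pooled_sign"),
                       level = 0.95, seed = NULL) {
  cfg <- list(min_mas = min_mas, min_studies = min_studies,
              tau2_method = match.arg(tau2_method),
              ci_method = match.arg(ci_method),
              robust = match.arg(robust),
              unclear_direction_policy = match.arg(unclear_direction_policy),
              level = level, seed = seed)
  class(cfg) <- "metaepi_config"
  cfg
}

# Align every arm's SMD with the meta-analysis's expected direction of
# benefit; returns the studies table with an `smd_aligned` column and a
# log of excluded meta-analyses (unclear direction under "exclude").
.align_dataset <- function(studies, mas, policy = "exclude") {
  dir <- mas$expected_direction[match(studies$ma_id, mas$ma_id)]
  log <- data.frame(ma_id = character(0), reason = character(0))
  drop_mas <- character(0)
  studies$smd_aligned <- studies$smd
  neg <- dir == "benefit_negative"
  studies$smd_aligned[neg] <- -studies$smd[neg]
  unclear <- unique(studies$ma_id[dir == "unclear"])
  for (id in unclear) {
    rows <- studies$ma_id == id
    if (policy == "pooled_sign" && sum(rows) >= 2) {
      pooled <- pool_random_effects(studies$smd[rows], studies$var[rows],
                                    method = "DL")
      if (pooled$estimate < 0) studies$smd_aligned[rows] <- -studies$smd[rows]
      log <- rbind(log, data.frame(ma_id = id,
                                   reason = "unclear_direction_aligned_by_pooled_sign"))
    } else {
      drop_mas <- c(drop_mas, id)
      log <- rbind(log, data.frame(ma_id = id,
                                   reason = "unclear_direction_excluded"))
    }
  }
  list(studies = studies[!(studies$ma_id %in% drop_mas), , drop = FALSE],
       log = log)
}

#' Eligible meta-analyses for a characteristic
#'
#' A meta-analysis is eligible for a given risk-of-bias characteristic
#' if, after excluding arms without a rating, it includes at least
#' `min_studies` studies with at least one study at high or unclear
#' risk and at least one at low risk.
#'
#' @param dataset A `metaepi_dataset` (see [validate_dataset()] or
#'   [simulate_dataset()]).
#' @param characteristic One of [rob_characteristics].
#' @param min_studies Minimum studies per meta-analysis (default 3).
#'
#' @return A list with `eligible` (character vector of ma_ids) and
#'   `log` (data frame of excluded ma_ids with reasons).
#' @export
filter_eligible_mas <- function(dataset, characteristic, min_studies = 3) {
  characteristic <- match.arg(characteristic, rob_characteristics)
  studies <- dataset$studies
  col <- paste0("rob_", characteristic)
  if (!col %in% names(studies)) stop("missing rating column: ", col)
  grp <- dichotomize(studies[[col]])
  keep <- grp != "excluded"
  log <- data.frame(ma_id = character(0), reason = character(0))
  eligible <- character(0)
  for (id in unique(studies$ma_id)) {
    rows <- keep & studies$ma_id == id
    if (!any(rows)) {
      log <- rbind(log, data.frame(ma_id = id, reason = "no_rated_arms"))
      next
    }
    by_study <- tapply(grp[rows], studies$study_id[rows],
                       function(g) c(any(g == "exposed"), any(g == "unexposed")))
    n_studies <- length(by_study)
    has_exposed <- any(vapply(by_study, `[`, logical(1), 1))
    has_unexposed <- any(vapply(by_study, `[`, logical(1), 2))
    if (n_studies < min_studies) {
      log <- rbind(log, data.frame(ma_id = id, reason = "fewer_than_min_studies"))
    } else if (!has_exposed || !has_unexposed) {
      log <- rbind(log, data.frame(ma_id = id, reason = "no_rating_contrast"))
    } else {
      eligible <- c(eligible, id)
    }
  }
  list(eligible = eligible, log = log)
}

.skipped_result <- function(characteristic, reason, robust = FALSE,
                            n_eligible = 0L) {
  out <- list(characteristic = characteristic, pooled_dmsd = NA_real_,
              se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              tau2 = NA_real_, i2 = NA_real_, n_mas = n_eligible,
              n_arms = 0L,
              per_ma = data.frame(), skipped = TRUE, reason = reason,
              robust = robust, exclusions = data.frame())
  class(out) <- "metaepi_result"
  out
}

#' Two-step meta-epidemiological analysis for one characteristic
#'
#' Step 1 estimates, within each eligible meta-analysis, the difference
#' in SMD (DMSD) between arms at high or unclear risk of bias and arms
#' at low risk by random-effects meta-regression of the
#' direction-aligned SMDs on the dichotomized rating. Step 2 combines
#' the per-meta-analysis DMSDs by random-effects meta-analysis. A
#' positive pooled DMSD indicates a larger effect size in studies at
#' high or unclear risk of bias.
#'
#' The analysis is only performed when at least `config$min_mas`
#' meta-analyses are eligible; otherwise a skipped result is returned
#' (a data finding, not an error).
#'
#' @param dataset A `metaepi_dataset`.
#' @param characteristic One of [rob_characteristics].
#' @param config A [run_config()] list.
#'
#' @return An object of class `"metaepi_result"`: pooled DMSD with
#'   confidence interval, `tau2`, `i2` (percent, heterogeneity of
#'   DMSDs across meta-analyses), `n_mas`, `n_arms`, the per-MA DMSD
#'   table, and exclusion logs.
#' @export
run_characteristic <- function(dataset, characteristic, config = run_config()) {
  characteristic <- match.arg(characteristic, rob_characteristics)
  robust <- !identical(config$robust, "none")
  studies <- dataset$studies
  if (nrow(studies) == 0) {
    return(.skipped_result(characteristic, "no data", robust))
  }
  aligned <- .align_dataset(studies, dataset$mas,
                            policy = config$unclear_direction_policy)
  studies <- aligned$studies
  elig <- filter_eligible_mas(list(studies = studies, mas = dataset$mas),
                              characteristic, config$min_studies)
  exclusions <- rbind(aligned$log, elig$log)
  if (length(elig$eligible) < config$min_mas) {
    res <- .skipped_result(
      characteristic,
      sprintf("fewer than %d eligible meta-analyses (%d)",
              config$min_mas, length(elig$eligible)),
      robust, n_eligible = length(elig$eligible))
    res$exclusions <- exclusions
    return(res)
  }

  col <- paste0("rob_", characteristic)
  grp <- dichotomize(studies[[col]])
  per_ma <- vector("list", length(elig$eligible))
  for (i in seq_along(elig$eligible)) {
    id <- elig$eligible[i]
    rows <- which(studies$ma_id == id & grp != "excluded")
    y <- studies$smd_aligned[rows]
    v <- studies$var[rows]
    lab <- as.integer(grp[rows] == "exposed")
    fit <- tryCatch(
      meta_regress_binary(y, v, lab, method = config$tau2_method),
      error = function(e) e)
    if (inherits(fit, "error")) {
      exclusions <- rbind(exclusions,
                          data.frame(ma_id = id, reason = conditionMessage(fit)))
      next
    }
    se <- fit$se_slope
    if (robust) {
      rse <- tryCatch(
        robust_se(fit, studies$study_id[rows], type = config$robust),
        error = function(e) e)
      if (inherits(rse, "error")) {
        exclusions <- rbind(exclusions,
                            data.frame(ma_id = id, reason = conditionMessage(rse)))
        next
      }
      se <- rse$se
    }
    per_ma[[i]] <- data.frame(
      ma_id = id, dmsd = fit$slope, se = se,
      n_high_unclear = sum(lab == 1L), n_low = sum(lab == 0L),
      tau2_residual = fit$tau2_residual, robust = robust)
  }
  per_ma <- do.call(rbind, per_ma[!vapply(per_ma, is.null, logical(1))])
  if (is.null(per_ma) || nrow(per_ma) < config$min_mas) {
    res <- .skipped_result(
      characteristic,
      sprintf("fewer than %d meta-analyses with estimable DMSD",
              config$min_mas),
      robust, n_eligible = if (is.null(per_ma)) 0L else nrow(per_ma))
    res$exclusions <- exclusions
    return(res)
  }

  pooled <- pool_random_effects(per_ma$dmsd, per_ma$se^2,
                                method = config$tau2_method,
                                ci_method = config$ci_method,
                                level = config$level)
  out <- list(characteristic = characteristic,
              pooled_dmsd = pooled$estimate, se = pooled$se,
              ci_low = pooled$ci_low, ci_high = pooled$ci_high,
              tau2 = pooled$tau2, i2 = pooled$i2,
              n_mas = nrow(per_ma),
              n_arms = sum(per_ma$n_high_unclear + per_ma$n_low),
              per_ma = per_ma, skipped = FALSE, reason = NA_character_,
              robust = robust, exclusions = exclusions)
  class(out) <- "metaepi_result"
  out
}

#' Robust-variance sensitivity analysis for one characteristic
#'
#' Identical to [run_characteristic()] except that step-1 standard
#' errors are replaced by cluster-robust (default CR2) standard errors
#' clustered on `study_id`, accounting for the dependency of multiple
#' experimental arms of the same study. Meta-analyses in which all arms
#' belong to a single study are excluded and logged.
#'
#' @inheritParams run_characteristic
#' @param type Robust-variance type (`"CR2"`, `"CR1"`, `"CR0"`).
#' @return A `"metaepi_result"` with `robust = TRUE`.
#' @export
run_sensitivity_robust <- function(dataset, characteristic,
                                   config = run_config(), type = "CR2") {
  config$robust <- match.arg(type, c("CR2", "CR1", "CR0"))
  run_characteristic(dataset, characteristic, config)
}

#' Run the meta-epidemiological analysis for every characteristic
#'
#' @inheritParams run_characteristic
#' @return An object of class `"metaepi_results"`: a list of one
#'   `"metaepi_result"` per characteristic in [rob_characteristics]
#'   order. `summary()`/`as.data.frame()` give the forest-style table
#'   (estimate, CI, I2, counts, skip reasons).
#' @export
run_all <- function(dataset, config = run_config()) {
  res <- lapply(rob_characteristics, function(ch)
    run_characteristic(dataset, ch, config))
  names(res) <- rob_characteristics
  class(res) <- "metaepi_results"
  res
}

#' @export
as.data.frame.metaepi_results <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(characteristic = r$characteristic,
               dmsd = r$pooled_dmsd, ci_low = r$ci_low, ci_high = r$ci_high,
               tau2 = r$tau2, i2 = r$i2, n_mas = r$n_mas, n_arms = r$n_arms,
               skipped = r$skipped, reason = r$reason,
               robust = r$robust, row.names = NULL)
  }))
}

#' @export
summary.metaepi_results <- function(object, digits = 2, ...) {
  tab <- as.data.frame(object)
  tab$dmsd <- round(tab$dmsd, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$i2 <- round(tab$i2, 1)
  tab
}

#' @export
print.metaepi_result <- function(x, digits = 2, ...) {
  cat("Meta-epidemiological analysis:", x$characteristic,
      if (isTRUE(x$robust)) "(robust-variance sensitivity)" else "", "\n")
  if (x$skipped) {
    cat("  skipped:", x$reason, "\n")
  } else {
    cat(sprintf("  DMSD = %.*f [%.*f, %.*f]  (MAs = %d, arms = %d, I2 = %.1f%%)\n",
                digits, x$pooled_dmsd, digits, x$ci_low, digits, x$ci_high,
                x$n_mas, x$n_arms, x$i2))
    cat("  Positive DMSD: larger effect size in high/unclear risk-of-bias arms.\n")
  }
  invisible(x)
}

#' @export
print.metaepi_results <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
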