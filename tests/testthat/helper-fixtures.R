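# In-code fixtures: small hand-built datasets exercising the pipeline
# without any stored files.

# one meta-analysis worth of arm rows
toy_ma <- function(ma_id, smd, var, rating, study_id = seq_along(smd),
                   characteristic = "randomization") {
  df <- data.frame(ma_id = ma_id,
                   study_id = paste0(ma_id, "_S", study_id),
                   arm_id = stats::ave(seq_along(smd),
                                       paste0(ma_id, study_id), FUN = seq_along),
                   smd = smd, var = var, stringsAsFactors = FALSE)
  for (ch in metaepi::rob_characteristics) {
    df[[paste0("rob_", ch)]] <- "not_assessed"
  }
  df[[paste0("rob_", characteristic)]] <- rating
  df
}

toy_dataset <- function(studies, directions = NULL) {
  ids <- unique(studies$ma_id)
  if (is.null(directions)) directions <- rep("benefit_positive", length(ids))
  mas <- data.frame(ma_id = ids, expected_direction = directions,
                    design = "therapeutic", stringsAsFactors = FALSE)
  out <- list(studies = studies, mas = mas, truth = NULL)
  class(out) <- "metaepi_dataset"
  out
}

# a dataset with n_elig eligible MAs (3 studies, mixed ratings) plus
# some ineligible ones, all for one characteristic
toy_elig_dataset <- function(n_elig, characteristic = "randomization",
                             seed = 1) {
  set.seed(seed)
  parts <- lapply(seq_len(n_elig), function(k) {
    toy_ma(sprintf("E%02d", k), rnorm(4, 0.5, 0.4), runif(4, 0.05, 0.2),
           c("low", "low", "high", "unclear"), characteristic = characteristic)
  })
  do.call(rbind, parts) |> toy_dataset()
}

# brute-force WLS oracle: explicit 2x2 normal-equations solve
wls_oracle <- function(y, v, x, tau2) {
  w <- 1 / (v + tau2)
  X <- cbind(1, x)
  A <- t(X) %*% diag(w) %*% X
  b <- t(X) %*% diag(w) %*% y
  beta <- solve(A, b)
  list(beta = unname(drop(beta)), vcov = unname(solve(A)))
}
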