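## Random-effects meta-analysis primitives used by the two-step
## meta-epidemiological pipeline. All fits are weighted least squares
## with inverse-variance weights 1/(v_i + tau2); tau2 is estimated by
## DerSimonian-Laird (closed form) or REML (bounded scalar search).

# residual heterogeneity for a WLS fit with design matrix X
# DL: tau2 = max(0, (Q_E - (n - p)) / tr(P)),  P = W - W X (X'WX)^-1 X'W
# REML: maximizer of the restricted log-likelihood, truncated at 0
.tau2_estimate <- function(yi, vi, X, method = c("REML", "DL")) {
  method <- match.arg(method)
  n <- length(yi)
  p <- ncol(X)
  if (n <= p) return(0)
  if (method == "DL") {
    w <- 1 / vi
    W <- diag(w, n)
    XtWX_inv <- solve(crossprod(X * w, X))
    P <- W - (X * w) %*% XtWX_inv %*% t(X * w)
    Q <- drop(crossprod(yi, P %*% yi))
    tr_p <- sum(diag(P))
    return(max(0, (Q - (n - p)) / tr_p))
  }
  # REML restricted log-likelihood (constants dropped)
  nll <- function(tau2) {
    w <- 1 / (vi + tau2)
    XtWX <- crossprod(X * w, X)
    beta <- solve(XtWX, crossprod(X * w, yi))
    resid <- yi - drop(X %*% beta)
    0.5 * (sum(log(vi + tau2)) + determinant(XtWX, logarithm = TRUE)$modulus +
             sum(w * resid^2))
  }
  upper <- 10 * max(stats::var(yi), max(vi))
  if (upper <= 0) return(0)
  opt <- stats::optimize(nll, interval = c(0, upper), tol = 1e-8)
  if (nll(0) <= opt$objective) 0 else max(0, opt$minimum)
}

#' Between-study heterogeneity variance
#'
#' Estimates tau-squared, the variance of true effects across studies
#' in a random-effects model, by DerSimonian-Laird (method of moments)
#' or restricted maximum likelihood.
#'
#' @param effects Numeric vector of effect sizes (>= 2).
#' @param variances Strictly positive sampling variances, same length.
#' @param method `"REML"` (default) or `"DL"`.
#'
#' @return A non-negative scalar.
#' @export
estimate_tau2 <- function(effects, variances, method = c("REML", "DL")) {
  .check_effects(effects, variances)
  .tau2_estimate(effects, variances, matrix(1, length(effects), 1), method)
}

.check_effects <- function(effects, variances, min_n = 2) {
  if (length(effects) < min_n) {
    stop("insufficient data: need at least ", min_n, " effects")
  }
  if (length(variances) != length(effects)) {
    stop("effects and variances differ in length")
  }
  if (all(variances == 0)) {
    stop("all sampling variances are zero: nothing to pool")
  }
  if (any(variances <= 0) || any(!is.finite(variances)) || any(!is.finite(effects))) {
    stop("variances must be finite and strictly positive; effects finite")
  }
  invisible(TRUE)
}

#' Random-effects pooling of effect sizes
#'
#' Inverse-variance weighted mean with weights 1/(v_i + tau2).
#' Heterogeneity statistics (Cochran's Q, I-squared) use fixed-effect
#' weights 1/v_i; I2 = max(0, (Q - df)/Q) * 100.
#'
#' @inheritParams estimate_tau2
#' @param ci_method `"wald"` (normal) or `"knapp_hartung"` (t with
#'   k - 1 df and the Knapp-Hartung variance rescaling).
#' @param level Confidence level (default 0.95).
#' @param tau2 Optional fixed tau-squared overriding estimation.
#'
#' @return An object of class `"pooled_estimate"`: a list with
#'   `estimate`, `se`, `ci_low`, `ci_high`, `tau2`, `q_stat`, `df`,
#'   `i2` (percent), `k`, `method`, `ci_method`.
#' @export
pool_random_effects <- function(effects, variances, method = c("REML", "DL"),
                                ci_method = c("wald", "knapp_hartung"),
                                level = 0.95, tau2 = NULL) {
  method <- match.arg(method)
  ci_method <- match.arg(ci_method)
  .check_effects(effects, variances)
  k <- length(effects)
  if (is.null(tau2)) {
    tau2 <- .tau2_estimate(effects, variances, matrix(1, k, 1), method)
  }
  wstar <- 1 / (variances + tau2)
  est <- sum(wstar * effects) / sum(wstar)
  se <- sqrt(1 / sum(wstar))

  # heterogeneity on fixed-effect weights
  w <- 1 / variances
  mu_fe <- sum(w * effects) / sum(w)
  q <- sum(w * (effects - mu_fe)^2)
  df <- k - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0

  alpha <- 1 - level
  if (ci_method == "knapp_hartung" && df > 0) {
    se_ci <- sqrt(sum(wstar * (effects - est)^2) / (df * sum(wstar)))
    crit <- stats::qt(1 - alpha / 2, df)
  } else {
    se_ci <- se
    crit <- stats::qnorm(1 - alpha / 2)
  }
  out <- list(estimate = est, se = if (ci_method == "knapp_hartung") se_ci else se,
              ci_low = est - crit * se_ci, ci_high = est + crit * se_ci,
              tau2 = tau2, q_stat = q, df = df, i2 = i2, k = k,
              method = method, ci_method = ci_method, level = level)
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, digits = 4, ...) {
  cat("Random-effects pooled estimate (", x$method, ")\n", sep = "")
  cat(sprintf("  estimate = %.*f, se = %.*f, %d%% CI [%.*f, %.*f]\n",
              digits, x$estimate, digits, x$se, round(100 * x$level),
              digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  k = %d, tau2 = %.*f, Q = %.*f (df = %d), I2 = %.1f%%\n",
              x$k, digits, x$tau2, digits, x$q_stat, x$df, x$i2))
  invisible(x)
}

#' Random-effects meta-regression on a binary moderator
#'
#' Weighted least-squares regression of effect sizes on an intercept
#' and a 0/1 moderator, with weights 1/(v_i + tau2_residual). The
#' slope is the difference in (weighted) mean effect between the two
#' groups -- in the meta-epidemiological pipeline, the DMSD between
#' high/unclear-risk (label 1) and low-risk (label 0) arms.
#'
#' @inheritParams estimate_tau2
#' @param labels Vector of 0/1 moderator values; both values must occur.
#'
#' @return An object of class `"meta_regression"`: a list with
#'   `intercept`, `slope`, `se_slope`, `se_intercept`,
#'   `tau2_residual`, and the fit internals (`X`, `weights`,
#'   `residuals`, `vi`, `vcov`) needed by [robust_se()].
#' @export
meta_regress_binary <- function(effects, variances, labels,
                                method = c("REML", "DL")) {
  method <- match.arg(method)
  .check_effects(effects, variances, min_n = 3)
  labels <- as.integer(labels)
  if (length(labels) != length(effects)) stop("labels length mismatch")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2) {
    stop("no contrast: moderator takes a single value")
  }
  X <- cbind(1, labels)
  tau2 <- .tau2_estimate(effects, variances, X, method)
  w <- 1 / (variances + tau2)
  XtWX_inv <- solve(crossprod(X * w, X))
  beta <- unname(drop(XtWX_inv %*% crossprod(X * w, effects)))
  vc <- XtWX_inv
  resid <- effects - drop(X %*% beta)
  out <- list(intercept = beta[1], slope = beta[2],
              se_slope = sqrt(vc[2, 2]), se_intercept = sqrt(vc[1, 1]),
              tau2_residual = tau2, robust = FALSE, method = method,
              X = X, weights = w, residuals = resid, vi = variances,
              vcov = vc, n = length(effects))
  class(out) <- "meta_regression"
  out
}

#' @export
print.meta_regression <- function(x, digits = 4, ...) {
  cat("Random-effects meta-regression (binary moderator, ", x$method, ")\n", sep = "")
  cat(sprintf("  slope (group 1 - group 0) = %.*f, se = %.*f%s\n",
              digits, x$slope, digits, x$se_slope,
              if (isTRUE(x$robust)) " [cluster-robust]" else ""))
  cat(sprintf("  intercept = %.*f, residual tau2 = %.*f, n = %d\n",
              digits, x$intercept, digits, x$tau2_residual, x$n))
  invisible(x)
}

# symmetric inverse square root with pseudo-inversion of null directions
.inv_sqrt_sym <- function(S, tol = 1e-12) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  d <- ifelse(e$values > tol, 1 / sqrt(pmax(e$values, tol)), 0)
  e$vectors %*% (d * t(e$vectors))
}

#' Cluster-robust standard error of the meta-regression slope
#'
#' Sandwich-type variance clustered on study, accounting for the
#' dependency among multiple experimental arms of the same study.
#' `"CR2"` (default) applies the bias-reducing small-sample adjustment
#' with Satterthwaite degrees of freedom; `"CR1"` rescales CR0 by
#' m/(m - 1) over m clusters; `"CR0"` is the unadjusted estimator.
#'
#' @param fit A `"meta_regression"` fit from [meta_regress_binary()].
#' @param cluster_ids Cluster (study) identifier per observation.
#' @param type `"CR2"`, `"CR1"` or `"CR0"`.
#'
#' @return A list with `se` (robust standard error of the slope),
#'   `df` (Satterthwaite df for CR2, m - 1 otherwise), and `type`.
#'
#' @details The CR2 adjustment matrices A_j satisfy
#'   A_j (Phi_j - X_j M X_j') A_j' = Phi_j under the working covariance
#'   Phi = diag(v_i + tau2), so the estimator is exactly unbiased when
#'   the working model holds. Satterthwaite df come from matching the
#'   first two moments of the variance estimator under that model.
#' @export
robust_se <- function(fit, cluster_ids, type = c("CR2", "CR1", "CR0")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "meta_regression"))
  if (length(cluster_ids) != fit$n) stop("cluster_ids length mismatch")
  cl <- factor(cluster_ids)
  m <- nlevels(cl)
  if (m < 2) stop("insufficient clusters: need >= 2")

  X <- fit$X
  w <- fit$weights
  n <- fit$n
  M <- solve(crossprod(X * w, X))
  e <- fit$residuals
  phi <- 1 / w # working variances v_i + tau2
  idx <- split(seq_len(n), cl)

  meat <- matrix(0, 2, 2)
  zlist <- vector("list", m)
  cvec <- c(0, 1)
  for (j in seq_len(m)) {
    i <- idx[[j]]
    Xj <- X[i, , drop = FALSE]
    Wj <- w[i]
    if (type == "CR2") {
      # A_j = Phi^{1/2} G^{-1/2} Phi^{-1/2}, G = I - Phi^{-1/2} Xj M Xj' Phi^{-1/2}
      sphi <- sqrt(phi[i])
      G <- diag(length(i)) - (Xj / sphi) %*% M %*% t(Xj / sphi)
      Aj <- (sphi * .inv_sqrt_sym(G)) / rep(sphi, each = length(i))
    } else {
      Aj <- diag(length(i))
    }
    gj <- crossprod(Xj * Wj, Aj %*% e[i])
    meat <- meat + tcrossprod(gj)
    zlist[[j]] <- drop(t(Aj) %*% (Wj * (Xj %*% M %*% cvec)))
  }
  V <- M %*% meat %*% M
  if (type == "CR1") V <- V * m / (m - 1)
  se <- sqrt(V[2, 2])

  if (type == "CR2") {
    # Satterthwaite: Q = e' (sum_j p_j p_j') e with p_j the padded z_j;
    # under Var(y) = Phi, Q ~ sum lambda_i chi2_1 with lambda eigenvalues
    # of U U', U[, j] = Phi^{1/2} (I - H)' p_j; df = tr^2 / tr of square.
    Ht <- (X * w) %*% M %*% t(X) # transpose of the hat matrix X M X' W
    U <- matrix(0, n, m)
    for (j in seq_len(m)) {
      p <- numeric(n)
      p[idx[[j]]] <- zlist[[j]]
      U[, j] <- sqrt(phi) * (p - drop(Ht %*% p))
    }
    Gmat <- crossprod(U)
    df <- sum(diag(Gmat))^2 / sum(Gmat^2)
  } else {
    df <- m - 1
  }
  list(se = se, df = df, type = type)
}
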