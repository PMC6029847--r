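## Multivariate correlation with missing data. The study's "REML"
## missing-data correlation is implemented as maximum-likelihood estimation
## of a multivariate-normal mean/covariance by EM over missing-at-random
## cells; correlations are read off the converged covariance. Complete-data
## pearson/spearman go through stats::cor pairwise-complete.

## Log-likelihood of observed entries under N(mu, Sigma), rows grouped by
## missingness pattern.
mvn_obs_loglik <- function(X, mu, Sigma, patterns) {
  ll <- 0
  for (pat in patterns) {
    obs <- pat$obs
    S_oo <- Sigma[obs, obs, drop = FALSE]
    ch <- chol(S_oo)
    xc <- sweep(X[pat$rows, obs, drop = FALSE], 2, mu[obs])
    z <- backsolve(ch, t(xc), transpose = TRUE)
    ll <- ll + sum(-0.5 * colSums(z^2)) -
      length(pat$rows) * (sum(log(diag(ch))) + 0.5 * length(obs) * log(2 * pi))
  }
  ll
}

## EM for MVN mean/covariance with MCAR/MAR missing cells.
em_mvn_fit <- function(X, tol = 1e-8, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X)
  keep <- rowSums(!is.na(X)) > 0
  X <- X[keep, , drop = FALSE]; n <- nrow(X)

  mu <- colMeans(X, na.rm = TRUE)
  Sigma <- stats::cov(X, use = "pairwise.complete.obs")
  Sigma[is.na(Sigma)] <- 0
  ## clamp to positive definite
  ev <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-6 * max(ev$values, 1e-12))
  Sigma <- ev$vectors %*% (lam * t(ev$vectors))

  miss_mat <- is.na(X)
  pat_key <- apply(miss_mat, 1, function(r) paste(as.integer(r), collapse = ""))
  patterns <- lapply(split(seq_len(n), pat_key), function(rows) {
    m <- miss_mat[rows[1], ]
    list(rows = rows, obs = which(!m), mis = which(m))
  })

  ll_old <- -Inf; converged <- FALSE; iter <- 0L
  for (iter in seq_len(max_iter)) {
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    for (pat in patterns) {
      obs <- pat$obs; mis <- pat$mis
      Xo <- X[pat$rows, obs, drop = FALSE]
      m_rows <- length(pat$rows)
      if (length(mis) == 0L) {
        sum_x <- sum_x + colSums(X[pat$rows, , drop = FALSE])
        sum_xx <- sum_xx + crossprod(X[pat$rows, , drop = FALSE])
        next
      }
      S_oo_inv <- solve(Sigma[obs, obs, drop = FALSE])
      B <- Sigma[mis, obs, drop = FALSE] %*% S_oo_inv
      cond_mu <- matrix(mu[mis], m_rows, length(mis), byrow = TRUE) +
        sweep(Xo, 2, mu[obs]) %*% t(B)
      C <- Sigma[mis, mis, drop = FALSE] -
        B %*% Sigma[obs, mis, drop = FALSE]
      Xhat <- matrix(0, m_rows, p)
      Xhat[, obs] <- Xo
      Xhat[, mis] <- cond_mu
      sum_x <- sum_x + colSums(Xhat)
      sxx <- crossprod(Xhat)
      sxx[mis, mis] <- sxx[mis, mis] + m_rows * C
      sum_xx <- sum_xx + sxx
    }
    mu <- sum_x / n
    Sigma <- sum_xx / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- mvn_obs_loglik(X, mu, Sigma, patterns)
    if (is.finite(ll) && abs(ll - ll_old) < tol * max(1, abs(ll))) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll_old, iterations = iter,
       converged = converged, n = n)
}

#' Correlation matrix with missing-data support
#'
#' Pairwise correlations among the numeric variables of a cohort table.
#' `"pearson"` and `"spearman"` are computed pairwise-complete;
#' `"em_mvn"` estimates the multivariate-normal mean and covariance by EM
#' over missing-at-random cells (maximum likelihood, converged on the
#' observed-data log-likelihood) and reads correlations off the converged
#' covariance -- on complete data this coincides with Pearson. P-values use
#' the t approximation `t = r sqrt((n - 2) / (1 - r^2))` with the pairwise
#' effective n (both variables observed).
#'
#' @param table Data.frame; non-numeric columns are ignored.
#' @param method `"pearson"`, `"spearman"` or `"em_mvn"`.
#' @param vars Optional character vector selecting variables.
#' @param log_transform Log10-transform positive variables first (the
#'   study's convention for moduli and densities).
#' @param tol,max_iter EM convergence tolerance (relative change of the
#'   observed-data log-likelihood) and iteration cap.
#' @return A `correlation_result`: list `variables`, `r`, `p`, `n_eff`,
#'   `method`, `converged`, `iterations`, plus `mu`/`sigma` for `em_mvn`.
#'   Variables with fewer than 3 observed values are dropped with a warning.
#' @export
correlation_matrix <- function(table, method = c("em_mvn", "pearson", "spearman"),
                               vars = NULL, log_transform = FALSE,
                               tol = 1e-8, max_iter = 500L) {
  method <- match.arg(method)
  num <- vapply(table, is.numeric, logical(1))
  X <- as.matrix(table[, num, drop = FALSE])
  if (!is.null(vars)) {
    cm_check(all(vars %in% colnames(X)), "cm_validation_error",
             "requested variables not present/numeric")
    X <- X[, vars, drop = FALSE]
  }
  n_obs <- colSums(!is.na(X))
  if (any(n_obs < 3)) {
    warning(sprintf("dropping variables with < 3 observed values: %s",
                    paste(colnames(X)[n_obs < 3], collapse = ", ")))
    X <- X[, n_obs >= 3, drop = FALSE]
  }
  cm_check(ncol(X) >= 2, "cm_validation_error", "need >= 2 usable variables")
  cm_check(sum(rowSums(!is.na(X)) > 0) >= 3, "cm_insufficient_data",
           "need >= 3 rows with data")
  if (log_transform) {
    cm_check(all(X > 0, na.rm = TRUE), "cm_validation_error",
             "log transform requires positive values")
    X <- log10(X)
  }
  p <- ncol(X)
  n_eff <- crossprod(!is.na(X))

  converged <- TRUE; iterations <- 0L; mu <- NULL; Sigma <- NULL
  if (method == "em_mvn") {
    fit <- em_mvn_fit(X, tol = tol, max_iter = max_iter)
    sdv <- sqrt(diag(fit$Sigma))
    r <- fit$Sigma / tcrossprod(sdv)
    diag(r) <- 1
    converged <- fit$converged; iterations <- fit$iterations
    mu <- fit$mu; Sigma <- fit$Sigma
    if (!converged) warning("EM did not converge within max_iter")
  } else {
    r <- stats::cor(X, use = "pairwise.complete.obs", method = method)
  }
  dimnames(r) <- list(colnames(X), colnames(X))

  tstat <- r * sqrt(pmax(n_eff - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  pmat <- 2 * stats::pt(-abs(tstat), df = pmax(n_eff - 2, 1))
  diag(pmat) <- NA_real_
  dimnames(pmat) <- dimnames(r)

  structure(list(variables = colnames(X), r = r, p = pmat, n_eff = n_eff,
                 method = method, converged = converged,
                 iterations = iterations, mu = mu, sigma = Sigma),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s over %d variables%s\n", x$method,
              length(x$variables),
              if (x$method == "em_mvn")
                sprintf(" (EM: %d iterations, %s)", x$iterations,
                        if (x$converged) "converged" else "NOT converged")
              else ""))
  print(round(x$r, 3))
  invisible(x)
}
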