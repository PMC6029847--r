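## Statistical layer: two-group tests, Holm-Sidak adjustment, omnibus +
## Dunnett/Dunn post hoc comparisons, and 4PL dose-response fitting.
## Wraps stats:: routines for the standard tests; the adjustment,
## Dunnett quantiles and Dunn z-tests are computed here.

test_result <- function(method, statistic, df, p, p_adjusted = NA_real_,
                        labels = c(NA, NA), n = NA_integer_, extra = list()) {
  structure(c(list(method = method, statistic = unname(statistic),
                   df = unname(df), p = unname(p),
                   p_adjusted = unname(p_adjusted), labels = labels, n = n),
              extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s [%s vs %s]: stat = %.4g, df = %s, p = %.4g%s\n",
              x$method, x$labels[1], x$labels[2], x$statistic,
              paste(signif(x$df, 4), collapse = ","), x$p,
              if (!is.na(x$p_adjusted)) sprintf(" (adj %.4g)", x$p_adjusted) else ""))
  invisible(x)
}

#' Two-group and one-sample tests
#'
#' The study's single-comparison tests: Welch's t (unequal variances),
#' Student's t, the two-sided Mann-Whitney U (exact when the combined n is
#' at most 20 and there are no ties, otherwise the normal approximation
#' with mid-ranks and tie-corrected variance), and the one-sample t-test.
#' `log_transform` applies log10 first (positive data required), matching
#' the study's analysis of moduli and ratios.
#'
#' @param x,y Numeric samples (`y` omitted for `one_sample_t`).
#' @param method One of `"welch_t"`, `"student_t"`, `"mann_whitney"`,
#'   `"one_sample_t"`.
#' @param log_transform Log10-transform the data first.
#' @param mu Null value for the one-sample t-test.
#' @param labels Group labels carried into the result.
#' @return A `test_result`.
#' @export
pairwise_tests <- function(x, y = NULL,
                           method = c("welch_t", "student_t", "mann_whitney",
                                      "one_sample_t"),
                           log_transform = FALSE, mu = 0,
                           labels = c("x", "y")) {
  method <- match.arg(method)
  if (log_transform) {
    cm_check(all(x > 0) && (is.null(y) || all(y > 0)), "cm_validation_error",
             "log transform requires strictly positive values")
    x <- log10(x); if (!is.null(y)) y <- log10(y)
    if (method == "one_sample_t" && mu > 0) mu <- log10(mu)
  }
  if (method == "one_sample_t") {
    cm_check(length(x) >= 2, "cm_insufficient_data", "need n >= 2")
    tt <- stats::t.test(x, mu = mu)
    return(test_result("one_sample_t", tt$statistic, tt$parameter, tt$p.value,
                       labels = c(labels[1], sprintf("mu=%g", mu)),
                       n = length(x)))
  }
  cm_check(length(x) >= 2 && length(y) >= 2, "cm_insufficient_data",
           "need n >= 2 per sample")
  if (method %in% c("welch_t", "student_t")) {
    equal_var <- method == "student_t"
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      ## degenerate constant samples: define t = 0 (equal means) or Inf
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      return(test_result(method, if (eq) 0 else Inf,
                         length(x) + length(y) - 2, if (eq) 1 else 0,
                         labels = labels, n = c(length(x), length(y)),
                         extra = list(degenerate = TRUE)))
    }
    tt <- stats::t.test(x, y, var.equal = equal_var)
    return(test_result(method, tt$statistic, tt$parameter, tt$p.value,
                       labels = labels, n = c(length(x), length(y))))
  }
  ## Mann-Whitney
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  test_result("mann_whitney", wt$statistic, NA_real_, wt$p.value,
              labels = labels, n = c(length(x), length(y)),
              extra = list(exact = exact, ties = ties))
}

#' Holm-Sidak step-down adjustment
#'
#' Sorted ascending, `p_(i)` is adjusted to `1 - (1 - p_(i))^(m - i + 1)`
#' with running-maximum enforcement of monotonicity, then returned in the
#' original order. At `m = 1` the p-value is unchanged.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_holm_sidak <- function(p) {
  cm_check(all(p >= 0 & p <= 1, na.rm = TRUE), "cm_validation_error",
           "p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## Two-sided Dunnett adjusted p-values from per-comparison t statistics.
## corr[i, j] = lambda_i lambda_j with lambda_i = sqrt(n_i / (n_i + n_0));
## the multivariate-t rectangle probability is evaluated by quadrature
## (exact in the univariate case). The internal quasi-MC stream is run
## under a fixed local seed so results are reproducible.
dunnett_p <- function(t_stats, n_treat, n_control, df) {
  lam <- sqrt(n_treat / (n_treat + n_control))
  R <- outer(lam, lam)
  diag(R) <- 1
  k <- length(t_stats)
  vapply(t_stats, function(tv) {
    if (!is.finite(tv)) return(0)
    a <- abs(tv)
    pr <- with_seed(271828L,
                    mvtnorm::pmvt(lower = rep(-a, k), upper = rep(a, k),
                                  df = as.integer(round(df)), corr = R,
                                  algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                                                 maxpts = 1e5)))
    p_adj <- 1 - as.numeric(pr)
    p_raw <- 2 * stats::pt(-a, df)
    ## the quadrature's absolute tolerance cannot resolve probabilities
    ## below ~1e-5; there the Bonferroni product k * raw is exact to first
    ## order (inclusion-exclusion with vanishing joint tails)
    if (p_adj < 1e-5) p_adj <- k * p_raw
    ## clamp into the mathematical envelope [raw, min(1, k * raw)]
    min(max(p_adj, p_raw), min(1, k * p_raw))
  }, numeric(1))
}

#' Multi-group tests with comparisons against a control
#'
#' Omnibus test plus per-group-vs-control adjusted comparisons, in the
#' study's three flavours: one-way ANOVA with Dunnett's test, randomized-
#' block (repeated-measures, sphericity assumed) ANOVA with Dunnett's test,
#' and Kruskal-Wallis with Dunn's test (Bonferroni-adjusted z-tests on mean
#' ranks with tie correction).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @param design `"anova_dunnett"`, `"rm_anova_dunnett"` or `"kruskal_dunn"`.
#' @param control Control group label (default: first factor level).
#' @param blocks Block (donor) labels; required, complete and balanced for
#'   the repeated-measures design.
#' @param log_transform Log10-transform the response first.
#' @return List with `omnibus` (a `test_result`) and `comparisons` (list of
#'   `test_result`, one per non-control group, carrying adjusted p-values).
#' @export
multigroup_tests <- function(values, groups,
                             design = c("anova_dunnett", "rm_anova_dunnett",
                                        "kruskal_dunn"),
                             control = NULL, blocks = NULL,
                             log_transform = FALSE) {
  design <- match.arg(design)
  groups <- factor(groups)
  cm_check(nlevels(groups) >= 2, "cm_validation_error", "need >= 2 groups")
  if (is.null(control)) control <- levels(groups)[1]
  cm_check(control %in% levels(groups), "cm_missing_control",
           sprintf("control group '%s' not present", control))
  groups <- stats::relevel(groups, ref = control)
  if (log_transform) {
    cm_check(all(values > 0), "cm_validation_error",
             "log transform requires positive values")
    values <- log10(values)
  }
  treat <- setdiff(levels(groups), control)

  if (design == "kruskal_dunn") {
    if (stats::sd(values) == 0) {
      ## identical constants: H = 0 by definition, no post hoc evidence
      comps <- lapply(treat, function(g)
        test_result("dunn_z", 0, NA_real_, 1, p_adjusted = 1,
                    labels = c(g, control)))
      return(list(omnibus = test_result("kruskal_wallis", 0,
                                        nlevels(groups) - 1, NA_real_,
                                        n = length(values),
                                        extra = list(zero_variance = TRUE)),
                  comparisons = comps))
    }
    kw <- stats::kruskal.test(values, groups)
    N <- length(values)
    rk <- rank(values)
    tie_tab <- table(values)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
    varfac <- N * (N + 1) / 12 - tie_corr
    mean_rank <- tapply(rk, groups, mean)
    n_g <- tapply(rk, groups, length)
    comps <- lapply(treat, function(g) {
      z <- (mean_rank[[g]] - mean_rank[[control]]) /
        sqrt(varfac * (1 / n_g[[g]] + 1 / n_g[[control]]))
      p_raw <- 2 * stats::pnorm(-abs(z))
      test_result("dunn_z", z, NA_real_, p_raw,
                  p_adjusted = min(p_raw * length(treat), 1),
                  labels = c(g, control), n = c(n_g[[g]], n_g[[control]]))
    })
    omnibus <- test_result("kruskal_wallis", kw$statistic, kw$parameter,
                           kw$p.value, n = N)
    return(list(omnibus = omnibus, comparisons = comps))
  }

  if (design == "rm_anova_dunnett") {
    cm_check(!is.null(blocks), "cm_validation_error",
             "repeated-measures design requires blocks")
    blocks <- factor(blocks)
    tab <- table(groups, blocks)
    cm_check(all(tab == 1), "cm_incomplete_blocks",
             "repeated-measures design requires exactly one value per group x block")
    fit <- stats::aov(values ~ groups + blocks)
    n_per <- nlevels(blocks)
  } else {
    fit <- stats::aov(values ~ groups)
    n_per <- NULL
  }
  an <- summary(fit)[[1]]
  rn <- trimws(rownames(an))
  ms_err <- an[match("Residuals", rn), "Mean Sq"]
  df_err <- an[match("Residuals", rn), "Df"]
  Fg <- an[match("groups", rn), "F value"]
  pg <- an[match("groups", rn), "Pr(>F)"]
  df_grp <- an[match("groups", rn), "Df"]
  mean_g <- tapply(values, groups, mean)
  zero_var <- !is.finite(ms_err) || ms_err <= .Machine$double.eps * max(abs(values), 1)
  n_g <- tapply(values, groups, length)
  n_t <- if (is.null(n_per)) unname(n_g[treat]) else rep(n_per, length(treat))
  n_0 <- if (is.null(n_per)) n_g[[control]] else n_per
  t_stats <- vapply(treat, function(g) {
    i <- match(g, treat)
    se <- sqrt(ms_err * (1 / n_t[i] + 1 / n_0))
    if (zero_var) {
      if (isTRUE(all.equal(mean_g[[g]], mean_g[[control]]))) 0 else Inf
    } else (mean_g[[g]] - mean_g[[control]]) / se
  }, numeric(1))
  p_adj <- if (zero_var) as.numeric(t_stats == 0)
  else dunnett_p(t_stats, n_t, n_0, df_err)
  comps <- lapply(seq_along(treat), function(i) {
    test_result("dunnett_t", t_stats[i], df_err,
                p = if (zero_var) p_adj[i] else
                  2 * stats::pt(-abs(t_stats[i]), df_err),
                p_adjusted = p_adj[i],
                labels = c(treat[i], control), n = c(n_t[i], n_0))
  })
  omnibus <- test_result(if (design == "rm_anova_dunnett") "rm_anova" else "anova_f",
                         if (zero_var) 0 else Fg,
                         c(df_grp, df_err),
                         if (zero_var) NA_real_ else pg,
                         n = length(values),
                         extra = list(zero_variance = zero_var))
  list(omnibus = omnibus, comparisons = comps)
}

#' Four-parameter logistic dose-response fit
#'
#' Fits `y = bottom + (top - bottom) / (1 + 10^(hill (log10 d - log10 IC50)))`
#' on log10 dose by Levenberg-Marquardt least squares; for inhibition data
#' (activity falling with dose) the hill slope is positive and the IC50 is
#' the dose at the midpoint of the plateaus.
#'
#' @param doses Dose levels (> 0), at least 4 distinct values.
#' @param responses Responses (e.g. % activity), same length.
#' @return A `dose_response_fit`: list `ic50`, `hill`, `top`, `bottom`,
#'   `residual_norm`, `converged`.
#' @export
fit_dose_response <- function(doses, responses) {
  cm_check(length(doses) == length(responses), "cm_validation_error",
           "doses and responses must align")
  cm_check(all(doses > 0), "cm_validation_error", "doses must be > 0")
  cm_check(length(unique(doses)) >= 4, "cm_insufficient_data",
           "need >= 4 distinct dose levels")
  span <- diff(range(responses))
  if (span < 1e-8 * max(1, abs(mean(responses))))
    cm_stop("cm_no_fit", "flat response: no dose dependence to fit")
  ld <- log10(doses)
  mid <- (max(responses) + min(responses)) / 2
  start <- list(top = max(responses), bottom = min(responses),
                lic50 = ld[which.min(abs(responses - mid))], hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      responses ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - lic50))),
      start = start,
      lower = c(top = -Inf, bottom = -Inf, lic50 = min(ld) - 3, hill = 0.05),
      upper = c(top = Inf, bottom = Inf, lic50 = max(ld) + 3, hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) cm_stop("cm_no_fit",
                                paste("4PL fit failed:", conditionMessage(e))))
  cf <- stats::coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  structure(list(ic50 = 10^cf[["lic50"]], hill = cf[["hill"]],
                 top = cf[["top"]], bottom = cf[["bottom"]],
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = isTRUE(conv)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> IC50 = %.4g, hill = %.3g, top = %.4g, bottom = %.4g%s\n",
              x$ic50, x$hill, x$top, x$bottom,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}
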