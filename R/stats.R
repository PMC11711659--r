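# Cohort-level inference: Gaussian GLM predictor screen with Wald tests,
# within- vs between-animal randomization test, and the nonparametric
# comparison battery (rank-sum, Kruskal-Wallis + Dunn, Spearman).

GLM_PREDICTORS <- c("genotype", "gender", "age_weeks",
                    "threshold_contra", "threshold_ipsi")

#' Gaussian GLM predictor screen with Wald tests
#'
#' Fits `measure ~ C(genotype) + C(gender) + age + contralateral threshold +
#' ipsilateral threshold` with a Gaussian family and reports, per predictor,
#' the coefficient, its standard error, and a Wald p-value. The reference
#' distribution for the Wald statistic is standard normal by default (the
#' large-sample GLM convention); a t reference on the residual degrees of
#' freedom is available.
#'
#' @param table cohort table: one row per (animal, stimulated ear) with the
#'   predictor columns and the response.
#' @param response name of the response column (an AEP measure).
#' @param predictors predictor column names; categorical columns are coded as
#'   factors. Defaults to the standard five-predictor screen.
#' @param reference `"normal"` or `"t"` reference for Wald p-values.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return An object of class `glm_result`: coefficient table
#'   (`term`, `estimate`, `se`, `statistic`, `p_value`, `significant`),
#'   `n_used`, `n_dropped`, `sigma`, `degenerate` flag.
#' @export
fit_glm <- function(table, response, predictors = GLM_PREDICTORS,
                    reference = c("normal", "t"), alpha = 0.05) {
  reference <- match.arg(reference)
  stop_if_not(response %in% names(table), "response '%s' not found", response)
  missing_pred <- setdiff(predictors, names(table))
  stop_if_not(length(missing_pred) == 0, "predictor '%s' not found",
              paste(missing_pred, collapse = ", "))
  dat <- table[, c(response, predictors), drop = FALSE]
  for (p in predictors) {
    if (is.character(dat[[p]]) || is.logical(dat[[p]])) {
      dat[[p]] <- factor(dat[[p]])
    }
  }
  complete <- stats::complete.cases(dat)
  n_dropped <- sum(!complete)
  dat <- dat[complete, , drop = FALSE]
  form <- stats::reformulate(if (length(predictors)) predictors else "1",
                             response = as.name(response))
  mm <- stats::model.matrix(form, dat)
  stop_if_not(nrow(dat) >= ncol(mm) + 1,
              "too few complete rows (%d) for %d coefficients",
              nrow(dat), ncol(mm))
  if (qr(mm)$rank < ncol(mm)) {
    stop("collinear design: predictors are linearly dependent", call. = FALSE)
  }
  fit <- stats::glm(form, data = dat, family = stats::gaussian())
  est <- stats::coef(fit)
  df_res <- fit$df.residual
  sigma2 <- sum(stats::residuals(fit)^2) / df_res
  degenerate <- sigma2 < 1e-12
  se <- sqrt(diag(stats::vcov(fit)))
  z <- est / se
  p <- if (reference == "normal") 2 * stats::pnorm(-abs(z))
       else 2 * stats::pt(-abs(z), df_res)
  if (degenerate) p[] <- NA_real_
  tab <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se), statistic = unname(z),
                    p_value = unname(p),
                    significant = !is.na(p) & p < alpha,
                    row.names = NULL)
  out <- list(coefficients = tab, n_used = nrow(dat), n_dropped = n_dropped,
              sigma = sqrt(sigma2), degenerate = degenerate,
              reference = reference, response = response, fit = fit)
  class(out) <- "glm_result"
  out
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("Gaussian GLM for %s (n = %d, %d dropped; %s Wald reference)\n",
              x$response, x$n_used, x$n_dropped, x$reference))
  if (x$degenerate) cat("  [degenerate fit: zero residual variance]\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

spearman_rho <- function(x, y) {
  xr <- rank(x); yr <- rank(y)
  xc <- xr - mean(xr); yc <- yr - mean(yr)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) return(NA_real_)
  sum(xc * yc) / den
}

#' Within- versus between-animal randomization test
#'
#' Tests whether paired measures from the two ears of the same animal are more
#' correlated than measures from independent animals. The observed statistic
#' is the Spearman correlation across animals of (left-ear, right-ear) values;
#' the null distribution re-pairs the right-ear values across animals at
#' random `n_perm` times. If the observed within-animal correlation falls
#' inside the central 95% interval of the null, ears behave like independent
#' units.
#'
#' @param table cohort table with `animal_id`, `ear` (`"left"`/`"right"`) and
#'   the measure column.
#' @param measure name of the measure column.
#' @param n_perm number of random re-pairings (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @param conf confidence level of the null interval (default 0.95).
#' @return An object of class `rand_test_result`: `observed`, `null` (vector
#'   of permuted correlations), `ci` (bounds), `inside_ci`, `n_animals`,
#'   `n_perm`.
#' @export
within_between_randomization <- function(table, measure, n_perm = 10000,
                                         seed = NULL, conf = 0.95) {
  stop_if_not(measure %in% names(table), "measure '%s' not found", measure)
  wide <- split(table, table$animal_id)
  pairs <- vapply(wide, function(d) {
    l <- d[[measure]][d$ear == "left"]
    r <- d[[measure]][d$ear == "right"]
    if (length(l) == 1 && length(r) == 1 && is.finite(l) && is.finite(r)) {
      c(l, r)
    } else c(NA_real_, NA_real_)
  }, numeric(2))
  keep <- is.finite(pairs[1, ]) & is.finite(pairs[2, ])
  x <- pairs[1, keep]; y <- pairs[2, keep]
  n <- length(x)
  stop_if_not(n >= 5, "at least 5 animals with both ears measured are required (got %d)", n)
  observed <- spearman_rho(x, y)
  with_seed(seed, {
    xr <- rank(x); yr <- rank(y)
    xc <- xr - mean(xr); yc <- yr - mean(yr)
    den <- sqrt(sum(xc^2) * sum(yc^2))
    perm_idx <- vapply(seq_len(n_perm), function(j) sample.int(n),
                       integer(n))
    null <- as.numeric(crossprod(xc, matrix(yc[perm_idx], nrow = n))) / den
    a <- (1 - conf) / 2
    ci <- stats::quantile(null, c(a, 1 - a), names = FALSE)
    out <- list(observed = observed, null = null, ci = ci,
                inside_ci = observed >= ci[1] && observed <= ci[2],
                n_animals = n, n_perm = n_perm, measure = measure)
    class(out) <- "rand_test_result"
    out
  })
}

#' @export
print.rand_test_result <- function(x, ...) {
  cat(sprintf("Within/between-animal randomization test for %s\n", x$measure))
  cat(sprintf("  observed within-animal rho = %.3f; null 95%% CI [%.3f, %.3f] (%d permutations, %d animals)\n",
              x$observed, x$ci[1], x$ci[2], x$n_perm, x$n_animals))
  cat(sprintf("  observed %s the null interval\n",
              if (x$inside_ci) "inside" else "OUTSIDE"))
  invisible(x)
}

dunn_posthoc <- function(values, groups, p_adjust = "none") {
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v_base <- N * (N + 1) / 12 - tie_corr
  gl <- levels(groups)
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  combs <- utils::combn(gl, 2)
  z <- p <- numeric(ncol(combs))
  for (j in seq_len(ncol(combs))) {
    g1 <- combs[1, j]; g2 <- combs[2, j]
    sej <- sqrt(v_base * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    z[j] <- if (sej > 0) (mean_r[[g1]] - mean_r[[g2]]) / sej else NA_real_
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z,
             p_value = p, p_adjusted = stats::p.adjust(p, method = p_adjust),
             row.names = NULL)
}

#' Nonparametric group comparison
#'
#' Two groups are compared with the two-tailed Mann-Whitney U rank test;
#' three or more with the Kruskal-Wallis H test followed by pairwise Dunn
#' post-hoc comparisons (z statistics from mean ranks with tie correction,
#' unadjusted by default).
#'
#' @param values numeric measure values.
#' @param groups group labels, e.g. `"WT"`, `"Df1-NH"`, `"Df1-HI"`.
#' @param p_adjust multiplicity adjustment method for Dunn p-values (a
#'   [stats::p.adjust()] method; default `"none"`).
#' @return An object of class `group_compare_result`: `method`, `statistic`,
#'   `p_value`, `pairwise` (Dunn table, or `NULL` for two groups),
#'   `degenerate` flag (all observations identical).
#' @export
group_compare <- function(values, groups, p_adjust = "none") {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  counts <- table(groups)
  stop_if_not(length(counts) >= 2, "at least two non-empty groups are required")
  stop_if_not(all(counts >= 2), "every group needs at least 2 observations")
  if (length(unique(values)) == 1) {
    out <- list(method = "degenerate", statistic = NA_real_, p_value = 1,
                pairwise = NULL, degenerate = TRUE, n = length(values))
    class(out) <- "group_compare_result"
    return(out)
  }
  if (length(counts) == 2) {
    gl <- levels(groups)
    wt <- stats::wilcox.test(values[groups == gl[1]], values[groups == gl[2]],
                             alternative = "two.sided", exact = NULL)
    out <- list(method = "mann-whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value, pairwise = NULL, degenerate = FALSE,
                n = length(values))
  } else {
    kw <- stats::kruskal.test(values, groups)
    out <- list(method = "kruskal-wallis", statistic = unname(kw$statistic),
                df = unname(kw$parameter), p_value = kw$p.value,
                pairwise = dunn_posthoc(values, groups, p_adjust),
                degenerate = FALSE, n = length(values))
  }
  class(out) <- "group_compare_result"
  out
}

#' @export
print.group_compare_result <- function(x, ...) {
  cat(sprintf("Group comparison (%s): statistic = %.4g, p = %.4g, n = %d\n",
              x$method, x$statistic, x$p_value, x$n))
  if (!is.null(x$pairwise)) {
    cat("Dunn post-hoc comparisons:\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      perm <- append(sub[r, ], n, after = pos - 1L)
      out[row, ] <- perm
      row <- row + 1L
    }
  }
  out
}

#' Spearman rank correlation with two-tailed p-value
#'
#' Spearman's rho with average ranks for ties. For n <= 7 without ties the
#' two-tailed p-value is computed by exact enumeration over all rank
#' permutations; otherwise by the t approximation on `n - 2` degrees of
#' freedom.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return List with `rho`, `p_value`, `n`, `method`. Constant inputs yield
#'   `rho = NA` with a warning (flagged undefined).
#' @export
rank_correlation <- function(x, y) {
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stop_if_not(n >= 3, "at least 3 complete pairs are required")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant input: correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined"))
  }
  rho <- spearman_rho(x, y)
  no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
  if (n <= 7 && no_ties) {
    xr <- rank(x); yr <- rank(y)
    perms <- all_permutations(n)
    xc <- xr - mean(xr)
    den <- sum(xc^2)   # == sum(yc^2) for untied ranks
    # rho for every permuted pairing: cor(xr, yr[perm])
    rhos <- as.numeric(matrix(yr[t(perms)], ncol = n, byrow = TRUE) %*% xc) / den
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}
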