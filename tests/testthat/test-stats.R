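# Cohort-level inference: GLM Wald screen, randomization test, rank battery.

sim_table <- function(n = 100, beta_geno = 0, sd = 1, seed = 1) {
  set.seed(seed)
  geno <- sample(c("WT", "Df1"), n, replace = TRUE)
  data.frame(
    animal_id = sprintf("a%03d", seq_len(n)),
    genotype = geno,
    gender = sample(c("F", "M"), n, replace = TRUE),
    age_weeks = rnorm(n, 10, 1.4),
    threshold_contra = sample(seq(20, 90, 5), n, replace = TRUE),
    threshold_ipsi = sample(seq(20, 90, 5), n, replace = TRUE),
    y = beta_geno * (geno == "WT") + rnorm(n, 0, sd))
}

test_that("a perfectly predicted response is fit exactly and flagged degenerate", {
  tab <- sim_table(50, seed = 2)
  tab$y <- 2 * tab$age_weeks
  res <- fit_glm(tab, "y")
  age_row <- res$coefficients[res$coefficients$term == "age_weeks", ]
  expect_equal(age_row$estimate, 2, tolerance = 1e-8)
  expect_true(res$degenerate)
  expect_true(is.na(age_row$p_value))
})

test_that("an intercept-only model returns the sample mean", {
  tab <- sim_table(30, seed = 3)
  res <- fit_glm(tab, "y", predictors = character(0))
  expect_equal(res$coefficients$estimate[1], mean(tab$y), tolerance = 1e-12)
})

test_that("coefficients equal the closed-form least-squares oracle", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(10:20, 1)
    tab <- sim_table(n, seed = 100 + rep)
    res <- fit_glm(tab, "y")
    X <- stats::model.matrix(~ factor(genotype) + factor(gender) + age_weeks +
                               threshold_contra + threshold_ipsi, tab)
    beta <- solve(crossprod(X), crossprod(X, tab$y))
    expect_equal(unname(res$coefficients$estimate), as.numeric(beta),
                 tolerance = 1e-8)
  }
})

test_that("an injected genotype effect is recovered without bias", {
  ests <- vapply(1:25, function(i) {
    tab <- sim_table(100, beta_geno = 0.5, sd = 1, seed = 200 + i)
    res <- fit_glm(tab, "y")
    res$coefficients$estimate[grepl("genotype", res$coefficients$term)]
  }, numeric(1))
  # mean of 25 independent estimates, each with SE ~ 0.2
  expect_lt(abs(mean(ests) - 0.5), 3 * sd(ests) / sqrt(25))
})

test_that("collinear designs and missing data are handled explicitly", {
  tab <- sim_table(40, seed = 6)
  tab$threshold_ipsi <- tab$threshold_contra   # exact collinearity
  expect_error(fit_glm(tab, "y"), "collinear")
  tab2 <- sim_table(40, seed = 7)
  tab2$y[1:5] <- NA
  res <- fit_glm(tab2, "y")
  expect_equal(res$n_dropped, 5)
  expect_equal(res$n_used, 35)
})

paired_table <- function(left, right) {
  n <- length(left)
  data.frame(animal_id = rep(sprintf("m%03d", seq_len(n)), each = 2),
             ear = rep(c("left", "right"), n),
             v = as.numeric(rbind(left, right)))
}

test_that("perfect within-animal pairing yields observed correlation 1", {
  vals <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  res <- within_between_randomization(paired_table(vals, vals), "v",
                                      n_perm = 200, seed = 1)
  expect_equal(res$observed, 1)
  expect_equal(res$n_animals, 7)
})

test_that("the randomization test is seed-reproducible and label-invariant", {
  set.seed(8)
  tab <- paired_table(rnorm(12), rnorm(12))
  r1 <- within_between_randomization(tab, "v", n_perm = 500, seed = 42)
  r2 <- within_between_randomization(tab, "v", n_perm = 500, seed = 42)
  expect_identical(r1$null, r2$null)
  expect_equal(length(r1$null), 500)
  # relabeling animals leaves the observed statistic unchanged
  tab2 <- tab
  tab2$animal_id <- factor(tab2$animal_id,
                           labels = sample(LETTERS[1:12]))
  r3 <- within_between_randomization(tab2, "v", n_perm = 500, seed = 42)
  expect_equal(r3$observed, r1$observed)
  expect_error(within_between_randomization(paired_table(1:3, 1:3), "v"),
               "at least 5")
})

test_that("two tiny samples give the exact rank-sum p-value", {
  res <- group_compare(c(1, 2, 3, 4, 5, 6),
                       c("a", "a", "a", "b", "b", "b"))
  expect_equal(res$method, "mann-whitney")
  expect_equal(res$p_value, 0.1)   # 2/20 arrangements as extreme
})

test_that("three-group comparisons run Kruskal-Wallis with Dunn post-hocs", {
  set.seed(9)
  v <- c(rnorm(10), rnorm(10) + 3, rnorm(10))
  g <- rep(c("WT", "Df1-NH", "Df1-HI"), each = 10)
  res <- group_compare(v, g)
  expect_equal(res$method, "kruskal-wallis")
  expect_lt(res$p_value, 0.01)
  expect_equal(nrow(res$pairwise), 3)
  # the shifted group differs from both others
  pw <- res$pairwise
  hit <- pw$p_value[(pw$group1 == "Df1-NH") | (pw$group2 == "Df1-NH")]
  expect_true(all(hit < 0.05))
  # z statistics against a hand-computed mean-rank oracle for one pair
  r <- rank(v)
  N <- length(v)
  ties <- table(r)
  vb <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  z_or <- (mean(r[g == "Df1-HI"]) - mean(r[g == "Df1-NH"])) /
    sqrt(vb * (1 / 10 + 1 / 10))
  expect_equal(pw$z[pw$group1 == "Df1-HI" & pw$group2 == "Df1-NH"], z_or,
               tolerance = 1e-12)
})

test_that("degenerate all-identical data are flagged, not rejected", {
  res <- group_compare(rep(2, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_error(group_compare(c(1, 2), c("a", "b")), "at least 2")
})

test_that("rank correlation handles monotone and constant inputs", {
  x <- c(2, 5, 1, 9, 7)
  expect_equal(rank_correlation(x, x)$rho, 1)
  expect_equal(rank_correlation(x, -x)$rho, -1)
  expect_warning(res <- rank_correlation(x, rep(1, 5)), "constant")
  expect_true(is.na(res$rho))
})

test_that("small-sample Spearman p matches exact enumeration", {
  # independent oracle: enumerate all 120 pairings of 5 ranks
  perm5 <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perm5 <- perm5[apply(perm5, 1, function(r) length(unique(r)) == 5), ]
  x <- c(10, 3, 25, 40, 8)
  y <- c(1.2, 0.5, 2.0, 1.9, 0.8)
  res <- rank_correlation(x, y)
  expect_equal(res$method, "exact")
  xr <- rank(x); yr <- rank(y)
  rho_obs <- cor(xr, yr)
  rho_all <- apply(perm5, 1, function(p) cor(xr, yr[p]))
  expect_equal(res$rho, rho_obs, tolerance = 1e-12)
  expect_equal(res$p_value, mean(abs(rho_all) >= abs(rho_obs) - 1e-12),
               tolerance = 1e-12)
})
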