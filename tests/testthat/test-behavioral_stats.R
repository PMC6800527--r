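block_data <- function(n = 300, noise = 0.1, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n * 3), n)
  x <- cbind(f[, 1], f[, 1], f[, 1], f[, 2], f[, 2], f[, 2],
             f[, 3], f[, 3], f[, 3]) + matrix(rnorm(n * 9, 0, noise), n)
  colnames(x) <- paste0("m", 1:9)
  x
}

test_that("PCA retains block components and satisfies its identities", {
  x <- block_data(seed = 3, noise = 0.01)
  p <- pca_varimax(x)
  expect_equal(p$retained_k, 3)
  expect_equal(sum(p$eigenvalues), 9, tolerance = 1e-8)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_true(all(p$eigenvalues[seq_len(p$retained_k)] > 1))
  # rotation matrix orthonormal
  expect_equal(crossprod(p$rotmat), diag(3), tolerance = 1e-8)
  # each rotated component loads > 0.9 on exactly one block
  blocks <- list(1:3, 4:6, 7:9)
  hit <- vapply(1:3, function(j) {
    big <- which(abs(p$loadings[, j]) > 0.9)
    which(vapply(blocks, function(b) setequal(big, b), TRUE))
  }, 0L)
  expect_true(setequal(hit, 1:3))
  # sign convention: dominant loading positive
  for (j in 1:3) expect_gt(max(p$loadings[, j]), 0)
  # communalities preserved by rotation (against unrotated loadings)
  ev <- eigen(cor(x), symmetric = TRUE)
  A <- ev$vectors[, 1:3] %*% diag(sqrt(ev$values[1:3]))
  expect_equal(unname(rowSums(p$loadings^2)), unname(rowSums(A^2)),
               tolerance = 1e-8)
  expect_equal(sum(p$explained_var) + 100 *
                 sum(p$eigenvalues[-(1:3)]) / 9, 100, tolerance = 1e-6)
  expect_equal(nrow(p$scores), nrow(x))
})

test_that("PCA input contracts are enforced", {
  x <- block_data()
  expect_error(pca_varimax(x[1:10, ]), "twice as many rows")
  xx <- x; xx[3, 5] <- NA
  expect_error(pca_varimax(xx), "missing")
  xc <- x; xc[, 2] <- 1
  expect_error(pca_varimax(xc), "constant")
})

test_that("varimax is monotone, idempotent on simple structure, and agrees with stats::varimax", {
  # perfect simple structure is a fixed point up to sign/permutation
  L0 <- rbind(diag(3) * 0.9, diag(3) * 0.8, diag(3) * 0.7)
  r <- varimax_rotate(L0)
  agg <- abs(t(r$loadings) %*% L0)
  expect_equal(sort(apply(agg, 1, max)), sort(diag(t(L0) %*% L0)),
               tolerance = 1e-6)
  set.seed(8)
  for (i in 1:5) {
    A <- matrix(rnorm(27), 9, 3)
    r <- varimax_rotate(A, tol = 1e-10)
    expect_true(all(diff(r$criterion) >= -1e-12))  # non-decreasing sweeps
    expect_true(r$converged)
    # independent reference: stats::varimax criterion value
    sv <- stats::varimax(A, normalize = TRUE, eps = 1e-10)
    expect_equal(varimax_criterion(r$loadings),
                 varimax_criterion(A %*% sv$rotmat), tolerance = 1e-6)
    expect_equal(crossprod(r$rotmat), diag(3), tolerance = 1e-10)
  }
})

test_that("split-plot ANOVA reproduces design degrees of freedom", {
  ns <- c(16, 16, 16, 15)
  subs <- unlist(lapply(1:4, function(g) sprintf("g%d_%02d", g,
                                                 seq_len(ns[g]))))
  meta <- data.frame(subject_id = subs, group = rep(paste0("g", 1:4), ns),
                     sex = unlist(lapply(ns, function(n)
                       rep(c("m", "f"), length.out = n))))
  d <- merge(meta, expand.grid(subject_id = subs, bin = 1:6,
                               view = c("3D", "top", "front")))
  set.seed(10); d$y <- rnorm(nrow(d))
  fit <- splitplot_anova(d, "y", "subject_id", c("group", "sex"),
                         c("bin", "view"))
  dfs <- function(e) unlist(anova_effect(fit, e)[, c("df_num", "df_den")])
  expect_equal(unname(dfs("group")), c(3, 55))
  expect_equal(unname(dfs("bin")), c(5, 275))
  expect_equal(unname(dfs("group:bin")), c(15, 275))
  expect_equal(unname(dfs("view")), c(2, 110))
  expect_equal(unname(dfs("bin:view")), c(10, 550))
})

test_that("two within levels reduce to the squared paired t statistic", {
  set.seed(11)
  n <- 14
  d <- data.frame(subject = factor(rep(1:n, 2)),
                  cond = factor(rep(c("a", "b"), each = n)),
                  y = rnorm(2 * n))
  fit <- splitplot_anova(d, "y", "subject", character(0), "cond")
  Fval <- anova_effect(fit, "cond")$statistic
  tt <- t.test(d$y[d$cond == "a"], d$y[d$cond == "b"], paired = TRUE)
  expect_equal(Fval, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(anova_effect(fit, "cond")$p, tt$p.value, tolerance = 1e-9)
})

test_that("subjects with incomplete within cells are dropped listwise", {
  d <- expand.grid(subject = factor(1:10), bin = factor(1:3))
  d$grp <- factor(rep(rep(c("a", "b"), each = 5), 3))
  set.seed(3); d$y <- rnorm(nrow(d))
  d <- d[!(d$subject == 1 & d$bin == 2), ]
  expect_warning(fit <- splitplot_anova(d, "y", "subject", "grp", "bin"),
                 "dropped")
  expect_equal(unname(unlist(anova_effect(fit, "grp")[, c("df_num",
                                                          "df_den")])),
               c(1, 7))
})

test_that("Dunnett adjustment matches a large Monte-Carlo oracle", {
  k <- 3; df <- 30
  corr <- matrix(0.5, k, k); diag(corr) <- 1  # balanced many-to-one
  set.seed(99)
  zz <- matrix(rnorm(1e6 * k), ncol = k) %*% chol(corr)
  tt <- abs(zz / sqrt(rchisq(1e6, df) / df))
  tmax <- pmax(tt[, 1], tt[, 2], tt[, 3])
  means <- c(control = 0, a = 2.2, b = 0.9, c = -1.4)
  # within design with n = 2, ms_error = 1: se = 1, so t = mean difference
  r <- dunnett_contrasts(means, n = 2, ms_error = 1, df_error = df,
                         control = "control", design = "within")
  for (i in 1:3) {
    expect_equal(r$p[i], mean(tmax >= abs(r$statistic[i])),
                 tolerance = 0.002)
  }
})

test_that("Dunnett p-values are monotone and bounded by Bonferroni", {
  means <- c(ctrl = 0, a = 0.4, b = 0.9, c = 1.5)
  r <- dunnett_contrasts(means, n = 10, ms_error = 1, df_error = 36,
                         control = "ctrl")
  ord <- order(abs(r$statistic))
  expect_true(all(diff(r$p[ord]) <= 1e-10))
  expect_true(all(r$p <= pmin(3 * r$p_unadj, 1) + 1e-6))
  expect_true(all(r$p >= r$p_unadj - 1e-10))
  expect_error(dunnett_contrasts(means, 10, 1, 36, control = "absent"),
               "absent")
})

test_that("residual diagnostics summarize strata and flag violations", {
  set.seed(21)
  d <- expand.grid(subject = factor(1:24), bin = factor(1:6))
  d$grp <- factor(rep(rep(c("a", "b"), each = 12), 6))
  d$y <- rnorm(nrow(d))
  fit <- splitplot_anova(d, "y", "subject", "grp", "bin")
  dg <- residual_diagnostics(fit)
  expect_true(length(dg) >= 2)
  for (s in names(dg)) expect_lt(abs(dg[[s]]$skewness), 0.8)
  # between-cell residuals (subject stratum) sum to zero within cells
  pr <- stats::proj(fit$fit)
  rsub <- pr[["subject"]][, "Residuals"]
  sums <- tapply(rsub, fit$data$grp, sum)
  expect_equal(unname(as.numeric(sums)), c(0, 0), tolerance = 1e-8)
  # exponential response raises the kurtosis flag somewhere
  d$y <- rexp(nrow(d), rate = 0.2)
  fit2 <- splitplot_anova(d, "y", "subject", "grp", "bin")
  dg2 <- residual_diagnostics(fit2)
  expect_true(any(vapply(dg2, function(s) s$kurtosis_flag ||
                           s$skewness_flag, TRUE)))
})
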