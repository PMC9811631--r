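test_that("REML matches closed-form ANOVA estimators on balanced one-way data", {
  set.seed(42)
  for (i in 1:5) {
    k <- 10; m <- 10
    g <- gl(k, m)
    y <- rep(rnorm(k, 0, sqrt(2)), each = m) + rnorm(k * m)
    X <- matrix(1, k * m, 1)
    Z <- list(group = outer(g, levels(g), "==") * 1)
    fit <- reml_fit(y, X, Z)
    oracle <- oracle_oneway(y, g)
    expect_equal(fit$sigma2[["group"]], oracle[["between"]],
                 tolerance = 1e-6)
    expect_equal(fit$sigma2[["residual"]], oracle[["within"]],
                 tolerance = 1e-6)
  }
})

test_that("profiled likelihood equals the brute-force dense computation", {
  set.seed(7)
  sim <- small_sim(seed = 19)
  m <- build_sge_matrices(dyadic_table(sim), "nodule_proportion")
  for (keep in list(1:12, 5:30, 1:25)) { # tiny instances, <= 30 rows
    y <- m$y[keep]; X <- m$X[keep, , drop = FALSE]
    Z <- lapply(m$Z, function(z) z[keep, , drop = FALSE])
    fit <- reml_fit(y, X, Z)
    bf_at_fit <- bruteforce_reml_loglik(
      y, X, Z, fit$sigma2[names(Z)], fit$sigma2[["residual"]])
    expect_equal(fit$loglik, bf_at_fit, tolerance = 1e-8)
  }
})

test_that("signed incidence equals explicit correlated bivariate effects", {
  # proportion-style data, both orientations, corr -1; and shoot-style +1
  sim <- small_sim(seed = 23)
  dy <- dyadic_table(sim)
  for (trait in c("nodule_proportion", "shoot_mass")) {
    m <- build_sge_matrices(dy, trait)
    keep <- 1:14
    y <- m$y[keep]; X <- m$X[keep, , drop = FALSE]
    Z <- lapply(m$Z, function(z) z[keep, , drop = FALSE])
    fit <- reml_fit(y, X, Z)
    d <- dy[!is.na(dy$competitor_strain) &
              dy$focal_strain < dy$competitor_strain, ][keep, ]
    rho <- if (trait == "nodule_proportion") -1 else 1
    bf <- bruteforce_bivariate_loglik(
      y, X, d$focal_strain, d$competitor_strain, rho,
      s2g = fit$sigma2[["strain"]],
      Zother = Z[c("gxg", "block")],
      s2other = fit$sigma2[c("gxg", "block")],
      s2e = fit$sigma2[["residual"]])
    expect_equal(fit$loglik, bf, tolerance = 1e-8)
  }
})

test_that("unconstrained fit agrees with lme4 on the same model", {
  skip_if_not_installed("lme4")
  sim <- small_sim(seed = 31)
  m <- build_sge_matrices(dyadic_table(sim), "nodule_number")
  fit <- reml_fit(m$y, m$X, m$Z)
  pick <- function(z) colnames(z)[max.col(z, ties.method = "first")]
  d <- data.frame(y = m$y, marker = m$X[, 2],
                  dge = pick(m$Z$dge), sge = pick(m$Z$sge),
                  gxg = pick(m$Z$gxg), block = pick(m$Z$block),
                  pot = pick(m$Z$pot))
  lf <- lme4::lmer(
    y ~ marker + (1 | dge) + (1 | sge) + (1 | gxg) + (1 | block) +
      (1 | pot),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  lv <- setNames(vc$vcov, vc$grp)
  for (k in c("dge", "sge", "gxg", "block", "pot")) {
    expect_equal(fit$sigma2[[k]], lv[[k]], tolerance = 0.02)
  }
})

test_that("null structure collapses all group variances to the boundary", {
  set.seed(99)
  n <- 120
  y <- rnorm(n)
  g1 <- rep(1:6, each = 20); g2 <- rep(1:20, 6)
  Z <- list(a = outer(g1, 1:6, "==") * 1, b = outer(g2, 1:20, "==") * 1)
  fit <- reml_fit(y, matrix(1, n, 1), Z)
  # group variances stay within sampling error of the zero boundary and the
  # total phenotypic variance is preserved
  expect_lt(fit$sigma2[["a"]], 0.15)
  expect_lt(fit$sigma2[["b"]], 0.15)
  expect_equal(sum(fit$sigma2), var(y), tolerance = 0.1)
})

test_that("model matrices implement the constraint geometry", {
  sim <- simulate_experiment(sim_config(seed = 4))
  dy <- dyadic_table(sim)
  mn <- build_sge_matrices(dy, "nodule_number")
  expect_equal(mn$n_rows, 896) # 28 pairs x 2 reciprocal x 8 blocks x 2 rows
  expect_equal(ncol(mn$Z$pot), 448)
  mp <- build_sge_matrices(dy, "nodule_proportion")
  expect_true(all(rowSums(mp$Z$strain) == 0)) # +1 focal, -1 competitor
  ms <- build_sge_matrices(dy, "shoot_mass")
  expect_true(all(rowSums(ms$Z$strain) == 2)) # +1 each strain
  expect_identical(ms$transform, "log")
})

test_that("nested LRTs are monotone and identities hold", {
  sim <- small_sim(seed = 47)
  fit <- fit_sge(dyadic_table(sim), "nodule_number")
  for (cmp in c("DGE", "main SGE", "G x G SGE", "block", "plant pot")) {
    lrt <- lrt_component(fit, cmp)
    expect_gte(lrt$chisq, 0)
    expect_equal(lrt$df, 1L)
    expect_equal(lrt$p_value,
                 pchisq(lrt$chisq, 1, lower.tail = FALSE))
  }
  # component not in the model: identical fits, chi2 = 0, p = 1
  fp <- fit_sge(dyadic_table(sim), "nodule_proportion")
  lrt0 <- lrt_component(fp, "plant pot")
  expect_equal(lrt0$chisq, 0)
  expect_equal(lrt0$p_value, 1)
  expect_error(lrt_component(fit, "residual"), "residual")
  # constrained trait: DGE and SGE are one shared test
  expect_equal(lrt_component(fp, "DGE")$chisq,
               lrt_component(fp, "main SGE")$chisq)
})

test_that("variance proportions sum to one in every fit", {
  sim <- small_sim(seed = 53)
  for (tr in c("nodule_number", "nodule_proportion", "shoot_mass")) {
    f <- fit_sge(dyadic_table(sim), tr)
    expect_equal(sum(f$vc$proportion), 1, tolerance = 1e-9)
    expect_true(all(f$vc$variance >= 0))
  }
})

test_that("variance_table assembles the cross-trait partition", {
  sim <- small_sim(seed = 59)
  dy <- dyadic_table(sim)
  fits <- list(nodule_number = fit_sge(dy, "nodule_number"),
               shoot_mass = fit_sge(dy, "shoot_mass"))
  vt <- variance_table(fits)
  expect_setequal(unique(vt$trait), c("nodule_number", "shoot_mass"))
  sums <- tapply(vt$pct_variation, vt$trait, sum)
  expect_true(all(abs(sums - 100) < 0.1))
  expect_true(all(is.na(vt$chisq[vt$component == "residual"])))
})
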