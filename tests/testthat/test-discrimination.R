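test_that("genotypic means are plain per-strain averages", {
  d <- tibble::tibble(
    pot_id = c("p1", "p2", "p3"), block = 1,
    focal_strain = c("A", "A", "B"), competitor_strain = NA_character_,
    focal_marker = "red", nodule_score = c(2, 4, 6),
    nodule_proportion = NA_real_, shoot_mass_g = c(0.5, 0.7, 0.2),
    treatment = "one_strain")
  gm <- genotypic_means(d, "nodule_number", "one_strain")
  expect_equal(gm$mean[gm$strain == "A"], 3)
  expect_equal(gm$n[gm$strain == "A"], 2L)
  expect_equal(gm$mean[gm$strain == "B"], 6)
})

test_that("strains with no observations yield NA with a warning", {
  d <- tibble::tibble(
    pot_id = c("p1", "p2"), block = 1,
    focal_strain = c("A", "B"), competitor_strain = c("B", "A"),
    focal_marker = c("red", "green"), nodule_score = c(3, 1),
    nodule_proportion = c(0.75, 0.25), shoot_mass_g = 0.4,
    treatment = "two_strain")
  expect_warning(gm <- genotypic_means(d, "shoot_mass", "one_strain"),
                 "No shoot_mass")
  expect_true(all(is.na(gm$mean)))
})

test_that("zero-noise simulation recovers the configured expectations", {
  cfg <- sim_config(n_strains = 4, n_blocks = 2, seed = 3,
                    choice_strength = 0, marker_effect = 0,
                    nodule_vc = c(dge = 0, sge = 0, gxg = 0, block = 0,
                                  pot = 0, resid = 0),
                    shoot_vc = c(gxg = 0, block = 0, resid = 0),
                    discretize = FALSE)
  sim <- simulate_experiment(cfg)
  gm <- genotypic_means(sim, "nodule_number", "two_strain")
  expect_true(all(abs(gm$mean - cfg$mean_total_nodules / 2) < 1e-9))
  gw <- genotypic_means(sim, "shoot_mass", "one_strain")
  expect_equal(gw$mean,
               exp(cfg$shoot_mean_log +
                     2 * cfg$shoot_quality_link * sort(cfg$strain_quality)),
               tolerance = 1e-12)
})

test_that("means regression matches the normal-equations oracle", {
  set.seed(12)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    tab <- tibble::tibble(strain = paste0("S", 1:n),
                          x = rnorm(n), y = rnorm(n))
    r <- fit_means_regression(tab, "x", "y")
    o <- ols_oracle(tab$x, tab$y)
    expect_equal(r$slope, o$slope, tolerance = 1e-10)
    expect_equal(r$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(r$f_statistic, o$f, tolerance = 1e-10)
    expect_equal(r$p_value, o$p, tolerance = 1e-10)
    expect_equal(r$r_squared, o$r2, tolerance = 1e-10)
    expect_equal(r$df2, n - 2L)
  }
})

test_that("F p-values agree with the F distribution at known quantiles", {
  # p = SF of F(1, 6): spot-check three quantiles computed independently
  # from the Beta representation: F = (x/1) / ((1-x)/6) with x ~ Beta(1/2, 3)
  for (f0 in c(1, 5.99, 20)) {
    p_beta <- 1 - stats::pbeta(f0 / (f0 + 6), 1 / 2, 3)
    expect_equal(stats::pf(f0, 1, 6, lower.tail = FALSE), p_beta,
                 tolerance = 1e-12)
  }
})

test_that("collinear and flat edge cases behave as specified", {
  tab <- tibble::tibble(strain = paste0("S", 1:8), x = 1:8, y = 2 * (1:8))
  r <- fit_means_regression(tab, "x", "y")
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  expect_lt(r$p_value, 1e-12)

  flat <- tibble::tibble(strain = paste0("S", 1:6), x = 1:6, y = 3)
  rf <- fit_means_regression(flat, "x", "y")
  expect_equal(rf$slope, 0)
  expect_equal(rf$f_statistic, 0)
  expect_equal(rf$p_value, 1)

  expect_error(fit_means_regression(tab[1:2, ], "x", "y"), ">= 3")
  bad <- tibble::tibble(strain = paste0("S", 1:5), x = 1, y = rnorm(5))
  expect_error(fit_means_regression(bad, "x", "y"), "zero variance")
})

test_that("derived per-pot traits follow the ratio definitions", {
  d <- tibble::tibble(
    pot_id = c("p1", "p2", "p3"), block = 1,
    focal_strain = "A", competitor_strain = NA_character_,
    focal_marker = "red", nodule_score = c(10, 0, 4),
    nodule_proportion = NA_real_, shoot_mass_g = c(0.5, 0.3, 0),
    treatment = "one_strain")
  dt <- derived_traits(d)
  expect_equal(dt$nodules_per_gram[dt$pot_id == "p1"], 20)
  expect_equal(dt$shoot_per_nodule[dt$pot_id == "p1"], 0.05)
  expect_true(is.na(dt$shoot_per_nodule[dt$pot_id == "p2"])) # 0 nodules
  expect_true(is.na(dt$nodules_per_gram[dt$pot_id == "p3"])) # 0 shoot
  expect_equal(unname(attr(dt, "n_excluded")["shoot_per_nodule"]), 1L)
})

test_that("intra-nodule CFU shares are computed per nodule", {
  sim <- small_sim(seed = 67)
  cfu <- tibble::tibble(
    pot_id = sim$plants$pot_id[sim$plants$treatment == "two_strain"][1],
    nodule_id = "n1", class = "mixed_colour",
    strain = c(sim$plants$strain_a[sim$plants$treatment == "two_strain"][1],
               sim$plants$strain_b[sim$plants$treatment == "two_strain"][1]),
    cfu = c(300, 100))
  ds <- sim
  ds$cfu <- cfu
  tab <- rhizosge:::cfu_strain_means(ds)
  expect_equal(tab$cfu_share_mixed_two[!is.na(tab$cfu_share_mixed_two)],
               c(0.75, 0.25))
})

test_that("genotypic means ignore row order and marker labels when inert", {
  cfg <- sim_config(n_strains = 4, n_blocks = 3, seed = 71,
                    marker_effect = 0)
  sim <- simulate_experiment(cfg)
  dy <- dyadic_table(sim)
  gm1 <- genotypic_means(dy, "nodule_number", "two_strain")
  gm2 <- genotypic_means(dy[sample(nrow(dy)), ], "nodule_number",
                         "two_strain")
  expect_equal(gm1, gm2)
})
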