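test_that("the same seed reproduces the dataset exactly", {
  a <- simulate_experiment(sim_config(n_strains = 4, n_blocks = 2, seed = 5))
  b <- simulate_experiment(sim_config(n_strains = 4, n_blocks = 2, seed = 5))
  expect_identical(a$plants, b$plants)
  expect_identical(a$nodules, b$nodules)
  expect_identical(a$observations, b$observations)
  expect_identical(a$cfu, b$cfu)
  c <- simulate_experiment(sim_config(n_strains = 4, n_blocks = 2, seed = 6))
  expect_false(identical(a$observations, c$observations))
})

test_that("degenerate config (no variance, no choice) splits pots evenly", {
  cfg <- sim_config(n_strains = 4, n_blocks = 2, seed = 3,
                    choice_strength = 0, marker_effect = 0,
                    nodule_vc = c(dge = 0, sge = 0, gxg = 0, block = 0,
                                  pot = 0, resid = 0),
                    discretize = FALSE)
  sim <- simulate_experiment(cfg)
  two <- sim$observations[!is.na(sim$observations$competitor_strain), ]
  expect_true(all(abs(two$nodule_proportion - 0.5) < 1e-12))
  # expected scores identical across the pot
  expect_lt(stats::sd(two$nodule_score), 1e-12)
})

test_that("simulated data passes the data-model validation", {
  for (seed in c(1, 21)) {
    sim <- simulate_experiment(sim_config(n_strains = 5, n_blocks = 3,
                                          seed = seed))
    expect_true(validate_experiment(sim, observations = sim$observations))
  }
})

test_that("negative variance components are rejected at config time", {
  expect_error(sim_config(nodule_vc = c(dge = -1, sge = 1, gxg = 1,
                                        block = 1, pot = 1, resid = 1)),
               "non-negative")
})

test_that("block effect variance matches its target across many blocks", {
  cfg <- sim_config(n_strains = 2, n_blocks = 300, seed = 8,
                    nodule_vc = c(dge = 0, sge = 0, gxg = 0, block = 9,
                                  pot = 0, resid = 1))
  sim <- simulate_experiment(cfg)
  expect_equal(var(sim$truth$block_nodule), 9,
               tolerance = 0.2) # Monte-Carlo error at 300 blocks
})

test_that("partner-choice signature emerges when quality drives nodulation", {
  slopes <- sapply(1:5, function(i) {
    sim <- simulate_experiment(sim_config(n_strains = 6, n_blocks = 3,
                                          seed = 40 + i))
    tab <- genotypic_mean_table(sim)
    fit_means_regression(tab, "shoot_mass_one",
                         "nodule_proportion_two")$slope
  })
  expect_true(all(slopes > 0))
})

test_that("CFU simulation is seeded and linked to quality", {
  sim <- small_sim(seed = 13)
  sim2 <- small_sim(seed = 13)
  expect_identical(sim$cfu, sim2$cfu)
  expect_true(all(sim$cfu$cfu >= 0))
  expect_true(all(sim$cfu$class %in% c("single_colour", "mixed_colour")))
  # null link: regression of strain mean CFU on quality is flat on average
  ps <- sapply(1:6, function(i) {
    s <- simulate_experiment(sim_config(n_strains = 6, n_blocks = 3,
                                        seed = 60 + i, cfu_link = 0,
                                        cfu_blocks = 3))
    sanctions_summaries(s)$among_nodule$p_value
  })
  expect_true(all(ps >= 0 & ps <= 1))
  expect_gt(mean(ps), 0.2) # no systematic rejection under the null
})

test_that("strong CFU link yields positive sanctions regressions", {
  s <- simulate_experiment(sim_config(n_strains = 8, n_blocks = 4,
                                      seed = 77, cfu_link = 1,
                                      cfu_blocks = 4))
  sanc <- sanctions_summaries(s)
  expect_gt(sanc$among_nodule$slope, 0)
  expect_gt(sanc$intra_nodule$slope, 0)
  expect_lt(sanc$among_nodule$p_value, 0.05)
  expect_lt(sanc$intra_nodule$p_value, 0.05)
})
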