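test_that("the full design reproduces the experiment's arithmetic", {
  d <- generate_design(8, 8, 2)
  expect_equal(nrow(d), 592)
  expect_equal(unname(table(d$block)), rep(74L, 8), ignore_attr = TRUE)
  two <- d[d$treatment == "two_strain", ]
  pairs <- unique(paste(two$strain_a, two$strain_b))
  expect_equal(length(pairs), 28)
  # each pair appears twice per block with reciprocal marker assignments
  per <- dplyr::count(two, block, strain_a, strain_b)
  expect_true(all(per$n == 2))
  recip <- dplyr::count(two, strain_a, strain_b, marker_a)
  expect_true(all(recip$n == 8)) # once per block per orientation
})

test_that("a 2-strain, 1-block design enumerates by hand", {
  d <- generate_design(2, 1, 2)
  expect_equal(nrow(d), 8) # 4 one-strain + 2 reciprocal pair pots + 2 ctrl
  expect_equal(sum(d$treatment == "one_strain"), 4)
  expect_equal(sum(d$treatment == "two_strain"), 2)
  expect_equal(sum(d$treatment == "control"), 2)
})

test_that("design counts follow B(2S + 2*C(S,2) + C) and stay balanced", {
  for (s in 2:6) {
    b <- 3; ctl <- 1
    d <- generate_design(s, b, ctl)
    expect_equal(nrow(d), b * (2 * s + 2 * choose(s, 2) + ctl))
    expect_false(any(duplicated(d$pot_id)))
    # every strain appears equally often per block (one-strain + pair pots)
    cnt <- table(c(d$strain_a, d$strain_b), c(d$block, d$block))
    expect_true(all(cnt == cnt[1, 1]))
  }
})

test_that("design generation is deterministic and rejects bad inputs", {
  expect_identical(generate_design(5, 2, 1), generate_design(5, 2, 1))
  expect_error(generate_design(1, 3), "n_strains")
  expect_error(generate_design(4, 3, markers = c("red", "green", "blue")),
               "two distinct")
})

test_that("nodule scores give 1 per single and 0.5 per mixed nodule", {
  d <- generate_design(2, 1, 0, strain_ids = c("A", "B"))
  pot <- d$pot_id[d$treatment == "two_strain"][1]
  tal <- tibble::tibble(pot_id = pot, strain = c("A", "B"),
                        singles = c(3, 2), mixed = 1)
  obs <- tally_to_observations(tal, d)
  expect_equal(obs$nodule_score, c(3.5, 2.5))
  expect_equal(obs$nodule_proportion, c(3.5 / 6, 2.5 / 6))
  expect_equal(sum(obs$nodule_score), 3 + 2 + 1) # pot total
  expect_equal(sum(obs$nodule_proportion), 1)

  # empty pot: zero scores, undefined proportions
  tal0 <- tibble::tibble(pot_id = pot, strain = c("A", "B"),
                         singles = 0, mixed = 0)
  obs0 <- tally_to_observations(tal0, d)
  expect_equal(obs0$nodule_score, c(0, 0))
  expect_true(all(is.na(obs0$nodule_proportion)))

  # all-mixed pot splits evenly
  talm <- tibble::tibble(pot_id = pot, strain = c("A", "B"),
                         singles = 0, mixed = 4)
  obsm <- tally_to_observations(talm, d)
  expect_equal(obsm$nodule_score, c(2, 2))
  expect_equal(obsm$nodule_proportion, c(0.5, 0.5))
})

test_that("tallies for strains never inoculated are rejected", {
  d <- generate_design(3, 1, 0)
  pot <- d$pot_id[d$treatment == "two_strain"][1]
  bad <- tibble::tibble(pot_id = pot,
                        strain = "S99", singles = 1, mixed = 0)
  expect_error(tally_to_observations(bad, d), "not inoculated")
})

test_that("two-strain proportions always sum to one when nodules formed", {
  sim <- small_sim()
  chk <- sim$observations |>
    dplyr::filter(!is.na(competitor_strain), !is.na(nodule_proportion)) |>
    dplyr::summarise(s = sum(nodule_proportion), .by = pot_id)
  expect_true(all(abs(chk$s - 1) < 1e-12))
})
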