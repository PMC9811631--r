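#' Configuration for a synthetic co-inoculation experiment
#'
#' Bundles every knob of the generative model: design sizes, the latent
#' strain quality axis, variance components for the nodulation and shoot
#' mass traits, the strength of the quality-to-nodulation link (partner
#' choice) and the quality-to-CFU link (sanctions). The defaults emulate
#' the full greenhouse design (8 strains x 2 markers x 8 blocks, reciprocal
#' two-strain marker assignments, 2 controls per block) with
#' nodule-number variance components in the ratio 32 : 14 : 7 : 3 : 7 : 37
#' for DGE : SGE : GxG : block : pot : residual.
#'
#' @param n_strains,n_blocks,n_controls_per_block Design sizes.
#' @param seed Integer seed; fully determines the simulated dataset.
#' @param strain_quality Numeric vector (length `n_strains`) of latent
#'   strain qualities (standardised units). Default: evenly spaced values
#'   centred on 0 with unit standard deviation.
#' @param mean_total_nodules Expected total nodule count per two-strain pot.
#' @param mixed_fraction Expected fraction of a pot's nodules that are
#'   mixed-colour (co-infected).
#' @param choice_strength Log-odds of a strain's expected nodule share per
#'   unit quality difference (the partner-choice link); 0 disables choice.
#' @param marker_effect Additive fluorescent-marker effect on the latent
#'   nodule count (second marker relative to first); default 0.
#' @param decouple_choice If `TRUE`, nodulation success is driven by a
#'   permuted copy of the quality axis, severing the link between partner
#'   choice and host benefit (a no-benefit null).
#' @param nodule_vc Named variance components for the latent focal-strain
#'   nodule count: `dge`, `sge`, `gxg`, `block`, `pot`, `resid`.
#' @param shoot_mean_log Mean log shoot mass (log grams) of an inoculated
#'   plant with average-quality symbionts.
#' @param shoot_quality_link Increase in log shoot mass per unit of
#'   (occupancy-weighted) mean symbiont quality, per symbiont.
#' @param shoot_vc Named variance components on the log shoot mass scale:
#'   `gxg` (unordered-pair interaction), `block`, `resid`.
#' @param cfu_meanlog,cfu_sdlog Log-normal parameters for CFU per nodule.
#' @param cfu_link Increase in log CFU per unit strain quality (the
#'   sanctions link); also tilts the within-nodule CFU share in mixed
#'   nodules; 0 disables sanctions.
#' @param cfu_blocks Number of blocks with nodule-level CFU phenotyping.
#' @param discretize If `TRUE` (default) latent nodule counts are converted
#'   to integer single/mixed colour tallies and scores are recomputed from
#'   the tallies; if `FALSE` scores stay continuous (pure Gaussian mode,
#'   used for exact parameter-recovery checks).
#'
#' @return A list with class `"sge_sim_config"`.
#' @export
sim_config <- function(n_strains = 8, n_blocks = 8, n_controls_per_block = 2,
                       seed = 1,
                       strain_quality = NULL,
                       mean_total_nodules = 40,
                       mixed_fraction = 0.1,
                       choice_strength = 1,
                       marker_effect = 0,
                       decouple_choice = FALSE,
                       nodule_vc = c(dge = 16, sge = 7, gxg = 3.5,
                                     block = 1.5, pot = 3.5, resid = 18.5),
                       shoot_mean_log = log(0.3),
                       shoot_quality_link = 0.3,
                       shoot_vc = c(gxg = 0.016, block = 0.027, resid = 0.19),
                       cfu_meanlog = 11, cfu_sdlog = 0.5, cfu_link = 0.5,
                       cfu_blocks = 2,
                       discretize = TRUE) {
  if (is.null(strain_quality)) {
    q <- seq(-1, 1, length.out = n_strains)
    strain_quality <- as.numeric(scale(q))
  }
  if (length(strain_quality) != n_strains) {
    abort("`strain_quality` must have one value per strain.")
  }
  nodule_vc <- nodule_vc[c("dge", "sge", "gxg", "block", "pot", "resid")]
  shoot_vc <- shoot_vc[c("gxg", "block", "resid")]
  if (anyNA(nodule_vc) || anyNA(shoot_vc)) {
    abort("Variance components must be complete named vectors.")
  }
  if (any(nodule_vc < 0) || any(shoot_vc < 0)) {
    abort("Variance components must be non-negative.")
  }
  structure(
    list(n_strains = n_strains, n_blocks = n_blocks,
         n_controls_per_block = n_controls_per_block, seed = seed,
         strain_quality = strain_quality,
         mean_total_nodules = mean_total_nodules,
         mixed_fraction = mixed_fraction,
         choice_strength = choice_strength, marker_effect = marker_effect,
         decouple_choice = decouple_choice,
         nodule_vc = nodule_vc, shoot_mean_log = shoot_mean_log,
         shoot_quality_link = shoot_quality_link, shoot_vc = shoot_vc,
         cfu_meanlog = cfu_meanlog, cfu_sdlog = cfu_sdlog,
         cfu_link = cfu_link, cfu_blocks = cfu_blocks,
         discretize = discretize),
    class = "sge_sim_config")
}

rnorm0 <- function(n, var) {
  if (var > 0) rnorm(n, 0, sqrt(var)) else numeric(n)
}

#' Simulate a complete synthetic co-inoculation experiment
#'
#' Generates the full design, then draws Gaussian latent phenotypes with
#' direct genetic effects (focal strain), main social genetic effects
#' (competitor strain), ordered-pair genotype-by-genotype interactions,
#' block, pot and residual terms. The expected nodule share of a strain in
#' a two-strain pot is a logistic function of `choice_strength` times the
#' strain quality difference; log shoot mass gains
#' `2 * shoot_quality_link` times the nodule-occupancy-weighted mean
#' quality of the two symbionts (so the benefit of hosting a good strain
#' flows through nodule occupancy), plus an unordered-pair interaction,
#' block and residual terms. All latent draws are returned in `$truth` so
#' recovery can be tested.
#'
#' @param config A [sim_config()] object.
#' @return A list with class `"rhizo_sim"` (inheriting `"rhizo_data"`):
#'   `plants` (design with simulated `shoot_mass_g`), `nodules` (colour
#'   tallies; `NULL` in pure Gaussian mode), `observations` (per-strain
#'   dyadic records), `cfu` (nodule-level CFU counts for the phenotyped
#'   blocks), and `truth` (latent effects and the config).
#' @examples
#' sim <- simulate_experiment(sim_config(n_strains = 4, n_blocks = 2, seed = 7))
#' head(sim$observations)
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sge_sim_config"))
  set.seed(substream_seed(config$seed, "phenotypes"))

  plants <- generate_design(config$n_strains, config$n_blocks,
                            config$n_controls_per_block)
  strains <- attr(plants, "strain_ids")
  markers <- attr(plants, "markers")
  q <- setNames(config$strain_quality, strains)
  q_nod <- q
  if (config$decouple_choice) {
    q_nod <- setNames(sample(q), strains)
  }
  vc <- config$nodule_vc
  svc <- config$shoot_vc

  d <- setNames(rnorm0(length(strains), vc[["dge"]]), strains)
  s <- setNames(rnorm0(length(strains), vc[["sge"]]), strains)
  op <- expand.grid(focal = strains, comp = strains,
                    stringsAsFactors = FALSE)
  op <- op[op$focal != op$comp, ]
  g_ord <- setNames(rnorm0(nrow(op), vc[["gxg"]]),
                    paste(op$focal, op$comp, sep = ":"))
  b_nod <- setNames(rnorm0(config$n_blocks, vc[["block"]]),
                    seq_len(config$n_blocks))
  up <- utils::combn(strains, 2)
  up_id <- paste(up[1, ], up[2, ], sep = ":")
  g_shoot <- setNames(rnorm0(length(up_id), svc[["gxg"]]), up_id)
  b_shoot <- setNames(rnorm0(config$n_blocks, svc[["block"]]),
                      seq_len(config$n_blocks))

  two <- plants %>% filter(.data$treatment == "two_strain")
  one <- plants %>% filter(.data$treatment == "one_strain")
  Tn <- config$mean_total_nodules
  cs <- config$choice_strength
  me <- config$marker_effect

  p_pot <- setNames(rnorm0(nrow(two), vc[["pot"]]), two$pot_id)
  share_a <- plogis(cs * (q_nod[two$strain_a] - q_nod[two$strain_b]))
  lat <- function(strain, comp, marker, share, pot_id, block) {
    Tn * share + me * (marker == markers[2]) +
      d[strain] + s[comp] + g_ord[paste(strain, comp, sep = ":")] +
      b_nod[as.character(block)] + p_pot[pot_id] +
      rnorm0(length(strain), vc[["resid"]])
  }
  y_a <- pmax(0, lat(two$strain_a, two$strain_b, two$marker_a, share_a,
                     two$pot_id, two$block))
  y_b <- pmax(0, lat(two$strain_b, two$strain_a, two$marker_b, 1 - share_a,
                     two$pot_id, two$block))

  # one-strain pots: same quality link (doubled logistic so q = 0 gives the
  # two-strain total), DGE and block effects, pot variance absorbed into
  # the residual since there is a single observation per pot
  y_one <- pmax(0, 2 * Tn * plogis(cs * q_nod[one$strain_a]) +
                  me * (one$marker_a == markers[2]) +
                  2 * d[one$strain_a] + b_nod[as.character(one$block)] +
                  rnorm0(nrow(one), vc[["pot"]] + vc[["resid"]]))

  if (config$discretize) {
    N2 <- round(y_a + y_b)
    m2 <- rbinom(length(N2), N2, config$mixed_fraction)
    sA <- pmax(0, pmin(N2 - m2, round(y_a - 0.5 * m2)))
    sB <- N2 - m2 - sA
    nodules <- bind_rows(
      tibble(pot_id = rep(two$pot_id, 2),
             strain = c(two$strain_a, two$strain_b),
             singles = c(sA, sB), mixed = rep(m2, 2)),
      tibble(pot_id = one$pot_id, strain = one$strain_a,
             singles = round(y_one), mixed = 0)
    ) %>% arrange(.data$pot_id, .data$strain)
    observations <- tally_to_observations(nodules, plants)
  } else {
    nodules <- NULL
    obs_two <- tibble(
      pot_id = rep(two$pot_id, 2), block = rep(two$block, 2),
      focal_strain = c(two$strain_a, two$strain_b),
      competitor_strain = c(two$strain_b, two$strain_a),
      focal_marker = c(two$marker_a, two$marker_b),
      nodule_score = c(y_a, y_b))
    obs_one <- tibble(
      pot_id = one$pot_id, block = one$block,
      focal_strain = one$strain_a, competitor_strain = NA_character_,
      focal_marker = one$marker_a, nodule_score = y_one)
    observations <- bind_rows(obs_two, obs_one) %>%
      group_by(.data$pot_id) %>%
      mutate(tot = sum(.data$nodule_score),
             nodule_proportion = ifelse(.data$tot > 0,
                                        .data$nodule_score / .data$tot,
                                        NA_real_)) %>%
      ungroup() %>% select(-"tot") %>%
      arrange(.data$pot_id, .data$focal_strain)
  }

  # realised occupancy of strain_a in each two-strain pot (0.5 if no nodules)
  occ_a <- observations %>%
    filter(.data$pot_id %in% two$pot_id,
           .data$focal_strain == two$strain_a[match(.data$pot_id,
                                                    two$pot_id)]) %>%
    arrange(match(.data$pot_id, two$pot_id)) %>%
    pull(.data$nodule_proportion)
  occ_a[is.na(occ_a)] <- 0.5

  pair_key <- paste(two$strain_a, two$strain_b, sep = ":")
  log_w_two <- config$shoot_mean_log +
    2 * config$shoot_quality_link *
      (occ_a * q[two$strain_a] + (1 - occ_a) * q[two$strain_b]) +
    g_shoot[pair_key] + b_shoot[as.character(two$block)] +
    rnorm0(nrow(two), svc[["resid"]])
  log_w_one <- config$shoot_mean_log +
    2 * config$shoot_quality_link * q[one$strain_a] +
    b_shoot[as.character(one$block)] + rnorm0(nrow(one), svc[["resid"]])

  plants$shoot_mass_g[match(two$pot_id, plants$pot_id)] <- exp(log_w_two)
  plants$shoot_mass_g[match(one$pot_id, plants$pot_id)] <- exp(log_w_one)
  ctrl <- plants$treatment == "control"
  plants$shoot_mass_g[ctrl] <- exp(-2.5 + 0.3 * rnorm(sum(ctrl)))

  sim <- structure(
    list(plants = plants, nodules = nodules, observations = observations,
         cfu = NULL,
         truth = list(quality = q, quality_nodulation = q_nod, dge = d,
                      sge = s, gxg_ordered = g_ord, block_nodule = b_nod,
                      pot = p_pot, gxg_shoot = g_shoot,
                      block_shoot = b_shoot, config = config)),
    class = c("rhizo_sim", "rhizo_data"))
  sim$cfu <- simulate_cfu(config, sim)
  validate_experiment(sim, observations = sim$observations)
  sim
}

#' Simulate nodule-level CFU counts
#'
#' Emulates destructive nodule phenotyping in the first `cfu_blocks`
#' blocks: one single-colour nodule per one-strain pot, and up to two
#' single-colour nodules plus one mixed-colour nodule per two-strain pot,
#' sampled from the pot's tally. CFU per single-colour nodule is log-normal
#' with log-mean `cfu_meanlog + cfu_link * quality(strain)`; a mixed
#' nodule's total CFU is split binomially with expected share logistic in
#' `cfu_link` times the within-nodule quality difference.
#'
#' @param config A [sim_config()] object.
#' @param dataset A simulated dataset containing `plants` and `nodules`
#'   tallies (i.e. `discretize = TRUE`).
#' @return A tibble `pot_id`, `nodule_id`, `class`, `strain`, `cfu`
#'   (one row per strain per nodule), or `NULL` if `cfu_blocks` is 0.
#' @export
simulate_cfu <- function(config, dataset) {
  if (config$cfu_blocks < 1) return(NULL)
  if (is.null(dataset$nodules)) {
    if (config$discretize) abort("Dataset has no nodule tallies.")
    return(NULL) # pure Gaussian mode has no discrete nodules to sample
  }
  set.seed(substream_seed(config$seed, "cfu"))
  q <- dataset$truth$quality %||%
    setNames(config$strain_quality, sort(unique(dataset$nodules$strain)))
  plants <- dataset$plants %>%
    filter(.data$block <= config$cfu_blocks, .data$treatment != "control")
  tal <- dataset$nodules %>% filter(.data$pot_id %in% plants$pot_id)
  if (nrow(tal) == 0) return(NULL)

  draw_single <- function(strain, n) {
    round(rlnorm(n, config$cfu_meanlog + config$cfu_link * q[strain],
                 config$cfu_sdlog))
  }
  out <- vector("list", nrow(plants))
  for (i in seq_len(nrow(plants))) {
    pt <- plants[i, ]
    ti <- tal %>% filter(.data$pot_id == pt$pot_id)
    if (nrow(ti) == 0) next
    rows <- list()
    # single-colour nodules: 1 per one-strain pot, up to 2 per two-strain pot
    pool <- rep(ti$strain, times = ti$singles)
    n_take <- min(if (pt$treatment == "two_strain") 2L else 1L, length(pool))
    if (n_take > 0) {
      picked <- sample(pool, n_take)
      rows$single <- tibble(
        pot_id = pt$pot_id,
        nodule_id = sprintf("%s_N%d", pt$pot_id, seq_len(n_take)),
        class = "single_colour", strain = picked,
        cfu = as.numeric(draw_single(picked, n_take)))
    }
    # one mixed-colour nodule where available
    if (pt$treatment == "two_strain" && ti$mixed[1] >= 1) {
      total <- round(rlnorm(1, config$cfu_meanlog, config$cfu_sdlog))
      sh <- plogis(config$cfu_link * (q[pt$strain_a] - q[pt$strain_b]))
      cfu_a <- rbinom(1, total, sh)
      rows$mixed <- tibble(
        pot_id = pt$pot_id,
        nodule_id = sprintf("%s_M1", pt$pot_id),
        class = "mixed_colour",
        strain = c(pt$strain_a, pt$strain_b),
        cfu = as.numeric(c(cfu_a, total - cfu_a)))
    }
    out[[i]] <- bind_rows(rows)
  }
  bind_rows(out)
}

#' Assemble the dyadic analysis table
#'
#' Joins per-strain nodule observations with pot-level covariates into the
#' tidy table the variance-partition models consume: one row per inoculated
#' strain per pot with `pot_id`, `block`, `treatment`, `focal_strain`,
#' `competitor_strain`, `focal_marker`, `nodule_score`,
#' `nodule_proportion`, `shoot_mass_g`.
#'
#' @param dataset A `rhizo_sim`/`rhizo_data` list with `plants` and
#'   `observations`, or an already-dyadic data frame (returned unchanged
#'   apart from column checks).
#' @return A tibble, one row per (pot, strain).
#' @export
dyadic_table <- function(dataset) {
  if (is.data.frame(dataset)) {
    req <- c("pot_id", "block", "focal_strain", "competitor_strain",
             "focal_marker", "nodule_score", "nodule_proportion")
    miss <- setdiff(req, names(dataset))
    if (length(miss)) {
      abort(paste0("Dyadic table missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    return(as_tibble(dataset))
  }
  if (is.null(dataset$observations)) {
    if (is.null(dataset$nodules)) {
      abort("Dataset has neither observations nor nodule tallies.")
    }
    dataset$observations <- tally_to_observations(dataset$nodules,
                                                  dataset$plants)
  }
  dataset$observations %>%
    left_join(dataset$plants %>%
                select("pot_id", "treatment", "shoot_mass_g"),
              by = "pot_id")
}
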