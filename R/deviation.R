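#' Deviation of two-strain host fitness from the neutral expectation
#'
#' Under no partner choice, two strains inoculated in equal ratios should
#' contribute equally, so host fitness in the two-strain pot is expected to
#' equal the average of the host's fitness with each strain alone. The
#' deviation scales the departure from that expectation by its size:
#' `(w_pair - m) / m` with `m = (w1 + w2) / 2`. Positive values mean the
#' host did better than the neutral mixture predicts. The statistic is
#' unitless and invariant to rescaling all three fitness values.
#'
#' @param w_pair Host fitness in the two-strain pot (e.g. shoot mass, g).
#' @param w1,w2 Host fitness genotypic means in the one-strain inocula of
#'   the two strains (same units). All three may be vectors.
#' @return Numeric vector of deviations.
#' @examples
#' neutral_deviation(0.45, 0.20, 0.40) # 0.5
#' @export
neutral_deviation <- function(w_pair, w1, w2) {
  m <- (w1 + w2) / 2
  if (any(!is.na(m) & m <= 0)) {
    abort("Neutral expectation (w1 + w2)/2 must be positive.")
  }
  (w_pair - m) / m
}

#' Deviation records for all two-strain pots
#'
#' Computes, for every two-strain pot, the deviation of host fitness from
#' the neutral expectation together with the proportion of the pot's
#' nodules initiated by the more beneficial strain (R1). Benefit ranking
#' comes from one-strain shoot-mass genotypic means; ties are broken
#' lexicographically and flagged. Pots whose nodule proportion is
#' undefined (no nodules) or whose strains lack a one-strain mean are
#' skipped with a message.
#'
#' @param dataset A `rhizo_sim`/`rhizo_data` list or dyadic table.
#' @param fitness `"shoot_mass"` (host fitness = shoot mass, g) or
#'   `"per_nodule"` (shoot mass per nodule, the module-scaled variant).
#' @param benefit Optional per-strain benefit table (`strain`, `mean`)
#'   overriding the internally computed one-strain shoot-mass means.
#' @return A tibble with one row per usable pot: `pot_id`, `block`,
#'   `strain_r1`, `strain_r2`, `w_pair`, `w1`, `w2`, `deviation`,
#'   `prop_beneficial`, `tie`.
#' @export
deviation_table <- function(dataset,
                            fitness = c("shoot_mass", "per_nodule"),
                            benefit = NULL) {
  fitness <- match.arg(fitness)
  d <- dyadic_table(dataset)
  if (!"treatment" %in% names(d)) {
    d$treatment <- ifelse(is.na(d$competitor_strain), "one_strain",
                          "two_strain")
  }
  if (is.null(benefit)) {
    benefit <- suppressWarnings(
      genotypic_means(dataset, "shoot_mass", "one_strain"))
  }
  w_trait <- if (fitness == "shoot_mass") "shoot_mass" else
    "shoot_per_nodule"
  w_one <- suppressWarnings(genotypic_means(dataset, w_trait, "one_strain"))
  rank_of <- setNames(benefit$mean, benefit$strain)
  w_of <- setNames(w_one$mean, w_one$strain)

  two <- d %>%
    filter(.data$treatment == "two_strain",
           .data$focal_strain < .data$competitor_strain)
  n0 <- nrow(two)

  sa <- two$focal_strain
  sb <- two$competitor_strain
  tie <- !is.na(rank_of[sa]) & !is.na(rank_of[sb]) &
    rank_of[sa] == rank_of[sb]
  a_first <- ifelse(tie, TRUE, rank_of[sa] >= rank_of[sb])
  r1 <- ifelse(a_first, sa, sb)
  r2 <- ifelse(a_first, sb, sa)
  prop_r1 <- ifelse(a_first, two$nodule_proportion,
                    1 - two$nodule_proportion)
  w_pair <- if (fitness == "shoot_mass") two$shoot_mass_g else {
    tot <- d %>%
      filter(.data$pot_id %in% two$pot_id) %>%
      group_by(.data$pot_id) %>%
      summarise(tot = sum(.data$nodule_score), .groups = "drop")
    tt <- setNames(tot$tot, tot$pot_id)[two$pot_id]
    ifelse(tt > 0, two$shoot_mass_g / tt, NA_real_)
  }

  rec <- tibble(pot_id = two$pot_id, block = two$block,
                strain_r1 = r1, strain_r2 = r2,
                w_pair = w_pair,
                w1 = unname(w_of[r1]), w2 = unname(w_of[r2]),
                prop_beneficial = prop_r1, tie = tie)
  usable <- complete.cases(rec[, c("w_pair", "w1", "w2",
                                   "prop_beneficial")])
  n_skip <- sum(!usable)
  if (n_skip > 0) {
    inform(sprintf(
      "deviation_table: skipped %d of %d pots (missing fitness, means, or nodule proportion).",
      n_skip, n0))
  }
  rec <- rec[usable, ]
  rec$deviation <- neutral_deviation(rec$w_pair, rec$w1, rec$w2)
  rec %>% select("pot_id", "block", "strain_r1", "strain_r2", "w_pair",
                 "w1", "w2", "deviation", "prop_beneficial", "tie")
}

#' Mixed-model test of the benefit of partner choice
#'
#' Fits, by maximum likelihood, a linear mixed model of the neutral
#' deviation on the proportion of nodules initiated by the more beneficial
#' strain, with random intercepts for that strain, the competitor strain,
#' and block; the fixed slope is tested by a likelihood-ratio chi-square
#' (1 df) against the intercept-only mixed model. A positive, significant
#' slope means hosts that more effectively direct nodulation toward the
#' better strain gain more fitness than the neutral mixture predicts.
#'
#' @param records Deviation records from [deviation_table()].
#' @return Object of class `"deviation_fit"`: `slope`, `chisq`, `df`,
#'   `p_value`, `n`, fitted `model` and `null_model` (lme4 fits), and the
#'   records used.
#' @export
fit_deviation_model <- function(records) {
  req <- c("deviation", "prop_beneficial", "strain_r1", "strain_r2",
           "block")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    abort(paste0("Records are missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  for (g in c("strain_r1", "strain_r2", "block")) {
    if (dplyr::n_distinct(records[[g]]) < 2) {
      abort(sprintf("Random grouping '%s' needs >= 2 levels.", g))
    }
  }
  if (sd(records$deviation) < 1e-10) {
    # constant response: both models are degenerate and identical
    return(structure(list(slope = 0, intercept = records$deviation[1],
                          chisq = 0, df = 1L, p_value = 1,
                          n = nrow(records), model = NULL,
                          null_model = NULL,
                          records = as_tibble(records)),
                     class = "deviation_fit"))
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- suppressWarnings(suppressMessages(
    lme4::lmer(deviation ~ prop_beneficial + (1 | strain_r1) +
                 (1 | strain_r2) + (1 | block),
               data = records, REML = FALSE, control = ctrl)))
  null <- suppressWarnings(suppressMessages(
    lme4::lmer(deviation ~ 1 + (1 | strain_r1) + (1 | strain_r2) +
                 (1 | block),
               data = records, REML = FALSE, control = ctrl)))
  chi2 <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  structure(list(slope = unname(lme4::fixef(full)["prop_beneficial"]),
                 intercept = unname(lme4::fixef(full)["(Intercept)"]),
                 chisq = chi2, df = 1L,
                 p_value = pchisq(chi2, 1, lower.tail = FALSE),
                 n = nrow(records), model = full, null_model = null,
                 records = as_tibble(records)),
            class = "deviation_fit")
}

#' @export
print.deviation_fit <- function(x, ...) {
  cat(sprintf("Benefit-of-partner-choice model (n = %d pots)\n", x$n))
  cat(sprintf("  slope = %.4g, chisq(1) = %.3g, p = %.3g\n",
              x$slope, x$chisq, x$p_value))
  invisible(x)
}
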