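#' Per-strain genotypic means for one trait
#'
#' Unweighted mean of a trait per strain across blocks, markers and pots,
#' under a treatment filter. Strain genotypic means are the unit of the
#' partner-choice and sanctions regressions.
#'
#' @param dataset A `rhizo_sim`/`rhizo_data` list or dyadic table.
#' @param trait One of `"shoot_mass"`, `"nodule_number"`,
#'   `"nodule_proportion"`, `"nodules_per_gram"`, `"shoot_per_nodule"`.
#' @param treatment `"one_strain"` or `"two_strain"`.
#' @return A tibble `strain`, `mean`, `n`, `se`; strains with no
#'   observations get `NA` with a warning.
#' @export
genotypic_means <- function(dataset,
                            trait = c("shoot_mass", "nodule_number",
                                      "nodule_proportion",
                                      "nodules_per_gram",
                                      "shoot_per_nodule"),
                            treatment = c("one_strain", "two_strain")) {
  trait <- match.arg(trait)
  treatment <- match.arg(treatment)
  d <- dyadic_table(dataset)
  if (!"treatment" %in% names(d)) {
    d$treatment <- ifelse(is.na(d$competitor_strain), "one_strain",
                          "two_strain")
  }
  all_strains <- sort(unique(c(d$focal_strain,
                               na.omit(d$competitor_strain))))
  d <- d %>% filter(.data$treatment == !!treatment)

  vals <- switch(trait,
    shoot_mass = d %>%
      distinct(.data$pot_id, .data$focal_strain, .keep_all = TRUE) %>%
      mutate(value = .data$shoot_mass_g),
    nodule_number = d %>% mutate(value = .data$nodule_score),
    nodule_proportion = d %>% mutate(value = .data$nodule_proportion),
    nodules_per_gram = d %>%
      group_by(.data$pot_id) %>%
      mutate(pot_total = sum(.data$nodule_score)) %>% ungroup() %>%
      mutate(value = ifelse(!is.na(.data$shoot_mass_g) &
                              .data$shoot_mass_g > 0,
                            .data$pot_total / .data$shoot_mass_g,
                            NA_real_)),
    shoot_per_nodule = d %>%
      group_by(.data$pot_id) %>%
      mutate(pot_total = sum(.data$nodule_score)) %>% ungroup() %>%
      mutate(value = ifelse(.data$pot_total > 0,
                            .data$shoot_mass_g / .data$pot_total,
                            NA_real_)))

  out <- vals %>%
    filter(!is.na(.data$value)) %>%
    group_by(strain = .data$focal_strain) %>%
    summarise(mean = mean(.data$value), n = dplyr::n(),
              se = sd(.data$value) / sqrt(dplyr::n()), .groups = "drop")
  missing <- setdiff(all_strains, out$strain)
  if (length(missing)) {
    warn(sprintf("No %s observations under %s for strain(s): %s",
                 trait, treatment, paste(missing, collapse = ", ")))
    out <- bind_rows(out, tibble(strain = missing, mean = NA_real_,
                                 n = 0L, se = NA_real_))
  }
  out %>% arrange(.data$strain)
}

#' Wide table of strain genotypic means
#'
#' Collects, one row per strain, the genotypic means the discrimination
#' analyses use: one-strain shoot-mass benefit, one-strain nodule number,
#' two-strain nodule proportion, the derived per-gram and per-nodule
#' traits, and (when CFU data is present) mean CFU per single-colour
#' nodule and mean within-nodule CFU share in mixed nodules, both from
#' two-strain pots.
#'
#' @param dataset A `rhizo_sim`/`rhizo_data` list.
#' @param growth_rate Optional named numeric vector (or two-column data
#'   frame `strain`, `growth_rate`) of axenic growth rates to append.
#' @return A tibble, one row per strain.
#' @export
genotypic_mean_table <- function(dataset, growth_rate = NULL) {
  grab <- function(trait, treatment, nm) {
    x <- suppressWarnings(genotypic_means(dataset, trait, treatment)) %>%
      select("strain", "mean")
    names(x)[2] <- nm
    x
  }
  out <- grab("shoot_mass", "one_strain", "shoot_mass_one") %>%
    left_join(grab("nodule_number", "one_strain", "nodule_number_one"),
              by = "strain") %>%
    left_join(grab("nodule_proportion", "two_strain",
                   "nodule_proportion_two"), by = "strain") %>%
    left_join(grab("nodules_per_gram", "one_strain",
                   "nodules_per_gram_one"), by = "strain") %>%
    left_join(grab("shoot_per_nodule", "one_strain",
                   "shoot_per_nodule_one"), by = "strain")
  if (!is.data.frame(dataset) && !is.null(dataset$cfu)) {
    cfu_means <- cfu_strain_means(dataset)
    out <- out %>% left_join(cfu_means, by = "strain")
  }
  if (!is.null(growth_rate)) {
    gr <- if (is.data.frame(growth_rate)) {
      as_tibble(growth_rate)[, c("strain", "growth_rate")]
    } else {
      tibble(strain = names(growth_rate),
             growth_rate = as.numeric(growth_rate))
    }
    out <- out %>% left_join(gr, by = "strain")
  }
  out
}

cfu_strain_means <- function(dataset) {
  two_pots <- dataset$plants %>%
    filter(.data$treatment == "two_strain") %>% pull(.data$pot_id)
  cfu <- dataset$cfu %>% filter(.data$pot_id %in% two_pots)
  singles <- cfu %>%
    filter(.data$class == "single_colour") %>%
    group_by(strain = .data$strain) %>%
    summarise(cfu_single_two = mean(.data$cfu), .groups = "drop")
  mixed <- cfu %>%
    filter(.data$class == "mixed_colour") %>%
    group_by(.data$pot_id, .data$nodule_id) %>%
    mutate(share = if (sum(.data$cfu) > 0) .data$cfu / sum(.data$cfu)
           else NA_real_) %>%
    ungroup() %>%
    filter(!is.na(.data$share)) %>%
    group_by(strain = .data$strain) %>%
    summarise(cfu_share_mixed_two = mean(.data$share), .groups = "drop")
  dplyr::full_join(singles, mixed, by = "strain")
}

#' Fixed-effects regression on strain genotypic means
#'
#' Ordinary least squares of one column of genotypic means on another at
#' the strain level, with the slope tested by F on (1, n - 2) degrees of
#' freedom — the test behind the partner-choice and sanctions analyses.
#'
#' @param data A per-strain table such as [genotypic_mean_table()].
#' @param x,y Column names (strings) of predictor and response means.
#' @return An object of class `"means_reg"`: `slope`, `intercept`,
#'   `f_statistic`, `df1`, `df2`, `p_value`, `r_squared`, `n`, plus the
#'   complete-case data used.
#' @examples
#' tab <- tibble::tibble(strain = letters[1:8], a = 1:8,
#'                       b = 2 * (1:8) + rnorm(8, 0, 0.1))
#' fit_means_regression(tab, "a", "b")
#' @export
fit_means_regression <- function(data, x, y) {
  d <- tibble(strain = data$strain %||% seq_len(nrow(data)),
              x = data[[x]], y = data[[y]])
  d <- d[complete.cases(d[, c("x", "y")]), ]
  n <- nrow(d)
  if (n < 3) {
    abort(sprintf("Need >= 3 strains with both means; got %d.", n))
  }
  if (var(d$x) == 0) {
    abort("Predictor means have zero variance; slope is not estimable.")
  }
  fit <- lm(y ~ x, data = d)
  sm <- suppressWarnings(summary(fit))
  ssr <- sum((fitted(fit) - mean(d$y))^2)
  sse <- sum(residuals(fit)^2)
  f_stat <- if (sse == 0) Inf else (ssr / 1) / (sse / (n - 2))
  if (var(d$y) == 0) f_stat <- 0
  p <- pf(f_stat, 1, n - 2, lower.tail = FALSE)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 f_statistic = f_stat, df1 = 1L, df2 = as.integer(n - 2),
                 p_value = p, r_squared = sm$r.squared, n = n,
                 x = x, y = y, data = d, lm = fit),
            class = "means_reg")
}

#' @export
print.means_reg <- function(x, ...) {
  cat(sprintf("Genotypic-means regression: %s ~ %s (n = %d strains)\n",
              x$y, x$x, x$n))
  cat(sprintf("  slope = %.4g, F(%d,%d) = %.3g, p = %.3g, R2 = %.3f\n",
              x$slope, x$df1, x$df2, x$f_statistic, x$p_value,
              x$r_squared))
  invisible(x)
}

#' Per-pot derived symbiosis traits
#'
#' Computes nodules per gram of shoot (nodulation scaled by plant size) and
#' shoot mass per nodule (benefit per symbiotic module) for every
#' inoculated pot, leaving undefined ratios `NA` and reporting how many
#' were excluded.
#'
#' @param dataset A `rhizo_sim`/`rhizo_data` list or dyadic table.
#' @return A tibble `pot_id`, `treatment`, `total_nodules`,
#'   `shoot_mass_g`, `nodules_per_gram`, `shoot_per_nodule`, with
#'   exclusion counts in attribute `"n_excluded"`.
#' @export
derived_traits <- function(dataset) {
  d <- dyadic_table(dataset)
  if (!"treatment" %in% names(d)) {
    d$treatment <- ifelse(is.na(d$competitor_strain), "one_strain",
                          "two_strain")
  }
  out <- d %>%
    group_by(.data$pot_id, .data$treatment) %>%
    summarise(total_nodules = sum(.data$nodule_score),
              shoot_mass_g = .data$shoot_mass_g[1], .groups = "drop") %>%
    mutate(nodules_per_gram = ifelse(!is.na(.data$shoot_mass_g) &
                                       .data$shoot_mass_g > 0,
                                     .data$total_nodules /
                                       .data$shoot_mass_g, NA_real_),
           shoot_per_nodule = ifelse(.data$total_nodules > 0,
                                     .data$shoot_mass_g /
                                       .data$total_nodules, NA_real_))
  attr(out, "n_excluded") <-
    c(nodules_per_gram = sum(is.na(out$nodules_per_gram)),
      shoot_per_nodule = sum(is.na(out$shoot_per_nodule)))
  out
}

#' The standard partner-choice regression battery
#'
#' Runs the genotypic-means regressions that test partner choice: whether
#' strains conferring more one-strain shoot mass (the benefit axis) form
#' more nodules alone, a higher proportion of nodules in competition, more
#' nodules per gram of shoot, and more shoot mass per nodule; optionally
#' also the axenic growth-rate null checks.
#'
#' @param dataset A `rhizo_sim`/`rhizo_data` list.
#' @param growth_rate Optional axenic growth rates (see
#'   [genotypic_mean_table()]).
#' @return A tibble with one row per regression: `test`, `x`, `y`,
#'   `slope`, `f_statistic`, `df1`, `df2`, `p_value`, `r_squared`, `n`.
#' @export
partner_choice_tests <- function(dataset, growth_rate = NULL) {
  tab <- genotypic_mean_table(dataset, growth_rate = growth_rate)
  specs <- list(
    c("nodule_number_one_strain", "shoot_mass_one", "nodule_number_one"),
    c("nodule_proportion_two_strain", "shoot_mass_one",
      "nodule_proportion_two"),
    c("nodules_per_gram", "shoot_mass_one", "nodules_per_gram_one"),
    c("shoot_per_nodule", "shoot_mass_one", "shoot_per_nodule_one"))
  if ("growth_rate" %in% names(tab)) {
    specs <- c(specs, list(
      c("growth_rate_vs_nodule_number", "growth_rate",
        "nodule_number_one"),
      c("growth_rate_vs_nodule_proportion", "growth_rate",
        "nodule_proportion_two")))
  }
  purrr::map_dfr(specs, function(s) {
    r <- fit_means_regression(tab, s[2], s[3])
    tibble(test = s[1], x = s[2], y = s[3], slope = r$slope,
           f_statistic = r$f_statistic, df1 = r$df1, df2 = r$df2,
           p_value = r$p_value, r_squared = r$r_squared, n = r$n)
  })
}

#' Among-nodule and intra-nodule sanctions regressions
#'
#' Tests whether more beneficial strains (higher one-strain shoot-mass
#' genotypic mean) reach larger within-nodule populations in two-strain
#' pots: among-nodule sanctions regress each strain's mean CFU in
#' single-colour nodules on its benefit mean; intra-nodule sanctions
#' regress each strain's mean CFU share within mixed-colour nodules
#' (computed per nodule, then averaged) on its benefit mean.
#'
#' @param dataset A `rhizo_sim`/`rhizo_data` list with a `cfu` table.
#' @param benefit Optional per-strain benefit table (`strain`, `mean`);
#'   defaults to one-strain shoot-mass genotypic means from `dataset`.
#' @return A list of two `"means_reg"` objects, `among_nodule` and
#'   `intra_nodule`, plus the per-strain table used.
#' @export
sanctions_summaries <- function(dataset, benefit = NULL) {
  if (is.null(dataset$cfu) || nrow(dataset$cfu) == 0) {
    abort("Dataset has no CFU table; sanctions cannot be computed.")
  }
  if (is.null(benefit)) {
    benefit <- suppressWarnings(
      genotypic_means(dataset, "shoot_mass", "one_strain"))
  }
  tab <- cfu_strain_means(dataset) %>%
    left_join(benefit %>% select("strain", benefit = "mean"),
              by = "strain")
  list(among_nodule = fit_means_regression(tab, "benefit",
                                           "cfu_single_two"),
       intra_nodule = fit_means_regression(tab, "benefit",
                                           "cfu_share_mixed_two"),
       strain_means = tab)
}
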