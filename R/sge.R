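ind_matrix <- function(f, levels, sign = NULL) {
  f <- factor(f, levels = levels)
  Z <- matrix(0, length(f), length(levels),
              dimnames = list(NULL, levels))
  Z[cbind(seq_along(f), as.integer(f))] <- if (is.null(sign)) 1 else sign
  Z
}

signed_strain_matrix <- function(focal, comp, levels, comp_sign) {
  Z <- ind_matrix(focal, levels)
  Zc <- ind_matrix(comp, levels)
  Z + comp_sign * Zc
}

#' Assemble response and design matrices for a variance-partition model
#'
#' Builds, from the dyadic two-strain table, the response vector, fixed
#' design (intercept + fluorescent marker) and random-effect incidence
#' matrices for one of the three traits:
#'
#' * `nodule_number` — one row per strain per pot (two per pot); separate
#'   focal-strain (DGE) and competitor-strain (main SGE) indicators,
#'   ordered-pair G x G, block and pot terms; no variance constraints.
#' * `nodule_proportion` — one row per pot (the orientation with the
#'   lexicographically smaller strain as focal; the mirrored row is
#'   redundant since the two proportions sum to 1); a single strain term
#'   with +1 focal / -1 competitor incidence imposes DGE = main SGE with
#'   correlation -1; unordered-pair G x G signed by orientation; block.
#'   Pots with no nodules are excluded (proportion undefined).
#' * `shoot_mass` — one row per pot on the natural-log scale; strain term
#'   with +1/+1 incidence imposes DGE = main SGE with correlation +1;
#'   unordered-pair G x G; block.
#'
#' @param data Dyadic table ([dyadic_table()]) or `rhizo_sim` dataset.
#' @param trait One of `"nodule_number"`, `"nodule_proportion"`,
#'   `"shoot_mass"`.
#' @param transform `"auto"` (log for shoot mass, identity otherwise),
#'   `"identity"` or `"log"`.
#' @return A list of class `"sge_matrices"`: `y`, `X`, `Z` (named list of
#'   incidence matrices), `trait`, `constraint`, `transform`, `n_rows`,
#'   `n_pots`, `n_excluded`.
#' @export
build_sge_matrices <- function(data,
                               trait = c("nodule_number",
                                         "nodule_proportion",
                                         "shoot_mass"),
                               transform = "auto") {
  trait <- match.arg(trait)
  data <- dyadic_table(data)
  two <- data %>% filter(!is.na(.data$competitor_strain))
  if ("treatment" %in% names(two)) {
    bad <- two$treatment != "two_strain"
    if (any(bad)) abort("Non two-strain rows carry a competitor strain.")
  }
  if (nrow(two) == 0) abort("No two-strain observations to model.")
  if (transform == "auto") {
    transform <- if (trait == "shoot_mass") "log" else "identity"
  }
  strains <- sort(unique(c(two$focal_strain, two$competitor_strain)))
  markers <- sort(unique(two$focal_marker))
  blocks <- sort(unique(two$block))

  make_X <- function(marker) {
    X <- cbind(`(Intercept)` = 1,
               marker = as.numeric(marker == markers[length(markers)]))
    if (length(markers) < 2) X <- X[, 1, drop = FALSE]
    X
  }
  tf <- function(v) if (transform == "log") log(v) else v

  if (trait == "nodule_number") {
    keep <- !is.na(two$nodule_score)
    d <- two[keep, ]
    opair <- paste(d$focal_strain, d$competitor_strain, sep = ":")
    Z <- list(
      dge = ind_matrix(d$focal_strain, strains),
      sge = ind_matrix(d$competitor_strain, strains),
      gxg = ind_matrix(opair, sort(unique(opair))),
      block = ind_matrix(d$block, blocks),
      pot = ind_matrix(d$pot_id, sort(unique(d$pot_id))))
    out <- list(y = tf(d$nodule_score), X = make_X(d$focal_marker), Z = Z,
                constraint = "unconstrained",
                n_pots = dplyr::n_distinct(d$pot_id),
                n_excluded = sum(!keep))
  } else {
    # one orientation per pot: lexicographically smaller strain as focal
    d <- two %>%
      filter(.data$focal_strain < .data$competitor_strain) %>%
      arrange(.data$pot_id)
    resp <- if (trait == "nodule_proportion") d$nodule_proportion
            else d$shoot_mass_g
    keep <- !is.na(resp) & (trait != "shoot_mass" | resp > 0)
    n_excl <- sum(!keep)
    if (n_excl > 0) {
      inform(sprintf("%s model: excluded %d pot(s) with undefined response.",
                     trait, n_excl))
    }
    d <- d[keep, ]
    resp <- resp[keep]
    comp_sign <- if (trait == "nodule_proportion") -1 else 1
    upair <- paste(pmin(d$focal_strain, d$competitor_strain),
                   pmax(d$focal_strain, d$competitor_strain), sep = ":")
    gxg_sign <- ifelse(d$focal_strain < d$competitor_strain, 1,
                       if (trait == "nodule_proportion") -1 else 1)
    Z <- list(
      strain = signed_strain_matrix(d$focal_strain, d$competitor_strain,
                                    strains, comp_sign),
      gxg = ind_matrix(upair, sort(unique(upair)), sign = gxg_sign),
      block = ind_matrix(d$block, blocks))
    out <- list(y = tf(resp), X = make_X(d$focal_marker), Z = Z,
                constraint = if (trait == "nodule_proportion")
                  "dge_eq_sge_corr_minus1" else "dge_eq_sge_corr_plus1",
                n_pots = nrow(d), n_excluded = n_excl)
  }
  structure(c(out, list(trait = trait, transform = transform,
                        n_rows = length(out$y), strains = strains)),
            class = "sge_matrices")
}

component_labels <- c(dge = "DGE", sge = "main SGE", strain = "DGE",
                      gxg = "G x G SGE", block = "block",
                      pot = "plant pot", residual = "residual")

#' Partition phenotypic variance into social genetic effect components
#'
#' Fits the constrained REML mixed model for one trait of the two-strain
#' co-inoculation data and partitions phenotypic variance into DGE, main
#' SGE, G x G SGE, block, (for nodule number) pot, and residual components.
#' For the constrained traits the single strain variance is reported on
#' both the DGE and the main SGE rows and counted twice in the phenotypic
#' denominator, matching how an equal-variance focal/competitor effect
#' contributes to a single observation.
#'
#' @inheritParams build_sge_matrices
#' @param ... Passed to [reml_fit()].
#' @return An object of class `"sge_fit"`: the underlying `reml_fit`, the
#'   model matrices, and `vc`, a tibble with one row per component
#'   (`component`, `variance`, `proportion`).
#' @examples
#' sim <- simulate_experiment(sim_config(n_strains = 5, n_blocks = 3, seed = 2))
#' fit <- fit_sge(dyadic_table(sim), "nodule_number")
#' fit$vc
#' @export
fit_sge <- function(data, trait = c("nodule_number", "nodule_proportion",
                                    "shoot_mass"),
                    transform = "auto", ...) {
  trait <- match.arg(trait)
  mats <- build_sge_matrices(data, trait, transform)
  fit <- reml_fit(mats$y, mats$X, mats$Z, ...)
  vc <- variance_proportions(fit, mats)
  structure(list(trait = trait, constraint = mats$constraint,
                 transform = mats$transform, fit = fit, matrices = mats,
                 vc = vc, n_rows = mats$n_rows, n_pots = mats$n_pots,
                 n_excluded = mats$n_excluded),
            class = "sge_fit")
}

variance_proportions <- function(fit, mats) {
  s2 <- fit$sigma2
  terms <- setdiff(names(s2), "residual")
  # per-observation variance contribution of each term = sigma2 * mean
  # row sum of squared incidence (2 for the shared +-1 strain term)
  w <- vapply(terms, function(k) mean(rowSums(mats$Z[[k]]^2)), numeric(1))
  denom <- sum(w * s2[terms]) + s2[["residual"]]
  rows <- list()
  for (k in terms) {
    if (k == "strain") {
      rows[[length(rows) + 1]] <-
        tibble(component = c("DGE", "main SGE"), term = k,
               variance = s2[[k]], proportion = s2[[k]] / denom)
    } else {
      rows[[length(rows) + 1]] <-
        tibble(component = component_labels[[k]], term = k,
               variance = s2[[k]], proportion = w[[k]] * s2[[k]] / denom)
    }
  }
  rows[[length(rows) + 1]] <-
    tibble(component = "residual", term = "residual",
           variance = s2[["residual"]],
           proportion = s2[["residual"]] / denom)
  bind_rows(rows)
}

#' Likelihood-ratio test of a variance component
#'
#' Refits the model without the named component and compares restricted
#' log-likelihoods: `chi2 = 2 (logL_full - logL_reduced)` on 1 degree of
#' freedom (each component here is a single variance parameter). For the
#' constrained traits, removing `"DGE"` or `"main SGE"` removes the single
#' shared strain term — both components are tested jointly by one test and
#' share the reported statistic. The chi-square reference is conservative
#' when the true variance sits on the boundary.
#'
#' @param fit An `"sge_fit"` object.
#' @param component One of `"DGE"`, `"main SGE"`, `"G x G SGE"`, `"block"`,
#'   `"plant pot"` (or the internal term names `dge`, `sge`, `strain`,
#'   `gxg`, `block`, `pot`).
#' @param ... Passed to [reml_fit()] for the reduced fit.
#' @return A tibble: `component`, `term`, `chisq`, `df`, `p_value`.
#' @export
lrt_component <- function(fit, component, ...) {
  stopifnot(inherits(fit, "sge_fit"))
  term <- resolve_term(fit, component)
  if (identical(term, "residual")) {
    abort("The residual variance cannot be removed.")
  }
  if (!term %in% names(fit$matrices$Z)) {
    return(tibble(component = component, term = term, chisq = 0,
                  df = 1L, p_value = 1))
  }
  Zred <- fit$matrices$Z[setdiff(names(fit$matrices$Z), term)]
  red <- reml_fit(fit$matrices$y, fit$matrices$X, Zred, ...)
  ll_full <- fit$fit$loglik
  chi2 <- 2 * (ll_full - red$loglik)
  if (chi2 < -1e-2) {
    # the stored full fit under-optimised; warm-start it from the reduced
    # optimum with the dropped term at the boundary
    warm <- log(pmax(red$gamma, 1e-8))
    refull <- reml_fit(fit$matrices$y, fit$matrices$X, fit$matrices$Z,
                       start = warm)
    ll_full <- max(ll_full, refull$loglik)
    chi2 <- 2 * (ll_full - red$loglik)
  }
  if (chi2 < 0 && chi2 > -1e-2) chi2 <- 0
  if (chi2 < 0) {
    warn(sprintf("Reduced model log-likelihood exceeds full (%.3g); clamped.",
                 chi2))
    chi2 <- 0
  }
  tibble(component = component, term = term, chisq = chi2, df = 1L,
         p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

resolve_term <- function(fit, component) {
  key <- tolower(gsub("[^a-z+]", "", tolower(component)))
  constrained <- fit$constraint != "unconstrained"
  switch(key,
    "dge" = if (constrained) "strain" else "dge",
    "mainsge" = , "sge" = if (constrained) "strain" else "sge",
    "dge+sge" = , "strain" = if (constrained) "strain"
      else abort("DGE and SGE are separate terms in an unconstrained fit."),
    "gxgsge" = , "gxg" = "gxg",
    "block" = "block",
    "plantpot" = , "pot" = "pot",
    "residual" = "residual",
    abort(sprintf("Unknown component '%s'.", component)))
}

#' Variance-partition table across traits
#'
#' Combines several [fit_sge()] fits into one tidy table of variance
#' proportions (as percentages) with likelihood-ratio chi-square statistics
#' and p-values for every non-residual component — the standard
#' components-by-traits partition summary for a co-inoculation experiment.
#'
#' @param ... Named `"sge_fit"` objects (names become the `trait` column),
#'   or a single named list of them.
#' @return A tibble: `trait`, `component`, `pct_variation`, `chisq`, `df`,
#'   `p_value`.
#' @export
variance_table <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "sge_fit")) {
    fits <- fits[[1]]
  }
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$trait, character(1))
  }
  purrr::imap_dfr(fits, function(fit, trait_name) {
    tests <- purrr::map_dfr(unique(fit$vc$term[fit$vc$term != "residual"]),
                            function(term) {
      lab <- if (term == "strain") "DGE" else component_labels[[term]]
      lrt_component(fit, lab)[, c("term", "chisq", "df", "p_value")]
    })
    fit$vc %>%
      left_join(tests, by = "term") %>%
      mutate(trait = trait_name,
             pct_variation = 100 * .data$proportion) %>%
      select("trait", "component", "pct_variation", "chisq", "df",
             "p_value")
  })
}

#' @export
print.sge_fit <- function(x, ...) {
  cat(sprintf("Variance partition for %s (%s, %s transform)\n",
              x$trait, x$constraint, x$transform))
  cat(sprintf("  %d rows, %d pots, %d excluded; REML logLik %.3f\n",
              x$n_rows, x$n_pots, x$n_excluded, x$fit$loglik))
  df <- as.data.frame(x$vc[, c("component", "variance", "proportion")])
  df$pct <- sprintf("%.1f%%", 100 * df$proportion)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
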