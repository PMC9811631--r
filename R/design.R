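#' Generate the full co-inoculation experimental design
#'
#' Builds the randomized-complete-block design used throughout the package:
#' in every block, each strain is grown alone under each of the two
#' fluorescent markers, every unordered pair of strains is grown twice with
#' reciprocal marker assignments, and a fixed number of uninoculated control
#' pots is added. With 8 strains, 8 blocks and 2 controls per block this
#' yields 592 pots (16 one-strain + 56 two-strain + 2 control = 74 per
#' block).
#'
#' Output order is deterministic (blocks, then one-strain, two-strain,
#' control pots in lexicographic strain order), so the same call always
#' produces the same table.
#'
#' @param n_strains Number of rhizobium strains (>= 2).
#' @param n_blocks Number of complete blocks (>= 1).
#' @param n_controls_per_block Number of uninoculated control pots per block.
#' @param strain_ids Optional character vector of strain identifiers
#'   (length `n_strains`). Defaults to `"S01"`, `"S02"`, ...
#' @param markers Character vector of exactly two fluorescent marker labels.
#'
#' @return A tibble with one row per pot and columns `pot_id`, `block`,
#'   `treatment` (`"control"`, `"one_strain"`, `"two_strain"`), `strain_a`,
#'   `marker_a`, `strain_b`, `marker_b` (both `NA` except for two-strain
#'   pots) and `shoot_mass_g` (initialised to `NA`).
#'
#' @examples
#' design <- generate_design(8, 8, 2)
#' nrow(design) # 592
#' @export
generate_design <- function(n_strains, n_blocks, n_controls_per_block = 2,
                            strain_ids = NULL,
                            markers = c("red", "green")) {
  if (n_strains < 2) {
    abort("`n_strains` must be >= 2: a co-inoculation design needs strain pairs.")
  }
  if (n_blocks < 1) abort("`n_blocks` must be >= 1.")
  if (n_controls_per_block < 0) abort("`n_controls_per_block` must be >= 0.")
  if (length(markers) != 2L || anyDuplicated(markers)) {
    abort("`markers` must be exactly two distinct marker labels.")
  }
  strain_ids <- strain_ids %||% sprintf("S%02d", seq_len(n_strains))
  if (length(strain_ids) != n_strains || anyDuplicated(strain_ids)) {
    abort("`strain_ids` must be `n_strains` distinct identifiers.")
  }
  strain_ids <- sort(as.character(strain_ids))

  pairs <- utils::combn(strain_ids, 2)

  one_block <- function(b) {
    one <- tidyr::expand_grid(strain_a = strain_ids, marker_a = markers) %>%
      mutate(treatment = "one_strain",
             strain_b = NA_character_, marker_b = NA_character_)
    two <- tibble(strain_a = rep(pairs[1, ], each = 2),
                  strain_b = rep(pairs[2, ], each = 2),
                  marker_a = rep(markers, ncol(pairs)),
                  marker_b = rep(rev(markers), ncol(pairs)),
                  treatment = "two_strain")
    ctrl <- tibble(strain_a = NA_character_, marker_a = NA_character_,
                   strain_b = NA_character_, marker_b = NA_character_,
                   treatment = rep("control", n_controls_per_block))
    bind_rows(one, two, ctrl) %>% mutate(block = b)
  }

  design <- purrr::map_dfr(seq_len(n_blocks), one_block) %>%
    mutate(pot_id = sprintf("B%02d_P%03d", as.integer(.data$block),
                            as.integer(stats::ave(.data$block, .data$block,
                                                  FUN = seq_along))),
           shoot_mass_g = NA_real_) %>%
    select("pot_id", "block", "treatment", "strain_a", "marker_a",
           "strain_b", "marker_b", "shoot_mass_g")
  attr(design, "strain_ids") <- strain_ids
  attr(design, "markers") <- markers
  design
}

#' Convert nodule colour tallies to per-strain observations
#'
#' Applies the nodule scoring rule: a strain receives a count of 1 for each
#' single-colour nodule of its marker and 0.5 for each mixed-colour nodule,
#' so the two scores in a two-strain pot always sum to the pot's total
#' nodule count. The nodule proportion is the score divided by the pot
#' total, undefined (`NA`) when a pot formed no nodules.
#'
#' @param nodules Tally table with columns `pot_id`, `strain`, `singles`
#'   (single-colour nodule count for that strain) and `mixed` (the pot's
#'   mixed-colour nodule count, repeated on each of the pot's rows;
#'   one-strain pots have `mixed = 0`).
#' @param plants Design table as produced by [generate_design()] (used to
#'   check that tallied strains were actually inoculated and to attach the
#'   focal marker and competitor strain).
#'
#' @return A tibble with one row per inoculated strain per pot: `pot_id`,
#'   `block`, `focal_strain`, `competitor_strain` (`NA` in one-strain pots),
#'   `focal_marker`, `nodule_score`, `nodule_proportion`.
#' @export
tally_to_observations <- function(nodules, plants) {
  req <- c("pot_id", "strain", "singles", "mixed")
  miss <- setdiff(req, names(nodules))
  if (length(miss)) {
    abort(paste0("Tally table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(nodules$singles < 0) || any(nodules$mixed < 0)) {
    abort("Nodule counts must be non-negative.")
  }
  bad_mixed <- nodules %>%
    group_by(.data$pot_id) %>%
    summarise(k = dplyr::n_distinct(.data$mixed), .groups = "drop") %>%
    filter(.data$k > 1L)
  if (nrow(bad_mixed)) {
    abort(paste0("Inconsistent `mixed` count within pot(s): ",
                 paste(bad_mixed$pot_id, collapse = ", ")))
  }

  inoculated <- plants %>% filter(.data$treatment != "control")
  inoc <- bind_rows(
    inoculated %>%
      mutate(focal_strain = .data$strain_a,
             competitor_strain = .data$strain_b,
             focal_marker = .data$marker_a),
    inoculated %>%
      filter(!is.na(.data$strain_b)) %>%
      mutate(focal_strain = .data$strain_b,
             competitor_strain = .data$strain_a,
             focal_marker = .data$marker_b)
  ) %>%
    select("pot_id", "block", "focal_strain", "competitor_strain",
           "focal_marker")

  unknown <- dplyr::anti_join(
    nodules, inoc, by = c(pot_id = "pot_id", strain = "focal_strain"))
  if (nrow(unknown)) {
    abort(paste0("Tally references strain(s) not inoculated in their pot: ",
                 paste(unique(paste(unknown$pot_id, unknown$strain)),
                       collapse = ", ")))
  }

  inoc %>%
    filter(.data$pot_id %in% nodules$pot_id) %>%
    left_join(nodules, by = c(pot_id = "pot_id", focal_strain = "strain")) %>%
    mutate(singles = dplyr::coalesce(.data$singles, 0),
           mixed = dplyr::coalesce(.data$mixed, 0),
           nodule_score = .data$singles + 0.5 * .data$mixed) %>%
    group_by(.data$pot_id) %>%
    mutate(pot_total = sum(.data$nodule_score),
           nodule_proportion = ifelse(.data$pot_total > 0,
                                      .data$nodule_score / .data$pot_total,
                                      NA_real_)) %>%
    ungroup() %>%
    select("pot_id", "block", "focal_strain", "competitor_strain",
           "focal_marker", "nodule_score", "nodule_proportion") %>%
    arrange(.data$pot_id, .data$focal_strain)
}
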