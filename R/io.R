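#' Default schema mapping for experiment tables
#'
#' Column names used on disk can differ from the names the package uses
#' internally (e.g. when adapting an external data deposit). A schema is a
#' named list with one character vector per table, mapping internal names to
#' file column names; edit entries to match your files.
#'
#' @return A list with elements `plants`, `nodules`, `cfu`, `observations`,
#'   each a named character vector `internal_name = file_column_name`.
#' @export
default_schema <- function() {
  list(
    plants = c(pot_id = "pot_id", block = "block", treatment = "treatment",
               strain_a = "strain_a", marker_a = "marker_a",
               strain_b = "strain_b", marker_b = "marker_b",
               shoot_mass_g = "shoot_mass_g"),
    nodules = c(pot_id = "pot_id", strain = "strain",
                singles = "singles", mixed = "mixed"),
    cfu = c(pot_id = "pot_id", nodule_id = "nodule_id", class = "class",
            strain = "strain", cfu = "cfu"),
    observations = c(pot_id = "pot_id", block = "block",
                     focal_strain = "focal_strain",
                     competitor_strain = "competitor_strain",
                     focal_marker = "focal_marker",
                     nodule_score = "nodule_score",
                     nodule_proportion = "nodule_proportion")
  )
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, na = c("", "NA"))
}

apply_schema <- function(df, mapping, table, path) {
  missing <- setdiff(unname(mapping), names(df))
  if (length(missing)) {
    abort(sprintf("Table '%s' (%s) is missing required column(s): %s",
                  table, path, paste(missing, collapse = ", ")))
  }
  df <- df[, unname(mapping), drop = FALSE]
  names(df) <- names(mapping)
  as_tibble(df)
}

#' Read and validate the experiment tables
#'
#' Reads the pot-level plant table and (optionally) the nodule tally and
#' nodule CFU tables from delimited text files (`.csv` or `.tsv`), renames
#' columns through a schema mapping, coerces types, and validates the
#' dataset with [validate_experiment()].
#'
#' @param plants_path Path to the pot-level table.
#' @param nodules_path,cfu_path Optional paths to the nodule tally and
#'   nodule-level CFU tables.
#' @param schema Schema mapping as returned by [default_schema()]; override
#'   entries to adapt external column names.
#' @return A list with class `"rhizo_data"`: tibbles `plants`, `nodules`
#'   (or `NULL`), `cfu` (or `NULL`).
#' @export
read_experiment_tables <- function(plants_path, nodules_path = NULL,
                                   cfu_path = NULL, schema = default_schema()) {
  plants <- apply_schema(read_delim_auto(plants_path), schema$plants,
                         "plants", plants_path)
  plants <- plants %>%
    mutate(across(c("pot_id", "treatment", "strain_a", "marker_a",
                    "strain_b", "marker_b"), as.character),
           block = as.integer(.data$block),
           shoot_mass_g = as.numeric(.data$shoot_mass_g))
  nodules <- cfu <- NULL
  if (!is.null(nodules_path)) {
    nodules <- apply_schema(read_delim_auto(nodules_path), schema$nodules,
                            "nodules", nodules_path) %>%
      mutate(across(c("pot_id", "strain"), as.character),
             across(c("singles", "mixed"), as.numeric))
  }
  if (!is.null(cfu_path)) {
    cfu <- apply_schema(read_delim_auto(cfu_path), schema$cfu,
                        "cfu", cfu_path) %>%
      mutate(across(c("pot_id", "nodule_id", "class", "strain"),
                    as.character),
             cfu = as.numeric(.data$cfu))
  }
  dataset <- structure(list(plants = plants, nodules = nodules, cfu = cfu),
                       class = "rhizo_data")
  validate_experiment(dataset)
  dataset
}

#' Write the experiment tables as CSV
#'
#' Inverse of [read_experiment_tables()]: writes `plants.csv` and, when
#' present, `nodules.csv` and `cfu.csv` into `dir`. Values round-trip
#' bit-for-bit for integers and categoricals and to full double precision
#' for reals.
#'
#' @param dataset A `rhizo_data` list (or any list with a `plants` tibble
#'   and optional `nodules`/`cfu` tibbles).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_experiment_tables <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(plants = file.path(dir, "plants.csv"))
  readr::write_csv(dataset$plants, paths[["plants"]], progress = FALSE)
  for (tab in c("nodules", "cfu")) {
    if (!is.null(dataset[[tab]])) {
      p <- file.path(dir, paste0(tab, ".csv"))
      readr::write_csv(dataset[[tab]], p, progress = FALSE)
      paths[[tab]] <- p
    }
  }
  invisible(paths)
}

rows_msg <- function(idx) paste(head(idx, 10L), collapse = ", ")

#' Validate an experiment dataset
#'
#' Checks the structural invariants of the data model and aborts with a
#' message naming the offending rows on the first violation found:
#' unique pot ids; treatment consistent with the number of strain labels;
#' two-strain pots have distinct strains and distinct markers; shoot mass
#' non-negative; nodule counts non-negative; CFU classes valid; and, when an
#' observations table is supplied, nodule proportions within \[0, 1\].
#'
#' @param dataset A `rhizo_data` list, or a plants tibble.
#' @param observations Optional per-strain observation table to check.
#' @return Invisibly `TRUE` when all checks pass.
#' @export
validate_experiment <- function(dataset, observations = NULL) {
  if (is.data.frame(dataset)) dataset <- list(plants = dataset)
  plants <- dataset$plants

  dup <- which(duplicated(plants$pot_id))
  if (length(dup)) {
    abort(sprintf("Duplicated pot_id in plants (rows %s): %s",
                  rows_msg(dup),
                  paste(unique(plants$pot_id[dup]), collapse = ", ")))
  }
  bad_tr <- which(!plants$treatment %in%
                    c("control", "one_strain", "two_strain"))
  if (length(bad_tr)) {
    abort(sprintf("Unknown treatment in plants rows %s", rows_msg(bad_tr)))
  }
  n_lab <- (!is.na(plants$strain_a)) + (!is.na(plants$strain_b))
  want <- c(control = 0L, one_strain = 1L, two_strain = 2L)[plants$treatment]
  bad_lab <- which(n_lab != want)
  if (length(bad_lab)) {
    abort(sprintf(
      "Strain labels inconsistent with treatment in plants rows %s",
      rows_msg(bad_lab)))
  }
  two <- plants$treatment == "two_strain"
  bad_two <- which(two & (plants$strain_a == plants$strain_b |
                            plants$marker_a == plants$marker_b))
  if (length(bad_two)) {
    abort(sprintf(
      "Two-strain pots need distinct strains and distinct markers (rows %s)",
      rows_msg(bad_two)))
  }
  bad_mass <- which(!is.na(plants$shoot_mass_g) & plants$shoot_mass_g < 0)
  if (length(bad_mass)) {
    abort(sprintf("Negative shoot mass in plants rows %s", rows_msg(bad_mass)))
  }

  if (!is.null(dataset$nodules)) {
    nd <- dataset$nodules
    bad <- which(nd$singles < 0 | nd$mixed < 0 |
                   nd$singles != round(nd$singles) |
                   nd$mixed != round(nd$mixed))
    if (length(bad)) {
      abort(sprintf("Invalid nodule counts in nodules rows %s", rows_msg(bad)))
    }
    orphan <- which(!nd$pot_id %in% plants$pot_id)
    if (length(orphan)) {
      abort(sprintf("nodules rows %s reference unknown pot_id",
                    rows_msg(orphan)))
    }
  }
  if (!is.null(dataset$cfu)) {
    cf <- dataset$cfu
    bad_cl <- which(!cf$class %in% c("single_colour", "mixed_colour"))
    if (length(bad_cl)) {
      abort(sprintf("Unknown nodule class in cfu rows %s", rows_msg(bad_cl)))
    }
    bad_c <- which(cf$cfu < 0)
    if (length(bad_c)) {
      abort(sprintf("Negative CFU in cfu rows %s", rows_msg(bad_c)))
    }
  }
  if (!is.null(observations)) {
    p <- observations$nodule_proportion
    bad_p <- which(!is.na(p) & (p < 0 | p > 1))
    if (length(bad_p)) {
      abort(sprintf("nodule_proportion outside [0, 1] in rows %s",
                    rows_msg(bad_p)))
    }
  }
  invisible(TRUE)
}
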