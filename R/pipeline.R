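#' Run the full co-inoculation analysis pipeline
#'
#' Orchestrates an end-to-end run: obtain data (simulate from a
#' [sim_config()], use an in-memory dataset, or read tables from disk),
#' validate it, partition variance for the three traits, run the
#' partner-choice regression battery, the sanctions regressions (when CFU
#' data is present), and the neutral-deviation model. Identical input and
#' seed give identical reports; any stage failure is reported with the
#' stage name, and stages already completed are kept in the output
#' directory.
#'
#' @param input One of: a `sim_config` object (data is simulated), a
#'   `rhizo_sim`/`rhizo_data` list, or a named list of file paths
#'   (`plants`, optional `nodules`, `cfu`) read via
#'   [read_experiment_tables()].
#' @param out_dir Optional directory; machine-readable CSV/JSON outputs
#'   and a plain-text report are written there.
#' @param traits Traits to partition variance for.
#' @param growth_rate Optional axenic growth rates passed to
#'   [partner_choice_tests()].
#' @param schema Schema mapping used when `input` is a list of paths.
#' @return A list of class `"rhizo_report"`: `variance_partition`,
#'   `partner_choice`, `sanctions` (tibble or `NULL` with
#'   `sanctions_note`), `deviation` (summary tibble), `deviation_records`,
#'   `excluded`, `provenance`.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         traits = c("nodule_number", "nodule_proportion",
                                    "shoot_mass"),
                         growth_rate = NULL, schema = default_schema()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  save_csv <- function(df, file) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      readr::write_csv(df, file.path(out_dir, file), progress = FALSE)
    }
  }

  seed <- NA_integer_
  dataset <- stage("data", {
    if (inherits(input, "sge_sim_config")) {
      seed <- input$seed
      simulate_experiment(input)
    } else if (inherits(input, "rhizo_data") || is.list(input) &&
                 is.data.frame(input$plants)) {
      input
    } else if (is.list(input) && is.character(input$plants)) {
      read_experiment_tables(input$plants, input$nodules, input$cfu,
                             schema = schema)
    } else {
      abort("Unrecognised `input`.")
    }
  })
  if (inherits(input, "sge_sim_config")) seed <- input$seed

  stage("validate", validate_experiment(dataset,
                                        observations =
                                          dataset$observations))
  dyad <- stage("data", dyadic_table(dataset))

  fits <- stage("sge_reml", {
    out <- lapply(traits, function(tr) fit_sge(dyad, tr))
    setNames(out, traits)
  })
  vt <- stage("sge_reml", variance_table(fits))
  save_csv(vt, "variance_partition.csv")

  pc <- stage("discrimination", partner_choice_tests(dataset,
                                                     growth_rate))
  save_csv(pc, "partner_choice.csv")

  sanctions <- NULL
  sanctions_note <- NULL
  if (!is.null(dataset$cfu) && nrow(dataset$cfu) > 0) {
    sanc <- stage("sanctions", sanctions_summaries(dataset))
    sanctions <- purrr::imap_dfr(
      sanc[c("among_nodule", "intra_nodule")],
      function(r, nm) tibble(test = nm, slope = r$slope,
                             f_statistic = r$f_statistic, df1 = r$df1,
                             df2 = r$df2, p_value = r$p_value,
                             r_squared = r$r_squared, n = r$n))
    save_csv(sanctions, "sanctions.csv")
  } else {
    sanctions_note <- "not computed: no CFU table supplied"
  }

  dev_rec <- stage("deviation", deviation_table(dataset))
  dev_fit <- stage("deviation", fit_deviation_model(dev_rec))
  dev_sum <- tibble(slope = dev_fit$slope, chisq = dev_fit$chisq,
                    df = dev_fit$df, p_value = dev_fit$p_value,
                    n_pots = dev_fit$n)
  save_csv(dev_rec, "deviation_records.csv")
  save_csv(dev_sum, "deviation_model.csv")

  report <- structure(list(
    variance_partition = vt,
    partner_choice = pc,
    sanctions = sanctions,
    sanctions_note = sanctions_note,
    deviation = dev_sum,
    deviation_records = dev_rec,
    fits = fits,
    deviation_fit = dev_fit,
    excluded = setNames(
      lapply(fits, function(f) f$n_excluded), traits),
    provenance = list(package = "rhizosge",
                      version = as.character(utils::packageVersion("rhizosge")),
                      r_version = paste(R.version$major, R.version$minor,
                                        sep = "."),
                      seed = seed)),
    class = "rhizo_report")

  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(variance_partition = vt, partner_choice = pc,
           sanctions = sanctions %||% sanctions_note,
           deviation = dev_sum, provenance = report$provenance),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  report
}

#' @export
print.rhizo_report <- function(x, ...) {
  cat("== Co-inoculation analysis report ==\n")
  cat(sprintf("rhizosge %s, R %s, seed %s\n\n", x$provenance$version,
              x$provenance$r_version, x$provenance$seed))
  cat("-- Variance partition (% of phenotypic variance) --\n")
  print(as.data.frame(x$variance_partition), row.names = FALSE,
        digits = 4)
  cat("\n-- Partner-choice regressions on strain genotypic means --\n")
  print(as.data.frame(x$partner_choice), row.names = FALSE, digits = 4)
  cat("\n-- Sanctions regressions --\n")
  if (is.null(x$sanctions)) {
    cat(x$sanctions_note, "\n")
  } else {
    print(as.data.frame(x$sanctions), row.names = FALSE, digits = 4)
  }
  cat("\n-- Benefit of partner choice (deviation model) --\n")
  print(as.data.frame(x$deviation), row.names = FALSE, digits = 4)
  invisible(x)
}
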