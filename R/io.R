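# Readers, writers, configuration and descriptive summaries. The canonical
# on-disk format is tidy CSV with the labelling-dataset column schema;
# fractions are stored as decimals in [0, 1], days as floats, counts as
# non-negative reals (flow-cytometry estimates).

LABELLING_COLUMNS <- c("mouse_id", "cohort", "subset", "lineage", "day",
                       "n_cells", "f_ki67hi", "f_brdu", "f_brdu_in_ki67hi",
                       "f_brdu_in_ki67lo")

#' Read a labelling dataset
#'
#' Reads and validates a tidy CSV timecourse table. Rows with fractions
#' outside \[0, 1\] or negative counts/days are rejected with their row
#' numbers. The `"study-xlsx"` dialect (the layout of the original
#' supplementary workbook) is not provided by this installation: export the
#' relevant sheet to the tidy CSV schema instead.
#'
#' @param path file path.
#' @param dialect `"tidy-csv"` (canonical) or `"study-xlsx"`.
#' @return validated labelling data.frame.
#' @export
read_labelling_table <- function(path, dialect = c("tidy-csv",
                                                   "study-xlsx")) {
  dialect <- match.arg(dialect)
  if (dialect == "study-xlsx")
    stop("the study-xlsx dialect is not available; export the sheet to ",
         "tidy CSV with columns ", paste(LABELLING_COLUMNS, collapse = ", "),
         call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(LABELLING_COLUMNS, names(d))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- d[LABELLING_COLUMNS]
  num_cols <- setdiff(LABELLING_COLUMNS,
                      c("mouse_id", "cohort", "subset", "lineage"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(d[[cl]]))
    bad <- which(!is.na(d[[cl]]) & is.na(v))
    if (length(bad))
      stop("non-numeric values in column `", cl, "` at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    d[[cl]] <- v
  }
  for (cl in grep("^f_", LABELLING_COLUMNS, value = TRUE)) {
    bad <- which(!is.na(d[[cl]]) & (d[[cl]] < 0 | d[[cl]] > 1))
    if (length(bad))
      stop("fraction `", cl, "` outside [0, 1] at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(d$day < 0 | d$n_cells < 0)
  if (length(bad))
    stop("negative day or count at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  message(sprintf("read %d rows from %s", nrow(d), path))
  d
}

#' Write a labelling dataset to tidy CSV
#'
#' @param dataset a labelling data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labelling_table <- function(dataset, path) {
  utils::write.csv(dataset[LABELLING_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' YAML configuration with a fixed vocabulary; unknown keys are rejected so
#' that typos never silently fall back to defaults. The resolved
#' configuration and seed are reported via `message()` so every run is
#' logged.
#'
#' @param path YAML file path.
#' @return named list of settings with class `memkin_config`.
#' @export
read_config <- function(path) {
  known <- c("structure", "priors", "design", "seed", "rtol", "atol_scale",
             "stages", "n_steps", "n_walkers", "burnin", "thin",
             "dataset", "out")
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(list(structure = "branched", seed = 1,
                                rtol = 1e-8, atol_scale = 1e-10,
                                stages = 1), cfg)
  message("resolved config: ",
          paste(names(cfg), vapply(cfg, function(x)
            paste(format(x), collapse = ","), character(1)),
            sep = "=", collapse = "; "))
  class(cfg) <- "memkin_config"
  cfg
}

#' Descriptive cohort summaries with rank tests
#'
#' Medians of the Ki67-high fraction and of cell counts by subset, lineage
#' and cohort, with standard two-sided rank tests offered as descriptive
#' convenience: Mann-Whitney (unpaired) across cohorts within each subset
#' and lineage, and Wilcoxon across lineages within each subset and cohort
#' (paired by mouse when the design is paired, unpaired otherwise). Groups
#' with fewer than 2 mice per side have their test skipped with a note.
#'
#' @param dataset a labelling data.frame.
#' @return list with `medians` (data.frame) and `tests` (data.frame with
#'   `comparison`, `subset`, `group`, `p_value`, `note`).
#' @export
summarize_cohort <- function(dataset) {
  med <- stats::aggregate(
    cbind(f_ki67hi, n_cells) ~ subset + lineage + cohort, data = dataset,
    FUN = stats::median, na.action = stats::na.omit)
  names(med)[names(med) == "f_ki67hi"] <- "median_f_ki67hi"
  names(med)[names(med) == "n_cells"] <- "median_n_cells"

  tests <- list()
  add_test <- function(comparison, subset, group, x, y, paired = FALSE) {
    if (length(x) < 2 || length(y) < 2 ||
        (paired && length(x) != length(y))) {
      tests[[length(tests) + 1]] <<- data.frame(
        comparison = comparison, subset = subset, group = group,
        p_value = NA_real_, note = "skipped: insufficient group size")
      return(invisible())
    }
    p <- suppressWarnings(
      stats::wilcox.test(x, y, paired = paired, exact = NULL)$p.value)
    tests[[length(tests) + 1]] <<- data.frame(
      comparison = comparison, subset = subset, group = group,
      p_value = p, note = "")
  }
  for (s in unique(dataset$subset)) {
    ds <- dataset[dataset$subset == s & !is.na(dataset$f_ki67hi), ]
    for (l in unique(ds$lineage)) {
      co <- unique(ds$cohort)
      if (length(co) == 2)
        add_test("young_vs_old", s, l,
                 ds$f_ki67hi[ds$lineage == l & ds$cohort == co[1]],
                 ds$f_ki67hi[ds$lineage == l & ds$cohort == co[2]])
    }
    for (co in unique(ds$cohort)) {
      li <- unique(ds$lineage)
      if (length(li) == 2) {
        xh <- ds[ds$cohort == co & ds$lineage == li[1], ]
        xd <- ds[ds$cohort == co & ds$lineage == li[2], ]
        paired <- identical(sort(xh$mouse_id), sort(xd$mouse_id)) &&
          nrow(xh) == nrow(xd)
        if (paired) {
          xh <- xh[order(xh$mouse_id), ]; xd <- xd[order(xd$mouse_id), ]
        }
        add_test("host_vs_donor", s, co, xh$f_ki67hi, xd$f_ki67hi,
                 paired = paired)
      }
    }
  }
  list(medians = med,
       tests = if (length(tests)) do.call(rbind, tests)
               else data.frame(comparison = character(), subset = character(),
                               group = character(), p_value = numeric(),
                               note = character()))
}

#' Serialize a parameter set to a flat YAML configuration
#'
#' Writes a [kinetic_params()] set as flat key-value YAML with the model
#' structure recorded under a `structure:` key; [read_params()] restores
#' both.
#'
#' @param params a [kinetic_params()].
#' @param structure a [model_structure()] or name.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, structure, path) {
  structure <- as_structure(structure)
  yaml::write_yaml(c(list(structure = structure$name), unclass(params)),
                   path, precision = 15)
  invisible(path)
}

#' Read a parameter set written by [write_params()]
#'
#' @param path YAML file with a `structure:` key and flat parameter values.
#' @return list with `structure` (a [model_structure()]) and `params`
#'   (a [kinetic_params()]).
#' @export
read_params <- function(path) {
  v <- yaml::read_yaml(path)
  if (is.null(v$structure))
    stop("parameter file needs a `structure:` key", call. = FALSE)
  st <- model_structure(v$structure)
  v$structure <- NULL
  list(structure = st, params = do.call(kinetic_params, v))
}

#' Write replacement-fit posterior summaries and the influx prior
#'
#' Persists a [fit_replacement()] result as a CSV of posterior quantile
#' summaries and (optionally) the influx prior specification consumed by
#' [fit_model()] as YAML.
#'
#' @param fit an `influx_estimate`.
#' @param csv_path output CSV for the posterior summary table.
#' @param yaml_path optional output YAML for the [influx_prior()] spec.
#' @return `csv_path`, invisibly.
#' @export
write_influx_estimate <- function(fit, csv_path, yaml_path = NULL) {
  s <- as.data.frame(fit$summary)
  s <- cbind(parameter = rownames(s), s)
  names(s) <- c("parameter", "q2.5", "q50", "q97.5")
  utils::write.csv(s, csv_path, row.names = FALSE)
  if (!is.null(yaml_path))
    yaml::write_yaml(influx_prior(fit), yaml_path, precision = 15)
  invisible(csv_path)
}

#' Read a prior specification from YAML
#'
#' @param path YAML file of named prior specifications (as produced by
#'   [write_influx_estimate()]), usable as the `priors` argument of
#'   [fit_model()].
#' @return named list of prior specifications.
#' @export
read_priors <- function(path) {
  yaml::read_yaml(path)
}
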