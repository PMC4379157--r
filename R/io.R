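#' Measurement table schemas
#'
#' Required columns for each raw CSV the pipeline reads.  Extra columns
#' are tolerated (with a message); missing required columns are an error.
#'
#' @format named list of character vectors.
#' @export
measurement_schemas <- list(
  plots = c("site", "treatment", "replicate", "agb_n_uptake_kg_ha"),
  isotope = c("site", "treatment", "replicate", "pool", "atom_pct_15n",
              "total_n_kg_ha"),
  mesocosm = c("site", "treatment", "replicate", "agb_n_uptake_kg_ha"),
  water = c("site", "date", "location", "nh4_n_mg_l", "no3_n_mg_l"),
  fallow = c("site", "measure", "replicate", "units", "value")
)

#' Read and validate a measurement CSV
#'
#' @param path CSV file path.
#' @param schema one of `names(measurement_schemas)`.
#' @return validated data frame.
#' @export
read_measurements <- function(path, schema) {
  schema <- match.arg(schema, names(measurement_schemas))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- measurement_schemas[[schema]]
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(schema, " table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), required)
  if (length(extra))
    message("ignoring extra column(s) in ", path, ": ",
            paste(extra, collapse = ", "))
  numcols <- setdiff(required, c("site", "treatment", "pool", "location",
                                 "measure", "units", "date"))
  for (cl in numcols) {
    df[[cl]] <- as.numeric(df[[cl]])
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad))
      stop("non-numeric ", cl, " in ", path, " at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (cl != "value" && any(df[[cl]] < 0))
      stop("negative ", cl, " in ", path, " at row(s) ",
           paste(which(df[[cl]] < 0), collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a synthetic site dataset as CSV files plus ground truth
#'
#' Writes the five measurement tables in the schemas the readers expect,
#' plus `truth.json` holding the scenario's closed-form budget ledger.
#'
#' @param data a `"synthetic_site"` object from [generate_site_data()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_site_data <- function(data, dir) {
  stopifnot(inherits(data, "synthetic_site"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in c("plots", "isotope", "mesocosm", "water", "fallow"))
    utils::write.csv(data[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  truth <- data$truth$ledger
  jsonlite::write_json(
    list(seed = data$seed,
         ledger = stats::setNames(as.list(truth$value), truth$item)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full budget pipeline from a configuration
#'
#' Reads the five raw measurement CSVs, summarises them into budget
#' inputs, fits the annual budget and (optionally) writes a tidy CSV
#' ledger and a full-precision JSON report.
#'
#' @param config named list (or path to a YAML file, requires the `yaml`
#'   package) with elements `data_dir` (directory holding `plots.csv`,
#'   `isotope.csv`, `mesocosm.csv`, `water.csv`, `fallow.csv`),
#'   `cn_ratio`, `bulk_density`, and optionally `som_pct_c`, `f_min`,
#'   `n_deposition`, `n_fixation`, `nue`, `nue_grid`, `se_mode`,
#'   `out_dir`.
#' @return the `"n_budget"` fit, invisibly if a report is written.
#' @export
run_budget <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  for (key in c("data_dir", "cn_ratio", "bulk_density"))
    if (is.null(config[[key]]))
      stop("config is missing required key: ", key, call. = FALSE)
  get_or <- function(key, default) {
    if (is.null(config[[key]])) default else config[[key]]
  }
  tables <- lapply(stats::setNames(nm = names(measurement_schemas)),
                   function(s) read_measurements(
                     file.path(config$data_dir, paste0(s, ".csv")), s))
  profile <- soil_profile(cn_ratio = config$cn_ratio,
                          som_pct_c = get_or("som_pct_c", 0.58),
                          bulk_density = config$bulk_density,
                          f_min = get_or("f_min", 0.67))
  consts <- budget_constants(n_deposition = get_or("n_deposition", 6),
                             n_fixation = get_or("n_fixation", 25),
                             nue = get_or("nue", 0.5))
  et <- et_model(cumulative_et_m = get_or("et_m", 0.634),
                 crop_coefficient = get_or("crop_coefficient", 1.06))
  site <- site_from_tables(tables$plots, tables$isotope, tables$mesocosm,
                           tables$water, tables$fallow,
                           et = et, profile = profile)
  fit <- n_budget(site, consts, se_mode = get_or("se_mode", "paper"),
                  nue_grid = get_or("nue_grid", seq(0.30, 0.90, 0.05)))
  if (!is.null(config$out_dir)) {
    write_budget_report(fit, config$out_dir)
    return(invisible(fit))
  }
  fit
}

#' Write budget reports
#'
#' Writes `closs_report.csv` — the tidy ledger plus the NUE sensitivity
#' curve, rounded by the display convention (one decimal for N lines,
#' integers for C lines, two decimals for subsidence) — and
#' `budget_report.json` at full precision.
#'
#' @param fit an `"n_budget"` fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_budget_report <- function(fit, dir) {
  stopifnot(inherits(fit, "n_budget"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  led <- fit$ledger
  tidy <- data.frame(site = fit$site$site, nue = fit$constants$nue,
                     line_item = led$item,
                     value = .display_round(led$value, led$units),
                     se = .display_round(led$se, led$units),
                     units = led$units)
  sen <- fit$sensitivity
  tidy <- rbind(tidy, data.frame(
    site = fit$site$site, nue = sen$nue, line_item = "net_c_loss",
    value = round(sen$net_c_loss), se = round(sen$net_c_loss_se),
    units = "kg C ha-1"))
  utils::write.csv(tidy, file.path(dir, "closs_report.csv"),
                   row.names = FALSE)
  report <- list(
    site = fit$site$site,
    se_mode = fit$se_mode,
    constants = unclass(fit$constants),
    profile = unclass(fit$site$profile),
    ledger = stats::setNames(
      lapply(seq_len(nrow(led)), function(i)
        list(value = signif(led$value[i], 12), se = signif(led$se[i], 12),
             units = led$units[i])),
      led$item),
    nue_sensitivity = sen)
  jsonlite::write_json(report, file.path(dir, "budget_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
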