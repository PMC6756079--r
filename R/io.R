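# File I/O for model inputs. A model-input set is a directory holding
#   config.yaml            model settings, scenarios, cost-table metadata
#   adherence_studies.csv  name,n,scale,low,medium,high
#   risk_studies.csv       name,n,rr_lm,lo_lm,hi_lm,rr_lh,lo_lh,hi_lh
#   cost_table_<id>.csv    category,kind,amount_base,amount_2017,variable_share
# Numeric fields are written in shortest-round-trip decimal form, so a
# write/load cycle reproduces every double bit-identically.

#' Load a complete model-input set
#'
#' With \code{path = NULL} returns the bundled published tables and the
#' reproduction configuration; otherwise reads and validates the CSV/YAML
#' input set in the directory \code{path}. Derived fields (standard
#' errors, table totals) are populated during validation; schema
#' violations raise errors naming the offending row and field.
#'
#' @param path Directory containing the input set, or NULL for the
#'   bundled fixtures.
#' @return A list with class \code{model_inputs}: \code{adherence},
#'   \code{risk}, \code{costs} (named list of [cost_table()]s) and
#'   \code{config} (a [coi_config()]).
#' @export
load_model_inputs <- function(path = NULL) {
  if (is.null(path)) {
    out <- list(adherence = us_adherence_studies(),
                risk = cvd_risk_studies(),
                costs = list(us = us_cost_table(), canada = canada_cost_table()),
                config = coi_config())
    class(out) <- "model_inputs"
    return(out)
  }
  if (!dir.exists(path)) stopf("input directory '%s' does not exist", path)
  need_file <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stopf("input set is missing '%s'", f)
    fp
  }
  cfg <- yaml::read_yaml(need_file("config.yaml"))
  num <- function(x, field) {
    if (is.null(x)) stopf("config.yaml: missing field '%s'", field)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stopf("config.yaml: field '%s' is not numeric", field)
    v
  }
  scenarios <- lapply(cfg$scenarios, function(s) {
    scenario_shift(label = s$label, f_lm = num(s$f_lm, "f_lm"),
                   f_mh = num(s$f_mh, "f_mh"),
                   mode = s$mode %||% "calibrated",
                   mean_reduction = if (!is.null(s$mean_reduction))
                     num(s$mean_reduction, "mean_reduction"))
  })
  m <- cfg$model %||% list()
  config <- coi_config(
    n_draws = num(m$n_draws %||% 10000, "n_draws"),
    seed = num(m$seed %||% 42, "seed"),
    weighting = m$weighting %||% "equal",
    rr_scale = m$rr_scale %||% "raw",
    spread_mode = m$spread_mode %||% "select",
    discount_rate = num(m$discount_rate %||% 0.018, "discount_rate"),
    horizon = num(m$horizon %||% 10, "horizon"),
    scenarios = scenarios)
  adherence <- adherence_studies(
    utils::read.csv(need_file("adherence_studies.csv"), stringsAsFactors = FALSE))
  risk <- risk_studies(
    utils::read.csv(need_file("risk_studies.csv"), stringsAsFactors = FALSE))
  if (is.null(cfg$cost_tables) || !length(cfg$cost_tables))
    stopf("config.yaml: no cost tables declared")
  costs <- lapply(names(cfg$cost_tables), function(id) {
    meta <- cfg$cost_tables[[id]]
    cats <- utils::read.csv(need_file(meta$file %||% sprintf("cost_table_%s.csv", id)),
                            stringsAsFactors = FALSE)
    cost_table(country = meta$country %||% id,
               currency = meta$currency %||% "$",
               units = meta$units %||% "billion",
               base_year = as.integer(num(meta$base_year, "base_year")),
               categories = cats,
               cpi_factor = num(meta$cpi_factor, "cpi_factor"),
               annual_growth = num(meta$annual_growth, "annual_growth"),
               total_2017 = if (!is.null(meta$total_2017))
                 num(meta$total_2017, "total_2017"))
  })
  names(costs) <- names(cfg$cost_tables)
  out <- list(adherence = adherence, risk = risk, costs = costs, config = config)
  class(out) <- "model_inputs"
  out
}

#' Write a model-input set to a directory
#'
#' Inverse of [load_model_inputs()]: emits the CSV/YAML schema with
#' full-precision numerics, so loading the written set reproduces every
#' field exactly.
#'
#' @param inputs A \code{model_inputs} list.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_model_inputs <- function(inputs, dir) {
  stopifnot(inherits(inputs, "model_inputs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_num_csv <- function(df, file, num_cols) {
    for (col in num_cols) df[[col]] <- num_chr(df[[col]])
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, quote = TRUE)
  }
  adh <- as.data.frame(inputs$adherence)[c("name", "n", "scale", "low", "medium", "high")]
  write_num_csv(adh, "adherence_studies.csv", c("low", "medium", "high"))
  rsk <- as.data.frame(inputs$risk)[c("name", "n", "rr_lm", "lo_lm", "hi_lm",
                                      "rr_lh", "lo_lh", "hi_lh")]
  write_num_csv(rsk, "risk_studies.csv",
                c("rr_lm", "lo_lm", "hi_lm", "rr_lh", "lo_lh", "hi_lh"))
  cost_meta <- list()
  for (id in names(inputs$costs)) {
    tb <- inputs$costs[[id]]
    fname <- sprintf("cost_table_%s.csv", id)
    write_num_csv(tb$categories, fname,
                  c("amount_base", "amount_2017", "variable_share"))
    cost_meta[[id]] <- list(
      file = fname, country = tb$country, currency = tb$currency,
      units = tb$units, base_year = as.integer(tb$base_year),
      cpi_factor = num_chr(tb$cpi_factor),
      annual_growth = num_chr(tb$annual_growth),
      total_2017 = num_chr(tb$total_2017))
  }
  cfg <- inputs$config
  yaml::write_yaml(list(
    model = list(n_draws = cfg$n_draws, seed = cfg$seed,
                 weighting = cfg$weighting, rr_scale = cfg$rr_scale,
                 spread_mode = cfg$spread_mode,
                 discount_rate = num_chr(cfg$discount_rate),
                 horizon = cfg$horizon),
    scenarios = lapply(cfg$scenarios, function(s) {
      out <- list(label = s$label, f_lm = num_chr(s$f_lm),
                  f_mh = num_chr(s$f_mh), mode = s$mode)
      if (!is.null(s$mean_reduction))
        out$mean_reduction <- num_chr(s$mean_reduction)
      out
    }),
    cost_tables = cost_meta), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Dump a normalized JSON image of the loaded model inputs
#'
#' Provenance record of everything the model consumes, including derived
#' fields (standard errors, totals), written with full numeric precision.
#'
#' @param inputs A \code{model_inputs} list.
#' @param path Output JSON file.
#' @return \code{path}, invisibly.
#' @export
model_inputs_json <- function(inputs, path) {
  stopifnot(inherits(inputs, "model_inputs"))
  obj <- list(
    adherence_studies = as.data.frame(inputs$adherence),
    risk_studies = as.data.frame(inputs$risk),
    cost_tables = lapply(inputs$costs, function(tb)
      list(country = tb$country, currency = tb$currency, units = tb$units,
           base_year = tb$base_year, cpi_factor = tb$cpi_factor,
           annual_growth = tb$annual_growth, total_2017 = tb$total_2017,
           categories = tb$categories)),
    config = list(
      n_draws = inputs$config$n_draws, seed = inputs$config$seed,
      weighting = inputs$config$weighting, rr_scale = inputs$config$rr_scale,
      spread_mode = inputs$config$spread_mode,
      discount_rate = inputs$config$discount_rate,
      horizon = inputs$config$horizon,
      scenarios = lapply(inputs$config$scenarios, unclass)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
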