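#' Declarative configuration of a full pipeline run
#'
#' @param outdir output directory for all stage artifacts.
#' @param seed master seed; every stochastic stage derives a sub-seed from it.
#' @param simulate logical; generate inputs with the synthetic module
#'   (`sim` overrides) or read them from `input_dir` (the CSV schemas of
#'   [write_study_csvs()]).
#' @param sim named list of [sim_config()] overrides.
#' @param input_dir directory of input CSVs when `simulate = FALSE`.
#' @param levels global warming levels (degrees C), strictly increasing.
#' @param n_sim Monte-Carlo draws per projection.
#' @param df_per_year time-spline degrees of freedom per year (first stage).
#' @param basis named list of [basis_spec()] overrides.
#' @param meta_formula meta-regression formula over metadata columns.
#' @param qm_by_month logical; monthly (default) or annual quantile maps.
#' @param threshold_years threshold of the city-count summary.
#' @param stages character subset of
#'   `c("simulate", "fit", "pool", "climate", "project", "compare")`;
#'   toggled-off stages are skipped (and noted in the manifest).
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir,
                       seed = 1L,
                       simulate = TRUE,
                       sim = list(),
                       input_dir = NULL,
                       levels = c(1, 1.5, 2, 3),
                       n_sim = 1000,
                       df_per_year = 8,
                       basis = list(),
                       meta_formula = ~1,
                       qm_by_month = TRUE,
                       threshold_years = 10,
                       stages = c("simulate", "fit", "pool", "climate",
                                  "project", "compare")) {
  if (any(levels <= 0) || any(diff(levels) <= 0)) {
    stop_config("levels must be positive and strictly increasing")
  }
  if (!is_count(n_sim)) stop_config("n_sim must be a count >= 1")
  bad <- setdiff(stages, c("simulate", "fit", "pool", "climate", "project",
                           "compare"))
  if (length(bad)) stop_config("unknown stages: %s", paste(bad, collapse = ", "))
  if (!simulate && is.null(input_dir)) {
    stop_config("input_dir is required when simulate = FALSE")
  }
  cfg <- list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
              sim = sim, input_dir = input_dir, levels = levels,
              n_sim = n_sim, df_per_year = df_per_year, basis = basis,
              meta_formula = meta_formula, qm_by_month = qm_by_month,
              threshold_years = threshold_years, stages = stages)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Accepts the fields of [run_config()]; `meta_formula` may be given as a
#' character string.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$meta_formula)) {
    doc$meta_formula <- stats::as.formula(doc$meta_formula)
  }
  do.call(run_config, doc)
}

config_hash <- function(config) {
  canon <- config
  canon$meta_formula <- deparse(canon$meta_formula)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(canon[order(names(canon))]), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

#' Read the pipeline's input CSVs
#'
#' Inverse of [write_study_csvs()]: loads the per-location daily series and
#' model series, the global anomaly, COVID-19 and metadata tables.
#'
#' @param dir directory of input CSVs.
#' @return list with `series`, `model_daily`, `anomaly`, `covid`, `metadata`.
#' @export
read_study_csvs <- function(dir) {
  loc_files <- sort(list.files(dir, "^location_[0-9]+\\.csv$",
                               full.names = TRUE))
  if (!length(loc_files)) stop_config("no location_*.csv files in %s", dir)
  series <- lapply(loc_files, function(f) {
    df <- utils::read.csv(f)
    df$date <- as.Date(df$date)
    df
  })
  mod_files <- sort(list.files(dir, "^models_location_[0-9]+\\.csv$",
                               full.names = TRUE))
  model_daily <- lapply(mod_files, function(f) {
    df <- utils::read.csv(f)
    df$date <- as.Date(df$date)
    split(df, df$model_id)
  })
  anomaly <- utils::read.csv(file.path(dir, "global_anomaly.csv"))
  covid <- utils::read.csv(file.path(dir, "covid.csv"))
  metadata <- utils::read.csv(file.path(dir, "metadata.csv"))
  list(series = series, model_daily = model_daily, anomaly = anomaly,
       covid = covid, metadata = metadata)
}

#' Validate pipeline input files
#'
#' Schema checks for every input CSV: required columns, types, date
#' continuity, non-negative counts. Schema violations are fatal errors; date
#' gaps are warnings.
#'
#' @param dir directory of input CSVs (e.g. a [write_study_csvs()] output).
#' @return list of class `validation_report` with `errors` and `warnings`
#'   character vectors.
#' @export
validate_inputs <- function(dir) {
  errors <- character(0); warns <- character(0)
  note_err <- function(...) errors <<- c(errors, sprintf(...))
  note_warn <- function(...) warns <<- c(warns, sprintf(...))
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      note_err("%s: missing columns %s", file, paste(miss, collapse = ", "))
      return(FALSE)
    }
    TRUE
  }
  check_dates <- function(dates, file) {
    d <- as.Date(dates)
    if (any(is.na(d))) {
      note_err("%s: unparseable dates (row %d)", file, which(is.na(d))[1])
      return()
    }
    gaps <- diff(d)
    big <- which(gaps > 1)
    for (g in big) {
      note_warn("%s: date gap of %d days after %s", file,
                as.integer(gaps[g]) - 1L, format(d[g]))
    }
  }
  for (f in sort(list.files(dir, "^location_[0-9]+\\.csv$"))) {
    df <- utils::read.csv(file.path(dir, f))
    if (!need(df, c("date", "deaths", "tmean"), f)) next
    check_dates(df$date, f)
    if (any(df$deaths < 0, na.rm = TRUE)) {
      note_err("%s: negative deaths at row %d", f, which(df$deaths < 0)[1])
    }
    if (any(df$deaths != round(df$deaths), na.rm = TRUE)) {
      note_err("%s: non-integer deaths at row %d", f,
               which(df$deaths != round(df$deaths))[1])
    }
    if (any(!is.finite(df$tmean))) {
      note_err("%s: non-finite temperature at row %d", f,
               which(!is.finite(df$tmean))[1])
    }
  }
  for (f in sort(list.files(dir, "^models_location_[0-9]+\\.csv$"))) {
    df <- utils::read.csv(file.path(dir, f))
    if (!need(df, c("model_id", "date", "tmean"), f)) next
    for (m in unique(df$model_id)) check_dates(df$date[df$model_id == m],
                                               sprintf("%s[model %s]", f, m))
  }
  f <- "global_anomaly.csv"
  if (file.exists(file.path(dir, f))) {
    df <- utils::read.csv(file.path(dir, f))
    need(df, c("model_id", "year", "anomaly"), f)
  } else note_err("%s: file missing", f)
  f <- "covid.csv"
  if (file.exists(file.path(dir, f))) {
    df <- utils::read.csv(file.path(dir, f))
    if (need(df, c("country", "deaths_2020", "deaths_2021",
                   "crude_rate_per_1000", "population"), f)) {
      for (cn in c("deaths_2020", "deaths_2021", "population")) {
        if (any(df[[cn]] < 0)) note_err("%s: negative %s at row %d", f, cn,
                                        which(df[[cn]] < 0)[1])
      }
    }
  } else note_err("%s: file missing", f)
  f <- "metadata.csv"
  if (file.exists(file.path(dir, f))) {
    df <- utils::read.csv(file.path(dir, f))
    need(df, c("location_id", "country", "region", "climate_class",
               "gdp_pc", "lon", "lat"), f)
  } else note_err("%s: file missing", f)
  structure(list(errors = errors, warnings = warns),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Input validation: %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  ERROR:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

write_pipeline_csv <- function(df, path) {
  utils::write.csv(format_csv_numbers(df), path, row.names = FALSE,
                   quote = FALSE)
}

#' Run the full heat-mortality pipeline
#'
#' Executes the enabled stages in order — simulate (or read) inputs, fit the
#' first-stage DLNMs, pool and derive BLUPs, prepare climate windows and
#' bias corrections, project heat impacts at each warming level, and build
#' the COVID-19 comparison — writing every stage's outputs under
#' `config$outdir` together with a manifest (configuration hash, seed,
#' package version, per-stage status and row counts). Reruns under an
#' identical configuration produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly; stage results are attached as the
#'   `results` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("heatmort")),
                   stages = list())
  results <- list()
  note <- function(stage, status, rows = NA_integer_) {
    manifest$stages[[stage]] <<- list(status = status, rows = rows)
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) {
      note(stage, "skipped")
      return(NULL)
    }
    tryCatch(fn(), error = function(e) {
      note(stage, "failed")
      manifest$stages[[stage]]$error <<- conditionMessage(e)
      jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- inputs ---------------------------------------------------------------
  inputs <- run_stage("simulate", function() {
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    study <- simulate_study(scfg)
    write_study_csvs(study, file.path(config$outdir, "inputs"))
    note("simulate", "ok", scfg$n_locations)
    list(series = study$series, model_daily = study$model_daily,
         anomaly = study$anomaly, covid = study$covid,
         metadata = study$metadata, truth = study$truth)
  })
  if (is.null(inputs)) {
    inputs <- read_study_csvs(config$input_dir %||%
                                file.path(config$outdir, "inputs"))
  }
  results$inputs <- inputs
  nl <- length(inputs$series)
  baselines <- vapply(inputs$series, function(s) mean(s$deaths), 0)

  # --- first stage ----------------------------------------------------------
  spec <- do.call(basis_spec, config$basis)
  curves <- run_stage("fit", function() {
    crvs <- lapply(seq_len(nl), function(i) {
      cumulative_curve(heat_dlnm(inputs$series[[i]], spec,
                                 config$df_per_year))
    })
    for (i in seq_len(nl)) {
      curve_to_json(crvs[[i]], file.path(config$outdir,
                                         sprintf("curve_%02d.json", i)))
    }
    note("fit", "ok", nl)
    crvs
  })
  results$curves <- curves

  # --- pooling --------------------------------------------------------------
  blups <- run_stage("pool", function() {
    if (is.null(curves)) stop("pooling requires the fit stage")
    pooled <- heat_meta(curves, config$meta_formula, inputs$metadata)
    bl <- blup(pooled)
    meta_to_json(pooled, file.path(config$outdir, "meta_blups.json"))
    note("pool", "ok", nl)
    results$meta <<- pooled
    bl
  })
  results$blups <- blups

  # --- climate preparation --------------------------------------------------
  windows <- run_stage("climate", function() {
    w <- gwl_windows(inputs$anomaly, config$levels)
    write_pipeline_csv(w, file.path(config$outdir, "gwl_windows.csv"))
    note("climate", "ok", nrow(w))
    w
  })
  results$windows <- windows

  # --- projection -----------------------------------------------------------
  impacts <- run_stage("project", function() {
    if (is.null(blups) || is.null(windows)) {
      stop("projection requires the pool and climate stages")
    }
    all_rows <- list(); case_rows <- list()
    for (i in seq_len(nl)) {
      per_model <- lapply(inputs$model_daily[[i]], function(md) {
        w <- windows[windows$model_id == md$model_id[1], , drop = FALSE]
        corrected_window_temps(md[, c("date", "tmean")],
                               inputs$series[[i]][, c("date", "tmean")], w,
                               by_month = config$qm_by_month)
      })
      names(per_model) <- vapply(inputs$model_daily[[i]],
                                 function(md) as.character(md$model_id[1]), "")
      for (k in seq_along(config$levels)) {
        lev <- config$levels[k]
        wt <- lapply(per_model, function(pm) pm[[as.character(lev)]])
        wt <- wt[!vapply(wt, is.null, TRUE)]
        imp <- project_heat(blups[[i]], wt, lev, baselines[i],
                            n_sim = config$n_sim,
                            seed = substream_seed(config$seed, "montecarlo",
                                                  i, k),
                            location = i)
        all_rows[[length(all_rows) + 1L]] <- as.data.frame(imp)
        if (nrow(imp)) {
          case_rows[[length(case_rows) + 1L]] <- summarize_cases(imp)
        }
      }
    }
    imp_df <- do.call(rbind, all_rows)
    write_pipeline_csv(imp_df, file.path(config$outdir, "impacts.csv"))
    note("project", "ok", nrow(imp_df))
    list(impacts = imp_df, cases = do.call(rbind, case_rows))
  })
  results$impacts <- impacts

  # --- comparison -----------------------------------------------------------
  comparison <- run_stage("compare", function() {
    if (is.null(impacts)) stop("comparison requires the project stage")
    tab <- build_comparison_table(impacts$cases, inputs$covid,
                                  inputs$metadata, config$threshold_years)
    write_pipeline_csv(as.data.frame(tab),
                       file.path(config$outdir, "comparison.csv"))
    write_pipeline_csv(attr(tab, "counts"),
                       file.path(config$outdir, "city_counts.csv"))
    note("compare", "ok", nrow(tab))
    tab
  })
  results$comparison <- comparison

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}
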