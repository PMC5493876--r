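# End-to-end orchestration: simulate (optional) -> graph -> impute ->
# per-(stratum, indicator) fit -> predict -> aggregate -> validate, with a
# machine-readable manifest.

registry_col_classes <- list(
  integer = c("person_id", "age", "hhsize", "hhcap", "hhinc", "urb"),
  character = c("household_id", "neighbourhood_id", "sex", "eth", "mar",
                "hhtype", "hhincsrc", "home"))

#' Write / read registry and survey tables as CSV
#'
#' Column contract of the person records; absent values are written as
#' empty fields, never sentinel numbers.
#'
#' @param records a registry or survey table.
#' @param path CSV path.
#' @return `path` (write) or a data.table (read).
#' @export
write_registry_csv <- function(records, path) {
  data.table::fwrite(data.table::as.data.table(records), path, na = "")
  invisible(path)
}

#' @rdname write_registry_csv
#' @export
read_registry_csv <- function(path) {
  out <- data.table::fread(path, colClasses = registry_col_classes,
                           na.strings = "")
  out[]
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline, with defaults matching the
#' production constants of the method: 10 km buffer, 10-knot smooths
#' (5 for household size) inside [default_model_spec()], sanitisation
#' below 10 adults, 200 calibration bins, a 2/3-1/3 train/validation
#' split and 1000 Monte-Carlo draws. Every stochastic stage derives an
#' explicit sub-seed from `seed`.
#'
#' @param output_dir directory for all artifacts.
#' @param population a [population_config()] describing the synthetic
#'   registry (simulation mode), or NULL when reading inputs from files.
#' @param geometry_path,registry_path,survey_path input files (GeoJSON /
#'   CSV) used when `population` is NULL.
#' @param indicators indicator columns to model (default: those of the
#'   population config).
#' @param spec a [model_spec()]; default [default_model_spec()].
#' @param merge_map named character vector merging small strata into
#'   partners (see [plan_runs()]).
#' @param buffer_m estimation buffer, metres.
#' @param sanitise_below sanitisation threshold (adults).
#' @param n_bins calibration quantile bins.
#' @param split_fractions train/validation fractions.
#' @param mc_draws Monte-Carlo draws (used when `run_mc`).
#' @param run_mc compute Monte-Carlo uncertainty per area.
#' @param run_validation fit on the training split and emit a calibration
#'   table per indicator.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(output_dir,
                       population = population_config(),
                       geometry_path = NULL, registry_path = NULL,
                       survey_path = NULL,
                       indicators = NULL, spec = default_model_spec(),
                       merge_map = character(),
                       buffer_m = 10000, sanitise_below = 10L,
                       n_bins = 200L, split_fractions = c(2 / 3, 1 / 3),
                       mc_draws = 1000L, run_mc = FALSE,
                       run_validation = TRUE, seed = 1L) {
  if (is.null(population) &&
      (is.null(geometry_path) || is.null(registry_path) ||
       is.null(survey_path))) {
    stop("either a population config (simulate) or all three input paths")
  }
  structure(list(output_dir = output_dir, population = population,
                 geometry_path = geometry_path,
                 registry_path = registry_path, survey_path = survey_path,
                 indicators = indicators %||% population$indicators,
                 spec = spec, merge_map = merge_map, buffer_m = buffer_m,
                 sanitise_below = as.integer(sanitise_below),
                 n_bins = as.integer(n_bins),
                 split_fractions = split_fractions,
                 mc_draws = as.integer(mc_draws), run_mc = run_mc,
                 run_validation = run_validation, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the small-area-estimation pipeline end to end
#'
#' Executes: simulate (or load) geometry, registry and survey; inject and
#' impute missingness; per effective stratum and indicator build the
#' buffered, connected estimation graph, fit the structured additive
#' model on the respondents, predict the core-region registry, replace
#' respondents' values by their observed outcomes and aggregate to the
#' three area levels; optionally Monte-Carlo uncertainty and a
#' train/validation calibration table; finally write all artifacts plus a
#' manifest capturing seeds, parameters and per-fit convergence, from
#' which any run can be reproduced.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `estimates`, `fits`, `calibration`,
#'   `manifest`, and the file paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(...) file.path(config$output_dir, ...)
  paths <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate or load ------------------------------------------------
  if (!is.null(config$population)) {
    graph <- stage("simulate-geometry", generate_geometry(config$population))
    pop <- stage("simulate-population",
                 generate_population(config$population, graph))
    registry <- registry_table(pop)
    survey <- survey_table(pop)
    registry <- stage("missingness",
                      inject_missingness(registry,
                                         config$population$missingness_rates,
                                         seed = config$seed))
  } else {
    graph <- stage("load-geometry", read_geojson(config$geometry_path))
    registry <- stage("load-registry", read_registry_csv(config$registry_path))
    survey <- stage("load-survey",
                    data.table::fread(config$survey_path, na.strings = ""))
    pop <- NULL
  }
  write_geojson(graph, paths["geometry"] <- out_path("geometry.geojson"))
  write_edges_csv(graph, paths["edges"] <- out_path("edges.csv"))
  write_registry_csv(registry, paths["registry"] <- out_path("registry.csv"))
  data.table::fwrite(survey, paths["survey"] <- out_path("survey.csv"),
                     na = "")

  # --- impute ----------------------------------------------------------
  registry <- stage("impute", impute_registry(registry, seed = config$seed))
  write_registry_csv(registry,
                     paths["registry_imputed"] <- out_path("registry_imputed.csv"))

  # --- per-(stratum, indicator) fits ----------------------------------
  strata <- sort(unique(graph$areas$stratum_id))
  plan <- plan_runs(strata, config$indicators, config$merge_map)
  fit_records <- merge(registry, survey[, !"neighbourhood_id", with = FALSE],
                       by = "person_id")
  areas_map <- data.table::as.data.table(
    graph$areas[, c("neighbourhood_id", "district_id", "municipality_id",
                    "stratum_id")])

  fits <- list()
  estimates <- list()
  values_all <- list()
  dir.create(out_path("fits"), showWarnings = FALSE)
  eff_groups <- split(plan$members, plan$effective_stratum)
  for (r in seq_len(nrow(plan))) {
    eff <- plan$effective_stratum[r]
    members <- strsplit(plan$members[r], "+", fixed = TRUE)[[1L]]
    ind <- plan$indicator[r]
    run_id <- paste0(eff, "_", ind)

    sel <- stage(paste0("buffer:", run_id), {
      core <- unlist(lapply(members, function(s)
        buffer_select(graph, s, 0)$core))
      buf <- setdiff(unique(unlist(lapply(members, function(s)
        buffer_select(graph, s, config$buffer_m)$estimation))), core)
      list(core = core, buffer = buf, estimation = c(core, buf))
    })
    est_graph <- stage(paste0("graph:", run_id),
                       connect_subgraphs(graph_subset(graph, sel$estimation)))

    est_records <- fit_records[fit_records$neighbourhood_id %in%
                                 sel$estimation & !is.na(fit_records[[ind]])]
    fit <- stage(paste0("fit:", run_id),
                 fit_star(config$spec, est_records, outcome = ind,
                          graph = est_graph, stratum_id = eff))
    write_fitted_star(fit, out_path("fits", paste0(run_id, ".json")))
    fits[[run_id]] <- fit

    core_registry <- registry[registry$neighbourhood_id %in% sel$core]
    core_registry <- merge(core_registry, areas_map, by = "neighbourhood_id")
    probs <- stage(paste0("predict:", run_id),
                   predict_population(fit, core_registry))
    core_survey <- survey[survey$neighbourhood_id %in% sel$core]
    values <- overwrite_observed(probs, core_survey, ind)
    values_all[[ind]] <- c(values_all[[ind]], values)

    for (level in c("neighbourhood", "district", "municipality")) {
      est <- aggregate_prevalence(values, core_registry, level,
                                  config$sanitise_below)
      est[, indicator := ind]
      if (config$run_mc) {
        mc <- monte_carlo_uncertainty(fit, core_registry, core_survey, ind,
                                      level, n_draws = config$mc_draws,
                                      seed = config$seed,
                                      sanitise_below = config$sanitise_below)
        est <- merge(est, mc[, .(area_id, mc_sd)], by = "area_id",
                     sort = FALSE)
      }
      estimates[[level]] <- data.table::rbindlist(
        c(list(estimates[[level]]), list(est)), use.names = TRUE,
        fill = TRUE)
    }
  }
  for (level in names(estimates)) {
    est <- estimates[[level]][order(indicator, area_id)]
    estimates[[level]] <- est
    write_estimates_csv(est,
                        paths[paste0("estimates_", level)] <-
                          out_path(paste0("estimates_", level, ".csv")))
  }

  # --- validation ------------------------------------------------------
  calibration <- list()
  if (config$run_validation) {
    for (ind in config$indicators) {
      resp <- fit_records[!is.na(fit_records[[ind]])]
      sp <- split_train_validation(resp, config$split_fractions,
                                   seed = config$seed)
      preds <- rep(NA_real_, nrow(sp$validation))
      for (eff in unique(plan$effective_stratum)) {
        members <- strsplit(eff_groups[[eff]][1L], "+", fixed = TRUE)[[1L]]
        sel_est <- unique(unlist(lapply(members, function(s)
          buffer_select(graph, s, config$buffer_m)$estimation)))
        est_graph <- connect_subgraphs(graph_subset(graph, sel_est))
        tr <- sp$train[sp$train$neighbourhood_id %in% sel_est]
        fit <- stage(paste0("validate-fit:", eff, "_", ind),
                     fit_star(config$spec, tr, outcome = ind,
                              graph = est_graph, stratum_id = eff))
        core <- unlist(lapply(members, function(s) buffer_select(graph, s, 0)$core))
        rows <- which(sp$validation$neighbourhood_id %in% core)
        if (length(rows)) {
          preds[rows] <- predict_prob(fit, sp$validation[rows])
        }
      }
      ok <- !is.na(preds)
      tab <- calibration_bins(preds[ok], sp$validation[[ind]][ok],
                              n_bins = min(config$n_bins, sum(ok)),
                              ids = sp$validation$person_id[ok])
      calibration[[ind]] <- tab
      write_calibration_csv(tab,
                            paths[paste0("calibration_", ind)] <-
                              out_path(paste0("calibration_", ind, ".csv")))
    }
  }

  # --- manifest --------------------------------------------------------
  manifest <- list(
    schema = "starsae-manifest/1",
    package_version = as.character(utils::packageVersion("starsae")),
    seed = config$seed,
    parameters = list(buffer_m = config$buffer_m,
                      sanitise_below = config$sanitise_below,
                      n_bins = config$n_bins,
                      split_fractions = config$split_fractions,
                      mc_draws = if (config$run_mc) config$mc_draws,
                      merge_map = as.list(config$merge_map),
                      indicators = config$indicators),
    population = if (!is.null(config$population))
      unclass(config$population),
    n_fits = length(fits),
    fits = lapply(fits, function(f) list(
      stratum = f$stratum_id, indicator = f$outcome,
      n = f$n, p = f$p, converged = f$converged,
      iterations = f$iterations,
      lambda = as.list(f$lambda), edf = as.list(f$edf))))
  jsonlite::write_json(manifest, paths["manifest"] <- out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(list(estimates = estimates, fits = fits,
                 calibration = calibration, manifest = manifest,
                 graph = graph, registry = registry, survey = survey,
                 paths = paths))
}
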