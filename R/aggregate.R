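# Population prediction, replacement by observed outcomes, aggregation to
# the three area levels, sanitisation, and Monte-Carlo uncertainty.

level_column <- function(level) {
  switch(level,
         neighbourhood = "neighbourhood_id",
         district = "district_id",
         municipality = "municipality_id",
         stop("level must be neighbourhood, district or municipality"))
}

#' Predict outcome probabilities for a region's registry population
#'
#' Applies the fitted linear predictor to every (imputed) registry record
#' of the stratum's core region and transforms to probabilities. Buffer
#' individuals are estimation-only and must not be passed here.
#'
#' @param fit a [fitted_star] object.
#' @param registry imputed registry records of the core region.
#' @return numeric probability vector named by `person_id`.
#' @export
predict_population <- function(fit, registry) {
  registry <- as.data.frame(registry)
  if (nrow(registry) == 0L) return(setNames(numeric(0), character(0)))
  setNames(predict_prob(fit, registry), registry$person_id)
}

#' Replace predicted probabilities by observed survey outcomes
#'
#' Survey respondents carry their observed 0/1 outcome instead of the
#' model probability, the standard plug-in step in unit-level small area
#' estimation; everyone else keeps the model probability. Respondents
#' with no recorded outcome for this indicator keep the model probability
#' and are counted in the `n_missing_outcome` attribute.
#'
#' @param probabilities named probability vector from
#'   [predict_population()].
#' @param survey survey table with `person_id` and the outcome column.
#' @param indicator outcome column name in `survey`.
#' @return numeric vector of person-level values (probabilities, with
#'   observed 0/1 where known).
#' @export
overwrite_observed <- function(probabilities, survey, indicator) {
  survey <- as.data.frame(survey)
  if (nrow(survey) == 0L) {
    return(structure(probabilities, n_missing_outcome = 0L))
  }
  ids <- as.character(survey$person_id)
  if (!all(ids %in% names(probabilities))) {
    stop("survey contains person ids absent from the predictions")
  }
  y <- survey[[indicator]]
  if (is.null(y)) stop("indicator column ", indicator, " not in survey")
  keep <- !is.na(y)
  n_missing <- sum(!keep)
  if (n_missing > 0L) {
    message(n_missing, " respondent(s) without observed ", indicator,
            " kept as model probabilities")
  }
  out <- probabilities
  out[ids[keep]] <- as.numeric(y[keep])
  structure(out, n_missing_outcome = n_missing)
}

#' Aggregate person-level values into area prevalence estimates
#'
#' Area prevalence is the mean of the person-level values over the
#' persons in the area; areas with fewer than `sanitise_below` adults are
#' sanitised (prevalence suppressed, flag set).
#'
#' @param values person-level values named by person id (from
#'   [overwrite_observed()] or [predict_population()]).
#' @param registry registry records carrying the person-to-area mapping
#'   (`person_id` plus the id column of `level`; join `graph$areas` in if
#'   needed).
#' @param level `"neighbourhood"`, `"district"` or `"municipality"`.
#' @param sanitise_below minimum adult count for disclosure (default 10).
#' @return a `prevalence_estimate` data.table: `area_id`, `level`,
#'   `n_adults`, `prevalence` (NA when sanitised), `sanitised`.
#' @export
aggregate_prevalence <- function(values, registry, level = "neighbourhood",
                                 sanitise_below = 10L) {
  col <- level_column(level)
  registry <- data.table::as.data.table(registry)
  if (!col %in% names(registry)) stop("registry lacks column ", col)
  if (!all(as.character(registry$person_id) %in% names(values))) {
    stop("person(s) without a value; predict the full region first")
  }
  if (anyNA(registry[[col]])) stop("person with unknown area id")
  dt <- data.table::data.table(
    area_id = registry[[col]],
    value = unname(values[as.character(registry$person_id)]))
  est <- dt[, .(n_adults = .N, prevalence = mean(value)), by = area_id]
  est[, level := level]
  est[, sanitised := n_adults < sanitise_below]
  est[sanitised == TRUE, prevalence := NA_real_]
  data.table::setcolorder(est, c("area_id", "level", "n_adults",
                                 "prevalence", "sanitised"))
  est <- est[order(area_id)]
  data.table::setattr(est, "class",
                      c("prevalence_estimate", class(est)))
  est[]
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat("prevalence_estimate:", nrow(x), x$level[1L], "areas;",
      sum(x$sanitised), "sanitised\n")
  NextMethod()
}

#' Monte-Carlo uncertainty of area prevalence estimates
#'
#' Implements the five-step simulation recipe: (1) draw coefficient
#' vectors from the multivariate normal with the fitted mean and
#' covariance; (2) compute person probabilities per draw; (3) draw
#' Bernoulli outcomes per person, replacing the draw by the observed
#' outcome for survey respondents; (4) aggregate to area prevalence per
#' draw; (5) summarise across draws by mean and standard deviation.
#'
#' @param fit a [fitted_star] with a valid covariance.
#' @param registry imputed core-region registry records.
#' @param survey survey table (`person_id` + indicator column); may be
#'   empty.
#' @param indicator outcome column in `survey`.
#' @param level aggregation level.
#' @param n_draws number of coefficient draws (>= 2; default 1000).
#' @param seed integer seed.
#' @param sanitise_below sanitisation threshold.
#' @return a data.table: `area_id`, `level`, `n_adults`, `mc_mean`,
#'   `mc_sd`, `sanitised`.
#' @export
monte_carlo_uncertainty <- function(fit, registry, survey, indicator,
                                    level = "neighbourhood",
                                    n_draws = 1000L, seed = 1L,
                                    sanitise_below = 10L) {
  if (n_draws < 2L) stop("n_draws must be >= 2")
  V <- fit$cov
  if (is.null(V)) stop("fit carries no covariance")
  V <- (V + t(V)) / 2
  ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(abs(diag(V)))) {
    stop("coefficient covariance is not positive semi-definite")
  }
  registry <- data.table::as.data.table(registry)
  col <- level_column(level)
  n <- nrow(registry)
  area <- registry[[col]]
  areas <- sort(unique(area))
  a_idx <- match(area, areas)
  n_area <- tabulate(a_idx, length(areas))

  # fixed observed outcomes for respondents
  survey <- as.data.frame(survey)
  obs_idx <- integer(0); obs_y <- numeric(0)
  if (nrow(survey) > 0L) {
    m <- match(as.character(survey$person_id), as.character(registry$person_id))
    keep <- !is.na(m) & !is.na(survey[[indicator]])
    obs_idx <- m[keep]
    obs_y <- as.numeric(survey[[indicator]][keep])
  }

  # design at the registry records, built once
  Xb <- Matrix::Matrix(0, n, fit$p, sparse = TRUE)
  Xb[, 1L] <- 1
  for (nm in names(fit$terms)) {
    ti <- fit$terms[[nm]]
    Xb[, ti$cols] <- predict_term_block(ti, as.data.frame(registry), nm)
  }

  L <- tryCatch(chol(V + diag(1e-12 * max(diag(V), 1), nrow(V))),
                error = function(e) {
                  eg <- eigen(V, symmetric = TRUE)
                  vals <- pmax(eg$values, 0)
                  t(eg$vectors %*% (sqrt(vals) * t(eg$vectors)))
                })
  sums <- matrix(0, length(areas), 2L)  # running sum and sum of squares
  with_seed(stage_seed(seed, "mc"), {
    for (b in seq_len(n_draws)) {
      beta_b <- fit$beta + drop(t(L) %*% rnorm(fit$p))
      p_b <- plogis(drop(as.matrix(Xb %*% beta_b)))
      y_b <- rbinom(n, 1L, p_b)
      if (length(obs_idx)) y_b[obs_idx] <- obs_y
      prev_b <- rowsum(y_b, a_idx, reorder = TRUE)[, 1L] / n_area
      sums[, 1L] <- sums[, 1L] + prev_b
      sums[, 2L] <- sums[, 2L] + prev_b^2
    }
  })
  mc_mean <- sums[, 1L] / n_draws
  mc_var <- pmax((sums[, 2L] - n_draws * mc_mean^2) / (n_draws - 1L), 0)
  out <- data.table::data.table(
    area_id = areas, level = level, n_adults = n_area,
    mc_mean = mc_mean, mc_sd = sqrt(mc_var),
    sanitised = n_area < sanitise_below)
  out[sanitised == TRUE, `:=`(mc_mean = NA_real_, mc_sd = NA_real_)]
  out[]
}

#' Plan the per-stratum, per-indicator model runs
#'
#' Applies the stratum merge map (small strata folded into a partner,
#' e.g. two sparsely sampled regions combined) and crosses the effective
#' strata with the indicators: one run per pair.
#'
#' @param strata character vector of stratum ids.
#' @param indicators character vector of indicator names.
#' @param merge_map named character vector mapping a stratum onto the
#'   partner it is merged into (may be empty).
#' @return data.table with `effective_stratum`, `members` and
#'   `indicator`; `nrow` is the number of model runs.
#' @export
plan_runs <- function(strata, indicators, merge_map = character()) {
  strata <- unique(as.character(strata))
  if (length(merge_map)) {
    bad <- setdiff(c(names(merge_map), unname(merge_map)), strata)
    if (length(bad)) stop("merge map references unknown strata: ",
                          paste(bad, collapse = ", "))
  }
  eff <- setNames(strata, strata)
  for (from in names(merge_map)) {
    to <- merge_map[[from]]
    eff[eff == from] <- eff[[to]]
  }
  groups <- split(names(eff), unname(eff))
  plan <- data.table::CJ(effective_stratum = names(groups),
                         indicator = indicators, sorted = TRUE)
  plan[, members := vapply(effective_stratum,
                           function(s) paste(groups[[s]], collapse = "+"), "")]
  data.table::setcolorder(plan, c("effective_stratum", "members", "indicator"))
  plan[]
}

#' Write prevalence estimates to CSV
#'
#' Columns `area_id`, `level`, `n_adults`, `prevalence_pct` (one decimal,
#' empty when sanitised), optional `mc_sd_pct`, `sanitised`. Prevalences
#' are stored internally as proportions and formatted as percentages only
#' here, at the output layer.
#'
#' @param estimates a `prevalence_estimate` (optionally with `mc_sd`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  out <- data.table::copy(data.table::as.data.table(estimates))
  out[, prevalence_pct := ifelse(sanitised, NA_character_,
                                 sprintf("%.1f", 100 * prevalence))]
  out[, prevalence := NULL]
  cols <- c("area_id", "level", "n_adults", "prevalence_pct")
  if ("mc_sd" %in% names(out)) {
    out[, mc_sd_pct := ifelse(sanitised, NA_character_,
                              sprintf("%.2f", 100 * mc_sd))]
    out[, mc_sd := NULL]
    cols <- c(cols, "mc_sd_pct")
  }
  data.table::setcolorder(out, c(cols, "sanitised"))
  data.table::fwrite(out, path, na = "")
  invisible(path)
}
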