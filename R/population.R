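#' Categorical level sets of the registry predictors
#'
#' Named list of the level sets used for the categorical registry
#' predictors: sex (2), ethnicity (7), marital status (4), household type
#' (7), household income source (11) and home ownership (3). The first
#' level of each set is the reference category. Household size is coded
#' 1..10 with 10 meaning "10 or more"; household capital, household income
#' and urbanisation are percentile classes 1..100.
#'
#' @format named list of character vectors.
#' @export
registry_levels <- list(
  sex = c("male", "female"),
  eth = c("Autochthonous", "Morocco", "Turkey", "Suriname",
          "Netherlands Antilles", "Other non-western", "Other western"),
  mar = c("Unmarried", "Married", "Divorced", "Widowed"),
  hhtype = c("Single person household", "Unmarried without children",
             "Married without children", "Unmarried with children",
             "Married with children", "Single parent family", "Other"),
  hhincsrc = c("Salaried", "Independent", "Capital", "Unemployment benefit",
               "Disability benefit", "Old-age benefit",
               "Social welfare benefit", "Other benefit", "Student loan",
               "Other", "None"),
  home = c("Homeowner", "Renting with housing allowance",
           "Renting no housing allowance"))

missingness_groups <- list(
  hh_structure = c("hhtype", "hhsize"),
  hh_economic  = c("hhcap", "hhinc", "hhincsrc", "home"))

#' Configuration of the synthetic registry generator
#'
#' Bundles the knobs of the synthetic population: map size and shape,
#' population size, survey sampling fraction (default 0.03, a ~3%
#' proportionally sampled survey), record-level missingness rates for the
#' two household field groups (defaults 0.0026% for household type/size
#' and 0.70% for the four economic fields, the orders of magnitude seen in
#' Dutch registry data), and the master seed.
#'
#' @param n_neighbourhoods number of neighbourhood polygons (>= 1).
#' @param geometry_kind `"lattice"` (unit square cells) or `"irregular"`
#'   (jittered quadrilaterals).
#' @param mean_persons_per_neighbourhood expected adults (19+) per
#'   neighbourhood.
#' @param survey_fraction proportion surveyed, in (0, 1).
#' @param missingness_rates named proportions in \[0, 1) for any of the six
#'   fields `hhtype, hhsize, hhcap, hhinc, hhincsrc, home`; rates must agree
#'   within each of the two jointly-missing groups.
#' @param indicators character vector of outcome names to simulate.
#' @param n_strata number of strata (health-service regions) to carve the
#'   map into.
#' @param cell_size_m lattice cell edge, metres.
#' @param seed master integer seed; all stages derive sub-streams from it.
#' @return object of class `population_config`.
#' @export
population_config <- function(n_neighbourhoods = 200L,
                              geometry_kind = c("lattice", "irregular"),
                              mean_persons_per_neighbourhood = 150,
                              survey_fraction = 0.03,
                              missingness_rates = c(hhtype = 0.000026,
                                                    hhsize = 0.000026,
                                                    hhcap = 0.007,
                                                    hhinc = 0.007,
                                                    hhincsrc = 0.007,
                                                    home = 0.007),
                              indicators = "overweight",
                              n_strata = 1L,
                              cell_size_m = 1000,
                              seed = 1L) {
  geometry_kind <- match.arg(geometry_kind)
  n_neighbourhoods <- as.integer(n_neighbourhoods)
  if (is.na(n_neighbourhoods) || n_neighbourhoods < 1L) {
    stop("n_neighbourhoods must be a positive integer")
  }
  if (mean_persons_per_neighbourhood <= 0) {
    stop("mean_persons_per_neighbourhood must be positive")
  }
  if (!(survey_fraction > 0 && survey_fraction < 1)) {
    stop("survey_fraction must lie in (0, 1)")
  }
  check_missingness_rates(missingness_rates)
  structure(list(
    n_neighbourhoods = n_neighbourhoods, geometry_kind = geometry_kind,
    mean_persons_per_neighbourhood = mean_persons_per_neighbourhood,
    survey_fraction = survey_fraction, missingness_rates = missingness_rates,
    indicators = indicators, n_strata = as.integer(n_strata),
    cell_size_m = cell_size_m, seed = as.integer(seed)),
    class = "population_config")
}

check_missingness_rates <- function(rates) {
  if (length(rates) == 0L) return(invisible(TRUE))
  allowed <- unlist(missingness_groups, use.names = FALSE)
  bad <- setdiff(names(rates), allowed)
  if (length(bad)) {
    stop("missingness rates allowed only for fields ",
         paste(allowed, collapse = ", "), "; got: ", paste(bad, collapse = ", "))
  }
  if (any(rates < 0 | rates >= 1)) stop("missingness rates must lie in [0, 1)")
  for (g in missingness_groups) {
    r <- rates[names(rates) %in% g]
    if (length(r) > 1L && length(unique(unname(r))) > 1L) {
      stop("fields ", paste(g, collapse = "+"),
           " go missing jointly and must share one rate")
    }
  }
  invisible(TRUE)
}

#' @export
print.population_config <- function(x, ...) {
  cat("population_config:", x$n_neighbourhoods, x$geometry_kind,
      "neighbourhoods x ~", x$mean_persons_per_neighbourhood,
      "persons; survey fraction", x$survey_fraction,
      "; strata", x$n_strata, "; seed", x$seed, "\n")
  invisible(x)
}

# ---- ground truth -----------------------------------------------------------

#' Ground-truth outcome model for the synthetic registry
#'
#' Defines the Bernoulli-logit data-generating process: an intercept, a sex
#' main effect, a smooth unimodal age effect peaking near 65 (plus an
#' age-by-sex interaction shifting the female peak toward 75), log-odds
#' differences per categorical level, weak linear trends in the percentile
#' predictors, a household-size trend, and a spatially correlated
#' neighbourhood effect simulated from a zero-mean intrinsic autoregression
#' on the adjacency graph (see [simulate_spatial_effect()]). Smooth terms
#' and the spatial effect are centred over the generated population when
#' the outcomes are built, matching the sum-to-zero convention of the
#' fitted model.
#'
#' @param intercept log-odds intercept.
#' @param sex_effect added log-odds for females.
#' @param categorical_effects named list (by predictor) of named numeric
#'   vectors of per-level log-odds differences (reference level 0).
#' @param smooth_functions named list of callables for `age`, `hhsize`,
#'   `hhcap`, `hhinc`, `urb` (uncentred).
#' @param interaction_age_by_sex callable; added for females.
#' @param spatial_sd target standard deviation of the neighbourhood effect
#'   on the log-odds scale.
#' @return object of class `true_model`.
#' @export
true_model <- function(
    intercept = -0.1,
    sex_effect = -0.25,
    categorical_effects = list(
      eth = c(Autochthonous = 0, Morocco = 0.45, Turkey = 0.6,
              Suriname = 0.3, `Netherlands Antilles` = 0.25,
              `Other non-western` = 0.2, `Other western` = 0.05),
      mar = c(Unmarried = 0, Married = 0.15, Divorced = 0.3, Widowed = 0.35),
      hhtype = c(`Single person household` = 0,
                 `Unmarried without children` = 0.1,
                 `Married without children` = 0.15,
                 `Unmarried with children` = 0.2,
                 `Married with children` = 0.25,
                 `Single parent family` = 0.3, Other = 0.1),
      hhincsrc = c(Salaried = 0, Independent = 0.05, Capital = 0.2,
                   `Unemployment benefit` = 0.15, `Disability benefit` = 0.25,
                   `Old-age benefit` = 0.2, `Social welfare benefit` = 0.3,
                   `Other benefit` = 0.25, `Student loan` = -0.4,
                   Other = 0.1, None = 0.05),
      home = c(Homeowner = 0, `Renting with housing allowance` = 0.15,
               `Renting no housing allowance` = 0.1)),
    smooth_functions = list(
      age = function(a) 1.6 * exp(-0.5 * ((a - 65) / 18)^2),
      hhsize = function(s) 0.06 * (s - 2.5),
      hhcap = function(c) -0.004 * (c - 50.5),
      hhinc = function(c) -0.003 * (c - 50.5),
      urb = function(u) -0.002 * (u - 50.5)),
    interaction_age_by_sex = function(a) {
      0.9 * exp(-0.5 * ((a - 82) / 16)^2) - 0.45 * exp(-0.5 * ((a - 48) / 16)^2)
    },
    spatial_sd = 0.3) {
  for (p in names(categorical_effects)) {
    lev <- registry_levels[[p]]
    if (!setequal(names(categorical_effects[[p]]), lev)) {
      stop("categorical_effects$", p, " must be named by its level set")
    }
  }
  structure(list(intercept = intercept, sex_effect = sex_effect,
                 categorical_effects = categorical_effects,
                 smooth_functions = smooth_functions,
                 interaction_age_by_sex = interaction_age_by_sex,
                 spatial_sd = spatial_sd),
            class = "true_model")
}

#' Simulate a spatially correlated neighbourhood effect
#'
#' Draws one realisation of a zero-mean intrinsic autoregression on the
#' adjacency graph: coefficients are sampled along the non-null
#' eigenvectors of the MRF penalty with variance inversely proportional to
#' the eigenvalue, then centred and rescaled to standard deviation `sd`.
#' Disconnected components each get their own zero mean.
#'
#' @param graph an [area_graph].
#' @param sd target standard deviation on the log-odds scale.
#' @param seed integer seed.
#' @return named numeric vector over neighbourhood ids.
#' @export
simulate_spatial_effect <- function(graph, sd = 0.3, seed = 1L) {
  ids <- graph_ids(graph)
  d <- length(ids)
  if (d == 1L) return(setNames(0, ids))
  K <- unclass(mrf_penalty(graph))
  eg <- eigen(K, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-9
  with_seed(stage_seed(seed, "spatial"), {
    z <- rnorm(sum(pos)) / sqrt(eg$values[pos])
    g <- drop(eg$vectors[, pos, drop = FALSE] %*% z)
  })
  g <- g - mean(g)
  g <- if (sd(g) > 0) g * sd / sd(g) else rep(0, d)
  setNames(g, ids)
}

# ---- population generation --------------------------------------------------

#' Generate a synthetic registry population with known ground truth
#'
#' Simulates adults (19+) nested in households nested in neighbourhoods.
#' Household sizes follow a truncated geometric distribution; household
#' fields (type, size, capital, income, income source, home ownership) are
#' drawn once per household and shared by members; capital, income and
#' urbanisation are person-weighted empirical percentile classes 1..100
#' computed within the generated population. Binary outcomes are drawn
#' from the Bernoulli-logit ground truth and a ~`survey_fraction` survey
#' sample is drawn without replacement, proportionally across
#' neighbourhoods.
#'
#' @param config a [population_config()].
#' @param geometry an [area_graph] from [generate_geometry()].
#' @param truth a [true_model()]; its spatial effect is simulated on
#'   `geometry` unless `spatial_effect` is supplied.
#' @param spatial_effect optional named log-odds vector over neighbourhood
#'   ids, overriding simulation (length must match the geometry).
#' @return object of class `synthetic_population`: list with `persons` (a
#'   data.table; one row per person, including ground-truth `eta_true`,
#'   `p_true` and outcome columns), `truth`, `centering` (the constants
#'   subtracted to centre each smooth), `spatial_centred`, `graph` and
#'   `config`.
#' @export
generate_population <- function(config, geometry, truth = true_model(),
                                spatial_effect = NULL) {
  stopifnot(inherits(config, "population_config"),
            inherits(geometry, "area_graph"), inherits(truth, "true_model"))
  ids <- graph_ids(geometry)
  if (is.null(spatial_effect)) {
    spatial_effect <- simulate_spatial_effect(geometry, truth$spatial_sd,
                                              config$seed)
  }
  if (length(spatial_effect) != length(ids) ||
      !setequal(names(spatial_effect), ids)) {
    stop("spatial_effect must be named over exactly the geometry's ",
         "neighbourhood ids")
  }
  spatial_effect <- spatial_effect[ids]

  persons <- with_seed(stage_seed(config$seed, "persons"), {
    draw_persons(config, ids)
  })
  n <- nrow(persons)

  # person-weighted percentile classes from household / neighbourhood latents
  persons[, `:=`(hhcap = percentile_class(persons$lat_cap, persons$household_id),
                 hhinc = percentile_class(persons$lat_inc, persons$household_id),
                 urb = percentile_class(persons$lat_urb,
                                        persons$neighbourhood_id))]
  persons[, c("lat_cap", "lat_inc", "lat_urb") := NULL]

  # linear predictor under the truth, smooths centred over this population
  centering <- c()
  eta <- rep(truth$intercept, n)
  eta <- eta + ifelse(persons$sex == "female", truth$sex_effect, 0)
  for (p in names(truth$categorical_effects)) {
    eta <- eta + unname(truth$categorical_effects[[p]][persons[[p]]])
  }
  for (p in names(truth$smooth_functions)) {
    v <- truth$smooth_functions[[p]](persons[[p]])
    centering[p] <- mean(v)
    eta <- eta + v - centering[p]
  }
  v <- truth$interaction_age_by_sex(persons$age) *
    (persons$sex == "female")
  centering["age_by_sex"] <- mean(v)
  eta <- eta + v - centering["age_by_sex"]
  sp <- spatial_effect[persons$neighbourhood_id]
  centering["spatial"] <- mean(sp)
  spatial_centred <- spatial_effect - centering["spatial"]
  eta <- eta + unname(sp) - centering["spatial"]

  persons[, eta_true := eta]
  persons[, p_true := plogis(eta)]
  with_seed(stage_seed(config$seed, "outcomes"), {
    for (ind in config$indicators) {
      persons[, (ind) := rbinom(n, 1L, persons$p_true)]
    }
  })

  # survey: proportional within-neighbourhood sample without replacement
  with_seed(stage_seed(config$seed, "survey"), {
    persons[, is_respondent := FALSE]
    idx <- split(seq_len(n), persons$neighbourhood_id)
    for (rows in idx) {
      target <- config$survey_fraction * length(rows)
      k <- floor(target) + (runif(1L) < (target - floor(target)))
      if (k > 0L) {
        persons$is_respondent[rows[sample.int(length(rows), k)]] <- TRUE
      }
    }
  })
  data.table::setkey(persons, person_id)

  structure(list(persons = persons, truth = truth, centering = centering,
                 spatial_centred = spatial_centred, graph = geometry,
                 config = config),
            class = "synthetic_population")
}

draw_persons <- function(config, ids) {
  per_nb <- lapply(ids, function(id) {
    target <- max(1L, stats::rpois(1L, config$mean_persons_per_neighbourhood))
    sizes <- integer(0)
    while (sum(sizes) < target) {
      sizes <- c(sizes, min(1L + rgeom(1L, 1 / 2.2), 12L))
    }
    sizes
  })
  hh_sizes <- unlist(per_nb)
  n_hh <- length(hh_sizes)
  hh_nb <- rep(ids, vapply(per_nb, length, integer(1L)))
  n <- sum(hh_sizes)

  # household-level fields
  hhtype <- character(n_hh)
  one <- hh_sizes == 1L; two <- hh_sizes == 2L; more <- hh_sizes >= 3L
  hhtype[one] <- "Single person household"
  hhtype[two] <- sample(registry_levels$hhtype[c(2L, 3L, 7L)], sum(two),
                        replace = TRUE, prob = c(0.3, 0.6, 0.1))
  hhtype[more] <- sample(registry_levels$hhtype[c(4L, 5L, 6L, 7L)], sum(more),
                         replace = TRUE, prob = c(0.15, 0.6, 0.15, 0.1))
  hhincsrc <- sample(registry_levels$hhincsrc, n_hh, replace = TRUE,
                     prob = c(0.55, 0.08, 0.01, 0.03, 0.04, 0.18, 0.04,
                              0.02, 0.03, 0.01, 0.01))
  home <- sample(registry_levels$home, n_hh, replace = TRUE,
                 prob = c(0.57, 0.13, 0.30))
  lat_inc <- rnorm(n_hh) +
    c(Salaried = 0.6, Independent = 0.5, Capital = 0.8,
      `Unemployment benefit` = -0.6, `Disability benefit` = -0.5,
      `Old-age benefit` = -0.1, `Social welfare benefit` = -1,
      `Other benefit` = -0.4, `Student loan` = -1.2, Other = 0,
      None = -0.8)[hhincsrc]
  lat_cap <- 0.6 * lat_inc + rnorm(n_hh)
  lat_urb <- setNames(rnorm(length(ids)), ids)

  hh_id <- sprintf("H%07d", seq_len(n_hh))
  pid_hh <- rep(seq_len(n_hh), hh_sizes)
  persons <- data.table::data.table(
    person_id = seq_len(n),
    household_id = hh_id[pid_hh],
    neighbourhood_id = hh_nb[pid_hh],
    age = as.integer(pmin(pmax(round(19 + rgamma(n, shape = 2, scale = 13)),
                               19L), 105L)),
    sex = sample(registry_levels$sex, n, replace = TRUE),
    eth = sample(registry_levels$eth, n, replace = TRUE,
                 prob = c(0.79, 0.02, 0.02, 0.02, 0.01, 0.06, 0.08)),
    mar = sample(registry_levels$mar, n, replace = TRUE,
                 prob = c(0.33, 0.48, 0.11, 0.08)),
    hhtype = hhtype[pid_hh],
    hhsize = pmin(hh_sizes, 10L)[pid_hh],
    hhincsrc = hhincsrc[pid_hh],
    home = home[pid_hh],
    lat_cap = lat_cap[pid_hh],
    lat_inc = lat_inc[pid_hh],
    lat_urb = unname(lat_urb[hh_nb[pid_hh]]))
  persons
}

# Person-weighted percentile class 1..100: groups (households or
# neighbourhoods) are ranked by their latent value; each group's class is
# the percentile of its mid person rank, so members share one class and the
# person-level marginal is uniform up to rounding.
percentile_class <- function(latent, group) {
  dt <- data.table::data.table(latent = latent, group = group)
  gs <- dt[, .(lat = latent[1L], n = .N), by = group]
  gs <- gs[order(lat, group)]
  gs[, cum := cumsum(n)]
  gs[, cls := pmin(pmax(ceiling(100 * (cum - n / 2) / sum(n)), 1L), 100L)]
  out <- gs$cls[match(group, gs$group)]
  as.integer(out)
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("synthetic_population:", nrow(x$persons), "persons in",
      length(unique(x$persons$household_id)), "households,",
      length(unique(x$persons$neighbourhood_id)), "neighbourhoods\n")
  cat("  respondents:", sum(x$persons$is_respondent),
      sprintf("(%.1f%%)", 100 * mean(x$persons$is_respondent)),
      "; indicators:", paste(x$config$indicators, collapse = ", "), "\n")
  invisible(x)
}

#' Registry view of a synthetic population
#'
#' The registry table: one row per person with the 12 predictors and area
#' ids, without outcomes or ground truth.
#'
#' @param pop a `synthetic_population`.
#' @return a data.table.
#' @export
registry_table <- function(pop) {
  cols <- c("person_id", "household_id", "neighbourhood_id", "age", "sex",
            "eth", "mar", "hhtype", "hhsize", "hhcap", "hhinc", "hhincsrc",
            "home", "urb")
  pop$persons[, ..cols]
}

#' Survey view of a synthetic population
#'
#' Respondents only, with their observed binary outcomes.
#'
#' @param pop a `synthetic_population`.
#' @return a data.table with `person_id` and one 0/1 column per indicator.
#' @export
survey_table <- function(pop) {
  cols <- c("person_id", "neighbourhood_id", pop$config$indicators)
  pop$persons[pop$persons$is_respondent, ..cols]
}

# ---- missingness ------------------------------------------------------------

#' Inject record-level missingness into registry fields
#'
#' Selects records completely at random and blanks household fields in
#' their two jointly-missing groups: type+size as one group, and
#' capital+income+income source+home ownership as the other. Only those
#' six fields may carry a rate.
#'
#' @param records registry data.frame/data.table (modified copy returned).
#' @param rates named proportions, as in [population_config()].
#' @param seed integer seed.
#' @return a data.table with `NA`s injected.
#' @export
inject_missingness <- function(records, rates, seed = 1L) {
  check_missingness_rates(rates)
  out <- data.table::as.data.table(records)
  n <- nrow(out)
  with_seed(stage_seed(seed, "missingness"), {
    for (gname in names(missingness_groups)) {
      fields <- missingness_groups[[gname]]
      r <- unique(unname(rates[names(rates) %in% fields]))
      if (length(r) == 0L || r == 0) next
      hit <- runif(n) < r
      for (f in intersect(fields, names(out))) {
        if (is.integer(out[[f]])) out[hit, (f) := NA_integer_]
        else if (is.numeric(out[[f]])) out[hit, (f) := NA_real_]
        else out[hit, (f) := NA_character_]
      }
    }
  })
  out[]
}
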