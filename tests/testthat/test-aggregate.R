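fake_registry <- function(nb_sizes, level_map = NULL) {
  # nb_sizes: named person counts per neighbourhood
  nb <- rep(names(nb_sizes), nb_sizes)
  out <- data.table::data.table(
    person_id = seq_along(nb), neighbourhood_id = nb)
  if (!is.null(level_map)) {
    out <- merge(out, level_map, by = "neighbourhood_id", sort = FALSE)
  }
  out[order(person_id)]
}

test_that("aggregation averages person values and sanitises small areas", {
  lm <- data.table::data.table(
    neighbourhood_id = c("N1", "N2", "N3"),
    district_id = c("D1", "D1", "D2"),
    municipality_id = "M1")
  reg <- fake_registry(c(N1 = 20L, N2 = 80L, N3 = 9L), lm)
  vals <- setNames(rep(NA_real_, nrow(reg)), reg$person_id)
  vals[reg$neighbourhood_id == "N1"] <- 0.1
  vals[reg$neighbourhood_id == "N2"] <- 0.5
  vals[reg$neighbourhood_id == "N3"] <- 0.3
  nbh <- aggregate_prevalence(vals, reg, "neighbourhood")
  expect_equal(nbh[area_id == "N2", prevalence], 0.5)
  # area of 9 persons is sanitised, prevalence suppressed
  expect_true(nbh[area_id == "N3", sanitised])
  expect_true(is.na(nbh[area_id == "N3", prevalence]))
  # weighted district mean: (20*0.1 + 80*0.5)/100 = 0.42
  dis <- aggregate_prevalence(vals, reg, "district")
  expect_equal(dis[area_id == "D1", prevalence], 0.42)
  # sanitisation is monotone in the threshold
  nbh15 <- aggregate_prevalence(vals, reg, "neighbourhood",
                                sanitise_below = 15L)
  expect_true(all(nbh$area_id[nbh$sanitised] %in%
                    nbh15$area_id[nbh15$sanitised]))
})

test_that("aggregation is consistent across the three levels", {
  pop <- fx_pop25()
  reg <- merge(registry_table(pop),
               data.table::as.data.table(
                 pop$graph$areas[, c("neighbourhood_id", "district_id",
                                     "municipality_id")]),
               by = "neighbourhood_id")
  vals <- setNames(pop$persons$p_true, pop$persons$person_id)
  nbh <- aggregate_prevalence(vals, reg, "neighbourhood", sanitise_below = 1L)
  dis <- aggregate_prevalence(vals, reg, "district", sanitise_below = 1L)
  mun <- aggregate_prevalence(vals, reg, "municipality", sanitise_below = 1L)
  # district prevalence equals the person-weighted mean of its neighbourhoods
  key <- unique(reg[, .(neighbourhood_id, district_id, municipality_id)])
  nbh2 <- merge(nbh, key, by.x = "area_id", by.y = "neighbourhood_id")
  up <- nbh2[, .(prev = sum(prevalence * n_adults) / sum(n_adults)),
             by = district_id]
  cmp <- merge(up, dis, by.x = "district_id", by.y = "area_id")
  expect_equal(cmp$prev, cmp$prevalence, tolerance = 1e-12)
  dis2 <- merge(dis, unique(key[, .(district_id, municipality_id)]),
                by.x = "area_id", by.y = "district_id")
  up2 <- dis2[, .(prev = sum(prevalence * n_adults) / sum(n_adults)),
              by = municipality_id]
  cmp2 <- merge(up2, mun, by.x = "municipality_id", by.y = "area_id")
  expect_equal(cmp2$prev, cmp2$prevalence, tolerance = 1e-12)
})

test_that("observed outcomes replace model probabilities", {
  probs <- setNames(c(0.2, 0.4, 0.6), c("1", "2", "3"))
  sv0 <- data.frame(person_id = integer(0), ow = integer(0))
  expect_equal(unname(overwrite_observed(probs, sv0, "ow")[1:3]),
               c(0.2, 0.4, 0.6))
  sv1 <- data.frame(person_id = 1L, ow = 1L)
  out <- overwrite_observed(probs, sv1, "ow")
  expect_equal(unname(out["1"]), 1)
  expect_equal(unname(out["2"]), 0.4)
  # all persons respondents: the aggregate equals the observed sample mean
  sv_all <- data.frame(person_id = 1:3, ow = c(1L, 0L, 1L))
  out_all <- overwrite_observed(probs, sv_all, "ow")
  reg <- data.table::data.table(person_id = 1:3, neighbourhood_id = "N1")
  est <- aggregate_prevalence(out_all, reg, "neighbourhood",
                              sanitise_below = 1L)
  expect_equal(est$prevalence, 2 / 3)
  # respondent with a missing outcome keeps the model probability, logged
  sv_na <- data.frame(person_id = 1:2, ow = c(NA_integer_, 0L))
  expect_message(out_na <- overwrite_observed(probs, sv_na, "ow"),
                 "without observed")
  expect_equal(unname(out_na["1"]), 0.2)
  expect_equal(attr(out_na, "n_missing_outcome"), 1L)
  # survey ids must be known
  sv_bad <- data.frame(person_id = 99L, ow = 1L)
  expect_error(overwrite_observed(probs, sv_bad, "ow"), "absent")
})

test_that("Monte-Carlo uncertainty behaves at its analytic limits", {
  fit <- fx_fit25()
  pop <- fx_pop25()
  reg <- registry_table(pop)[neighbourhood_id %in% c("N0001", "N0002")]
  sv <- survey_table(pop)[person_id %in% reg$person_id]
  fit0 <- fit
  fit0$cov <- matrix(0, fit$p, fit$p)
  # fully observed area: zero coefficient and outcome noise -> sd exactly 0
  reg1 <- reg[1:20]
  sv_all <- data.table::data.table(person_id = reg1$person_id,
                                   overweight = rep(c(0L, 1L), 10L))
  mc0 <- monte_carlo_uncertainty(fit0, reg1, sv_all, "overweight",
                                 n_draws = 50L, seed = 3L,
                                 sanitise_below = 1L)
  expect_equal(mc0$mc_sd, rep(0, nrow(mc0)), tolerance = 1e-12)
  expect_equal(mc0$mc_mean, rep(0.5, nrow(mc0)))
  # zero covariance, no respondents: binomial closed form p(1-p)/n
  mc1 <- monte_carlo_uncertainty(fit0, reg, sv[0], "overweight",
                                 n_draws = 2000L, seed = 4L,
                                 sanitise_below = 1L)
  p_hat <- predict_population(fit, reg)
  for (nb in mc1$area_id) {
    idx <- reg$neighbourhood_id == nb
    n_a <- sum(idx)
    expected_sd <- sqrt(sum(p_hat[idx] * (1 - p_hat[idx])) / n_a^2)
    expect_lt(abs(mc1[area_id == nb, mc_sd] - expected_sd) / expected_sd, 0.2)
  }
  # MC mean tracks the plug-in aggregate within 3 MC standard errors
  plug <- aggregate_prevalence(p_hat, reg, "neighbourhood",
                               sanitise_below = 1L)
  cmp <- merge(mc1, plug, by = "area_id")
  mc_se <- cmp$mc_sd / sqrt(2000)
  expect_true(all(abs(cmp$mc_mean - cmp$prevalence) <= 3 * mc_se + 1e-3))
  expect_error(monte_carlo_uncertainty(fit, reg, sv, "overweight",
                                       n_draws = 1L), "n_draws")
  fit_bad <- fit
  fit_bad$cov <- -diag(fit$p)
  expect_error(monte_carlo_uncertainty(fit_bad, reg, sv, "overweight",
                                       n_draws = 10L),
               "positive semi-definite")
})

test_that("run planning applies merges and crosses strata with indicators", {
  strata28 <- sprintf("S%02d", 1:28)
  inds26 <- sprintf("ind%02d", 1:26)
  plan <- plan_runs(strata28, inds26, merge_map = c(S02 = "S01"))
  expect_equal(nrow(plan), 27L * 26L)
  expect_true("S01+S02" %in% plan$members ||
                "S02+S01" %in% plan$members)
  expect_equal(nrow(plan_runs("S01", "overweight")), 1L)
  expect_equal(nrow(plan_runs(strata28, inds26)), 28L * 26L)
  expect_error(plan_runs(strata28, inds26, c(S99 = "S01")), "unknown")
})

test_that("estimate CSVs format prevalences as percentages at output only", {
  est <- data.table::data.table(
    area_id = c("N1", "N2"), level = "neighbourhood",
    n_adults = c(100L, 5L), prevalence = c(0.4567, NA),
    sanitised = c(FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_estimates_csv(est, path)
  txt <- readLines(path)
  expect_match(txt[2L], "45.7")
  expect_match(txt[3L], ",,", fixed = TRUE)  # sanitised row empty
})
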