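test_that("a null truth yields ~50% outcome frequency", {
  cfg <- population_config(n_neighbourhoods = 9L,
                           mean_persons_per_neighbourhood = 400, seed = 21L)
  truth0 <- true_model(intercept = 0, sex_effect = 0,
                       categorical_effects = lapply(
                         true_model()$categorical_effects,
                         function(v) { v[] <- 0; v }),
                       smooth_functions = lapply(
                         true_model()$smooth_functions,
                         function(f) function(x) rep(0, length(x))),
                       interaction_age_by_sex = function(a) rep(0, length(a)),
                       spatial_sd = 0)
  pop <- generate_population(cfg, generate_geometry(cfg), truth0)
  n <- nrow(pop$persons)
  expect_true(abs(mean(pop$persons$overweight) - 0.5) < 3 * sqrt(0.25 / n))
  expect_equal(unique(pop$persons$p_true), 0.5)
})

test_that("an extreme negative intercept yields all-zero outcomes", {
  cfg <- population_config(n_neighbourhoods = 4L,
                           mean_persons_per_neighbourhood = 200, seed = 22L)
  truth <- true_model(intercept = -20)
  pop <- generate_population(cfg, generate_geometry(cfg), truth)
  # max |non-intercept contribution| << 20, so p < plogis(-10) < 5e-5;
  # at desk n the probability of any positive outcome is negligible
  expect_true(all(pop$persons$p_true < 1e-4))
  expect_equal(sum(pop$persons$overweight), 0L)
})

test_that("survey sampling is proportional at the configured fraction", {
  cfg <- population_config(n_neighbourhoods = 50L,
                           mean_persons_per_neighbourhood = 400,
                           survey_fraction = 0.03, seed = 23L)
  pop <- generate_population(cfg, generate_geometry(cfg))
  n <- nrow(pop$persons)
  k <- sum(pop$persons$is_respondent)
  expect_true(abs(k - 0.03 * n) <= 3 * sqrt(n * 0.03 * 0.97))
  # proportional: per-neighbourhood counts within rounding of 3%
  per_nb <- pop$persons[, .(n = .N, k = sum(is_respondent)),
                        by = neighbourhood_id]
  expect_true(all(abs(per_nb$k - 0.03 * per_nb$n) <= 1))
  # respondents have an observed outcome
  sv <- survey_table(pop)
  expect_equal(nrow(sv), k)
  expect_true(all(sv$overweight %in% 0:1))
})

test_that("generation is byte-identical under the same seed", {
  cfg <- population_config(n_neighbourhoods = 9L,
                           mean_persons_per_neighbourhood = 60, seed = 24L)
  g <- generate_geometry(cfg)
  p1 <- generate_population(cfg, g)
  p2 <- generate_population(cfg, g)
  expect_identical(as.data.frame(p1$persons), as.data.frame(p2$persons))
  expect_identical(p1$spatial_centred, p2$spatial_centred)
})

test_that("households share household-level fields and hhsize is capped", {
  pop <- fx_pop25()
  per_hh <- pop$persons[, .(
    one_type = data.table::uniqueN(hhtype) == 1L,
    one_cap = data.table::uniqueN(hhcap) == 1L,
    one_src = data.table::uniqueN(hhincsrc) == 1L,
    size_field = hhsize[1L], size_real = .N,
    one_nb = data.table::uniqueN(neighbourhood_id) == 1L),
    by = household_id]
  expect_true(all(per_hh$one_type & per_hh$one_cap & per_hh$one_src &
                    per_hh$one_nb))
  expect_equal(per_hh$size_field, pmin(per_hh$size_real, 10L))
})

test_that("record invariants hold: ages, level sets, percentile ranges", {
  pop <- fx_pop25()
  p <- pop$persons
  expect_true(all(p$age >= 19 & p$age <= 105))
  for (f in c("sex", "eth", "mar", "hhtype", "hhincsrc", "home")) {
    expect_true(all(p[[f]] %in% registry_levels[[f]]))
  }
  for (f in c("hhcap", "hhinc", "urb")) {
    expect_true(all(p[[f]] %in% 1:100))
  }
  # percentile marginals are near-uniform (deciles, allowing household
  # clustering to inflate the variance)
  n <- nrow(p)
  for (f in c("hhcap", "hhinc")) {
    dec <- table(cut(p[[f]], breaks = seq(0, 100, by = 10)))
    expect_true(all(abs(dec - n / 10) < 4 * sqrt(n / 10 * 3)))
  }
})

test_that("neighbourhood prevalence converges to the truth's mean probability", {
  cfg <- population_config(n_neighbourhoods = 16L,
                           mean_persons_per_neighbourhood = 1000, seed = 26L)
  pop <- generate_population(cfg, generate_geometry(cfg))
  nb <- pop$persons[, .(freq = mean(overweight), p = mean(p_true), n = .N),
                    by = neighbourhood_id]
  z <- abs(nb$freq - nb$p) / sqrt(nb$p * (1 - nb$p) / nb$n)
  expect_true(mean(z <= 3) >= 15 / 16)
  expect_true(all(z <= 4.5))
})

test_that("smooth terms and the spatial effect are centred over the population", {
  pop <- fx_pop25()
  p <- pop$persons
  tr <- pop$truth
  for (f in names(tr$smooth_functions)) {
    v <- tr$smooth_functions[[f]](p[[f]]) - pop$centering[f]
    expect_equal(mean(v), 0, tolerance = 1e-10)
  }
  expect_equal(mean(pop$spatial_centred[p$neighbourhood_id]), 0,
               tolerance = 1e-10)
})

test_that("missingness injection hits the configured field groups jointly", {
  pop <- fx_pop25()
  reg <- registry_table(pop)
  # zero rates leave records unchanged
  expect_identical(as.data.frame(inject_missingness(reg, c(hhcap = 0), 1L)),
                   as.data.frame(reg))
  rates <- c(hhtype = 0.01, hhsize = 0.01, hhcap = 0.007, hhinc = 0.007,
             hhincsrc = 0.007, home = 0.007)
  out <- inject_missingness(reg, rates, seed = 31L)
  n <- nrow(out)
  miss4 <- is.na(out$hhcap)
  expect_identical(miss4, is.na(out$hhinc))
  expect_identical(miss4, is.na(out$hhincsrc))
  expect_identical(miss4, is.na(out$home))
  expect_true(abs(sum(miss4) - 0.007 * n) <= 3 * sqrt(n * 0.007 * 0.993))
  miss2 <- is.na(out$hhtype)
  expect_identical(miss2, is.na(out$hhsize))
  expect_true(abs(sum(miss2) - 0.01 * n) <= 3 * sqrt(n * 0.01 * 0.99))
  # rate 1 blanks the whole group
  all_gone <- inject_missingness(reg, c(hhcap = 0.999999), seed = 1L)
  expect_true(mean(is.na(all_gone$hhcap)) > 0.99)
  # determinism
  out2 <- inject_missingness(reg, rates, seed = 31L)
  expect_identical(as.data.frame(out), as.data.frame(out2))
  # unknown fields rejected
  expect_error(inject_missingness(reg, c(age = 0.1), 1L), "allowed only")
  expect_error(population_config(missingness_rates = c(hhcap = 0.1,
                                                       hhinc = 0.2)),
               "jointly")
})
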