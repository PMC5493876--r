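test_that("design dimensions follow the closed-form block sizes", {
  pop <- fx_pop25()
  # intercept-plus-sex spec: two columns, no penalties
  d0 <- build_design(model_spec(term_linear("sex")), pop$persons)
  expect_equal(ncol(d0$X), 2L)
  expect_length(starsae:::penalized_terms(d0), 0L)
  # full default spec: 1 intercept + (1+6+3+6+10+2) dummies
  #   + 5 ten-knot smooths of 11 constrained columns + one 5-knot smooth
  #   of 6 + MRF with d-1 columns
  d1 <- build_design(default_model_spec(), pop$persons, graph = pop$graph,
                     outcome = "overweight")
  expect_equal(ncol(d1$X), 1L + 28L + 5L * 11L + 6L + (25L - 1L))
  expect_length(starsae:::penalized_terms(d1), 7L)
  # ridge variant adds another d-1 columns
  d2 <- build_design(default_model_spec(ridge = TRUE), pop$persons,
                     graph = pop$graph)
  expect_equal(ncol(d2$X), ncol(d1$X) + 24L)
})

test_that("every penalized block satisfies its sum-to-zero constraint", {
  pop <- fx_pop25()
  d <- build_design(default_model_spec(), pop$persons, graph = pop$graph)
  X <- as.matrix(d$X)
  for (nm in starsae:::penalized_terms(d)) {
    ti <- d$terms[[nm]]
    expect_lt(max(abs(colSums(X[, ti$cols, drop = FALSE]))) /
                nrow(X), 1e-10)
    # transformed penalties stay PSD
    ev <- eigen(ti$penalty, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
  }
})

test_that("unseen levels error and absent levels merge into the reference", {
  df <- fx_logit_frame(100L)
  spec <- model_spec(term_linear("g1", levels = c("a", "b", "c")))
  df_bad <- df; df_bad$g1[1L] <- "z"
  expect_error(build_design(spec, df_bad), "unseen category")
  df_absent <- df; df_absent$g1[df_absent$g1 == "c"] <- "a"
  expect_warning(d <- build_design(spec, df_absent), "merged")
  expect_equal(ncol(d$X), 2L)  # intercept + b only
})

test_that("unpenalized IRLS matches an ordinary logistic fit", {
  df <- fx_logit_frame(500L)
  d <- build_design(fx_spec_logit(4L), df, outcome = "y")
  ours <- penalized_irls(d, lambda = c("s(age)" = 0), tol = 1e-12)
  B <- bspline_basis(df$age, 4L)
  cs <- colSums(B); j <- which.max(abs(cs))
  Z <- matrix(0, ncol(B), ncol(B) - 1L)
  Z[seq_len(ncol(B))[-j], ] <- diag(ncol(B) - 1L); Z[j, ] <- -cs[-j] / cs[j]
  Xg <- cbind(model.matrix(~ g1 + g2, df), B %*% Z)
  ref <- glm.fit(Xg, df$y, family = binomial(),
                 control = list(epsilon = 1e-12))
  expect_lt(max(abs(unname(ours$beta) - unname(coef(ref)))), 1e-6)
  expect_true(ours$converged)
})

test_that("huge smoothing drives a second-order-penalized smooth to a line", {
  df <- fx_logit_frame(800L, seed = 8L)
  d <- build_design(fx_spec_logit(10L), df, outcome = "y")
  f <- penalized_irls(d, lambda = c("s(age)" = 1e12), tol = 1e-12)
  fs <- starsae:::new_fitted_star(d, f, c("s(age)" = 1e12), NA_real_)
  grid <- data.frame(g1 = "a", g2 = "u", age = seq(25, 85, length.out = 40))
  eta <- predict_linear(fs, grid)
  expect_lt(max(abs(diff(eta, differences = 3))), 1e-6)
  # edf collapses to the penalty null space within the constraint (~1)
  expect_lt(f$edf_by_term[["s(age)"]], 1.05)
})

test_that("complete separation is caught and flagged, not fatal", {
  df <- data.frame(g1 = rep(c("a", "b"), each = 20), y = 0L)
  spec <- model_spec(term_linear("g1", levels = c("a", "b")))
  d <- build_design(spec, df, outcome = "y")
  f <- penalized_irls(d, maxit = 50L)
  expect_false(f$converged)
  expect_true(all(f$fitted < 1e-3))
  expect_gt(length(f$trace), 1L)
})

test_that("rank-deficient designs error naming collinear columns", {
  df <- fx_logit_frame(200L)
  df$g3 <- df$g2  # exact duplicate predictor
  spec <- model_spec(term_linear("g2", levels = c("u", "v")),
                     term_linear("g3", levels = c("u", "v"), name = "dup"))
  d <- build_design(spec, df, outcome = "y")
  expect_error(penalized_irls(d), "rank deficient")
})

test_that("REML optimum matches a criterion grid search", {
  df <- fx_logit_frame(1500L, seed = 31L, nonlinear = TRUE)
  d <- build_design(model_spec(term_smooth("age", 10L)), df, outcome = "y")
  sel <- reml_select(d)
  rhos <- seq(-4, 8, by = 0.25)
  vals <- vapply(rhos, function(r) reml_criterion(d, c("s(age)" = 10^r)),
                 numeric(1L))
  # the optimiser's criterion is at least the grid's best (within resolution)
  expect_gt(sel$reml, max(vals) - 1e-3)
  best_rho <- rhos[which.max(vals)]
  expect_lt(abs(log10(sel$lambda[["s(age)"]]) - best_rho), 0.5)
})

test_that("REML distinguishes non-linear from linear truths via edf", {
  df_nl <- fx_logit_frame(5000L, seed = 32L, nonlinear = TRUE)
  d_nl <- build_design(model_spec(term_smooth("age", 10L)), df_nl,
                       outcome = "y")
  expect_gt(reml_select(d_nl)$edf[["s(age)"]], 2)
  df_li <- fx_logit_frame(5000L, seed = 33L, nonlinear = FALSE)
  d_li <- build_design(model_spec(term_smooth("age", 10L)), df_li,
                       outcome = "y")
  expect_lte(reml_select(d_li)$edf[["s(age)"]], 2.5)
})

test_that("edf is monotone non-increasing in the smoothing parameter", {
  df <- fx_logit_frame(1000L, seed = 34L)
  d <- build_design(fx_spec_logit(10L), df, outcome = "y")
  edfs <- vapply(c(1e-3, 1e-1, 10, 1e3, 1e6), function(l) {
    penalized_irls(d, lambda = c("s(age)" = l))$edf_by_term[["s(age)"]]
  }, numeric(1L))
  expect_true(all(diff(edfs) < 1e-8))
})

test_that("prediction round-trips the training fit and handles edge cases", {
  fit <- fx_fit25()
  pop <- fx_pop25()
  # round-trip: predictions on the estimation sample equal fitted values
  d <- build_design(fx_spec_lean(), pop$persons, graph = pop$graph,
                    outcome = "overweight")
  refit <- penalized_irls(d, fit$lambda)
  p <- predict_prob(fit, pop$persons)
  expect_equal(unname(p), unname(refit$fitted), tolerance = 1e-6)
  # eta = 0 -> p = 0.5 through the link
  expect_equal(plogis(0), 0.5)
  # intercept-only coefficients give constant probability
  fit0 <- fit
  fit0$beta[] <- 0; fit0$beta[1L] <- 0.7
  expect_equal(unique(round(predict_prob(fit0, pop$persons[1:50]), 12)),
               round(plogis(0.7), 12))
  # fitted smooth and MRF average to zero over the estimation sample
  eta_terms <- predict_linear(fit, pop$persons)
  ti <- fit$terms[["s(age)"]]
  B <- bspline_basis(pop$persons$age, ti$n_knots, ti$degree, xr = ti$xr)
  expect_equal(mean(B %*% ti$Z %*% fit$beta[ti$cols]), 0, tolerance = 1e-8)
  gmrf <- term_coefficients(fit, "mrf(neigh)")
  expect_equal(mean(gmrf[pop$persons$neighbourhood_id]), 0, tolerance = 1e-8)
  # unknown neighbourhood: zero spatial contribution with a warning
  nd <- as.data.frame(pop$persons[1:2])
  nd$neighbourhood_id <- "NOPE"
  expect_warning(p2 <- predict_prob(fit, nd), "outside the estimation graph")
  expect_true(all(p2 > 0 & p2 < 1))
})

test_that("REML fit agrees with an independent mgcv cross-check", {
  df <- fx_logit_frame(2000L, seed = 35L)
  d <- build_design(model_spec(term_smooth("age", 10L)), df, outcome = "y")
  sel <- reml_select(d)
  ours <- penalized_irls(d, sel$lambda)$fitted
  ref <- mgcv::gam(y ~ s(age, bs = "ps", k = 12), data = df,
                   family = binomial(), method = "REML")
  expect_gt(cor(ours, fitted(ref)), 0.99)
  expect_lt(sqrt(mean((ours - fitted(ref))^2)), 0.02)
})

test_that("fitted models round-trip through JSON serialisation", {
  fit <- fx_fit25()
  pop <- fx_pop25()
  path <- withr::local_tempfile(fileext = ".json")
  write_fitted_star(fit, path)
  back <- read_fitted_star(path)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$lambda, fit$lambda)
  expect_equal(back$edf, fit$edf, tolerance = 1e-12)
  expect_equal(as.numeric(back$cov), as.numeric(fit$cov), tolerance = 1e-10)
  expect_equal(predict_prob(back, pop$persons[1:200]),
               predict_prob(fit, pop$persons[1:200]), tolerance = 1e-10)
})
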