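# Penalized IRLS and Laplace-approximate REML smoothing selection for the
# Bernoulli-logit structured additive model.

bernoulli_loglik <- function(y, eta) {
  sum(y * plogis(eta, log.p = TRUE) + (1 - y) * plogis(-eta, log.p = TRUE))
}

#' Penalized iteratively reweighted least squares
#'
#' Maximises the Bernoulli log-likelihood minus half the sum of the
#' quadratic penalties `lambda_j gamma_j' K_j gamma_j` by Newton (Fisher
#' scoring) steps on the working weighted least-squares problem, with step
#' halving if the penalized deviance increases. Convergence is declared
#' when the relative change in penalized deviance falls below `tol`;
#' divergence (complete separation) is caught by the iteration cap /
#' coefficient blow-up and flagged via `converged = FALSE`.
#'
#' @param design a [build_design()] result (must carry `y`, or pass `y`).
#' @param lambda named non-negative smoothing parameters, one per
#'   penalized term (missing names default to 0).
#' @param y optional response overriding `design$y`.
#' @param beta_init optional warm-start coefficient vector.
#' @param tol relative penalized-deviance convergence tolerance.
#' @param maxit iteration cap.
#' @param compute_cov return the coefficient covariance (inverse penalized
#'   Fisher information at convergence).
#' @return list with `beta`, `cov` (or NULL), `loglik`, `deviance`,
#'   `penalized_deviance`, `log_det_A` (log-determinant of the penalized
#'   Fisher information), `edf_by_term`, `iterations`, `converged`, and
#'   the iteration `trace` of penalized deviances.
#' @export
penalized_irls <- function(design, lambda = NULL, y = NULL, beta_init = NULL,
                           tol = 1e-8, maxit = 100L, compute_cov = TRUE) {
  stopifnot(inherits(design, "design_blocks"))
  y <- y %||% design$y
  if (is.null(y)) stop("no response: build the design with `outcome`")
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  pen <- penalized_terms(design)
  lambda <- complete_lambda(lambda, pen)
  if (any(lambda < 0)) stop("lambda must be non-negative")
  S <- assemble_penalty(design, lambda)

  beta <- beta_init %||% c(qlogis(min(max(mean(y), 0.01), 0.99)),
                           rep(0, p - 1L))
  eta <- drop(as.matrix(X %*% beta))
  pdev_of <- function(beta, eta) {
    -2 * bernoulli_loglik(y, eta) + sum(beta * as.numeric(S %*% beta))
  }
  pdev <- pdev_of(beta, eta)
  trace <- pdev
  converged <- FALSE
  A <- NULL
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    Xw <- X * w
    A <- Matrix::forceSymmetric(Matrix::crossprod(X, Xw) + S)
    b <- Matrix::crossprod(Xw, z)
    beta_new <- suppressWarnings(tryCatch(
      as.numeric(Matrix::solve(A, b)),
      error = function(e) diagnose_rank(design, A, e)))
    eta_new <- drop(as.matrix(X %*% beta_new))
    pdev_new <- pdev_of(beta_new, eta_new)
    half <- 0L
    while ((!is.finite(pdev_new) || pdev_new > pdev + 1e-10) && half < 30L) {
      half <- half + 1L
      beta_new <- (beta_new + beta) / 2
      eta_new <- drop(as.matrix(X %*% beta_new))
      pdev_new <- pdev_of(beta_new, eta_new)
    }
    delta <- abs(pdev - pdev_new) / (abs(pdev_new) + 0.1)
    beta <- beta_new; eta <- eta_new; pdev <- pdev_new
    trace <- c(trace, pdev)
    if (max(abs(beta)) > 1e4) break  # separation / divergence guard
    if (delta < tol) { converged <- TRUE; break }
  }
  if (converged && max(abs(eta)) > 20) {
    # fitted probabilities pinned at 0/1: quasi-separation, the optimum is
    # on the boundary and the coefficients are not meaningful
    converged <- FALSE
  }
  if (is.null(A)) {  # maxit = 0 edge
    mu <- plogis(eta); w <- pmax(mu * (1 - mu), 1e-10)
    A <- Matrix::forceSymmetric(Matrix::crossprod(X, X * w) + S)
  }

  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- Matrix::forceSymmetric(Matrix::crossprod(X, X * w))
  A <- Matrix::forceSymmetric(H + S)
  R <- chol(as.matrix(A))
  log_det_A <- 2 * sum(log(diag(R)))
  cov <- NULL
  edf_by_term <- NULL
  if (compute_cov) {
    cov <- chol2inv(R)
    Fmat <- cov %*% as.matrix(H)
    dF <- diag(Fmat)
    edf_by_term <- vapply(design$terms, function(ti) sum(dF[ti$cols]),
                          numeric(1L))
  }
  ll <- bernoulli_loglik(y, eta)
  list(beta = setNames(beta, colnames(X)), cov = cov, loglik = ll,
       deviance = -2 * ll, penalized_deviance = pdev,
       log_det_A = log_det_A, edf_by_term = edf_by_term,
       lambda = lambda, iterations = it, converged = converged,
       trace = trace, fitted = mu, eta = eta)
}

complete_lambda <- function(lambda, pen) {
  out <- setNames(rep(0, length(pen)), pen)
  if (is.null(lambda)) return(out)
  if (is.null(names(lambda))) {
    if (length(lambda) == 1L) lambda <- rep(lambda, length(pen))
    stopifnot(length(lambda) == length(pen))
    names(lambda) <- pen
  }
  bad <- setdiff(names(lambda), pen)
  if (length(bad)) stop("lambda for unknown penalized term(s): ",
                        paste(bad, collapse = ", "))
  out[names(lambda)] <- lambda
  out
}

diagnose_rank <- function(design, A, e) {
  qr_ <- qr(as.matrix(A))
  if (qr_$rank < ncol(A)) {
    bad <- colnames(design$X)[sort(qr_$pivot[(qr_$rank + 1L):ncol(A)])]
    stop("design is rank deficient after constraints; collinear columns: ",
         paste(head(bad, 10L), collapse = ", "))
  }
  stop(e)
}

#' Laplace-approximate REML criterion at fixed smoothing parameters
#'
#' The restricted log-likelihood approximated at the penalized MLE:
#' penalized log-likelihood, plus half the log pseudo-determinant of the
#' total penalty (over its range space), minus half the log-determinant of
#' the penalized Fisher information, plus the Gaussian normalising
#' constant for the penalized coefficients.
#'
#' @param design a [build_design()] result with a response.
#' @param lambda named positive smoothing parameters.
#' @param fit optional pre-computed [penalized_irls()] result at `lambda`.
#' @return scalar criterion value (to be maximised).
#' @export
reml_criterion <- function(design, lambda, fit = NULL) {
  pen <- penalized_terms(design)
  lambda <- complete_lambda(lambda, pen)
  if (is.null(fit)) {
    fit <- penalized_irls(design, lambda, compute_cov = FALSE)
  }
  ld_S <- 0; Mp <- 0
  for (nm in pen) {
    ti <- design$terms[[nm]]
    ld_S <- ld_S + ti$penalty_rank * log(lambda[[nm]]) + ti$penalty_logdet
    Mp <- Mp + ti$penalty_rank
  }
  pll <- fit$loglik - fit$penalized_deviance / 2 + fit$deviance / 2  # = ll - pen/2
  pll + ld_S / 2 - fit$log_det_A / 2 + Mp * log(2 * pi) / 2
}

#' Select smoothing parameters by REML and fit the model
#'
#' Maximises the Laplace-approximate restricted likelihood over the log
#' smoothing parameters (box-constrained quasi-Newton, warm-starting the
#' inner penalized-IRLS solve from the previous coefficients), then
#' refits at the optimum and packages the result.
#'
#' @param design a [build_design()] result with a response.
#' @param lambda_init named (or scalar) initial smoothing parameters.
#' @param lower,upper bounds for lambda on the log10 scale (defaults
#'   1e-12, 1e12).
#' @param outer_tol convergence tolerance on the REML criterion.
#' @param inner_tol penalized-IRLS deviance tolerance.
#' @param stratum_id,indicator optional labels stored on the fit.
#' @return a [fitted_star] object.
#' @export
reml_select <- function(design, lambda_init = 1, lower = -12, upper = 12,
                        outer_tol = 1e-6, inner_tol = 1e-8,
                        stratum_id = NA_character_,
                        indicator = NA_character_) {
  pen <- penalized_terms(design)
  if (length(pen) == 0L) stop("no penalized term; use penalized_irls directly")
  l0 <- complete_lambda(if (length(lambda_init) == 1L)
    setNames(rep(lambda_init, length(pen)), pen) else lambda_init, pen)
  l0[l0 <= 0] <- 1
  env <- new.env()
  env$beta <- NULL
  env$trace <- numeric(0)
  objective <- function(rho) {
    lambda <- setNames(10^rho, pen)
    fit <- penalized_irls(design, lambda, beta_init = env$beta,
                          tol = inner_tol, compute_cov = FALSE)
    if (fit$converged) env$beta <- unname(fit$beta)
    v <- reml_criterion(design, lambda, fit)
    env$trace <- c(env$trace, v)
    if (!is.finite(v)) return(1e10)
    -v
  }
  opt <- optim(log10(l0), objective, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(factr = outer_tol / .Machine$double.eps,
                              maxit = 200L))
  if (!opt$convergence %in% c(0L, 1L)) {
    stop("REML optimisation failed: ", opt$message,
         " (criterion trace: ", paste(round(tail(env$trace, 5L), 4), collapse = ", "),
         ")")
  }
  at_bound <- abs(opt$par - lower) < 1e-6 | abs(opt$par - upper) < 1e-6
  if (any(at_bound)) {
    message("smoothing parameter(s) at search bound: ",
            paste(pen[at_bound], collapse = ", "))
  }
  lambda <- setNames(10^opt$par, pen)
  fit <- penalized_irls(design, lambda, beta_init = env$beta,
                        tol = inner_tol, compute_cov = TRUE)
  new_fitted_star(design, fit, lambda, reml = -opt$value,
                  stratum_id = stratum_id, indicator = indicator)
}

#' Fit a structured additive prevalence model
#'
#' Convenience wrapper: builds the constrained design from the
#' specification, records and graph, then selects smoothing parameters by
#' REML ([reml_select()]); with no penalized terms it reduces to an
#' ordinary logistic fit via [penalized_irls()].
#'
#' @param spec a [model_spec()].
#' @param records fully observed person records.
#' @param outcome 0/1 outcome column name.
#' @param graph connected estimation-set [area_graph] (for spatial terms).
#' @param ... passed to [reml_select()].
#' @return a [fitted_star] object.
#' @export
fit_star <- function(spec, records, outcome, graph = NULL, ...) {
  design <- build_design(spec, records, graph = graph, outcome = outcome)
  if (length(penalized_terms(design)) == 0L) {
    fit <- penalized_irls(design)
    return(new_fitted_star(design, fit, lambda = setNames(numeric(0), NULL),
                           reml = NA_real_, ...))
  }
  reml_select(design, indicator = outcome, ...)
}

# ---- fitted_star ------------------------------------------------------------

#' Fitted structured additive regression model
#'
#' @description
#' The result of [reml_select()] / [fit_star()]: coefficients in the
#' constrained parameterisation, their covariance (inverse penalized
#' Fisher information), REML-selected smoothing parameters, per-term
#' effective degrees of freedom, convergence diagnostics, and the term
#' metadata needed to rebuild design blocks at prediction time.
#'
#' `coef()` and `vcov()` return the constrained-parameterisation
#' quantities; [term_coefficients()] maps a penalized term back to its
#' full (sum-to-zero) coefficient vector.
#'
#' @name fitted_star
NULL

new_fitted_star <- function(design, fit, lambda, reml,
                            stratum_id = NA_character_,
                            indicator = NA_character_) {
  structure(list(
    beta = fit$beta, cov = fit$cov, lambda = lambda,
    edf = fit$edf_by_term, reml = reml,
    loglik = fit$loglik, deviance = fit$deviance,
    iterations = fit$iterations, converged = fit$converged,
    terms = design$terms, n = design$n, p = length(fit$beta),
    outcome = if (!is.na(indicator)) indicator else design$outcome,
    stratum_id = stratum_id),
    class = "fitted_star")
}

#' @export
print.fitted_star <- function(x, ...) {
  cat("fitted_star:", x$p, "coefficients,", x$n, "records",
      if (!is.na(x$outcome)) paste0("[", x$outcome, "]"), "\n")
  if (length(x$lambda)) {
    cat("  lambda (REML):",
        paste(sprintf("%s=%.3g", names(x$lambda), x$lambda), collapse = ", "),
        "\n")
  }
  if (!is.null(x$edf)) {
    cat("  edf:", paste(sprintf("%s=%.2f", names(x$edf), x$edf),
                        collapse = ", "), "\n")
  }
  cat("  converged:", x$converged, "in", x$iterations, "IRLS iterations\n")
  invisible(x)
}

#' @export
coef.fitted_star <- function(object, ...) object$beta

#' @export
vcov.fitted_star <- function(object, ...) object$cov

#' Full coefficients of a penalized term
#'
#' Back-transforms a penalized term's constrained coefficients to the full
#' sum-to-zero parameterisation (e.g. one value per neighbourhood for the
#' MRF term).
#'
#' @param fit a [fitted_star] object.
#' @param term term name.
#' @return numeric vector (named by area id for spatial terms).
#' @export
term_coefficients <- function(fit, term) {
  ti <- fit$terms[[term]]
  if (is.null(ti)) stop("unknown term ", term)
  if (is.null(ti$Z)) stop("term ", term, " is not penalized")
  g <- drop(ti$Z %*% fit$beta[ti$cols])
  if (!is.null(ti$area_ids)) names(g) <- ti$area_ids
  g
}

# Rebuild one term's constrained design block on new records.
predict_term_block <- function(ti, records, term_name) {
  n <- nrow(records)
  if (ti$kind == "linear_categorical") {
    v <- records[[ti$predictor]]
    unseen <- setdiff(unique(v), ti$levels)
    if (length(unseen)) {
      stop("unseen category level(s) for ", ti$predictor, ": ",
           paste(unseen, collapse = ", "))
    }
    i <- which(v %in% ti$dummy_levels)
    return(Matrix::sparseMatrix(i = i, j = match(v[i], ti$dummy_levels),
                                x = 1, dims = c(n, length(ti$dummy_levels))))
  }
  if (ti$kind %in% c("smooth_bspline", "smooth_bspline_by")) {
    B <- bspline_basis(as.numeric(records[[ti$predictor]]), ti$n_knots,
                       ti$degree, xr = ti$xr)
    if (ti$kind == "smooth_bspline_by") {
      B <- B * as.numeric(records[[ti$by]] == ti$by_level)
    }
    return(Matrix::Matrix(B %*% ti$Z, sparse = TRUE))
  }
  if (ti$kind %in% c("mrf", "ridge")) {
    v <- as.character(records[[ti$predictor]])
    known <- v %in% ti$area_ids
    if (!all(known)) {
      warning(sum(!known), " record(s) in neighbourhoods outside the ",
              "estimation graph; their ", term_name,
              " contribution is set to 0")
    }
    i <- which(known)
    B <- Matrix::sparseMatrix(i = i, j = match(v[i], ti$area_ids), x = 1,
                              dims = c(n, length(ti$area_ids)))
    return(B %*% ti$Z)
  }
  stop("unknown term kind ", ti$kind)
}

#' Linear predictor and probabilities for new records
#'
#' Applies the fitted structured additive predictor to records (log-odds),
#' and transforms to probabilities via the inverse logit. Records in
#' neighbourhoods outside the estimation graph get a zero spatial
#' contribution (the centred prior mean) with a warning.
#'
#' @param fit a [fitted_star] object.
#' @param records fully observed person records.
#' @return numeric vector: log-odds (`predict_linear`) or probabilities in
#'   (0, 1) (`predict_prob`).
#' @export
predict_linear <- function(fit, records) {
  records <- as.data.frame(records)
  n <- nrow(records)
  eta <- rep(fit$beta[[1L]], n)
  for (nm in names(fit$terms)) {
    ti <- fit$terms[[nm]]
    Xb <- predict_term_block(ti, records, nm)
    eta <- eta + drop(as.matrix(Xb %*% fit$beta[ti$cols]))
  }
  eta
}

#' @rdname predict_linear
#' @export
predict_prob <- function(fit, records) {
  plogis(predict_linear(fit, records))
}

#' @export
predict.fitted_star <- function(object, newdata,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (type == "link") predict_linear(object, newdata)
  else predict_prob(object, newdata)
}

# ---- serialisation ----------------------------------------------------------

#' Serialise a fitted model to JSON (+ MatrixMarket covariance)
#'
#' Writes the coefficients, smoothing parameters, edf, convergence state
#' and per-term metadata as a versioned JSON document, and the coefficient
#' covariance as a MatrixMarket file next to it (`<path>.cov.mtx`).
#'
#' @param fit a [fitted_star] object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fitted_star <- function(fit, path) {
  terms <- lapply(fit$terms, function(ti) {
    ti$Z <- NULL  # reconstructed from drop_index + constraint on read
    ti$penalty <- NULL
    ti
  })
  Zs <- lapply(fit$terms, function(ti) {
    if (is.null(ti$Z)) NULL else as.matrix(ti$Z)
  })
  doc <- list(schema = "starsae-fit/1",
              outcome = fit$outcome, stratum_id = fit$stratum_id,
              n = fit$n, p = fit$p,
              beta = as.list(fit$beta), lambda = as.list(fit$lambda),
              edf = as.list(fit$edf), reml = fit$reml,
              loglik = fit$loglik, deviance = fit$deviance,
              iterations = fit$iterations, converged = fit$converged,
              terms = terms, Z = Zs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(fit$cov)) {
    Matrix::writeMM(methods::as(Matrix::Matrix(fit$cov, sparse = TRUE),
                                "generalMatrix"),
                    paste0(path, ".cov.mtx"))
  }
  invisible(path)
}

#' Read a fitted model written by [write_fitted_star()]
#'
#' @param path JSON path.
#' @return a [fitted_star] object.
#' @export
read_fitted_star <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "starsae-fit/1")) stop("unknown fit schema")
  terms <- lapply(names(doc$terms), function(nm) {
    ti <- doc$terms[[nm]]
    ti$cols <- as.integer(unlist(ti$cols))
    if (!is.null(ti$xr)) ti$xr <- as.numeric(unlist(ti$xr))
    Z <- doc$Z[[nm]]
    if (!is.null(Z)) ti$Z <- as.matrix(Z)
    ti
  })
  names(terms) <- names(doc$terms)
  covp <- paste0(path, ".cov.mtx")
  cov <- if (file.exists(covp)) as.matrix(Matrix::readMM(covp)) else NULL
  structure(list(
    beta = setNames(as.numeric(unlist(doc$beta)), names(doc$beta)),
    cov = cov,
    lambda = setNames(as.numeric(unlist(doc$lambda)), names(doc$lambda)),
    edf = setNames(as.numeric(unlist(doc$edf)), names(doc$edf)),
    reml = doc$reml, loglik = doc$loglik, deviance = doc$deviance,
    iterations = doc$iterations, converged = doc$converged,
    terms = terms, n = doc$n, p = doc$p,
    outcome = doc$outcome, stratum_id = doc$stratum_id),
    class = "fitted_star")
}
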