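#' Model terms for structured additive regression
#'
#' Constructors for the term types of the structured additive predictor:
#'
#' * `term_linear()` -- dummy-coded categorical effect; the reference level
#'   (first of the level set by default) is absorbed into the intercept.
#' * `term_smooth()` -- P-spline smooth of a numeric predictor: B-spline
#'   basis on `n_knots` equidistant knots with an `penalty_order`-th order
#'   difference penalty. With `by`/`by_level`, a varying-coefficient
#'   (interaction) smooth multiplied by the 0/1 indicator
#'   `predictor_by == by_level`.
#' * `term_mrf()` -- Markov-random-field spatial effect: one coefficient per
#'   neighbourhood, incidence design, penalty from [mrf_penalty()].
#' * `term_ridge()` -- exchangeable random-intercept effect per
#'   neighbourhood with an identity (ridge) penalty; off by default in
#'   [default_model_spec()].
#'
#' Every smooth/MRF/ridge term is constrained to sum to zero over the
#' estimation sample (implemented by reparameterisation, see
#' [build_design()]).
#'
#' @param predictor column name of the predictor.
#' @param reference_level reference category (default: first level of the
#'   predictor's level set).
#' @param levels optional explicit level set (defaults to
#'   [registry_levels]).
#' @param n_knots number of equidistant knots (default 10).
#' @param degree B-spline degree (default 3).
#' @param penalty_order difference-penalty order (default 2).
#' @param by,by_level optional categorical predictor and level defining a
#'   varying-coefficient smooth.
#' @param name term name (defaults to a descriptive label).
#' @return object of class `term_spec`.
#' @name model_terms
NULL

#' @rdname model_terms
#' @export
term_linear <- function(predictor, reference_level = NULL, levels = NULL,
                        name = predictor) {
  levels <- levels %||% registry_levels[[predictor]]
  if (is.null(levels)) stop("no level set known for predictor ", predictor)
  reference_level <- reference_level %||% levels[1L]
  if (!reference_level %in% levels) {
    stop("reference level ", reference_level, " not in level set of ",
         predictor)
  }
  structure(list(name = name, kind = "linear_categorical",
                 predictor = predictor, levels = levels,
                 reference_level = reference_level),
            class = "term_spec")
}

#' @rdname model_terms
#' @export
term_smooth <- function(predictor, n_knots = 10L, degree = 3L,
                        penalty_order = 2L, by = NULL, by_level = NULL,
                        name = NULL) {
  if (n_knots < penalty_order + 1L) {
    stop("n_knots must be at least penalty_order + 1")
  }
  if (!is.null(by) && is.null(by_level)) stop("by requires by_level")
  name <- name %||%
    if (is.null(by)) paste0("s(", predictor, ")")
    else paste0("s(", predictor, "|", by, "=", by_level, ")")
  structure(list(name = name,
                 kind = if (is.null(by)) "smooth_bspline" else "smooth_bspline_by",
                 predictor = predictor, n_knots = as.integer(n_knots),
                 degree = as.integer(degree),
                 penalty_order = as.integer(penalty_order),
                 by = by, by_level = by_level),
            class = "term_spec")
}

#' @rdname model_terms
#' @export
term_mrf <- function(predictor = "neighbourhood_id", name = "mrf(neigh)") {
  structure(list(name = name, kind = "mrf", predictor = predictor),
            class = "term_spec")
}

#' @rdname model_terms
#' @export
term_ridge <- function(predictor = "neighbourhood_id", name = "ridge(neigh)") {
  structure(list(name = name, kind = "ridge", predictor = predictor),
            class = "term_spec")
}

#' @export
print.term_spec <- function(x, ...) {
  cat("term_spec:", x$name, "[", x$kind, "on", x$predictor, "]\n")
  invisible(x)
}

#' Assemble a structured-additive model specification
#'
#' An ordered list of [model_terms] plus an always-on intercept and the
#' logit link. At most one MRF term is allowed and term names must be
#' unique.
#'
#' @param ... `term_spec` objects (or one list of them).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(...) {
  terms <- list(...)
  if (length(terms) == 1L && !inherits(terms[[1L]], "term_spec")) {
    terms <- terms[[1L]]
  }
  stopifnot(all(vapply(terms, inherits, logical(1L), "term_spec")))
  nms <- vapply(terms, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate term names")
  if (sum(vapply(terms, function(t) t$kind == "mrf", logical(1L))) > 1L) {
    stop("at most one mrf term allowed")
  }
  structure(list(terms = terms, intercept = TRUE, link = "logit"),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec with", length(x$terms), "terms (+ intercept, logit link):\n")
  for (t in x$terms) cat("  -", t$name, "[", t$kind, "]\n")
  invisible(x)
}

#' The default prevalence-model specification
#'
#' The full structured additive predictor used for the health indicators:
#' sex, ethnicity, marital status, household type, income source and home
#' ownership as dummy-coded categorical terms; 10-knot cubic P-splines for
#' age, the age-by-sex interaction, household capital, household income and
#' urbanisation; a 5-knot P-spline for household size; and an MRF spatial
#' effect over the neighbourhood graph. A ridge (random-intercept) term is
#' available via `ridge = TRUE` but off by default.
#'
#' @param ridge include an exchangeable neighbourhood ridge term.
#' @return a [model_spec()].
#' @export
default_model_spec <- function(ridge = FALSE) {
  terms <- list(
    term_linear("sex"),
    term_smooth("age", n_knots = 10L),
    term_smooth("age", n_knots = 10L, by = "sex", by_level = "female"),
    term_linear("eth"),
    term_linear("mar"),
    term_linear("hhtype"),
    term_smooth("hhsize", n_knots = 5L),
    term_smooth("hhcap", n_knots = 10L),
    term_smooth("hhinc", n_knots = 10L),
    term_linear("hhincsrc"),
    term_linear("home"),
    term_smooth("urb", n_knots = 10L),
    term_mrf())
  if (ridge) terms <- c(terms, list(term_ridge()))
  model_spec(terms)
}
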