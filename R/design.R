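# Design construction: turns a model_spec plus records (and the adjacency
# graph for spatial terms) into a sparse design matrix with per-term
# penalty blocks, with sum-to-zero constraints absorbed by
# reparameterisation.

#' Build constrained design and penalty blocks
#'
#' Evaluates every term of the specification on the records: categorical
#' terms are dummy-coded with the reference absorbed into the intercept;
#' smooth terms get their B-spline basis (knots anchored on the observed
#' range); the MRF/ridge terms get a 0/1 neighbourhood incidence block.
#' Each penalized block is reparameterised so the fitted term sums to zero
#' over the estimation sample: with constraint vector `c = colSums(B)` (or
#' `colSums(B * by)` for interaction smooths; the neighbourhood person
#' counts for the MRF), one coefficient is expressed in the others through
#' `c'gamma = 0` and the penalty is transformed consistently. Simple
#' column-mean centring would not handle the MRF null space; the
#' reparameterisation removes it exactly.
#'
#' Categorical levels absent from the records are merged into the
#' reference with a warning. Values outside a predictor's level set, or
#' neighbourhoods missing from the graph, are errors.
#'
#' @param spec a [model_spec()].
#' @param records data.frame of fully observed persons (run imputation
#'   first).
#' @param graph an [area_graph] covering all record neighbourhoods
#'   (required iff the spec has an MRF or ridge term). Use the connected
#'   estimation-set graph from [connect_subgraphs()].
#' @param outcome optional column name of the 0/1 response to attach.
#' @return object of class `design_blocks`: sparse design `X` (first
#'   column the intercept), response `y` (or NULL), and per-term metadata
#'   (`cols`, penalty `K`, its positive-eigenvalue log-determinant and
#'   rank, the reparameterisation, and what prediction needs to rebuild
#'   the block).
#' @export
build_design <- function(spec, records, graph = NULL, outcome = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n == 0L) stop("no records")

  needs_graph <- any(vapply(spec$terms, function(t) t$kind %in% c("mrf", "ridge"),
                            logical(1L)))
  if (needs_graph && is.null(graph)) stop("spec has a spatial term; graph required")

  blocks <- list(Matrix::Matrix(1, n, 1L, sparse = TRUE,
                                dimnames = list(NULL, "(Intercept)")))
  terms_out <- list()
  col_at <- 1L

  for (ts in spec$terms) {
    built <- switch(ts$kind,
      linear_categorical = build_linear_block(ts, records),
      smooth_bspline = build_smooth_block(ts, records),
      smooth_bspline_by = build_smooth_block(ts, records),
      mrf = build_area_block(ts, records, graph, kind = "mrf"),
      ridge = build_area_block(ts, records, graph, kind = "ridge"),
      stop("unknown term kind ", ts$kind))
    if (is.null(built)) next  # degenerate term dropped (warned inside)
    d <- ncol(built$X)
    built$info$cols <- col_at + seq_len(d)
    col_at <- col_at + d
    colnames(built$X) <- paste0(ts$name, ".", seq_len(d))
    blocks[[length(blocks) + 1L]] <- built$X
    terms_out[[ts$name]] <- built$info
  }

  X <- do.call(cbind, blocks)
  y <- NULL
  if (!is.null(outcome)) {
    y <- records[[outcome]]
    if (is.null(y)) stop("outcome column ", outcome, " not found")
    if (!all(y %in% c(0L, 1L))) stop("outcome must be binary 0/1")
    y <- as.numeric(y)
  }
  structure(list(X = X, y = y, terms = terms_out, n = n,
                 outcome = outcome %||% NA_character_),
            class = "design_blocks")
}

build_linear_block <- function(ts, records) {
  v <- records[[ts$predictor]]
  if (is.null(v)) stop("predictor ", ts$predictor, " not found")
  if (anyNA(v)) stop("predictor ", ts$predictor, " has missing values")
  unseen <- setdiff(unique(v), ts$levels)
  if (length(unseen)) {
    stop("unseen category level(s) for ", ts$predictor, ": ",
         paste(unseen, collapse = ", "))
  }
  dummy_levels <- setdiff(ts$levels, ts$reference_level)
  absent <- setdiff(dummy_levels, unique(v))
  if (length(absent)) {
    warning("levels of ", ts$predictor, " absent from the sample merged ",
            "into the reference: ", paste(absent, collapse = ", "))
    dummy_levels <- setdiff(dummy_levels, absent)
  }
  if (length(dummy_levels) == 0L) return(NULL)
  i <- which(v %in% dummy_levels)
  j <- match(v[i], dummy_levels)
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(nrow(records), length(dummy_levels)))
  list(X = X, info = list(kind = ts$kind, predictor = ts$predictor,
                          levels = ts$levels, dummy_levels = dummy_levels,
                          reference_level = ts$reference_level,
                          penalty = NULL))
}

build_smooth_block <- function(ts, records) {
  v <- records[[ts$predictor]]
  if (is.null(v)) stop("predictor ", ts$predictor, " not found")
  if (anyNA(v)) stop("predictor ", ts$predictor, " has missing values")
  B <- bspline_basis(as.numeric(v), ts$n_knots, ts$degree)
  xr <- attr(B, "xr")
  w <- rep(1, nrow(B))
  if (ts$kind == "smooth_bspline_by") {
    byv <- records[[ts$by]]
    if (is.null(byv)) stop("by variable ", ts$by, " not found")
    w <- as.numeric(byv == ts$by_level)
    B <- B * w
  }
  K <- unclass(difference_penalty(ncol(B), ts$penalty_order))
  rp <- reparam_sum_to_zero(B, K)
  if (is.null(rp)) {
    warning("smooth term ", ts$name, " degenerate (empty constraint); dropped")
    return(NULL)
  }
  list(X = Matrix::Matrix(rp$Xc, sparse = TRUE),
       info = c(list(kind = ts$kind, predictor = ts$predictor,
                     n_knots = ts$n_knots, degree = ts$degree,
                     penalty_order = ts$penalty_order, xr = xr,
                     by = ts$by, by_level = ts$by_level),
                rp$info))
}

build_area_block <- function(ts, records, graph, kind) {
  v <- as.character(records[[ts$predictor]])
  if (is.null(records[[ts$predictor]])) {
    stop("predictor ", ts$predictor, " not found")
  }
  ids <- graph_ids(graph)
  bad <- setdiff(unique(v), ids)
  if (length(bad)) {
    stop("neighbourhood(s) not in graph: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  if (length(ids) < 2L) {
    warning("spatial term ", ts$name, " dropped: graph has a single area")
    return(NULL)
  }
  B <- Matrix::sparseMatrix(i = seq_along(v), j = match(v, ids), x = 1,
                            dims = c(length(v), length(ids)))
  K <- if (kind == "mrf") unclass(mrf_penalty(graph)) else diag(length(ids))
  rp <- reparam_sum_to_zero(B, K)
  list(X = rp$Xc,
       info = c(list(kind = kind, predictor = ts$predictor, area_ids = ids),
                rp$info))
}

# Reparameterise a penalized block under the constraint c' gamma = 0 with
# c = colSums(B): gamma = Z theta where one coefficient (the one with the
# largest |c|, so never an empty area) is solved from the others. Returns
# the constrained design B Z, transformed penalty Z' K Z, and the spectral
# quantities REML needs (positive-eigenvalue log-determinant and rank).
reparam_sum_to_zero <- function(B, K) {
  cvec <- Matrix::colSums(B)
  if (all(abs(cvec) < 1e-12)) return(NULL)
  d <- ncol(B)
  j <- which.max(abs(cvec))
  alpha <- cvec[-j] / cvec[j]
  Z <- matrix(0, d, d - 1L)
  Z[seq_len(d)[-j], ] <- diag(d - 1L)
  Z[j, ] <- -alpha
  Xc <- B[, -j, drop = FALSE] -
    B[, j, drop = FALSE] %*% Matrix::Matrix(alpha, 1L, d - 1L)
  Kt <- crossprod(Z, K %*% Z)
  Kt <- (Kt + t(Kt)) / 2
  ev <- eigen(Kt, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev > max(ev) * 1e-9
  list(Xc = Xc,
       info = list(penalty = Kt, Z = Z, drop_index = j,
                   penalty_rank = sum(pos),
                   penalty_logdet = sum(log(ev[pos]))))
}

#' @export
print.design_blocks <- function(x, ...) {
  cat("design_blocks:", x$n, "records x", ncol(x$X), "columns;",
      sum(vapply(x$terms, function(t) !is.null(t$penalty), logical(1L))),
      "penalized terms\n")
  invisible(x)
}

penalized_terms <- function(design) {
  names(design$terms)[vapply(design$terms,
                             function(t) !is.null(t$penalty), logical(1L))]
}

# Assemble the total penalty matrix S(lambda) as a sparse p x p matrix.
assemble_penalty <- function(design, lambda) {
  p <- ncol(design$X)
  S <- Matrix::Matrix(0, p, p, sparse = TRUE)
  for (nm in names(lambda)) {
    ti <- design$terms[[nm]]
    S[ti$cols, ti$cols] <- S[ti$cols, ti$cols] + lambda[[nm]] * ti$penalty
  }
  Matrix::forceSymmetric(S)
}
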