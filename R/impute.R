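# Single imputation of missing household fields via multinomial logit on
# the fully observed individual predictors (age spline, sex, ethnicity,
# marital status).

imputable_fields <- c("hhtype", "hhsize", "hhcap", "hhinc", "hhincsrc", "home")
percentile_fields <- c("hhcap", "hhinc")

# Natural cubic spline of age with boundary knots 22 and 80 (linear tails)
# and interior knots 30 and 50.
age_spline <- function(age) {
  splines::ns(age, knots = c(30, 50), Boundary.knots = c(22, 80))
}

# shared fixed-knot formula; spelled out (not via the helper) so that
# model-frame machinery can standardise the spline call
imputer_formula <- .target ~ splines::ns(age, knots = c(30, 50),
                                         Boundary.knots = c(22, 80)) +
  sex + eth + mar

imputer_frame <- function(records) {
  data.frame(age = as.numeric(records$age),
             sex = factor(records$sex, levels = registry_levels$sex),
             eth = factor(records$eth, levels = registry_levels$eth),
             mar = factor(records$mar, levels = registry_levels$mar))
}

#' Fit a single-imputation model for a household field
#'
#' Maximum-likelihood multinomial logit of the (possibly class-reduced)
#' target on a natural cubic spline of age (knots at ages 22, 30, 50 and
#' 80; linear tails), sex, ethnicity and marital status, fitted on the
#' records where the target is observed. For the percentile fields
#' (`hhcap`, `hhinc`) the 100 percentile classes are first reduced to five
#' classes of 20 contiguous percentiles.
#'
#' @param records registry records (with missing values in the target).
#' @param target one of `hhtype`, `hhsize`, `hhcap`, `hhinc`, `hhincsrc`,
#'   `home`.
#' @return object of class `imputation_model`: the fitted multinomial
#'   logit, the class labels, and for percentile fields the class-to-range
#'   map.
#' @export
fit_imputer <- function(records, target) {
  if (!target %in% imputable_fields) {
    stop("target must be one of ", paste(imputable_fields, collapse = ", "))
  }
  records <- as.data.frame(records)
  obs <- !is.na(records[[target]])
  if (!any(obs)) stop("no observed values for ", target)
  v <- records[[target]][obs]
  if (target %in% percentile_fields) {
    classes <- as.character(1:5)
    ranges <- lapply(1:5, function(cl) (20L * (cl - 1L) + 1L):(20L * cl))
    names(ranges) <- classes
    yv <- as.character((as.integer(v) - 1L) %/% 20L + 1L)
  } else if (target == "hhsize") {
    classes <- as.character(1:10)
    ranges <- NULL
    yv <- as.character(as.integer(v))
  } else {
    classes <- registry_levels[[target]]
    ranges <- NULL
    yv <- as.character(v)
  }
  seen <- classes[classes %in% unique(yv)]
  if (length(seen) < 2L) {
    warning("single observed class for ", target,
            "; imputations will all be ", seen)
    return(structure(list(target = target, classes = classes, seen = seen,
                          ranges = ranges, model = NULL, degenerate = TRUE),
                     class = "imputation_model"))
  }
  df <- imputer_frame(records[obs, , drop = FALSE])
  if (min(df$age) > 22 || max(df$age) < 80) {
    # knots must be covered for the linear tails to be extrapolation, not
    # interpolation; fitting still works, so only note it
    message("observed age range does not cover the spline knots 22..80")
  }
  df$.target <- factor(yv, levels = seen)
  fit <- nnet::multinom(imputer_formula, data = df, trace = FALSE,
                        maxit = 300L, MaxNWts = 5000L)
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, 1L, dimnames = list(seen[2L], names(cf)))
  structure(list(target = target, classes = classes, seen = seen,
                 ranges = ranges, coefmat = cf, degenerate = FALSE),
            class = "imputation_model")
}

#' @export
print.imputation_model <- function(x, ...) {
  cat("imputation_model for", x$target, "-", length(x$seen), "of",
      length(x$classes), "classes observed",
      if (x$degenerate) "(degenerate)", "\n")
  invisible(x)
}

predict_class_probs <- function(model, records) {
  if (model$degenerate) {
    p <- matrix(1, nrow(records), 1L, dimnames = list(NULL, model$seen))
    return(p)
  }
  df <- imputer_frame(records)
  if (anyNA(df)) stop("record missing a predictor required by the imputer")
  X <- model.matrix(imputer_formula[-2L], data = df)
  eta <- X %*% t(model$coefmat)  # log-odds vs the baseline class
  p <- cbind(1, exp(eta))
  p <- p / rowSums(p)
  colnames(p) <- model$seen
  p
}

#' Impute missing household fields
#'
#' Draws each missing field once from the imputer's predicted class
#' probabilities. Households are imputed jointly: one class draw per
#' household (using its first member's individual predictors), copied to
#' all members with a missing value -- household fields are household
#' attributes, so within-household consistency is enforced. For the
#' percentile fields the drawn class (1..5) is completed by an integer
#' percentile sampled uniformly from the class's 20-wide range. Observed
#' values are never altered.
#'
#' @param records registry records with missing household fields.
#' @param models named list of [fit_imputer()] results (one per field with
#'   missing values).
#' @param seed integer seed for the class and percentile draws.
#' @return a data.table with no missing values in the imputed fields.
#' @export
impute <- function(records, models, seed = 1L) {
  out <- data.table::as.data.table(records)
  with_seed(stage_seed(seed, "impute"), {
    for (model in models) {
      f <- model$target
      if (!f %in% names(out)) next
      # a household attribute observed on any member is known for all of
      # them: copy it before drawing anything
      miss <- which(is.na(out[[f]]))
      if (length(miss) && "household_id" %in% names(out)) {
        known <- out[!is.na(get(f)), .(.v = get(f)[1L]), by = household_id]
        fill <- known$.v[match(out$household_id[miss], known$household_id)]
        ok <- !is.na(fill)
        if (any(ok)) {
          data.table::set(out, i = miss[ok], j = f, value = fill[ok])
        }
      }
      miss <- which(is.na(out[[f]]))
      if (length(miss) == 0L) next
      hh <- out$household_id[miss]
      first_rows <- miss[!duplicated(hh)]
      probs <- predict_class_probs(model, as.data.frame(out[first_rows]))
      k <- ncol(probs)
      u <- runif(length(first_rows))
      cum <- probs %*% upper.tri(diag(k), diag = TRUE)
      cls_idx <- rowSums(u > cum) + 1L
      cls <- model$seen[pmin(cls_idx, k)]
      if (f %in% percentile_fields) {
        val <- vapply(cls, function(cl) {
          r <- model$ranges[[cl]]
          r[sample.int(length(r), 1L)]
        }, integer(1L))
      } else if (f == "hhsize") {
        val <- as.integer(cls)
      } else {
        val <- cls
      }
      hh_val <- setNames(val, out$household_id[first_rows])
      fill <- hh_val[hh]
      if (is.integer(out[[f]])) fill <- as.integer(fill)
      data.table::set(out, i = miss, j = f, value = unname(fill))
    }
  })
  targets <- vapply(models, `[[`, "", "target")
  still <- vapply(intersect(targets, names(out)),
                  function(f) anyNA(out[[f]]), logical(1L))
  if (any(still)) {
    stop("imputation left missing values in: ",
         paste(names(still)[still], collapse = ", "))
  }
  out[]
}

#' Fit imputers and impute all six household fields
#'
#' Convenience wrapper: fits [fit_imputer()] for every imputable field
#' that has missing values and applies [impute()].
#'
#' @param records registry records.
#' @param seed integer seed.
#' @return a data.table with zero missing values.
#' @export
impute_registry <- function(records, seed = 1L) {
  records <- data.table::as.data.table(records)
  fields <- intersect(imputable_fields, names(records))
  fields <- fields[vapply(fields, function(f) anyNA(records[[f]]), logical(1L))]
  if (length(fields) == 0L) return(records)
  models <- lapply(fields, function(f) fit_imputer(records, f))
  impute(records, models, seed = seed)
}

#' Serialise an imputation model to JSON
#'
#' Stores the multinomial coefficients, class labels and percentile
#' ranges; [read_imputer()] restores an equivalent model.
#'
#' @param model an `imputation_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_imputer <- function(model, path) {
  doc <- list(schema = "starsae-imputer/1", target = model$target,
              classes = model$classes, seen = model$seen,
              ranges = model$ranges, degenerate = model$degenerate,
              coef = if (!model$degenerate) {
                list(rows = rownames(model$coefmat),
                     cols = colnames(model$coefmat),
                     values = as.numeric(model$coefmat))
              })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_imputer
#' @param path JSON path written by `write_imputer`.
#' @export
read_imputer <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "starsae-imputer/1")) stop("unknown imputer schema")
  cf <- NULL
  if (!isTRUE(doc$degenerate)) {
    cf <- matrix(doc$coef$values, nrow = length(doc$coef$rows),
                 dimnames = list(doc$coef$rows, doc$coef$cols))
  }
  ranges <- if (!is.null(doc$ranges)) {
    lapply(doc$ranges, function(r) as.integer(unlist(r)))
  }
  structure(list(target = doc$target, classes = as.character(doc$classes),
                 seen = as.character(doc$seen), ranges = ranges,
                 coefmat = cf, degenerate = isTRUE(doc$degenerate)),
            class = "imputation_model")
}
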