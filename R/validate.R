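# Calibration assessment by train/validation splitting and quantile
# binning, plus comparison of two estimate sets and extreme-area ranking.

#' Split respondents into training and validation sets
#'
#' Seeded random split with sizes within one of the exact fractions
#' (default 2/3 training, 1/3 validation); disjoint and exhaustive.
#'
#' @param respondents data.frame of respondents (any rows).
#' @param fractions length-2 proportions summing to 1.
#' @param seed integer seed.
#' @return list with `train` and `validation` data.frames.
#' @export
split_train_validation <- function(respondents, fractions = c(2 / 3, 1 / 3),
                                   seed = 1L) {
  if (abs(sum(fractions)) - 1 > 1e-12 || length(fractions) != 2L) {
    stop("fractions must be two proportions summing to 1")
  }
  n <- nrow(respondents)
  if (is.null(n) || n == 0L) stop("empty input")
  n_train <- round(n * fractions[1L])
  idx <- with_seed(stage_seed(seed, "split"), sample.int(n, n_train))
  list(train = respondents[idx, , drop = FALSE],
       validation = respondents[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Calibration table by quantile bins
#'
#' Sorts records by predicted probability (ties broken stably by record
#' id), splits them into `n_bins` contiguous groups of near-equal size
#' (differing by at most one), and averages predicted probabilities and
#' observed outcomes per bin. A least-squares regression of observed on
#' predicted bin means summarises the table: slope 1 and intercept 0
#' indicate perfect calibration.
#'
#' @param predicted numeric probability vector.
#' @param observed aligned 0/1 outcomes.
#' @param n_bins number of quantile bins (default 200; must not exceed
#'   the number of records).
#' @param ids optional record ids for tie-breaking (default input order).
#' @return object of class `calibration_table`: data.table with `bin`,
#'   `n`, `mean_pred`, `mean_obs`, plus attributes `slope`, `intercept`
#'   and `n_bins`.
#' @export
calibration_bins <- function(predicted, observed, n_bins = 200L, ids = NULL) {
  n <- length(predicted)
  stopifnot(length(observed) == n)
  if (n_bins > n) stop("n_bins exceeds the number of records")
  ids <- ids %||% seq_len(n)
  ord <- order(predicted, ids)
  bin <- ceiling(seq_len(n) * n_bins / n)
  dt <- data.table::data.table(bin = bin,
                               pred = predicted[ord], obs = observed[ord])
  tab <- dt[, .(n = .N, mean_pred = mean(pred), mean_obs = mean(obs)),
            by = bin]
  fit <- lm(mean_obs ~ mean_pred, data = tab)
  data.table::setattr(tab, "slope", unname(coef(fit)[2L]))
  data.table::setattr(tab, "intercept", unname(coef(fit)[1L]))
  data.table::setattr(tab, "n_bins", as.integer(n_bins))
  data.table::setattr(tab, "class", c("calibration_table", class(tab)))
  tab[]
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("calibration_table: %d bins, mean size %.1f, slope %.3f, intercept %.4f\n",
              attr(x, "n_bins"), mean(x$n), attr(x, "slope"),
              attr(x, "intercept")))
  NextMethod()
}

#' Write a calibration table to CSV
#'
#' @param tab a `calibration_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(tab, path) {
  data.table::fwrite(data.table::as.data.table(tab), path)
  invisible(path)
}

#' Compare two sets of area estimates
#'
#' Pairs the non-sanitised areas shared by both sets and reports the
#' Pearson correlation, the mean difference (a - b), and the attenuation
#' ratio sd(a)/sd(b) -- a ratio below 1 quantifies model estimates being
#' less extreme (shrunk) relative to, e.g., direct survey-weighted
#' estimates.
#'
#' @param set_a,set_b `prevalence_estimate` tables (or data.frames with
#'   `area_id`, `prevalence`, optional `sanitised`).
#' @return list with the paired table and `correlation`,
#'   `mean_difference`, `attenuation_ratio`, `n_areas`.
#' @export
compare_estimates <- function(set_a, set_b) {
  a <- data.table::as.data.table(set_a)
  b <- data.table::as.data.table(set_b)
  if ("sanitised" %in% names(a)) a <- a[sanitised == FALSE]
  if ("sanitised" %in% names(b)) b <- b[sanitised == FALSE]
  m <- merge(a[, .(area_id, prev_a = prevalence)],
             b[, .(area_id, prev_b = prevalence)], by = "area_id")
  if (nrow(m) == 0L) stop("no overlapping non-sanitised areas")
  list(paired = m[],
       n_areas = nrow(m),
       correlation = if (nrow(m) > 1L) cor(m$prev_a, m$prev_b) else NA_real_,
       mean_difference = mean(m$prev_a - m$prev_b),
       attenuation_ratio = if (nrow(m) > 1L && sd(m$prev_b) > 0)
         sd(m$prev_a) / sd(m$prev_b) else NA_real_)
}

#' Most extreme area estimates with population profiles
#'
#' Ranks the non-sanitised areas by prevalence and returns the top and
#' bottom `k`, each with a summary of its population (size, mean age,
#' dominant categories) to support plausibility audits of outlying
#' neighbourhoods. Ties are broken by area id.
#'
#' @param estimates a `prevalence_estimate` table.
#' @param registry registry records for the profiles (optional).
#' @param k how many areas at each end.
#' @return list with `top` and `bottom` data.tables.
#' @export
extreme_areas <- function(estimates, registry = NULL, k = 5L) {
  if (k < 1L) stop("k must be >= 1")
  est <- data.table::as.data.table(estimates)
  est <- est[sanitised == FALSE]
  if (k > nrow(est)) {
    warning("k exceeds the number of non-sanitised areas; truncated")
    k <- nrow(est)
  }
  est <- est[order(-prevalence, area_id)]
  top <- est[seq_len(k)]
  bottom <- est[order(prevalence, area_id)][seq_len(k)]
  if (!is.null(registry)) {
    col <- level_column(est$level[1L])
    reg <- data.table::as.data.table(registry)
    profile <- function(tab) {
      prof <- reg[get(col) %in% tab$area_id,
                  .(mean_age = mean(age),
                    pct_female = 100 * mean(sex == "female"),
                    top_eth = names(sort(table(eth), decreasing = TRUE))[1L],
                    top_hhtype = names(sort(table(hhtype),
                                            decreasing = TRUE))[1L]),
                  by = c(col)]
      data.table::setnames(prof, col, "area_id")
      merge(tab, prof, by = "area_id", sort = FALSE)
    }
    top <- profile(top)
    bottom <- profile(bottom)
  }
  list(top = top[], bottom = bottom[])
}
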