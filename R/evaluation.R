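# Evaluation protocol: percentage relative error, Bland-Altman limits of
# agreement, regression summaries, localization error aggregation, and the
# subject-level k-fold cross-validation harness.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Percentage relative error
#'
#' `|pred - truth| / |truth| * 100`; scale-invariant.
#'
#' @param pred,truth scalars or equal-length vectors (elementwise).
#' @return percentage relative error(s).
#' @export
pre <- function(pred, truth) {
  if (any(truth == 0))
    stop_bodycomp("percentage relative error undefined for truth == 0",
                  "bodycomp_undefined_statistic")
  abs(pred - truth) / abs(truth) * 100
}

#' Bland-Altman limits of agreement
#'
#' Bias is the mean of (pred - truth); the limits of agreement are
#' `bias +/- 1.96 * sd` of the paired differences (population sd).
#'
#' @param pred,truth equal-length numeric vectors (n >= 2).
#' @return named numeric c(bias, upper_loa, lower_loa).
#' @export
bland_altman <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  stopifnot(length(pred) >= 2)
  d <- pred - truth
  bias <- mean(d)
  s <- pop_sd(d)
  c(bias = bias, upper_loa = bias + 1.96 * s, lower_loa = bias - 1.96 * s)
}

#' Regression and agreement summary for one index
#'
#' Ordinary least squares of `pred` on `truth`, Pearson r with its two-sided
#' p-value, r^2, Bland-Altman bias and limits of agreement, and the
#' percentage relative error aggregated as mean +/- sd over subjects.
#'
#' @param pred,truth equal-length numeric vectors (n >= 3, non-constant).
#' @return an `agreement_summary` (one-row data.frame) with columns `r`,
#'   `p_value`, `r2`, `bias`, `upper_loa`, `lower_loa`, `pre_mean`, `pre_sd`.
#' @export
regression_summary <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 3)
  if (pop_sd(pred) == 0 || pop_sd(truth) == 0)
    stop("constant input series: regression undefined")
  ct <- cor.test(truth, pred, method = "pearson")
  fit <- lm(pred ~ truth)
  ba <- bland_altman(pred, truth)
  pres <- pre(pred, truth)
  out <- data.frame(r = unname(ct$estimate), p_value = ct$p.value,
                    r2 = unname(ct$estimate)^2,
                    bias = unname(ba["bias"]),
                    upper_loa = unname(ba["upper_loa"]),
                    lower_loa = unname(ba["lower_loa"]),
                    pre_mean = mean(pres), pre_sd = pop_sd(pres))
  attr(out, "fit") <- fit
  class(out) <- c("agreement_summary", class(out))
  out
}

#' Aggregate localization errors
#'
#' @param errors_mm numeric vector of per-case absolute errors in mm.
#' @return named numeric: `mae`, `sd` (population), `pct_under_10mm`
#'   (strictly less than 10 mm, as a percentage).
#' @export
localization_summary <- function(errors_mm) {
  stopifnot(length(errors_mm) >= 1)
  e <- abs(errors_mm)
  c(mae = mean(e), sd = pop_sd(e), pct_under_10mm = 100 * mean(e < 10))
}

#' Deterministic subject-level k-fold partition
#'
#' @param subjects vector of subject identifiers (or an integer count).
#' @param k number of folds.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return list of `k` disjoint index vectors covering all subjects.
#' @export
kfold_split <- function(subjects, k = 5, seed = 1) {
  n <- if (length(subjects) == 1 && is.numeric(subjects)) subjects else length(subjects)
  if (k > n) stop("k (", k, ") exceeds the number of subjects (", n, ")")
  perm <- with_seed(seed, sample.int(n))
  split(perm, rep_len(seq_len(k), n))
}

#' k-fold cross-validation harness
#'
#' Partitions subjects with [kfold_split()], trains on k-1 folds and
#' evaluates on the held-out fold, then aggregates fold metrics as
#' mean +/- sd (population). Optionally refits on the complete dataset for
#' external testing.
#'
#' @param dataset a list of subjects (any per-subject structure).
#' @param k number of folds (default 5).
#' @param seed integer seed for the partition.
#' @param train_fn function(train_subset) -> fitted object.
#' @param metric_fn function(fitted, test_subset) -> named numeric vector.
#' @param final_fit also train on the complete dataset (default TRUE).
#' @return list with `folds` (data.frame of per-fold metrics), `aggregate`
#'   (data.frame with mean and sd per metric), `assignments` (the partition)
#'   and `final` (fit on all subjects, or NULL).
#' @export
kfold_harness <- function(dataset, k = 5, seed = 1, train_fn, metric_fn,
                          final_fit = TRUE) {
  folds <- kfold_split(length(dataset), k = k, seed = seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    fit <- train_fn(dataset[-test_idx])
    rows[[f]] <- c(fold = f, metric_fn(fit, dataset[test_idx]))
  }
  folds_df <- as.data.frame(do.call(rbind, rows))
  mets <- setdiff(names(folds_df), "fold")
  aggregate <- data.frame(metric = mets,
                          mean = vapply(mets, function(m) mean(folds_df[[m]]), 0),
                          sd = vapply(mets, function(m) pop_sd(folds_df[[m]]), 0),
                          row.names = NULL)
  list(folds = folds_df, aggregate = aggregate, assignments = folds,
       final = if (final_fit) train_fn(dataset) else NULL)
}
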