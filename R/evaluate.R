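#' Spearman rank correlation with large-sample p-value
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' standard large-sample t approximation.
#'
#' @param x,y equal-length numeric vectors, length >= 3, neither constant.
#' @return List with `rs` and `p_value`.
#' @export
spearman_rs <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector",
         call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rs = unname(ct$estimate), p_value = ct$p.value)
}

#' Error and fit metrics of predictions against ground truth
#'
#' `mae` is the mean absolute error in degrees, `mse` the mean squared
#' error in degrees squared, and `r_squared` the
#' coefficient-of-determination-against-truth form
#' `1 - SS_res / SS_tot` (which penalizes bias, unlike the squared
#' correlation of a refit line).
#'
#' @param predicted,truth equal-length numeric vectors, length >= 2.
#' @return List with `r_squared`, `mae`, `mse`; `r_squared` is `NA` (with
#'   a warning) when the truth vector is constant.
#' @export
regression_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch",
                                               call. = FALSE)
  if (length(truth) < 2) stop("need at least 2 observations", call. = FALSE)
  err <- predicted - truth
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant truth vector: r_squared undefined", call. = FALSE)
    NA_real_
  } else 1 - sum(err^2) / ss_tot
  list(r_squared = r2, mae = mean(abs(err)), mse = mean(err^2))
}

#' Agreement metrics between predicted and ground-truth NSAs
#'
#' Bundles Spearman's rank correlation (with its large-sample p-value) and
#' the regression metrics of [regression_metrics()], all computed on the
#' same index set.
#'
#' @param predicted,truth equal-length numeric vectors, length >= 3.
#' @return An object of class `agreement_metrics`: list with `spearman_rs`,
#'   `p_value`, `r_squared`, `mae`, `mse`, `n`.
#' @export
agreement_metrics <- function(predicted, truth) {
  sp <- spearman_rs(predicted, truth)
  rm <- regression_metrics(predicted, truth)
  structure(list(spearman_rs = sp$rs, p_value = sp$p_value,
                 r_squared = rm$r_squared, mae = rm$mae, mse = rm$mse,
                 n = length(truth)), class = "agreement_metrics")
}

#' @export
print.agreement_metrics <- function(x, ...) {
  cat(sprintf("  rs %.3f (P %s)  R2 %.3f  MAE %.3f  MSE %.3f  (n = %d)\n",
              x$spearman_rs,
              format.pval(x$p_value, digits = 2), x$r_squared, x$mae,
              x$mse, x$n))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom. When every value in every group is identical
#' the statistic is 0 by convention (p-value 1).
#'
#' @param groups list of (at least two) non-empty numeric vectors.
#' @return List with `H` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("groups must be non-empty", call. = FALSE)
  values <- unlist(groups)
  if (length(unique(values)) == 1L) return(list(H = 0, p_value = 1))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

#' Shuffled-repetition reliability protocol
#'
#' Repeats the whole fusion experiment `n_repetitions` times; repetition
#' `r` reshuffles the patient order with seed `base_seed + r`, re-splits,
#' re-trains the network, and computes agreement metrics on the held-out
#' fold both for the fused predictions and for the raw computer-vision AP
#' NSAs (the pre-fusion baseline). Summary means and standard deviations
#' are recomputable from the stored per-repetition list.
#'
#' @param records NSA record data frame, see [train_fusion()].
#' @param config a [fusion_config()]; its seed is overridden per
#'   repetition.
#' @param n_repetitions number of repetitions (the full protocol uses
#'   1000; the package default keeps routine runs fast).
#' @param base_seed integer base seed.
#' @return An object of class `reliability_summary`: list with
#'   `n_repetitions`, `per_repetition` (data frame of per-repetition
#'   metrics for the fused model and the CV-only baseline), and `summary`
#'   (mean and sd of every metric for both models).
#' @export
run_reliability <- function(records, config = fusion_config(),
                            n_repetitions = 50, base_seed = 1L) {
  if (n_repetitions < 1) stop("n_repetitions must be >= 1", call. = FALSE)
  rows <- vector("list", 2L * n_repetitions)
  for (r in seq_len(n_repetitions)) {
    seed_r <- as.integer(base_seed + r)
    cfg <- config
    cfg$seed <- seed_r
    res <- tryCatch({
      fit <- train_fusion(records, cfg)
      test <- fit$records[fit$split$test, , drop = FALSE]
      fused <- predict(fit)
      list(fused = agreement_metrics(fused, test$nsa_ap_clinician),
           cv = agreement_metrics(test$nsa_ap_cv, test$nsa_ap_clinician))
    }, error = function(e)
      stop(sprintf("repetition %d (seed %d) failed: %s", r, seed_r,
                   conditionMessage(e)), call. = FALSE))
    as_row <- function(m, lab)
      data.frame(repetition = r, model = lab, seed = seed_r,
                 spearman_rs = m$spearman_rs, p_value = m$p_value,
                 r_squared = m$r_squared, mae = m$mae, mse = m$mse,
                 n = m$n, stringsAsFactors = FALSE)
    rows[[2L * r - 1L]] <- as_row(res$fused, "fused")
    rows[[2L * r]] <- as_row(res$cv, "cv_only")
  }
  per_rep <- do.call(rbind, rows)
  metric_cols <- c("spearman_rs", "r_squared", "mae", "mse")
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$model), function(d)
    data.frame(model = d$model[1],
               metric = metric_cols,
               mean = vapply(metric_cols, function(m) mean(d[[m]]),
                             numeric(1)),
               sd = vapply(metric_cols, function(m) stats::sd(d[[m]]),
                           numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(n_repetitions = n_repetitions, per_repetition = per_rep,
                 summary = summ, base_seed = base_seed),
            class = "reliability_summary")
}

#' @export
print.reliability_summary <- function(x, ...) {
  cat(sprintf("reliability_summary: %d repetition(s), base seed %d\n",
              x$n_repetitions, x$base_seed))
  print(x$summary, digits = 4)
  invisible(x)
}
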