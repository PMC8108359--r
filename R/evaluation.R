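## Simulation-study metrics: raw bias, coverage rate, confidence-interval
## width and root mean squared error per method/scenario, and TPR-FDR curves
## at fixed adjusted-p thresholds.

#' Replicate-level estimation metrics
#'
#' Summarises replicated estimates of a known true coefficient: raw bias
#' RB = mean(estimate) - true, coverage rate CR = fraction of confidence
#' intervals containing the truth, mean CI width, and root mean squared error
#' RMSE = sqrt(mean((estimate - true)^2)). On the squared scale,
#' MSE = variance + bias^2. Replicates with any NA entry (failed fits) are
#' excluded from the metric denominators and counted in `n_failed`.
#'
#' @param estimates,ci_lo,ci_hi Aligned numeric vectors of per-replicate
#'   estimates and 95% confidence bounds (NA marks a failed replicate).
#' @param true_value The generating coefficient value.
#' @return One-row data.frame: `rb`, `cr`, `ci_width`, `rmse`, `n_reps`,
#'   `n_failed`.
#' @export
compute_metrics <- function(estimates, ci_lo, ci_hi, true_value) {
  if (length(estimates) == 0L) stop("no replicates provided")
  stopifnot(length(ci_lo) == length(estimates),
            length(ci_hi) == length(estimates),
            length(true_value) == 1L)
  ok <- !(is.na(estimates) | is.na(ci_lo) | is.na(ci_hi))
  if (!any(ok)) stop("all replicates failed")
  e <- estimates[ok]; lo <- ci_lo[ok]; hi <- ci_hi[ok]
  data.frame(rb = mean(e) - true_value,
             cr = mean(lo <= true_value & true_value <= hi),
             ci_width = mean(hi - lo),
             rmse = sqrt(mean((e - true_value)^2)),
             n_reps = sum(ok), n_failed = sum(!ok))
}

#' TPR-FDR operating points at fixed significance thresholds
#'
#' At each adjusted-p threshold: discoveries are clusters with adjusted p at
#' or below the threshold; TPR = true discoveries / number of truly
#' associated clusters; FDR = false discoveries / max(1, discoveries), so
#' zero discoveries give FDR = 0. The `controlled` flag marks thresholds
#' where the achieved FDR is at or below the nominal level (the filled-dot
#' convention of TPR-FDR benchmark plots).
#'
#' @param adjusted_p Adjusted p-values, one per cluster (NA allowed for
#'   untested clusters; they never count as discoveries).
#' @param truth Logical vector: is the cluster truly associated?
#' @param thresholds Significance thresholds (default 0.01, 0.05, 0.1).
#' @return data.frame per threshold: `threshold`, `tpr`, `fdr`,
#'   `n_discoveries`, `controlled`. TPR is NA when no cluster is truly
#'   associated.
#' @export
tpr_fdr <- function(adjusted_p, truth, thresholds = c(0.01, 0.05, 0.1)) {
  stopifnot(length(adjusted_p) == length(truth))
  truth <- as.logical(truth)
  n_true <- sum(truth)
  rows <- lapply(thresholds, function(th) {
    disc <- !is.na(adjusted_p) & adjusted_p <= th
    tp <- sum(disc & truth)
    fp <- sum(disc & !truth)
    fdr <- fp / max(1L, sum(disc))
    data.frame(threshold = th,
               tpr = if (n_true > 0) tp / n_true else NA_real_,
               fdr = fdr, n_discoveries = sum(disc),
               controlled = fdr <= th)
  })
  do.call(rbind, rows)
}
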