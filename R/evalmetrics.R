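# Evaluation: MAPE, Pearson r, Lin's concordance correlation, RMSE and mean
# bias error; per-fold summaries and final-fold selection.

#' Compute the five evaluation metrics
#'
#' MAPE = (100/n) sum |o - p| / |o| (observations with |o| below `mape_min`
#' are excluded and counted); r is the Pearson product-moment correlation;
#' CCC = 2 r s_o s_p / (s_o^2 + s_p^2 + (m_o - m_p)^2) with population
#' variances (Lin's original definition); RMSE = sqrt(mean (p - o)^2);
#' MBE = mean(p - o), positive meaning overestimation. Zero-variance series
#' leave r and CCC flagged undefined (`NA`) rather than silently zeroed.
#'
#' @param observed,predicted equal-length numeric vectors (n >= 2).
#' @param unit unit tag carried into the report (e.g. `"ST"`, `"dB SPL"`).
#'   Both series must be in this unit; the report's RMSE/MBE inherit it.
#' @param dataset_tag one of `"train"`, `"validation"`, `"test"`.
#' @param mape_min exclusion threshold on |observed| for MAPE (default 1e-6).
#' @return an object of class `eval_report` with fields `mape`, `pearson_r`,
#'   `ccc`, `rmse`, `mbe`, `n_frames`, `n_mape_excluded`, `unit`,
#'   `dataset_tag`.
#' @export
compute_metrics <- function(observed, predicted, unit = "a.u.",
                            dataset_tag = "test", mape_min = 1e-6) {
  if (length(observed) != length(predicted))
    stopf("compute_metrics: length mismatch (%d vs %d)", length(observed),
          length(predicted))
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]; p <- predicted[ok]
  n <- length(o)
  if (n < 2L) stopf("compute_metrics: need at least 2 paired values")
  use <- abs(o) >= mape_min
  mape <- if (any(use)) 100 * mean(abs(o[use] - p[use]) / abs(o[use]))
          else NA_real_
  err <- p - o
  rmse <- sqrt(mean(err^2))
  mbe <- mean(err)
  vo <- mean(o^2) - mean(o)^2        # population variances
  vp <- mean(p^2) - mean(p)^2
  if (vo > 0 && vp > 0) {
    r <- cor(o, p)
    ccc <- 2 * r * sqrt(vo) * sqrt(vp) / (vo + vp + (mean(o) - mean(p))^2)
  } else {
    r <- NA_real_; ccc <- NA_real_
  }
  structure(list(mape = mape, pearson_r = r, ccc = ccc, rmse = rmse,
                 mbe = mbe, n_frames = n, n_mape_excluded = sum(!use),
                 unit = unit, dataset_tag = dataset_tag),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report %s, n=%d> MAPE %.2f%%  r %.3f  CCC %.3f  RMSE %.3f %s  MBE %+.3f %s\n",
    x$dataset_tag, x$n_frames, x$mape, x$pearson_r, x$ccc, x$rmse, x$unit,
    x$mbe, x$unit))
  invisible(x)
}

#' Select the final fold by validation CCC
#'
#' Argmax of validation CCC; ties broken by lower validation RMSE, then by
#' the lowest fold index.
#'
#' @param reports list of `eval_report`s, one per fold (validation data).
#' @return the selected fold index.
#' @export
select_final_fold <- function(reports) {
  stopifnot(length(reports) >= 1L)
  ccc <- vapply(reports, `[[`, 0, "ccc")
  rmse <- vapply(reports, `[[`, 0, "rmse")
  if (all(is.na(ccc))) stopf("select_final_fold: all CCC undefined")
  ccc[is.na(ccc)] <- -Inf
  best <- which(ccc == max(ccc))
  if (length(best) > 1L) best <- best[rmse[best] == min(rmse[best])]
  best[1]
}

#' Mean and SD of each metric across folds
#'
#' @param reports list of `eval_report`s (>= 2).
#' @return data frame with one row per metric and columns `mean`, `sd`
#'   (sample SD).
#' @export
summarize_folds <- function(reports) {
  stopifnot(length(reports) >= 2L)
  metrics <- c("mape", "pearson_r", "ccc", "rmse", "mbe")
  vals <- vapply(reports, function(r) unlist(r[metrics]),
                 numeric(length(metrics)))
  data.frame(metric = metrics,
             mean = rowMeans(vals),
             sd = apply(vals, 1, sd),
             row.names = NULL)
}

#' Write an eval report as key-value text
#' @param report an `eval_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
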