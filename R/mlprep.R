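# Dataset preparation: task-stratified 80-20 holdout with 5-fold assignment
# of the remainder (a 60-20-20 train-validation-test split per fold),
# Gaussian-noise augmentation, and PCA at a 90% explained-variance target.

#' Task-stratified split with k-fold assignment
#'
#' Holds out `test_frac` of the frames within each task stratum, then
#' assigns the remaining frames to `k` folds, also per stratum, so each
#' (train, validation) pair preserves the task proportions. Strata with
#' fewer than `k` frames go wholly to training (with a warning).
#'
#' @param labels per-frame task labels (character or factor).
#' @param seed integer seed; the split is deterministic under it.
#' @param test_frac test fraction (default 0.2).
#' @param k number of folds (default 5).
#' @param groups optional per-frame recording identifiers; when given the
#'   split is recording-atomic: whole recordings are assigned to one
#'   partition (test or a single fold), still stratified by task.
#' @return an object of class `dataset_split`: integer index vectors `test`
#'   and `trainval`, the `fold` assignment (1..k, aligned with `trainval`),
#'   `labels`, `k`.
#' @export
stratified_split <- function(labels, seed, test_frac = 0.2, k = 5L,
                             groups = NULL) {
  stopifnot(length(labels) > 0, !anyNA(labels))
  labels <- as.character(labels)
  n <- length(labels)
  if (!is.null(groups)) {
    stopifnot(length(groups) == n)
    groups <- as.character(groups)
  }
  test <- integer(0); trainval <- integer(0); fold <- integer(0)
  with_seed(derive_seed(seed, "split"), {
    for (lab in sort(unique(labels))) {
      idx <- which(labels == lab)
      # sampling units: frames, or whole recordings when groups are given
      units <- if (is.null(groups)) as.list(idx)
               else unname(split(idx, groups[idx]))
      if (length(units) < k) {
        warning(sprintf("stratum '%s' has %d < %d units; assigned to training",
                        lab, length(units), k), call. = FALSE)
        trainval <- c(trainval, idx)
        fold <- c(fold, rep(0L, length(idx)))   # 0: train-only in every fold
        next
      }
      units <- units[sample(length(units))]
      n_test <- round(test_frac * length(units))
      test <- c(test, unlist(units[seq_len(n_test)]))
      rest <- if (n_test > 0) units[-seq_len(n_test)] else units
      f <- rep(seq_len(k), length.out = length(rest))
      trainval <- c(trainval, unlist(rest))
      fold <- c(fold, rep(f, lengths(rest)))
    }
  })
  o <- order(trainval)
  structure(list(test = sort(test), trainval = trainval[o], fold = fold[o],
                 labels = labels, k = as.integer(k)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d frames: %d test, %d train+val in %d folds\n",
              length(x$labels), length(x$test), length(x$trainval), x$k))
  invisible(x)
}

#' Per-fold (train, validation) index pairs
#'
#' Each fold serves once as validation; frames with fold assignment 0
#' (undersized strata) stay in training everywhere. PCA and augmentation
#' must be re-fit within each pair's training portion.
#'
#' @param split a [stratified_split()].
#' @return list of `k` lists with elements `train` and `validation`
#'   (frame indices).
#' @export
make_folds <- function(split) {
  stopifnot(inherits(split, "dataset_split"))
  lapply(seq_len(split$k), function(f)
    list(train = split$trainval[split$fold != f],
         validation = split$trainval[split$fold == f]))
}

#' Gaussian-noise augmentation of a training set
#'
#' Appends one noisy copy per row: `row + N(0, (scale * sd_feature)^2)`
#' per feature, targets copied unchanged. Training data only.
#'
#' @param x numeric feature matrix (rows = frames).
#' @param y numeric target vector aligned with `x`.
#' @param scale noise SD as a fraction of each feature's SD (default 0.1).
#' @param seed integer seed.
#' @return list with augmented `x` (2n rows), `y`, and logical `augmented`
#'   marking the noisy copies.
#' @export
augment_gaussian <- function(x, y, scale = 0.1, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y), nrow(x) > 0)
  if (scale < 0) stopf("augment_gaussian: scale must be >= 0")
  sds <- apply(x, 2, sd)
  noise <- with_seed(derive_seed(seed, "augment"), {
    matrix(rnorm(length(x)), nrow(x), ncol(x)) %*% diag(scale * sds,
                                                        ncol(x))
  })
  list(x = rbind(x, x + noise), y = c(y, y),
       augmented = rep(c(FALSE, TRUE), each = nrow(x)))
}

#' Fit PCA retaining a target explained variance
#'
#' Features are z-scored (constant columns are centred and excluded from
#' the rotation, i.e. zero loading), the covariance eigendecomposition is
#' taken on the training data, and the smallest component count whose
#' cumulative explained-variance ratio reaches `variance_target` is
#' retained.
#'
#' @param x training feature matrix.
#' @param variance_target cumulative explained-variance bound (default 0.90).
#' @return an object of class `pca_model`: `center`, `scale`, `rotation`
#'   (features x retained), `n_components`, `explained_ratio` (all
#'   components), `feature_names`.
#' @export
fit_pca <- function(x, variance_target = 0.90) {
  stopifnot(is.matrix(x), nrow(x) > 1)
  ctr <- colMeans(x)
  sds <- apply(x, 2, sd)
  keep <- sds > 1e-12
  scl <- ifelse(keep, sds, 1)
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  p <- prcomp(z[, keep, drop = FALSE], center = FALSE, scale. = FALSE)
  ratio <- p$sdev^2 / sum(p$sdev^2)
  ncomp <- which(cumsum(ratio) >= variance_target - 1e-12)[1]
  rot <- matrix(0, ncol(x), ncomp,
                dimnames = list(colnames(x), paste0("PC", seq_len(ncomp))))
  rot[keep, ] <- p$rotation[, seq_len(ncomp), drop = FALSE]
  structure(list(center = ctr, scale = scl, rotation = rot,
                 n_components = ncomp, explained_ratio = ratio,
                 feature_names = colnames(x)),
            class = "pca_model")
}

#' Project features with a fitted PCA model
#' @param model a [fit_pca()] model.
#' @param x feature matrix with the training feature layout.
#' @return scores matrix (rows x `n_components`).
#' @export
apply_pca <- function(model, x) {
  stopifnot(inherits(model, "pca_model"), ncol(x) == length(model$center))
  sweep(sweep(x, 2, model$center), 2, model$scale, "/") %*% model$rotation
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components (%.1f%% variance) of %d features\n",
              x$n_components,
              100 * sum(x$explained_ratio[seq_len(x$n_components)]),
              length(x$center)))
  invisible(x)
}
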