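# Splitting, augmentation, PCA, folds; no-leakage recomputation.

test_that("stratified split arithmetic and proportions", {
  labels <- rep(c("tone", "phrase", "vcv", "passage"), each = 250)
  sp <- stratified_split(labels, seed = 3)
  expect_length(sp$test, 200L)
  expect_length(sp$trainval, 800L)
  expect_setequal(c(sp$test, sp$trainval), seq_along(labels))
  expect_equal(as.vector(table(sp$fold)), rep(160L, 5))
  # per-task proportions preserved within 2% in every partition
  global <- prop.table(table(labels))
  for (part in list(sp$test, sp$trainval)) {
    pp <- prop.table(table(labels[part]))
    expect_lt(max(abs(pp - global[names(pp)])), 0.02)
  }
  for (f in 1:5) {
    va <- sp$trainval[sp$fold == f]
    pp <- prop.table(table(labels[va]))
    expect_lt(max(abs(pp - global[names(pp)])), 0.02)
  }
})

test_that("split is deterministic under seed and warns on tiny strata", {
  labels <- sample(c("a", "b"), 300, replace = TRUE)
  s1 <- stratified_split(labels, seed = 9)
  s2 <- stratified_split(labels, seed = 9)
  expect_identical(s1, s2)
  s3 <- stratified_split(labels, seed = 10)
  expect_false(identical(s1$test, s3$test))
  labs <- c(rep("big", 100), rep("rare", 3))
  expect_warning(sp <- stratified_split(labs, seed = 1), "rare")
  expect_true(all(which(labs == "rare") %in% sp$trainval))
  expect_true(all(sp$fold[sp$trainval %in% which(labs == "rare")] == 0L))
})

test_that("make_folds pairs are disjoint and cover the non-test portion", {
  sp <- stratified_split(rep(c("x", "y"), 150), seed = 2)
  folds <- make_folds(sp)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0L)
    expect_setequal(c(f$train, f$validation), sp$trainval)
  }
  vals <- lapply(folds, `[[`, "validation")
  expect_setequal(unlist(vals), sp$trainval)
  expect_equal(sum(lengths(vals)), length(sp$trainval))
})

test_that("augmentation doubles rows and matches the noise model", {
  with_seed_local(1, {
    x <- matrix(rnorm(10000 * 5, sd = rep(c(1, 5, 0.2, 10, 2), each = 10000)),
                10000, 5)
    y <- rnorm(10000)
  })
  a0 <- augment_gaussian(x, y, scale = 0, seed = 4)
  expect_equal(a0$x[10001:20000, ], x, ignore_attr = TRUE)
  expect_equal(a0$y, c(y, y))
  a <- augment_gaussian(x, y, scale = 0.1, seed = 4)
  expect_equal(nrow(a$x), 2L * nrow(x))
  diff <- a$x[10001:20000, ] - x
  sds <- apply(x, 2, sd)
  expect_true(all(abs(apply(diff, 2, sd) / (0.1 * sds) - 1) < 0.05))
  expect_error(augment_gaussian(x, y, scale = -1), ">= 0")
  expect_identical(augment_gaussian(x, y, seed = 4)$x, a$x)
})

test_that("PCA recovers rank and meets the variance bound minimally", {
  with_seed_local(8, {
    basis <- qr.Q(qr(matrix(rnorm(20 * 2), 20, 2)))
    scores <- matrix(rnorm(500 * 2, sd = c(3, 2)), 500, 2)
    x <- scores %*% t(basis) + matrix(rnorm(500 * 20, sd = 1e-4), 500, 20)
  })
  m <- fit_pca(x, 0.90)
  expect_equal(m$n_components, 2L)
  # ratios nonincreasing, sum <= 1
  expect_true(all(diff(m$explained_ratio) <= 1e-12))
  expect_lte(sum(m$explained_ratio), 1 + 1e-9)
  # minimality: one fewer component falls below the bound
  cums <- cumsum(m$explained_ratio)
  expect_gte(cums[m$n_components], 0.90)
  if (m$n_components > 1L) expect_lt(cums[m$n_components - 1L], 0.90)
  # projected training data has diagonal covariance
  sc <- apply_pca(m, x)
  cv <- cov(sc)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
})

test_that("constant feature columns get zero loading", {
  with_seed_local(2, x <- cbind(rnorm(100), 5, rnorm(100)))
  colnames(x) <- c("a", "const", "b")
  m <- fit_pca(x, 0.9)
  expect_true(all(m$rotation["const", ] == 0))
  expect_true(all(is.finite(apply_pca(m, x))))
})

test_that("fold-wise statistics depend only on the training portion", {
  labels <- rep(c("t1", "t2"), each = 100)
  with_seed_local(3, {
    x <- matrix(rnorm(200 * 6), 200, 6)
    y <- rnorm(200)
  })
  sp <- stratified_split(labels, seed = 5)
  folds <- make_folds(sp)
  f <- folds[[2]]
  aug <- augment_gaussian(x[f$train, ], y[f$train], seed = 11)
  pca <- fit_pca(aug$x, 0.9)
  # recompute from the indices alone: identical statistics
  aug2 <- augment_gaussian(x[f$train, ], y[f$train], seed = 11)
  pca2 <- fit_pca(aug2$x, 0.9)
  expect_identical(pca$center, pca2$center)
  expect_identical(pca$rotation, pca2$rotation)
  # and they differ from statistics that would include validation rows
  pca_leak <- fit_pca(rbind(aug$x, x[f$validation, ]), 0.9)
  expect_false(isTRUE(all.equal(pca$center, pca_leak$center)))
})

test_that("recording-atomic mode keeps whole recordings together", {
  labels <- rep(c("tone", "phrase"), each = 200)
  groups <- paste0("rec", rep(1:20, each = 20))
  sp <- stratified_split(labels, seed = 12, groups = groups)
  part_of <- function(i) {
    if (i %in% sp$test) "test" else paste0("fold", sp$fold[sp$trainval == i])
  }
  for (g in unique(groups)) {
    idx <- which(groups == g)
    expect_length(unique(vapply(idx, part_of, "")), 1L)
  }
  expect_setequal(c(sp$test, sp$trainval), seq_along(labels))
  expect_identical(sp, stratified_split(labels, seed = 12, groups = groups))
})
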