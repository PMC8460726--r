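test_that("hyperparameter grids match the prescribed search spaces", {
  for (alg in c("xgboost", "gbrt")) {
    g <- enumerateGrid(alg)
    expect_equal(nrow(g), 16L)
    expect_setequal(unique(g$n_estimators), c(50L, 100L))
    expect_setequal(unique(g$max_depth), c(5L, 10L))
    expect_setequal(unique(g$min_samples_leaf), c(1L, 2L))
    expect_setequal(unique(g$learning_rate), c(0.1, 0.2))
  }
  for (alg in c("lasso", "ridge", "elasticnet")) {
    g <- enumerateGrid(alg)
    expect_equal(nrow(g), 16L)
    expect_equal(min(g$penalty), 1e-6)
    expect_equal(max(g$penalty), 1e6)
    # log-even spacing
    expect_equal(diff(log10(g$penalty)), rep(12 / 15, 15))
  }
  g <- enumerateGrid("svm")
  expect_equal(nrow(g), 16L)
  expect_equal(sort(unique(g$C)), 10^seq(-3, 3, length.out = 4))
  expect_equal(sort(unique(g$gamma)), 10^seq(-3, 3, length.out = 4))
  g <- enumerateGrid("random_forest")
  expect_equal(nrow(g), 24L) # full 2x2x2 x 3 max-features enumeration
  expect_setequal(unique(g$max_features), c("all", "sqrt", "log2"))
  expect_error(enumerateGrid("deepnet"), "arg")
})

test_that("grouped split never separates shared spacers or targets", {
  dl <- designLibrary(nBase = 60, variantFraction = 0.3, barcodesPer = 1, seed = 61)
  tab <- as.data.frame(designs(dl$library))
  sp <- groupedSplit(tab, testFraction = 0.2, seed = 7)
  tr <- tab[tab$pair_id %in% sp$train, ]
  te <- tab[tab$pair_id %in% sp$test, ]
  expect_equal(length(intersect(tr$spacer, te$spacer)), 0L)
  expect_equal(length(intersect(tr$wide_target, te$wide_target)), 0L)
  # a PAM-silent variant is always on its parent's side
  parents <- sub("^pegv", "peg", grep("^pegv", tab$pair_id, value = TRUE))
  for (v in grep("^pegv", tab$pair_id, value = TRUE)) {
    p <- sub("^pegv", "peg", v)
    expect_equal(v %in% sp$test, p %in% sp$test)
  }
  # deterministic under a fixed seed
  sp2 <- groupedSplit(tab, testFraction = 0.2, seed = 7)
  expect_identical(sp, sp2)
  sp3 <- groupedSplit(tab, testFraction = 0.2, seed = 8)
  expect_false(identical(sp$test, sp3$test))
})

test_that("a 665-pair design splits to about 568 training pairs", {
  dl <- designLibrary(seed = 71) # defaults: 507 + 158 = 665 pegRNAs
  tab <- as.data.frame(designs(dl$library))
  tab <- tab[!duplicated(sub("_bc[0-9]+$", "", tab$pair_id)), ]
  expect_equal(nrow(tab), 665L)
  sp <- groupedSplit(tab, testFraction = 97 / 665, seed = 1)
  # exact up to the granularity of one group (parent + variant = 2)
  expect_lte(abs(length(sp$train) - 568L), 2L)
})

test_that("cross-validation scores an oracle at 1 and a null near 0", {
  set.seed(91)
  n <- 40
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- exp(x[, 1]) # monotone in f1, positive
  groups <- seq_len(n)
  # lasso with almost no penalty acts as the oracle here
  cv <- crossValidate(x, y, groups, "lasso", k = 5, seed = 2)
  expect_gt(cv$cvRho, 0.95)
  # permutation null: |rho| small at n = 500
  set.seed(92)
  n <- 500
  xp <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  yp <- exp(rnorm(n)) # labels independent of features
  cvp <- crossValidate(xp, yp, seq_len(n), "ridge",
    grid = data.frame(penalty = 1), k = 5, seed = 3
  )
  expect_lt(abs(cvp$scores[1]), 0.1)
})

test_that("fold assignment is group-aware and seed-deterministic", {
  groups <- rep(1:20, each = 3)
  f1 <- groupKFold(groups, k = 5, seed = 4)
  f2 <- groupKFold(groups, k = 5, seed = 4)
  expect_identical(f1, f2)
  # every group lies in exactly one fold
  expect_true(all(tapply(f1, groups, function(v) length(unique(v))) == 1))
  expect_error(groupKFold(rep(1:3, 2), k = 5), "at least k")
})

test_that("test evaluation is tie-aware Spearman correlation", {
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(10, 20, 30, 40)), 1)
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(40, 30, 20, 10)), -1)
  # hand-computed tied-rank correlation: ranks x = (1.5, 1.5, 3, 4),
  # y = (1, 2.5, 2.5, 4); Pearson on those ranks:
  x <- c(5, 5, 7, 9)
  y <- c(1, 3, 3, 8)
  rx <- c(1.5, 1.5, 3, 4)
  ry <- c(1, 2.5, 2.5, 4)
  expect_equal(spearmanRho(x, y), cor(rx, ry))
  expect_warning(r0 <- spearmanRho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_equal(r0, 0)
  expect_error(spearmanRho(1:2, 1:2), "at least 3")
})

test_that("each learner fits and predicts on the fold-change scale", {
  set.seed(101)
  n <- 60
  p <- 8
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- exp(0.8 * x[, 1] + rnorm(n, 0, 0.1))
  for (alg in c(
    "xgboost", "gbrt", "random_forest", "lasso", "ridge",
    "elasticnet", "svm"
  )) {
    grid <- enumerateGrid(alg)
    m <- fitLearner(alg, grid[1, , drop = FALSE], x, y, seed = 5)
    pred <- predictLearner(m, x)
    expect_equal(length(pred), n)
    expect_true(all(is.finite(pred)))
    expect_gt(suppressWarnings(spearmanRho(pred, y)), 0)
  }
})

test_that("tree SHAP is additive and a stump credits its only feature", {
  set.seed(111)
  n <- 80
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- ifelse(x[, 2] > 0, 3, 1) # single-feature step function
  cfg <- data.frame(
    n_estimators = 50L, max_depth = 1L, min_samples_leaf = 1L,
    learning_rate = 0.2
  )
  m <- fitLearner("xgboost", cfg, x, y, seed = 6)
  sh <- shapAttribution(m, x)
  # additivity: contributions + bias reproduce the prediction exactly
  pred <- predictLearner(m, x)
  recon <- rowSums(sh$contributions) + sh$bias
  expect_lt(max(abs(recon - pred)), 1e-4)
  # the stump's feature carries (essentially) all attribution
  share <- colMeans(abs(sh$contributions))
  expect_equal(sh$ranking$feature[1], "f2")
  expect_gt(share["f2"] / sum(share), 0.99)
  # non-tree models are rejected
  ml <- fitLearner(
    "ridge", data.frame(penalty = 1), x, pmax(y, 0.1),
    seed = 1
  )
  expect_error(shapAttribution(ml, x), "tree")
})

test_that("PBS-Tm binning uses [20,30) style bins with percentile summaries", {
  b <- binByPBSTm(c(19.9, 20.0, 29.99, 30, 45, 55), rep(1, 6))
  expect_equal(b$n, c(1, 2, 1, 1, 1))
  expect_equal(b$bin, c("<20", "[20,30)", "[30,40)", "[40,50)", ">=50"))
  # all records in one bin leaves the others empty with n = 0
  one <- binByPBSTm(rep(25, 10), 1:10)
  expect_equal(one$n, c(0, 10, 0, 0, 0))
  expect_equal(one$median[2], 5.5)
  expect_equal(one$q25[2], quantile(1:10, 0.25, names = FALSE))
  expect_equal(one$p90[2], quantile(1:10, 0.9, names = FALSE))
  expect_true(all(one$n[-2] == 0))
})

test_that("bin medians fall with Tm under the planted negative slope", {
  dl <- designLibrary(nBase = 150, variantFraction = 0, barcodesPer = 1, seed = 121)
  ft <- simulateFoldTable(dl$library, noiseSd = 0.01, seed = 122)
  b <- binByPBSTm(ft$pbs_tm, ft$adjusted_fold)
  med <- b$median[b$n >= 5]
  expect_true(all(diff(med) < 0))
})

test_that("model selection is reproducible and leak-free on a small screen", {
  dl <- designLibrary(nBase = 60, variantFraction = 0.2, barcodesPer = 1, seed = 131)
  lib <- dl$library
  ft <- simulateFoldTable(lib, seed = 132)
  fm <- suppressWarnings(extractFeatures(lib, mfeEngine = "bundled"))
  v <- featureValues(fm)
  rownames(v) <- sub("_bc[0-9]+$", "", rownames(v))
  tab <- as.data.frame(designs(lib))
  tab$pair_id <- sub("_bc[0-9]+$", "", tab$pair_id)
  sp <- groupedSplit(tab, testFraction = 0.2, seed = 9)
  res <- selectModel(v, ft, sp,
    algorithms = c("lasso", "ridge"), k = 5, seed = 10
  )
  per <- as.data.frame(res@perAlgorithm)
  expect_equal(nrow(per), 2L)
  expect_equal(res@winner, per$algorithm[which.max(per$cv_rho)])
  # reproducibility: same data and seed give the identical result
  res2 <- selectModel(v, ft, sp,
    algorithms = c("lasso", "ridge"), k = 5, seed = 10
  )
  expect_equal(
    as.data.frame(res2@perAlgorithm), per
  )
})
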