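.ALGORITHMS <- c(
  "xgboost", "gbrt", "random_forest", "lasso", "ridge", "elasticnet", "svm"
)

#' Grouping of pairs that must not be separated by a split
#'
#' Pairs sharing a pegRNA spacer or a target sequence (a PAM-silent
#' variant shares its parent's target) belong to the same group and always
#' fall on the same side of any split or fold. Groups are the connected
#' components of the shares-spacer-or-target relation (union-find).
#'
#' @param spacer,target Character vectors, one element per pair.
#' @return Integer vector of group ids.
#' @export
pairGroups <- function(spacer, target) {
  n <- length(spacer)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  for (key in list(spacer, target)) {
    first <- match(key, key)
    for (i in which(first != seq_len(n))) unite(first[i], i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Grouped train/test split
#'
#' Randomly samples whole groups (see \code{\link{pairGroups}}) into the
#' test partition until it reaches the requested fraction, so that neither
#' pegRNA spacers nor target sequences are shared between training and
#' test data. Partition sizes are exact up to the granularity of one
#' group.
#'
#' @param table A data.frame with columns \code{pair_id}, \code{spacer},
#'   \code{wide_target} (a \linkS4class{PairLibrary} is also accepted).
#' @param testFraction Fraction of pairs for the test partition.
#' @param seed Integer RNG seed; the split is fully determined by
#'   (data, seed).
#' @return List with \code{train}, \code{test} (pair ids), \code{groups}
#'   (per-pair group id, named by pair id), and \code{seed}.
#' @export
groupedSplit <- function(table, testFraction = 0.15, seed = 1L) {
  if (is(table, "PairLibrary")) table <- as.data.frame(designs(table))
  groups <- pairGroups(table$spacer, table$wide_target)
  n <- nrow(table)
  target_test <- testFraction * n
  sizes <- table(groups)
  if (max(sizes) > max(target_test, n - target_test)) {
    stop("a group exceeds the partition budget")
  }
  rng <- .withSeed(seed, {
    sample(as.integer(names(sizes)))
  })
  cum <- cumsum(sizes[as.character(rng)])
  n_test_groups <- which(cum >= target_test)[1]
  test_groups <- rng[seq_len(n_test_groups)]
  is_test <- groups %in% test_groups
  list(
    train = table$pair_id[!is_test],
    test = table$pair_id[is_test],
    groups = stats::setNames(groups, table$pair_id),
    seed = seed
  )
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Enumerate the hyperparameter grid of a learner
#'
#' \itemize{
#'   \item \code{xgboost}, \code{gbrt}: 16 configurations = \{50, 100\}
#'     estimators x \{5, 10\} maximum depth x \{1, 2\} minimum samples
#'     per leaf x \{0.1, 0.2\} learning rate.
#'   \item \code{random_forest}: the same tree grid without the learning
#'     rate, crossed with 3 max-features rules (all, sqrt, log2): 24
#'     configurations (enumerated in full even though 16 were searched
#'     per learner elsewhere; the discrepancy is recorded in run
#'     manifests).
#'   \item \code{lasso}, \code{ridge}, \code{elasticnet}: 16 penalties
#'     log-evenly spaced in [1e-6, 1e6].
#'   \item \code{svm}: RBF kernel; C and gamma each take 4 points
#'     log-evenly spaced in [1e-3, 1e3]: 16 configurations.
#' }
#'
#' @param algorithm One of \code{"xgboost"}, \code{"gbrt"},
#'   \code{"random_forest"}, \code{"lasso"}, \code{"ridge"},
#'   \code{"elasticnet"}, \code{"svm"}.
#' @return A data.frame, one row per configuration.
#' @export
enumerateGrid <- function(algorithm) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  tree_grid <- expand.grid(
    n_estimators = c(50L, 100L), max_depth = c(5L, 10L),
    min_samples_leaf = c(1L, 2L), learning_rate = c(0.1, 0.2),
    KEEP.OUT.ATTRS = FALSE
  )
  switch(algorithm,
    xgboost = ,
    gbrt = tree_grid,
    random_forest = expand.grid(
      n_estimators = c(50L, 100L), max_depth = c(5L, 10L),
      min_samples_leaf = c(1L, 2L),
      max_features = c("all", "sqrt", "log2"),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    ),
    lasso = ,
    ridge = ,
    elasticnet = data.frame(penalty = 10^seq(-6, 6, length.out = 16)),
    svm = expand.grid(
      C = 10^seq(-3, 3, length.out = 4),
      gamma = 10^seq(-3, 3, length.out = 4),
      KEEP.OUT.ATTRS = FALSE
    )
  )
}

.isLogScaleLearner <- function(algorithm) {
  algorithm %in% c("lasso", "ridge", "elasticnet", "svm")
}

#' Fit one learner configuration
#'
#' Linear and SVM learners are trained on the log-transformed fold change
#' with features standardized on training statistics only; tree ensembles
#' are trained on the raw target. Predictions from
#' \code{\link{predictLearner}} are always on the original fold-change
#' scale.
#'
#' @param algorithm See \code{\link{enumerateGrid}}.
#' @param config One row of the learner's grid.
#' @param x Numeric feature matrix (training rows).
#' @param y Numeric response (adjusted fold change).
#' @param seed Integer seed for the stochastic learners.
#' @return A fitted-learner object (list with class
#'   \code{"pescreenLearner"}).
#' @export
fitLearner <- function(algorithm, config, x, y, seed = 1L) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  logy <- .isLogScaleLearner(algorithm)
  yt <- if (logy) log(y) else y
  center <- scale_ <- NULL
  if (logy) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  }
  fit <- switch(algorithm,
    xgboost = xgboost::xgb.train(
      params = list(
        max_depth = config$max_depth,
        min_child_weight = config$min_samples_leaf,
        learning_rate = config$learning_rate,
        objective = "reg:squarederror", nthread = 1, seed = seed
      ),
      data = xgboost::xgb.DMatrix(x, label = yt, nthread = 1),
      nrounds = config$n_estimators, verbose = 0
    ),
    gbrt = xgboost::xgb.train(
      # classic gradient-boosted regression trees: no L1/L2 shrinkage on
      # leaf weights, exact greedy splits
      params = list(
        max_depth = config$max_depth,
        min_child_weight = config$min_samples_leaf,
        learning_rate = config$learning_rate,
        lambda = 0, alpha = 0,
        objective = "reg:squarederror", nthread = 1, seed = seed
      ),
      data = xgboost::xgb.DMatrix(x, label = yt, nthread = 1),
      nrounds = config$n_estimators, verbose = 0
    ),
    random_forest = {
      p <- ncol(x)
      mtry <- switch(config$max_features,
        all = p, sqrt = max(1L, floor(sqrt(p))),
        log2 = max(1L, floor(log2(p)))
      )
      ranger::ranger(
        x = x, y = yt, num.trees = config$n_estimators,
        max.depth = config$max_depth,
        min.node.size = config$min_samples_leaf,
        mtry = mtry, seed = seed, num.threads = 1, verbose = FALSE
      )
    },
    lasso = glmnet::glmnet(x, yt, alpha = 1, lambda = config$penalty),
    ridge = glmnet::glmnet(x, yt, alpha = 0, lambda = config$penalty),
    elasticnet = glmnet::glmnet(x, yt, alpha = 0.5, lambda = config$penalty),
    svm = e1071::svm(
      x = x, y = yt, type = "eps-regression", kernel = "radial",
      cost = config$C, gamma = config$gamma, scale = FALSE
    )
  )
  structure(
    list(
      algorithm = algorithm, config = config, fit = fit,
      logy = logy, center = center, scale = scale_,
      features = colnames(x)
    ),
    class = "pescreenLearner"
  )
}

#' Predict fold changes from a fitted learner
#'
#' @param model A \code{"pescreenLearner"} from \code{\link{fitLearner}}.
#' @param x Feature matrix.
#' @return Numeric predictions on the fold-change scale.
#' @export
predictLearner <- function(model, x) {
  x <- x[, model$features, drop = FALSE]
  if (model$logy) {
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  }
  p <- switch(model$algorithm,
    xgboost = ,
    gbrt = stats::predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1)),
    random_forest = stats::predict(model$fit, data = x)$predictions,
    lasso = ,
    ridge = ,
    elasticnet = as.numeric(stats::predict(model$fit, newx = x)),
    svm = as.numeric(stats::predict(model$fit, newdata = x))
  )
  if (model$logy) exp(p) else p
}

#' Spearman rank correlation between predictions and observations
#'
#' Average-rank tie handling (the standard Spearman definition).
#'
#' @param predicted,observed Numeric vectors, length >= 3.
#' @return Spearman rho; 0 (with a warning) when either vector is
#'   constant.
#' @export
spearmanRho <- function(predicted, observed) {
  if (length(predicted) < 3) stop("need at least 3 observations")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("constant predictions or labels; recording rho = 0")
    return(0)
  }
  stats::cor(predicted, observed, method = "spearman")
}

#' Group-aware k-fold assignment
#'
#' Groups are shuffled with the seed and dealt round-robin to folds, so no
#' spacer or target spans two folds.
#'
#' @param groups Integer vector of group ids (one per row).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per row.
#' @export
groupKFold <- function(groups, k = 5L, seed = 1L) {
  ug <- unique(groups)
  if (length(ug) < k) stop("need at least k groups for k folds")
  shuffled <- .withSeed(seed, sample(ug))
  fold_of_group <- stats::setNames(
    rep(seq_len(k), length.out = length(shuffled)), shuffled
  )
  unname(fold_of_group[as.character(groups)])
}

#' Cross-validate a hyperparameter grid
#'
#' Fivefold (by default) group-aware cross-validation; each
#' configuration's score is the mean over folds of the Spearman
#' correlation between predicted and observed fold change. Ties in the CV
#' score are broken toward the smallest grid index.
#'
#' @param x Feature matrix (training rows).
#' @param y Adjusted fold change (training rows).
#' @param groups Group id per row (see \code{\link{pairGroups}}).
#' @param algorithm Learner name.
#' @param grid Optional grid; defaults to
#'   \code{enumerateGrid(algorithm)}.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling folds and stochastic learners.
#' @return List with \code{bestIndex}, \code{bestConfig}, \code{cvRho}
#'   (best mean CV Spearman), and \code{scores} (per-configuration).
#' @export
crossValidate <- function(x, y, groups, algorithm, grid = NULL,
                          k = 5L, seed = 1L) {
  if (is.null(grid)) grid <- enumerateGrid(algorithm)
  folds <- groupKFold(groups, k = k, seed = seed)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    rhos <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- fitLearner(
        algorithm, grid[g, , drop = FALSE],
        x[tr, , drop = FALSE], y[tr],
        seed = seed
      )
      pred <- predictLearner(model, x[!tr, , drop = FALSE])
      rhos[f] <- suppressWarnings(spearmanRho(pred, y[!tr]))
    }
    scores[g] <- mean(rhos)
  }
  best <- which.max(scores) # first maximum: smallest grid index wins ties
  list(
    bestIndex = best,
    bestConfig = grid[best, , drop = FALSE],
    cvRho = scores[best],
    scores = scores
  )
}

#' Evaluate a fitted model on held-out data
#'
#' @param model A \code{"pescreenLearner"}.
#' @param x,y Held-out features and observed fold changes.
#' @return Spearman rho.
#' @export
evaluateTest <- function(model, x, y) {
  spearmanRho(predictLearner(model, x), y)
}

#' Select among the seven learners by grouped cross-validation
#'
#' For each learner, the full hyperparameter grid is cross-validated on
#' the training partition (group-aware folds); the best configuration is
#' refitted on all training rows and evaluated once on the test
#' partition by Spearman correlation. The winner is the learner with the
#' highest cross-validation score; the held-out score never influences
#' selection.
#'
#' @param features A \linkS4class{FeatureMatrix} (or plain matrix with
#'   pair ids as row names).
#' @param foldTable A data.frame with \code{pair_id} and
#'   \code{adjusted_fold}.
#' @param split A split from \code{\link{groupedSplit}}.
#' @param algorithms Learners to compare (default all seven).
#' @param k CV folds, default 5.
#' @param seed Integer seed.
#' @return A \linkS4class{ModelSelectionResult}.
#' @export
selectModel <- function(features, foldTable, split,
                        algorithms = .ALGORITHMS, k = 5L, seed = 1L) {
  x <- if (is(features, "FeatureMatrix")) featureValues(features) else features
  y <- stats::setNames(foldTable$adjusted_fold, foldTable$pair_id)
  xtr <- x[split$train, , drop = FALSE]
  ytr <- y[split$train]
  gtr <- split$groups[split$train]
  xte <- x[split$test, , drop = FALSE]
  yte <- y[split$test]
  rows <- list()
  models <- list()
  for (alg in algorithms) {
    cv <- crossValidate(xtr, ytr, gtr, alg, k = k, seed = seed)
    model <- fitLearner(alg, cv$bestConfig, xtr, ytr, seed = seed)
    test_rho <- evaluateTest(model, xte, yte)
    models[[alg]] <- model
    rows[[alg]] <- data.frame(
      algorithm = alg, best_index = cv$bestIndex,
      cv_rho = cv$cvRho, test_rho = test_rho,
      stringsAsFactors = FALSE
    )
  }
  per <- do.call(rbind, rows)
  winner <- per$algorithm[which.max(per$cv_rho)]
  new("ModelSelectionResult",
    perAlgorithm = S4Vectors::DataFrame(per),
    winner = winner, models = models, split = split
  )
}

setMethod("show", "ModelSelectionResult", function(object) {
  per <- as.data.frame(object@perAlgorithm)
  cat("ModelSelectionResult (winner:", object@winner, ")\n")
  print(per, row.names = FALSE, digits = 3)
})

#' Exact tree-SHAP attribution for a boosted-tree model
#'
#' Per-pair, per-feature additive attributions from the tree-SHAP
#' algorithm: for every pair the attributions sum to the prediction minus
#' the expected value (the bias). The global ranking orders features by
#' mean absolute attribution.
#'
#' @param model A \code{"pescreenLearner"} whose fit is an xgboost
#'   booster (\code{xgboost} or \code{gbrt}); other learners are
#'   rejected (a model-agnostic fallback is out of scope).
#' @param x Feature matrix.
#' @return List with \code{contributions} (pairs x features matrix),
#'   \code{bias} (expected value), and \code{ranking} (data.frame of
#'   features ordered by mean |attribution|).
#' @export
shapAttribution <- function(model, x) {
  if (!inherits(model, "pescreenLearner") ||
    !model$algorithm %in% c("xgboost", "gbrt")) {
    stop(
      "tree SHAP requires a tree-ensemble (xgboost/gbrt) model; ",
      "use a model-agnostic attribution method for other learners"
    )
  }
  x <- x[, model$features, drop = FALSE]
  contrib <- stats::predict(
    model$fit, xgboost::xgb.DMatrix(x, nthread = 1),
    predcontrib = TRUE
  )
  bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
  bias <- contrib[, bias_col]
  contrib <- contrib[, setdiff(colnames(contrib), bias_col), drop = FALSE]
  mean_abs <- colMeans(abs(contrib))
  ranking <- data.frame(
    feature = names(mean_abs)[order(mean_abs, decreasing = TRUE)],
    mean_abs_attribution = sort(mean_abs, decreasing = TRUE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(contributions = contrib, bias = bias, ranking = ranking)
}

#' Bin fold changes by PBS melting temperature
#'
#' Bins: (-Inf, 20), [20, 30), [30, 40), [40, 50), [50, Inf) degrees
#' Celsius. For each bin the count, median, quartiles, and 10th/90th
#' percentiles of the fold change are reported.
#'
#' @param pbsTm Numeric PBS melting temperatures.
#' @param fold Numeric fold changes (same length).
#' @return A data.frame, one row per bin.
#' @export
binByPBSTm <- function(pbsTm, fold) {
  breaks <- c(-Inf, 20, 30, 40, 50, Inf)
  labels <- c("<20", "[20,30)", "[30,40)", "[40,50)", ">=50")
  bin <- cut(pbsTm, breaks = breaks, labels = labels, right = FALSE)
  stats_of <- function(v) {
    if (length(v) == 0) {
      return(c(
        n = 0, median = NA, q25 = NA, q75 = NA, p10 = NA, p90 = NA
      ))
    }
    q <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    c(n = length(v), median = q[3], q25 = q[2], q75 = q[4], p10 = q[1], p90 = q[5])
  }
  out <- t(vapply(
    split(fold, bin), stats_of,
    numeric(6)
  ))
  data.frame(bin = rownames(out), out, row.names = NULL)
}
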