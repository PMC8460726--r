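#' End-to-end planted-rate recovery study
#'
#' Designs a synthetic library, simulates reads with known per-pair
#' outcome proportions, runs the full quantification chain
#' (demultiplexing by the 22-nt key, wide-target classification,
#' tallying, frequencies), and compares the estimated intended-edit
#' percentages with the planted ones. Sequencing error is off so the
#' planted proportions are exactly the read-generation probabilities and
#' the comparison isolates the quantification chain itself.
#'
#' @param nPairs Number of pegRNA/target pairs (default 100).
#' @param depth Reads per pair (default 5000).
#' @param seed Integer seed.
#' @return List with \code{perPair} (planted vs estimated percentages),
#'   \code{mae} (mean absolute error, percentage points), and
#'   \code{assignmentAccuracy}.
#' @export
runPlantedRateStudy <- function(nPairs = 100L, depth = 5000L, seed = 1L) {
  dl <- designLibrary(
    nBase = nPairs, variantFraction = 0, barcodesPer = 1,
    seed = seed
  )
  lib <- dl$library
  planted <- .withSeed(seed + 1L, data.frame(
    pair_id = pairIds(lib),
    intended_rate = stats::runif(nPairs, 0.01, 0.5),
    indel_rate = 0.03,
    sub_rate = 0.02,
    depth = depth,
    stringsAsFactors = FALSE
  ))
  sim <- simulateReads(lib, planted, seed = seed + 2L, errorRate = 0)
  idx <- buildBarcodeIndex(lib)
  asg <- assignReads(sim$reads, idx)
  acc <- mean(asg == sim$truth$pair_id)
  oc <- tallyScreen(sim$reads, lib, asg)
  eff <- endogenousFrequencies(oc)
  per <- merge(planted, eff, by = "pair_id")
  per$planted_pct <- 100 * per$intended_rate
  per$error_pp <- per$intended_pct - per$planted_pct
  list(
    perPair = per[, c("pair_id", "planted_pct", "intended_pct", "error_pp")],
    mae = mean(abs(per$error_pp)),
    assignmentAccuracy = acc
  )
}

#' Fold-increase modeling study on the planted PBS-Tm effect
#'
#' Designs a library of \code{nBase} pegRNAs plus PAM-silent variants
#' (600 in total with the defaults), simulates a fold-change table whose
#' log fold increase decreases with the PBS melting temperature,
#' extracts the 1,820-feature encoding, performs the grouped train/test
#' split, selects among the seven learners by fivefold group-aware
#' cross-validation, computes tree-SHAP attributions from the
#' boosted-tree model, and bins the fold increase by PBS Tm.
#'
#' @param nBase Base pegRNAs (default 480; with the default variant
#'   fraction 0.25 the library has 600 pegRNAs).
#' @param variantFraction Fraction of pegRNAs with a PAM-silent variant.
#' @param testFraction Test partition fraction (default 0.15).
#' @param algorithms Learners to compare (default all seven).
#' @param seed Integer seed.
#' @return List with \code{selection} (a
#'   \linkS4class{ModelSelectionResult}), \code{shap} (tree-SHAP output),
#'   \code{bins} (PBS-Tm bin summaries), \code{foldTable},
#'   \code{split}, and \code{leakage} (shared spacer/target counts
#'   between partitions, both 0 by construction).
#' @export
runFoldIncreaseStudy <- function(nBase = 480L, variantFraction = 0.25,
                                 testFraction = 0.15,
                                 algorithms = .ALGORITHMS, seed = 1L) {
  dl <- designLibrary(
    nBase = nBase, variantFraction = variantFraction,
    barcodesPer = 1, seed = seed
  )
  lib <- dl$library
  ft <- simulateFoldTable(lib, seed = seed + 1L)
  fm <- suppressWarnings(extractFeatures(lib, mfeEngine = "auto"))
  x <- featureValues(fm)
  tab <- as.data.frame(designs(lib))
  split <- groupedSplit(tab, testFraction = testFraction, seed = seed + 2L)
  sel <- selectModel(x, ft, split, algorithms = algorithms, seed = seed + 3L)
  tr <- tab[tab$pair_id %in% split$train, ]
  te <- tab[tab$pair_id %in% split$test, ]
  leakage <- c(
    shared_spacers = length(intersect(tr$spacer, te$spacer)),
    shared_targets = length(intersect(tr$wide_target, te$wide_target))
  )
  tree_alg <- intersect(c("xgboost", "gbrt"), algorithms)[1]
  shap <- if (!is.na(tree_alg)) {
    shapAttribution(sel@models[[tree_alg]], x[split$train, , drop = FALSE])
  }
  bins <- binByPBSTm(ft$pbs_tm, ft$adjusted_fold)
  list(
    selection = sel, shap = shap, bins = bins, foldTable = ft,
    split = split, leakage = leakage, nPegRNAs = dl$nPegRNAs
  )
}
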