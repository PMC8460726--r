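test_that("read classification follows the intended/unintended/indel rules", {
  lib <- makeTinyLibrary()
  for (i in 1:3) {
    pair <- designs(lib)[i, ]
    wt <- pair$wide_target
    ed <- pair$edited_wide_target

    expect_equal(
      as.character(classifyReads(makeRead(ed, pair), pair)), "INTENDED"
    )
    expect_equal(
      as.character(classifyReads(makeRead(wt, pair), pair)), "WILDTYPE"
    )
    # desired edit plus one extra substitution is not intended
    extra <- ed
    substr(extra, 3, 3) <- setdiff(
      c("A", "C", "G", "T"), substr(ed, 3, 3)
    )[1]
    expect_equal(
      as.character(classifyReads(makeRead(extra, pair), pair)),
      "UNINTENDED_EDIT"
    )
    # a 2-nt deletion relative to the wild type is an indel
    del <- paste0(substr(wt, 1, 9), substr(wt, 12, nchar(wt)))
    expect_equal(
      as.character(classifyReads(makeRead(del, pair), pair)), "INDEL"
    )
    # unlocatable wide-target region is discarded
    expect_equal(
      as.character(classifyReads(paste0("AAAA", ed, "TTTT"), pair)),
      "DISCARD"
    )
  }
})

test_that("an intended indel with an extra indel is INDEL, alone is INTENDED", {
  lib <- makeTinyLibrary()
  pair <- designs(lib)[3, ] # deletion edit
  ed <- pair$edited_wide_target
  expect_true(nchar(ed) != nchar(pair$wide_target))
  expect_equal(
    as.character(classifyReads(makeRead(ed, pair), pair)), "INTENDED"
  )
  extra <- paste0(substr(ed, 1, 4), substr(ed, 6, nchar(ed)))
  expect_equal(
    as.character(classifyReads(makeRead(extra, pair), pair)), "INDEL"
  )
})

test_that("tallies are consistent with per-read classification", {
  lib <- makeTinyLibrary()
  pair <- designs(lib)[1, ]
  reads <- c(
    rep(makeRead(pair$edited_wide_target, pair), 30),
    rep(makeRead(pair$wide_target, pair), 70)
  )
  oc <- outcomeCounts(tallyPair(reads, pair))
  expect_equal(oc$n_total, 100L)
  expect_equal(oc$n_intended, 30L)
  expect_equal(oc$n_unintended_edit, 0L)
  expect_equal(oc$n_indel, 0L)
  expect_equal(oc$n_wildtype, 70L)

  zero <- outcomeCounts(tallyPair(character(0), pair))
  expect_true(all(unlist(zero[-1]) == 0))
})

test_that("tallies recover planted rates within 3 binomial SDs", {
  dl <- designLibrary(nBase = 1, variantFraction = 0, barcodesPer = 1, seed = 21)
  n <- 5000L
  sim <- simulateReads(dl$library,
    seed = 22, errorRate = 0,
    defaultTruth = list(
      intended_rate = 0.12, indel_rate = 0.03, sub_rate = 0, depth = n
    )
  )
  oc <- outcomeCounts(tallyScreen(sim$reads, dl$library))
  sd_int <- sqrt(n * 0.12 * 0.88)
  sd_ind <- sqrt(n * 0.03 * 0.97)
  expect_lt(abs(oc$n_intended - n * 0.12), 3 * sd_int)
  expect_lt(abs(oc$n_indel - n * 0.03), 3 * sd_ind)
  expect_equal(oc$n_total, n)
})

test_that("frequency statistics implement count/total x 100", {
  counts <- new("OutcomeCounts", counts = S4Vectors::DataFrame(
    pair_id = c("A", "B", "C"),
    n_total = c(100L, 250L, 3L),
    n_intended = c(5L, 0L, 1L),
    n_unintended_edit = c(2L, 0L, 0L),
    n_indel = c(1L, 0L, 0L),
    n_wildtype = c(92L, 250L, 2L),
    n_discarded = c(0L, 10L, 0L)
  ))
  eff <- endogenousFrequencies(counts)
  expect_equal(eff$intended_pct, c(5, 0, 100 / 3))
  expect_equal(eff$unintended_pct, c(2, 0, 0))
  expect_equal(eff$indel_pct, c(1, 0, 0))
  expect_equal(eff$passes_coverage, c(TRUE, TRUE, FALSE))
  # library efficiency and intended frequency agree on identical counts
  expect_equal(libraryEfficiency(counts), eff$intended_pct)
})

test_that("frequencies on simulated reads match a brute-force recount", {
  dl <- designLibrary(nBase = 4, variantFraction = 0, barcodesPer = 1, seed = 31)
  sim <- simulateReads(dl$library,
    seed = 32, errorRate = 0,
    defaultTruth = list(
      intended_rate = 0.25, indel_rate = 0.1, sub_rate = 0.05, depth = 400L
    )
  )
  oc <- tallyScreen(sim$reads, dl$library)
  eff <- endogenousFrequencies(oc)
  # independent recount straight from the simulator's truth labels
  recount <- table(sim$truth$pair_id, sim$truth$outcome)
  for (i in seq_len(nrow(eff))) {
    id <- eff$pair_id[i]
    expect_equal(
      eff$intended_pct[i],
      100 * recount[id, "INTENDED"] / sum(recount[id, ])
    )
    expect_equal(
      eff$indel_pct[i],
      100 * recount[id, "INDEL"] / sum(recount[id, ])
    )
  }
})

test_that("classification outcomes partition reads and percentages sum <= 100", {
  dl <- designLibrary(nBase = 3, variantFraction = 0, barcodesPer = 1, seed = 41)
  sim <- simulateReads(dl$library,
    seed = 42,
    defaultTruth = list(
      intended_rate = 0.3, indel_rate = 0.2, sub_rate = 0.1, depth = 300L
    )
  )
  oc <- tallyScreen(sim$reads, dl$library)
  d <- outcomeCounts(oc)
  expect_equal(
    d$n_total,
    d$n_intended + d$n_unintended_edit + d$n_indel + d$n_wildtype
  )
  eff <- endogenousFrequencies(oc)
  sums <- eff$intended_pct + eff$unintended_pct + eff$indel_pct
  expect_true(all(sums <= 100 + 1e-9))
})

test_that("substitution window counts equal an independent mean", {
  lib <- makeTinyLibrary()
  pair <- designs(lib)[1, ]
  wt <- pair$wide_target
  set.seed(5)
  # plant substitutions at known window offsets
  reads <- character(0)
  planted <- integer(36)
  names(planted) <- as.character(-10:25)
  for (r in 1:50) {
    offs <- sample(-10:25, sample(0:2, 1))
    region <- wt
    for (o in offs) {
      p <- 22 + o
      ref <- substr(region, p, p)
      substr(region, p, p) <- setdiff(c("A", "C", "G", "T"), ref)[1]
    }
    # avoid accidentally recreating the edited reference
    if (region == pair$edited_wide_target) next
    for (o in offs) planted[as.character(o)] <- planted[as.character(o)] + 1L
    reads <- c(reads, makeRead(region, pair))
  }
  win <- substitutionWindow(reads, pair, excludeIntended = FALSE)
  expect_identical(win, planted)
  expect_equal(
    unintendedSubstitutionRate(win, length(reads)),
    100 * mean(planted) / length(reads)
  )
})

test_that("substitution rate handles constant and empty windows", {
  zero <- setNames(integer(36), as.character(-10:25))
  expect_equal(unintendedSubstitutionRate(zero, 100), 0)
  const <- setNames(rep(7L, 36), as.character(-10:25))
  expect_equal(unintendedSubstitutionRate(const, 200), 100 * 7 / 200)
  expect_error(unintendedSubstitutionRate(integer(0), 10), "empty")
})

test_that("coverage filter keeps 100 reads and drops 99", {
  rec <- data.frame(pair_id = c("A", "B", "C"), n_total = c(99L, 100L, 101L))
  kept <- coverageFilter(rec)
  expect_identical(kept$pair_id, c("B", "C"))
  # independent filter on a mixed synthetic table
  set.seed(8)
  tab <- data.frame(pair_id = paste0("p", 1:200), n_total = rpois(200, 100))
  expect_identical(
    coverageFilter(tab)$pair_id, tab$pair_id[tab$n_total >= 100]
  )
})

test_that("adjusted fold change reproduces the worked ratios and identities", {
  expect_equal(signif(adjustedFoldChange(0.015, 0.15), 2), 2.2)
  expect_equal(signif(adjustedFoldChange(1.5, 15), 2), 9.4)
  for (x in c(0, 0.5, 3, 80)) {
    expect_equal(adjustedFoldChange(x, x), 1)
  }
  expect_error(adjustedFoldChange(-1, 5), "non-negative")
})

test_that("adjusted fold change is monotone and converges to the raw fold", {
  f <- adjustedFoldChange(2, c(1, 2, 5, 10))
  expect_true(all(diff(f) > 0)) # increasing in hyPE2
  g <- adjustedFoldChange(c(1, 2, 5, 10), 2)
  expect_true(all(diff(g) < 0)) # decreasing in PE2
  expect_equal(adjustedFoldChange(40, 80), 80 / 40, tolerance = 0.01)
})

test_that("PE2 stratification uses >= 1% as high and reports rescues", {
  rec <- data.frame(
    pair_id = paste0("p", 1:5),
    pe2_pct = c(1.0, 0.99, 0, 5, 0.5),
    hype2_pct = c(2, 1.5, 0.2, 10, 0.9)
  )
  s <- stratifyByPE2(rec)
  expect_setequal(s$high$pair_id, c("p1", "p4"))
  expect_setequal(s$low$pair_id, c("p2", "p3", "p5"))
  expect_setequal(s$rescued$pair_id, "p2")
  # partition sizes match independent counts on a synthetic table
  set.seed(3)
  tab <- data.frame(
    pair_id = paste0("q", 1:300),
    pe2_pct = exp(runif(300, log(0.01), log(30))),
    hype2_pct = exp(runif(300, log(0.01), log(30)))
  )
  s2 <- stratifyByPE2(tab)
  expect_equal(nrow(s2$high), sum(tab$pe2_pct >= 1))
  expect_equal(nrow(s2$low), sum(tab$pe2_pct < 1))
  expect_equal(
    nrow(s2$rescued), sum(tab$pe2_pct < 1 & tab$hype2_pct >= 1)
  )
})

test_that("intended-rate estimates are unbiased across many simulated pairs", {
  dl <- designLibrary(nBase = 200, variantFraction = 0, barcodesPer = 1, seed = 51)
  rate <- 0.15
  depth <- 300L
  sim <- simulateReads(dl$library,
    seed = 52, errorRate = 0,
    defaultTruth = list(
      intended_rate = rate, indel_rate = 0.05, sub_rate = 0.02,
      depth = depth
    )
  )
  eff <- endogenousFrequencies(tallyScreen(sim$reads, dl$library))
  err <- eff$intended_pct - 100 * rate
  se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 3 * se + 1e-9)
})
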