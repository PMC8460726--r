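#' Classify reads against a pair's wide target references
#'
#' The wide-target region of each read is located by exact match of the
#' two constant 10-nt anchors that border the wide target in the amplicon;
#' a read in which either anchor cannot be found is discarded. The
#' extracted region is then compared with the pair's references:
#' \itemize{
#'   \item \code{INTENDED}: region equals the edited wide target exactly
#'     (the read contains the desired edit and no unintended mutation);
#'   \item \code{WILDTYPE}: region equals the unedited wide target exactly;
#'   \item \code{UNINTENDED_EDIT}: region has the length of one of the two
#'     references but matches neither (substitution-only mismatch);
#'   \item \code{INDEL}: region length differs from both references;
#'   \item \code{DISCARD}: region not locatable.
#' }
#' An intended insertion or deletion that matches the edited wide target
#' exactly is \code{INTENDED}, not \code{INDEL}; an extra indel on top of
#' the intended edit changes the region length and is \code{INDEL}.
#'
#' @param readSeqs Character vector (or \code{DNAStringSet}) of read
#'   sequences assigned to this pair.
#' @param pair A single-row \linkS4class{PairLibrary} (or one row of its
#'   designs).
#' @param anchors Character(2), the left and right 10-nt anchors.
#' @return Factor with levels \code{INTENDED}, \code{UNINTENDED_EDIT},
#'   \code{INDEL}, \code{WILDTYPE}, \code{DISCARD}.
#' @export
classifyReads <- function(readSeqs, pair,
                          anchors = c(.ANCHOR_LEFT, .ANCHOR_RIGHT)) {
  if (is(pair, "PairLibrary")) pair <- designs(pair)[1, ]
  reads <- as.character(readSeqs)
  region <- extractWideRegion(reads, anchors)
  out <- rep("DISCARD", length(reads))
  located <- !is.na(region)
  wt <- pair$wide_target
  ed <- pair$edited_wide_target
  len <- nchar(region)
  out[located & region == ed] <- "INTENDED"
  out[located & region == wt & wt != ed] <- "WILDTYPE"
  remaining <- located & out == "DISCARD"
  same_len <- remaining & (len == nchar(wt) | len == nchar(ed))
  out[remaining & !same_len] <- "INDEL"
  # same length as a reference but not equal to it: substitution-only
  # mismatch unless a gapped alignment against the equal-length
  # reference reports an insertion/deletion (e.g. a stray 1-nt deletion
  # in a pair whose intended edit is a deletion of the same length)
  idx <- which(same_len)
  if (length(idx) > 0) {
    ref <- ifelse(len[idx] == nchar(wt), wt, ed)
    for (r in unique(ref)) {
      sel <- idx[ref == r]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(region[sel]), r,
        type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1
        ),
        gapOpening = 2, gapExtension = 0.5
      )
      has_gap <- Biostrings::nindel(aln)@insertion[, "Length"] > 0 |
        Biostrings::nindel(aln)@deletion[, "Length"] > 0
      out[sel] <- ifelse(has_gap, "INDEL", "UNINTENDED_EDIT")
    }
  }
  factor(out, levels = .OUTCOME_LEVELS)
}

.OUTCOME_LEVELS <- c(
  "INTENDED", "UNINTENDED_EDIT", "INDEL", "WILDTYPE", "DISCARD"
)

# locate the region between the two anchors; NA when not locatable
extractWideRegion <- function(reads, anchors = c(.ANCHOR_LEFT, .ANCHOR_RIGHT)) {
  left <- regexpr(anchors[1], reads, fixed = TRUE)
  out <- rep(NA_character_, length(reads))
  has_left <- left > 0L
  if (!any(has_left)) {
    return(out)
  }
  start <- left[has_left] + nchar(anchors[1])
  tail_part <- substr(reads[has_left], start, nchar(reads[has_left]))
  right <- regexpr(anchors[2], tail_part, fixed = TRUE)
  ok <- right > 0L
  res <- rep(NA_character_, sum(has_left))
  res[ok] <- substr(tail_part[ok], 1L, right[ok] - 1L)
  out[has_left] <- res
  out
}

#' Tally classified reads for one pair
#'
#' @param readSeqs Reads assigned to the pair (character or
#'   \code{DNAStringSet}).
#' @param pair A single-row \linkS4class{PairLibrary}.
#' @param anchors See \code{\link{classifyReads}}.
#' @return A one-row \linkS4class{OutcomeCounts}. Discarded reads are
#'   excluded from \code{n_total}.
#' @export
tallyPair <- function(readSeqs, pair,
                      anchors = c(.ANCHOR_LEFT, .ANCHOR_RIGHT)) {
  if (is(pair, "PairLibrary")) pair <- designs(pair)[1, ]
  cls <- classifyReads(readSeqs, pair, anchors)
  tab <- table(cls)
  new("OutcomeCounts", counts = S4Vectors::DataFrame(
    pair_id = pair$pair_id,
    n_total = as.integer(sum(tab) - tab[["DISCARD"]]),
    n_intended = as.integer(tab[["INTENDED"]]),
    n_unintended_edit = as.integer(tab[["UNINTENDED_EDIT"]]),
    n_indel = as.integer(tab[["INDEL"]]),
    n_wildtype = as.integer(tab[["WILDTYPE"]]),
    n_discarded = as.integer(tab[["DISCARD"]])
  ))
}

#' Tally a whole screen: assign, classify and count per pair
#'
#' @param reads \code{DNAStringSet} of all reads.
#' @param lib A \linkS4class{PairLibrary}.
#' @param assignments Optional precomputed result of
#'   \code{\link{assignReads}}; computed when missing.
#' @param anchors See \code{\link{classifyReads}}.
#' @return An \linkS4class{OutcomeCounts} with one row per pair in
#'   \code{lib} (pairs with no assigned reads have all-zero counts).
#' @export
tallyScreen <- function(reads, lib, assignments = NULL,
                        anchors = c(.ANCHOR_LEFT, .ANCHOR_RIGHT)) {
  if (is.null(assignments)) {
    assignments <- assignReads(reads, buildBarcodeIndex(lib))
  }
  reads <- as.character(reads)
  ids <- pairIds(lib)
  d <- designs(lib)
  rows <- vector("list", length(ids))
  by_pair <- split(seq_along(reads), factor(assignments, levels = ids))
  for (i in seq_along(ids)) {
    rows[[i]] <- outcomeCounts(
      tallyPair(reads[by_pair[[i]]], d[i, ], anchors)
    )
  }
  new("OutcomeCounts", counts = do.call(rbind, rows))
}

#' @rdname OutcomeCounts-accessors
#' @param x An \linkS4class{OutcomeCounts}.
#' @export
setMethod("outcomeCounts", "OutcomeCounts", function(x) x@counts)

setMethod("show", "OutcomeCounts", function(object) {
  d <- object@counts
  cat(
    "OutcomeCounts for", nrow(d), "pairs;",
    sum(d$n_total), "classified reads,", sum(d$n_discarded), "discarded\n"
  )
})

#' Library-mode prime-editing efficiency
#'
#' The percentage of barcode-assigned reads carrying the intended edit:
#' read counts with the intended edit and specified barcode, divided by
#' total read counts with the specified barcode, times 100.
#'
#' @param counts An \linkS4class{OutcomeCounts}.
#' @return Numeric vector of percentages, \code{NA} where \code{n_total}
#'   is zero (the pair is excluded downstream).
#' @export
libraryEfficiency <- function(counts) {
  d <- outcomeCounts(counts)
  ifelse(d$n_total > 0, 100 * d$n_intended / d$n_total, NA_real_)
}

#' Intended / unintended / indel frequencies
#'
#' Each frequency is the corresponding read count divided by the total
#' read count, times 100 (the convention used at endogenous sites; on
#' identical counts the intended frequency equals the library
#' efficiency).
#'
#' @param counts An \linkS4class{OutcomeCounts}.
#' @return A data.frame with \code{pair_id}, \code{intended_pct},
#'   \code{unintended_pct}, \code{indel_pct}, and \code{passes_coverage}
#'   (total read count at least \code{minReads}).
#' @param minReads Coverage threshold used to set \code{passes_coverage}.
#' @export
endogenousFrequencies <- function(counts, minReads = 100L) {
  d <- outcomeCounts(counts)
  pct <- function(n) ifelse(d$n_total > 0, 100 * n / d$n_total, NA_real_)
  data.frame(
    pair_id = d$pair_id,
    intended_pct = pct(d$n_intended),
    unintended_pct = pct(d$n_unintended_edit),
    indel_pct = pct(d$n_indel),
    passes_coverage = d$n_total >= minReads,
    stringsAsFactors = FALSE
  )
}

#' Per-position substitution counts in the nick-site window
#'
#' For reads without an indel (region length equal to the reference), each
#' window position is compared with the reference base; intended
#' substitutions are not counted as unintended when
#' \code{excludeIntended} is \code{TRUE}. Offsets are relative to the nick
#' site between protospacer positions 17/18; offset 0 is the first base 3'
#' of the nick, negative offsets are 5' of it. The default window spans
#' offsets -10 to +25 inclusive.
#'
#' @param readSeqs Reads assigned to the pair.
#' @param pair Single-row \linkS4class{PairLibrary}.
#' @param window Integer(2): first and last offset, inclusive.
#' @param excludeIntended Logical; do not count positions where the read
#'   matches the edited reference while differing from the unedited one.
#' @param anchors See \code{\link{classifyReads}}.
#' @return Named integer vector of substitution read counts, one per
#'   offset.
#' @export
substitutionWindow <- function(readSeqs, pair, window = c(-10L, 25L),
                               excludeIntended = TRUE,
                               anchors = c(.ANCHOR_LEFT, .ANCHOR_RIGHT)) {
  if (is(pair, "PairLibrary")) pair <- designs(pair)[1, ]
  stopifnot(window[1] <= window[2])
  offsets <- seq(window[1], window[2])
  positions <- .NICK_POS + 1L + offsets # 1-based wide-target positions
  wt <- pair$wide_target
  if (any(positions < 1L | positions > nchar(wt))) {
    stop("window extends beyond the wide target")
  }
  # a base is a substitution only if the read carries no indel (indel
  # reads are already counted by the indel frequency)
  cls <- classifyReads(readSeqs, pair, anchors)
  region <- extractWideRegion(as.character(readSeqs), anchors)
  region <- region[!is.na(region) & nchar(region) == nchar(wt) &
    !(cls %in% c("INDEL", "DISCARD"))]
  counts <- integer(length(offsets))
  names(counts) <- as.character(offsets)
  if (length(region) == 0) {
    return(counts)
  }
  ed <- pair$edited_wide_target
  same_len_ed <- nchar(ed) == nchar(wt)
  for (j in seq_along(positions)) {
    p <- positions[j]
    ref <- substr(wt, p, p)
    obs <- substr(region, p, p)
    is_sub <- obs != ref
    if (excludeIntended && same_len_ed) {
      edb <- substr(ed, p, p)
      if (edb != ref) is_sub <- is_sub & obs != edb
    }
    counts[j] <- sum(is_sub)
  }
  counts
}

#' Average substitution rate over the nick-site window
#'
#' The per-position substitution read counts are averaged across the
#' window and the mean is treated as a read count: rate = mean count /
#' total reads x 100.
#'
#' @param windowCounts Named integer vector from
#'   \code{\link{substitutionWindow}}.
#' @param totalReads Total read count (denominator).
#' @return Percentage.
#' @export
unintendedSubstitutionRate <- function(windowCounts, totalReads) {
  if (length(windowCounts) == 0) stop("empty substitution window")
  stopifnot(totalReads > 0)
  100 * mean(windowCounts) / totalReads
}

#' Exclude pairs with insufficient deep-sequencing coverage
#'
#' Pairs with total read counts below \code{minReads} are excluded (99
#' reads are excluded, 100 retained at the default threshold).
#'
#' @param records A data.frame carrying \code{n_total} (or an
#'   \linkS4class{OutcomeCounts}).
#' @param minReads Minimum total read count, default 100.
#' @return The retained subset, same type as the input.
#' @export
coverageFilter <- function(records, minReads = 100L) {
  if (is(records, "OutcomeCounts")) {
    keep <- records@counts$n_total >= minReads
    return(new("OutcomeCounts", counts = records@counts[keep, , drop = FALSE]))
  }
  records[records$n_total >= minReads, , drop = FALSE]
}

#' Pseudocounted fold change between two editor efficiencies
#'
#' Adds 0.1 percentage points to both efficiencies before taking their
#' ratio: (hyPE2 \% + 0.1) / (PE2 \% + 0.1). The pseudocount keeps the
#' ratio defined when the PE2 efficiency is 0\% and attenuates spuriously
#' large fold changes at very low efficiencies.
#'
#' @param pe2Pct PE2 efficiency in percent (>= 0).
#' @param hype2Pct hyPE2 efficiency in percent (>= 0).
#' @param pseudocount Pseudocount in percentage points, default 0.1.
#' @return Numeric fold change (vectorized).
#' @export
#' @examples
#' adjustedFoldChange(0.015, 0.15) # 2.2-fold, not 10-fold
#' adjustedFoldChange(1.5, 15) # 9.4-fold, close to 10-fold
adjustedFoldChange <- function(pe2Pct, hype2Pct, pseudocount = 0.1) {
  if (any(pe2Pct < 0, na.rm = TRUE) || any(hype2Pct < 0, na.rm = TRUE)) {
    stop("efficiencies must be non-negative percentages")
  }
  (hype2Pct + pseudocount) / (pe2Pct + pseudocount)
}

#' Build a fold-change table from PE2 and hyPE2 efficiencies
#'
#' @param pairId Character vector of pair ids.
#' @param pe2Pct,hype2Pct Efficiencies in percent.
#' @param pseudocount See \code{\link{adjustedFoldChange}}.
#' @param pe2Threshold PE2 efficiency (\%) below which the raw fold change
#'   is considered error-prone, default 1.
#' @return A data.frame with \code{pair_id}, \code{pe2_pct},
#'   \code{hype2_pct}, \code{raw_fold} (\code{NA} when PE2 is 0),
#'   \code{adjusted_fold}, and \code{pe2_ge_1pct}.
#' @export
foldChangeTable <- function(pairId, pe2Pct, hype2Pct, pseudocount = 0.1,
                            pe2Threshold = 1.0) {
  data.frame(
    pair_id = pairId,
    pe2_pct = pe2Pct,
    hype2_pct = hype2Pct,
    raw_fold = ifelse(pe2Pct > 0, hype2Pct / pe2Pct, NA_real_),
    adjusted_fold = adjustedFoldChange(pe2Pct, hype2Pct, pseudocount),
    pe2_ge_1pct = pe2Pct >= pe2Threshold,
    stringsAsFactors = FALSE
  )
}

#' Partition pairs by PE2 efficiency
#'
#' Pairs with PE2 efficiency at or above the threshold form the
#' \code{high} stratum used for fold-change statistics; pairs below it
#' form the \code{low} stratum (excluded from fold-change analysis as
#' error-prone). Within \code{low}, the subset whose hyPE2 efficiency
#' reaches the threshold is reported as \code{rescued}.
#'
#' @param records A data.frame with \code{pe2_pct} and \code{hype2_pct}.
#' @param threshold Percent threshold, default 1.
#' @return List with elements \code{high}, \code{low}, \code{rescued}.
#' @export
stratifyByPE2 <- function(records, threshold = 1.0) {
  high <- records[records$pe2_pct >= threshold, , drop = FALSE]
  low <- records[records$pe2_pct < threshold, , drop = FALSE]
  rescued <- low[low$hype2_pct >= threshold, , drop = FALSE]
  list(high = high, low = low, rescued = rescued)
}
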