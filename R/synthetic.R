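.randSeq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(.BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate unique barcodes with a minimum pairwise Hamming distance
#'
#' @param n Number of barcodes.
#' @param len Barcode length (default 18).
#' @param minDist Minimum pairwise Hamming distance (default 3).
#' @param maxTries Rejection-sampling budget per barcode.
#' @return Character vector of \code{n} barcodes.
#' @export
randomBarcodes <- function(n, len = 18L, minDist = 3L, maxTries = 1000L) {
  accepted <- matrix(0L, nrow = n, ncol = len)
  out <- character(n)
  base_int <- utf8ToInt(paste(.BASES, collapse = ""))
  k <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      cand <- sample(base_int, len, replace = TRUE)
      if (k > 0L) {
        mism <- rowSums(accepted[seq_len(k), , drop = FALSE] !=
          matrix(cand, k, len, byrow = TRUE))
        if (min(mism) < minDist) next
      }
      k <- k + 1L
      accepted[k, ] <- cand
      out[i] <- intToUtf8(cand)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not satisfy the barcode distance constraint after ",
        maxTries, " tries at barcode ", i)
    }
  }
  out
}

#' Design a synthetic pegRNA/target pair library
#'
#' Emulates the structure of a barcode-paired screening library: base
#' pegRNAs with deletion-, insertion-, and substitution-inducing edits
#' (default mix 100:100:200-like, i.e. 25/25/50\%), a subset of pegRNAs
#' admitting a PAM-silent variant that adds a synonymous NGG-disrupting
#' change to the parent's edit on the same target, and
#' \code{barcodesPer} barcodes per pegRNA (each barcode is one oligo and
#' one row of the pair table). Barcodes are unique with pairwise Hamming
#' distance >= 3. With the defaults (507 base pegRNAs, a variant
#' fraction of 158/507, 3 barcodes) the library reproduces the reference
#' arithmetic: 507 + 158 = 665 pegRNAs and 665 x 3 = 1,995 oligos.
#'
#' @param nBase Number of base pegRNAs (default 507).
#' @param editMix Proportions of deletion/insertion/substitution edits.
#' @param variantFraction Fraction of base pegRNAs that admit a
#'   PAM-silent variant (default 158/507).
#' @param barcodesPer Barcodes (oligos) per pegRNA, default 3.
#' @param seed Integer seed; the design is seed-deterministic.
#' @return List with \code{library} (a \linkS4class{PairLibrary}),
#'   \code{nPegRNAs}, and \code{nOligos}.
#' @export
designLibrary <- function(nBase = 507L,
                          editMix = c(
                            deletion = 0.25, insertion = 0.25,
                            substitution = 0.5
                          ),
                          variantFraction = 158 / 507,
                          barcodesPer = 3L, seed = 1L) {
  .withSeed(seed, {
    n_variant <- round(variantFraction * nBase)
    editMix <- editMix / sum(editMix)
    types <- sample(
      rep(names(editMix), diff(round(cumsum(c(0, editMix)) * nBase)))
    )
    peg <- vector("list", nBase)
    for (i in seq_len(nBase)) {
      # wide target: 4-nt flank + protospacer + NGG + 20-nt flank
      proto <- .randSeq(1, 20)
      wide <- paste0(
        .randSeq(1, 4), proto, paste0(sample(.BASES, 1), "GG"),
        .randSeq(1, 20)
      )
      type <- types[i]
      if (type == "deletion") {
        offset <- sample(c(1:3, 7:10), 1) # keep the PAM intact
        len <- sample(1:3, 1)
        if (offset <= 3) len <- min(len, 4 - offset)
        pos <- .NICK_POS + offset
        payload <- substr(wide, pos, pos + len - 1L)
      } else if (type == "insertion") {
        offset <- sample(1:10, 1)
        payload <- .randSeq(1, sample(1:3, 1))
      } else {
        offset <- sample(setdiff(1:10, 4:6), 1) # off-PAM substitution
        pos <- .NICK_POS + offset
        ref <- substr(wide, pos, pos)
        payload <- sample(setdiff(.BASES, ref), 1)
      }
      pbs_len <- sample(7:17, 1)
      rt_len <- sample(10:23, 1)
      peg[[i]] <- data.frame(
        peg_id = sprintf("peg%04d", i), spacer = proto,
        wide_target = wide, edit_type = type,
        edit_offset = offset, edit_payload = payload,
        pbs_len = pbs_len, rt_len = rt_len,
        stringsAsFactors = FALSE
      )
    }
    peg <- do.call(rbind, peg)
    # PAM-silent variants: same spacer and target, additional NGG>NGA
    # change carried with the parent's edit
    variant_of <- sample(nBase, n_variant)
    var <- peg[variant_of, ]
    var$peg_id <- sub("^peg", "pegv", var$peg_id)
    peg$pam_silent <- rep(FALSE, nrow(peg))
    var$pam_silent <- rep(TRUE, nrow(var))
    peg <- rbind(peg, var)
    n_peg <- nrow(peg)
    n_oligo <- n_peg * barcodesPer
    barcodes <- randomBarcodes(n_oligo)
    upstream4 <- .randSeq(n_oligo, 4)
    rows <- peg[rep(seq_len(n_peg), each = barcodesPer), ]
    rows$pair_id <- if (barcodesPer == 1L) {
      rows$peg_id
    } else {
      paste0(rows$peg_id, "_bc", rep(seq_len(barcodesPer), times = n_peg))
    }
    rows$barcode <- barcodes
    rows$upstream4 <- upstream4
    rows$edited_wide_target <- mapply(
      applyEdit, rows$wide_target, rows$edit_type, rows$edit_offset,
      rows$edit_payload, rows$pam_silent,
      USE.NAMES = FALSE
    )
    # PBS primes from the nicked strand 3' end; RT template encodes the
    # edited sequence downstream of the nick
    rows$pbs <- revComp(substr(
      rows$wide_target, .NICK_POS - rows$pbs_len + 1L, .NICK_POS
    ))
    rows$rt_template <- revComp(substr(
      rows$edited_wide_target, .NICK_POS + 1L, .NICK_POS + rows$rt_len
    ))
    lib <- PairLibrary(rows[, .PAIR_COLUMNS])
    list(library = lib, nPegRNAs = n_peg, nOligos = n_oligo)
  })
}

#' Simulate screen reads with planted outcome rates
#'
#' For each pair, \code{depth} reads are drawn from a multinomial over
#' (intended, indel, unintended substitution, wild type) with the
#' planted per-pair rates. Reads have the amplicon structure
#' \code{pad - left anchor - wide-target region - right anchor -
#' upstream4 - barcode - pad}. Optional per-base sequencing errors are
#' placed outside the 22-nt barcode key (and outside the anchors) by
#' default, so demultiplexing truth stays exact; \code{errorInKey}
#' switches them into the key to measure assignment loss.
#'
#' @param lib A \linkS4class{PairLibrary}.
#' @param truth A data.frame with \code{pair_id}, \code{intended_rate},
#'   \code{indel_rate}, \code{sub_rate}, \code{depth}; or \code{NULL} to
#'   use \code{defaultTruth} for all pairs.
#' @param seed Integer seed.
#' @param fastqPath Optional path; when given, reads are written as FASTQ
#'   (gzip if the path ends in \code{.gz}).
#' @param errorRate Per-base sequencing error rate outside the key.
#' @param errorInKey Place sequencing errors inside the 22-nt key too.
#' @param defaultTruth Named list of rates used when \code{truth} is
#'   \code{NULL}.
#' @return List with \code{reads} (a \code{DNAStringSet}) and
#'   \code{truth} (a data.frame with read id, pair id, and true outcome).
#' @export
simulateReads <- function(lib, truth = NULL, seed = 1L, fastqPath = NULL,
                          errorRate = 0.001, errorInKey = FALSE,
                          defaultTruth = list(
                            intended_rate = 0.12, indel_rate = 0.03,
                            sub_rate = 0.02, depth = 500L
                          )) {
  d <- designs(lib)
  if (is.null(truth)) {
    truth <- data.frame(
      pair_id = d$pair_id,
      intended_rate = defaultTruth$intended_rate,
      indel_rate = defaultTruth$indel_rate,
      sub_rate = defaultTruth$sub_rate,
      depth = defaultTruth$depth,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(d$pair_id %in% truth$pair_id))
  truth <- truth[match(d$pair_id, truth$pair_id), ]
  .withSeed(seed, {
    all_seq <- vector("list", nrow(d))
    all_lab <- vector("list", nrow(d))
    for (i in seq_len(nrow(d))) {
      depth <- truth$depth[i]
      if (depth == 0) next
      pr <- c(
        truth$intended_rate[i], truth$indel_rate[i], truth$sub_rate[i]
      )
      stopifnot(all(pr >= 0), sum(pr) <= 1)
      counts <- as.vector(stats::rmultinom(1, depth, c(pr, 1 - sum(pr))))
      wt <- d$wide_target[i]
      ed <- d$edited_wide_target[i]
      regions <- c(
        rep(ed, counts[1]),
        .mutateIndel(wt, counts[2], ed),
        .mutateSub(wt, ed, counts[3]),
        rep(wt, counts[4])
      )
      outcome <- rep(
        c("INTENDED", "INDEL", "UNINTENDED_EDIT", "WILDTYPE"), counts
      )
      pad5 <- .randSeq(depth, 5)
      pad3 <- .randSeq(depth, 5)
      reads <- paste0(
        pad5, .ANCHOR_LEFT, regions, .ANCHOR_RIGHT,
        d$upstream4[i], d$barcode[i], pad3
      )
      if (errorRate > 0) {
        key_start <- 5L + 10L + nchar(regions) + 10L + 1L
        reads <- .addSeqErrors(reads, errorRate,
          protectFrom = if (errorInKey) rep(NA, depth) else key_start,
          protectLen = 22L
        )
      }
      all_seq[[i]] <- reads
      all_lab[[i]] <- data.frame(
        pair_id = d$pair_id[i], outcome = outcome,
        stringsAsFactors = FALSE
      )
    }
    seqs <- unlist(all_seq)
    lab <- do.call(rbind, all_lab)
    ids <- sprintf("read%07d", seq_along(seqs))
    lab$read_id <- ids
    reads <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    if (!is.null(fastqPath)) {
      Biostrings::writeXStringSet(reads, fastqPath,
        format = "fastq",
        compress = grepl("\\.gz$", fastqPath)
      )
    }
    list(reads = reads, truth = lab[, c("read_id", "pair_id", "outcome")])
  })
}

# random 1-3 nt deletions in the wide-target region, distinct from both
# references
.mutateIndel <- function(wt, n, ed = "") {
  if (n == 0) {
    return(character(0))
  }
  len <- nchar(wt)
  vapply(seq_len(n), function(i) {
    repeat {
      dlen <- sample(1:3, 1)
      pos <- sample(len - dlen, 1)
      out <- paste0(substr(wt, 1, pos - 1), substr(wt, pos + dlen, len))
      if (out != ed) {
        return(out)
      }
    }
  }, character(1))
}

# single random substitutions, never reproducing the edited reference
.mutateSub <- function(wt, ed, n) {
  if (n == 0) {
    return(character(0))
  }
  len <- nchar(wt)
  vapply(seq_len(n), function(i) {
    repeat {
      pos <- sample(len, 1)
      ref <- substr(wt, pos, pos)
      alt <- sample(setdiff(.BASES, ref), 1)
      out <- wt
      substr(out, pos, pos) <- alt
      if (out != ed) {
        return(out)
      }
    }
  }, character(1))
}

.addSeqErrors <- function(reads, rate, protectFrom = NA, protectLen = 0L) {
  lens <- nchar(reads)
  protectFrom <- rep_len(protectFrom, length(reads))
  n_err <- stats::rbinom(length(reads), lens, rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    allowed <- seq_len(lens[i])
    if (!is.na(protectFrom[i])) {
      allowed <- setdiff(
        allowed, seq(protectFrom[i], protectFrom[i] + protectLen - 1L)
      )
    }
    pos <- sample(allowed, min(n_err[i], length(allowed)))
    r <- reads[i]
    for (p in pos) {
      ref <- substr(r, p, p)
      substr(r, p, p) <- sample(setdiff(.BASES, ref), 1)
    }
    reads[i] <- r
  }
  reads
}

#' Simulate a fold-change table with a planted PBS-Tm effect
#'
#' The log adjusted fold change is drawn as \code{intercept + slope x
#' Tm(PBS) + Normal(0, noiseSd)}; the default slope is negative, so the
#' fold increase decreases with the PBS melting temperature. PE2
#' efficiencies come from a mixture with a sub-1\% stratum (fraction
#' \code{lowFraction} uniform on [0, 1)\%, remainder log-uniform on [1,
#' 40]\%) and the hyPE2 efficiency is back-computed from the adjusted
#' fold change with the 0.1 pseudocount.
#'
#' @param lib A \linkS4class{PairLibrary} (one row per pegRNA is used;
#'   barcode replicates of the same pegRNA are collapsed).
#' @param intercept,slope Planted effect on the natural-log fold scale;
#'   defaults 2.4 and -0.05 per degree Celsius.
#' @param noiseSd Noise standard deviation on the log scale, default 0.2.
#' @param lowFraction Fraction of pairs in the sub-1\% PE2 stratum.
#' @param seed Integer seed.
#' @return A data.frame with \code{pair_id}, \code{pbs_tm},
#'   \code{pe2_pct}, \code{hype2_pct}, \code{adjusted_fold},
#'   \code{log_fold}.
#' @export
simulateFoldTable <- function(lib, intercept = 2.4, slope = -0.05,
                              noiseSd = 0.2, lowFraction = 0.15,
                              seed = 1L) {
  stopifnot(noiseSd >= 0)
  d <- designs(lib)
  keep <- !duplicated(sub("_bc[0-9]+$", "", d$pair_id))
  d <- d[keep, ]
  pair_id <- sub("_bc[0-9]+$", "", d$pair_id)
  tm <- meltingTemperature(d$pbs, mode = "dna")
  .withSeed(seed, {
    logf <- intercept + slope * tm + stats::rnorm(length(tm), 0, noiseSd)
    fold <- exp(logf)
    low <- stats::runif(length(tm)) < lowFraction
    pe2 <- ifelse(
      low, stats::runif(length(tm), 0, 1),
      exp(stats::runif(length(tm), log(1), log(40)))
    )
    hype2 <- pmax((pe2 + 0.1) * fold - 0.1, 0)
    data.frame(
      pair_id = pair_id, pbs_tm = tm, pe2_pct = pe2,
      hype2_pct = hype2,
      adjusted_fold = adjustedFoldChange(pe2, hype2),
      log_fold = log(adjustedFoldChange(pe2, hype2)),
      stringsAsFactors = FALSE
    )
  })
}
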