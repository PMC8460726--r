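# small in-code fixtures shared across tests

# a hand-built 3-pair library with one edit of each type
makeTinyLibrary <- function() {
  wt <- function(f5, proto, pamN, f3) paste0(f5, proto, pamN, "GG", f3)
  w1 <- wt("AAGG", "ACGTACGTACGTACGTACGT", "T", "CCCCAAAATTTTGGGGCCAA")
  w2 <- wt("TTCA", "GGCCAATTGGCCAATTGGCC", "A", "ACACACACACGTGTGTGTGT")
  w3 <- wt("CGCG", "TTTTAAAACCCCGGGGTACG", "C", "GATCGATCGATCGATCGATC")
  d <- data.frame(
    pair_id = c("P1", "P2", "P3"),
    spacer = c(
      "ACGTACGTACGTACGTACGT", "GGCCAATTGGCCAATTGGCC",
      "TTTTAAAACCCCGGGGTACG"
    ),
    barcode = c(
      "AAACCCGGGTTTAAACCG", "CCCGGGTTTAAACCCGGA",
      "GGGTTTAAACCCGGGTTC"
    ),
    upstream4 = c("ACGT", "TGCA", "GATC"),
    wide_target = c(w1, w2, w3),
    edit_type = c("substitution", "insertion", "deletion"),
    edit_offset = c(1L, 2L, 1L),
    edit_payload = c("G", "TT", substr(w3, 22, 22)),
    pam_silent = FALSE,
    stringsAsFactors = FALSE
  )
  d$edited_wide_target <- mapply(
    applyEdit, d$wide_target, d$edit_type, d$edit_offset, d$edit_payload
  )
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x))
  )
  d$pbs <- rc(substr(d$wide_target, 21 - 11, 21))
  d$rt_template <- rc(substr(d$edited_wide_target, 22, 22 + 12))
  PairLibrary(d)
}

# wrap a wide-target region in a full synthetic amplicon read
makeRead <- function(region, pair, pad5 = "CATTG", pad3 = "GTTAC") {
  d <- if (is(pair, "PairLibrary")) designs(pair)[1, ] else pair
  paste0(
    pad5, "GTTCACTGCC", region, "CAGGTGCTGA",
    d$upstream4, d$barcode, pad3
  )
}

# exhaustive enumeration oracle for the bundled folding energy model:
# all non-crossing pair sets (minimum hairpin loop 3), energy counted
# only for stacked pairs
enumMFE <- function(seq, minloop = 3) {
  score <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)
  b <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(b)
  can <- function(i, j) {
    !is.na(score[paste0(b[i], b[j])]) && j - i > minloop
  }
  best <- 0
  gen <- function(i, pairs, avail) {
    if (i > n) {
      e <- 0
      if (nrow(pairs) >= 2) {
        for (r in seq_len(nrow(pairs))) {
          pi <- pairs[r, 1]
          pj <- pairs[r, 2]
          if (any(pairs[, 1] == pi + 1 & pairs[, 2] == pj - 1)) {
            e <- e - (score[paste0(b[pi], b[pj])] +
              score[paste0(b[pi + 1], b[pj - 1])]) / 2
          }
        }
      }
      best <<- min(best, e)
      return()
    }
    if (!avail[i]) {
      gen(i + 1, pairs, avail)
      return()
    }
    gen(i + 1, pairs, avail)
    for (j in seq_len(n)) {
      if (j > i && avail[j] && can(i, j)) {
        ok <- TRUE
        if (nrow(pairs) > 0) {
          for (r in seq_len(nrow(pairs))) {
            a <- pairs[r, 1]
            bb <- pairs[r, 2]
            if ((a < i && i < bb && bb < j) ||
              (i < a && a < j && j < bb)) {
              ok <- FALSE
              break
            }
          }
        }
        if (ok) {
          av <- avail
          av[c(i, j)] <- FALSE
          gen(i + 1, rbind(pairs, c(i, j)), av)
        }
      }
    }
  }
  gen(1, matrix(integer(0), ncol = 2), rep(TRUE, n))
  unname(best)
}
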