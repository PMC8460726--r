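.BASES <- c("A", "C", "G", "T")
.DINUCS <- as.vector(outer(.BASES, .BASES, paste0))

#' The fixed 1,820-feature layout registry
#'
#' The encoding of a pegRNA/target pair comprises six groups (1,820
#' features in total):
#' \describe{
#'   \item{POSDEP_MONO_TARGET}{one-hot nucleotide per wide-target position
#'     (47 x 4 = 188);}
#'   \item{POSDEP_DI_TARGET}{one-hot dinucleotide per adjacent wide-target
#'     position pair (46 x 16 = 736);}
#'   \item{POSDEP_MONO_EXT}{one-hot nucleotide per position of the pegRNA
#'     3' extension (RT template followed by PBS), right-aligned in a
#'     42-nt window with all-zero left padding (42 x 4 = 168);}
#'   \item{POSDEP_DI_EXT}{one-hot dinucleotide over the extension window
#'     (41 x 16 = 656);}
#'   \item{POSINDEP_COUNTS}{position-independent mono- and dinucleotide
#'     counts for the wide target, PBS and RT template ((4 + 16) x 3 =
#'     60);}
#'   \item{SCALARS}{12 scalars: melting temperatures of the PBS:target
#'     duplex (\code{Tm_PBS}), the RT template against its synthesized
#'     DNA (RNA/DNA mode, \code{Tm_RT}), the full extension
#'     (\code{Tm_EXT}), and their difference (\code{Tm_PBS_minus_RT});
#'     GC counts and GC fractions of PBS, RT template and extension; the
#'     self-folding minimum free energy of the extension; and the
#'     on-target (DeepSpCas9-style) score.}
#' }
#' The layout is a registry: models always travel with the layout and its
#' checksum, so an alternative breakdown with the same total can be
#' swapped without touching the learners.
#'
#' @param wideLen Wide-target length (default 47).
#' @param extLen Extension-window length (default 42).
#' @return A \code{DataFrame} with columns \code{group}, \code{name},
#'   \code{description}, one row per feature.
#' @export
featureLayout <- function(wideLen = .WIDE_TARGET_LEN,
                          extLen = .EXT_WINDOW_LEN) {
  rows <- list()
  add <- function(group, name, desc) {
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, name = name, description = desc,
      stringsAsFactors = FALSE
    )
  }
  for (p in seq_len(wideLen)) {
    add(
      "POSDEP_MONO_TARGET", paste0("WT", sprintf("%02d", p), "_", .BASES),
      sprintf("wide target position %d is %s", p, .BASES)
    )
  }
  for (p in seq_len(wideLen - 1L)) {
    add(
      "POSDEP_DI_TARGET", paste0("WT", sprintf("%02d", p), "_", .DINUCS),
      sprintf("wide target positions %d-%d are %s", p, p + 1L, .DINUCS)
    )
  }
  for (p in seq_len(extLen)) {
    add(
      "POSDEP_MONO_EXT", paste0("EXT", sprintf("%02d", p), "_", .BASES),
      sprintf("extension window position %d is %s", p, .BASES)
    )
  }
  for (p in seq_len(extLen - 1L)) {
    add(
      "POSDEP_DI_EXT", paste0("EXT", sprintf("%02d", p), "_", .DINUCS),
      sprintf("extension window positions %d-%d are %s", p, p + 1L, .DINUCS)
    )
  }
  for (s in c("WT", "PBS", "RT")) {
    add(
      "POSINDEP_COUNTS", paste0("N_", s, "_", .BASES),
      sprintf("count of %s in %s", .BASES, s)
    )
    add(
      "POSINDEP_COUNTS", paste0("N_", s, "_", .DINUCS),
      sprintf("count of %s in %s", .DINUCS, s)
    )
  }
  scalars <- c(
    Tm_PBS = "melting temperature of the PBS:target duplex (deg C)",
    Tm_RT = "melting temperature of RT template vs synthesized DNA (deg C)",
    Tm_EXT = "melting temperature of the full 3' extension (deg C)",
    Tm_PBS_minus_RT = "Tm difference between PBS and RT segments (deg C)",
    GC_count_PBS = "GC count of the PBS",
    GC_count_RT = "GC count of the RT template",
    GC_count_EXT = "GC count of the extension",
    GC_frac_PBS = "GC fraction of the PBS",
    GC_frac_RT = "GC fraction of the RT template",
    GC_frac_EXT = "GC fraction of the extension",
    MFE_EXT = "self-folding minimum free energy of the extension (kcal/mol)",
    DeepSpCas9 = "on-target activity score of the protospacer"
  )
  add("SCALARS", names(scalars), unname(scalars))
  d <- do.call(rbind, rows)
  S4Vectors::DataFrame(d)
}

.layoutChecksum <- function(layout) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(layout$group, layout$name, sep = ":"), tmp)
  unname(tools::md5sum(tmp))
}

# one-hot encode one sequence into a (positions x 4|16) block, flattened;
# right-aligned when the window is longer than the sequence (left padding
# stays all-zero)
.oneHotBlock <- function(seq, window, alphabet, k) {
  n_sym <- length(alphabet)
  n_pos <- window - k + 1L
  v <- numeric(n_pos * n_sym)
  len <- nchar(seq)
  if (len > window) stop("sequence longer than its window")
  offset <- window - len # left padding
  if (len >= k) {
    for (p in seq_len(len - k + 1L)) {
      sym <- substr(seq, p, p + k - 1L)
      idx <- match(sym, alphabet)
      if (is.na(idx)) stop("non-ACGT character in sequence")
      v[(offset + p - 1L) * n_sym + idx] <- 1
    }
  }
  v
}

.countBlock <- function(seq, alphabet, k) {
  len <- nchar(seq)
  v <- numeric(length(alphabet))
  if (len >= k) {
    subs <- substring(seq, seq_len(len - k + 1L), k:len)
    tab <- table(factor(subs, levels = alphabet))
    v <- as.numeric(tab)
  }
  v
}

.gcCount <- function(seq) {
  nchar(seq) - nchar(gsub("[GC]", "", seq))
}

#' Encode pegRNA/target pairs as 1,820-feature vectors
#'
#' See \code{\link{featureLayout}} for the encoding. Melting temperatures
#' use the nearest-neighbor default setting
#' (\code{\link{meltingTemperature}}); the extension self-folding MFE uses
#' \code{\link{selfFoldingMFE}}. The on-target score column is looked up
#' from \code{scores} when given; otherwise it is filled with
#' \code{defaultScore} and a warning is recorded (the external deep
#' on-target model is pluggable, not bundled).
#'
#' @param lib A \linkS4class{PairLibrary}.
#' @param scores Optional named numeric vector or two-column data.frame
#'   (pair_id, score) of precomputed on-target scores; every pair must be
#'   present.
#' @param defaultScore Constant used when \code{scores} is \code{NULL}.
#' @param mfeEngine Engine passed to \code{\link{selfFoldingMFE}}.
#' @return A \linkS4class{FeatureMatrix} (pairs x 1,820).
#' @export
extractFeatures <- function(lib, scores = NULL, defaultScore = 0,
                            mfeEngine = "auto") {
  d <- designs(lib)
  layout <- featureLayout()
  n <- nrow(d)
  wide <- d$wide_target
  if (any(nchar(wide) != .WIDE_TARGET_LEN)) {
    stop("wide target must be exactly ", .WIDE_TARGET_LEN, " nt")
  }
  ext <- paste0(d$rt_template, d$pbs) # 5'->3' extension: RTT then PBS
  if (any(nchar(ext) > .EXT_WINDOW_LEN)) {
    stop("pegRNA extension longer than the ", .EXT_WINDOW_LEN, "-nt window")
  }
  mono_t <- t(vapply(
    wide, .oneHotBlock, numeric(.WIDE_TARGET_LEN * 4L),
    window = .WIDE_TARGET_LEN, alphabet = .BASES, k = 1L,
    USE.NAMES = FALSE
  ))
  di_t <- t(vapply(
    wide, .oneHotBlock, numeric((.WIDE_TARGET_LEN - 1L) * 16L),
    window = .WIDE_TARGET_LEN, alphabet = .DINUCS, k = 2L,
    USE.NAMES = FALSE
  ))
  mono_e <- t(vapply(
    ext, .oneHotBlock, numeric(.EXT_WINDOW_LEN * 4L),
    window = .EXT_WINDOW_LEN, alphabet = .BASES, k = 1L,
    USE.NAMES = FALSE
  ))
  di_e <- t(vapply(
    ext, .oneHotBlock, numeric((.EXT_WINDOW_LEN - 1L) * 16L),
    window = .EXT_WINDOW_LEN, alphabet = .DINUCS, k = 2L,
    USE.NAMES = FALSE
  ))
  cnt <- t(mapply(function(w, p, r) {
    c(
      .countBlock(w, .BASES, 1L), .countBlock(w, .DINUCS, 2L),
      .countBlock(p, .BASES, 1L), .countBlock(p, .DINUCS, 2L),
      .countBlock(r, .BASES, 1L), .countBlock(r, .DINUCS, 2L)
    )
  }, wide, d$pbs, d$rt_template, USE.NAMES = FALSE))
  tm_pbs <- meltingTemperature(d$pbs, mode = "dna")
  tm_rt <- meltingTemperature(d$rt_template, mode = "rna_dna")
  tm_ext <- meltingTemperature(ext, mode = "dna")
  mfe <- selfFoldingMFE(ext, engine = mfeEngine)
  sc <- .resolveScores(scores, d$pair_id, defaultScore)
  scal <- cbind(
    tm_pbs, tm_rt, tm_ext, tm_pbs - tm_rt,
    .gcCount(d$pbs), .gcCount(d$rt_template), .gcCount(ext),
    .gcCount(d$pbs) / nchar(d$pbs),
    .gcCount(d$rt_template) / nchar(d$rt_template),
    .gcCount(ext) / nchar(ext),
    mfe, sc
  )
  values <- cbind(mono_t, di_t, mono_e, di_e, cnt, scal)
  colnames(values) <- as.character(layout$name)
  rownames(values) <- d$pair_id
  new("FeatureMatrix",
    values = values, layout = layout,
    checksum = .layoutChecksum(layout)
  )
}

.resolveScores <- function(scores, ids, defaultScore) {
  if (is.null(scores)) {
    warning(
      "no on-target scorer supplied; using constant ", defaultScore,
      " for the DeepSpCas9 column"
    )
    return(rep(defaultScore, length(ids)))
  }
  if (is.data.frame(scores)) {
    scores <- stats::setNames(as.numeric(scores[[2]]), scores[[1]])
  }
  missing_ids <- setdiff(ids, names(scores))
  if (length(missing_ids) > 0) {
    stop(
      "score table missing pair id(s): ",
      paste(head(missing_ids, 5), collapse = ", ")
    )
  }
  unname(scores[ids])
}

#' Read precomputed on-target scores
#'
#' @param path Two-column TSV (pair_id, score) with a header.
#' @return Named numeric vector.
#' @export
readScoreTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d[[2]]), d[[1]])
}

#' @rdname FeatureMatrix-accessors
#' @param x A \linkS4class{FeatureMatrix}.
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-accessors
#' @export
setMethod("layoutInfo", "FeatureMatrix", function(x) x@layout)

#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  cat(
    "FeatureMatrix:", nrow(object@values), "pairs x",
    ncol(object@values), "features ( checksum", object@checksum, ")\n"
  )
})

#' Write a feature matrix and its layout
#'
#' @param fm A \linkS4class{FeatureMatrix}.
#' @param path Output TSV path (pairs x features); the layout is written
#'   alongside as \code{<path>.layout.json}.
#' @return Invisibly, \code{path}.
#' @export
writeFeatureMatrix <- function(fm, path) {
  d <- data.frame(
    pair_id = rownames(featureValues(fm)),
    featureValues(fm), check.names = FALSE
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(
      checksum = fm@checksum,
      features = as.data.frame(layoutInfo(fm))
    ),
    paste0(path, ".layout.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
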