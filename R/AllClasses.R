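#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## Amplicon geometry shared by the simulator and the classifier.
## The wide target is 4 nt upstream flank + 20-nt protospacer + NGG PAM +
## 20 nt downstream flank; the SpCas9 H840A nick falls between protospacer
## positions 17 and 18, i.e. after wide-target position 21.
.WIDE_TARGET_LEN <- 47L
.PROTO_START <- 5L # 1-based start of the protospacer in the wide target
.NICK_POS <- 21L # nick is between wide-target positions 21 and 22
.EXT_WINDOW_LEN <- 42L # fixed window for the pegRNA 3' extension encoding

## Constant 10-nt anchors flanking the wide target in every amplicon
## (vector-backbone sequence shared across the library, like the common
## priming regions of the oligo pool).
.ANCHOR_LEFT <- "GTTCACTGCC"
.ANCHOR_RIGHT <- "CAGGTGCTGA"

.PAIR_COLUMNS <- c(
  "pair_id", "spacer", "pbs", "rt_template", "barcode", "upstream4",
  "wide_target", "edited_wide_target", "edit_type", "edit_offset",
  "edit_payload", "pam_silent"
)

#' PairLibrary: a validated table of pegRNA/target pair designs
#'
#' One row per oligo: a pegRNA (spacer, primer-binding site, RT template),
#' its 18-nt barcode with the 4-nt sequence immediately upstream in the
#' amplicon, the wide target sequence (protospacer + NGG PAM + flanks), the
#' edited wide target, and the edit specification (type, offset from the
#' nick site, payload). PAM-silent variant rows carry \code{pam_silent =
#' TRUE}: their edited target additionally converts the NGG PAM to NGA.
#'
#' @slot designs A \code{DataFrame} with one row per pair and the columns
#'   \code{pair_id}, \code{spacer}, \code{pbs}, \code{rt_template},
#'   \code{barcode}, \code{upstream4}, \code{wide_target},
#'   \code{edited_wide_target}, \code{edit_type}, \code{edit_offset},
#'   \code{edit_payload}, \code{pam_silent}.
#' @export
setClass("PairLibrary", slots = c(designs = "DataFrame"))

setValidity("PairLibrary", function(object) {
  d <- object@designs
  msgs <- character(0)
  missing_cols <- setdiff(.PAIR_COLUMNS, colnames(d))
  if (length(missing_cols) > 0) {
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(d$pair_id)) {
    msgs <- c(msgs, "duplicate pair_id")
  }
  bad <- which(nchar(d$barcode) != 18L)
  if (length(bad) > 0) {
    msgs <- c(msgs, sprintf(
      "field barcode: length != 18 nt for pair(s) %s",
      paste(head(d$pair_id[bad], 5), collapse = ", ")
    ))
  }
  bad <- which(nchar(d$upstream4) != 4L)
  if (length(bad) > 0) {
    msgs <- c(msgs, sprintf(
      "field upstream4: length != 4 nt for pair(s) %s",
      paste(head(d$pair_id[bad], 5), collapse = ", ")
    ))
  }
  seq_cols <- c(
    "spacer", "pbs", "rt_template", "barcode", "upstream4",
    "wide_target", "edited_wide_target"
  )
  for (col in seq_cols) {
    if (length(d[[col]]) > 0 && any(grepl("[^ACGT]", d[[col]]))) {
      msgs <- c(msgs, sprintf("field %s: non-ACGT characters", col))
    }
  }
  if (length(d$spacer) > 0 && any(nchar(d$spacer) != 20L)) {
    msgs <- c(msgs, "field spacer: length != 20 nt")
  }
  if (length(d$pbs) > 0 &&
    any(nchar(d$pbs) < 7L | nchar(d$pbs) > 17L)) {
    msgs <- c(msgs, "field pbs: length outside 7-17 nt")
  }
  key <- paste0(d$upstream4, d$barcode)
  if (anyDuplicated(key)) {
    dup <- d$pair_id[key %in% key[duplicated(key)]]
    msgs <- c(msgs, sprintf(
      "22-nt barcode key shared by pairs: %s",
      paste(head(dup, 6), collapse = ", ")
    ))
  }
  if (nrow(d) > 0) {
    # protospacer followed by NGG must be present in the wide target
    proto <- substr(d$wide_target, .PROTO_START, .PROTO_START + 19L)
    pam23 <- substr(
      d$wide_target, .PROTO_START + 21L, .PROTO_START + 22L
    )
    bad <- which(proto != d$spacer | pam23 != "GG")
    if (length(bad) > 0) {
      msgs <- c(msgs, sprintf(
        "field wide_target: no protospacer+NGG match for pair(s) %s",
        paste(head(d$pair_id[bad], 5), collapse = ", ")
      ))
    }
    expect <- mapply(
      applyEdit, d$wide_target, d$edit_type, d$edit_offset,
      d$edit_payload, d$pam_silent,
      USE.NAMES = FALSE
    )
    bad <- which(expect != d$edited_wide_target)
    if (length(bad) > 0) {
      msgs <- c(msgs, sprintf(
        "field edited_wide_target: inconsistent with edit spec for pair(s) %s",
        paste(head(d$pair_id[bad], 5), collapse = ", ")
      ))
    }
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' BarcodeIndex: exact-match lookup from 22-nt keys to pair ids
#'
#' The key is the 4-nt upstream sequence concatenated with the 18-nt
#' barcode; lookup is exact (no mismatch tolerance) and N never matches.
#'
#' @slot keys Character vector of 22-nt keys.
#' @slot pairIds Character vector of pair ids, parallel to \code{keys}.
#' @export
setClass("BarcodeIndex", slots = c(keys = "character", pairIds = "character"))

setValidity("BarcodeIndex", function(object) {
  msgs <- character(0)
  if (length(object@keys) != length(object@pairIds)) {
    msgs <- c(msgs, "keys and pairIds differ in length")
  }
  if (length(object@keys) > 0 && any(nchar(object@keys) != 22L)) {
    msgs <- c(msgs, "all keys must be 22 nt")
  }
  if (anyDuplicated(object@keys)) {
    msgs <- c(msgs, "duplicate 22-nt keys")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' OutcomeCounts: per-pair read tallies by classification
#'
#' Reads assigned to a pair are classified as intended edit, unintended
#' edit (substitution-only mismatch), indel, wild type, or discarded
#' (wide-target region not locatable). The total excludes discarded reads
#' and is the denominator of all frequency statistics.
#'
#' @slot counts A \code{DataFrame} with columns \code{pair_id},
#'   \code{n_total}, \code{n_intended}, \code{n_unintended_edit},
#'   \code{n_indel}, \code{n_wildtype}, \code{n_discarded}.
#' @export
setClass("OutcomeCounts", slots = c(counts = "DataFrame"))

setValidity("OutcomeCounts", function(object) {
  d <- object@counts
  need <- c(
    "pair_id", "n_total", "n_intended", "n_unintended_edit",
    "n_indel", "n_wildtype", "n_discarded"
  )
  missing_cols <- setdiff(need, colnames(d))
  if (length(missing_cols) > 0) {
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  num <- setdiff(need, "pair_id")
  for (col in num) {
    if (any(d[[col]] < 0)) return(sprintf("%s has negative counts", col))
  }
  tot <- d$n_intended + d$n_unintended_edit + d$n_indel + d$n_wildtype
  if (any(d$n_total != tot)) {
    return("n_total must equal intended + unintended + indel + wildtype")
  }
  TRUE
})

#' FeatureMatrix: fixed-length feature encoding of pegRNA/target pairs
#'
#' A numeric matrix (pairs x features) aligned to a named feature layout
#' registry; the layout and its checksum travel with the matrix so a model
#' trained on one encoding is never applied to another.
#'
#' @slot values Numeric matrix, rows = pairs, columns = features.
#' @slot layout A \code{DataFrame} with columns \code{group}, \code{name},
#'   \code{description}, one row per feature, in column order.
#' @slot checksum Single character, digest of the layout.
#' @export
setClass("FeatureMatrix", slots = c(
  values = "matrix", layout = "DataFrame", checksum = "character"
))

setValidity("FeatureMatrix", function(object) {
  msgs <- character(0)
  if (ncol(object@values) != nrow(object@layout)) {
    msgs <- c(msgs, "matrix columns must match layout rows")
  }
  if (anyDuplicated(object@layout$name)) {
    msgs <- c(msgs, "feature names must be unique")
  }
  if (!identical(colnames(object@values), as.character(object@layout$name))) {
    msgs <- c(msgs, "matrix column names must equal layout names")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' ModelSelectionResult: outcome of the grouped model-selection harness
#'
#' For each learner the best hyperparameter configuration by mean
#' cross-validated Spearman correlation, plus the held-out test Spearman
#' correlation of that configuration (computed once, after selection); the
#' winner is the learner with the highest cross-validation score.
#'
#' @slot perAlgorithm A \code{DataFrame}, one row per learner: algorithm,
#'   best configuration index, mean CV Spearman rho, test Spearman rho.
#' @slot winner Single character, the winning algorithm.
#' @slot models List of fitted best models, one per learner.
#' @slot split The \code{list} describing the grouped train/test split.
#' @export
setClass("ModelSelectionResult", slots = c(
  perAlgorithm = "DataFrame", winner = "character",
  models = "list", split = "list"
))
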