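#' Construct a PairLibrary from a data frame of designs
#'
#' @param designs A data.frame or DataFrame with the pair-design columns
#'   (see \linkS4class{PairLibrary}).
#' @return A validated \linkS4class{PairLibrary}.
#' @export
PairLibrary <- function(designs) {
  d <- S4Vectors::DataFrame(designs)
  missing_cols <- setdiff(.PAIR_COLUMNS, colnames(d))
  if (length(missing_cols) > 0) {
    stop(
      "pair table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }
  d <- d[, .PAIR_COLUMNS]
  d$edit_offset <- as.integer(d$edit_offset)
  d$pam_silent <- as.logical(d$pam_silent)
  new("PairLibrary", designs = d)
}

#' Accessors for PairLibrary
#'
#' @param x A \linkS4class{PairLibrary}.
#' @name PairLibrary-accessors
#' @aliases pairIds designs barcodeKeys
NULL

#' @rdname PairLibrary-accessors
#' @export
setMethod("pairIds", "PairLibrary", function(x) x@designs$pair_id)

#' @rdname PairLibrary-accessors
#' @export
setMethod("designs", "PairLibrary", function(x) x@designs)

#' @rdname PairLibrary-accessors
#' @export
setMethod("barcodeKeys", "PairLibrary", function(x) {
  paste0(x@designs$upstream4, x@designs$barcode)
})

#' @export
setMethod("length", "PairLibrary", function(x) nrow(x@designs))

setMethod("show", "PairLibrary", function(object) {
  d <- object@designs
  cat(
    "PairLibrary with", nrow(d), "pegRNA/target pairs (",
    sum(!d$pam_silent), "base,", sum(d$pam_silent), "PAM-silent )\n"
  )
  if (nrow(d) > 0) {
    cat("  edit types:", paste(sprintf(
      "%s=%d", names(table(d$edit_type)), as.integer(table(d$edit_type))
    ), collapse = " "), "\n")
  }
})

#' Subset a PairLibrary by index or pair id
#'
#' @param x A \linkS4class{PairLibrary}.
#' @param i Numeric/logical index or character vector of pair ids.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "PairLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@designs$pair_id)
  initialize(x, designs = x@designs[i, , drop = FALSE])
})

#' Read a pegRNA/target pair table
#'
#' The table is a TSV with a header naming all pair-design fields. All
#' design invariants (18-nt barcode, 4-nt upstream sequence, unique pair
#' ids and 22-nt keys, protospacer+NGG present in the wide target, edited
#' target consistent with the edit specification) are validated on load.
#'
#' @param path Path to the TSV file.
#' @return A \linkS4class{PairLibrary}.
#' @export
readPairTable <- function(path) {
  d <- tryCatch(
    utils::read.delim(path,
      colClasses = "character",
      check.names = FALSE, stringsAsFactors = FALSE
    ),
    error = function(e) stop("cannot parse pair table '", path, "': ",
      conditionMessage(e),
      call. = FALSE
    )
  )
  n_fields <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(n_fields != n_fields[1])
  if (length(bad) > 0) {
    stop("malformed pair table row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  PairLibrary(d)
}

#' Write a pegRNA/target pair table
#'
#' Inverse of \code{\link{readPairTable}}: the written TSV round-trips
#' field-for-field.
#'
#' @param lib A \linkS4class{PairLibrary}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writePairTable <- function(lib, path) {
  d <- as.data.frame(designs(lib))
  d$pam_silent <- ifelse(d$pam_silent, "TRUE", "FALSE")
  utils::write.table(d, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read an efficiency table (pair id plus percent efficiencies)
#'
#' @param path TSV with a header; first column the pair id, remaining
#'   columns numeric percentages.
#' @return A data.frame.
#' @export
readEfficiencyTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in colnames(d)[-1]) d[[col]] <- as.numeric(d[[col]])
  d
}
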