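#' Apply an edit specification to a wide target sequence
#'
#' Edits are specified relative to the nick site (between protospacer
#' positions 17 and 18): offset 1 is the first nucleotide 3' of the nick.
#' A substitution replaces \code{nchar(payload)} bases starting at the
#' offset; an insertion inserts the payload immediately before the offset
#' position; a deletion removes the bases starting at the offset, which
#' must equal the payload. When \code{pamSilent} is \code{TRUE} the NGG
#' PAM is first converted to NGA (third PAM base G>A), emulating a
#' PAM-disrupting silent change carried alongside the primary edit.
#'
#' @param wideTarget Character, the 47-nt wide target sequence.
#' @param type One of \code{"substitution"}, \code{"insertion"},
#'   \code{"deletion"}.
#' @param offset Integer offset from the nick site (>= 1).
#' @param payload Character, the substituted/inserted/deleted bases.
#' @param pamSilent Logical, apply the PAM-silent G>A change first.
#' @return The edited wide target sequence.
#' @export
#' @examples
#' wt <- paste0(
#'   "AAGG", "ACGTACGTACGTACGTACGT", "TGG",
#'   "CCCCAAAATTTTGGGGCCCC"
#' )
#' applyEdit(wt, "substitution", 1L, "A")
applyEdit <- function(wideTarget, type, offset, payload,
                      pamSilent = FALSE) {
  stopifnot(length(wideTarget) == 1L, offset >= 1L)
  out <- wideTarget
  if (isTRUE(pamSilent)) {
    # third PAM base: protospacer start + 22 (1-based)
    pos <- .PROTO_START + 22L
    substr(out, pos, pos) <- "A"
  }
  pos <- .NICK_POS + offset # 1-based position of the edit start
  len <- nchar(payload)
  switch(type,
    substitution = {
      if (pos + len - 1L > nchar(out)) {
        stop("substitution extends beyond the wide target")
      }
      substr(out, pos, pos + len - 1L) <- payload
      out
    },
    insertion = {
      paste0(substr(out, 1L, pos - 1L), payload, substr(out, pos, nchar(out)))
    },
    deletion = {
      if (substr(out, pos, pos + len - 1L) != payload) {
        stop("deletion payload does not match the wide target at the offset")
      }
      paste0(substr(out, 1L, pos - 1L), substr(out, pos + len, nchar(out)))
    },
    stop("unknown edit type: ", type)
  )
}

# reverse complement for plain character vectors
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
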