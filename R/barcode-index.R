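#' Build the 22-nt barcode index for a pair library
#'
#' Each pair is keyed by the 4 nt immediately upstream of its barcode
#' concatenated with the 18-nt barcode. Keys must be unique across the
#' library; a collision aborts with the offending pair ids.
#'
#' @param lib A \linkS4class{PairLibrary}.
#' @return A \linkS4class{BarcodeIndex}.
#' @export
buildBarcodeIndex <- function(lib) {
  keys <- barcodeKeys(lib)
  ids <- pairIds(lib)
  if (anyDuplicated(keys)) {
    clash <- ids[keys %in% keys[duplicated(keys)]]
    stop(
      "22-nt key collision between pairs: ",
      paste(clash, collapse = ", ")
    )
  }
  new("BarcodeIndex", keys = keys, pairIds = ids)
}

#' @export
setMethod("length", "BarcodeIndex", function(x) length(x@keys))

setMethod("show", "BarcodeIndex", function(object) {
  cat("BarcodeIndex with", length(object@keys), "22-nt keys\n")
})

#' Assign reads to pairs by exact 22-nt key match
#'
#' Scans each read for an exact occurrence of any 22-nt key (4-nt upstream
#' sequence + 18-nt barcode). Matching is exact: a single mismatch, or an N
#' at any key position, prevents assignment. A read containing keys of two
#' distinct pairs is ambiguous and left unassigned, so ambiguity never
#' inflates any pair's denominator. Reads shorter than 22 nt are
#' unassigned, not an error.
#'
#' @param reads A \code{DNAStringSet} (or character vector) of read
#'   sequences.
#' @param index A \linkS4class{BarcodeIndex}.
#' @return Character vector of pair ids, \code{NA} for unassigned reads.
#' @export
assignReads <- function(reads, index) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  out <- rep(NA_character_, length(reads))
  if (length(reads) == 0 || length(index) == 0) {
    return(out)
  }
  keep <- Biostrings::width(reads) >= 22L
  if (!any(keep)) {
    return(out)
  }
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(index@keys))
  hits <- Biostrings::vwhichPDict(pdict, reads[keep])
  # keys are unique per pair, so >1 distinct key hit means ambiguity
  n_hits <- lengths(hits)
  one <- n_hits == 1L
  res <- rep(NA_character_, sum(keep))
  res[one] <- index@pairIds[unlist(hits[one])]
  out[keep] <- res
  out
}

#' @rdname assignReads
#' @param read A single read sequence (character or \code{DNAString}).
#' @return For \code{assignRead}: a single pair id or \code{NA}.
#' @export
assignRead <- function(read, index) {
  assignReads(Biostrings::DNAStringSet(as.character(read)), index)[1]
}

#' Read amplicon reads from a FASTQ file
#'
#' @param path Path to a FASTQ file (gzip-compressed allowed).
#' @return A \code{DNAStringSet} of read sequences, named by read id.
#' @export
readFastqReads <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
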