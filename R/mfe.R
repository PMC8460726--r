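#' Minimum self-folding free energy of an RNA sequence
#'
#' Predicts the minimum free energy (MFE) of the sequence's secondary
#' structure. Two engines are available:
#' \itemize{
#'   \item \code{"vienna"}: the ViennaRNA \code{RNAfold} program (full
#'     Turner energy model), invoked in batch; requires \code{RNAfold} on
#'     the \code{PATH}.
#'   \item \code{"bundled"}: a lightweight stacking energy model computed
#'     by dynamic programming. Allowed pairs are GC/CG, AU/UA and the
#'     GU/UG wobble, hairpin loops must contain at least 3 unpaired
#'     bases, and only stacked (helix-internal) pairs contribute energy:
#'     a stack of pairs p1 on p2 contributes \eqn{-(s(p1)+s(p2))/2} with
#'     \eqn{s(GC)=3}, \eqn{s(AU)=2}, \eqn{s(GU)=1} kcal/mol. Isolated
#'     pairs are energetically neutral, so a sequence with no
#'     complementary stretch of length 2 or more has MFE 0 (unfolded).
#' }
#' The open chain has energy 0, so the MFE is never positive.
#'
#' @param seq RNA (or DNA; T is read as U) sequence, character vector.
#' @param engine \code{"auto"} (ViennaRNA when available, else bundled),
#'   \code{"vienna"}, or \code{"bundled"}.
#' @return Numeric vector of MFE values in kcal/mol (all <= 0).
#' @export
selfFoldingMFE <- function(seq, engine = c("auto", "vienna", "bundled")) {
  engine <- match.arg(engine)
  if (engine == "auto") {
    engine <- if (nzchar(Sys.which("RNAfold"))) "vienna" else "bundled"
  }
  seq <- chartr("tT", "uU", toupper(seq))
  seq <- chartr("T", "U", seq)
  if (any(!nzchar(seq))) stop("empty sequence")
  if (engine == "vienna") .mfeVienna(seq) else .mfeBundled(seq)
}

.mfeVienna <- function(seqs) {
  out <- system2("RNAfold", c("--noPS"),
    input = paste(seqs, collapse = "\n"),
    stdout = TRUE, stderr = FALSE
  )
  # every second line ends in "( -1.20 )" (or "(  0.00)")
  energy_lines <- out[seq(2, length(out), by = 2)]
  m <- regmatches(
    energy_lines,
    regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)$", energy_lines)
  )
  as.numeric(gsub("[()\\s]", "", gsub("[() ]", "", m)))
}

.BP_SCORE <- c(
  "GC" = 3, "CG" = 3, "AU" = 2, "UA" = 2, "GU" = 1, "UG" = 1
)

.mfeBundled <- function(seqs) {
  vapply(seqs, .mfeBundledOne, numeric(1), USE.NAMES = FALSE)
}

# DP over (i,j) intervals; V(i,j) = best energy with i,j paired, W(i,j) =
# best energy of any structure on i..j. Only consecutive pairs (stacks)
# carry energy, so V(i,j) = min(W(i+1,j-1), stack + V(i+1,j-1)).
.mfeBundledOne <- function(seq, minloop = 3L) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  if (n < minloop + 2L) {
    return(0)
  }
  pscore <- function(i, j) {
    s <- .BP_SCORE[paste0(b[i], b[j])]
    if (is.na(s)) NA_real_ else s
  }
  V <- matrix(Inf, n, n)
  W <- matrix(0, n, n)
  for (span in seq(minloop + 1L, n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      sij <- pscore(i, j)
      if (!is.na(sij)) {
        best <- W[i + 1L, j - 1L]
        if (j - i - 2L > minloop) {
          sin_ <- pscore(i + 1L, j - 1L)
          if (!is.na(sin_) && is.finite(V[i + 1L, j - 1L])) {
            best <- min(best, -(sij + sin_) / 2 + V[i + 1L, j - 1L])
          }
        }
        V[i, j] <- best
      }
      # decomposition for W
      w <- W[i + 1L, j]
      for (k in seq(i + minloop + 1L, j)) {
        if (is.finite(V[i, k])) {
          rest <- if (k < j) W[k + 1L, j] else 0
          w <- min(w, V[i, k] + rest)
        }
      }
      W[i, j] <- w
    }
  }
  W[1L, n]
}
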