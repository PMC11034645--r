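# Dense similarity networks: local sequence alignment for proteins and
# fingerprint Dice similarity for drugs. Alignment is exact affine-gap
# dynamic programming (catalogs here are desk scale; no heuristics).

#' BLOSUM50 substitution matrix
#'
#' The standard BLOSUM50 amino-acid scoring table (from Biostrings).
#'
#' @return integer matrix of substitution scores.
#' @export
blosum50 <- function() {
  e <- new.env()
  utils::data("BLOSUM50", package = "Biostrings", envir = e)
  e$BLOSUM50
}

#' Smith-Waterman local alignment score
#'
#' Best local alignment score under an affine gap model in which a gap of
#' length L costs `gap_open + gap_extend * (L - 1)` (EMBOSS `water`
#' semantics). Returns 0 when no positive-scoring local alignment exists.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param substitution substitution score matrix (default [blosum50()]).
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return non-negative alignment score.
#' @export
smith_waterman_score <- function(seq_a, seq_b, substitution = blosum50(),
                                 gap_open = 10, gap_extend = 0.5) {
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  unknown <- setdiff(c(a, b), rownames(substitution))
  if (length(unknown)) stop_probkg("residue '%s' not in substitution table", unknown[1])
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return(0)
  S <- substitution[a, b, drop = FALSE]
  H <- matrix(0, n + 1L, m + 1L)   # best local score ending at (i, j)
  E <- matrix(-Inf, n + 1L, m + 1L) # gap in seq_a (consumes b)
  F <- matrix(-Inf, n + 1L, m + 1L) # gap in seq_b (consumes a)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1L] - gap_open, E[i, j - 1L] - gap_extend)
      F[i, j] <- max(H[i - 1L, j] - gap_open, F[i - 1L, j] - gap_extend)
      h <- max(0, H[i - 1L, j - 1L] + S[i - 1L, j - 1L], E[i, j], F[i, j])
      H[i, j] <- h
      if (h > best) best <- h
    }
  }
  best
}

#' Protein sequence similarity network
#'
#' Pairwise Smith-Waterman scores normalized by the geometric mean of the
#' self-alignment scores: `sim[i, j] = SW(i, j) / sqrt(SW(i, i) * SW(j, j))`.
#' The normalization bounds entries in `[0, 1]` with unit diagonal so the
#' grid satisfies the probabilistic-adjacency contract; set
#' `normalize = FALSE` for raw scores.
#'
#' @param sequences named character vector of sequences, or a FASTA path;
#'   one sequence per catalogued protein id.
#' @param protein_ids optional ordered id vector (defaults to the names of
#'   `sequences`); every id must have a sequence.
#' @param normalize divide by geometric-mean self-scores (default TRUE).
#' @param ... passed to [smith_waterman_score()].
#' @return symmetric similarity matrix with unit diagonal.
#' @export
protein_similarity_matrix <- function(sequences, protein_ids = NULL,
                                      normalize = TRUE, ...) {
  if (is.character(sequences) && length(sequences) == 1 && file.exists(sequences)) {
    ss <- Biostrings::readAAStringSet(sequences)
    sequences <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  ids <- protein_ids %||% names(sequences)
  missing <- setdiff(ids, names(sequences))
  if (length(missing)) stop_probkg("missing sequence for protein '%s'", missing[1])
  sequences <- sequences[ids]
  n <- length(ids)
  sw <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- smith_waterman_score(sequences[[i]], sequences[[j]], ...)
      sw[i, j] <- s; sw[j, i] <- s
    }
  }
  if (!normalize) return(sw)
  self <- diag(sw)
  if (any(self <= 0)) stop_probkg("non-positive self-alignment score; cannot normalize")
  out <- sw / sqrt(outer(self, self))
  # numerical guard: scores are exact, but clamp roundoff above 1
  out[out > 1] <- 1
  out
}

#' Drug structural similarity network from fingerprint bit-sets
#'
#' Dice similarity `2 |A n B| / (|A| + |B|)` over on-bit index sets, e.g.
#' Morgan fingerprints of radius 2 computed by an external cheminformatics
#' tool. Two empty fingerprints give 0 with a warning.
#'
#' @param fingerprints named list of integer vectors (on-bit indices) per
#'   drug id, or a TSV path with header `drug_id<TAB>bits` where `bits` is a
#'   comma-separated index list.
#' @param drug_ids optional ordered id vector (defaults to names).
#' @return symmetric similarity matrix; diagonal is 1 for non-empty
#'   fingerprints.
#' @export
drug_similarity_matrix <- function(fingerprints, drug_ids = NULL) {
  if (is.character(fingerprints) && length(fingerprints) == 1 && file.exists(fingerprints)) {
    tab <- utils::read.delim(fingerprints, colClasses = "character")
    fingerprints <- stats::setNames(
      lapply(tab[[2]], function(x) {
        if (!nzchar(x)) integer(0) else as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
      }),
      tab[[1]])
  }
  ids <- drug_ids %||% names(fingerprints)
  missing <- setdiff(ids, names(fingerprints))
  if (length(missing)) stop_probkg("missing fingerprint for drug '%s'", missing[1])
  fp <- lapply(fingerprints[ids], unique)
  n <- length(ids)
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  warned <- FALSE
  for (i in seq_len(n)) {
    for (j in i:n) {
      na <- length(fp[[i]]); nb <- length(fp[[j]])
      if (na + nb == 0L) {
        if (!warned) {
          warning("two empty fingerprints; Dice similarity defined as 0")
          warned <- TRUE
        }
        s <- 0
      } else {
        s <- 2 * length(intersect(fp[[i]], fp[[j]])) / (na + nb)
      }
      sim[i, j] <- s; sim[j, i] <- s
    }
  }
  sim
}
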