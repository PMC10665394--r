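# Cysteine families, homology subfamilies, dominant sequences and
# per-position residue frequency matrices.

#' Assign mature toxins to cysteine families
#'
#' Families are defined by the number of cysteines in the mature chain:
#' 6C, 8C, 9C and 10C; any other count falls into \code{other}. Toxins with
#' an odd cysteine count carry an unbound (non-disulfide) cysteine and are
#' flagged.
#'
#' @param sequences Character vector of mature sequences.
#' @param ids Optional toxin ids (default \code{names(sequences)} or an
#'   index).
#' @return A data frame with \code{toxin_id}, \code{cys_count},
#'   \code{family}, \code{unbound_cys}.
#' @export
assign_family <- function(sequences, ids = NULL) {
  if (is.null(ids)) ids <- names(sequences) %||% as.character(seq_along(sequences))
  cys <- vapply(sequences, function(s) {
    sum(chars(s) == "C")
  }, integer(1), USE.NAMES = FALSE)
  family <- ifelse(cys %in% c(6L, 8L, 9L, 10L), paste0(cys, "C"), "other")
  data.frame(toxin_id = ids, cys_count = cys, family = family,
             unbound_cys = cys %% 2L == 1L, stringsAsFactors = FALSE)
}

#' Pairwise sequence identity by global alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and gap -1
#' (linear penalty); identity is the number of matched positions divided by
#' the alignment length (including end gaps). Symmetric in its arguments.
#'
#' @param a,b Amino-acid strings.
#' @return Identity in [0, 1].
#' @export
#' @examples
#' pairwise_identity("ACDEF", "ACDFF")   # 0.8
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  letters_ab <- unique(c(chars(a), chars(b)))
  mat <- matrix(0, length(letters_ab), length(letters_ab),
                dimnames = list(letters_ab, letters_ab))
  diag(mat) <- 1
  if ("X" %in% letters_ab) mat["X", "X"] <- 0   # ambiguous never matches
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  len <- nchar(as.character(Biostrings::pattern(aln)))
  Biostrings::nmatch(aln) / len
}

#' All-against-all identity matrix
#'
#' @param sequences Character vector (names used as labels when present).
#' @return Symmetric matrix of pairwise identities with unit diagonal.
#' @export
identity_matrix <- function(sequences) {
  n <- length(sequences)
  m <- diag(1, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- pairwise_identity(sequences[i], sequences[j])
      }
    }
  }
  dimnames(m) <- list(names(sequences), names(sequences))
  m
}

#' Group toxins of one family into homology subfamilies
#'
#' Single-linkage clustering: two toxins join the same subfamily whenever a
#' chain of pairwise identities at or above \code{threshold} connects them.
#' Output ordering is deterministic: subfamilies sorted by size (descending)
#' then by their lexicographically smallest member id; the partition is
#' invariant to input order.
#'
#' @param ids Toxin ids.
#' @param sequences Mature sequences (same length as \code{ids}).
#' @param threshold Identity threshold (default 0.70).
#' @param idm Optional precomputed identity matrix.
#' @return A data frame with \code{toxin_id} and \code{subfamily}
#'   (\code{"SF1"}, \code{"SF2"}, ...).
#' @export
cluster_subfamilies <- function(ids, sequences, threshold = 0.70, idm = NULL) {
  n <- length(ids)
  stopifnot(length(sequences) == n)
  if (is.null(idm)) idm <- identity_matrix(sequences)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (idm[i, j] >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  size <- vapply(groups, length, integer(1))
  minid <- vapply(groups, function(g) min(ids[g]), character(1))
  groups <- groups[order(-size, minid)]
  sub <- character(n)
  for (k in seq_along(groups)) sub[groups[[k]]] <- paste0("SF", k)
  data.frame(toxin_id = ids, subfamily = sub, stringsAsFactors = FALSE)
}

#' Dominant sequence of a subfamily
#'
#' The member with the unique highest transcript count; a tie means the
#' subfamily has no dominant sequence.
#'
#' @param ids Member toxin ids.
#' @param transcript_counts Counts aligned with \code{ids}.
#' @return The dominant toxin id, or NA when the maximum is tied.
#' @export
dominant_sequence <- function(ids, transcript_counts) {
  stopifnot(length(ids) == length(transcript_counts), length(ids) >= 1L)
  mx <- max(transcript_counts)
  top <- ids[transcript_counts == mx]
  if (length(top) == 1L) top else NA_character_
}

#' Center-star multiple alignment
#'
#' A simple progressive aligner sufficient for per-position frequency
#' summaries: the center sequence (highest summed pairwise identity) is
#' aligned pairwise to every other member and gaps are merged
#' (once-a-gap-always-a-gap).
#'
#' @param sequences Character vector (length >= 1).
#' @return Character vector of equal-length aligned rows (gap \code{"-"}),
#'   in input order.
#' @export
center_star_align <- function(sequences) {
  n <- length(sequences)
  if (n == 1L) return(sequences)
  idm <- identity_matrix(sequences)
  ci <- which.max(rowSums(idm))
  center <- sequences[ci]
  nc <- nchar(center)
  alns <- lapply(sequences, function(s) {
    if (identical(s, center)) {
      return(list(c = chars(center), s = chars(s)))
    }
    letters_ab <- unique(c(chars(center), chars(s)))
    mat <- matrix(0, length(letters_ab), length(letters_ab),
                  dimnames = list(letters_ab, letters_ab))
    diag(mat) <- 1
    a <- Biostrings::pairwiseAlignment(
      center, s, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 1)
    list(c = chars(as.character(Biostrings::pattern(a))),
         s = chars(as.character(Biostrings::subject(a))))
  })
  # insertions relative to the center: block k = gaps before center residue k
  ins_blocks <- lapply(alns, function(al) {
    blocks <- vector("list", nc + 1L)
    for (k in seq_len(nc + 1L)) blocks[[k]] <- character(0)
    k <- 1L
    for (p in seq_along(al$c)) {
      if (al$c[p] == "-") {
        blocks[[k]] <- c(blocks[[k]], al$s[p])
      } else {
        k <- k + 1L
      }
    }
    blocks
  })
  ins_max <- vapply(seq_len(nc + 1L), function(k) {
    max(vapply(ins_blocks, function(b) length(b[[k]]), integer(1)))
  }, integer(1))
  aligned_to_center <- lapply(alns, function(al) al$s[al$c != "-"])
  out <- vapply(seq_len(n), function(i) {
    parts <- character(0)
    for (k in seq_len(nc)) {
      blk <- ins_blocks[[i]][[k]]
      parts <- c(parts, blk, rep("-", ins_max[k] - length(blk)),
                 aligned_to_center[[i]][k])
    }
    blk <- ins_blocks[[i]][[nc + 1L]]
    parts <- c(parts, blk, rep("-", ins_max[nc + 1L] - length(blk)))
    paste(parts, collapse = "")
  }, character(1))
  out
}

#' Per-position residue frequency matrix with information content
#'
#' Counts each of the 20 residues plus the gap per alignment column and
#' computes the small-sample-corrected information content in bits:
#' \eqn{IC_j = \log_2 20 - (H_j + (20-1)/(2 \ln 2 \cdot n_j))}, clamped at
#' zero, where \eqn{H_j} is the Shannon entropy of the residue frequencies in
#' column j (gaps excluded from the entropy, counted separately) and
#' \eqn{n_j} the number of non-gap residues.
#'
#' @param aligned Character vector of equal-length aligned rows.
#' @return A list with \code{counts} (21 x L matrix, rows = residues and
#'   \code{"-"}), \code{info} (length-L vector of bits) and \code{n_seq}.
#' @export
frequency_matrix <- function(aligned) {
  if (!length(aligned)) stop("no sequences")
  L <- unique(nchar(aligned))
  if (length(L) != 1L) stop("ragged alignment: rows differ in length")
  rows <- c(AA20, "-")
  mat <- matrix(0L, nrow = length(rows), ncol = L,
                dimnames = list(rows, NULL))
  split_rows <- lapply(aligned, chars)
  for (j in seq_len(L)) {
    col <- vapply(split_rows, `[`, character(1), j)
    tab <- table(factor(col, levels = rows))
    mat[, j] <- as.integer(tab)
  }
  info <- vapply(seq_len(L), function(j) {
    nres <- sum(mat[AA20, j])
    if (nres == 0L) return(0)
    p <- mat[AA20, j] / nres
    p <- p[p > 0]
    h <- -sum(p * log2(p))
    corr <- (length(AA20) - 1) / (2 * log(2) * nres)
    max(0, log2(length(AA20)) - h - corr)
  }, numeric(1))
  list(counts = mat, info = info, n_seq = length(aligned))
}
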