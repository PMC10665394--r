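# Precursor annotation: signal peptide, propeptide quadruplet cleavage,
# start-codon choice, and enumeration of C-terminally processed mature
# variants.

#' Built-in signal peptidase cleavage heuristic
#'
#' A lightweight stand-in for a dedicated signal peptide predictor, intended
#' for synthetic data and rough screening; reproducing published counts on
#' real data requires ingesting external predictions
#' ([ingest_signal_predictions()]). Candidate cut sites between
#' \code{min_site} and \code{max_site} residues are scored as a weighted sum
#' of the mean Kyte-Doolittle hydropathy of the 8-residue window upstream of
#' the cut (normalised to [0,1]) and bonuses for small residues (A,G,S,C,T)
#' at the -1 and -3 positions; the best-scoring site wins if it clears
#' \code{threshold}.
#'
#' @param protein Amino-acid string (precursor candidate, N-terminus first).
#' @param min_site,max_site Candidate cleavage sites (0-based index of the
#'   first mature-side residue), default 15-35.
#' @param threshold Minimum accepted score in [0,1].
#' @return A list with \code{cleavage_site} (NA when no credible signal),
#'   \code{score} and \code{source = "builtin"}.
#' @export
predict_signal_cleavage <- function(protein, min_site = 15L, max_site = 35L,
                                    threshold = 0.45) {
  no_signal <- list(cleavage_site = NA_integer_, score = 0, source = "builtin")
  n <- nchar(protein)
  if (n < 25L) return(no_signal)
  cc <- chars(protein)
  hi <- max(min(max_site, n - 5L), min_site)
  sites <- min_site:hi
  scores <- vapply(sites, function(cs) {
    win <- cc[max(1L, cs - 7L):cs]            # 8 residues upstream of the cut
    kd <- mean(KD_HYDROPATHY[win], na.rm = TRUE)
    s <- 0.7 * (kd + 4.5) / 9
    if (cc[cs] %in% SMALL_RESIDUES) s <- s + 0.15       # -1 position
    if (cs >= 3L && cc[cs - 2L] %in% SMALL_RESIDUES) s <- s + 0.15  # -3
    s
  }, numeric(1))
  best <- which.max(scores)
  if (scores[best] < threshold) return(no_signal)
  list(cleavage_site = sites[best], score = unname(scores[best]),
       source = "builtin")
}

#' Ingest externally produced signal peptide predictions
#'
#' Reads a TSV with columns \code{id} and \code{cleavage_site} (0-based index
#' of the first mature-side residue) and an optional \code{score}. External
#' predictions override the built-in heuristic. Duplicated ids keep the last
#' row with a warning.
#'
#' @param path TSV path.
#' @return A named list mapping id to a prediction list
#'   (\code{cleavage_site}, \code{score}, \code{source = "external"}).
#' @export
ingest_signal_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(list())
  if (!all(c("id", "cleavage_site") %in% names(df))) {
    stop("signal prediction TSV needs columns 'id' and 'cleavage_site'")
  }
  if (anyDuplicated(df$id)) {
    warning("duplicate ids in signal predictions; last entry wins")
    df <- df[!duplicated(df$id, fromLast = TRUE), , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    list(cleavage_site = as.integer(df$cleavage_site[i]),
         score = if ("score" %in% names(df)) df$score[i] else NA_real_,
         source = "external")
  })
  names(out) <- df$id
  out
}

#' Choose the initiator methionine for a precursor
#'
#' The Met closest downstream within 20-27 residues upstream of the signal
#' peptidase site is taken as the start codon; if no Met falls in that
#' window, the nearest Met within 15-35 residues is used; otherwise the
#' sequence is considered partial.
#'
#' @param protein Amino-acid string in which the cleavage site is expressed.
#' @param cleavage_site 0-based index of the first mature-side residue of the
#'   signal peptidase cut.
#' @return 0-based index of the chosen Met, or NA (partial).
#' @export
select_start_codon <- function(protein, cleavage_site) {
  cc <- chars(protein)
  mets <- which(cc == "M") - 1L                 # 0-based
  mets <- mets[mets < cleavage_site]
  if (!length(mets)) return(NA_integer_)
  d <- cleavage_site - mets
  in_win <- d >= 20L & d <= 27L
  if (any(in_win)) return(mets[in_win][which.min(d[in_win])])
  fallback <- d >= 15L & d <= 35L
  if (any(fallback)) return(mets[fallback][which.min(d[fallback])])
  NA_integer_
}

#' Locate the propeptide cleavage site via the XXKR/XXRR quadruplet
#'
#' Mature spider toxins are preceded by a processing quadruplet ending in KR
#' or RR. The region between the end of the signal peptide and the first
#' mature-region cysteine is scanned for quadruplets (four residues, none
#' ambiguous) ending in KR or RR; the mature chain starts directly after the
#' R of the most C-terminal such quadruplet. Without a quadruplet (or without
#' any downstream cysteine, which is flagged) the mature chain starts at the
#' signal peptide end, i.e. there is no propeptide.
#'
#' @param protein Amino-acid string.
#' @param signal_end 0-based index of the first residue after the signal
#'   peptide.
#' @return A list with \code{mature_start} (0-based) and \code{no_cys}
#'   (TRUE when no cysteine lies downstream of the signal).
#' @export
find_propeptide_cleavage <- function(protein, signal_end) {
  cc <- chars(protein)
  n <- length(cc)
  cys <- which(cc == "C") - 1L
  cys <- cys[cys >= signal_end]
  if (!length(cys)) {
    return(list(mature_start = signal_end, no_cys = TRUE))
  }
  first_cys <- cys[1]
  mature_start <- signal_end
  p <- signal_end                               # 0-based quadruplet start
  while (p + 4L <= first_cys) {
    quad <- cc[(p + 1L):(p + 4L)]
    tail2 <- paste(quad[3:4], collapse = "")
    if (!any(quad == "X") && tail2 %in% c("KR", "RR")) {
      mature_start <- p + 4L                    # most C-terminal wins
    }
    p <- p + 1L
  }
  list(mature_start = mature_start, no_cys = FALSE)
}

#' Enumerate processed mature-toxin variants
#'
#' Emits the untrimmed mature sequence, then successive carboxypeptidase
#' trims removing up to \code{trim_depth} C-terminal basic residues (K or R)
#' one at a time, and, for every intermediate ending in glycine, the amidated
#' variant in which that glycine is consumed by peptidylglycine
#' alpha-amidating monooxygenase (the preceding residue carries the amide;
#' amidation is a flag, never a sequence character). Variants are
#' de-duplicated by (sequence, amidated).
#'
#' @param mature_seq Mature amino-acid string.
#' @param trim_depth Maximum number of C-terminal K/R removed (default 2,
#'   which covers the canonical ...G-K-R amidation cassette).
#' @return A data frame with columns \code{variant_id}, \code{sequence},
#'   \code{amidated}, \code{provenance} (\code{full},
#'   \code{carboxypeptidase-trimmed} or \code{amidated}); the first row is
#'   always the untrimmed sequence.
#' @export
#' @examples
#' generate_mature_variants("CNTGKR")
generate_mature_variants <- function(mature_seq, trim_depth = 2L) {
  stopifnot(nzchar(mature_seq))
  rows <- list()
  add <- function(sequence, amidated, provenance) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sequence = sequence, amidated = amidated, provenance = provenance,
      stringsAsFactors = FALSE)
  }
  emit_amidated <- function(s) {
    if (nchar(s) > 1L && substr(s, nchar(s), nchar(s)) == "G") {
      add(substr(s, 1L, nchar(s) - 1L), TRUE, "amidated")
    }
  }
  cur <- mature_seq
  add(cur, FALSE, "full")
  emit_amidated(cur)
  trims <- 0L
  while (trims < trim_depth && nchar(cur) > 1L &&
         substr(cur, nchar(cur), nchar(cur)) %in% c("K", "R")) {
    cur <- substr(cur, 1L, nchar(cur) - 1L)
    trims <- trims + 1L
    add(cur, FALSE, "carboxypeptidase-trimmed")
    emit_amidated(cur)
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$sequence, out$amidated)), , drop = FALSE]
  out$variant_id <- paste0("v", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("variant_id", "sequence", "amidated", "provenance")]
}

#' Collapse precursors encoding identical CDS
#'
#' Clones with identical precursor protein sequences collapse to one entry
#' carrying the count of supporting reads (transcript count).
#'
#' @param precursors Data frame with at least columns \code{id} and
#'   \code{protein}.
#' @return One row per distinct protein: the first id encountered,
#'   \code{protein}, \code{transcript_count} and \code{member_ids}
#'   (semicolon-joined).
#' @export
dedup_cds <- function(precursors) {
  if (!nrow(precursors)) {
    return(data.frame(id = character(), protein = character(),
                      transcript_count = integer(), member_ids = character(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(precursors)), precursors$protein)
  sp <- sp[order(vapply(sp, min, integer(1)))]  # stable input order
  do.call(rbind, lapply(sp, function(idx) {
    data.frame(id = precursors$id[idx[1]],
               protein = precursors$protein[idx[1]],
               transcript_count = length(idx),
               member_ids = paste(precursors$id[idx], collapse = ";"),
               stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Annotate toxin-candidate ORFs into precursor segments
#'
#' For each ORF, the signal peptidase site is taken from external predictions
#' when available (keyed by \code{est_id}) and from the built-in heuristic
#' otherwise; the initiator Met is then re-selected relative to that site
#' ([select_start_codon()]), the protein re-anchored at it, and the
#' propeptide boundary located via the quadruplet rule. The segmentation
#' partitions the precursor: signal \code{[0, signal_end)}, propeptide
#' \code{[signal_end, mature_start)} (possibly empty), mature
#' \code{[mature_start, length)}.
#'
#' @param orfs Data frame from [detect_orfs()].
#' @param signals Optional named list from [ingest_signal_predictions()].
#' @param signal_threshold Passed to [predict_signal_cleavage()].
#' @return A data frame with one row per ORF: \code{id}, \code{protein}
#'   (re-anchored at the chosen start), \code{signal_end},
#'   \code{mature_start}, \code{start_codon_aa} (offset of the chosen Met in
#'   the original ORF protein), \code{completeness}, \code{has_signal},
#'   \code{mature} (mature sequence).
#' @export
annotate_precursors <- function(orfs, signals = NULL,
                                signal_threshold = 0.45) {
  rows <- lapply(seq_len(nrow(orfs)), function(i) {
    prot <- orfs$protein[i]
    id <- orfs$est_id[i]
    pred <- if (!is.null(signals) && !is.null(signals[[id]])) {
      signals[[id]]
    } else {
      predict_signal_cleavage(prot, threshold = signal_threshold)
    }
    base <- data.frame(id = id, protein = prot, signal_end = NA_integer_,
                       mature_start = NA_integer_, start_codon_aa = NA_integer_,
                       completeness = "partial", has_signal = FALSE,
                       mature = NA_character_, stringsAsFactors = FALSE)
    cs <- pred$cleavage_site
    if (is.na(cs)) return(base)
    start <- select_start_codon(prot, cs)
    partial_start <- is.na(start)
    if (partial_start) start <- 0L
    prot2 <- substr(prot, start + 1L, nchar(prot))
    cs2 <- cs - start
    pp <- find_propeptide_cleavage(prot2, cs2)
    base$protein <- prot2
    base$signal_end <- cs2
    base$mature_start <- pp$mature_start
    base$start_codon_aa <- start
    base$has_signal <- TRUE
    base$mature <- substr(prot2, pp$mature_start + 1L, nchar(prot2))
    base$completeness <- if (!partial_start && isTRUE(orfs$has_stop[i]))
      "complete" else "partial"
    base
  })
  do.call(rbind, rows)
}
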