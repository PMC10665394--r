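# High-level pipeline: reads -> translations -> motif classification ->
# toxin-candidate ORFs -> precursor annotation -> mature-variant database.

#' Select the toxin-candidate ORF for each motif-classified read
#'
#' Motif classification runs on full frame translations, so a winning hit
#' can occasionally sit in a frame fragment that is not the coding ORF (a
#' coincidental cysteine arrangement in another frame). Annotation therefore
#' re-anchors at the ORF level: for every read with a winning motif, each of
#' the read's ORFs is tested against the motif list (in precedence order, on
#' the ORF's own translation including its terminal stop), and among
#' motif-bearing ORFs the one whose motif ranks earliest wins (ties: complete
#' before stop-less, then longest protein, then lowest frame). This mirrors
#' the removal of the five non-coding frames after motif search.
#'
#' @param orfs Data frame from [detect_orfs()].
#' @param classification Data frame from [classify_reads()].
#' @param motifs The motif list used for classification.
#' @return The subset of \code{orfs}: at most one row per classified read,
#'   with the anchoring motif in column \code{orf_motif}.
#' @export
select_toxin_orfs <- function(orfs, classification, motifs = toxin_motifs()) {
  cl <- classification[!is.na(classification$motif), , drop = FALSE]
  n_cys_pat <- vapply(motifs, function(p) sum(p$type == 1L), integer(1))
  rows <- lapply(cl$est_id, function(id) {
    cand <- orfs[orfs$est_id == id, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    hit_motif <- vapply(seq_len(nrow(cand)), function(k) {
      aa <- paste0(cand$protein[k], if (cand$has_stop[k]) ".")
      first_motif_hit(aa, motifs, n_cys_pat)
    }, character(1))
    cand <- cand[!is.na(hit_motif), , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand$orf_motif <- hit_motif[!is.na(hit_motif)]
    ord <- order(match(cand$orf_motif, names(motifs)), -cand$has_stop,
                 -nchar(cand$protein), cand$frame)
    cand[ord[1], , drop = FALSE]
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- orfs[0, , drop = FALSE]
    out$orf_motif <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the toxin-mining pipeline on EST reads
#'
#' Convenience wrapper chaining six-frame translation, ORF detection, motif
#' classification, toxin-candidate ORF selection, precursor annotation and
#' CDS de-duplication.
#'
#' @param reads Data frame with \code{id}, \code{nt_seq} (e.g. from
#'   [read_est_fasta()]).
#' @param min_orf_len Minimum ORF protein length (default 40).
#' @param signals Optional external signal predictions
#'   ([ingest_signal_predictions()]).
#' @param motifs Motif list in precedence order (default [toxin_motifs()]).
#' @param trim_depth Carboxypeptidase trim depth for variant generation.
#' @return A list with \code{frames}, \code{orfs}, \code{classification}
#'   (with the \code{"impacts"} attribute), \code{toxin_orfs},
#'   \code{precursors}, \code{unique_precursors} (CDS-deduplicated with
#'   transcript counts) and \code{db} (mature-variant database with
#'   \code{group}/\code{variant_id}/\code{sequence}/\code{amidated}).
#' @export
mine_toxins <- function(reads, min_orf_len = 40L, signals = NULL,
                        motifs = toxin_motifs(), trim_depth = 2L) {
  frames <- six_frame_translate(reads)
  orfs <- detect_orfs(frames, min_len = min_orf_len)
  classification <- classify_reads(frames, motifs)
  torfs <- select_toxin_orfs(orfs, classification, motifs = motifs)
  precursors <- annotate_precursors(torfs, signals = signals)
  uniq <- dedup_cds(precursors[!is.na(precursors$mature), , drop = FALSE])
  db <- do.call(rbind, lapply(seq_len(nrow(uniq)), function(i) {
    prec <- precursors[precursors$id == uniq$id[i], , drop = FALSE][1, ]
    v <- generate_mature_variants(prec$mature, trim_depth = trim_depth)
    cbind(data.frame(group = uniq$id[i], stringsAsFactors = FALSE), v)
  }))
  list(frames = frames, orfs = orfs, classification = classification,
       toxin_orfs = torfs, precursors = precursors,
       unique_precursors = uniq, db = db)
}
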