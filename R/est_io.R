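# EST input, six-frame translation, ORF detection and read-length statistics.

#' Read EST records from a nucleotide FASTA file
#'
#' Reads single-pass EST reads from FASTA. Sequences are uppercased and RNA
#' uracil is mapped to thymine; the only residues accepted afterwards are
#' A, C, G, T and N. Record identifiers are the first whitespace-delimited
#' token of each header and must be unique.
#'
#' @param path Path to a FASTA file of nucleotide reads.
#' @return A data frame with columns \code{id}, \code{nt_seq} and
#'   \code{length} (nucleotides), one row per FASTA entry.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">e1", "ATGTAA"), fa)
#' read_est_fasta(fa)
read_est_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # quick structural check so parse errors can name the offending line
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) && !startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("malformed FASTA: line ", nonempty[1],
         " does not start a record ('>' expected): ",
         substr(lines[nonempty[1]], 1, 40))
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) {
    return(data.frame(id = character(), nt_seq = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("malformed FASTA: empty record id")
  if (anyDuplicated(ids)) {
    stop("duplicate EST id: ", ids[duplicated(ids)][1])
  }
  seqs <- unname(chartr("U", "T", toupper(as.character(set))))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("record '", ids[i], "' contains characters outside {A,C,G,T,N,U}")
  }
  data.frame(id = unname(ids), nt_seq = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

translate_frame <- function(nt, offset) {
  n <- nchar(nt)
  width <- ((n - offset) %/% 3L) * 3L
  if (width < 3L) return("")
  from <- seq(offset + 1L, offset + width, by = 3L)
  aa <- GENCODE[substring(nt, from, from + 2L)]
  aa[is.na(aa)] <- "X"                      # codons containing N
  chartr("*", STOP_CHAR, paste(aa, collapse = ""))
}

#' Six-frame translation of EST reads
#'
#' Translates each read in all six reading frames with the standard genetic
#' code. Frames 1-3 are the forward strand at offsets 0-2; frames 4-6 are the
#' reverse complement at offsets 0-2. Stop codons are rendered as \code{"."}
#' and any codon containing N as \code{"X"}.
#'
#' @param reads A data frame as returned by [read_est_fasta()] (columns
#'   \code{id}, \code{nt_seq}), or a single nucleotide string.
#' @return A data frame with columns \code{est_id}, \code{frame} (1-6) and
#'   \code{aa_seq}.
#' @export
six_frame_translate <- function(reads) {
  if (is.character(reads)) {
    reads <- data.frame(id = "seq1", nt_seq = toupper(reads),
                        stringsAsFactors = FALSE)
  }
  if (any(nchar(reads$nt_seq) < 3L)) {
    stop("sequences shorter than 3 nt cannot be translated")
  }
  out <- lapply(seq_len(nrow(reads)), function(i) {
    nt <- reads$nt_seq[i]
    rc <- revcomp(nt)
    aa <- c(vapply(0:2, function(o) translate_frame(nt, o), character(1)),
            vapply(0:2, function(o) translate_frame(rc, o), character(1)))
    data.frame(est_id = reads$id[i], frame = 1:6, aa_seq = aa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

orfs_in_frame <- function(aa, min_len, all_starts) {
  cc <- chars(aa)
  n <- length(cc)
  if (n == 0L) return(NULL)
  stops <- which(cc == STOP_CHAR)
  seg_start <- c(1L, stops + 1L)
  seg_end <- c(stops - 1L, n)            # inclusive, may be < start (empty)
  seg_has_stop <- c(rep(TRUE, length(stops)), FALSE)
  keep <- seg_end >= seg_start
  res <- list()
  for (k in which(keep)) {
    seg <- cc[seg_start[k]:seg_end[k]]
    mets <- which(seg == "M")
    if (!length(mets)) next
    starts <- if (all_starts) mets else mets[1]
    for (m in starts) {
      s0 <- seg_start[k] + m - 1L
      prot <- paste(seg[m:length(seg)], collapse = "")
      if (nchar(prot) < min_len) next
      res[[length(res) + 1L]] <- data.frame(
        start_aa = s0 - 1L,              # 0-based
        end_aa = seg_end[k],             # 0-based exclusive
        has_stop = seg_has_stop[k],
        protein = prot,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

#' Detect open reading frames in translated frames
#'
#' Reports Met-to-stop (or Met-to-end, \code{has_stop = FALSE}) segments of at
#' least \code{min_len} residues. Within one stop-bounded segment only the
#' longest ORF (first Met) is reported unless \code{all_starts = TRUE}.
#'
#' @param frames Data frame from [six_frame_translate()].
#' @param min_len Minimum protein length in residues (default 40; partial
#'   reads of toxin precursors must still pass).
#' @param all_starts Report every internal Met start as its own ORF.
#' @return A data frame with columns \code{est_id}, \code{frame},
#'   \code{start_aa}, \code{end_aa} (0-based half-open within the frame
#'   translation), \code{has_stop} and \code{protein} (no stop symbol).
#' @export
detect_orfs <- function(frames, min_len = 40L, all_starts = FALSE) {
  stopifnot(min_len >= 1L)
  out <- lapply(seq_len(nrow(frames)), function(i) {
    df <- orfs_in_frame(frames$aa_seq[i], min_len, all_starts)
    if (is.null(df)) return(NULL)
    cbind(data.frame(est_id = frames$est_id[i], frame = frames$frame[i],
                     stringsAsFactors = FALSE), df)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(est_id = character(), frame = integer(),
                      start_aa = integer(), end_aa = integer(),
                      has_stop = logical(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read-length statistics
#'
#' @param records Data frame from [read_est_fasta()] or an integer vector of
#'   lengths.
#' @return A list with \code{n}, \code{median} and a \code{histogram} data
#'   frame of 100-nt bins (\code{bin_start}, \code{bin_end}, \code{count}).
#' @export
length_stats <- function(records) {
  lens <- if (is.data.frame(records)) records$length else as.integer(records)
  if (!length(lens)) stop("no records: length statistics need at least one read")
  breaks <- seq(0L, (max(lens) %/% 100L + 1L) * 100L, by = 100L)
  counts <- table(cut(lens, breaks = breaks, right = FALSE))
  list(
    n = length(lens),
    median = stats::median(lens),
    histogram = data.frame(
      bin_start = utils::head(breaks, -1L),
      bin_end = breaks[-1L],
      count = as.integer(counts))
  )
}
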