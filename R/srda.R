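# Single-residue distribution analysis (SRDA): the cysteine-spacing encoding
# of a protein and the motif pattern language used to recognise toxin
# frameworks, with precedence-ordered read classification.

TOK_C <- 1L
TOK_SPACER <- 2L
TOK_STOP <- 3L

#' Encode a protein as its cysteine-spacing (SRDA) line
#'
#' A protein is reduced to the ordered sequence of its cysteines, the lengths
#' of the non-cysteine runs between them, and an optional terminal stop
#' symbol. Adjacent cysteines produce adjacent \code{C} tokens (a zero-length
#' spacer is never emitted), so \code{"AACCAAC."} serialises to
#' \code{"2CC2C."}. 'X' (ambiguous residue) counts toward spacer lengths and
#' never encodes as a cysteine. If an internal stop is present, the encoding
#' covers the sequence up to and including the first stop and the result is
#' flagged as truncated.
#'
#' @param aa_seq Amino-acid string over the 20 residues plus \code{X}, with an
#'   optional terminal \code{"."}.
#' @return An object of class \code{srda_encoding}: a list with \code{type}
#'   (token types), \code{n} (spacer lengths), \code{start}/\code{end}
#'   (0-based half-open residue spans per token), \code{length},
#'   \code{truncated}.
#' @export
#' @examples
#' srda_format(srda_encode("AACCAAC."))
srda_encode <- function(aa_seq) {
  cc <- chars(aa_seq)
  stop_at <- which(cc == STOP_CHAR)
  truncated <- FALSE
  if (length(stop_at)) {
    if (stop_at[1] < length(cc)) truncated <- TRUE
    cc <- cc[seq_len(stop_at[1])]
  }
  n <- length(cc)
  if (n == 0L) {
    return(structure(list(type = integer(0), n = integer(0),
                          start = integer(0), end = integer(0),
                          length = 0L, truncated = truncated),
                     class = "srda_encoding"))
  }
  cls <- ifelse(cc == "C", "C", ifelse(cc == STOP_CHAR, ".", "S"))
  r <- rle(cls)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  type <- vector("list", length(r$values))
  sp <- vector("list", length(r$values))
  st <- vector("list", length(r$values))
  en <- vector("list", length(r$values))
  for (k in seq_along(r$values)) {
    if (r$values[k] == "C") {
      idx <- run_start[k]:run_end[k]
      type[[k]] <- rep(TOK_C, length(idx))
      sp[[k]] <- rep(NA_integer_, length(idx))
      st[[k]] <- idx - 1L; en[[k]] <- idx
    } else if (r$values[k] == ".") {
      type[[k]] <- TOK_STOP; sp[[k]] <- NA_integer_
      st[[k]] <- run_start[k] - 1L; en[[k]] <- run_end[k]
    } else {
      type[[k]] <- TOK_SPACER; sp[[k]] <- r$lengths[k]
      st[[k]] <- run_start[k] - 1L; en[[k]] <- run_end[k]
    }
  }
  structure(list(type = unlist(type), n = unlist(sp), start = unlist(st),
                 end = unlist(en), length = n, truncated = truncated),
            class = "srda_encoding")
}

#' Serialise an SRDA encoding
#'
#' @param enc An \code{srda_encoding}.
#' @return The serialised line, e.g. \code{"2CC2C."}.
#' @export
srda_format <- function(enc) {
  paste(ifelse(enc$type == TOK_C, "C",
        ifelse(enc$type == TOK_STOP, STOP_CHAR, as.character(enc$n))),
        collapse = "")
}

#' Recover cysteine positions from an SRDA encoding
#'
#' @param enc An \code{srda_encoding}.
#' @return 0-based cysteine positions in the source sequence.
#' @export
srda_cys_positions <- function(enc) {
  enc$start[enc$type == TOK_C]
}

#' @export
print.srda_encoding <- function(x, ...) {
  cat("<srda_encoding> ", srda_format(x),
      if (x$truncated) " (truncated at internal stop)", "\n", sep = "")
  invisible(x)
}

PAT_C <- 1L
PAT_LIT <- 2L
PAT_HASH <- 3L
PAT_STAR <- 4L
PAT_NEQ <- 5L
PAT_STOP <- 6L

#' Parse a cysteine-framework motif formula
#'
#' The formula language (one token per symbol): \code{C} a cysteine; a digit
#' run an exact inter-cysteine spacer length (multi-digit runs are one
#' number, so \code{"C12C"} is a spacer of 12); \code{#} one spacer of length
#' 1-9, or an empty tail when directly before the terminal stop (digit 0 means
#' no residues between the last cysteine and the stop); \code{*} a gap in the
#' search line spanning any run of cysteine/spacer tokens; \code{.} the
#' translation stop; \code{n} with a trailing side condition such as
#' \code{"(n!=6)"} (or the same with a Unicode not-equal sign) one spacer whose
#' length differs from the stated value. Patterns without a terminal stop may
#' match anywhere.
#'
#' @param formula Formula string, e.g. \code{"C6C*CC*C*C#."}.
#' @param name Optional motif name.
#' @param category One of \code{"general"}, \code{"extended"},
#'   \code{"partial"}.
#' @return An object of class \code{srda_pattern}.
#' @export
parse_motif <- function(formula, name = formula, category = "general") {
  body <- formula
  neq_val <- NA_integer_
  m <- regexpr("\\(\\s*n\\s*(!=|≠)\\s*([0-9]+)\\s*\\)", body, perl = TRUE)
  if (m > 0) {
    cond <- regmatches(body, m)
    neq_val <- as.integer(sub(".*?([0-9]+).*", "\\1", cond))
    body <- trimws(sub("\\(\\s*n\\s*(!=|≠)\\s*[0-9]+\\s*\\)", "", body,
                       perl = TRUE))
  }
  cc <- chars(body)
  type <- integer(0); val <- integer(0)
  i <- 1L
  while (i <= length(cc)) {
    ch <- cc[i]
    if (ch == "C") {
      type <- c(type, PAT_C); val <- c(val, NA_integer_); i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      j <- i
      while (j <= length(cc) && grepl("[0-9]", cc[j])) j <- j + 1L
      type <- c(type, PAT_LIT)
      val <- c(val, as.integer(paste(cc[i:(j - 1L)], collapse = "")))
      i <- j
    } else if (ch == "#") {
      type <- c(type, PAT_HASH); val <- c(val, NA_integer_); i <- i + 1L
    } else if (ch == "*") {
      type <- c(type, PAT_STAR); val <- c(val, NA_integer_); i <- i + 1L
    } else if (ch == STOP_CHAR) {
      type <- c(type, PAT_STOP); val <- c(val, NA_integer_); i <- i + 1L
    } else if (ch == "n") {
      if (is.na(neq_val)) {
        stop("motif parse error at position ", i,
             ": 'n' requires a side condition like (n!=6)")
      }
      type <- c(type, PAT_NEQ); val <- c(val, neq_val); i <- i + 1L
    } else {
      stop("motif parse error at position ", i, ": illegal character '",
           ch, "' in formula '", formula, "'")
    }
  }
  if (any(type == PAT_STOP) && which(type == PAT_STOP)[1] != length(type)) {
    stop("motif parse error: stop symbol must be terminal in '", formula, "'")
  }
  structure(list(type = type, val = val, name = name, category = category,
                 formula = formula),
            class = "srda_pattern")
}

#' Serialise a motif pattern back to its formula string
#'
#' @param pattern An \code{srda_pattern}.
#' @return The formula string (side condition appended when present).
#' @export
format_motif <- function(pattern) {
  parts <- character(length(pattern$type))
  for (i in seq_along(pattern$type)) {
    parts[i] <- switch(pattern$type[i],
      "C", as.character(pattern$val[i]), "#", "*",
      "n", STOP_CHAR)
  }
  body <- paste(parts, collapse = "")
  if (any(pattern$type == PAT_NEQ)) {
    body <- paste0(body, " (n!=", pattern$val[pattern$type == PAT_NEQ][1], ")")
  }
  body
}

#' @export
print.srda_pattern <- function(x, ...) {
  cat("<srda_pattern> ", x$name, " [", x$category, "]: ",
      format_motif(x), "\n", sep = "")
  invisible(x)
}

#' The spider-toxin cysteine framework motifs
#'
#' The eight search motifs in precedence order: four general frameworks
#' (\code{Cys#1}-\code{Cys#4}), two extended (\code{extCys#2},
#' \code{extCys#1}) and two partial (\code{partCys#1}, \code{partCys#2})
#' motifs for C- or N-terminally incomplete reads. Extended/partial hits are
#' flagged as requiring external homology verification.
#'
#' @return A named list of \code{srda_pattern} objects in precedence order.
#' @export
toxin_motifs <- function() {
  spec <- list(
    list("Cys#1",     "C6C*CC*C*C#.",          "general"),
    list("Cys#2",     "C6C*CC*C1C*C1C#.",      "general"),
    list("Cys#3",     "CnC*CC*C*C#. (n!=6)",   "general"),
    list("Cys#4",     "CnC*CC*C1C*C1C#. (n!=6)", "general"),
    list("extCys#2",  "C#C*CC*C1C*C1C",        "extended"),
    list("extCys#1",  "C#C*CC*C*C",            "extended"),
    list("partCys#1", "C*CC*C*C#.",            "partial"),
    list("partCys#2", "C*CC*C1C",              "partial")
  )
  out <- lapply(spec, function(s) parse_motif(s[[2]], s[[1]], s[[3]]))
  names(out) <- vapply(spec, `[[`, character(1), 1L)
  out
}

# Backward dynamic program: E[pi, ti] = minimal end token index e (1-based,
# exclusive) such that pattern[pi..m] matches tokens[ti..e-1]; Inf if none.
srda_match_table <- function(enc, pattern) {
  ttype <- enc$type; tn <- enc$n
  n <- length(ttype); m <- length(pattern$type)
  E <- matrix(Inf, nrow = m + 1L, ncol = n + 1L)
  E[m + 1L, ] <- seq_len(n + 1L)
  for (pi in rev(seq_len(m))) {
    pt <- pattern$type[pi]; pv <- pattern$val[pi]
    nxt <- E[pi + 1L, ]
    row <- rep(Inf, n + 1L)
    if (pt == PAT_STAR) {
      # range-min of next row over runs of non-stop tokens (k >= 0 absorbed)
      rm_ <- rep(Inf, n + 1L)
      rm_[n + 1L] <- nxt[n + 1L]
      if (n >= 1L) {
        for (ti in n:1L) {
          rm_[ti] <- if (ttype[ti] == TOK_STOP) nxt[ti]
                     else min(nxt[ti], rm_[ti + 1L])
        }
      }
      row <- rm_
    } else if (pt == PAT_C) {
      ok <- which(ttype == TOK_C)
      row[ok] <- nxt[ok + 1L]
    } else if (pt == PAT_LIT) {
      ok <- which(ttype == TOK_SPACER & !is.na(tn) & tn == pv)
      row[ok] <- nxt[ok + 1L]
    } else if (pt == PAT_NEQ) {
      ok <- which(ttype == TOK_SPACER & !is.na(tn) & tn != pv)
      row[ok] <- nxt[ok + 1L]
    } else if (pt == PAT_HASH) {
      ok <- which(ttype == TOK_SPACER & !is.na(tn) & tn >= 1L & tn <= 9L)
      row[ok] <- nxt[ok + 1L]
      # empty match directly before the terminal stop (digit 0: C adjacent
      # to the stop symbol)
      if (pi < m && pattern$type[pi + 1L] == PAT_STOP) {
        at_stop <- which(ttype == TOK_STOP)
        row[at_stop] <- pmin(row[at_stop], nxt[at_stop])
      }
    } else if (pt == PAT_STOP) {
      ok <- which(ttype == TOK_STOP)
      row[ok] <- nxt[ok + 1L]
    }
    E[pi, ] <- row
  }
  E
}

#' Match a motif pattern against an SRDA encoding
#'
#' A match aligns the pattern tokens to a contiguous token subsequence of the
#' encoding: \code{C} matches a cysteine token, an exact spacer matches one
#' whole spacer token of that length (\code{"C16C"} never satisfies
#' \code{"C6C"}), \code{#} matches one spacer of length 1-9 or nothing when
#' directly before a matching terminal stop, \code{n (n!=v)} matches one
#' spacer of any other length, \code{*} matches any (possibly empty) run of
#' cysteine/spacer tokens (it never crosses a stop), and \code{.} matches the
#' stop token. Overlapping hits are de-duplicated leftmost-shortest.
#'
#' @param enc An \code{srda_encoding} (or amino-acid string, encoded on the
#'   fly).
#' @param pattern An \code{srda_pattern} (or formula string).
#' @return A data frame of matches with 1-based token span
#'   (\code{token_start}, \code{token_end} exclusive) and 0-based half-open
#'   residue interval (\code{res_start}, \code{res_end}); zero rows when the
#'   pattern does not occur.
#' @export
#' @examples
#' nrow(match_motif("C6C5CC1C4C3.", toxin_motifs()[["Cys#1"]]) ) > 0
match_motif <- function(enc, pattern) {
  if (is.character(enc)) enc <- srda_encode(enc)
  if (is.character(pattern)) pattern <- parse_motif(pattern)
  n <- length(enc$type)
  empty <- data.frame(token_start = integer(), token_end = integer(),
                      res_start = integer(), res_end = integer())
  if (n == 0L) return(empty)
  E <- srda_match_table(enc, pattern)
  hits <- list()
  ti <- 1L
  while (ti <= n) {
    e <- E[1L, ti]
    if (is.finite(e) && e > ti) {
      hits[[length(hits) + 1L]] <- data.frame(
        token_start = ti, token_end = as.integer(e),
        res_start = enc$start[ti], res_end = enc$end[e - 1L])
      ti <- as.integer(e)           # skip overlapping hits
    } else {
      ti <- ti + 1L
    }
  }
  if (!length(hits)) return(empty)
  do.call(rbind, hits)
}

#' Does a motif match an amino-acid sequence at least once?
#'
#' Convenience wrapper around [srda_encode()] and [match_motif()]. Sequences
#' with internal stops are matched segment by segment (each stop-terminated
#' segment keeps its stop), so a motif anchored at a stop can hit any coding
#' segment of a full frame translation.
#'
#' @param aa_seq Amino-acid string (may contain internal stops).
#' @param pattern An \code{srda_pattern}.
#' @return \code{TRUE} if any segment matches.
#' @export
motif_hits_sequence <- function(aa_seq, pattern) {
  nrow(match_motif_frame(aa_seq, pattern)) > 0L
}

# Match against a full frame translation: split at stops, each segment keeps
# its terminal stop, residue coordinates are reported in frame coordinates.
match_motif_frame <- function(aa_seq, pattern) {
  segs <- frame_segments(aa_seq)
  n_cys_pat <- sum(pattern$type == PAT_C)
  out <- list()
  for (s in segs) {
    if (s$n_cys < n_cys_pat) next
    mm <- match_motif(s$enc, pattern)
    if (nrow(mm)) {
      mm$res_start <- mm$res_start + s$offset
      mm$res_end <- mm$res_end + s$offset
      mm$encoded <- srda_format(s$enc)
      out[[length(out) + 1L]] <- mm
    }
  }
  if (!length(out)) {
    return(data.frame(token_start = integer(), token_end = integer(),
                      res_start = integer(), res_end = integer(),
                      encoded = character()))
  }
  do.call(rbind, out)
}

frame_segments <- function(aa_seq) {
  cc <- chars(aa_seq)
  stops <- which(cc == STOP_CHAR)
  bounds <- c(0L, stops)                       # segment k: (bounds[k], next]
  segs <- list()
  for (k in seq_along(bounds)) {
    from <- bounds[k] + 1L
    to <- if (k < length(bounds)) bounds[k + 1L] else length(cc)
    if (to < from) next
    n_cys <- sum(cc[from:to] == "C")
    if (n_cys == 0L) next                      # no motif can match
    seg <- paste(cc[from:to], collapse = "")
    segs[[length(segs) + 1L]] <- list(
      enc = srda_encode(seg),
      offset = from - 1L,
      n_cys = n_cys)
  }
  segs
}

# First (precedence-ordered) motif that matches an amino-acid sequence, or
# NA. Used to anchor ORFs and to screen synthetic reads.
first_motif_hit <- function(aa_seq, motifs, n_cys_pat) {
  n_cys <- sum(chars(aa_seq) == "C")
  for (mi in seq_along(motifs)) {
    if (n_cys < n_cys_pat[mi]) next
    if (motif_hits_sequence(aa_seq, motifs[[mi]])) return(names(motifs)[mi])
  }
  NA_character_
}

# First (precedence-ordered) motif hit for one read given its six frame
# translations; segments are encoded once and shared across motifs.
classify_one_read <- function(aa_by_frame, motifs, n_cys_pat) {
  segs_by_frame <- lapply(aa_by_frame, frame_segments)
  for (mi in seq_along(motifs)) {
    for (fi in seq_along(segs_by_frame)) {
      for (s in segs_by_frame[[fi]]) {
        if (s$n_cys < n_cys_pat[mi]) next
        mm <- match_motif(s$enc, motifs[[mi]])
        if (nrow(mm)) {
          return(list(mi = mi, fi = fi,
                      res_start = mm$res_start[1] + s$offset,
                      res_end = mm$res_end[1] + s$offset,
                      encoded = srda_format(s$enc)))
        }
      }
    }
  }
  NULL
}

#' Classify EST reads by cysteine framework motif
#'
#' Each read is tested motif by motif, in precedence order, across all six
#' frame translations (lowest frame wins for reporting); the first motif that
#' matches any frame claims the read, so every read contributes to at most one
#' motif's impact count. Extended and partial motif hits are flagged as
#' requiring external homology verification.
#'
#' @param frames Data frame from [six_frame_translate()].
#' @param motifs Named list of \code{srda_pattern}s in precedence order
#'   (default [toxin_motifs()]).
#' @return A data frame with one row per read: \code{est_id}, \code{motif}
#'   (NA when no motif matches), \code{frame}, \code{res_start},
#'   \code{res_end}, \code{encoded}, \code{needs_verification}. The per-motif
#'   impact counts are attached as attribute \code{"impacts"} (named integer
#'   vector; their sum is the toxin-candidate read count).
#' @export
classify_reads <- function(frames, motifs = toxin_motifs()) {
  ids <- unique(frames$est_id)
  n_cys_pat <- vapply(motifs, function(p) sum(p$type == PAT_C), integer(1))
  rows <- vector("list", length(ids))
  for (r in seq_along(ids)) {
    sub <- frames[frames$est_id == ids[r], , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    h <- classify_one_read(sub$aa_seq, motifs, n_cys_pat)
    rows[[r]] <- if (is.null(h)) {
      data.frame(est_id = ids[r], motif = NA_character_,
                 frame = NA_integer_, res_start = NA_integer_,
                 res_end = NA_integer_, encoded = NA_character_,
                 needs_verification = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(
        est_id = ids[r], motif = names(motifs)[h$mi],
        frame = sub$frame[h$fi], res_start = h$res_start,
        res_end = h$res_end, encoded = h$encoded,
        needs_verification =
          motifs[[h$mi]]$category %in% c("extended", "partial"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  impacts <- vapply(names(motifs), function(m) {
    sum(!is.na(res$motif) & res$motif == m)
  }, integer(1))
  attr(res, "impacts") <- impacts
  res
}
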