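# Independent brute-force oracles. These deliberately re-derive results by
# enumeration, not by calling the implementation paths they check.

# Build an amino-acid string from a cysteine-spacing line such as
# "C6C5CC1C4C3." (spacers become runs of 'A').
aa_from_line <- function(line) {
  toks <- regmatches(line, gregexpr("C|[0-9]+|\\.", line))[[1]]
  paste(vapply(toks, function(t) {
    if (t == "C") "C" else if (t == ".") "." else strrep("A", as.integer(t))
  }, character(1)), collapse = "")
}

# Random Cys/spacer sequence (valid encoding by construction).
random_encoding <- function(max_len = 60L, p_cys = 0.3, p_stop = 0.5) {
  len <- sample(10:max_len, 1L)
  cc <- sample(c("C", "A"), len, replace = TRUE, prob = c(p_cys, 1 - p_cys))
  s <- paste(cc, collapse = "")
  if (runif(1) < p_stop) s <- paste0(s, ".")
  srda_encode(s)
}

# Random star-free pattern: C-anchored, alternating spacer-constraint/C, with
# an optional "#." / "." tail.
random_nostar_pattern <- function() {
  parts <- "C"
  for (k in seq_len(sample(1:4, 1L))) {
    sp <- sample(c("lit", "hash", "neq"), 1L)
    parts <- c(parts, switch(sp,
      lit = as.character(sample(1:9, 1L)),
      hash = "#",
      neq = "n"), "C")
  }
  tail <- sample(c("", ".", "#."), 1L)
  formula <- paste0(paste(parts, collapse = ""), tail)
  if (grepl("n", formula, fixed = TRUE)) {
    formula <- paste0(formula, " (n!=", sample(1:9, 1L), ")")
  }
  parse_motif(formula)
}

# Position-by-position window matcher for star-free patterns. For these
# patterns every choice is forced by the current token type, so a single
# left-to-right scan per start decides the match.
oracle_match_nostar <- function(enc, pat) {
  stopifnot(!any(pat$type == 4L))     # no STAR
  n <- length(enc$type)
  m <- length(pat$type)
  for (start in seq_len(max(n, 0L))) {
    ti <- start
    ok <- TRUE
    for (pi in seq_len(m)) {
      pt <- pat$type[pi]; pv <- pat$val[pi]
      if (pt == 3L && pi < m && pat$type[pi + 1L] == 6L &&
          ti <= n && enc$type[ti] == 3L) {
        next                          # HASH matches emptily before the stop
      }
      if (ti > n) { ok <- FALSE; break }
      tt <- enc$type[ti]; tn <- enc$n[ti]
      good <- switch(pt,
        tt == 1L,                               # C
        tt == 2L && tn == pv,                   # LIT
        tt == 2L && tn >= 1L && tn <= 9L,       # HASH
        stop("unreachable"),
        tt == 2L && tn != pv,                   # NEQ
        tt == 3L)                               # STOP
      if (!good) { ok <- FALSE; break }
      ti <- ti + 1L
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# Substring-enumeration digestion oracle: a substring is a valid peptide iff
# its boundaries are protein ends or cleavage boundaries and it spans at most
# max_missed internal boundaries. Cut decisions re-derived from first
# principles per rule.
oracle_digest <- function(protein, rule, max_missed) {
  cc <- strsplit(protein, "")[[1]]
  n <- length(cc)
  is_cut <- vapply(seq_len(max(n - 1L, 0L)), function(b) {
    if (rule$side == "C") {
      cc[b] %in% rule$residues &&
        !(length(rule$no_cut_before) && cc[b + 1L] %in% rule$no_cut_before)
    } else {
      cc[b + 1L] %in% rule$residues
    }
  }, logical(1))
  cuts <- which(is_cut)
  res <- character(0)
  for (s in 0:(n - 1L)) {
    for (e in (s + 1L):n) {
      if (s != 0L && !(s %in% cuts)) next
      if (e != n && !(e %in% cuts)) next
      internal <- sum(cuts > s & cuts < e)
      if (internal > max_missed) next
      res <- c(res, substr(protein, s + 1L, e))
    }
  }
  sort(res)
}

# Brute-force FDR oracle: the largest target set of the form {score >= t}
# whose decoy/target ratio does not exceed alpha.
oracle_fdr <- function(psms, alpha) {
  best <- psms[0, , drop = FALSE]
  for (t in sort(unique(psms$score))) {
    keep <- !psms$decoy & psms$score >= t
    nt <- sum(keep)
    nd <- sum(psms$decoy & psms$score >= t)
    if (nt > 0L && nd / nt <= alpha && nt > nrow(best)) {
      best <- psms[keep, , drop = FALSE]
    }
  }
  best
}

random_protein <- function(len, pool = c("A", "C", "D", "E", "G", "K", "L",
                                         "N", "P", "R", "S", "T", "V")) {
  paste(sample(pool, len, replace = TRUE), collapse = "")
}
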