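# Proteomic validation: in-silico multi-protease digestion, peptide
# uniqueness, target-decoy FDR filtering, toxin identification, isoform
# selection, sequence coverage, amidation evidence and protease-set
# comparison.

#' Protease cleavage rules
#'
#' Returns the rule for one of the four proteases used for venom digestion:
#' trypsin (C-terminal to K/R, by default not before proline), Lys-C
#' (C-terminal to K), Glu-C (C-terminal to E; D can be added for
#' ammonium-bicarbonate conditions) and Asp-N (N-terminal to D).
#'
#' @param name One of \code{"trypsin"}, \code{"lysC"}, \code{"gluC"},
#'   \code{"aspN"}.
#' @param trypsin_proline_rule Suppress trypsin cuts before proline
#'   (default TRUE).
#' @param gluC_de Extend Glu-C specificity to \{E, D\} (default FALSE).
#' @return A list with \code{name}, \code{side} (\code{"C"} or \code{"N"}),
#'   \code{residues}, \code{no_cut_before}.
#' @export
protease_rule <- function(name = c("trypsin", "lysC", "gluC", "aspN"),
                          trypsin_proline_rule = TRUE, gluC_de = FALSE) {
  name <- match.arg(name)
  switch(name,
    trypsin = list(name = name, side = "C", residues = c("K", "R"),
                   no_cut_before = if (trypsin_proline_rule) "P" else character(0)),
    lysC = list(name = name, side = "C", residues = "K",
                no_cut_before = character(0)),
    gluC = list(name = name, side = "C",
                residues = if (gluC_de) c("E", "D") else "E",
                no_cut_before = character(0)),
    aspN = list(name = name, side = "N", residues = "D",
                no_cut_before = character(0))
  )
}

cleavage_sites <- function(protein, rule) {
  cc <- chars(protein)
  n <- length(cc)
  if (n < 2L) return(integer(0))
  b <- seq_len(n - 1L)                      # cut between residue b and b+1
  if (rule$side == "C") {
    ok <- cc[b] %in% rule$residues
    if (length(rule$no_cut_before)) {
      ok <- ok & !(cc[b + 1L] %in% rule$no_cut_before)
    }
  } else {
    ok <- cc[b + 1L] %in% rule$residues
  }
  b[ok]
}

#' In-silico protease digestion
#'
#' Cuts the protein at every site of the rule and reports all peptides
#' spanning at most \code{max_missed} internal (missed) sites. The 0-missed
#' peptides partition the protein.
#'
#' @param protein Amino-acid string.
#' @param rule A rule from [protease_rule()] (or a protease name).
#' @param max_missed Maximum missed cleavages, 0-4 (default 0).
#' @param min_len Minimum peptide length reported (default 1).
#' @return A data frame with \code{sequence}, \code{start}, \code{end}
#'   (0-based half-open in the protein), \code{missed}, \code{is_cterm}.
#' @export
#' @examples
#' digest("AKRPGKC", "trypsin")$sequence   # "AK", "RPGK", "C"
digest <- function(protein, rule, max_missed = 0L, min_len = 1L) {
  if (!nzchar(protein)) stop("cannot digest an empty protein")
  stopifnot(max_missed >= 0L, max_missed <= 4L)
  if (is.character(rule)) rule <- protease_rule(rule)
  n <- nchar(protein)
  bounds <- c(0L, cleavage_sites(protein, rule), n)
  nb <- length(bounds)
  rows <- list()
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + max_missed)) {
      s <- bounds[i]; e <- bounds[j]
      if (e - s < min_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(protein, s + 1L, e),
        start = s, end = e, missed = j - i - 1L, is_cterm = e == n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

collapse_il <- function(x) chartr("I", "L", x)

# All theoretical peptides of a variant database for one protease.
# db: data.frame(group, variant_id, sequence, amidated).
theoretical_peptides <- function(db, protease, max_missed = 0L, min_len = 1L,
                                 il_equiv = TRUE, ...) {
  rule <- protease_rule(protease, ...)
  out <- lapply(seq_len(nrow(db)), function(i) {
    pep <- digest(db$sequence[i], rule, max_missed = max_missed,
                  min_len = min_len)
    cbind(data.frame(group = db$group[i], variant_id = db$variant_id[i],
                     variant_amidated = db$amidated[i],
                     stringsAsFactors = FALSE), pep)
  })
  out <- do.call(rbind, out)
  out$key <- if (il_equiv) collapse_il(out$sequence) else out$sequence
  out$protease <- protease
  out
}

#' Map theoretical peptides to their parent toxin groups
#'
#' Pools the digestion products of every database entry and records, for each
#' distinct peptide, the set of parent toxin groups. Uniqueness is defined at
#' the toxin-group level: a peptide shared only among isoforms of one toxin
#' is still unique. Isoleucine and leucine are treated as indistinguishable
#' by default (they have equal mass).
#'
#' @param db Variant database: data frame with \code{group},
#'   \code{variant_id}, \code{sequence}, \code{amidated}.
#' @param protease Protease name.
#' @param min_len Minimum peptide length (default 5, the usual floor for
#'   informative peptides).
#' @param max_missed Missed cleavages (default 0).
#' @param il_equiv Collapse I/L before comparing (default TRUE).
#' @param ... Passed to [protease_rule()].
#' @return A data frame with one row per distinct peptide key:
#'   \code{peptide} (a representative original sequence), \code{key},
#'   \code{parents} (semicolon-joined group ids), \code{n_parents},
#'   \code{unique}.
#' @export
uniqueness_map <- function(db, protease, min_len = 5L, max_missed = 0L,
                           il_equiv = TRUE, ...) {
  th <- theoretical_peptides(db, protease, max_missed = max_missed,
                             min_len = min_len, il_equiv = il_equiv, ...)
  sp <- split(seq_len(nrow(th)), th$key)
  out <- do.call(rbind, lapply(sp, function(idx) {
    groups <- sort(unique(th$group[idx]))
    data.frame(peptide = th$sequence[idx[1]], key = th$key[idx[1]],
               parents = paste(groups, collapse = ";"),
               n_parents = length(groups), unique = length(groups) == 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$key), , drop = FALSE]
}

#' Target-decoy FDR filtering of peptide-spectrum matches
#'
#' Finds the most permissive score threshold t at which the estimated false
#' discovery rate, decoys(score >= t) / targets(score >= t), does not exceed
#' \code{alpha}, and returns the target PSMs at or above it (ties included).
#' Lowering \code{alpha} never adds PSMs.
#'
#' @param psms Data frame with at least \code{score} and \code{decoy}.
#' @param alpha FDR level (default 0.01).
#' @return The accepted target rows of \code{psms}; zero rows when no
#'   threshold satisfies the level. The threshold is attached as attribute
#'   \code{"threshold"}.
#' @export
fdr_filter <- function(psms, alpha = 0.01) {
  stopifnot(all(c("score", "decoy") %in% names(psms)))
  targets <- psms[!psms$decoy, , drop = FALSE]
  if (!nrow(targets)) {
    out <- psms[0, , drop = FALSE]
    attr(out, "threshold") <- Inf
    return(out)
  }
  cand <- sort(unique(psms$score))
  dec_scores <- psms$score[psms$decoy]
  tgt_scores <- targets$score
  for (t in cand) {
    nd <- sum(dec_scores >= t)
    nt <- sum(tgt_scores >= t)
    if (nt > 0L && nd / nt <= alpha) {
      out <- targets[targets$score >= t, , drop = FALSE]
      attr(out, "threshold") <- t
      return(out)
    }
  }
  out <- targets[0, , drop = FALSE]
  attr(out, "threshold") <- Inf
  out
}

# Match accepted PSMs to theoretical peptides of a variant database.
# A PSM flagged as C-terminally amidated may only match a C-terminal peptide
# of an amidated variant; an unflagged PSM may match any other occurrence.
# Returns list(matches = data.frame(psm_row, protease, key, group,
# variant_id, is_cterm, start, end, unique), unmatched = psm rows).
match_psms <- function(accepted, db, max_missed = 4L, il_equiv = TRUE, ...) {
  proteases <- unique(accepted$protease)
  th_all <- do.call(rbind, lapply(proteases, function(p) {
    theoretical_peptides(db, p, max_missed = max_missed, min_len = 1L,
                         il_equiv = il_equiv, ...)
  }))
  if (is.null(th_all) || !nrow(accepted)) {
    return(list(matches = NULL, unmatched = seq_len(nrow(accepted))))
  }
  index <- split(seq_len(nrow(th_all)), paste(th_all$protease, th_all$key))
  keys <- paste(accepted$protease,
                if (il_equiv) collapse_il(accepted$peptide)
                else accepted$peptide)
  matches <- list()
  unmatched <- integer(0)
  for (i in seq_len(nrow(accepted))) {
    cand <- th_all[index[[keys[i]]], , drop = FALSE]
    amid_cterm <- cand$is_cterm & cand$variant_amidated
    cand <- if (isTRUE(accepted$cterm_amidated[i])) {
      cand[amid_cterm, , drop = FALSE]
    } else {
      cand[!amid_cterm, , drop = FALSE]
    }
    if (!nrow(cand)) {
      unmatched <- c(unmatched, i)
      next
    }
    groups <- sort(unique(cand$group))
    cand$psm_row <- i
    cand$unique <- length(groups) == 1L
    matches[[length(matches) + 1L]] <- cand
  }
  list(
    matches = if (length(matches)) do.call(rbind, matches) else NULL,
    unmatched = unmatched
  )
}

#' Union of residue intervals covered by peptides, as a fraction
#'
#' Locates every occurrence of every peptide in the toxin sequence and
#' reports the fraction of residues covered by the union of the matched
#' intervals (overlaps are not double-counted).
#'
#' @param sequence Toxin amino-acid string.
#' @param peptides Character vector of peptide sequences.
#' @param il_equiv Collapse I/L before locating (default TRUE).
#' @return Coverage in [0, 1].
#' @export
sequence_coverage <- function(sequence, peptides, il_equiv = TRUE) {
  if (!length(peptides)) return(0)
  n <- nchar(sequence)
  covered <- logical(n)
  seq_key <- if (il_equiv) collapse_il(sequence) else sequence
  for (p in unique(peptides)) {
    pk <- if (il_equiv) collapse_il(p) else p
    hits <- gregexpr(pk, seq_key, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (h in hits) covered[h:(h + nchar(pk) - 1L)] <- TRUE
  }
  mean(covered)
}

#' Identify toxins from accepted peptide-spectrum matches
#'
#' Replicates are merged by union. Each accepted PSM is mapped to the
#' theoretical peptides of its protease (observed peptides absent from every
#' theoretical digest are logged as unmatched and excluded). A toxin group is
#' \code{unique_identified} when at least one observed peptide maps to that
#' group alone, \code{group_evidence_only} when only shared peptides support
#' it, and \code{not_detected} otherwise. Among a group's isoforms the one
#' with unique-peptide evidence and the highest unique-peptide coverage is
#' chosen (ties: higher all-peptide coverage, then lexicographic id).
#'
#' @param accepted Accepted PSMs from [fdr_filter()]: columns \code{peptide},
#'   \code{protease}, \code{replicate}, \code{score}, \code{decoy},
#'   \code{cterm_amidated}.
#' @param db Variant database (\code{group}, \code{variant_id},
#'   \code{sequence}, \code{amidated}).
#' @param max_missed Missed-cleavage cap for the theoretical digests
#'   (default 4).
#' @param il_equiv Collapse I/L (default TRUE).
#' @param ... Passed to [protease_rule()].
#' @return A data frame with one row per toxin group: \code{toxin_id},
#'   \code{status}, \code{chosen_isoform}, \code{n_unique_peptides},
#'   \code{n_all_peptides}, \code{coverage_unique}, \code{coverage_all}.
#'   Unmatched observed peptides are attached as attribute
#'   \code{"unmatched"}.
#' @export
identify_toxins <- function(accepted, db, max_missed = 4L, il_equiv = TRUE,
                            ...) {
  groups <- unique(db$group)
  mp <- match_psms(accepted, db, max_missed = max_missed,
                   il_equiv = il_equiv, ...)
  mm <- mp$matches
  res <- lapply(groups, function(g) {
    row <- data.frame(toxin_id = g, status = "not_detected",
                      chosen_isoform = NA_character_,
                      n_unique_peptides = 0L, n_all_peptides = 0L,
                      coverage_unique = 0, coverage_all = 0,
                      stringsAsFactors = FALSE)
    if (is.null(mm)) return(row)
    gm <- mm[mm$group == g, , drop = FALSE]
    if (!nrow(gm)) return(row)
    upep <- unique(gm$key[gm$unique])
    apep <- unique(gm$key)
    row$n_unique_peptides <- length(upep)
    row$n_all_peptides <- length(apep)
    row$status <- if (length(upep)) "unique_identified" else
      "group_evidence_only"
    iso <- db[db$group == g, , drop = FALSE]
    cov_u <- vapply(iso$sequence, sequence_coverage, numeric(1),
                    peptides = upep, il_equiv = il_equiv, USE.NAMES = FALSE)
    cov_a <- vapply(iso$sequence, sequence_coverage, numeric(1),
                    peptides = apep, il_equiv = il_equiv, USE.NAMES = FALSE)
    has_unique_ev <- vapply(seq_len(nrow(iso)), function(k) {
      any(gm$unique & gm$variant_id == iso$variant_id[k])
    }, logical(1))
    ord <- order(-has_unique_ev, -cov_u, -cov_a, iso$variant_id)
    pick <- ord[1]
    row$chosen_isoform <- iso$variant_id[pick]
    row$coverage_unique <- cov_u[pick]
    row$coverage_all <- cov_a[pick]
    row
  })
  out <- do.call(rbind, res)
  attr(out, "unmatched") <- if (length(mp$unmatched))
    accepted$peptide[mp$unmatched] else character(0)
  out
}

#' Select the best-supported isoform of a toxin group
#'
#' @param iso Data frame of the group's isoforms (\code{variant_id},
#'   \code{sequence}).
#' @param unique_peptides,all_peptides Observed peptide sets for the group.
#' @param il_equiv Collapse I/L (default TRUE).
#' @return The chosen \code{variant_id}, or NA when there is no evidence.
#' @export
select_isoform <- function(iso, unique_peptides, all_peptides = unique_peptides,
                           il_equiv = TRUE) {
  if (!length(all_peptides)) return(NA_character_)
  cov_u <- vapply(iso$sequence, sequence_coverage, numeric(1),
                  peptides = unique_peptides, il_equiv = il_equiv,
                  USE.NAMES = FALSE)
  cov_a <- vapply(iso$sequence, sequence_coverage, numeric(1),
                  peptides = all_peptides, il_equiv = il_equiv,
                  USE.NAMES = FALSE)
  iso$variant_id[order(-cov_u, -cov_a, iso$variant_id)][1]
}

#' Amidation evidence categories from C-terminal peptides
#'
#' For each toxin group, the C-terminal peptides of its amidated variants
#' define the amidation site; accepted PSMs with those sequences are counted
#' by their amidation flag (the non-amidated counterpart is the same peptide
#' as a free acid). Categories for toxins with predicted amidation:
#' \code{confirmed_unique} (amidated PSMs only, site peptide unique to the
#' group), \code{confirmed_nonunique_group} (amidated PSMs only, site peptide
#' shared between groups), \code{ambiguous} (both forms observed),
#' \code{not_amidated} (only the free-acid form observed), \code{undefined}
#' (the C-terminal region was never covered). Toxins without predicted
#' amidation are reported as \code{not_amidated} unless amidated evidence
#' unexpectedly appears (then \code{ambiguous}).
#'
#' @param accepted Accepted PSMs ([fdr_filter()]).
#' @param db Variant database.
#' @param max_missed Missed-cleavage cap for C-terminal theoretical peptides
#'   (default 4).
#' @param il_equiv Collapse I/L (default TRUE).
#' @param ... Passed to [protease_rule()].
#' @return A data frame per toxin group: \code{toxin_id}, \code{predicted},
#'   \code{n_amidated}, \code{n_plain}, \code{site_unique}, \code{category}.
#' @export
amidation_evidence <- function(accepted, db, max_missed = 4L,
                               il_equiv = TRUE, ...) {
  groups <- unique(db$group)
  proteases <- unique(accepted$protease)
  th_all <- do.call(rbind, lapply(proteases, function(p) {
    theoretical_peptides(db, p, max_missed = max_missed, min_len = 1L,
                         il_equiv = il_equiv, ...)
  }))
  cterm <- th_all[th_all$is_cterm & th_all$variant_amidated, , drop = FALSE]
  psm_key <- if (il_equiv) collapse_il(accepted$peptide) else accepted$peptide
  res <- lapply(groups, function(g) {
    site_keys <- unique(cterm$key[cterm$group == g])
    predicted <- length(site_keys) > 0L
    site_unique <- NA
    n_amid <- 0L; n_plain <- 0L
    if (predicted) {
      obs <- psm_key %in% site_keys
      n_amid <- sum(obs & accepted$cterm_amidated)
      n_plain <- sum(obs & !accepted$cterm_amidated)
      parents <- unique(cterm$group[cterm$key %in% site_keys])
      site_unique <- length(parents) == 1L
    }
    category <- if (!predicted) {
      "not_amidated"
    } else if (n_amid == 0L && n_plain == 0L) {
      "undefined"
    } else if (n_amid > 0L && n_plain > 0L) {
      "ambiguous"
    } else if (n_amid > 0L) {
      if (site_unique) "confirmed_unique" else "confirmed_nonunique_group"
    } else {
      "not_amidated"
    }
    data.frame(toxin_id = g, predicted = predicted, n_amidated = n_amid,
               n_plain = n_plain, site_unique = site_unique,
               category = category, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Venn-region counts for sets of identifications
#'
#' @param sets Named list (length >= 2) of character vectors, e.g. toxins
#'   identified per protease.
#' @return A data frame with one row per non-empty region combination:
#'   \code{region} (ampersand-joined member names), \code{count}.
#' @export
protease_set_comparison <- function(sets) {
  stopifnot(length(sets) >= 2L)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  items <- unique(unlist(sets))
  member <- vapply(sets, function(s) items %in% s, logical(length(items)))
  if (length(items) == 1L) member <- matrix(member, nrow = 1L,
                                            dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    mask <- unlist(combos[k, ])
    cnt <- if (length(items)) {
      sum(apply(member, 1L, function(r) all(r == mask)))
    } else 0L
    data.frame(region = paste(names(sets)[mask], collapse = "&"),
               count = cnt, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
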