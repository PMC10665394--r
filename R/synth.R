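# Ground-truth-labelled synthetic data: EST reads encoding toxin precursors
# and multi-protease PSM tables. Every generated artifact is self-validated
# against the pipeline stage it exercises before being returned.

pick <- function(v) v[sample.int(length(v), 1L)]

# Residue pools. Mature spacers exclude C (the skeleton owns all cysteines);
# the tail spacer additionally excludes G/K/R so that C-terminal processing
# is controlled solely by the appended cassette. Propeptide filler avoids
# K/R (no spurious quadruplets) and small residues (no spurious signal
# peptidase sites directly downstream of the true one).
SPACER_AA <- setdiff(AA20, "C")
TAIL_AA <- setdiff(AA20, c("C", "G", "K", "R"))
PROP_AA <- c("E", "D", "Q", "N", "P")
CORE_AA <- c("L", "V", "I", "F")

# Inter-cysteine spacer lengths avoid 1 and 6 so that only the intended
# literal spacers of the planted motif can satisfy LIT(1)/LIT(6) tokens.
# The tail after the last cysteine stays short enough that appending a GR/GKR
# processing cassette keeps it within the single-digit range the '#' symbol
# of the general motifs tolerates.
FREE_SPACERS <- c(2L, 3L, 4L, 5L, 7L, 8L)
TAIL_SPACERS <- c(2L, 3L, 4L, 5L)

#' Synthetic data configuration
#'
#' Defaults emulate the study conditions: a median read length of 457 nt,
#' signal peptides of 18-25 residues, a propeptide ending in an XXKR/XXRR
#' quadruplet, cysteine frameworks drawn from the published family
#' proportions, and a four-protease PSM design with reversed-sequence decoys
#' under a two-component Gaussian score model.
#'
#' @param seed Integer seed; identical configurations give identical output.
#' @param n_toxins Number of distinct toxin precursors.
#' @param n_toxin_reads Total toxin-encoding reads (every toxin gets at least
#'   one read).
#' @param n_nontoxin_reads Reads carrying no toxin motif.
#' @param n_error_reads Toxin reads corrupted by one indel or a premature
#'   stop.
#' @param family_mix Proportions over the 6C/8C/9C/10C families (default
#'   follows the published 45/97/2/35 family split).
#' @param read_length_median,read_length_sdlog Log-normal read length model
#'   (nt).
#' @param signal_len,propeptide_len Integer ranges (residues).
#' @param cassette_probs Probabilities of the C-terminal processing cassette
#'   \code{none}/\code{GR}/\code{GKR} appended after the mature core
#'   (amidation is predicted exactly for GR/GKR).
#' @param psm List: \code{sampled_toxin_fraction}, \code{decoy_fraction},
#'   \code{score_separation}, \code{missed_cleavage_rate}, \code{mu_target},
#'   \code{min_peptide_len}.
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1L,
                         n_toxins = 12L,
                         n_toxin_reads = 40L,
                         n_nontoxin_reads = 10L,
                         n_error_reads = 5L,
                         family_mix = c("6C" = 0.25, "8C" = 0.54,
                                        "9C" = 0.01, "10C" = 0.20),
                         read_length_median = 457,
                         read_length_sdlog = 0.35,
                         signal_len = c(18L, 25L),
                         propeptide_len = c(8L, 16L),
                         cassette_probs = c(none = 0.8, GR = 0.1, GKR = 0.1),
                         psm = list()) {
  stopifnot(abs(sum(family_mix) - 1) < 1e-8,
            n_toxins >= 1L, n_toxin_reads >= n_toxins)
  psm_defaults <- list(sampled_toxin_fraction = 0.8, decoy_fraction = 0.5,
                       score_separation = 6, missed_cleavage_rate = 0.3,
                       mu_target = 10, min_peptide_len = 6L)
  psm <- utils::modifyList(psm_defaults, psm)
  structure(list(seed = as.integer(seed), n_toxins = n_toxins,
                 n_toxin_reads = n_toxin_reads,
                 n_nontoxin_reads = n_nontoxin_reads,
                 n_error_reads = n_error_reads, family_mix = family_mix,
                 read_length_median = read_length_median,
                 read_length_sdlog = read_length_sdlog,
                 signal_len = signal_len, propeptide_len = propeptide_len,
                 cassette_probs = cassette_probs, psm = psm),
            class = "synth_config")
}

spacer_run <- function(n, pool = SPACER_AA) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

#' Draw a mature toxin sequence satisfying a family's cysteine framework
#'
#' Builds a cysteine skeleton matching the family's general motif (6C:
#' Cys#1, or Cys#3 with a first spacer other than 6; 8C: Cys#2/Cys#4;
#' 9C/10C: extended skeletons that still satisfy Cys#1 through the gap
#' symbol), fills the spacers with random non-cysteine residues, and asserts
#' the motif label with the SRDA matcher before returning. Uses the current
#' RNG state.
#'
#' @param family One of \code{"6C"}, \code{"8C"}, \code{"9C"}, \code{"10C"}.
#' @return A list with \code{sequence}, \code{motif} (the satisfied motif
#'   name) and \code{cys_count}.
#' @export
make_mature <- function(family = c("6C", "8C", "9C", "10C")) {
  family <- match.arg(family)
  s1_is_6 <- stats::runif(1) < 0.7
  s1 <- if (s1_is_6) 6L else pick(setdiff(FREE_SPACERS, c(2L, 3L)))
  sp <- function() pick(FREE_SPACERS)
  tail_len <- pick(TAIL_SPACERS)
  if (family == "6C") {
    layout <- list("C", s1, "C", sp(), "C", "C", sp(), "C", sp(), "C")
    motif <- if (s1_is_6) "Cys#1" else "Cys#3"
  } else if (family == "8C") {
    layout <- list("C", s1, "C", sp(), "C", "C", sp(), "C", 1L, "C",
                   sp(), "C", 1L, "C")
    motif <- if (s1_is_6) "Cys#2" else "Cys#4"
  } else if (family == "9C") {
    layout <- list("C", 6L, "C", sp(), "C", sp(), "C", sp(), "C", sp(),
                   "C", "C", sp(), "C", sp(), "C")
    motif <- "Cys#1"
  } else {
    layout <- list("C", 6L, "C", sp(), "C", sp(), "C", sp(), "C", sp(),
                   "C", sp(), "C", "C", sp(), "C", sp(), "C")
    motif <- "Cys#1"
  }
  parts <- vapply(layout, function(el) {
    if (identical(el, "C")) "C" else spacer_run(el)
  }, character(1))
  seq <- paste0(paste(parts, collapse = ""), spacer_run(tail_len, TAIL_AA))
  stopifnot(motif_hits_sequence(paste0(seq, STOP_CHAR),
                                toxin_motifs()[[motif]]))
  fam <- assign_family(seq)
  stopifnot(fam$family == family)
  list(sequence = seq, motif = motif, cys_count = fam$cys_count)
}

#' Mutate a mature sequence while preserving its cysteine skeleton
#'
#' Substitutes \code{n_mut} randomly chosen non-cysteine positions with other
#' non-cysteine residues; useful for building homology subfamilies with known
#' structure. Positions can be restricted to a window.
#'
#' @param sequence Mature amino-acid string.
#' @param n_mut Number of substitutions.
#' @param window Optional 0-based half-open interval restricting mutable
#'   positions.
#' @return The mutated sequence.
#' @export
mutate_spacers <- function(sequence, n_mut, window = NULL) {
  cc <- chars(sequence)
  idx <- which(cc != "C")
  if (!is.null(window)) idx <- idx[idx > window[1] & idx <= window[2]]
  idx <- sample(idx, min(n_mut, length(idx)))
  for (i in idx) cc[i] <- pick(setdiff(SPACER_AA, cc[i]))
  paste(cc, collapse = "")
}

#' Draw a homolog-rich toxin family
#'
#' Generates one mature scaffold and near-identical members differing at
#' \code{n_mut} spacer positions, with the spacers enriched in K/R so that
#' tryptic peptides are short and widely shared among members while the
#' rarer-cutting proteases produce long, discriminating peptides -- the
#' sequence structure that makes single-enzyme identification ambiguous.
#' Uses the current RNG state.
#'
#' @param family Cysteine family of the scaffold.
#' @param n_members Members in the family (first one is the scaffold).
#' @param n_mut Substitutions per non-scaffold member.
#' @param kr_density Fraction of mutable spacer positions re-drawn as K/R.
#' @return Character vector of mature sequences.
#' @export
make_homolog_family <- function(family = "8C", n_members = 5L, n_mut = 2L,
                                kr_density = 0.3) {
  base <- make_mature(family)$sequence
  cc <- chars(base)
  mutable <- which(cc != "C")
  mutable <- mutable[mutable < length(cc) - 6L]   # keep the C-terminal tail
  kr <- sample(mutable, round(kr_density * length(mutable)))
  cc[kr] <- sample(c("K", "R"), length(kr), replace = TRUE)
  base <- paste(cc, collapse = "")
  c(base, vapply(seq_len(n_members - 1L), function(j) {
    mutate_spacers(base, n_mut, window = c(0L, length(cc) - 7L))
  }, character(1)))
}

make_signal <- function(len) {
  paste0("M", pick(c("K", "R")), spacer_run(len - 5L, CORE_AA), "ALA")
}

make_propeptide <- function(len) {
  paste0(spacer_run(len - 4L, PROP_AA), spacer_run(2L, PROP_AA),
         pick(c("KR", "RR")))
}

# One complete precursor protein with planted segmentation.
make_precursor_protein <- function(cfg, mature, cassette) {
  slen <- pick(seq(cfg$signal_len[1], cfg$signal_len[2]))
  plen <- pick(seq(cfg$propeptide_len[1], cfg$propeptide_len[2]))
  cass <- switch(cassette, none = "", GR = "GR", GKR = "GKR")
  protein <- paste0(make_signal(slen), make_propeptide(plen), mature, cass)
  list(protein = protein, signal_len = slen, propeptide_len = plen,
       mature = mature, cassette = cassette,
       amidation_predicted = cassette != "none")
}

#' Embed a precursor protein in a synthetic EST read
#'
#' Reverse-translates the protein with uniform synonymous codons, appends a
#' stop codon, places an in-frame upstream stop directly before the
#' initiator ATG, pads both UTRs with random nucleotides to a log-normal
#' target length, and randomly assigns the strand. The read is re-translated
#' and ORF-scanned before being returned; padding (and, if necessary, the
#' codon choice) is redrawn until the planted precursor is recovered as a
#' complete (stop-terminated) ORF of at least \code{min_orf_len} residues
#' and no competing ORF on the read carries a cysteine-framework motif.
#' Motif-free Met-to-end fragments in other frames are left in place -- they
#' are a property of real single-pass reads and are discarded downstream by
#' motif classification. Uses the current RNG state.
#'
#' @param protein Precursor amino-acid string.
#' @param id Read identifier.
#' @param cfg A \code{synth_config} (length model).
#' @param min_orf_len ORF length floor used for the self-check (default 40).
#' @return A list with \code{id}, \code{nt_seq}, \code{strand}, \code{frame},
#'   \code{start_aa}, \code{end_aa} (ORF coordinates in the detected frame).
#' @export
make_precursor_read <- function(protein, id, cfg, min_orf_len = 40L) {
  cds <- paste0(reverse_translate(protein), pick(c("TAA", "TAG", "TGA")))
  motifs <- toxin_motifs()
  n_cys_pat <- vapply(motifs, function(p) sum(p$type == 1L), integer(1))
  for (attempt in 1:60) {
    target <- round(stats::rlnorm(1, log(cfg$read_length_median),
                                  cfg$read_length_sdlog))
    target <- max(target, nchar(cds) + 12L)
    pad <- target - nchar(cds)
    u5 <- pick(seq(3L, pad - 3L))
    nt <- paste0(random_nt(u5 - 3L), "TAA", cds, random_nt(pad - u5))
    strand <- pick(c("+", "-"))
    if (strand == "-") nt <- revcomp(nt)
    orfs <- detect_orfs(
      six_frame_translate(data.frame(id = id, nt_seq = nt,
                                     stringsAsFactors = FALSE)),
      min_len = min_orf_len)
    hit <- which(orfs$protein == protein & orfs$has_stop)
    if (length(hit) != 1L) next
    competing <- vapply(setdiff(seq_len(nrow(orfs)), hit), function(k) {
      aa <- paste0(orfs$protein[k], if (orfs$has_stop[k]) STOP_CHAR)
      !is.na(first_motif_hit(aa, motifs, n_cys_pat))
    }, logical(1))
    if (!any(competing)) {
      return(list(id = id, nt_seq = nt, strand = strand,
                  frame = orfs$frame[hit], start_aa = orfs$start_aa[hit],
                  end_aa = orfs$end_aa[hit]))
    }
    if (attempt %% 20L == 0L) {    # the codon draw itself may be awkward
      cds <- paste0(reverse_translate(protein), pick(c("TAA", "TAG", "TGA")))
    }
  }
  stop("could not embed precursor '", id, "' in a clean read")
}

make_nontoxin_read <- function(id, cfg, motifs) {
  for (attempt in 1:100) {
    len <- max(60L, round(stats::rlnorm(1, log(cfg$read_length_median),
                                        cfg$read_length_sdlog)))
    nt <- random_nt(len)
    frames <- six_frame_translate(data.frame(id = id, nt_seq = nt,
                                             stringsAsFactors = FALSE))
    n_cys_pat <- vapply(motifs, function(p) sum(p$type == PAT_C), integer(1))
    hit <- classify_one_read(frames$aa_seq, motifs, n_cys_pat)
    if (is.null(hit)) return(list(id = id, nt_seq = nt))
  }
  stop("could not draw a motif-free read")
}

make_error_read <- function(protein, id, cfg) {
  base <- make_precursor_read(protein, id, cfg)
  nt <- base$nt_seq
  kind <- pick(c("indel", "stop"))
  if (kind == "indel") {
    pos <- pick(seq(round(nchar(nt) * 0.3), round(nchar(nt) * 0.7)))
    nt <- if (stats::runif(1) < 0.5) {
      paste0(substr(nt, 1, pos), substr(nt, pos + 2L, nchar(nt)))
    } else {
      paste0(substr(nt, 1, pos), pick(c("A", "C", "G", "T")),
             substr(nt, pos + 1L, nchar(nt)))
    }
  } else {
    # overwrite a codon in the middle of the read with a stop, in frame 1 of
    # whatever strand the read ended up on -- enough to corrupt the CDS
    pos <- (pick(seq(round(nchar(nt) / 6), round(nchar(nt) / 3))) %/% 3L) * 3L
    mid <- round(nchar(nt) / 2)
    at <- mid + pos %% 30L
    at <- min(at, nchar(nt) - 3L)
    nt <- paste0(substr(nt, 1, at), "TAA", substr(nt, at + 4L, nchar(nt)))
  }
  list(id = id, nt_seq = nt, error_kind = kind)
}

synth_toxin_set <- function(cfg) {
  n <- cfg$n_toxins
  fams <- sample(names(cfg$family_mix), n, replace = TRUE,
                 prob = cfg$family_mix)
  rows <- vector("list", n)
  # toxins 1 and 2 form a homolog pair sharing the C-terminal half (used to
  # plant group-level non-unique C-terminal evidence); both carry the GKR
  # amidation cassette
  for (i in seq_len(n)) {
    if (i == 2L) next
    mm <- make_mature(fams[i])
    seq <- mm$sequence
    # guarantee internal cleavage sites for every protease class
    cc <- chars(seq)
    free <- which(cc != "C")
    mid <- free[free > length(cc) * 0.25 & free < length(cc) * 0.55]
    late <- free[free > length(cc) * 0.6 & free < length(cc) * 0.9]
    if (length(mid) >= 2L) {
      ij <- sample(mid, 2L)
      cc[ij[1]] <- "E"; cc[ij[2]] <- "K"
    }
    if (length(late) >= 2L) {
      ij <- sample(late, 2L)
      cc[ij[1]] <- "E"; cc[ij[2]] <- "K"
    }
    seq <- paste(cc, collapse = "")
    cassette <- if (i == 1L) "GKR"
                else if (i <= 6L) pick(c("GR", "GKR"))
                else pick_cassette(cfg)
    rows[[i]] <- data.frame(toxin_id = sprintf("T%02d", i), family = fams[i],
                            motif = mm$motif, mature = seq,
                            cassette = cassette, stringsAsFactors = FALSE)
  }
  # homolog of toxin 1: mutate the N-terminal 40% only
  base <- rows[[1]]$mature
  sib <- mutate_spacers(base, n_mut = max(4L, round(nchar(base) * 0.12)),
                        window = c(0L, floor(nchar(base) * 0.4)))
  rows[[2]] <- data.frame(toxin_id = "T02", family = rows[[1]]$family,
                          motif = rows[[1]]$motif, mature = sib,
                          cassette = "GKR", stringsAsFactors = FALSE)
  toxins <- do.call(rbind, rows)
  toxins$amidation_predicted <- toxins$cassette != "none"
  # distinct matures required
  stopifnot(!anyDuplicated(toxins$mature))
  # the motif must still hold on the cassette-bearing mature, which is what
  # the classifier sees upstream of C-terminal processing
  motifs <- toxin_motifs()
  for (i in seq_len(nrow(toxins))) {
    cass <- switch(toxins$cassette[i], none = "", GR = "GR", GKR = "GKR")
    stopifnot(motif_hits_sequence(
      paste0(toxins$mature[i], cass, STOP_CHAR),
      motifs[[toxins$motif[i]]]))
  }
  toxins
}

pick_cassette <- function(cfg) {
  sample(names(cfg$cassette_probs), 1L, prob = cfg$cassette_probs)
}

variant_db <- function(toxins, trim_depth = 2L) {
  out <- lapply(seq_len(nrow(toxins)), function(i) {
    cass <- switch(toxins$cassette[i], none = "", GR = "GR", GKR = "GKR")
    v <- generate_mature_variants(paste0(toxins$mature[i], cass),
                                  trim_depth = trim_depth)
    cbind(data.frame(group = toxins$toxin_id[i], stringsAsFactors = FALSE), v)
  })
  db <- do.call(rbind, out)
  db[, c("group", "variant_id", "sequence", "amidated", "provenance")]
}

#' Simulate a multi-protease PSM table with planted ground truth
#'
#' A subset of toxins is "present in the venom". Each present toxin's venom
#' form (its amidated variant when amidation is planted, the untrimmed form
#' otherwise) is digested with all four proteases; zero-missed-cleavage
#' peptides are emitted as target PSMs (extra missed-cleavage peptides with
#' probability \code{missed_cleavage_rate}), with scores drawn from
#' N(mu_target, 1). Reversed-sequence decoys are added with scores from
#' N(mu_target - score_separation, 1). C-terminal peptides carry the
#' amidation flag dictated by the toxin's planted amidation-evidence
#' category: \code{confirmed_unique}/\code{confirmed_nonunique_group} emit
#' only amidated forms, \code{ambiguous} both, \code{not_amidated} only the
#' free acid, \code{undefined} none. Uses the current RNG state.
#'
#' @param db Variant database from the planted toxins.
#' @param truth Data frame with \code{toxin_id}, \code{sampled} and
#'   \code{category} per toxin.
#' @param psm_cfg The \code{psm} element of a \code{synth_config}.
#' @return A data frame of PSM rows: \code{peptide}, \code{protease},
#'   \code{replicate}, \code{score}, \code{decoy}, \code{cterm_amidated}.
#' @export
make_psm_table <- function(db, truth, psm_cfg) {
  proteases <- c("trypsin", "lysC", "gluC", "aspN")
  min_len <- psm_cfg$min_peptide_len
  rows <- list()
  emit <- function(peptide, protease, amidated) {
    reps <- if (stats::runif(1) < 0.6) c(1L, 2L) else 1L
    for (r in reps) {
      rows[[length(rows) + 1L]] <<- data.frame(
        peptide = peptide, protease = protease, replicate = r,
        score = stats::rnorm(1, psm_cfg$mu_target, 1), decoy = FALSE,
        cterm_amidated = amidated, stringsAsFactors = FALSE)
    }
  }
  for (g in truth$toxin_id[truth$sampled]) {
    cat_g <- truth$category[truth$toxin_id == g]
    vars <- db[db$group == g, , drop = FALSE]
    venom <- if (any(vars$amidated)) {
      vars[vars$amidated, , drop = FALSE][1, ]
    } else {
      vars[1, ]
    }
    use_amidated_form <- venom$amidated
    for (p in proteases) {
      pep <- digest(venom$sequence, p, max_missed = 0L, min_len = 1L)
      extra <- digest(venom$sequence, p, max_missed = 2L, min_len = 1L)
      extra <- extra[extra$missed > 0L &
                       stats::runif(nrow(extra)) < psm_cfg$missed_cleavage_rate,
                     , drop = FALSE]
      pep <- rbind(pep, extra)
      for (k in seq_len(nrow(pep))) {
        if (nchar(pep$sequence[k]) < min_len) next
        if (pep$is_cterm[k] && use_amidated_form) {
          if (cat_g %in% c("confirmed_unique", "confirmed_nonunique_group")) {
            emit(pep$sequence[k], p, TRUE)
          } else if (cat_g == "ambiguous") {
            emit(pep$sequence[k], p, TRUE)
            emit(pep$sequence[k], p, FALSE)
          } else if (cat_g == "not_amidated") {
            emit(pep$sequence[k], p, FALSE)
          }                                    # undefined: skip C-term
        } else {
          emit(pep$sequence[k], p, FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(), protease = character(),
                      replicate = integer(), score = numeric(),
                      decoy = logical(), cterm_amidated = logical(),
                      stringsAsFactors = FALSE))
  }
  targets <- do.call(rbind, rows)
  n_dec <- round(psm_cfg$decoy_fraction * nrow(targets))
  dec_src <- sample(targets$peptide, n_dec, replace = TRUE)
  all_keys <- unique(collapse_il(targets$peptide))
  decoys <- do.call(rbind, lapply(dec_src, function(s) {
    rs <- paste(rev(chars(s)), collapse = "")
    if (collapse_il(rs) %in% all_keys) {
      rs <- paste(sample(chars(s)), collapse = "")
    }
    data.frame(peptide = rs, protease = pick(proteases),
               replicate = pick(1:2),
               score = stats::rnorm(1, psm_cfg$mu_target -
                                      psm_cfg$score_separation, 1),
               decoy = TRUE, cterm_amidated = FALSE, stringsAsFactors = FALSE)
  }))
  out <- rbind(targets, decoys)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic venomics study
#'
#' Produces, from one seed, a planted toxin set (including one homolog pair
#' sharing its C-terminal half), EST reads encoding the precursors plus
#' motif-free and error reads, the mature-variant database, a four-protease
#' PSM table with decoys, and the full ground truth. Before returning, the
#' generator replays the pipeline on its own output (ORF detection per read
#' at generation time; FDR filtering, identification and amidation evidence
#' at the study level) and fails loudly on any inconsistency.
#'
#' @param cfg A [synth_config()].
#' @return A list with \code{config}, \code{toxins} (per-toxin truth),
#'   \code{reads} (id, nt_seq), \code{read_truth} (per-read type, frame,
#'   strand, ORF span, segmentation, motif, family), \code{db} (variant
#'   database), \code{psms}, \code{psm_truth} (per-toxin sampled flag and
#'   planted amidation category).
#' @export
synth_venomics <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  for (attempt in 1:10) {
    res <- try(synth_venomics_once(cfg), silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
  }
  stop("synthetic study generation failed: ",
       attr(res, "condition")$message)
}

synth_venomics_once <- function(cfg) {
  toxins <- synth_toxin_set(cfg)
  n <- nrow(toxins)

  # precursor proteins and per-toxin read counts (each toxin >= 1 read)
  prec <- lapply(seq_len(n), function(i) {
    make_precursor_protein(cfg, toxins$mature[i], toxins$cassette[i])
  })
  toxins$protein <- vapply(prec, `[[`, character(1), "protein")
  toxins$signal_len <- vapply(prec, `[[`, integer(1), "signal_len")
  toxins$propeptide_len <- vapply(prec, `[[`, integer(1), "propeptide_len")
  extra <- cfg$n_toxin_reads - n
  counts <- 1L + as.integer(stats::rmultinom(1, extra, rep(1, n)))
  toxins$transcript_count <- counts

  reads <- list(); truth <- list()
  ridx <- 0L
  for (i in seq_len(n)) {
    for (k in seq_len(counts[i])) {
      ridx <- ridx + 1L
      id <- sprintf("est%04d", ridx)
      rd <- make_precursor_read(toxins$protein[i], id, cfg)
      reads[[ridx]] <- data.frame(id = id, nt_seq = rd$nt_seq,
                                  stringsAsFactors = FALSE)
      truth[[ridx]] <- data.frame(
        id = id, type = "toxin", toxin_id = toxins$toxin_id[i],
        strand = rd$strand, frame = rd$frame, start_aa = rd$start_aa,
        end_aa = rd$end_aa, protein = toxins$protein[i],
        signal_len = toxins$signal_len[i],
        propeptide_len = toxins$propeptide_len[i],
        mature = toxins$mature[i], cassette = toxins$cassette[i],
        family = toxins$family[i], motif = toxins$motif[i],
        amidation_predicted = toxins$amidation_predicted[i],
        stringsAsFactors = FALSE)
    }
  }
  motifs <- toxin_motifs()
  for (k in seq_len(cfg$n_nontoxin_reads)) {
    ridx <- ridx + 1L
    id <- sprintf("est%04d", ridx)
    rd <- make_nontoxin_read(id, cfg, motifs)
    reads[[ridx]] <- data.frame(id = id, nt_seq = rd$nt_seq,
                                stringsAsFactors = FALSE)
    truth[[ridx]] <- data.frame(
      id = id, type = "nontoxin", toxin_id = NA_character_,
      strand = NA_character_, frame = NA_integer_, start_aa = NA_integer_,
      end_aa = NA_integer_, protein = NA_character_, signal_len = NA_integer_,
      propeptide_len = NA_integer_, mature = NA_character_,
      cassette = NA_character_, family = NA_character_,
      motif = NA_character_, amidation_predicted = NA,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(cfg$n_error_reads)) {
    ridx <- ridx + 1L
    id <- sprintf("est%04d", ridx)
    i <- pick(seq_len(n))
    rd <- make_error_read(toxins$protein[i], id, cfg)
    reads[[ridx]] <- data.frame(id = id, nt_seq = rd$nt_seq,
                                stringsAsFactors = FALSE)
    truth[[ridx]] <- data.frame(
      id = id, type = "error", toxin_id = toxins$toxin_id[i],
      strand = NA_character_, frame = NA_integer_, start_aa = NA_integer_,
      end_aa = NA_integer_, protein = toxins$protein[i],
      signal_len = NA_integer_, propeptide_len = NA_integer_,
      mature = NA_character_, cassette = NA_character_,
      family = toxins$family[i], motif = NA_character_,
      amidation_predicted = NA, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, reads)
  read_truth <- do.call(rbind, truth)

  db <- variant_db(toxins)

  # venom sampling and planted amidation categories
  predicted <- toxins$toxin_id[toxins$amidation_predicted]
  stopifnot(length(predicted) >= 6L)
  n_sampled <- max(6L, round(cfg$psm$sampled_toxin_fraction * n))
  forced <- c("T01", "T02", "T03", "T04", "T05", "T06")
  others <- setdiff(toxins$toxin_id, forced)
  sampled_ids <- c(forced, sample(others, max(0L, n_sampled - length(forced))))
  category <- rep(NA_character_, n)
  names(category) <- toxins$toxin_id
  category[c("T01", "T02")] <- "confirmed_nonunique_group"
  free_pred <- setdiff(intersect(predicted, forced), c("T01", "T02"))
  category[free_pred[1]] <- "confirmed_unique"
  category[free_pred[2]] <- "ambiguous"
  category[free_pred[3]] <- "not_amidated"
  category[free_pred[4]] <- "undefined"
  remaining_pred <- setdiff(predicted, names(category)[!is.na(category)])
  category[remaining_pred] <- "confirmed_unique"
  category[is.na(category)] <- "none"
  psm_truth <- data.frame(toxin_id = toxins$toxin_id,
                          sampled = toxins$toxin_id %in% sampled_ids,
                          predicted = toxins$amidation_predicted,
                          category = unname(category[toxins$toxin_id]),
                          stringsAsFactors = FALSE)
  psms <- make_psm_table(db, psm_truth, cfg$psm)

  validate_synth(cfg, toxins, db, psms, psm_truth)

  list(config = cfg, toxins = toxins, reads = reads, read_truth = read_truth,
       db = db, psms = psms, psm_truth = psm_truth)
}

# Study-level self-validation: the planted venom subset and amidation
# categories must be recovered by the pipeline itself.
validate_synth <- function(cfg, toxins, db, psms, psm_truth) {
  accepted <- fdr_filter(psms, alpha = 0.01)
  ident <- identify_toxins(accepted, db)
  detected <- sort(ident$toxin_id[ident$status == "unique_identified"])
  planted <- sort(psm_truth$toxin_id[psm_truth$sampled])
  if (!identical(detected, planted)) {
    stop("self-validation: detected set differs from planted venom subset")
  }
  amid <- amidation_evidence(accepted, db)
  for (i in seq_len(nrow(psm_truth))) {
    if (!psm_truth$sampled[i] || psm_truth$category[i] == "none") next
    got <- amid$category[amid$toxin_id == psm_truth$toxin_id[i]]
    if (!identical(got, psm_truth$category[i])) {
      stop("self-validation: amidation category mismatch for ",
           psm_truth$toxin_id[i], " (planted ", psm_truth$category[i],
           ", recovered ", got, ")")
    }
  }
  invisible(TRUE)
}

#' Two-component Gaussian PSM score model
#'
#' Draws target scores from N(mu, 1) and decoy scores from
#' N(mu - separation, 1); the simplest model under which target-decoy FDR
#' behaviour can be verified analytically. Uses the current RNG state.
#'
#' @param n_targets,n_decoys Counts.
#' @param separation Difference of the two means (default 6).
#' @param mu Target mean (default 10).
#' @return A PSM-like data frame with \code{peptide}, \code{score},
#'   \code{decoy}.
#' @export
make_score_psms <- function(n_targets = 500L, n_decoys = 500L,
                            separation = 6, mu = 10) {
  data.frame(
    peptide = c(sprintf("TGT%05d", seq_len(n_targets)),
                sprintf("DCY%05d", seq_len(n_decoys))),
    score = c(stats::rnorm(n_targets, mu, 1),
              stats::rnorm(n_decoys, mu - separation, 1)),
    decoy = rep(c(FALSE, TRUE), c(n_targets, n_decoys)),
    stringsAsFactors = FALSE)
}
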