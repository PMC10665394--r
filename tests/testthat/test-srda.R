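# The SRDA encoding, the motif pattern language and read classification.

test_that("encoding serialises cysteine spacing with adjacent-C collapsing", {
  expect_equal(srda_format(srda_encode("AACCAAC.")), "2CC2C.")
  expect_equal(srda_format(srda_encode("CCCCCC")), "CCCCCC")
  expect_equal(srda_format(srda_encode("XXCXAC")), "2C2C")  # X is a spacer

  enc <- srda_encode("AAC.GGC")
  expect_true(enc$truncated)
  expect_equal(srda_format(enc), "2C.")
})

test_that("encoding round-trips cysteine positions and length", {
  set.seed(11)
  for (k in 1:200) {
    aa <- paste(sample(c("C", "A", "G", "X"), sample(5:80, 1), replace = TRUE,
                       prob = c(.3, .4, .2, .1)), collapse = "")
    enc <- srda_encode(aa)
    cc <- strsplit(aa, "")[[1]]
    expect_equal(srda_cys_positions(enc), which(cc == "C") - 1L)
    expect_equal(enc$length, nchar(aa))
  }
})

test_that("motif formulas parse token-wise and round-trip", {
  p <- parse_motif("C6C*CC*C*C#.")
  expect_equal(length(p$type), 12L)
  expect_equal(format_motif(p), "C6C*CC*C*C#.")

  # multi-digit runs are a single literal spacer
  p <- parse_motif("C12C")
  expect_equal(p$type[2], 2L)
  expect_equal(p$val[2], 12L)

  p <- parse_motif("CnC*CC*C1C*C1C#. (n!=6)")
  expect_equal(p$val[2], 6L)
  expect_equal(format_motif(p), "CnC*CC*C1C*C1C#. (n!=6)")

  p <- parse_motif("C*CC*C1C")          # partial: no stop anchor
  expect_false(any(p$type == 6L))

  expect_error(parse_motif("C6C?"), "position 4")
  expect_error(parse_motif("CnC"), "side condition")
})

test_that("the bundled motif set is the eight frameworks in search order", {
  m <- toxin_motifs()
  expect_equal(names(m), c("Cys#1", "Cys#2", "Cys#3", "Cys#4", "extCys#2",
                           "extCys#1", "partCys#1", "partCys#2"))
  expect_equal(format_motif(m[["Cys#1"]]), "C6C*CC*C*C#.")
  expect_equal(format_motif(m[["Cys#4"]]), "CnC*CC*C1C*C1C#. (n!=6)")
  expect_equal(vapply(m, `[[`, character(1), "category"),
               c("Cys#1" = "general", "Cys#2" = "general",
                 "Cys#3" = "general", "Cys#4" = "general",
                 "extCys#2" = "extended", "extCys#1" = "extended",
                 "partCys#1" = "partial", "partCys#2" = "partial"))
})

test_that("token semantics: literals, gaps, hash and the stop anchor", {
  m <- toxin_motifs()
  hits <- function(line, pat) nrow(match_motif(srda_encode(aa_from_line(line)),
                                               m[[pat]])) > 0
  # canonical six-cysteine framework
  expect_true(hits("C6C5CC1C4C3.", "Cys#1"))
  # eight-cysteine knottin satisfies both Cys#1 (via the gap) and Cys#2
  expect_true(hits("C6C5CC1C1C4C1C2.", "Cys#1"))
  expect_true(hits("C6C5CC1C1C4C1C2.", "Cys#2"))
  # literal spacers match whole tokens, never digit substrings
  expect_false(hits("C12C5CC1C4C3.", "Cys#1"))
  expect_true(hits("C12C5CC1C4C3.", "Cys#3"))
  expect_false(hits("C16C5CC1C4C3.", "Cys#1"))
  # '#' accepts an empty tail directly before the stop (digit zero)
  expect_true(hits("C6C5CC1C4C.", "Cys#1"))
  # ...but a ten-residue tail is not a digit
  expect_false(hits("C6C5CC1C4C10.", "Cys#1"))
  # partial motif may end anywhere
  expect_true(hits("C2CC3C1C9C9C9", "partCys#2"))
})

test_that("matching agrees with a window enumerator on star-free patterns", {
  set.seed(101)
  n_checked <- 0L
  for (k in 1:500) {
    enc <- random_encoding()
    pat <- random_nostar_pattern()
    got <- nrow(match_motif(enc, pat)) > 0
    want <- oracle_match_nostar(enc, pat)
    expect_identical(got, want)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 500L)
})

test_that("matches are reported leftmost-shortest with residue spans", {
  enc <- srda_encode(aa_from_line("C2CC3C.C2CC3C."))
  mm <- match_motif(enc, parse_motif("C#C"))
  expect_true(nrow(mm) >= 1)
  expect_equal(mm$token_start[1], 1L)
  # the reported residue interval lies inside the source
  expect_true(all(mm$res_start >= 0 & mm$res_end <= enc$length))
})

test_that("a Cys#2 match implies a Cys#1 match (gap absorbs extra tokens)", {
  m <- toxin_motifs()
  set.seed(5)
  n_pos <- 0L
  for (k in 1:60) {
    mm <- make_mature(sample(c("6C", "8C", "9C", "10C"), 1))
    enc <- srda_encode(paste0(mm$sequence, "."))
    if (nrow(match_motif(enc, m[["Cys#2"]]))) {
      n_pos <- n_pos + 1L
      expect_true(nrow(match_motif(enc, m[["Cys#1"]])) > 0)
    }
  }
  expect_gt(n_pos, 5L)   # the draw must actually exercise the implication
})

test_that("classification is precedence-exclusive and impacts sum correctly", {
  st <- shared_study()
  pl <- shared_pipeline()
  cl <- pl$classification
  impacts <- attr(cl, "impacts")
  expect_equal(sum(impacts), sum(!is.na(cl$motif)))
  # one row per read, each read counted at most once
  expect_equal(nrow(cl), nrow(st$reads))
  expect_false(anyDuplicated(cl$est_id) > 0)
  # motif-free reads are never claimed
  nontoxin <- st$read_truth$id[st$read_truth$type == "nontoxin"]
  expect_true(all(is.na(cl$motif[cl$est_id %in% nontoxin])))
  # error-free toxin reads are always claimed, by a general motif
  toxin <- st$read_truth$id[st$read_truth$type == "toxin"]
  expect_true(all(!is.na(cl$motif[cl$est_id %in% toxin])))
  expect_true(all(!cl$needs_verification[cl$est_id %in% toxin]))
})
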