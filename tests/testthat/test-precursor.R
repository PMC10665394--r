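# Precursor segmentation and mature-variant enumeration.

test_that("the built-in heuristic cleaves a classic signal peptide", {
  # hydrophobic core ending ...GLALA | QSD: cut after the A at position 15
  p <- "MKTLVLLTLLGLALAQSDEEDARSTHEEEQRCAAACAA"
  sp <- predict_signal_cleavage(p)
  expect_equal(sp$cleavage_site, 15L)
  expect_equal(sp$source, "builtin")
  expect_gt(sp$score, 0.45)

  # acidic N-terminus: hydrophobicity below threshold
  sp <- predict_signal_cleavage(paste0("M", strrep("E", 40)))
  expect_true(is.na(sp$cleavage_site))

  # too short for a credible signal: a no-signal result, not an error
  sp <- predict_signal_cleavage("MKTLVLLTLL")
  expect_true(is.na(sp$cleavage_site))
})

test_that("external signal predictions are ingested and override", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tcleavage_site", "a\t21", "b\t19", "c\t25"), tsv)
  sigs <- ingest_signal_predictions(tsv)
  expect_equal(length(sigs), 3L)
  expect_equal(sigs[["b"]]$cleavage_site, 19L)
  expect_equal(sigs[["b"]]$source, "external")

  writeLines("id\tcleavage_site", tsv)
  expect_equal(length(ingest_signal_predictions(tsv)), 0L)

  writeLines(c("id\tcleavage_site", "a\t21", "a\t23"), tsv)
  expect_warning(sigs <- ingest_signal_predictions(tsv), "duplicate")
  expect_equal(sigs[["a"]]$cleavage_site, 23L)
})

met_protein <- function(met_dists, cleavage = 40L, len = 60L) {
  cc <- rep("A", len)
  cc[cleavage - met_dists + 1L] <- "M"   # 0-based Met index = cleavage - d
  paste(cc, collapse = "")
}

test_that("start codon selection prefers the 20-27 window, then 15-35", {
  expect_equal(select_start_codon(met_protein(c(19, 22, 30)), 40L), 40L - 22L)
  expect_equal(select_start_codon(met_protein(c(10, 33)), 40L), 40L - 33L)
  expect_equal(select_start_codon(met_protein(c(20, 27)), 40L), 40L - 20L)
  expect_true(is.na(select_start_codon(met_protein(c(5, 40)), 40L)))
  expect_true(is.na(select_start_codon(strrep("A", 60), 40L)))
})

test_that("propeptide cleavage uses the most C-terminal XXKR/XXRR quadruplet", {
  # signal | AEDSEKR GC...  -> quadruplet SEKR, mature starts at G
  p <- paste0("MAAA", "AEDSEKR", "GCAAA")
  expect_equal(find_propeptide_cleavage(p, 4L)$mature_start, 11L)

  # two quadruplets before the first Cys: the later one wins
  p <- paste0("MAAA", "AAKRDDRR", "GC")
  expect_equal(find_propeptide_cleavage(p, 4L)$mature_start, 12L)

  # no quadruplet: no propeptide
  p <- paste0("MAAA", "DDDD", "CAA")
  expect_equal(find_propeptide_cleavage(p, 4L)$mature_start, 4L)

  # ambiguous residues disqualify quadruplet membership
  p <- paste0("MAAA", "AXKR", "GC")
  expect_equal(find_propeptide_cleavage(p, 4L)$mature_start, 4L)

  # no downstream cysteine is flagged
  res <- find_propeptide_cleavage(paste0("MAAA", "AAKRGGG"), 4L)
  expect_true(res$no_cys)
  expect_equal(res$mature_start, 4L)
})

test_that("mature variants enumerate trims and amidation deterministically", {
  v <- generate_mature_variants("CNTGKR")
  expect_equal(v$sequence, c("CNTGKR", "CNTGK", "CNTG", "CNT"))
  expect_equal(v$amidated, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(v$provenance[1], "full")
  expect_equal(v$provenance[4], "amidated")

  expect_equal(nrow(generate_mature_variants("CNTA")), 1L)

  v <- generate_mature_variants("CG")
  expect_equal(v$sequence, c("CG", "C"))
  expect_equal(v$amidated, c(FALSE, TRUE))

  # trim depth bounds the number of basic residues removed
  v <- generate_mature_variants("CAKRKR", trim_depth = 2L)
  expect_setequal(v$sequence, c("CAKRKR", "CAKRK", "CAKR"))

  # the untrimmed sequence is always first
  set.seed(3)
  for (k in 1:20) {
    s <- random_protein(sample(8:30, 1))
    v <- generate_mature_variants(s)
    expect_equal(v$sequence[1], s)
    expect_false(anyDuplicated(paste(v$sequence, v$amidated)) > 0)
  }
})

test_that("identical CDS collapse with conserved transcript counts", {
  prec <- data.frame(id = c("a", "b", "c", "d"),
                     protein = c("MAC", "MAC", "MAC", "MCC"),
                     stringsAsFactors = FALSE)
  dd <- dedup_cds(prec)
  expect_equal(nrow(dd), 2L)
  expect_equal(sort(dd$transcript_count), c(1L, 3L))
  expect_equal(sum(dd$transcript_count), nrow(prec))
  expect_equal(nrow(dedup_cds(prec[0, ])), 0L)
})

test_that("planted precursor segmentations are recovered exactly", {
  st <- small_study()
  pl <- mine_toxins(st$reads)
  tt <- st$read_truth[st$read_truth$type == "toxin", ]
  prec <- pl$precursors[pl$precursors$id %in% tt$id, ]
  expect_equal(nrow(prec), nrow(tt))
  i <- match(prec$id, tt$id)
  expect_true(all(prec$signal_end == tt$signal_len[i]))
  expect_true(all(prec$mature_start == tt$signal_len[i] +
                    tt$propeptide_len[i]))
  expect_true(all(prec$mature == expected_mature(tt)[i]))
  expect_true(all(prec$completeness == "complete"))
  # segmentation partitions the precursor
  expect_true(all(prec$signal_end >= 0 &
                    prec$signal_end <= prec$mature_start &
                    prec$mature_start < nchar(prec$protein)))
  expect_true(all(paste0(substr(prec$protein, 1, prec$signal_end),
                         substr(prec$protein, prec$signal_end + 1,
                                prec$mature_start),
                         prec$mature) == prec$protein))
})
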