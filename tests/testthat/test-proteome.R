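# Digestion, uniqueness, FDR filtering, identification, coverage, amidation
# and protease-set comparison.

test_that("protease rules implement the four specificities", {
  expect_equal(digest("AKRPGKC", "trypsin")$sequence, c("AK", "RPGK", "C"))
  expect_equal(digest("AKRPGKC", protease_rule("trypsin",
                                               trypsin_proline_rule = FALSE)
                      )$sequence, c("AK", "R", "PGK", "C"))
  expect_equal(digest("AADCA", "aspN")$sequence, c("AA", "DCA"))
  expect_equal(digest("AEKDC", "gluC")$sequence, c("AE", "KDC"))
  expect_equal(digest("AEKDC", protease_rule("gluC", gluC_de = TRUE)
                      )$sequence, c("AE", "KD", "C"))
  expect_equal(digest("AKEC", "lysC")$sequence, c("AK", "EC"))
  expect_error(digest("", "trypsin"), "empty")
})

test_that("zero-missed peptides partition and counts match the oracle", {
  set.seed(17)
  for (k in 1:100) {
    prot <- random_protein(sample(10:60, 1))
    for (p in c("trypsin", "lysC", "gluC", "aspN")) {
      rule <- protease_rule(p)
      d0 <- digest(prot, rule, max_missed = 0L)
      expect_equal(paste(d0$sequence, collapse = ""), prot)
      mm <- sample(0:4, 1)
      dm <- digest(prot, rule, max_missed = mm)
      expect_equal(sort(dm$sequence), oracle_digest(prot, rule, mm))
      expect_true(all(dm$missed <= mm))
      expect_true(all(dm$is_cterm == (dm$end == nchar(prot))))
    }
  }
})

test_that("uniqueness is pooled at the toxin-group level", {
  db <- data.frame(group = c("T1", "T2"), variant_id = "v1",
                   sequence = c("AAAKCCCK", "AAAKDDDK"), amidated = FALSE,
                   stringsAsFactors = FALSE)
  um <- uniqueness_map(db, "trypsin", min_len = 3L)
  expect_equal(um$unique[um$peptide == "AAAK"], FALSE)
  expect_equal(um$parents[um$peptide == "AAAK"], "T1;T2")
  expect_true(all(um$unique[um$peptide %in% c("CCCK", "DDDK")]))

  # isoform-shared peptides stay unique
  db2 <- data.frame(group = "T1", variant_id = c("v1", "v2"),
                    sequence = c("AAAKCCCK", "AAAKCCC"), amidated = FALSE,
                    stringsAsFactors = FALSE)
  expect_true(all(uniqueness_map(db2, "trypsin", min_len = 3L)$unique))

  # I/L equivalence folds isobaric peptides together
  db3 <- data.frame(group = c("T1", "T2"), variant_id = "v1",
                    sequence = c("AILVK", "ALIVK"), amidated = FALSE,
                    stringsAsFactors = FALSE)
  expect_false(any(uniqueness_map(db3, "trypsin")$unique))
  expect_true(all(uniqueness_map(db3, "trypsin", il_equiv = FALSE)$unique))
})

test_that("uniqueness agrees with a substring-origin oracle", {
  set.seed(23)
  for (k in 1:30) {
    db <- data.frame(group = sprintf("T%d", 1:4), variant_id = "v1",
                     sequence = vapply(1:4, function(i)
                       random_protein(sample(15:40, 1)), character(1)),
                     amidated = FALSE, stringsAsFactors = FALSE)
    p <- sample(c("trypsin", "lysC", "gluC", "aspN"), 1)
    um <- uniqueness_map(db, p, min_len = 5L, il_equiv = FALSE)
    rule <- protease_rule(p)
    for (i in seq_len(nrow(um))) {
      parents <- db$group[vapply(db$sequence, function(s) {
        um$peptide[i] %in% oracle_digest(s, rule, 0L)
      }, logical(1))]
      expect_equal(um$parents[i], paste(sort(parents), collapse = ";"))
    }
  }
})

test_that("FDR filtering picks the largest compliant target set", {
  psms <- data.frame(peptide = "x", score = c(2:100, 1),
                     decoy = rep(c(FALSE, TRUE), c(99, 1)),
                     stringsAsFactors = FALSE)
  acc <- fdr_filter(psms, 0.01)
  expect_equal(nrow(acc), 99L)          # threshold rises to exclude the decoy
  expect_equal(attr(acc, "threshold"), 2)

  expect_equal(nrow(fdr_filter(data.frame(score = 1:5, decoy = TRUE), 0.01)),
               0L)
  expect_equal(nrow(fdr_filter(psms, 1)), 99L)

  set.seed(4)
  for (k in 1:20) {
    psms <- make_score_psms(n_targets = 80, n_decoys = 80, separation = 3)
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    acc <- fdr_filter(psms, alpha)
    want <- oracle_fdr(psms, alpha)
    expect_setequal(acc$peptide, want$peptide)
    # order invariance
    perm <- psms[sample(nrow(psms)), ]
    expect_setequal(fdr_filter(perm, alpha)$peptide, acc$peptide)
    # monotonicity: lowering alpha never adds PSMs
    expect_true(all(fdr_filter(psms, alpha / 5)$peptide %in% acc$peptide))
  }
})

toy_db <- function() {
  data.frame(group = c("T1", "T1", "T2"), variant_id = c("v1", "v2", "v1"),
             sequence = c("CCDDKAAWWK", "CCDDKAAWW", "CCDDKGGYYK"),
             amidated = FALSE, stringsAsFactors = FALSE)
}

psm_row <- function(peptide, protease = "trypsin", score = 10,
                    amidated = FALSE) {
  data.frame(peptide = peptide, protease = protease, replicate = 1L,
             score = score, decoy = FALSE, cterm_amidated = amidated,
             stringsAsFactors = FALSE)
}

test_that("identification distinguishes unique, group and absent evidence", {
  db <- toy_db()
  res <- identify_toxins(psm_row("AAWWK"), db)
  expect_equal(res$status[res$toxin_id == "T1"], "unique_identified")
  expect_equal(res$status[res$toxin_id == "T2"], "not_detected")

  # a peptide shared between groups gives group evidence only
  res <- identify_toxins(psm_row("CCDDK"), db)
  expect_equal(unique(res$status), "group_evidence_only")

  # an observed peptide absent from all theoretical digests is excluded
  res <- identify_toxins(psm_row("PPPPP"), db)
  expect_equal(attr(res, "unmatched"), "PPPPP")
  expect_true(all(res$status == "not_detected"))
})

test_that("isoform choice follows unique evidence, then coverage", {
  db <- toy_db()
  res <- identify_toxins(rbind(psm_row("AAWWK"), psm_row("CCDDK")), db)
  t1 <- res[res$toxin_id == "T1", ]
  expect_equal(t1$chosen_isoform, "v1")    # AAWWK is v1-only (C-terminal K)
  expect_gte(t1$coverage_all, t1$coverage_unique)

  iso <- data.frame(variant_id = c("v1", "v2"),
                    sequence = c("AAAABBBBCC", "AAAA"),
                    stringsAsFactors = FALSE)
  expect_equal(select_isoform(iso, unique_peptides = "AAAA"), "v2")
  expect_true(is.na(select_isoform(iso, character(0))))
})

test_that("coverage is a union of matched intervals", {
  s <- paste0(strrep("D", 20), strrep("E", 20), strrep("F", 10))
  expect_equal(sequence_coverage(s, c(strrep("D", 20), strrep("F", 10))), 0.6)
  # overlapping peptides are not double-counted
  s2 <- paste0("ACDEFGHIKL", "MNPQRSTVWY", "ACDEFGHIKL")
  expect_equal(sequence_coverage(s2, c("ACDEFGHIKL", "FGHIKLMNP")), 23 / 30)
  expect_equal(sequence_coverage(s2, character(0)), 0)
})

test_that("amidation evidence separates the five categories", {
  db <- data.frame(group = c("A", "A", "B", "B"),
                   variant_id = c("v1", "v2", "v1", "v2"),
                   sequence = c("CCKWWNTG", "CCKWWNT",
                                "CCKYYNTG", "CCKYYNT"),
                   amidated = c(FALSE, TRUE, FALSE, TRUE),
                   stringsAsFactors = FALSE)
  ev <- function(psms) amidation_evidence(psms, db)

  e <- ev(psm_row("WWNT", amidated = TRUE))
  expect_equal(e$category[e$toxin_id == "A"], "confirmed_unique")
  expect_equal(e$category[e$toxin_id == "B"], "undefined")

  e <- ev(rbind(psm_row("WWNT", amidated = TRUE), psm_row("WWNT")))
  expect_equal(e$category[e$toxin_id == "A"], "ambiguous")

  e <- ev(psm_row("WWNT"))
  expect_equal(e$category[e$toxin_id == "A"], "not_amidated")

  # a shared C-terminal peptide confirms at the group level
  db2 <- db
  db2$sequence <- c("CCKWWNTG", "CCKWWNT", "AAKWWNTG", "AAKWWNT")
  e <- amidation_evidence(psm_row("WWNT", amidated = TRUE), db2)
  expect_equal(unique(e$category), "confirmed_nonunique_group")
  expect_false(any(e$site_unique))
})

test_that("Venn regions cover all combinations", {
  vn <- protease_set_comparison(list(a = c("A", "B"), b = c("B", "C")))
  expect_equal(vn$count[vn$region == "a"], 1L)
  expect_equal(vn$count[vn$region == "b"], 1L)
  expect_equal(vn$count[vn$region == "a&b"], 1L)

  vn <- protease_set_comparison(list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(vn$count[vn$region == "x&y"], 2L)
  expect_equal(sum(vn$count), 2L)

  vn <- protease_set_comparison(list(x = "A", y = "B", z = character(0)))
  expect_equal(vn$count[vn$region == "x"], 1L)
  expect_equal(sum(vn$count), 2L)
})
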