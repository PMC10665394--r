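# EST input, six-frame translation, ORF detection, length statistics.

write_fasta <- function(lines) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(lines, fa)
  fa
}

test_that("FASTA reading normalises case and RNA and validates structure", {
  df <- read_est_fasta(write_fasta(c(">e1", "ATGTAA")))
  expect_equal(df, data.frame(id = "e1", nt_seq = "ATGTAA", length = 6L,
                              stringsAsFactors = FALSE))

  expect_equal(nrow(read_est_fasta(write_fasta(character(0)))), 0L)

  df <- read_est_fasta(write_fasta(c(">e1 some description", "atgn")))
  expect_equal(df$nt_seq, "ATGN")
  expect_equal(df$id, "e1")

  df <- read_est_fasta(write_fasta(c(">r", "augcua")))
  expect_equal(df$nt_seq, "ATGCTA")

  expect_error(read_est_fasta(write_fasta(c(">a", "ATG", ">a", "CCC"))),
               "duplicate")
  expect_error(read_est_fasta(write_fasta(c("ATG", ">a", "CCC"))),
               "line 1")
  expect_error(read_est_fasta(write_fasta(c(">a", "ATQG"))), "characters")
})

test_that("six-frame translation follows the standard code with '.' stops", {
  fr <- six_frame_translate("ATGTAA")
  expect_equal(fr$aa_seq[fr$frame == 1], "M.")

  fr <- six_frame_translate("ATG")
  expect_equal(fr$aa_seq, c("M", "", "", "H", "", ""))  # revcomp CAT -> H

  expect_error(six_frame_translate("AT"), "shorter")

  # codons containing N translate to X
  fr <- six_frame_translate("ATGNNGTAA")
  expect_equal(fr$aa_seq[fr$frame == 1], "MX.")
})

test_that("frame lengths follow floor arithmetic on a 457-nt read", {
  set.seed(1)
  nt <- paste(sample(c("A", "C", "G", "T"), 457, replace = TRUE),
              collapse = "")
  fr <- six_frame_translate(nt)
  expect_true(all(nchar(fr$aa_seq) %in% c(151L, 152L)))
  expect_equal(nchar(fr$aa_seq[fr$frame == 1]), 152L)
})

test_that("translating the reverse complement swaps forward/reverse frames", {
  set.seed(42)
  for (k in 1:20) {
    nt <- paste(sample(c("A", "C", "G", "T", "N"), sample(30:200, 1),
                       replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", nt), "")[[1]]),
                collapse = "")
    f1 <- six_frame_translate(nt)
    f2 <- six_frame_translate(rc)
    expect_setequal(f1$aa_seq[f1$frame <= 3], f2$aa_seq[f2$frame >= 4])
    expect_setequal(f1$aa_seq[f1$frame >= 4], f2$aa_seq[f2$frame <= 3])
  }
})

frames_df <- function(aa) {
  data.frame(est_id = "x", frame = 1L, aa_seq = aa, stringsAsFactors = FALSE)
}

test_that("ORF detection reports maximal Met-to-stop segments", {
  orfs <- detect_orfs(frames_df("AAM.MCCCC."), min_len = 1L)
  expect_equal(orfs$protein, c("M", "MCCCC"))
  expect_true(all(orfs$has_stop))
  # end_aa indexes the stop symbol
  expect_equal(substring("AAM.MCCCC.", orfs$end_aa + 1L, orfs$end_aa + 1L),
               c(".", "."))

  orfs <- detect_orfs(frames_df("MAAAA"), min_len = 3L)
  expect_equal(nrow(orfs), 1L)
  expect_false(orfs$has_stop)

  # nested starts: only the longest by default, all when asked
  orfs <- detect_orfs(frames_df("MAMAA."), min_len = 1L)
  expect_equal(orfs$protein, "MAMAA")
  orfs <- detect_orfs(frames_df("MAMAA."), min_len = 1L, all_starts = TRUE)
  expect_setequal(orfs$protein, c("MAMAA", "MAA"))
})

test_that("every ORF re-embeds exactly into its frame translation", {
  set.seed(9)
  for (k in 1:25) {
    aa <- paste(sample(c("M", "A", "C", ".", "K"), sample(20:120, 1),
                       replace = TRUE, prob = c(.1, .4, .2, .1, .2)),
                collapse = "")
    orfs <- detect_orfs(frames_df(aa), min_len = 1L)
    for (i in seq_len(nrow(orfs))) {
      expect_equal(substr(aa, orfs$start_aa[i] + 1L, orfs$end_aa[i]),
                   orfs$protein[i])
      if (orfs$has_stop[i]) {
        expect_equal(substr(aa, orfs$end_aa[i] + 1L, orfs$end_aa[i] + 1L), ".")
      }
    }
  }
})

test_that("length statistics use the middle-order median and 100-nt bins", {
  s <- length_stats(c(400L, 457L, 500L))
  expect_equal(s$median, 457)
  expect_equal(length_stats(c(1L, 3L))$median, 2)
  expect_equal(sum(s$histogram$count), 3L)
  expect_equal(s$histogram$count[s$histogram$bin_start == 400], 2L)
  expect_error(length_stats(integer(0)), "at least one")
})
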