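# Shared constants and small helpers.

# The 20 standard residues; 'X' is ambiguous (untranslatable codon), '.' is the
# stop symbol used throughout internal amino-acid strings. '*' is reserved for
# the motif pattern language and never appears in sequences.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

STOP_CHAR <- "."

# Kyte-Doolittle hydropathy index, used by the built-in signal peptide
# heuristic.
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  K = -3.9, L =  3.8, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
  X =  0.0
)

# Small residues tolerated at the -1/-3 positions of a signal peptidase site.
SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Uniform reverse translation table (codon chosen uniformly among synonyms).
CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  # standard table order: first base slowest, third base fastest
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), 4L),
                   rep(bases, 16L))
  aa <- chars(paste0(
    "FFLLSSSSYY..CC.WLLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  ))
  split(codons, aa)
})

# Forward lookup table for the standard genetic code (names = codons); any
# codon absent from the table (i.e. containing N) translates to 'X'.
GENCODE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

reverse_translate <- function(protein) {
  cc <- chars(protein)
  paste(vapply(cc, function(a) {
    syn <- CODON_TABLE[[a]]
    syn[sample.int(length(syn), 1L)]
  }, character(1)), collapse = "")
}

random_nt <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(nt) {
  paste(rev(chars(chartr("ACGTN", "TGCAN", nt))), collapse = "")
}
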