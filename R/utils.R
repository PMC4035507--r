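# Shared internal helpers: rounding, seeded RNG sub-streams, amino-acid
# tables and codon-level translation used across the simulation and the
# analysis stages.

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero for
#' non-negative input (0.5 -> 1), as printed tables in the phage-display
#' literature do, rather than the IEEE round-half-even used by [round()].
#'
#' @param x Non-negative numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))      # 1 2 3
#' round_half_up(94.444, 1)             # 94.4
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), all(is.na(x) | x >= 0))
  f <- 10^digits
  # epsilon guard: values such as 2.675 are stored just below the tie
  floor(x * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

#' Report a probability as a percentage
#'
#' @param p Probability (or vector) in \[0, 1\].
#' @param digits Decimal places of the percentage report (default 1).
#' @return `100 * p`, rounded half-up.
#' @export
as_percent <- function(p, digits = 1) {
  round_half_up(100 * p, digits)
}

# Derive a per-operation RNG seed from a global seed and an operation
# name, so that independent stages draw from independent streams.  Plain
# polynomial hash kept below 2^31 - 1.
derive_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  h <- 0
  for (k in utf8ToInt(op)) h <- (h * 131 + k) %% 1048573
  as.integer((as.numeric(seed) %% 1000003) * 2011 + h * 7 + 1) %% 2147483629L
}

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Kyte-Doolittle hydropathy values of a peptide
#'
#' @param aa_seq Single amino-acid string (20 standard residues).
#' @return Numeric vector of per-residue hydropathy values.
#' @export
kd_hydropathy <- function(aa_seq) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1)
  res <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  v <- KD_SCALE[res]
  if (anyNA(v)) {
    stop("non-standard amino acid(s): ",
         paste(unique(res[is.na(v)]), collapse = ", "))
  }
  unname(v)
}

# Bacterial genetic code (translation table 11).
GENETIC_CODE_11 <- Biostrings::getGeneticCode("11")
STOP_CODONS <- names(GENETIC_CODE_11)[GENETIC_CODE_11 == "*"]

# Split a nucleotide string into codons starting at `from` (0-based),
# full codons only.
split_codons <- function(seq, from = 0) {
  n <- nchar(seq)
  starts <- seq.int(from + 1, by = 3, length.out = (n - from) %/% 3)
  if (length(starts) == 0) return(character(0))
  substring(seq, starts, starts + 2)
}

# Translate a codon vector with table 11; stops become "*".
translate_codons <- function(codons) {
  aa <- GENETIC_CODE_11[codons]
  if (anyNA(aa)) stop("untranslatable codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  paste(aa, collapse = "")
}

check_dna_alphabet <- function(seq, what = "sequence") {
  if (grepl("[^ACGT]", seq)) {
    stop(what, " contains non-ACGT symbols (IUPAC ambiguity codes are ",
         "rejected by default)")
  }
  invisible(seq)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# One codon per amino acid for back-translation of synthetic proteins.
# Hydrophobic residues use codons whose frame-shifted readings, on
# either strand, are non-hydrophobic or stops (poly-CTC reads as
# poly-S/poly-P shifted and poly-E/R/G on the minus strand; poly-GTC
# likewise), so hydrophobic signal blocks do not bleed spurious
# transmembrane calls into the other reading frames of the synthetic
# genome.
BACKTRANSLATE <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
  Q = "CAA", E = "GAA", G = "GGG", H = "CAT", I = "ATA",
  L = "CTC", K = "AAA", M = "ATG", F = "TTC", P = "CCC",
  S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTC"
)

back_translate <- function(aa_seq) {
  res <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  cod <- BACKTRANSLATE[res]
  if (anyNA(cod)) stop("cannot back-translate residue(s): ",
                       paste(unique(res[is.na(cod)]), collapse = ", "))
  paste(cod, collapse = "")
}
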