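# Synthetic community generator.
#
# Emulates the DNA source of a secretome-selective shotgun library: a
# small community of replicons whose ORFs carry membrane-targeting
# signals at a configurable fraction, with every ORF labelled by its
# ground-truth signal category so downstream classification can be
# scored exactly.
#
# Replicon architecture (a deliberate design choice): ORFs are tiled
# back-to-back on the + strand, all in one frame, each ending in its
# TAA stop codon, with a single 12-nt stop cassette at the replicon
# start.  Every ORF is therefore immediately preceded by an in-frame
# stop, so a junction-anchored open run always begins exactly at an ORF
# start, and the fraction of genome covered by secretome ORFs equals
# the configured ORF fraction exactly -- which is what makes the
# analytic clone lottery (fraction x 1/2 x 1/3) hold without geometric
# corrections.

# stops in all three frames on both strands
START_CASSETTE <- "TTAATTAATTAA"

# Spacer/tail residues are restricted to glycine and proline (codons
# GGG and CCC): every frame-shifted or reverse-strand reading of a
# random G/P codon stream yields only G, A, P or R, so non-signal
# sequence can never mimic a transmembrane span (or any other
# detector motif) in any of the six frames.
POLAR_RESIDUES <- c("G", "P")

ORF_CATEGORIES <- c("TYPE_I", "TYPE_II", "TYPE_IV", "TMH_ANCHOR",
                    "TMH_INTERNAL_MULTI", "TAT", "NONE")

# pilot-library-like mix of signal types among secretome ORFs
DEFAULT_CATEGORY_WEIGHTS <- c(TYPE_I = 35, TYPE_II = 3, TYPE_IV = 1,
                              TMH_ANCHOR = 8, TMH_INTERNAL_MULTI = 6,
                              TAT = 0)

random_polar <- function(n) {
  if (n <= 0) return("")
  paste(sample(POLAR_RESIDUES, n, replace = TRUE), collapse = "")
}

#' Synthesize a membrane-targeting signal peptide
#'
#' Builds an N-terminal peptide of the requested category to the exact
#' architecture the built-in detectors test for, so generator output is
#' recognised by construction: TYPE_I has a charged n-region,
#' 8-leucine h-region and A-X-A cleavage box; TYPE_II a lipobox with
#' the cysteine at position 13; TYPE_IV the prepilin G|[GAS]F motif
#' plus hydrophobic run; TMH variants carry 20-residue hydrophobic
#' spans (N-terminal, or internal/double beyond residue 40); TAT the
#' S/T-R-R-x-F-L-K twin-arginine consensus.
#'
#' @param category One of TYPE_I, TYPE_II, TYPE_IV, TMH_ANCHOR,
#'   TMH_INTERNAL_MULTI, TAT.
#' @param seed Integer seed for the (small) random spacer choices.
#' @return Amino-acid string (signal region only, starting with M).
#' @export
synthesize_signal_peptide <- function(category, seed = 1) {
  if (!category %in% setdiff(ORF_CATEGORIES, "NONE")) {
    stop("unknown signal category: ", category)
  }
  withr::with_seed(derive_seed(seed, paste0("sigpep_", category)), {
    switch(category,
      TYPE_I = paste0("MK", random_polar(2), strrep("L", 8), "STASA"),
      TYPE_II = paste0("MK", random_polar(1), strrep("L", 6), "LAGC"),
      TYPE_IV = paste0("MGAF", "ILVIL", random_polar(2)),
      TMH_ANCHOR = paste0("MST", strrep("L", 20)),
      TMH_INTERNAL_MULTI = paste0("M", random_polar(50), strrep("L", 20),
                                  random_polar(8), strrep("L", 20)),
      TAT = paste0("MS", "TRRNFLK", strrep("L", 6))
    )
  })
}

# Largest-remainder allocation of n items by non-negative weights.
allocate_counts <- function(n, weights) {
  if (n == 0) return(stats::setNames(integer(length(weights)),
                                     names(weights)))
  w <- weights / sum(weights)
  raw <- n * w
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(weights))
}

# Small synthetic lineage table; taxids and names are invented.
#' Synthetic taxon lineage table
#'
#' A small invented lineage table (taxid, superkingdom..genus) used to
#' label synthetic replicons and to plant mock BLAST best hits.  All
#' names are synthetic placeholders, not real taxa.
#'
#' @param n Number of lineages (default 8, max 26).
#' @return data.frame with columns `taxid`, `superkingdom`, `phylum`,
#'   `class`, `order`, `family`, `genus`.
#' @export
synthetic_lineages <- function(n = 8) {
  stopifnot(n >= 1, n <= 26)
  tag <- LETTERS[seq_len(n)]
  data.frame(
    taxid = 1000L + seq_len(n),
    superkingdom = "Bacteria",
    phylum = paste0("Phylum_", rep(LETTERS[1:4], length.out = n)),
    class = paste0("Class_", tag),
    order = paste0("Order_", tag),
    family = paste0("Family_", tag),
    genus = paste0("Genus_", tag)
  )
}

#' Generate a synthetic community with known signal ground truth
#'
#' Creates `n_replicons` circular replicons tiling `n_orfs` equal-length
#' ORFs, of which exactly `round(secretome_fraction * n_orfs)` carry a
#' membrane-targeting signal (exact-count allocation across categories
#' by `category_weights`, positions randomised).  Deterministic for a
#' fixed seed.
#'
#' @param n_replicons Number of replicons (>= 1).
#' @param n_orfs Total ORF count (> 0, >= `n_replicons`).
#' @param secretome_fraction Fraction of ORFs with a signal (default
#'   0.20).
#' @param seed Integer seed.
#' @param orf_length_aa Protein length of every ORF in residues,
#'   excluding the stop (default 150; must fit the longest signal).
#' @param category_weights Named non-negative weights over the six
#'   signal categories (default: pilot-library-like mix with TAT = 0).
#' @param max_replicon_length Optional cap on replicon length (nt); an
#'   error is raised if the ORFs do not fit.
#' @return A `synthetic_community`: list with `replicons`
#'   (DNAStringSet), `orfs` (data.frame: orf_id, replicon_id, start,
#'   end 0-based half-open incl. stop codon, strand, signal_category,
#'   protein), and `taxon_labels` (replicon -> lineage).
#' @examples
#' com <- generate_community(1, 100, 0.20, seed = 42)
#' sum(com$orfs$signal_category != "NONE")  # exactly 20
#' @export
generate_community <- function(n_replicons, n_orfs,
                               secretome_fraction = 0.20, seed = 1,
                               orf_length_aa = 150,
                               category_weights = DEFAULT_CATEGORY_WEIGHTS,
                               max_replicon_length = NULL) {
  stopifnot(n_replicons >= 1, n_orfs > 0,
            secretome_fraction >= 0, secretome_fraction <= 1)
  if (n_orfs < n_replicons) stop("need at least one ORF per replicon")
  min_len <- 110  # longest signal architecture (internal/double TMH)
  if (orf_length_aa < min_len) {
    stop("`orf_length_aa` must be >= ", min_len,
         " to fit every signal architecture")
  }
  category_weights <- category_weights[
    setdiff(ORF_CATEGORIES, "NONE")[
      setdiff(ORF_CATEGORIES, "NONE") %in% names(category_weights)]]
  if (!length(category_weights) || any(category_weights < 0)) {
    stop("`category_weights` must be non-negative weights over signal ",
         "categories")
  }

  n_secr <- round(secretome_fraction * n_orfs)
  counts <- allocate_counts(n_secr, category_weights)

  categories <- rep("NONE", n_orfs)
  withr::with_seed(derive_seed(seed, "community_layout"), {
    secr_idx <- sample.int(n_orfs, n_secr)
    categories[secr_idx] <- sample(rep(names(counts), counts))
  })

  proteins <- character(n_orfs)
  withr::with_seed(derive_seed(seed, "community_proteins"), {
    for (i in seq_len(n_orfs)) {
      head_aa <- if (categories[i] == "NONE") {
        paste0("M", random_polar(2))
      } else {
        synthesize_signal_peptide(categories[i],
                                  seed = derive_seed(seed, paste0("p", i)))
      }
      tail_len <- orf_length_aa - nchar(head_aa)
      if (tail_len < 0) stop("`orf_length_aa` too short for signal")
      proteins[i] <- paste0(head_aa, random_polar(tail_len))
    }
  })

  orf_nt <- vapply(proteins, function(p) paste0(back_translate(p), "TAA"),
                   character(1), USE.NAMES = FALSE)
  orf_len <- 3 * (orf_length_aa + 1)

  per <- ceiling(n_orfs / n_replicons)
  rep_of_orf <- rep(seq_len(n_replicons), each = per)[seq_len(n_orfs)]
  rep_ids <- sprintf("replicon_%02d", seq_len(n_replicons))

  replicons <- character(n_replicons)
  orf_rows <- vector("list", n_orfs)
  for (r in seq_len(n_replicons)) {
    idx <- which(rep_of_orf == r)
    replicons[r] <- paste0(START_CASSETTE, paste(orf_nt[idx], collapse = ""))
    if (!is.null(max_replicon_length) &&
        nchar(replicons[r]) > max_replicon_length) {
      stop("sizing error: ORFs exceed the replicon length budget (",
           nchar(replicons[r]), " > ", max_replicon_length, " nt)")
    }
    offset <- nchar(START_CASSETTE)
    for (k in seq_along(idx)) {
      i <- idx[k]
      start <- offset + (k - 1) * orf_len
      orf_rows[[i]] <- data.frame(
        orf_id = sprintf("orf_%05d", i),
        replicon_id = rep_ids[r],
        start = start, end = start + orf_len, strand = "+",
        signal_category = categories[i],
        protein = proteins[i]
      )
    }
  }
  orfs <- do.call(rbind, orf_rows)
  rownames(orfs) <- NULL

  lineages <- synthetic_lineages(min(26, max(2, n_replicons)))
  tax <- lineages[rep(seq_len(nrow(lineages)),
                      length.out = n_replicons), , drop = FALSE]
  tax <- cbind(replicon_id = rep_ids, tax)
  rownames(tax) <- NULL

  structure(
    list(
      replicons = Biostrings::DNAStringSet(
        stats::setNames(replicons, rep_ids)),
      orfs = orfs,
      taxon_labels = tax,
      settings = list(n_replicons = n_replicons, n_orfs = n_orfs,
                      secretome_fraction = secretome_fraction,
                      orf_length_aa = orf_length_aa, seed = seed)
    ),
    class = "synthetic_community"
  )
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "Synthetic community: %d replicon(s), %d ORFs (%d secretome, %.1f%%)\n",
    length(x$replicons), nrow(x$orfs),
    sum(x$orfs$signal_category != "NONE"),
    100 * mean(x$orfs$signal_category != "NONE")))
  invisible(x)
}
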