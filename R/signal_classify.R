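# Heuristic membrane-targeting signal detectors and the category
# decision logic.
#
# The detectors are deliberately simple deterministic rules capturing
# the canonical architecture of each signal type (charged n-region,
# hydrophobic h-region, motif), not reimplementations of the published
# neural-network/HMM predictors.  For real data, external predictor
# verdicts can be supplied as a table and override the built-in rules
# per category; the testable core is the decision logic.

SIGNAL_CATEGORIES <- c("TYPE_I", "TYPE_II", "TYPE_IV", "TMH_ANCHOR",
                       "TMH_INTERNAL_MULTI", "TAT", "NONCLASSICAL",
                       "BACKGROUND")

#' Detect a classical (type I) signal peptide
#'
#' Fires iff the peptide has (i) at least one K/R within residues 1-5
#' (positively charged n-region), (ii) a hydrophobic core: some 7-residue
#' window within residues 6-20 with mean Kyte-Doolittle hydropathy
#' > 1.6, and (iii) an A-X-A signal-peptidase-I box ending at a position
#' in 15-30 (the cleavage site).
#'
#' @param aa_seq Amino-acid string (>= 24 residues for a meaningful
#'   call; shorter input simply cannot fire).
#' @return List `(verdict, cleavage_pos)`; `cleavage_pos` is the
#'   position of the last A of the earliest qualifying A-X-A, or NA.
#' @export
detect_spI <- function(aa_seq) {
  n <- nchar(aa_seq)
  res <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  has_charge <- any(res[seq_len(min(5, n))] %in% c("K", "R"))
  hyd <- FALSE
  if (n >= 12) {
    kd <- kd_hydropathy(aa_seq)
    for (s in 6:min(14, n - 6)) {
      if (mean(kd[s:(s + 6)]) > 1.6) { hyd <- TRUE; break }
    }
  }
  cleave <- NA_integer_
  for (p in 15:min(30, n)) {
    if (p >= 3 && res[p] == "A" && res[p - 2] == "A") { cleave <- p; break }
  }
  list(verdict = has_charge && hyd && !is.na(cleave),
       cleavage_pos = cleave)
}

#' Detect a lipoprotein (type II) signal peptide
#'
#' Fires iff the peptide matches the lipobox `[LVIFG][ASTVG][GAS]C`
#' with the invariant cysteine (the lipidation site) at position 12-35,
#' and carries at least one K/R within residues 1-7.
#'
#' @param aa_seq Amino-acid string.
#' @return List `(verdict, cys_pos)`.
#' @export
detect_lipobox <- function(aa_seq) {
  n <- nchar(aa_seq)
  res <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  has_charge <- any(res[seq_len(min(7, n))] %in% c("K", "R"))
  m <- gregexpr("[LVIFG][ASTVG][GAS]C", aa_seq)[[1]]
  cys <- NA_integer_
  if (m[1] > 0) {
    cys_positions <- m + 3L  # C is the 4th residue of the match
    cys_positions <- cys_positions[cys_positions >= 12 & cys_positions <= 35]
    if (length(cys_positions)) cys <- cys_positions[1]
  }
  list(verdict = has_charge && !is.na(cys), cys_pos = cys)
}

#' Detect a pilin-like (type IV) signal
#'
#' Fires on the class-III prepilin architecture: a glycine immediately
#' preceding a `[GAS]F` pair within the first 12 residues (the
#' prepilin-peptidase cleavage G|F motif) followed by a run of at least
#' five strongly hydrophobic residues.
#'
#' @param aa_seq Amino-acid string.
#' @return List `(verdict, motif_pos)` where `motif_pos` is the
#'   position of the conserved glycine, or NA.
#' @export
detect_pilin <- function(aa_seq) {
  m <- regexpr("G[GAS]F[AILMFVW]{5}", aa_seq)[[1]]
  verdict <- m > 0 && m <= 12
  list(verdict = verdict, motif_pos = if (verdict) m else NA_integer_)
}

#' Detect a twin-arginine (Tat) signal
#'
#' Fires on the S/T-R-R-x-F-L-K consensus with the twin arginines in
#' the N-terminal region (motif starting within the first 15 residues).
#'
#' @param aa_seq Amino-acid string.
#' @return List `(verdict, motif_pos)`.
#' @export
detect_tat <- function(aa_seq) {
  m <- regexpr("[ST]RR.FLK", aa_seq)[[1]]
  verdict <- m > 0 && m <= 15
  list(verdict = verdict, motif_pos = if (verdict) m else NA_integer_)
}

#' Detect transmembrane helices by sliding-window hydropathy
#'
#' Classic Kyte-Doolittle scan: every window of `window` residues whose
#' mean hydropathy exceeds `threshold` marks a candidate membrane
#' span; overlapping qualifying windows are merged into maximal
#' intervals.
#'
#' @param aa_seq Amino-acid string.
#' @param window Window size in residues (default 19).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @return data.frame with columns `start`, `end` (1-based inclusive
#'   residue positions); zero rows when nothing qualifies or the
#'   sequence is shorter than `window`.
#' @export
detect_tmh <- function(aa_seq, window = 19, threshold = 1.6) {
  n <- nchar(aa_seq)
  empty <- data.frame(start = integer(), end = integer())
  if (n < window) return(empty)
  kd <- kd_hydropathy(aa_seq)
  means <- as.numeric(stats::filter(kd, rep(1 / window, window),
                                    sides = 1))
  # means[i] covers residues (i - window + 1) .. i
  qual <- which(!is.na(means) & means > threshold) - window + 1L
  if (!length(qual)) return(empty)
  r <- rle(diff(qual) == 1)
  # merge window starts into maximal intervals
  breaks <- c(0, which(diff(qual) != 1), length(qual))
  out <- do.call(rbind, lapply(seq_len(length(breaks) - 1), function(i) {
    s <- qual[breaks[i] + 1]
    e <- qual[breaks[i + 1]] + window - 1L
    data.frame(start = s, end = e)
  }))
  rownames(out) <- NULL
  out
}

#' Classify the membrane-targeting signal of a fusion region
#'
#' Applies the built-in detectors with fixed precedence (specific motifs
#' above generic hydropathy):
#' `TYPE_IV > TYPE_II > TAT > TYPE_I > TMH_ANCHOR` (first helix starting
#' at residue <= 40) `> TMH_INTERNAL_MULTI > NONCLASSICAL`
#' (`secp_score >= secp_threshold`) `> BACKGROUND`.  Regions shorter
#' than `min_fusion_len` residues are background regardless of content.
#' External predictor verdicts, when supplied, override the built-in
#' detector for the same category.
#'
#' @param orf A `fusion_orf` from [extract_fusion_orf()], or a plain
#'   amino-acid string.
#' @param secp_score Optional non-classical secretion score.
#' @param external_calls Optional data.frame `(category, verdict)` of
#'   external predictor verdicts for this region; `verdict` logical.
#' @param params A [model_params()].
#' @return A `signal_call`: list with `category`, `evidence` (named
#'   logical vector of detector verdicts) and `secp_score`.
#' @export
classify_signal <- function(orf, secp_score = NA_real_,
                            external_calls = NULL,
                            params = model_params()) {
  aa <- if (inherits(orf, "fusion_orf")) orf$aa_seq else orf
  stopifnot(is.character(aa), length(aa) == 1)
  evidence <- c(TYPE_IV = detect_pilin(aa)$verdict,
                TYPE_II = detect_lipobox(aa)$verdict,
                TAT = detect_tat(aa)$verdict,
                TYPE_I = detect_spI(aa)$verdict)
  tmh <- detect_tmh(aa)
  evidence["TMH_ANCHOR"] <- nrow(tmh) > 0 && tmh$start[1] <= 40
  evidence["TMH_INTERNAL_MULTI"] <- nrow(tmh) > 0 && !evidence["TMH_ANCHOR"]
  if (!is.null(external_calls)) {
    if (!is.data.frame(external_calls) ||
        !all(c("category", "verdict") %in% names(external_calls))) {
      stop("malformed external predictor table: need columns ",
           "`category` and `verdict`")
    }
    for (i in seq_len(nrow(external_calls))) {
      cat_i <- as.character(external_calls$category[i])
      if (!cat_i %in% names(evidence)) {
        stop("malformed external predictor table at row ", i,
             ": unknown category '", cat_i, "'")
      }
      v <- external_calls$verdict[i]
      if (is.na(v)) {
        stop("malformed external predictor table at row ", i,
             ": verdict must be TRUE/FALSE")
      }
      evidence[cat_i] <- isTRUE(as.logical(v))
    }
  }
  category <- if (nchar(aa) < params$min_fusion_len) {
    "BACKGROUND"
  } else if (evidence[["TYPE_IV"]]) "TYPE_IV"
  else if (evidence[["TYPE_II"]]) "TYPE_II"
  else if (evidence[["TAT"]]) "TAT"
  else if (evidence[["TYPE_I"]]) "TYPE_I"
  else if (evidence[["TMH_ANCHOR"]]) "TMH_ANCHOR"
  else if (evidence[["TMH_INTERNAL_MULTI"]]) "TMH_INTERNAL_MULTI"
  else if (!is.na(secp_score) && secp_score >= params$secp_threshold) {
    "NONCLASSICAL"
  } else "BACKGROUND"
  structure(list(category = category, evidence = evidence,
                 secp_score = secp_score),
            class = "signal_call")
}

#' Tally signal categories across a set of calls
#'
#' @param calls List of `signal_call` objects (or a character vector of
#'   categories).
#' @param sequences Optional character vector of the underlying protein
#'   sequences; when given, a distinct-sequence tally (after 100%
#'   identity deduplication via [dedup_sequences()]) is attached.
#' @return data.frame `(category, count)` over all categories, in the
#'   fixed category order; attribute `distinct` holds the deduplicated
#'   tally when `sequences` is supplied.
#' @export
tally_signal_categories <- function(calls, sequences = NULL) {
  cats <- if (is.character(calls)) calls else {
    vapply(calls, function(x) x$category, character(1))
  }
  bad <- setdiff(unique(cats), SIGNAL_CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  tab <- table(factor(cats, levels = SIGNAL_CATEGORIES))
  out <- data.frame(category = names(tab), count = as.integer(tab))
  if (!is.null(sequences)) {
    stopifnot(length(sequences) == length(cats))
    clusters <- dedup_sequences(sequences)
    keep <- !duplicated(clusters$cluster)
    dtab <- table(factor(cats[keep], levels = SIGNAL_CATEGORIES))
    attr(out, "distinct") <- data.frame(category = names(dtab),
                                        count = as.integer(dtab))
  }
  out
}
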