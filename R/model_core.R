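# Selection-probability model and enrichment arithmetic.
#
# A metagenomic insert ends up displayed on the virion surface (and so
# survives sarcosyl selection) only if it (i) encodes a membrane-targeting
# signal, (ii) was cloned in the orientation of the display cassette, and
# (iii) is translationally in-frame with the vector-encoded pIII C-domain.
# Under random shearing and blunt cloning these are independent lotteries,
# giving the expected pre-selection frequency
#   f_exp = secretome_fraction * p_orientation * p_frame.

#' Model parameters and analysis thresholds
#'
#' Bundles the clone-lottery probabilities and every threshold used by
#' the downstream analysis stages, with validation.  Defaults follow the
#' standard secretome phage-display analysis settings: ~20% of bacterial
#' ORFs encode secretome (secreted/surface/membrane) proteins, blunt
#' cloning gives 1/2 correct orientation and 1/3 correct frame, fusions
#' shorter than 24 aa are background, dbCAN hits are kept at
#' E < 1e-5 for alignments > 80 aa (otherwise E < 1e-3), and taxonomic
#' best hits require E < 1e-5 with query coverage > 30%.
#'
#' @param secretome_fraction Fraction of community ORFs carrying a
#'   membrane-targeting signal (default 0.20).
#' @param p_orientation Probability an insert is cloned in the cassette
#'   orientation (default 0.5).
#' @param p_frame Probability the insert ORF is in-frame with pIII
#'   (default 1/3).
#' @param min_fusion_len Minimum insert-encoded fusion length in amino
#'   acids (default 24); shorter fusions are background.
#' @param secp_threshold Non-classical secretion score threshold
#'   (default 0.5).
#' @param aln_len_cutoff Domain-hit alignment length (aa) above which the
#'   strict E-value applies (default 80).
#' @param evalue_strict,evalue_relaxed Domain-hit E-value cutoffs
#'   (defaults 1e-5 and 1e-3; strict must be smaller).
#' @param bits_cohesin_slh Bit-score threshold for taxonomic assignment
#'   of cohesin- and SLH-containing ORFs (default 40).
#' @param bits_dockerin Bit-score threshold for dockerin-containing ORFs
#'   (default 35).
#' @param qcov_min Minimum query coverage for best-hit taxonomy
#'   (fraction, default 0.30).
#' @param identity_min Minimum identity for rank roll-ups (fraction,
#'   default 0.30); hits below it are "Unassigned".
#' @param alpha Significance level for proportion comparisons
#'   (default 0.001).
#' @param background_escape Per-clone probability that a non-displaying
#'   clone survives selection anyway (default 0.002, which places the
#'   residual background near the ~5% seen in pilot libraries).
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params()
#' expected_selection_frequency(p)          # 1/15
#' as_percent(expected_selection_frequency(p))  # 3.3
#' @export
model_params <- function(secretome_fraction = 0.20,
                         p_orientation = 0.5,
                         p_frame = 1 / 3,
                         min_fusion_len = 24,
                         secp_threshold = 0.5,
                         aln_len_cutoff = 80,
                         evalue_strict = 1e-5,
                         evalue_relaxed = 1e-3,
                         bits_cohesin_slh = 40,
                         bits_dockerin = 35,
                         qcov_min = 0.30,
                         identity_min = 0.30,
                         alpha = 0.001,
                         background_escape = 0.002) {
  p <- list(
    secretome_fraction = secretome_fraction,
    p_orientation = p_orientation,
    p_frame = p_frame,
    min_fusion_len = min_fusion_len,
    secp_threshold = secp_threshold,
    aln_len_cutoff = aln_len_cutoff,
    evalue_strict = evalue_strict,
    evalue_relaxed = evalue_relaxed,
    bits_cohesin_slh = bits_cohesin_slh,
    bits_dockerin = bits_dockerin,
    qcov_min = qcov_min,
    identity_min = identity_min,
    alpha = alpha,
    background_escape = background_escape
  )
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  probs <- c("secretome_fraction", "p_orientation", "p_frame", "qcov_min",
             "identity_min", "alpha", "background_escape")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("`", nm, "` must be a probability in [0, 1]")
    }
  }
  pos <- c("min_fusion_len", "aln_len_cutoff", "evalue_strict",
           "evalue_relaxed", "bits_cohesin_slh", "bits_dockerin",
           "secp_threshold")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop("`", nm, "` must be a positive number")
    }
  }
  if (p$evalue_strict >= p$evalue_relaxed) {
    stop("`evalue_strict` must be smaller than `evalue_relaxed`")
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Secretome phage-display model parameters\n")
  cat(sprintf("  lottery: secretome %.3g x orientation %.3g x frame %.3g\n",
              x$secretome_fraction, x$p_orientation, x$p_frame))
  cat(sprintf("  expected selected fraction: %.4g (%s%%)\n",
              expected_selection_frequency(x),
              format(as_percent(expected_selection_frequency(x)))))
  cat(sprintf("  min fusion length: %d aa; background escape: %.3g\n",
              as.integer(x$min_fusion_len), x$background_escape))
  invisible(x)
}

#' Expected fraction of clones surviving secretome selection
#'
#' The product of the three independent clone lotteries: carrying a
#' secretome ORF, correct orientation, and correct reading frame.  With
#' the defaults (0.20, 1/2, 1/3) this is 1/30 of the library: about
#' 3.3% of primary clones are expected to display and survive.
#'
#' @param params A [model_params()] object.
#' @return The expected selected fraction as a probability.  Use
#'   [as_percent()] for the one-decimal percentage report.
#' @examples
#' as_percent(expected_selection_frequency(model_params()))  # 3.3
#' @export
expected_selection_frequency <- function(params = model_params()) {
  validate_model_params(params)
  params$secretome_fraction * params$p_orientation * params$p_frame
}

#' Fold enrichment of secretome clones after selection
#'
#' Compares the observed post-selection frequency of secretome-encoding
#' clones with the expected pre-selection frequency.  By default the
#' observed percentage is first rounded to `decimals` places (the
#' reporting precision) and the fold is taken on the rounded value, so
#' that printed frequencies reproduce printed folds; `exact = TRUE`
#' uses the unrounded ratio instead.
#'
#' @param n_observed Number of secretome-positive clones among those
#'   sequenced after selection.
#' @param n_total Total clones examined (> 0).
#' @param expected_freq_pct Expected pre-selection frequency, as a
#'   percentage (> 0), e.g. `as_percent(expected_selection_frequency(p))`.
#' @param decimals Reporting precision of the observed percentage
#'   (default 1).
#' @param exact Use the unrounded observed frequency (default FALSE).
#' @return An `enrichment_result`: list with `observed_freq` (reported
#'   percentage), `observed_exact`, `expected_freq`, `fold`,
#'   `fold_rounded` (half-up integer), `n_observed`, `n_total`.
#' @examples
#' enrichment_fold(85, 90, 3.3)  # observed 94.4%, ~29-fold
#' @export
enrichment_fold <- function(n_observed, n_total, expected_freq_pct,
                            decimals = 1, exact = FALSE) {
  stopifnot(length(n_observed) == 1, length(n_total) == 1)
  if (!is.numeric(n_total) || n_total <= 0) {
    stop("`n_total` must be > 0: enrichment ratio undefined")
  }
  if (!is.numeric(expected_freq_pct) || expected_freq_pct <= 0) {
    stop("`expected_freq_pct` must be > 0: enrichment ratio undefined")
  }
  if (n_observed < 0 || n_observed > n_total) {
    stop("`n_observed` must lie in [0, n_total]")
  }
  observed_exact <- 100 * n_observed / n_total
  observed <- round_half_up(observed_exact, decimals)
  fold <- (if (exact) observed_exact else observed) / expected_freq_pct
  structure(
    list(
      observed_freq = observed,
      observed_exact = observed_exact,
      expected_freq = expected_freq_pct,
      fold = fold,
      fold_rounded = round_half_up(fold, 0),
      n_observed = n_observed,
      n_total = n_total
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment: observed %s%% (%d/%d) vs expected %s%% -> %.1f-fold (~%d)\n",
    format(x$observed_freq), x$n_observed, x$n_total,
    format(x$expected_freq), x$fold, as.integer(x$fold_rounded)))
  invisible(x)
}
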