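# In silico sarcosyl selection.
#
# A clone survives selection iff its insert encodes an in-frame fusion
# of at least `min_fusion_len` codons with pIII AND that fusion carries
# a membrane-targeting signal.  Clones failing the rule survive
# independently with probability `background_escape`, lumping all real
# causes of residual background (cryptic targeting, detergent
# resistance) into one free parameter.

#' Apply secretome selection to a clone library
#'
#' Two classifier routes are provided.  `"truth"` (the perfect
#' classifier) applies the selection rule to the generator's
#' ground-truth labels: selected iff `truth_secretome & truth_in_frame`.
#' `"detect"` runs the sequence-level pipeline on each insert:
#' [extract_fusion_orf()] followed by [classify_signal()], selecting
#' clones whose fusion region classifies to any non-background
#' category.  Escape draws are deterministic for a fixed seed, and are
#' not re-drawn when an earlier selection outcome is re-selected (so
#' selection is idempotent).
#'
#' @param clones A `clone_library` from [shear_and_clone()] (or a prior
#'   selection outcome).
#' @param cassette A [vector_cassette()] (used by the `"detect"` route).
#' @param params A [model_params()].
#' @param classifier `"truth"` or `"detect"`.
#' @param seed Integer seed for the escape lottery.
#' @return A `selection_outcome`: the clone table plus `selected`
#'   (logical) and `reason` (one of `selected_secretome`,
#'   `background_escape`, `not_in_frame`, `too_short`, `no_signal`).
#' @export
simulate_selection <- function(clones, cassette = default_cassette(),
                               params = model_params(),
                               classifier = c("truth", "detect"),
                               seed = 1) {
  classifier <- match.arg(classifier)
  stopifnot(is.data.frame(clones), nrow(clones) > 0)
  n <- nrow(clones)

  if (classifier == "truth") {
    if (!all(c("truth_secretome", "truth_in_frame") %in% names(clones))) {
      stop("truth classifier needs `truth_secretome`/`truth_in_frame` ",
           "columns")
    }
    pass <- clones$truth_secretome & clones$truth_in_frame
    fail_reason <- ifelse(clones$truth_in_frame, "no_signal",
                          "not_in_frame")
  } else {
    if (!"insert" %in% names(clones) || anyNA(clones$insert)) {
      stop("detect classifier needs insert sequences ",
           "(shear_and_clone(..., sequences = TRUE))")
    }
    pass <- logical(n)
    fail_reason <- character(n)
    for (i in seq_len(n)) {
      fo <- extract_fusion_orf(clones$insert[i], cassette, params)
      if (is.null(fo)) {
        fail_reason[i] <- "too_short"
      } else {
        call <- classify_signal(fo, params = params)
        if (call$category == "BACKGROUND") {
          fail_reason[i] <- "no_signal"
        } else {
          pass[i] <- TRUE
        }
      }
    }
  }

  # escape lottery; prior escapes are honoured, not re-drawn
  prior_escape <- if ("reason" %in% names(clones)) {
    !is.na(clones$reason) & clones$reason == "background_escape"
  } else rep(FALSE, n)
  escape <- prior_escape
  fresh <- !pass & !prior_escape
  if (params$background_escape > 0 && any(fresh)) {
    withr::with_seed(derive_seed(seed, "selection_escape"), {
      u <- stats::runif(n)
    })
    escape[fresh] <- u[fresh] < params$background_escape
  }

  reason <- ifelse(pass, "selected_secretome",
                   ifelse(escape, "background_escape", fail_reason))
  out <- clones
  out$selected <- pass | escape
  out$reason <- reason
  class(out) <- unique(c("selection_outcome", class(out)))
  attr(out, "classifier") <- classifier
  attr(out, "params") <- params
  out
}

#' Summarise a selection outcome
#'
#' Computes the realised secretome frequency among selected clones, the
#' model-expected frequency, the fold enrichment, and the residual
#' background fraction (escapes among selected).
#'
#' @param outcome A [simulate_selection()] result.
#' @param params A [model_params()] (defaults to the parameters stored
#'   in the outcome).
#' @return List with `n_total`, `n_selected`, `selected_fraction`,
#'   `enrichment` (an `enrichment_result`, or NULL when nothing was
#'   selected), `background_fraction`, and
#'   `estimated_secretome_fraction` (the selected fraction divided by
#'   `p_orientation * p_frame`, inverting the clone lottery).
#' @export
summarize_selection <- function(outcome, params = NULL) {
  stopifnot(inherits(outcome, "selection_outcome"))
  if (is.null(params)) params <- attr(outcome, "params")
  if (is.null(params)) params <- model_params()
  n <- nrow(outcome)
  n_sel <- sum(outcome$selected)
  sel_frac <- n_sel / n
  est <- sel_frac / (params$p_orientation * params$p_frame)
  if (n_sel == 0) {
    return(list(n_total = n, n_selected = 0L, selected_fraction = 0,
                enrichment = NULL, background_fraction = NA_real_,
                estimated_secretome_fraction = est))
  }
  n_true <- sum(outcome$reason == "selected_secretome")
  n_escape <- sum(outcome$reason == "background_escape")
  enr <- enrichment_fold(
    n_true, n_sel,
    as_percent(expected_selection_frequency(params)))
  list(n_total = n, n_selected = as.integer(n_sel),
       selected_fraction = sel_frac, enrichment = enr,
       background_fraction = n_escape / n_sel,
       estimated_secretome_fraction = est)
}
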