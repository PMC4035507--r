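# Random shearing and blunt cloning of community DNA into the display
# cassette, with ground-truth clone labels.
#
# Replicons are treated as circular for shearing, so the insert 3'
# junction is uniform over the genome and the clone lottery
# (secretome-ORF hit x orientation x frame congruence) factorises
# exactly as the analytic selection model assumes.

#' Shear a community and clone inserts into the display cassette
#'
#' Draws `n_clones` inserts with positions uniform on the (circular)
#' replicons and lengths from a truncated log-normal (or uniform, or
#' degenerate) distribution on `[len_min, len_max]`; each insert is
#' cloned in the cassette orientation with probability `p_orientation`,
#' otherwise reverse-complemented.  Ground-truth labels are computed
#' from the annotation by junction-frame arithmetic:
#' `truth_secretome` is TRUE when the insert's 3' junction falls inside
#' a secretome ORF read in the cloned orientation, and `truth_in_frame`
#' when that ORF's codon grid is congruent with the pIII frame at the
#' junction.  Deterministic for a fixed seed.
#'
#' @param community A [generate_community()] result.
#' @param n_clones Number of clones (> 0).
#' @param len_min,len_max Insert length range in nt (defaults 700 and
#'   5000; `len_min >= 60`).
#' @param seed Integer seed.
#' @param p_orientation Probability of cassette orientation (default
#'   0.5).
#' @param cassette A [vector_cassette()]; only its `frame_offset`
#'   enters the truth arithmetic.
#' @param length_dist `"lognormal"` (default; `meanlog`, `sdlog`
#'   truncated to the range) or `"uniform"`.
#' @param meanlog,sdlog Log-normal parameters (defaults log(1500), 0.5).
#' @param sequences Keep insert sequences (default TRUE).  FALSE keeps
#'   only coordinates and truth labels, for large lottery-level
#'   simulations.
#' @return A `clone_library` data.frame: clone_id, replicon_id,
#'   src_start (0-based), length, orientation ("forward"/"reverse"),
#'   truth_secretome, truth_in_frame, truth_category, insert (or NA).
#' @export
shear_and_clone <- function(community, n_clones,
                            len_min = 700, len_max = 5000, seed = 1,
                            p_orientation = 0.5,
                            cassette = default_cassette(),
                            length_dist = c("lognormal", "uniform"),
                            meanlog = log(1500), sdlog = 0.5,
                            sequences = TRUE) {
  stopifnot(inherits(community, "synthetic_community"), n_clones > 0)
  if (len_min < 60) stop("`len_min` must be >= 60 nt")
  if (len_max < len_min) stop("`len_max` must be >= `len_min`")
  length_dist <- match.arg(length_dist)
  rep_len <- Biostrings::width(community$replicons)
  if (any(rep_len < len_max)) {
    stop("sizing error: replicon(s) shorter than `len_max` (",
         paste(rep_len[rep_len < len_max], collapse = ", "), " nt)")
  }
  rep_ids <- names(community$replicons)
  q <- cassette$frame_offset

  withr::with_seed(derive_seed(seed, "shear_and_clone"), {
    lens <- if (len_min == len_max) {
      rep(len_min, n_clones)
    } else if (length_dist == "uniform") {
      sample.int(len_max - len_min + 1L, n_clones, replace = TRUE) +
        len_min - 1L
    } else {
      lo <- stats::plnorm(len_min, meanlog, sdlog)
      hi <- stats::plnorm(len_max, meanlog, sdlog)
      pmin(pmax(round(stats::qlnorm(
        stats::runif(n_clones, lo, hi), meanlog, sdlog)),
        len_min), len_max)
    }
    rep_idx <- sample.int(length(rep_len), n_clones, replace = TRUE,
                          prob = rep_len)
    starts <- floor(stats::runif(n_clones) * rep_len[rep_idx])
    forward <- stats::runif(n_clones) < p_orientation
  })

  # junction base: last insert base on the genome, in cloned orientation
  junction <- ifelse(forward,
                     (starts + lens - 1) %% rep_len[rep_idx],
                     starts)

  orfs <- community$orfs
  truth_secretome <- logical(n_clones)
  truth_in_frame <- logical(n_clones)
  truth_category <- rep(NA_character_, n_clones)
  for (r in seq_along(rep_ids)) {
    sel <- which(rep_idx == r)
    if (!length(sel)) next
    o <- orfs[orfs$replicon_id == rep_ids[r], , drop = FALSE]
    hit <- findInterval(junction[sel], o$start)
    inside <- hit >= 1
    inside[inside] <- junction[sel][inside] < o$end[hit[inside]]
    ok <- sel[inside & forward[sel]]
    h <- hit[inside & forward[sel]]
    if (length(ok)) {
      cat_ok <- o$signal_category[h]
      truth_category[ok] <- cat_ok
      truth_secretome[ok] <- cat_ok != "NONE"
      # pIII frame congruence: ORF codon grid must meet the junction in
      # phase with the downstream flank
      truth_in_frame[ok] <-
        ((o$start[h] - starts[ok]) %% 3) == ((lens[ok] - q) %% 3)
    }
  }
  truth_secretome[!forward] <- FALSE
  truth_in_frame[!forward] <- FALSE

  insert <- rep(NA_character_, n_clones)
  if (sequences) {
    for (r in seq_along(rep_ids)) {
      sel <- which(rep_idx == r)
      if (!length(sel)) next
      g <- as.character(community$replicons[[r]])
      g2 <- paste0(g, substr(g, 1, len_max))  # circular extraction
      ins <- substring(g2, starts[sel] + 1, starts[sel] + lens[sel])
      rev <- !forward[sel]
      if (any(rev)) {
        ins[rev] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(ins[rev])))
      }
      insert[sel] <- ins
    }
  }

  out <- data.frame(
    clone_id = sprintf("clone_%06d", seq_len(n_clones)),
    replicon_id = rep_ids[rep_idx],
    src_start = as.integer(starts),
    length = as.integer(lens),
    orientation = ifelse(forward, "forward", "reverse"),
    truth_secretome = truth_secretome,
    truth_in_frame = truth_in_frame,
    truth_category = truth_category,
    insert = insert
  )
  class(out) <- c("clone_library", class(out))
  out
}
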