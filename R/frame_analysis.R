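# Insert-pIII junction location and reading-frame analysis.
#
# The display cassette is: promoter .. ATG .. MCS [insert] pIII C-domain.
# Translation initiates at the cassette ATG and reads through the insert
# into pIII, so the displayed insert-encoded region is the maximal
# stop-free codon run, in the frame congruent with the pIII C-domain,
# ending at the insert's 3' junction.

#' Display-cassette definition
#'
#' The two vector flanks surrounding the cloning site.  `frame_offset`
#' is the codon phase of the first base of the downstream flank: 0 means
#' the pIII C-domain coding sequence resumes exactly on a codon
#' boundary at the junction.
#'
#' @param upstream_flank Vector sequence ending at the insert 5'
#'   junction (contains the cassette ATG).
#' @param downstream_flank Vector sequence beginning at the insert 3'
#'   junction (start of the pIII C-domain codon phase).
#' @param frame_offset Integer 0-2 (default 0).
#' @return Object of class `vector_cassette`.
#' @export
vector_cassette <- function(upstream_flank, downstream_flank,
                            frame_offset = 0) {
  stopifnot(is.character(upstream_flank), nzchar(upstream_flank),
            is.character(downstream_flank), nzchar(downstream_flank),
            frame_offset %in% 0:2)
  upstream_flank <- toupper(upstream_flank)
  downstream_flank <- toupper(downstream_flank)
  check_dna_alphabet(upstream_flank, "upstream_flank")
  check_dna_alphabet(downstream_flank, "downstream_flank")
  structure(
    list(upstream_flank = upstream_flank,
         downstream_flank = downstream_flank,
         frame_offset = as.integer(frame_offset)),
    class = "vector_cassette"
  )
}

#' Default synthetic display cassette
#'
#' A compact phagemid-style cassette used by the simulator: an upstream
#' flank carrying the cassette ATG and a multiple cloning site, and a
#' downstream flank opening the pIII C-domain phase on a codon boundary
#' (`frame_offset = 0`).  Purely synthetic sequence; not any deposited
#' vector.
#'
#' @return A [vector_cassette()].
#' @export
default_cassette <- function() {
  vector_cassette(
    upstream_flank   = "GGCTAACTAAGGATGCCATGGCCGAGCTCGGTACC",
    downstream_flank = "GGTGGAGGTTCGGCCGAAACTGTTGAAAGTTGTTTAGCA",
    frame_offset = 0
  )
}

#' Locate the insert within a read carrying vector flanks
#'
#' Exact-match search for the flank anchors (the last `min_anchor` nt of
#' the upstream flank and the first `min_anchor` nt of the downstream
#' flank) in the read, in both orientations.  Supports reads covering
#' only the 3' joint, as produced by sequencing back from within pIII.
#' Ties between equal anchor matches resolve to the leftmost match.
#'
#' @param read Nucleotide string.
#' @param cassette A [vector_cassette()].
#' @param min_anchor Anchor length in nt (default 15).
#' @return List with `start`, `end` (0-based half-open insert interval
#'   within the read, in the orientation of the anchors found) and
#'   `orientation` (`"forward"` or `"reverse"`).
#' @export
locate_junction <- function(read, cassette, min_anchor = 15) {
  stopifnot(inherits(cassette, "vector_cassette"),
            is.character(read), length(read) == 1)
  read <- toupper(read)
  if (nchar(read) < min_anchor) stop("read shorter than `min_anchor`")
  up <- cassette$upstream_flank
  dn <- cassette$downstream_flank
  if (nchar(up) < min_anchor || nchar(dn) < min_anchor) {
    stop("cassette flanks shorter than `min_anchor`")
  }
  up_anchor <- substr(up, nchar(up) - min_anchor + 1, nchar(up))
  dn_anchor <- substr(dn, 1, min_anchor)

  find_anchors <- function(seq) {
    i_up <- regexpr(up_anchor, seq, fixed = TRUE)[1]
    i_dn <- regexpr(dn_anchor, seq, fixed = TRUE)[1]
    list(up = i_up, dn = i_dn, any = i_up > 0 || i_dn > 0)
  }

  fwd <- find_anchors(read)
  rev <- find_anchors(revcomp(read))
  if (fwd$any && rev$any) {
    stop("junction ambiguity: cassette anchors match both orientations")
  }
  if (!fwd$any && !rev$any) stop("no junction: cassette anchors not found")
  hit <- if (fwd$any) fwd else rev
  orientation <- if (fwd$any) "forward" else "reverse"
  n <- nchar(read)
  start <- if (hit$up > 0) hit$up - 1L + min_anchor else 0L
  end <- if (hit$dn > 0) hit$dn - 1L else n
  if (end < start) stop("no junction: anchors in inconsistent order")
  list(start = as.integer(start), end = as.integer(end),
       orientation = orientation)
}

#' Extract the insert-encoded region fused to pIII
#'
#' Determines the reading frame congruent with the pIII C-domain (the
#' frame whose codon boundaries, anchored at the insert 3' junction,
#' continue into the downstream flank at its `frame_offset` phase) and
#' returns the maximal stop-free codon run in that frame ending at the
#' junction, bounded upstream by the first in-frame stop or the insert
#' edge.  The run is the open region translated through into pIII; no
#' initiation codon is required inside the insert by default because
#' translation initiates at the cassette ATG (`require_start = TRUE`
#' additionally anchors the region at the first ATG/GTG/TTG in the run).
#'
#' @param insert Insert nucleotide string, as cloned (ACGT only).
#' @param cassette A [vector_cassette()].
#' @param params A [model_params()]; `min_fusion_len` gates the call.
#' @param require_start Require a bacterial initiation codon within the
#'   run (default FALSE).
#' @return A `fusion_orf` (list with `frame`, `nt_start`, `nt_end`
#'   0-based half-open insert coordinates, `aa_seq`, `length_aa`,
#'   `in_frame_with_piii = TRUE`), or `NULL` when the open run is
#'   shorter than `min_fusion_len` codons.
#' @examples
#' cas <- default_cassette()
#' extract_fusion_orf(strrep("GGTTCA", 15), cas)  # 30 aa fusion
#' extract_fusion_orf("GGGTTTAAACCC", cas)        # NULL: 4 aa < 24
#' @export
extract_fusion_orf <- function(insert, cassette = default_cassette(),
                               params = model_params(),
                               require_start = FALSE) {
  stopifnot(inherits(cassette, "vector_cassette"),
            is.character(insert), length(insert) == 1)
  insert <- toupper(insert)
  if (nchar(insert) < 3) stop("insert shorter than one codon")
  check_dna_alphabet(insert, "insert")
  L <- nchar(insert)
  # codon starts p (0-based) with p == (L - frame_offset) mod 3 keep the
  # downstream flank in phase across the junction
  p0 <- (L - cassette$frame_offset) %% 3
  codons <- split_codons(insert, from = p0)
  n_cod <- length(codons)
  # drop a final codon that would overrun the junction into the flank
  while (n_cod > 0 && p0 + 3 * n_cod > L) n_cod <- n_cod - 1
  if (n_cod == 0) return(NULL)
  codons <- codons[seq_len(n_cod)]
  stops <- which(codons %in% STOP_CODONS)
  first <- if (length(stops)) max(stops) + 1L else 1L
  if (require_start) {
    starts <- which(codons %in% c("ATG", "GTG", "TTG"))
    starts <- starts[starts >= first]
    if (!length(starts)) return(NULL)
    first <- min(starts)
  }
  length_aa <- n_cod - first + 1L
  if (length_aa < params$min_fusion_len) return(NULL)
  run <- codons[first:n_cod]
  structure(
    list(
      frame = as.integer(p0),
      nt_start = as.integer(p0 + 3 * (first - 1)),
      nt_end = as.integer(p0 + 3 * n_cod),
      aa_seq = translate_codons(run),
      length_aa = as.integer(length_aa),
      in_frame_with_piii = TRUE
    ),
    class = "fusion_orf"
  )
}

#' Enumerate maximal open reading regions in all six frames
#'
#' Stop-to-stop convention: every maximal stop-free codon run in each of
#' the three frames of each strand.  Used as the independent frame
#' oracle for the junction-anchored extraction.
#'
#' @param sequence Nucleotide string (ACGT).
#' @param min_len_aa Minimum run length in codons (default 1).
#' @return data.frame with columns `strand` ("+"/"-"), `frame` (0-2),
#'   `start`, `end` (0-based half-open, on the analysed strand's own
#'   forward coordinates), `length_aa`.
#' @export
enumerate_orfs <- function(sequence, min_len_aa = 1) {
  stopifnot(min_len_aa >= 1)
  sequence <- toupper(sequence)
  check_dna_alphabet(sequence, "sequence")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    for (f in 0:2) {
      codons <- split_codons(s, from = f)
      if (!length(codons)) next
      is_stop <- codons %in% STOP_CODONS
      r <- rle(!is_stop)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values & r$lengths >= min_len_aa
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        strand = strand, frame = f,
        start = f + 3 * (starts[keep] - 1),
        end = f + 3 * ends[keep],
        length_aa = r$lengths[keep]
      )
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      length_aa = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
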