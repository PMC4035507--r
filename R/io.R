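# File formats and configuration: FASTA round-trips, GFF3 community
# annotation, vector trimming, tabular reports, YAML/JSON config.

#' Read a FASTA file
#'
#' Thin wrapper over Biostrings that rejects duplicate record ids
#' (listing them) and handles CRLF input identically to LF.
#'
#' @param path File path.
#' @param type `"DNA"` or `"AA"`.
#' @return A DNAStringSet or AAStringSet.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  names(x) <- ids
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  x
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param x XStringSet (or named character vector, taken as DNA unless
#'   `type = "AA"`).
#' @param path Output path.
#' @param type Used when `x` is a character vector.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (is.character(x)) {
    x <- if (type == "DNA") Biostrings::DNAStringSet(x) else
      Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Write and read tab-separated report tables
#'
#' @param table data.frame.
#' @param path File path.
#' @return `path` invisibly; `read_tsv_report` returns the data.frame.
#' @export
write_tsv_report <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_report
#' @export
read_tsv_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a synthetic community as FASTA + GFF3
#'
#' Replicons go to `<prefix>.fasta`; ORF annotations (with a
#' `signal_category` attribute on each gene) to `<prefix>.gff3` in
#' 1-based inclusive GFF coordinates.
#'
#' @param community A [generate_community()] result.
#' @param prefix Output path prefix.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_community <- function(community, prefix) {
  stopifnot(inherits(community, "synthetic_community"))
  fasta <- paste0(prefix, ".fasta")
  gff <- paste0(prefix, ".gff3")
  write_fasta(community$replicons, fasta)
  o <- community$orfs
  gr <- GenomicRanges::GRanges(
    seqnames = o$replicon_id,
    ranges = IRanges::IRanges(start = o$start + 1L, end = o$end),
    strand = o$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- o$orf_id
  S4Vectors::mcols(gr)$signal_category <- o$signal_category
  rtracklayer::export(gr, gff, format = "GFF3")
  invisible(c(fasta = fasta, gff3 = gff))
}

#' Read a community annotation back from GFF3
#'
#' @param path GFF3 path written by [write_community()].
#' @return data.frame `(orf_id, replicon_id, start, end, strand,
#'   signal_category)` with 0-based half-open coordinates.
#' @export
read_community_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  data.frame(
    orf_id = S4Vectors::mcols(gr)$ID,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    signal_category = S4Vectors::mcols(gr)$signal_category)
}

#' Write clone inserts as FASTA with structured headers
#'
#' Headers are `clone_id|orientation|replicon:src_start`, so truth
#' metadata survives a FASTA round-trip.
#'
#' @param clones A `clone_library` with sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clones <- function(clones, path) {
  stopifnot(!anyNA(clones$insert))
  ids <- sprintf("%s|%s|%s:%d", clones$clone_id, clones$orientation,
                 clones$replicon_id, clones$src_start)
  write_fasta(stats::setNames(clones$insert, ids), path)
}

#' Trim vector flanks from reads
#'
#' Removes cassette flank sequence from read ends, SeqClean-style:
#' each flank is located allowing at most one mismatch per 15 nt of
#' flank length; everything up to the end of an upstream-flank match,
#' and from the start of a downstream-flank match, is removed.  Reads
#' that are entirely vector are reported as discarded.
#'
#' @param reads Named character vector or DNAStringSet.
#' @param cassette A [vector_cassette()].
#' @param min_match Minimum flank match length in nt (default 15).
#' @return List with `trimmed` (named character vector of insert-only
#'   reads), `discarded` (ids) and `report` (data.frame: id,
#'   trimmed_5p, trimmed_3p, insert_len, status).
#' @export
trim_vector <- function(reads, cassette, min_match = 15) {
  stopifnot(inherits(cassette, "vector_cassette"))
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read_%04d", seq_along(reads))
  }
  find_flank <- function(read, flank) {
    # longest suffix/prefix windows first; tolerance 1 mismatch / 15 nt
    mm <- max(0L, nchar(flank) %/% 15)
    m <- Biostrings::matchPattern(flank, read, max.mismatch = mm)
    if (length(m) == 0) NULL else
      c(start = Biostrings::start(m)[1], end = Biostrings::end(m)[1])
  }
  up <- cassette$upstream_flank
  dn <- cassette$downstream_flank
  if (nchar(up) < min_match || nchar(dn) < min_match) {
    stop("cassette flanks shorter than `min_match`")
  }
  trimmed <- character(0)
  discarded <- character(0)
  report <- list()
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    id <- names(reads)[i]
    u <- find_flank(r, up)
    d <- find_flank(r, dn)
    from <- if (!is.null(u)) u["end"] + 1L else 1L
    to <- if (!is.null(d)) d["start"] - 1L else length(r)
    ins_len <- max(0L, to - from + 1L)
    status <- if (ins_len == 0) "discarded" else
      if (!is.null(u) || !is.null(d)) "trimmed" else "untrimmed"
    if (status == "discarded") {
      discarded <- c(discarded, id)
    } else {
      trimmed[id] <- as.character(Biostrings::subseq(r, from, to))
    }
    report[[i]] <- data.frame(
      id = id,
      trimmed_5p = if (is.null(u)) 0L else as.integer(u["end"]),
      trimmed_3p = if (is.null(d)) 0L else
        as.integer(length(r) - d["start"] + 1L),
      insert_len = as.integer(ins_len), status = status)
  }
  rep_tab <- do.call(rbind, report)
  rownames(rep_tab) <- NULL
  list(trimmed = trimmed, discarded = discarded, report = rep_tab)
}

#' Write and read the pipeline configuration
#'
#' YAML serialisation of [model_params()] plus cassette definition,
#' seed and free-form path entries, so a whole analysis is
#' reproducible from one file.
#'
#' @param params A [model_params()].
#' @param path Output path.
#' @param cassette Optional [vector_cassette()].
#' @param seed Optional integer seed.
#' @param extra Optional named list of additional entries.
#' @return `path` invisibly; `read_config` returns a list with
#'   `params` ([model_params()]), `cassette` (or NULL) and `seed`.
#' @export
write_config <- function(params, path, cassette = NULL, seed = NULL,
                         extra = list()) {
  cfg <- list(params = unclass(params))
  if (!is.null(cassette)) cfg$cassette <- unclass(cassette)
  if (!is.null(seed)) cfg$seed <- seed
  cfg <- c(cfg, extra)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$params)) {
    cfg$params <- do.call(model_params, cfg$params)
  }
  if (!is.null(cfg$cassette)) {
    cfg$cassette <- do.call(vector_cassette, cfg$cassette)
  }
  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) || cfg$seed < 0)) {
    stop("config `seed` must be a non-negative integer")
  }
  cfg
}
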