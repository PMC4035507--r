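# CAZyme domain-hit filtering, 100%-identity deduplication, cellulosome
# module classification and class roll-ups.

CELLULOSOME_FAMILIES <- c("dockerin", "cohesin", "SLH")
CAZY_CLASSES <- c("GH", "GT", "CE", "PL", "CBM", "AA")

# Map a dbCAN-style family name to its CAZy class (or cellulosome
# component).  Family names like "GH5", "CBM6", "dockerin", "cohesin",
# "SLH" (case-insensitive for the cellulosome components).
cazy_class_of <- function(family) {
  fam <- sub("\\.hmm$", "", family)
  low <- tolower(fam)
  out <- rep(NA_character_, length(fam))
  out[low %in% c("dockerin", "cohesin", "slh")] <- "cellulosome"
  pat <- "^(GH|GT|CE|PL|CBM|AA)([0-9_].*)?$"
  ok <- is.na(out) & grepl(pat, fam)
  out[ok] <- sub(pat, "\\1", fam[ok])
  out
}

#' Parse a domain-hit table
#'
#' Reads HMMER3 per-domain tabular output (`domtblout`: 23
#' whitespace-separated columns plus a free-text description tail,
#' `#` comment lines ignored) or the 10-column dbCAN parser TSV
#' dialect, into a uniform hit table.  Input order is preserved.  For
#' `domtblout` the scanning convention is hmmscan-style: the target is
#' the family HMM and the query is the ORF; the i-E-value and
#' per-domain score are used, and the alignment length is taken from
#' the alignment coordinates.
#'
#' @param path File path.
#' @param dialect `"domtblout"` or `"dbcan_tsv"`.
#' @return data.frame with columns `orf_id`, `family`, `aln_len`,
#'   `evalue`, `bitscore` (NA for the dbCAN dialect), `env_from`,
#'   `env_to` (1-based inclusive aa coordinates).
#' @export
parse_domain_hits <- function(path, dialect = c("domtblout", "dbcan_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(orf_id = character(), family = character(),
                      aln_len = integer(), evalue = numeric(),
                      bitscore = numeric(), env_from = integer(),
                      env_to = integer()))
  }
  parse_row <- function(line, lineno) {
    f <- strsplit(trimws(line), "[ \t]+")[[1]]
    need <- if (dialect == "domtblout") 22 else 10
    if (length(f) < need) {
      stop("malformed ", dialect, " row at line ", lineno, ": expected >= ",
           need, " fields, got ", length(f))
    }
    num <- function(x, what) {
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v)) stop("malformed ", dialect, " row at line ", lineno,
                         ": non-numeric ", what, " '", x, "'")
      v
    }
    if (dialect == "domtblout") {
      ali_from <- num(f[18], "ali from")
      ali_to <- num(f[19], "ali to")
      data.frame(orf_id = f[4], family = f[1],
                 aln_len = as.integer(ali_to - ali_from + 1),
                 evalue = num(f[13], "i-Evalue"),
                 bitscore = num(f[14], "domain score"),
                 env_from = as.integer(num(f[20], "env from")),
                 env_to = as.integer(num(f[21], "env to")))
    } else {
      q_from <- num(f[8], "query start")
      q_to <- num(f[9], "query end")
      data.frame(orf_id = f[3], family = sub("\\.hmm$", "", f[1]),
                 aln_len = as.integer(q_to - q_from + 1),
                 evalue = num(f[5], "E-value"),
                 bitscore = NA_real_,
                 env_from = as.integer(q_from),
                 env_to = as.integer(q_to))
    }
  }
  rows <- mapply(parse_row, lines[idx], idx, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$env_from > out$env_to)) stop("env_from > env_to in input")
  out
}

#' Filter domain hits by the two-branch length/E-value rule
#'
#' Keeps a hit iff its alignment is longer than `aln_len_cutoff`
#' residues with E-value below `evalue_strict`, or at most
#' `aln_len_cutoff` residues with E-value below `evalue_relaxed`
#' (short alignments get the relaxed E-value; long alignments do not).
#' Input order is preserved.
#'
#' @param hits Hit table from [parse_domain_hits()] (columns `aln_len`,
#'   `evalue`).
#' @param params A [model_params()].
#' @return The filtered hit table.
#' @export
filter_hits <- function(hits, params = model_params()) {
  stopifnot(all(c("aln_len", "evalue") %in% names(hits)))
  keep <- (hits$aln_len > params$aln_len_cutoff &
             hits$evalue < params$evalue_strict) |
    (hits$aln_len <= params$aln_len_cutoff &
       hits$evalue < params$evalue_relaxed)
  hits[keep, , drop = FALSE]
}

#' Cluster protein sequences at 100% identity
#'
#' Two sequences share a cluster iff they are identical or one is an
#' exact substring of the other (containment at 100% identity, the
#' semantics of greedy incremental clustering at a 1.0 identity
#' threshold).  The representative is the longest member, ties broken
#' lexicographically.
#'
#' @param proteins Character vector of sequences; names (ids) optional.
#' @return List with `cluster` (integer cluster index per input
#'   sequence, in input order), `representative` (character vector, one
#'   sequence per cluster) and `representative_id` (its name, when
#'   names were given).
#' @export
dedup_sequences <- function(proteins) {
  n <- length(proteins)
  if (n == 0) {
    return(list(cluster = integer(), representative = character(),
                representative_id = character()))
  }
  ids <- names(proteins)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  # canonical processing order: longest first, then lexicographic, so
  # clustering is invariant to input permutation
  ord <- order(-nchar(proteins), proteins, method = "radix")
  cluster <- integer(n)
  reps <- character(0)
  rep_ids <- character(0)
  for (i in ord) {
    s <- proteins[i]
    assigned <- 0L
    for (k in seq_along(reps)) {
      if (grepl(s, reps[k], fixed = TRUE)) { assigned <- k; break }
    }
    if (assigned == 0L) {
      reps <- c(reps, s)
      rep_ids <- c(rep_ids, ids[i])
      assigned <- length(reps)
    }
    cluster[i] <- assigned
  }
  list(cluster = cluster, representative = reps,
       representative_id = rep_ids)
}

#' Classify cellulosome modules per ORF
#'
#' Applies the dockerin-architecture rules to filtered hits grouped by
#' ORF: two or more dockerin-repeat hits make a complete dockerin
#' domain; one dockerin hit co-occurring with any non-dockerin CAZyme
#' module is a repeat-plus-other-module; one dockerin hit alone is a
#' single repeat.  Cohesin and SLH hits are reported as their own
#' kinds.
#'
#' @param hits Filtered hit table (columns `orf_id`, `family`).
#' @param dockerin_gap_max Optional maximum aa gap between the two
#'   repeats of a complete dockerin (default `Inf`, i.e. no cap;
#'   requires `env_from`/`env_to` when finite).
#' @return data.frame `(orf_id, kind, n_dockerin, n_support)` with one
#'   row per (ORF, kind); `kind` in `single_dockerin_repeat`,
#'   `complete_dockerin`, `repeat_plus_other_module`, `cohesin`, `slh`.
#' @export
classify_cellulosome <- function(hits, dockerin_gap_max = Inf) {
  stopifnot(all(c("orf_id", "family") %in% names(hits)))
  low <- tolower(sub("\\.hmm$", "", hits$family))
  out <- list()
  for (orf in unique(hits$orf_id)) {
    sel <- hits$orf_id == orf
    fam <- low[sel]
    n_dock <- sum(fam == "dockerin")
    n_other <- sum(!fam %in% c("dockerin", "cohesin", "slh"))
    if (n_dock >= 2) {
      complete <- TRUE
      if (is.finite(dockerin_gap_max)) {
        pos <- hits[sel & low == "dockerin", c("env_from", "env_to")]
        pos <- pos[order(pos$env_from), , drop = FALSE]
        gaps <- pos$env_from[-1] - pos$env_to[-nrow(pos)] - 1
        complete <- any(gaps <= dockerin_gap_max)
      }
      kind <- if (complete) "complete_dockerin" else
        if (n_other > 0) "repeat_plus_other_module" else
          "single_dockerin_repeat"
      out[[length(out) + 1]] <- data.frame(
        orf_id = orf, kind = kind, n_dockerin = n_dock,
        n_support = n_dock + n_other)
    } else if (n_dock == 1) {
      kind <- if (n_other > 0) "repeat_plus_other_module" else
        "single_dockerin_repeat"
      out[[length(out) + 1]] <- data.frame(
        orf_id = orf, kind = kind, n_dockerin = 1L,
        n_support = 1L + n_other)
    }
    for (comp in c("cohesin", "slh")) {
      n_c <- sum(fam == comp)
      if (n_c > 0) {
        out[[length(out) + 1]] <- data.frame(
          orf_id = orf, kind = comp, n_dockerin = 0L, n_support = n_c)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(orf_id = character(), kind = character(),
                      n_dockerin = integer(), n_support = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Roll up CAZy classes into a distribution table
#'
#' Counts filtered hits per CAZy class (GH, GT, CE, PL, CBM, AA) and
#' per cellulosome component (dockerin, cohesin, SLH; counted under
#' "cellulosome", not double-counted in any enzyme class), both over
#' all hits ("raw") and over hits on deduplicated cluster
#' representatives ("dedup"), with distributions as percentages of the
#' respective totals.  Class rows are reported to one decimal,
#' cellulosome component sub-rows to two, matching the conventional
#' reporting precision.
#'
#' @param hits Filtered hit table (columns `orf_id`, `family`).
#' @param clusters Optional [dedup_sequences()] result over the ORF
#'   protein sequences, or a character vector of representative ORF
#'   ids; when omitted, dedup columns equal raw columns.
#' @return A `cazy_class_table` data.frame: `class`, `count_raw`,
#'   `count_dedup`, `pct_raw`, `pct_dedup`, with class rows, a
#'   `cellulosome` row, its three component sub-rows (prefixed
#'   `cellulosome:`), and a `total` row.
#' @export
rollup_classes <- function(hits, clusters = NULL) {
  stopifnot(all(c("orf_id", "family") %in% names(hits)))
  cls <- cazy_class_of(hits$family)
  if (anyNA(cls)) {
    stop("unrecognised family name(s): ",
         paste(unique(hits$family[is.na(cls)]), collapse = ", "))
  }
  rep_ids <- if (is.null(clusters)) unique(hits$orf_id)
  else if (is.character(clusters)) clusters
  else clusters$representative_id
  in_dedup <- hits$orf_id %in% rep_ids
  low <- tolower(sub("\\.hmm$", "", hits$family))

  count_pair <- function(mask) {
    c(raw = sum(mask), dedup = sum(mask & in_dedup))
  }
  rows <- list()
  add <- function(name, mask) {
    p <- count_pair(mask)
    rows[[length(rows) + 1]] <<- data.frame(
      class = name, count_raw = unname(p["raw"]),
      count_dedup = unname(p["dedup"]))
  }
  for (cc in CAZY_CLASSES) add(cc, cls == cc)
  add("cellulosome", cls == "cellulosome")
  add("cellulosome:SLH", low == "slh")
  add("cellulosome:cohesins", low == "cohesin")
  add("cellulosome:dockerins", low == "dockerin")
  tab <- do.call(rbind, rows)
  total_raw <- sum(cls == "cellulosome" | cls %in% CAZY_CLASSES)
  total_dedup <- sum(in_dedup)
  is_sub <- grepl("^cellulosome:", tab$class)
  dec <- ifelse(is_sub, 2, 1)
  tab$pct_raw <- if (total_raw > 0) {
    round_half_up(100 * tab$count_raw / total_raw, dec)
  } else 0
  tab$pct_dedup <- if (total_dedup > 0) {
    round_half_up(100 * tab$count_dedup / total_dedup, dec)
  } else 0
  tab <- rbind(tab, data.frame(class = "total", count_raw = total_raw,
                               count_dedup = total_dedup,
                               pct_raw = 100, pct_dedup = 100))
  rownames(tab) <- NULL
  class(tab) <- c("cazy_class_table", class(tab))
  tab
}
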