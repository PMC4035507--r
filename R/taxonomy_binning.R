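# Best-hit taxonomic binning of ORFs and cellulosome-module sequences,
# and rank roll-ups with "Other" / "Unassigned" pooling.

LINEAGE_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
                   "genus")

#' Read BLAST tabular output (outfmt 6 dialect)
#'
#' Reads the 12 standard columns, plus optional `staxids` (13th) and
#' `qcovs` (14th) columns when present.  Coverage: `qcovs` is used
#' when available (as a percentage, converted to a fraction);
#' otherwise query coverage is computed as `length / query_len` using
#' the supplied query lengths.
#'
#' @param path File path.
#' @param query_lengths Optional named vector of query lengths (aa/nt,
#'   matching the alignment units) for coverage when `qcovs` is absent.
#' @return data.frame of hits with a `query_cov` fraction column.
#' @export
read_blast_tab <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  std <- c("qseqid", "sseqid", "pident", "length", "mismatch",
           "gapopen", "qstart", "qend", "sstart", "send", "evalue",
           "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(
      replicate(13, character(0), simplify = FALSE),
      c(std, "query_cov")))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- length(fields[[1]])
  if (nc < 12) stop("expected >= 12 tab-separated columns, got ", nc)
  if (any(lengths(fields) != nc)) {
    stop("ragged BLAST table: line ",
         which(lengths(fields) != nc)[1], " has ",
         lengths(fields)[lengths(fields) != nc][1], " fields, not ", nc)
  }
  raw <- as.data.frame(do.call(rbind, fields),
                       stringsAsFactors = FALSE)
  names(raw)[1:12] <- std
  if (nc >= 13) names(raw)[13] <- "staxids"
  if (nc >= 14) names(raw)[14] <- "qcovs"
  for (cc in c("pident", "length", "mismatch", "gapopen", "qstart",
               "qend", "sstart", "send", "evalue", "bitscore")) {
    raw[[cc]] <- as.numeric(raw[[cc]])
  }
  if ("staxids" %in% names(raw)) {
    raw$staxids <- as.integer(raw$staxids)
  }
  if ("qcovs" %in% names(raw)) {
    raw$query_cov <- as.numeric(raw$qcovs) / 100
  } else if (!is.null(query_lengths)) {
    ql <- query_lengths[raw$qseqid]
    raw$query_cov <- raw$length / as.numeric(ql)
  } else {
    raw$query_cov <- NA_real_
  }
  raw
}

#' Read a taxid -> lineage table
#'
#' Tab-separated with a header: `taxid` followed by the ranks
#' superkingdom..genus (missing ranks allowed).
#'
#' @param path File path.
#' @return data.frame keyed by `taxid`.
#' @export
read_lineage_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!"taxid" %in% names(tab)) stop("lineage table needs a `taxid` column")
  tab
}

best_hit <- function(hits) {
  # highest bitscore, tie -> lowest E-value, tie -> first in input
  ord <- order(-hits$bitscore, hits$evalue)
  hits[ord[1], , drop = FALSE]
}

#' Best-hit taxonomic assignment of a query
#'
#' Among the query's hits with `evalue < evalue_strict` and
#' `query_cov > qcov_min`, the best hit is the one with the highest
#' bit score (ties: lowest E-value, then first in input); its lineage
#' is the assignment.  No passing hit means unassigned.  A taxid
#' absent from the lineage table yields unassigned with a warning, not
#' an error.
#'
#' @param hits_for_query data.frame of the query's hits
#'   ([read_blast_tab()] layout: `pident`, `evalue`, `bitscore`,
#'   `query_cov`, `staxids`).
#' @param lineage_table Lineage table ([read_lineage_table()]).
#' @param params A [model_params()].
#' @return One-row data.frame: `query_id`, `status`
#'   (`assigned`/`unassigned`), the lineage ranks, `taxid`, `pident`,
#'   `bitscore`, `evalue` of the winning hit (NA when unassigned).
#' @export
assign_insert_taxon <- function(hits_for_query, lineage_table,
                                params = model_params()) {
  query_id <- if (nrow(hits_for_query)) hits_for_query$qseqid[1] else
    NA_character_
  unassigned <- data.frame(
    query_id = query_id, status = "unassigned",
    taxid = NA_integer_, pident = NA_real_, bitscore = NA_real_,
    evalue = NA_real_)
  for (rk in LINEAGE_RANKS) unassigned[[rk]] <- NA_character_
  if (!nrow(hits_for_query)) return(unassigned)
  if (!"query_cov" %in% names(hits_for_query) &&
      "qcovs" %in% names(hits_for_query)) {
    hits_for_query$query_cov <- as.numeric(hits_for_query$qcovs) / 100
  }
  pass <- hits_for_query$evalue < params$evalue_strict &
    !is.na(hits_for_query$query_cov) &
    hits_for_query$query_cov > params$qcov_min
  if (!any(pass)) return(unassigned)
  win <- best_hit(hits_for_query[pass, , drop = FALSE])
  row <- match(win$staxids, lineage_table$taxid)
  if (is.na(row)) {
    warning("taxid ", win$staxids, " not in lineage table; query ",
            query_id, " left unassigned")
    return(unassigned)
  }
  out <- data.frame(query_id = query_id, status = "assigned",
                    taxid = as.integer(win$staxids),
                    pident = win$pident, bitscore = win$bitscore,
                    evalue = win$evalue)
  for (rk in LINEAGE_RANKS) {
    out[[rk]] <- if (rk %in% names(lineage_table)) {
      as.character(lineage_table[[rk]][row])
    } else NA_character_
  }
  out
}

#' Assign taxa to all queries of a BLAST table
#'
#' Vectorised wrapper around [assign_insert_taxon()], grouping by
#' query id.
#'
#' @inheritParams assign_insert_taxon
#' @param hits Full hit table.
#' @return data.frame with one row per query, in first-appearance
#'   order.
#' @export
assign_taxa <- function(hits, lineage_table, params = model_params()) {
  qs <- unique(hits$qseqid)
  out <- lapply(qs, function(q) {
    assign_insert_taxon(hits[hits$qseqid == q, , drop = FALSE],
                        lineage_table, params)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Best-hit taxonomy of a cellulosome-module ORF
#'
#' Module-specific bit-score gates: cohesin- and SLH-containing ORFs
#' require the best hit to reach `bits_cohesin_slh` (default 40),
#' dockerin-containing ORFs `bits_dockerin` (default 35).  The
#' assignment is reported at family rank.
#'
#' @param hits_for_orf data.frame of the ORF's hits.
#' @param module_kind One of `"cohesin"`, `"slh"`, `"dockerin"`.
#' @param lineage_table Lineage table.
#' @param params A [model_params()].
#' @return One-row data.frame `(query_id, module_kind, status,
#'   family, taxid, bitscore)`.
#' @export
assign_module_taxon <- function(hits_for_orf, module_kind, lineage_table,
                                params = model_params()) {
  module_kind <- match.arg(tolower(module_kind),
                           c("cohesin", "slh", "dockerin"))
  thr <- if (module_kind == "dockerin") params$bits_dockerin else
    params$bits_cohesin_slh
  query_id <- if (nrow(hits_for_orf)) hits_for_orf$qseqid[1] else
    NA_character_
  unassigned <- data.frame(query_id = query_id,
                           module_kind = module_kind,
                           status = "unassigned",
                           family = NA_character_,
                           taxid = NA_integer_, bitscore = NA_real_)
  if (!nrow(hits_for_orf)) return(unassigned)
  win <- best_hit(hits_for_orf)
  if (is.na(win$bitscore) || win$bitscore < thr) return(unassigned)
  row <- match(win$staxids, lineage_table$taxid)
  if (is.na(row)) {
    warning("taxid ", win$staxids, " not in lineage table; ORF ",
            query_id, " left unassigned")
    return(unassigned)
  }
  data.frame(query_id = query_id, module_kind = module_kind,
             status = "assigned",
             family = as.character(lineage_table$family[row]),
             taxid = as.integer(win$staxids), bitscore = win$bitscore)
}

#' Roll assignments up to a rank with Other and Unassigned bins
#'
#' Percentages of all queries per taxon at the requested rank.
#' Queries that are unassigned, or whose winning hit is below the
#' identity cutoff (`identity_min`, default 30%), pool into
#' "Unassigned"; taxa under `other_threshold` percent of the dataset
#' pool into "Other".
#'
#' @param assignments [assign_taxa()] result.
#' @param rank One of `"phylum"`, `"family"`, `"genus"`.
#' @param params A [model_params()].
#' @param other_threshold Pooling threshold in percent (default 0.1).
#' @param decimals Reporting precision (default 1).
#' @return data.frame `(taxon, count, pct)`; percentages sum to 100
#'   up to rounding.
#' @export
rank_rollup <- function(assignments, rank = c("phylum", "family", "genus"),
                        params = model_params(), other_threshold = 0.1,
                        decimals = 1) {
  rank <- match.arg(rank)
  n <- nrow(assignments)
  if (n == 0) {
    return(data.frame(taxon = character(), count = integer(),
                      pct = numeric()))
  }
  taxon <- assignments[[rank]]
  low_ident <- !is.na(assignments$pident) &
    assignments$pident < 100 * params$identity_min
  unassigned <- assignments$status != "assigned" | is.na(taxon) |
    low_ident
  taxon[unassigned] <- "Unassigned"
  pct_exact <- 100 * table(taxon) / n
  pool <- names(pct_exact)[pct_exact < other_threshold &
                             names(pct_exact) != "Unassigned"]
  taxon[taxon %in% pool] <- "Other"
  tab <- table(taxon)
  out <- data.frame(taxon = names(tab), count = as.integer(tab))
  out$pct <- frequency(out$count, n, decimals)
  # stable display order: abundance, then name; bins last
  bin <- out$taxon %in% c("Other", "Unassigned")
  out <- out[order(bin, -out$count, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
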