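# Mock annotation tables with planted composition, for exercising the
# CAZyme and taxonomy stages without running external scanners.

#' Emit a mock domain-hit table with planted composition
#'
#' Assigns ORFs to composition rows sequentially without replacement
#' (so planted truths are disjoint and exactly recoverable), emits
#' `hits_per_orf` hits per assigned ORF with the requested E-value and
#' alignment length, and shuffles the row order.  Use
#' `hits_per_orf = 2` for the `dockerin` family to plant complete
#' dockerin domains, and above-cutoff E-values to plant decoys.
#'
#' @param protein_ids Character vector of available ORF ids.
#' @param composition data.frame with column `family` and `count`
#'   (ORFs per row); optional columns `hits_per_orf` (default 1),
#'   `evalue` (default 1e-10), `aln_len` (default 100), `bitscore`
#'   (default 60).  Zero rows give an empty table.
#' @param seed Integer seed.
#' @return Hit table in [parse_domain_hits()] layout.
#' @export
emit_mock_domain_hits <- function(protein_ids, composition, seed = 1) {
  stopifnot(is.data.frame(composition))
  empty <- data.frame(orf_id = character(), family = character(),
                      aln_len = integer(), evalue = numeric(),
                      bitscore = numeric(), env_from = integer(),
                      env_to = integer())
  if (nrow(composition) == 0) return(empty)
  if (!all(c("family", "count") %in% names(composition))) {
    stop("`composition` needs columns `family` and `count`")
  }
  fam_class <- cazy_class_of(composition$family)
  if (anyNA(fam_class)) {
    stop("unknown family tag(s): ",
         paste(composition$family[is.na(fam_class)], collapse = ", "))
  }
  defaults <- list(hits_per_orf = 1L, evalue = 1e-10, aln_len = 100L,
                   bitscore = 60)
  for (nm in names(defaults)) {
    if (!nm %in% names(composition)) composition[[nm]] <- defaults[[nm]]
  }
  if (sum(composition$count) > length(protein_ids)) {
    stop("requested ", sum(composition$count), " ORFs but only ",
         length(protein_ids), " protein ids available")
  }
  rows <- list()
  next_orf <- 1L
  for (i in seq_len(nrow(composition))) {
    cnt <- composition$count[i]
    if (cnt == 0) next
    orfs <- protein_ids[next_orf:(next_orf + cnt - 1L)]
    next_orf <- next_orf + cnt
    per <- composition$hits_per_orf[i]
    aln <- composition$aln_len[i]
    for (j in seq_len(per)) {
      rows[[length(rows) + 1]] <- data.frame(
        orf_id = orfs, family = composition$family[i],
        aln_len = as.integer(aln),
        evalue = composition$evalue[i],
        bitscore = composition$bitscore[i],
        env_from = as.integer(1 + (j - 1) * (aln + 10)),
        env_to = as.integer(j * aln + (j - 1) * 10))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  withr::with_seed(derive_seed(seed, "mock_domain_hits"), {
    out <- out[sample.int(nrow(out)), , drop = FALSE]
  })
  rownames(out) <- NULL
  out
}

#' Write a hit table as HMMER3 per-domain tabular output
#'
#' Emits a `domtblout`-dialect file (hmmscan convention: family as the
#' target, ORF as the query) that [parse_domain_hits()] reads back
#' losslessly for the fields it models.
#'
#' @param hits Hit table ([parse_domain_hits()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  header <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  lines <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    lines[i] <- sprintf(
      "%-20s -          %5d %-20s -          %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
      h$family, 200L, h$orf_id, 400L,
      h$evalue, ifelse(is.na(h$bitscore), 0, h$bitscore), 0.0, 1L, 1L,
      h$evalue, h$evalue, ifelse(is.na(h$bitscore), 0, h$bitscore), 0.0,
      1L, h$aln_len, h$env_from, h$env_from + h$aln_len - 1L,
      h$env_from, h$env_to, 0.95)
  }
  writeLines(c(header, lines, "#"), path)
  invisible(path)
}

#' Emit a mock BLAST tabular file with planted best hits
#'
#' Produces outfmt-6-style rows plus `staxids` and `qcovs` columns.
#' Each query receives one planted best hit (by default to a
#' seeded-random lineage from `lineage_table`) and `n_decoys`
#' lower-bit-score decoy hits.  An explicit `plan` overrides the
#' defaults per query.
#'
#' @param query_ids Character vector of query ids; empty gives an empty
#'   table.
#' @param lineage_table Lineage table as from [synthetic_lineages()]
#'   (non-empty, column `taxid`).
#' @param seed Integer seed.
#' @param plan Optional data.frame `(query_id, taxid)` with optional
#'   `pident`, `qcovs`, `bitscore`, `evalue` columns controlling the
#'   planted best hit per query.
#' @param n_decoys Decoy hits per query (default 2).
#' @return data.frame in [read_blast_tab()] layout (14 columns:
#'   the 12 standard outfmt-6 fields plus `staxids` and `qcovs`).
#' @export
emit_mock_blast_hits <- function(query_ids, lineage_table, seed = 1,
                                 plan = NULL, n_decoys = 2) {
  if (!is.data.frame(lineage_table) || nrow(lineage_table) == 0) {
    stop("`lineage_table` must be a non-empty data.frame")
  }
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore", "staxids", "qcovs")
  if (!length(query_ids)) {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
    return(out)
  }
  n <- length(query_ids)
  defaults <- data.frame(query_id = query_ids, pident = 80,
                         qcovs = 80, bitscore = 200, evalue = 1e-20)
  withr::with_seed(derive_seed(seed, "mock_blast_hits"), {
    defaults$taxid <- sample(lineage_table$taxid, n, replace = TRUE)
    if (!is.null(plan)) {
      stopifnot(all(c("query_id", "taxid") %in% names(plan)))
      m <- match(defaults$query_id, plan$query_id)
      for (nm in intersect(names(plan),
                           c("taxid", "pident", "qcovs", "bitscore",
                             "evalue"))) {
        ok <- !is.na(m)
        defaults[[nm]][ok] <- plan[[nm]][m[ok]]
      }
    }
    rows <- list()
    for (i in seq_len(n)) {
      d <- defaults[i, ]
      aln <- as.integer(round(3 * d$qcovs))  # nominal query length 300
      best <- data.frame(
        qseqid = d$query_id,
        sseqid = sprintf("subj_%s_best", d$query_id),
        pident = d$pident, length = aln,
        mismatch = as.integer(round(aln * (100 - d$pident) / 100)),
        gapopen = 0L, qstart = 1L, qend = aln,
        sstart = 1L, send = aln,
        evalue = d$evalue, bitscore = d$bitscore,
        staxids = d$taxid, qcovs = d$qcovs)
      rows[[length(rows) + 1]] <- best
      if (n_decoys > 0) {
        for (k in seq_len(n_decoys)) {
          rows[[length(rows) + 1]] <- data.frame(
            qseqid = d$query_id,
            sseqid = sprintf("subj_%s_decoy%d", d$query_id, k),
            pident = max(20, d$pident - 30),
            length = aln, mismatch = aln %/% 2, gapopen = 1L,
            qstart = 1L, qend = aln, sstart = 1L, send = aln,
            evalue = d$evalue * 1e6,
            bitscore = d$bitscore * 0.5 - k,
            staxids = sample(lineage_table$taxid, 1),
            qcovs = d$qcovs)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
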