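test_that("domtblout rows round-trip through write and parse", {
  hits <- data.frame(
    orf_id = sprintf("orf_%02d", 1:5),
    family = c("GH5", "dockerin", "cohesin", "CBM6", "SLH"),
    aln_len = c(120L, 22L, 150L, 60L, 90L),
    evalue = c(1e-20, 1e-8, 1e-30, 5e-4, 1e-12),
    bitscore = c(80, 45, 120, 30, 60),
    env_from = c(1L, 10L, 5L, 3L, 2L),
    env_to = c(120L, 31L, 154L, 62L, 91L))
  path <- withr::local_tempfile(fileext = ".domtblout")
  write_domtblout(hits, path)
  got <- parse_domain_hits(path, "domtblout")
  expect_equal(nrow(got), 5)
  expect_equal(got$orf_id, hits$orf_id)
  expect_equal(got$family, hits$family)
  expect_equal(got$aln_len, hits$aln_len)
  expect_equal(got$evalue, hits$evalue, tolerance = 0.01)
  expect_equal(got$env_from, hits$env_from)
  expect_equal(got$env_to, hits$env_to)
})

test_that("the dbCAN parser dialect and malformed rows are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "GH5.hmm\t300\torf_01\t400\t1e-20\t1\t290\t10\t350\t0.96",
    "dockerin.hmm\t22\torf_02\t200\t1e-08\t1\t22\t5\t26\t0.95"), path)
  got <- parse_domain_hits(path, "dbcan_tsv")
  expect_equal(got$family, c("GH5", "dockerin"))
  expect_equal(got$aln_len, c(341L, 22L))
  expect_true(all(is.na(got$bitscore)))
  # non-numeric E-value raises an error naming the line
  writeLines(c(
    "GH5.hmm\t300\torf_01\t400\t1e-20\t1\t290\t10\t350\t0.96",
    "GH6.hmm\t300\torf_02\t400\tnot_a_number\t1\t290\t10\t350\t0.96"),
    path)
  expect_error(parse_domain_hits(path, "dbcan_tsv"), "line 2")
  # empty file gives an empty hit list
  writeLines(character(0), path)
  expect_equal(nrow(parse_domain_hits(path, "dbcan_tsv")), 0)
  expect_error(parse_domain_hits("no/such/file.tsv"), "no such file")
})

test_that("hit filtering applies the two-branch cutoff rule", {
  p <- model_params()
  mk <- function(aln, e) data.frame(orf_id = "o", family = "GH5",
                                    aln_len = aln, evalue = e,
                                    bitscore = 50, env_from = 1,
                                    env_to = aln)
  # long alignment, strict E-value: kept
  expect_equal(nrow(filter_hits(mk(100, 1e-6), p)), 1)
  # short alignment under the relaxed E-value: kept
  expect_equal(nrow(filter_hits(mk(50, 1e-4), p)), 1)
  # long alignments get no relaxed branch
  expect_equal(nrow(filter_hits(mk(100, 1e-4), p)), 0)
  # boundary: exactly 80 aa is the short branch
  expect_equal(nrow(filter_hits(mk(80, 5e-4), p)), 1)
  expect_equal(nrow(filter_hits(mk(81, 5e-4), p)), 0)
})

test_that("filtering is monotone in both E-value cutoffs", {
  set.seed(202)
  hits <- data.frame(
    orf_id = sprintf("o%03d", 1:200),
    family = "GH5",
    aln_len = sample(10:200, 200, replace = TRUE),
    evalue = 10^runif(200, -12, -1),
    bitscore = 50, env_from = 1L, env_to = 100L)
  base <- filter_hits(hits, model_params())
  for (f in c(10, 100)) {
    tighter <- filter_hits(hits, model_params(
      evalue_strict = 1e-5 / f, evalue_relaxed = 1e-3 / f))
    expect_true(all(tighter$orf_id %in% base$orf_id))
    expect_lte(nrow(tighter), nrow(base))
  }
  # order is preserved
  expect_identical(base$orf_id, hits$orf_id[hits$orf_id %in% base$orf_id])
})

test_that("containment dedup matches the brute-force oracle", {
  expect_equal(max(dedup_sequences(c("MKA", "MKA"))$cluster), 1)
  d <- dedup_sequences(c("MKAT", "MKA"))
  expect_equal(max(d$cluster), 1)
  expect_equal(d$representative, "MKAT")
  expect_equal(max(dedup_sequences(c("MKA", "MRA"))$cluster), 2)
  # representative ties break lexicographically
  tie <- dedup_sequences(c(b = "MKB", a = "MKA"))
  expect_equal(max(tie$cluster), 2)
  set.seed(303)
  pool <- vapply(1:40, function(i) {
    paste(sample(c("A", "G", "K", "M"), sample(3:8, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  got <- dedup_sequences(pool)
  orc <- oracle_containment_clusters(pool)
  # every greedy cluster lies inside one containment component, so the
  # greedy partition refines the oracle's connected components
  expect_gte(length(unique(got$cluster)), length(unique(orc)))
  for (k in unique(got$cluster)) {
    expect_equal(length(unique(orc[got$cluster == k])), 1)
  }
  # identical sequences always share a cluster
  dup_pool <- c(pool, pool[1:5])
  gd <- dedup_sequences(dup_pool)$cluster
  expect_equal(gd[41:45], gd[1:5])
  # idempotence: clustering the representatives changes nothing
  again <- dedup_sequences(got$representative)
  expect_equal(sort(again$representative), sort(got$representative))
  # permutation invariance
  perm <- sample(seq_along(pool))
  got2 <- dedup_sequences(pool[perm])
  expect_setequal(got2$representative, got$representative)
  expect_equal(nrow(table(got$cluster)), nrow(table(got2$cluster)))
})

test_that("cellulosome module rules classify per ORF", {
  mk <- function(orf, fam, from = 1, to = 50) {
    data.frame(orf_id = orf, family = fam, aln_len = to - from + 1,
               evalue = 1e-10, bitscore = 50, env_from = from,
               env_to = to)
  }
  hits <- rbind(
    mk("o1", "dockerin", 1, 22), mk("o1", "dockerin", 40, 61),
    mk("o2", "dockerin"), mk("o2", "GH5", 100, 220),
    mk("o3", "dockerin"),
    mk("o4", "SLH"),
    mk("o5", "cohesin"), mk("o5", "cohesin", 200, 350))
  calls <- classify_cellulosome(hits)
  kind_of <- function(o) calls$kind[calls$orf_id == o]
  expect_equal(kind_of("o1"), "complete_dockerin")
  expect_equal(kind_of("o2"), "repeat_plus_other_module")
  expect_equal(kind_of("o3"), "single_dockerin_repeat")
  expect_equal(kind_of("o4"), "slh")
  expect_equal(kind_of("o5"), "cohesin")
  # a finite gap cap can demote distant repeat pairs
  far <- rbind(mk("o6", "dockerin", 1, 22), mk("o6", "dockerin", 500, 521))
  expect_equal(classify_cellulosome(far)$kind, "complete_dockerin")
  expect_equal(classify_cellulosome(far, dockerin_gap_max = 100)$kind,
               "single_dockerin_repeat")
})

test_that("class roll-up reproduces printed-table arithmetic", {
  mk <- function(orf, fam) data.frame(orf_id = orf, family = fam,
                                      aln_len = 100, evalue = 1e-10,
                                      bitscore = 50, env_from = 1,
                                      env_to = 100)
  hits <- rbind(mk("a", "GH5"), mk("b", "GH13"), mk("c", "GT2"),
                mk("d", "dockerin"), mk("d", "dockerin"),
                mk("e", "CBM6"), mk("f", "CE1"))
  tab <- rollup_classes(hits)
  row <- function(cl) tab[tab$class == cl, ]
  expect_equal(row("GH")$count_raw, 2)
  expect_equal(row("cellulosome")$count_raw, 2)
  expect_equal(row("cellulosome:dockerins")$count_raw, 2)
  expect_equal(row("total")$count_raw, 7)
  # class percentages sum to 100 +/- 0.1 after rounding
  classes <- tab[!grepl(":", tab$class) & tab$class != "total", ]
  expect_lt(abs(sum(classes$pct_raw) - 100), 0.1 + 1e-9)
  # single-class table rolls to 100%
  single <- rollup_classes(rbind(mk("x", "GH5"), mk("y", "GH9")))
  expect_equal(single[single$class == "GH", "pct_raw"], 100)
  # dedup counts use cluster representatives only
  clust <- list(representative_id = c("a", "c", "d", "e", "f"))
  tab2 <- rollup_classes(hits, clust)
  expect_equal(tab2[tab2$class == "GH", "count_dedup"], 1)
  expect_true(all(tab2$count_dedup <= tab2$count_raw))
})

test_that("cellulosome calls survive hit duplication plus dedup", {
  mk <- function(orf, fam) data.frame(orf_id = orf, family = fam,
                                      aln_len = 22, evalue = 1e-8,
                                      bitscore = 45, env_from = 1,
                                      env_to = 22)
  mk2 <- function(orf, fam, from, to) {
    data.frame(orf_id = orf, family = fam, aln_len = to - from + 1,
               evalue = 1e-8, bitscore = 45, env_from = from,
               env_to = to)
  }
  hits <- rbind(mk2("o1", "dockerin", 1, 22), mk2("o1", "dockerin", 40, 61),
                mk2("o2", "cohesin", 1, 150))
  base <- classify_cellulosome(hits)
  dup <- rbind(hits, hits)
  dedup <- unique(dup)
  expect_equal(classify_cellulosome(dedup), base)
})

test_that("planted mock composition is recovered end to end", {
  ids <- sprintf("p%03d", 1:60)
  comp <- data.frame(
    family = c("GH5", "GT2", "dockerin", "cohesin", "SLH"),
    count = c(20, 10, 8, 3, 2),
    hits_per_orf = c(1, 1, 2, 1, 1))
  hits <- emit_mock_domain_hits(ids, comp, seed = 77)
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), nrow(hits))  # all planted hits pass cutoffs
  tab <- rollup_classes(kept)
  expect_equal(tab[tab$class == "GH", "count_raw"], 20)
  expect_equal(tab[tab$class == "GT", "count_raw"], 10)
  expect_equal(tab[tab$class == "cellulosome:dockerins", "count_raw"], 16)
  calls <- classify_cellulosome(kept)
  expect_equal(sum(calls$kind == "complete_dockerin"), 8)
  expect_equal(sum(calls$kind == "cohesin"), 3)
  expect_equal(sum(calls$kind == "slh"), 2)
})
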