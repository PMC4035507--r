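test_that("community carries the exact configured secretome count", {
  com <- generate_community(1, 100, 0.20, seed = 42)
  expect_equal(sum(com$orfs$signal_category != "NONE"), 20)
  com0 <- generate_community(1, 100, 0.0, seed = 7)
  expect_equal(sum(com0$orfs$signal_category != "NONE"), 0)
  # ORF coordinates lie within replicon bounds and are codon-sized
  lens <- Biostrings::width(com$replicons)[
    match(com$orfs$replicon_id, names(com$replicons))]
  expect_true(all(com$orfs$end <= lens))
  expect_true(all((com$orfs$end - com$orfs$start) %% 3 == 0))
  # every ORF has a ground-truth label
  expect_true(all(com$orfs$signal_category %in%
                    c("TYPE_I", "TYPE_II", "TYPE_IV", "TMH_ANCHOR",
                      "TMH_INTERNAL_MULTI", "TAT", "NONE")))
})

test_that("community generation is deterministic for a fixed seed", {
  a <- generate_community(2, 60, 0.2, seed = 5)
  b <- generate_community(2, 60, 0.2, seed = 5)
  expect_identical(as.character(a$replicons), as.character(b$replicons))
  expect_identical(a$orfs, b$orfs)
  c <- generate_community(2, 60, 0.2, seed = 6)
  expect_false(identical(as.character(a$replicons),
                         as.character(c$replicons)))
})

test_that("community geometry errors are raised", {
  expect_error(generate_community(5, 3, 0.2, seed = 1), "one ORF per")
  expect_error(generate_community(1, 50, 0.2, seed = 1,
                                  orf_length_aa = 50), "orf_length_aa")
  expect_error(
    generate_community(1, 50, 0.2, seed = 1, max_replicon_length = 1000),
    "sizing")
})

test_that("synthesized signal peptides match their motif definitions", {
  # lipobox regex oracle, as on the canonical lipoprotein signal prefix
  lipo <- synthesize_signal_peptide("TYPE_II", seed = 3)
  expect_match(lipo, "[LVIFG][ASTVG][GAS]C")
  expect_true(detect_lipobox(paste0(lipo, strrep("S", 20)))$verdict)
  # a 20-mer of leucine passes the hydropathy rule by construction
  tmh <- synthesize_signal_peptide("TMH_ANCHOR", seed = 3)
  expect_true(nrow(detect_tmh(paste0(tmh, strrep("G", 10)))) >= 1)
  # the built-in detector accepts its own type I construction
  spi <- synthesize_signal_peptide("TYPE_I", seed = 3)
  expect_true(detect_spI(paste0(spi, strrep("G", 20)))$verdict)
  expect_error(synthesize_signal_peptide("TYPE_IX"), "unknown")
})

test_that("shearing respects length bounds, orientation and determinism", {
  com <- generate_community(1, 60, 0.2, seed = 9)
  cl <- shear_and_clone(com, 1000, len_min = 700, len_max = 5000,
                        seed = 4)
  expect_true(all(cl$length >= 700 & cl$length <= 5000))
  # forward fraction within 3 binomial sigma of 1/2
  sigma <- sqrt(0.25 / 1000)
  expect_lt(abs(mean(cl$orientation == "forward") - 0.5), 3 * sigma)
  # degenerate length distribution
  cl300 <- shear_and_clone(com, 50, len_min = 300, len_max = 300,
                           seed = 4)
  expect_true(all(cl300$length == 300))
  # determinism: same seed twice gives an identical clone set
  expect_identical(cl, shear_and_clone(com, 1000, seed = 4))
  expect_error(shear_and_clone(com, 10, len_min = 30), "len_min")
  expect_error(
    shear_and_clone(com, 10, len_max = 1e6, seed = 1), "sizing")
})

test_that("clone truth labels agree with the sequence-level analysis", {
  com <- generate_community(1, 80, 0.25, seed = 21)
  cl <- shear_and_clone(com, 400, seed = 22)
  out <- simulate_selection(cl, classifier = "detect",
                            params = model_params(background_escape = 0))
  truth <- cl$truth_secretome & cl$truth_in_frame
  # the detector route may only lose junction-boundary cases, never
  # select a clone the lottery says cannot display
  expect_true(all(truth[out$selected]))
  expect_gt(sum(out$selected) / max(1, sum(truth)), 0.5)
})

test_that("mock domain-hit tables carry the planted composition", {
  ids <- sprintf("orf_%03d", 1:40)
  comp <- data.frame(
    family = c("dockerin", "GH5", "cohesin"),
    count = c(10, 5, 3),
    hits_per_orf = c(2, 1, 1))
  hits <- emit_mock_domain_hits(ids, comp, seed = 1)
  calls <- classify_cellulosome(hits)
  expect_equal(sum(calls$kind == "complete_dockerin"), 10)
  expect_equal(sum(calls$kind == "cohesin"), 3)
  # decoys above the relaxed cutoff are all removed by filtering
  decoys <- emit_mock_domain_hits(
    ids, data.frame(family = "GH13", count = 8, evalue = 1e-2), seed = 1)
  expect_equal(nrow(filter_hits(decoys)), 0)
  # empty composition gives an empty, well-formed table
  empty <- emit_mock_domain_hits(ids, data.frame(family = character(),
                                                 count = integer()))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("orf_id", "family", "evalue") %in% names(empty)))
  expect_error(
    emit_mock_domain_hits(ids, data.frame(family = "NOPE", count = 1)),
    "unknown family")
  expect_error(
    emit_mock_domain_hits(ids[1:2], data.frame(family = "GH5", count = 9)),
    "available")
})

test_that("mock BLAST tables plant recoverable best hits", {
  lin <- synthetic_lineages(6)
  queries <- sprintf("q%02d", 1:20)
  tab <- emit_mock_blast_hits(queries, lin, seed = 2)
  asg <- assign_taxa(tab, lin)
  expect_true(all(asg$status == "assigned"))
  # planted taxid is the best hit's taxid
  best <- tab[grepl("_best$", tab$sseqid), ]
  expect_equal(asg$taxid[match(best$qseqid, asg$query_id)], best$staxids)
  # all identities below the cutoff leave every query unassigned in the
  # rank roll-up
  low <- emit_mock_blast_hits(
    queries, lin, seed = 2,
    plan = data.frame(query_id = queries,
                      taxid = rep(lin$taxid[1], 20), pident = 25))
  roll <- rank_rollup(assign_taxa(low, lin), "phylum")
  expect_equal(roll$taxon, "Unassigned")
  expect_equal(roll$pct, 100)
  # no queries -> empty table
  expect_equal(nrow(emit_mock_blast_hits(character(0), lin)), 0)
})
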