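test_that("type I detector requires charge, core and cleavage box", {
  spi <- paste0(synthesize_signal_peptide("TYPE_I", seed = 1),
                strrep("G", 30))
  r <- detect_spI(spi)
  expect_true(r$verdict)
  expect_true(r$cleavage_pos >= 15 && r$cleavage_pos <= 30)
  # no hydrophobic core
  expect_false(detect_spI(strrep("D", 50))$verdict)
  # canonical lipoprotein signal lacks the A-X-A box at 15-30
  lipo <- paste0("MKATKLVLGAVILGSTLLAGC", strrep("G", 20))
  expect_false(detect_spI(lipo)$verdict)
})

test_that("lipobox detector enforces motif, window and charge", {
  # canonical Braun-lipoprotein-style signal: fires with Cys at 21
  lipo <- paste0("MKATKLVLGAVILGSTLLAGC", strrep("G", 20))
  r <- detect_lipobox(lipo)
  expect_true(r$verdict)
  expect_equal(r$cys_pos, 21)
  # no cysteine, no call
  expect_false(detect_lipobox(strrep("MKLLLLASG", 5))$verdict)
  # lipobox beyond position 35 does not fire
  late <- paste0("MK", strrep("S", 37), "LAGC", strrep("S", 10))
  expect_false(detect_lipobox(late)$verdict)
})

test_that("hydropathy scan finds merged maximal membrane spans", {
  # N-terminal 20-mer of leucine: one interval starting at position 1
  one <- detect_tmh(paste0(strrep("L", 20), strrep("D", 30)))
  expect_equal(nrow(one), 1)
  expect_lte(one$start[1], 1)
  # two hydrophobic blocks separated by asparate: two intervals,
  # matching a direct window-scan oracle
  two_seq <- paste0(strrep("I", 20), strrep("D", 30), strrep("I", 20))
  two <- detect_tmh(two_seq)
  expect_equal(nrow(two), 2)
  orc <- oracle_tmh_windows(two_seq)
  covered <- logical(nchar(two_seq))
  for (i in seq_len(nrow(two))) covered[two$start[i]:two$end[i]] <- TRUE
  expect_equal(covered, orc)
  # all-glycine never qualifies; short sequences give an empty scan
  expect_equal(nrow(detect_tmh(strrep("G", 40))), 0)
  expect_equal(nrow(detect_tmh("LLLLL")), 0)
})

test_that("hydropathy scan ignores appended non-hydrophobic flanks", {
  core <- paste0(strrep("S", 10), strrep("L", 20), strrep("S", 10))
  base <- detect_tmh(core)
  padded <- detect_tmh(paste0(strrep("D", 15), core, strrep("E", 15)))
  expect_equal(nrow(base), 1)
  expect_equal(nrow(padded), 1)
  expect_equal(padded$start - 15, base$start)
  expect_equal(padded$end - 15, base$end)
})

test_that("classification follows the documented precedence", {
  # lipobox plus a transmembrane span classifies as TYPE_II
  both <- paste0("MKS", strrep("L", 6), "LAGC", strrep("L", 20),
                 strrep("S", 20))
  expect_equal(classify_signal(both)$category, "TYPE_II")
  # 20-aa regions are background regardless of content
  expect_equal(classify_signal(strrep("L", 20))$category, "BACKGROUND")
  # sub-threshold non-classical score stays background
  plain <- paste0("M", strrep("G", 49))
  expect_equal(classify_signal(plain, secp_score = 0.3)$category,
               "BACKGROUND")
  expect_equal(classify_signal(plain, secp_score = 0.7)$category,
               "NONCLASSICAL")
  # a helix starting well beyond residue 40 is internal, not an anchor
  internal <- paste0("M", strrep("G", 55), strrep("L", 20),
                     strrep("G", 30))
  expect_equal(classify_signal(internal)$category, "TMH_INTERNAL_MULTI")
})

test_that("external predictor verdicts override the built-in detectors", {
  plain <- paste0("M", strrep("G", 49))
  ext <- data.frame(category = "TYPE_I", verdict = TRUE)
  expect_equal(classify_signal(plain, external_calls = ext)$category,
               "TYPE_I")
  # malformed tables are rejected with the offending row named
  bad <- data.frame(category = "TYPE_IX", verdict = TRUE)
  expect_error(classify_signal(plain, external_calls = bad), "row 1")
  expect_error(classify_signal(plain, external_calls = data.frame(x = 1)),
               "malformed")
})

test_that("generator output classifies to its ground truth exactly", {
  com <- generate_community(2, 150, 0.25, seed = 13)
  got <- vapply(com$orfs$protein,
                function(p) classify_signal(p)$category, character(1),
                USE.NAMES = FALSE)
  expect_equal(got, expected_category(com$orfs$signal_category))
  # exactly one category per ORF: the calls partition the input
  expect_equal(length(got), nrow(com$orfs))
})

test_that("category tallies reproduce the pilot-style composition", {
  counts <- c(TYPE_I = 35, TMH_ANCHOR = 8, TMH_INTERNAL_MULTI = 6,
              TYPE_II = 3, TYPE_IV = 1)
  proteins <- unlist(lapply(names(counts), function(cat_) {
    vapply(seq_len(counts[[cat_]]), function(i) {
      paste0(synthesize_signal_peptide(cat_, seed = i),
             strrep("G", 60))
    }, character(1))
  }))
  calls <- lapply(proteins, classify_signal)
  tab <- tally_signal_categories(calls)
  got <- setNames(tab$count, tab$category)
  expect_equal(got[names(counts)], counts)
  expect_equal(sum(tab$count), 53)
  # empty input gives an all-zero table
  empty <- tally_signal_categories(character(0))
  expect_true(all(empty$count == 0))
  # duplicated sequences count once in the distinct tally
  dup <- c(proteins[1], proteins[1], proteins[40])
  tab2 <- tally_signal_categories(
    vapply(dup, function(p) classify_signal(p)$category, character(1)),
    sequences = dup)
  distinct <- attr(tab2, "distinct")
  expect_equal(sum(distinct$count), 2)
})
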