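---
title: "Modelling secretome-selective phage display: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling secretome-selective phage display: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasecretome)
```

## The experiment being modelled

Secretome-selective phage display turns a physical property of
filamentous phage into a screen for secreted and membrane proteins.
Sheared community DNA is blunt-cloned into a phagemid cassette
(promoter, start ATG, cloning site, then the C-domain of coat protein
pIII, with no vector-encoded signal sequence).  When a gIII-deleted
helper phage packages these phagemids, the virion only acquires its
pIII cap if the insert supplies, in frame with the pIII C-domain, a
peptide that targets the fusion to the inner membrane.  Capless
virions disassemble in the ionic detergent sarcosyl; capped ones
survive.  Recovering DNA from detergent-resistant particles therefore
selects clones whose inserts encode signal peptides, lipoproteins,
transmembrane anchors and the like — a community's *metasecretome*.

A random clone wins this screen only by passing three independent
lotteries:

* its insert covers a secretome-encoding ORF (probability
  `secretome_fraction`, ~0.20 for typical bacterial genomes),
* the insert is cloned in the cassette orientation (1/2 under blunt
  cloning),
* the ORF's codon grid is congruent with the pIII frame at the
  insert's 3' junction (1/3).

So the expected selected fraction is
`0.20 * 1/2 * 1/3 = 1/30`, reported as 3.3%.  Comparing an observed
post-selection secretome frequency with this expectation gives the
fold enrichment; at the conventional one-decimal reporting precision,
85 positives among 90 sequenced clones is 94.4%, a 29-fold
enrichment over 3.3%.

```{r model}
p <- model_params()
as_percent(expected_selection_frequency(p))
enrichment_fold(85, 90, 3.3)
```

### Rounding conventions

Published tables in this field round half-up, not half-even, and fold
ratios are taken on the *reported* (rounded) percentages: 94.4/3.3 =
28.6, printed as 29-fold.  `enrichment_fold()` therefore rounds the
observed percentage to the reporting precision before taking the
ratio; `exact = TRUE` disables this (the exact ratio rounds to 28
instead).  `round_half_up()` and `frequency()` implement the same
convention for all table arithmetic; class distribution rows use one
decimal and cellulosome module sub-rows two, matching the precision
at which such tables are printed.

## The synthetic community

Every downstream stage is exercised on synthetic data with exact
ground truth, generated by `generate_community()` and
`shear_and_clone()`.

**Replicon architecture.**  Each replicon tiles equal-length ORFs
(default 150 aa) back-to-back on the + strand, all in one frame, each
ending in its own TAA; a single 12-nt stop cassette opens the
replicon.  This layout is deliberate: every ORF is immediately
preceded by an in-frame stop, so the open reading region anchored at
any clone's 3' junction begins exactly at an ORF start, and secretome
ORFs occupy exactly the configured fraction of the genome.  Replicons
are treated as circular during shearing, making the junction position
uniform.  Together these give the clean factorisation
`P(selected) = secretome_fraction x p_orientation x p_frame` that the
analytic model assumes, with no geometric corrections — the simulator
*is* the model, plus sequence.

**Signal architecture.**  Exactly `round(fraction * n_orfs)` ORFs
receive a membrane-targeting signal (exact-count, largest-remainder
allocation over the categories; the default weights follow a
pilot-library-like mix: 35 type I, 8 TMH anchor, 6 internal/multiple
TMH, 3 lipoprotein, 1 pilin-like, 0 Tat).  Peptides are built to the
built-in detectors' definitions — e.g. a type I signal is
`MK` + spacer + 8 leucines + `STASA`, placing the A-X-A box at
position 17 — so `classify_signal()` recovers the ground-truth
category with 100% agreement by construction.  That invariant is what
the tests assert; it shows the decision logic is faithful to its
definitions, *not* that the heuristics would reproduce
SignalP/TMHMM/LipoP calls on real proteins.

**Codon discipline.**  Back-translation uses one codon per amino acid,
chosen so that frame-shifted and reverse-strand readings of signal
blocks and spacer regions are non-hydrophobic or stop-interrupted
(leucine is CTC — shifted readings give poly-S/poly-P, minus-strand
readings E/R/G; non-signal "tail" residues are drawn only from
glycine GGG and proline CCC, whose six-frame products are confined to
G/A/P/R).  Without this, off-frame readings of hydrophobic runs
masquerade as transmembrane helices and the sequence-level selection
acquires a large false-positive channel.  With it, the
sequence-detector route (`simulate_selection(classifier =
"detect")`) selects a strict subset of the lottery winners: the only
disagreement with ground truth is clones whose junction falls less
than signal-length + 24 codons into the ORF, a real boundary effect
the analytic model ignores (about a fifth of lottery winners at the
default geometry).  The acceptance checks therefore use the `"truth"`
classifier — the selection *rule* applied to known labels — which is
exactly the paper-style lottery.

**What the generator does not emulate.**  No sequencing error, no
homopolymer noise, no chimeras, no amplification bias, no real codon
usage, no length variation between ORFs, and intergenic DNA reduced
to stop cassettes.  Passing tests demonstrate correctness of the
arithmetic, the frame logic and the decision rules under controlled
conditions; they say nothing about detector sensitivity on real
sequence.

**Insert lengths** default to 0.7–5 kb (the cloneable range of a
sheared-DNA library), drawn from a log-normal (`meanlog = log(1500)`,
`sdlog = 0.5`) truncated to that range; no published length
distribution exists for such libraries beyond the range itself, so a
right-skewed shape typical of shearing was chosen once and left
alone.  `len_min = len_max` gives degenerate (fixed-length) inserts
for tests.

**Randomness.**  Every operation draws from its own stream, seeded by
a small hash of `(seed, operation_name)`, so adding draws to one
stage never perturbs another; all outputs are bit-identical for a
fixed seed.

## Frame analysis

`extract_fusion_orf()` finds the reading frame whose codon boundaries,
anchored at the insert's 3' junction, continue into the downstream
vector flank at its declared phase, and returns the maximal stop-free
codon run in that frame ending at the junction.  The region is *open*
— no initiation codon is required inside the insert, because
translation initiates at the cassette ATG upstream; runs shorter than
`min_fusion_len` (24 aa) are background.  `require_start = TRUE`
additionally anchors the region at the first ATG/GTG/TTG for users
who prefer the stricter convention; both are offered because sequence
reports in this field do not always state which was used.
Coordinates are 0-based half-open internally; translation uses the
bacterial code (table 11); IUPAC ambiguity codes are rejected rather
than guessed at.  `enumerate_orfs()` provides the stop-to-stop
six-frame enumeration used as an independent oracle in the tests.

## Signal classification

The detectors are transparent, deterministic rules: type I (K/R in
residues 1–5, a 7-residue window of mean Kyte–Doolittle hydropathy
> 1.6 within residues 6–20, A-X-A ending at 15–30), lipobox
(`[LVIFG][ASTVG][GAS]C` with the cysteine at 12–35 and early K/R),
pilin-like (G|[GAS]F within the first 12 residues plus a hydrophobic
run), twin-arginine (`[ST]RR.FLK` near the N-terminus), and
transmembrane helices (19-residue sliding window, mean > 1.6, merged
maximal intervals).  Precedence is
TYPE_IV > TYPE_II > TAT > TYPE_I > TMH_ANCHOR (first helix interval
starting at residue <= 40) > TMH_INTERNAL_MULTI > NONCLASSICAL
(score >= 0.5) > BACKGROUND: specific motifs outrank generic
hydropathy, and a published precedence does not exist, so this
ordering is a package decision.  External predictor verdicts, when
supplied as a table, override the built-in rule for their category —
on real data the published tools should be run and their calls fed
in; the package's contribution is the decision logic and bookkeeping,
not the predictors.

One numerical subtlety: a transmembrane interval is the union of all
qualifying 19-residue windows, so it extends a few residues into
flanking polar sequence; the "anchor" boundary (start <= 40) is
interpreted on that interval.  Helices beginning within ~7 residues
of position 40 are therefore gray-zone by construction.

## Selection simulation

`simulate_selection()` applies the rule *selected iff in-frame fusion
of >= 24 codons and non-background signal*, via either ground-truth
labels (`"truth"`) or the sequence pipeline (`"detect"`).  Clones
failing the rule survive independently with probability
`background_escape`.  The pilot-style observation — 5 of 90 selected
clones being background, 5.6% — pins this free parameter near 0.002
(solving `b/(1/30 + b) = 5/90` for the escaped fraction `b` of the
29/30 non-displaying majority); 0.002 is the default, and the
simulated residual background lands at 5–6% of selected clones.  All
causes of real background (cryptic targeting, detergent resistance)
are lumped into this single rate.  Selection is idempotent:
re-selecting a selected pool keeps prior escapes rather than
re-drawing them.

Problem sizes used by the tests and the acceptance script: a
2-replicon, 500-ORF community (~230 kb) and 10^5 coordinate-only
clones for the lottery check (the binomial 3-sigma band at that size
is ±0.17 percentage points around 3.33%); sequence-level runs use
10^2–10^3 clones.  These sizes make every check complete in seconds
while leaving the stochastic bands meaningful.

## CAZyme annotation and cellulosome calls

`parse_domain_hits()` reads HMMER3 per-domain tables (hmmscan
convention) and the 10-column dbCAN-parser TSV; `filter_hits()`
applies the two-branch rule *alignment > 80 aa and E < 1e-5,
otherwise E < 1e-3* — note the asymmetry: long alignments do not get
the relaxed branch.  `dedup_sequences()` clusters at 100% identity
with substring containment (greedy longest-first, representative =
longest then lexicographic), mirroring greedy incremental clustering
tools at a 1.0 threshold; it is deterministic and
permutation-invariant by canonical ordering.  `classify_cellulosome()`
calls, per ORF: two or more dockerin-repeat hits = complete dockerin
domain; one repeat with another CAZyme module; one repeat alone;
cohesin and SLH reported as their own kinds.  No maximum gap between
paired repeats is imposed by default (none is published); a
configurable cap exists.  `rollup_classes()` counts hits (overlaps
retained — the unit is the hit, not a non-overlapping domain
tiling), with deduplicated counts taken over cluster representatives,
and dockerin/cohesin/SLH counted once under "cellulosome" rather
than in any enzyme class.  Recomputing a published-style distribution
from counts can disagree with a printed percentage in the last digit
(e.g. 1147/12565 is 9.13%, sometimes printed as 9.2%); the roll-up
reports the recomputed value.

## Comparative statistics

`compare_proportions()` is a two-sided two-proportion z-test with
pooled variance, falling back to the exact conditional (Fisher) test
whenever a pooled expected cell is below 5.  The significance level
defaults to 0.001 because that is the asterisk convention in the
figures this mirrors; the original test behind such asterisks is
typically unstated, so the choice is documented here as an
assumption, and no multiple-testing correction is applied (matching
that reporting style).  `cog_rollup()` maps Pfam counts to COG-style
single-letter categories with unmapped families falling into S
(function unknown) — the catch-all's semantics.

## Taxonomic binning

Best-hit binning only (no lowest-common-ancestor logic): among hits
with E < 1e-5 and query coverage > 30%, the highest bit score wins,
ties by lower E-value, then input order.  Coverage uses a `qcovs`
column when present, otherwise alignment length over query length —
stated explicitly because standard 12-column tabular output carries
no coverage.  Cellulosome-module ORFs use bit-score gates instead
(40 for cohesin/SLH, 35 for dockerin) and report family rank.
`rank_rollup()` pools taxa under 0.1% into "Other" and routes
unassigned queries *and* assignments whose winning hit is below 30%
identity into "Unassigned"; the two threshold families are kept as
distinct operations because insert-level and module-level analyses
use different rules.  A user-supplied synonym map is the hook for
nomenclature curation (reclassified genera); no curation is
automated.

## Known limitations

* The heuristic detectors are architecture checks, not trained
  predictors; on real proteins they will misclassify sequences the
  published tools handle (that is what the external-call override is
  for).
* The escape rate is a lumped free parameter, calibrated to one
  observed background level, with no mechanistic content.
* Single-round selection only: no phage amplification bias or
  growth competition between rounds.
* The synthetic genome's codon discipline makes frame-shift artefacts
  rare by construction; real metagenomes are noisier in exactly the
  ways this generator avoids.
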