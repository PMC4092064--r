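---
title: "rrbsim: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rrbsim: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`rrbsim` simulates a reduced representation bisulfite sequencing (RRBS)
experiment against a synthetic genome with known methylation truth, processes
the reads the way an RRBS study would (trimming, bisulfite-aware unique
paired mapping, per-CpG calling) and runs the standard genome-wide analyses.
This vignette records the models, the parameters that matter, and the design
decisions that were genuinely open.

## The synthetic world

**Genome.** Background sequence is i.i.d. uniform over A/C/G/T. Uniform
sequence has a CG dinucleotide every ~16 bp, far denser than the ~1/100 bp
typical of mammalian bulk genome, so the generator first destroys every
native CG (rewriting its C to A or T, which cannot create a new CG on either
side) and then plants CpGs at the target per-bp rates: 0.01 outside islands
and 0.10 within `island_half_width` (500 bp) of each TSS. Planting is
Bernoulli per position with collisions skipped, so realized rates fall
slightly below their targets (by about the square of the rate); tests
therefore check the island/background density *ratio* (≈10) rather than
absolute counts. Genes have a fixed 5 kb span and at least 13 kb between
TSSs, so the ±6 kb profile flanks never overlap a neighbour; the TSS of a
minus-strand gene is the high end of its interval. All coordinates are
0-based, half-open, everywhere except the cytosine-report file (1-based, the
de-facto dialect).

**Methylome.** A configurable fraction of genes (default 0.2) is "active":
CpGs within ±1 kb of an active TSS get m = 0.05, all other CpGs m = 0.85,
each with truncated-normal jitter (sd 0.03, clipped to [0,1]). The jitter
keeps recovery tests non-degenerate without destroying bimodality. A CpG site
is keyed by the forward-strand position of its C and the probability applies
to both strands — mammalian CpG methylation is symmetric and the analyses
never distinguish strands.

**Expression.** Exactly `round(0.6 n)` genes are repressed (counts 0–9);
the rest draw log-uniform counts ≥ 10 spanning over two orders of magnitude.
Active genes stay out of the repressed set and, with probability `coupling`
(default 1), draw counts above the non-active range, so they land in the
"high" class of the median split. This makes the expression-stratified
profiles interpretable by construction: the high-expression stratum is the
unmethylated-promoter stratum.

## The library

MspI cuts C^CGG; fragments tile each contig exactly, and only those with
150–250 bp inserts survive size selection (inclusive bounds; the insert is
the span between cut offsets). MspI leaves 5'-CG overhangs, so the two
strands of a fragment `[p, e)` are staggered: the top-strand molecule covers
`[p, e)` and the bottom-strand molecule `[p+2, e+2)` — both therefore begin
5'-CGG, which is why nearly every read 1 starts with CGG (methylated CpG) or
TGG (unmethylated, converted). The fill-in of the overhang contributes two
bases at the molecule's 3' end whose C is synthesized unmethylated; they
surface as the first two bases of read 2 (typically "CA", hence the familiar
read-2 CAA start) and must be trimmed before calling. Truth tags on each
pair record the molecule's interval (the fragment interval, +2 for
bottom-strand molecules).

Per retained fragment the simulator draws Poisson(`mean_depth`) molecules,
assigns each a strand fairly, draws one Bernoulli(m) methylation state per
CpG per molecule (shared between mates, so overlapping mates can never
disagree), converts unmethylated Cs with probability
`conversion_efficiency` (default 0.995) and methylated Cs with probability
`1 - meth_protection` (default 0: the paper-style world has no inappropriate
conversion, but it is a parameter, not a constant), applies substitution
errors at `seq_error` per base, and emits Phred+33 qualities from a
two-level model (Q38, 3% low tail in 2–20). No PCR duplicates, adapter
read-through or indels are modelled — the aligner tolerates substitutions
only, matching its ≤1-mismatch contract.

## Trimming and alignment

Read 2 first loses its two fill-in bases. Both mates then get BWA-style
3' quality trimming: keep the prefix `[0, x)` maximizing
`S(x) = sum_{i>=x} (threshold − q_i)` with ties broken toward keeping more
bases; the threshold is Phred 20. Trimming is idempotent, and reads that fall
below the 50 bp seed are discarded with their mate (the spec of the protocol
gives no minimum; seeding imposes one naturally).

The aligner is a three-letter mapper: each contig is stored C→T and G→A
converted. A directional library needs only two search spaces: read 1 in
C→T space anchors the fragment start (top-strand origin), and its reverse
complement in G→A space anchors the fragment end (bottom-strand origin);
read 2 anchors the opposite end in the same space. One exact 50-mer seed per
mate (5' end) generates candidates; candidates are verified over the full
reads in fully converted space, so a genomic C read as T is never a mismatch.
A pair is accepted only if exactly one placement attains the minimal total
mismatch count, each mate has ≤1 mismatch, the orientation is FR and the
insert is within 150–250 bp; otherwise it is rejected with a reason
(`unmapped`, `ambiguous`, `orientation`, `insert_size`,
`too_many_mismatches`, `too_short`). Uniqueness is judged at the pair level,
not per mate. Reads with an error inside a 5' seed are lost, as with any
seed-based mapper; at the default error rate this costs ~9% of pairs.

## Calling and QC

Top-strand evidence (C methylated / T unmethylated at genomic C positions)
and bottom-strand evidence (G/A at genomic G positions) pool into one site
keyed by the forward-strand C. Where mates overlap, overlapping positions
count once, read 1 winning — one molecule must not be counted twice.
Aligned bases over *non-CpG* cytosines estimate the conversion failure rate:
with efficiency 0.995 and no true non-CpG methylation the QC reports ≈0.5%,
and anything under 1% indicates adequate conversion. Percentages are kept as
real numbers until report time. The coverage filter is inclusive
(`meth + unmeth >= min_cov`), with 10 as the working threshold and 100 for
high-stringency replicate comparisons; replicate correlations are Pearson
over the sites passing the threshold in both tables, and rise with the
threshold on heterogeneous-coverage libraries.

## Analyses

* **Region means** are unweighted means of per-site percentages; a region
  without passing sites is `no_data`, never 0.
* **TSS meta-profiles** use 1000 bp windows stepping 50 bp across ±6 kb
  (offsets −6000 … +5000, i.e. `(2·6000 − 1000)/50 + 1 = 221` full windows;
  edge windows are full-width, not truncated). Windows are evaluated in gene
  orientation; each gene contributes the mean of its covered sites in the
  window and genes are weighted equally, so CpG-dense genes cannot dominate.
* **TSS CpG content** is CG starts per window length in
  `[TSS−500, TSS+500)`, computed on forward coordinates regardless of
  strand (deterministic, documented convention), with genes classed "high"
  above 3.7%.
* **Histograms** use 10-point bins with the top bin closed.
* **Stratification** applies the same profile code per
  (expression class × CpG class × animal); paired t-tests
  (`t = mean(d)/(sd(d)/√n)`, df = n−1, two-sided) compare strata across
  animals, with zero-variance differences flagged degenerate (p = 1 when the
  mean is 0, else 0). Cross-method concordance runs one paired t-test per
  site across animals and counts sites with p ≥ 0.05 as indistinguishable —
  deliberately with no multiple-testing correction, since the summary of
  interest is a raw site count; an adjustment method is exposed but off.

## What a green test does and does not establish

The generator reproduces the *statistical structure* the analyses assume —
island CpG enrichment, bimodal methylation, expression-linked promoters —
not real genome features: no repeats, no assembly gaps, no CpG-island
annotation beyond the TSS windows, no PCR bias, no real base-quality
profiles. Green tests establish that the pipeline measures what the
synthetic world puts in, at the stated depths and error rates; they say
nothing about robustness to repetitive DNA or coverage bias.

One resolution limit deserves emphasis. Size selection concentrates coverage
almost entirely inside the islands: fragments flanking an island nearly
always exceed 250 bp and are discarded. Since the island (±500 bp) lies
wholly inside the unmethylated promoter (±1 kb), every profile window that
touches an island sees only low-methylation CpGs for active genes, and the
pooled profile is flat to within ~1 point across offsets ≈ −1450 … +450.
Which window inside that band attains the literal minimum is then decided by
which genes happen to contribute to each window (a 3–5 point
composition effect), not by methylation structure. With dense calls (every
CpG covered) the minimum localizes strictly to TSS-overlapping windows; with
pipeline calls the tests assert the minimum falls within the
promoter-overlapping band. This is a property of MspI-limited coverage, not
of the implementation.

## Numerical and scale choices

* Test and acceptance worlds are desk-scale by design: 500 kb genomes for
  QC-style checks (≈130,000 non-CpG observations at depth 120) and a 2.6 Mb,
  200-gene world for recovery and figure shapes (~20k pairs, about a minute
  on one CPU). Real RRBS volumes (tens of millions of reads) are out of
  scope.
* Recovery is checked at `min_cov = 30` on a library simulated at mean depth
  150: binomial counting noise alone makes ±3-point mean recovery impossible
  at literally 30 reads, so the depth is chosen to keep typical coverage
  well above the threshold.
* Seed-hit pairing in the aligner is bounded at 10 kb to keep the candidate
  join small; inserts beyond that cannot be accepted anyway.
* The equal-rate corner case (`island_cpg_rate == background_cpg_rate`) is
  allowed so "no island signal" worlds can be constructed.
* Replicate-correlation tests mix shallow (depth 12) and deep (depth 150)
  fragment subsets: a single Poisson depth gives too narrow a coverage
  spread for the 10× and 100× thresholds to select different site sets,
  whereas real RRBS coverage is strongly heterogeneous.
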