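---
title: "Detecting and predicting NAGNAG tandem-acceptor splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and predicting NAGNAG tandem-acceptor splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nagnag)
```

## The problem

A NAGNAG tandem acceptor is a 3′ splice site where two `AG` dinucleotides
sit three nucleotides apart, each preceded by any base N. The spliceosome
may join the upstream exon at the intron-proximal `AG` (the *E* variant —
the second `NAG` stays in the mRNA) or at the distal `AG` (the *I* variant
— the whole `NAGNAG` is removed). Sites with transcript evidence for both
acceptors are alternatively spliced (*EI*). Because the two isoforms
differ by exactly three nucleotides, no frameshift occurs; the typical
consequence is insertion or deletion of a single amino acid. Transcript
coverage in most genomes is far too shallow to observe every such choice
directly, which motivates a sequence-based predictor: given only the
acceptor neighbourhood, estimate whether a tandem site is spliced E, I,
or EI.

This package implements the full workflow: genomic discovery of tandem
acceptors at annotated intron–exon boundaries, adjudication of the
observed outcome from spliced alignments, a 31-feature sequence
representation, and a three-class naive Bayes classifier with
cross-validation, one-vs-rest ROC/AUC, and information-gain feature
ranking. A self-contained simulator produces genomes, annotations and
spliced alignments with known truth, so every stage is testable offline.

## Site discovery

Introns are derived from consecutive exons of each transcript in a GFF3
annotation; coordinates are 1-based inclusive throughout, and junction
coordinates denote the last intronic base of an acceptor `AG` — this
convention matches the input format and removes off-by-one ambiguity.
Introns whose coding-strand sequence does not end in `AG` are flagged
non-canonical and excluded from scanning rather than silently kept.

At each canonical acceptor the scanner looks for a second `AG` ending
three nucleotides upstream of the annotated acceptor (the motif is then
fully intronic and the annotated acceptor is the distal one) or at exon
positions +2/+3 (the second `NAG` is exonic; the annotated acceptor is
proximal). Both strands are handled by a single code path that maps minus
features onto the reverse-complemented contig. Three deliberate policies
cover cases the site definition leaves open:

* **Triple tandems** (`NAGNAGNAG`): each adjacent `AG` pair is emitted as
  its own site. Enumeration preserves information; collapsing would
  silently discard a candidate acceptor.
* **Ambiguity letters**: sites whose N positions are not plain
  `A`/`C`/`G`/`T` are skipped — the categorical features cannot represent
  them.
* **Shared acceptors**: transcripts of one gene often reuse an acceptor;
  sites are deduplicated on (seqid, strand, proximal junction), keeping
  the lowest-ordinal transcript as representative so reads are never
  double-counted.

Each site's 49-nt context is assembled mRNA-sense from four blocks: the
last 3 nt of the upstream exon, the 30 intronic nt immediately upstream
of the motif, the 6-nt motif, and 10 nt downstream. Positions a short
flank cannot supply are padded with the sentinel `X`; a site with a
sentinel at any *feature* position is excluded from training and
prediction and reported, while padding confined to the unused intronic
positions (context 4–13) is harmless.

## Evidence adjudication

Spliced alignments (BED12, GFF3 match features, or a documented TSV
dialect) pass three quality filters before counting: identity ≥ 0.95,
read coverage ≥ 0.90, and no block gap above 20,000 nt. Single-block
alignments cannot witness a junction and are discarded. An alignment
supports the E variant of a site when one of its gaps ends exactly at the
proximal junction, and I when at the distal junction. An alignment whose
*terminus* lies within 3 nt of either junction is ignored at that site
only — an alignment that merely ends at an exon boundary is ambiguous
there but its unambiguous junctions elsewhere remain usable. This
per-site interpretation is a deliberate choice: discarding such reads
globally would throw away clean evidence at unrelated sites.

Observed labels follow directly: support on one side only is
constitutive (E or I), support on both is EI, neither is uncovered.
Training examples are stricter, mirroring the support rules used for
label reliability: a constitutive training site needs ≥ 10 reads on one
acceptor and none on the other; an alternative training site needs ≥ 2
reads per variant with the minor variant carrying ≥ 10% of the total.
Sites failing both rules go to the prediction pool. Evidence pools (e.g.
Sanger and 454-style sets) are merged by element-wise summation with the
per-pool breakdown preserved, so a site supported one-sidedly in each of
two pools correctly flips to EI after merging. Tally percentages are
reported with round-half-up at one decimal.

## Features

The 31 predictors are:

* 28 positional nucleotides: the last 3 exonic nt, the 20 intronic nt
  immediately upstream of the motif, the two Ns of the `NAGNAG`, and the
  first 3 nt downstream. The motif's `AG` letters are constants and are
  not features. Feature names follow the positional scheme `exon_m3` …
  `up_m20` … `up_m1`, `N1`, `N2`, `down_p1` … `down_p3`.
* `y_content`: the number of pyrimidines among the 20 intronic upstream
  positions, a proxy for polypyrimidine-tract strength (integer, 0–20).
* `score_E`, `score_I`: acceptor-strength log-odds of the proximal and
  distal junctions. The scorer is a 23-position log₂-odds matrix over the
  window −20…+3 of a junction (acceptor `AG` fixed at −2/−1), trained on
  the acceptor windows of constitutive training sites with an add-one
  pseudocount against genome mononucleotide background frequencies. A
  position-specific log-odds model is the standard transparent choice
  for acceptor strength: a background-distributed window scores about
  zero, the training consensus scores maximally, and every cell is
  hand-checkable. Scores are dimensionless (base-2) and rank-compatible
  rather than calibrated to any external scorer, so absolute values
  should not be compared across training sets.

A reduced 5-feature view (`N1`, `N2`, `up_m1`, `up_m2`, `down_p1`)
supports cross-dataset transfer experiments where only the immediate
neighbourhood generalises.

## Classifier

A three-class naive Bayes model is used: class priors are training
frequencies; each categorical feature gets a Laplace-smoothed (+1,
configurable) class-conditional table over `A/C/G/T`; each numeric
feature gets a class-conditional Gaussian with a variance floor of 1e-9
so a within-class constant feature cannot divide by zero. Posteriors are
computed in log space with log-sum-exp normalization; a missing feature
simply drops its likelihood term. The predicted class is the posterior
argmax with exact ties broken in the fixed order E > I > EI — ties are
measure-zero in practice, but the rule makes predictions reproducible.

Cross-validation is stratified by class with a mandatory seed (2-, 5- or
10-fold; leave-one-out is deterministic), pooling out-of-fold posteriors
and reporting a one-vs-rest AUC per class. AUC is the rank-based
Mann–Whitney statistic with midrank tie handling, which equals the
trapezoidal area under the empirical ROC. Feature relevance is ranked by
information gain, H(Class) − H(Class|Feature) in bits; numeric features
are discretized into equal-frequency bins (default 10) first.

## The simulator

`simulate_dataset()` builds multi-exon genes on both strands of one
chromosome, plants tandem acceptors of known class, emits
junction-spanning alignments, and writes truth alongside. It emulates
the features the pipeline actually consumes:

* **Class mixture**: defaults to the observed proportions of covered
  tandem sites (E 0.536, I 0.405, EI 0.059).
* **Sequence signal**: the N of a used acceptor favours pyrimidines
  (C > T > A > G), the N of an unused acceptor drifts towards the rarely
  functional `GAG`, and both Ns of an EI site are strongly
  pyrimidine-enriched; the 20-nt upstream window carries a per-class
  pyrimidine probability (E 0.52, I 0.62, EI 0.78). The strengths
  interpolate linearly to a class-independent null at `signal = 0`, so
  experiments can sweep from chance-level to strong recovery. The
  default strengths were fixed once so that the classifier's
  parameter-recovery contract (per-class AUC ≥ 0.9 at 600 sites/class)
  holds with margin while the composition contrasts remain qualitative
  echoes of real acceptor logos. The no-third-`AG` constraint that keeps
  planted motifs unambiguous is applied identically to every class, so
  the zero-signal generator is class-exchangeable by construction.
* **Read model**: mean reads per covered site (default 15), an EI
  minor-isoform fraction drawn uniformly from 0.15–0.45 (covered EI
  sites always receive at least one read per variant, so a pure-EI
  configuration is labelled EI by construction), identity/coverage noise,
  and decoy alignments — single-exon, low-identity, low-coverage,
  oversized-intron and boundary-ending reads, each violating exactly one
  rule and tagged in its read id so filter tests are exact.

What it does **not** emulate: sequencing-error profiles and quality
strings, expression-level or tissue structure, alternative transcript
isoforms beyond the acceptor choice, overlapping genes, and non-canonical
(non-`GT`/`AG`) introns. Passing tests on simulated data therefore
demonstrate the correctness of the machinery and the recoverability of a
planted signal — not the absolute accuracy achievable on real
transcriptome data, where label noise, mapping artefacts and weaker
signal all intrude.

## Numerical and scale choices

* Percentages: round-half-up, one decimal for tallies.
* Pseudocounts: +1 for both the acceptor matrix and the categorical
  tables (configurable).
* Variance floor 1e-9; posterior normalization tolerance 1e-9.
* Test and experiment sizes were chosen to exercise every code path at
  interactive speed: hand fixtures of one or two genes for exact
  coordinate checks, 10–40 simulated genes for end-to-end runs, and 600
  contexts per class (1,800 total) for the cross-validated recovery and
  null-control experiments.

## Worked run

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(seed = 1), tempfile())
cfg <- pipeline_config(genome = sim$genome, annotation = sim$annotation,
                       alignments = list(sanger = sim$alignments),
                       out_dir = tempfile(), folds = 5, seed = 1)
manifest <- run_pipeline(cfg)
manifest$auc
```

## Known limitations

* The acceptor-strength scores are internal log-odds, not calibrated to
  any published splice-site scorer; only their ranking is meaningful.
* Naive Bayes assumes feature independence; adjacent nucleotide
  positions are correlated in real acceptors, so posteriors are
  over-confident even when the ranking (and hence AUC) is good.
* The evidence module consumes alignments; it does not compute them, and
  it trusts the supplied identity/coverage fields.
* Uncovered sites receive posteriors but no observed label; nothing in
  the package estimates coverage-dependent detection probability.
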