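# nagnag

Detection and prediction of **NAGNAG tandem-acceptor alternative
splicing** from genome sequence, gene annotation, and spliced transcript
alignments.

A NAGNAG acceptor is a 3′ splice site with two `AG` dinucleotides three
nucleotides apart (`N₁AGN₂AG`). Splicing at the intron-proximal `AG`
keeps the second `NAG` in the mRNA (the *E* variant); splicing at the
distal `AG` removes the whole motif (*I*); transcript support for both is
alternative splicing (*EI*), which inserts or deletes one codon without a
frameshift. The package is for genome scientists who want to (i) census
these sites in an annotated genome, (ii) adjudicate each site's observed
outcome from EST/RNA read alignments under explicit support rules, and
(iii) predict the outcome from sequence alone where coverage is too
shallow to observe it.

## What it computes

* **Scan** — all tandem acceptors at annotated intron–exon boundaries:
  an `AG` ending 3 nt upstream of the annotated acceptor, or at exon
  positions +2/+3, on either strand; each site carries its 49-nt
  mRNA-sense context (3 exonic + 30 intronic + motif + 10 downstream nt).
* **Evidence** — spliced alignments are filtered (identity ≥ 0.95, read
  coverage ≥ 0.90, intron ≤ 20,000 nt; single-exon and
  boundary-terminating alignments cannot witness a junction), junction
  support is counted per acceptor, and sites are labelled E / I / EI /
  uncovered. Training labels are stricter: ≥ 10 reads one-sided for
  constitutive, ≥ 2 reads per variant with a ≥ 10% minor fraction for
  alternative. Evidence pools merge by summation.
* **Features** — 31 predictors per site: 28 positional nucleotides
  around the motif, the pyrimidine count of the 20-nt upstream window
  (polypyrimidine-tract strength), and log₂-odds acceptor-strength
  scores of both junctions from a 23-position weight matrix trained on
  constitutive sites.
* **Classifier** — three-class naive Bayes (Laplace-smoothed categorical
  tables, Gaussian numeric features) giving posteriors P(E), P(I),
  P(EI); stratified cross-validation with per-class one-vs-rest ROC/AUC
  (rank-based, midrank ties); information-gain feature ranking; transfer
  prediction with a reduced 5-feature view.
* **Simulator** — synthetic genomes, annotations, alignments and truth
  tables with class-dependent sequence signal and per-rule decoy reads,
  so the whole pipeline is testable without external data.

## Worked example

```r
library(nagnag)

# simulate a small study with known truth, then run every stage
sim <- simulate_dataset(sim_config(seed = 1, n_genes = 40,
         class_mix = c(E = 0.40, I = 0.35, EI = 0.25), read_mean = 20),
       tempfile())
cfg <- pipeline_config(genome = sim$genome, annotation = sim$annotation,
                       alignments = list(sanger = sim$alignments),
                       out_dir = tempfile(), folds = 5, seed = 1)
manifest <- run_pipeline(cfg)
manifest$counts
#> $introns: 120   $sites: 79   $covered: 74   $training: 70   $features: 79
```

All 79 planted sites are rediscovered; the 70 sites meeting the training
read-depth rules are labelled identically to the simulator's truth
table. A larger classifier experiment (600 sites per class):

```r
sim <- simulate_contexts(600, sim_config(seed = 1))
lab <- sim$labels
wins <- ifelse(lab == "E", acceptor_windows(sim$contexts, "proximal"),
               acceptor_windows(sim$contexts, "distal"))
pwm <- train_acceptor_pwm(wins[lab != "EI"])
fv  <- extract_feature_vectors(sim$contexts, pwm)
cross_validate(fv, lab, k = 10, seed = 1)
#> 10-fold cross-validation (n = 1800)
#>   AUC E  (one-vs-rest): 0.953
#>   AUC I  (one-vs-rest): 0.929
#>   AUC EI (one-vs-rest): 0.965
#>   accuracy: 0.823
```

The AUCs say the splicing class is largely recoverable from the acceptor
neighbourhood alone; the information-gain ranking
(`rank_information_gain(fv, lab)`) puts the polypyrimidine-tract
Y-content, the two motif Ns and the acceptor-strength scores on top,
i.e. the signal lives in the splice site and its immediate vicinity.

A command-line wrapper over the same functions is installed at
`inst/scripts/nagnag` (subcommands `simulate` and `run-all`).

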