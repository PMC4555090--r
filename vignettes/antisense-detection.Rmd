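---
title: "Detecting antisense transcription in stranded metatranscriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting antisense transcription in stranded metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Strand-specific RNA-seq of a microbial community reports, for every read,
which DNA strand it was transcribed from. Comparing read strands with the
annotated strands of protein-coding genes reveals antisense transcription —
RNA from the strand opposite a gene's coding sequence, a candidate
regulator of the sense transcript. The catch is that library strandedness
is below 100%: a few percent of reads report the wrong strand because of
artifacts in cDNA synthesis and amplification. A gene with no antisense
transcription therefore still accumulates "antisense" reads in proportion
to its expression, and naive counting wildly overstates antisense activity
for highly expressed genes.

`antisensr` packages a complete treatment of this problem: strand-aware
read counting, an artifact-corrected binomial call per gene, species-level
summaries with eligibility filters, COG functional enrichment among the
called genes, and cross-sample dynamics — plus a synthetic community
generator with known ground truth that the whole test suite is built on.

## The calling model

Let a gene have $c$ mapped reads, $m$ of them antisense. Under the null
(no antisense transcription) each read is independently wrong-strand with
probability $p$, so $m \sim \mathrm{Binomial}(c, p)$ and the evidence
against the null is the upper tail

$$P(X \ge m) = \sum_{i=m}^{c} \binom{c}{i} p^i (1-p)^{c-i},$$

computed by `binomial_tail()` through the survival function (numerically
exact far into the tail, up to $c \sim 10^6$; the test suite checks it
against direct log-space summation to 12 significant digits). A gene is
called antisense-transcribed at $P \le \alpha$ with $\alpha = 0.05$.

Two deliberate choices here:

* **No multiple-testing correction by default.** The per-gene test is the
  unit of inference, and downstream summaries (ratios of called genes) are
  interpreted as rates, not as a controlled discovery list. A per-species,
  per-sample BH option (`call_antisense(adjust = TRUE)`) exists for users
  who want a controlled gene list; it is strictly more conservative.
* **The artifact rate is an upper bound, not a fit.** `artifact_p`
  defaults to 0.01, with 0.05 as a conservative variant. When estimated
  from data (`estimate_artifact_rate()`), $p$ is the *minimum* per-species
  ratio of antisense reads among species with at least `min_reads` mapped
  reads (default 10,000 — small enough to admit moderately sampled
  species, large enough that the ratio has a standard error below ~0.001):
  true antisense transcription inflates every species' ratio, so the
  minimum is the tightest available upper bound on the artifact rate. A
  floor of 0.001 prevents a zero-ratio species from degenerating the test.
  Because the bound errs high, the test errs conservative — which is also
  why the sharing-dynamics checks in the test suite call with the
  conservative $p$: at $p$ exactly equal to the true artifact rate, the
  per-gene $\alpha = 0.05$ leaks individual-specific false-positive
  singletons into the sharing histogram.

Derived per-gene quantities: the transcription category (`sense_only`,
`antisense_only`, `both`, `silent` — from raw counts, not from the test),
the dominance statistic $d = (s - a)/(s + a) \in [-1, 1]$ ($+1$ purely
sense, $-1$ purely antisense, undefined for silent genes), and FPKM
$= c \cdot 10^9 / (L \cdot T)$ with $L$ the gene length and $T$ by default
all reads assigned to any gene in the sample (configurable to all mapped
reads via `total_mapped`).

## Strand-aware counting

`count_strands()` replaces the classical pair of featureCounts runs with
opposite `-s` settings by a single assignment pass. Internal coordinates
are 1-based inclusive (the GFF convention); SAM/BAM positions are converted
on read, and the reference span of an alignment is the sum of its
M/D/N/=/X CIGAR operations. Reads unmapped, secondary or supplementary are
dropped at IO; MAPQ filtering defaults to off, PCR duplicates are not
removed. Assignment rules follow the counting tool's documented defaults:
1 bp of overlap assigns a read (configurable `min_overlap`), reads
overlapping two or more genes are typed `ambiguous` and discarded from
counts, reads overlapping none are `no_feature`. Orientation is
`sense` iff the read strand equals the gene strand, XOR-ed with a
`reverse` protocol flag; a second mate's strand is flipped before the
comparison. Every run satisfies `assigned + no_feature + ambiguous =
input reads`, and flipping the protocol exactly swaps the sense and
antisense columns — both are asserted in the test suite on every synthetic
run. Overlap lookup uses an interval index; a brute-force scan over all
genes is kept in the tests as the oracle for 1,000 randomized queries.

## Species summaries and filters

Per species and sample, `summarize_species()` reports the ratio of
antisense reads (over reads mapped to the species' genes) and the ratio of
genes with antisense transcription (over genes with *detectable
transcription*, defined as $\ge 1$ assigned read — the smallest defensible
threshold, configurable). Species with fewer than 100 expressed genes are
flagged ineligible: with few expressed genes the ratio's denominator is
unstable and mapping artifacts dominate. The same eligibility filter
restricts profile comparisons (`profile_correlation()` requires identical
eligible key sets in all compared conditions) and the expression-dominance
analysis (genes need $\ge 20$ reads, species $\ge 100$ supported genes,
and genes at $|d| = 1$ are excluded so the Spearman correlation of
$\log \mathrm{FPKM}$ against $|d|$ is not driven by the saturated ends).
`antisense_only_report()` lists high-confidence antisense-only genes: zero
sense reads, $\ge 3$ antisense reads, length $\ge 600$ bp (longer genes
are less likely to be annotation errors).

## COG enrichment

Within each genome with at least 30 antisense-called genes, every COG with
at least one member gene is tested for over-representation among the
called genes in two ways: a one-tailed binomial test with success
probability $K/N$ ($K$ COG members, $N$ all protein-coding genes — the
background includes genes without COG labels), and a one-tailed Fisher's
exact test on the table $[(k, K-k), (n-k, N-K-n+k)]$ evaluated as the
upper hypergeometric tail. The binomial family penalizes small COGs
heavily under FDR correction, which is why both families are reported. BH
correction is applied per genome and per test family, across the COGs
actually tested in that genome; correcting across genomes jointly is a
stricter alternative the data do not obviously demand, and per-genome
correction keeps each genome's result self-contained. Genes with several
COG labels count toward each; `summarize_categories()` splits multi-letter
category codes and counts each significant COG-genome pair once per
letter.

## The synthetic community generator

`simulate_community()` emulates the statistical structure the analysis
assumes, with ground truth recorded per sample and gene:

* **Layout**: one contig per species, genes placed non-overlapping with
  50–500 bp intergenic gaps, uniform lengths in 300–1500 bp, random
  strands; the contig grows to fit, so placement never fails.
* **Abundance**: explicit weights or a Dirichlet draw (default
  concentration 1). Per-gene expression is log-normal (meanlog 0, sdlog
  1.5 — a typical several-orders-of-magnitude bacterial expression spread)
  and normalised within species, so a species' expected share of sense
  reads equals its abundance exactly.
* **Antisense truth**: each gene is antisense-positive with probability
  `antisense_fraction` (default 0.10, matching the median ratio of genes
  with antisense transcription reported for gut communities), with an
  antisense:sense expression ratio drawn log-uniformly from [0.1, 10] —
  the observed ratio spectrum spans this range, and no published
  generative model exists, so the choice is a stand-in exposed in the
  config rather than asserted as fact. Per-sample resampling of antisense
  status is ON by default, emulating the strongly individual-specific
  antisense gene sets seen across human hosts; OFF models a species whose
  antisense complement is shared.
* **Artifacts**: template counts are multinomial over gene-by-strand
  cells; each template read then reports the wrong strand with probability
  $1 - \mathrm{strandedness}$ (default strandedness 0.99, i.e. the 1%
  artifact rate of the primary analysis). `emit_counts()` stops there;
  `emit_reads()` additionally places 100 bp reads uniformly in the gene
  body, clipped at the gene's 3' end so a read never leaves its source
  gene — which makes the two routes agree exactly per gene under the same
  seed, an identity the tests assert.
* **Determinism**: one master seed; per-sample and per-stage sub-streams
  are derived from it with a multiplicative congruential step, so any
  sample can be regenerated independently and all outputs are byte-stable.
* **Defaults**: 5 species × 500 genes, $10^6$ reads per sample, 8 samples
  — a community small enough to simulate in seconds but deep enough
  (~400× mean gene coverage) that calling operates in its intended regime.

What the generator does *not* model: nucleotide sequences and mapping
ambiguity, rRNA contamination, genomic DNA contamination, operon
structure, overlapping or misannotated genes, and paired-end fragments
(the counting path still honours mate semantics for real paired data).
Passing tests therefore demonstrate the statistical machinery —
error-rate control, parameter recovery, monotonicity, conservation — not
robustness to reference or mapping artifacts, which real data inject
before this pipeline begins.

## Numerical and degenerate-input choices

Tail probabilities are survival-function evaluations (never
$1 - \mathrm{CDF}$); probabilities below double-precision range underflow
to 0, which only ever strengthens a call. Silent genes carry `NA`
p-values and `d`, are never called, and are excluded from every ratio
denominator. Zero-variance profiles and degenerate rank sets raise typed
errors rather than returning `NA` correlations. BH adjustment is the
standard step-up (it is monotone and order-preserving, but not idempotent
— re-adjusting adjusted values inflates them, so `enrich_cogs()` adjusts
raw p-values exactly once per family). Ties in p-value sorting are broken
by COG id for deterministic output order; result tables are written sorted
by their declared keys so reruns are byte-identical, as recorded in the
pipeline manifest.

## Problem sizes in the test suite

The suite validates on communities of 3–5 species with 60–2,000 genes and
$3\times 10^4$ to $5\times 10^5$ reads per sample (the type-I-error check
uses 10,000 genes at 50 reads per gene), 1,000-instance oracle sweeps for
the exact tests, and 30-replicate null simulations for FDR control —
sizes chosen so each statistical property is measured with comfortable
Monte-Carlo margins while the whole suite runs in well under a minute per
file.

## Known limitations

The binomial call underestimates antisense transcription for genes and
species with few reads (low power), so between-species comparisons of the
called ratios should be read cautiously. The artifact-rate estimate is an
upper bound and inherits any true antisense signal present in the
least-antisense species. Enrichment treats genes as exchangeable — operon
structure and shared regulation are ignored. FPKM inherits the usual
caveats of composition effects in community data.
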