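---
title: "Detecting splicing-regulated microRNA recognition elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting splicing-regulated microRNA recognition elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicemre)
```

## The biological question

A microRNA recognition element (MRE) is a short site on an mRNA through
which a microRNA represses protein output.  When an MRE lies in or near a
cassette exon, alternative splicing can produce two isoform classes from
one gene: MRE-containing transcripts that remain under microRNA control,
and MRE-free transcripts that escape it.  If a tissue preferentially
expresses one class, splicing acts as a tissue-specific fine-tuning layer
on top of microRNA regulation.  `splicemre` detects such
*splicing-regulated MREs* from EST evidence and characterizes them: how
repressive they are, how they cluster into regions, how often true
(experimentally validated) sites are splicing-regulated compared to
random background sites, and how repression shows up in protein-level
(SILAC-style) measurements.

## Evidence model

ESTs are single-pass cDNA reads; in non-normalized libraries their counts
are roughly proportional to transcript abundance, so counting ESTs per
isoform class approximates isoform expression per tissue.  Each EST is
consumed as a spliced alignment to a single sense-strand reference
transcript (exon blocks in BED12).  Relative to a specified MRE interval,
an EST takes exactly one of five configurations:

* **I** — the EST does not span the complete MRE (uninformative);
* **II** — the MRE lies wholly inside one aligned exon block: the EST
  represents an MRE-containing isoform;
* **III** — the MRE lies wholly inside one inter-block gap (a putative
  intron): an MRE-free isoform;
* **IV** — the MRE straddles an exon–intron junction, so the isoform
  retains only a partial, likely non-functional site; it is counted as
  MRE-free;
* **V** — a defensive catch-all for structurally anomalous alignments,
  excluded like I.

Interval arithmetic is 0-based half-open internally, so an MRE sharing an
endpoint with a block is *contained*, never "straddling"; all files are
read and written 1-based inclusive, the convention of published site
coordinates.

## The enrichment test

For each tissue (optionally split into normal/cancer histology strata,
with "all other tissues" restricted to the same stratum) we form the
2×2 table

|              | MRE-free | MRE-containing |
|--------------|----------|----------------|
| focal tissue | a        | b              |
| all others   | c        | d              |

and evaluate the Fisher exact test from the hypergeometric distribution
with the statistic \(X = a\): with \(N = a+b+c+d\), \(K = a+c\) and
\(n = a+b\),
\[
P(X = k) = \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}},
\]
computed in log space from log-binomial coefficients.  `p_left`
(\(P(X \le a)\)) is small when the tissue is enriched for MRE-containing
isoforms; `p_right` (\(P(X \ge a)\)) when MRE-free isoforms dominate; the
two-tailed P sums all outcomes whose point probability does not exceed
the observed one (minimum-likelihood rule, with a \(1+10^{-7}\) relative
tolerance against floating-point ties).  Degenerate margins return 1 on
all tails.

A site is called **splicing-regulated** when any *tested* tissue reaches
`p_twotail < alpha` (default 0.05); the contributing direction (left or
right tail) is reported alongside.  Testing is gated on informative
evidence: a gene needs at least `min_gene_ests = 10` informative ESTs
(configurations II+III+IV) in total, a tissue at least
`min_tissue_ests = 10`.  The thresholds deliberately count informative
ESTs only — excluded configurations carry no isoform information — which
is the stricter reading of an "at least ten ESTs" rule.  No
multiple-testing correction is applied across tissues or sites; the
per-tissue level is the interface and the family-wise behaviour is
characterized empirically (below).

Catalog rows sharing one interval (the same element targeted by several
microRNAs) collapse to a single unique site before fractions of
regulated sites are computed.

## MRE regions and repressiveness

Reported sites for a heavily targeted gene pile up on nearly identical
intervals.  Sites with pairwise overlap of at least 90% are grouped into
an *MRE region*.  Two choices here were genuinely open and are fixed as
package conventions:

* the overlap fraction is \(|a \cap b| / \min(|a|, |b|)\) — with the
  shorter-site denominator a short site contained in a longer one counts
  as complete overlap, which is what lets many co-located microRNA sites
  form one region;
* grouping is single-linkage transitive closure, the simplest relation
  under which "grouped into a single region" is well defined; it is
  idempotent and input-order invariant (both property-tested).

A region's repression range is the min–max of its members' repressive
ratios (percent reduction of protein output, 0–100); the region is
**highly repressive** when the maximum reaches 30%, inclusive — the
inclusive boundary matters because reported regions with a single ratio
of exactly 30 are conventionally counted as highly repressive.

Site placement uses perfect full-length matching only (every exact
occurrence reported; `N` never matches on either side), and candidate
sites can be screened by the canonical seed: the 7-mer reverse
complement of microRNA nucleotides 2–8 (7mer-m8 style; A1/8mer variants
are out of scope).

## Random background and the signed-rank test

To judge whether observed regulated fractions exceed background, random
catalogs are drawn on the same references: for each site the source
sequence, start and length (uniform 18–22 nt, the size range of typical
MREs) are randomized, in sets of 100 sites.  Because random sites are
coordinates on the real references, they flow through the identical
enrichment machinery.  Per-set regulated fractions are compared to the
observed fraction with a one-sample Wilcoxon signed-rank test
(two-sided; the observed fraction is the hypothesized location).  Zero
differences are dropped and ties receive average ranks.  With \(n \le
25\) nonzero differences the P value is exact — the full null
distribution of the positive-rank sum is obtained by generating-function
convolution over the (doubled) ranks, which enumerates all \(2^n\) sign
assignments implicitly; beyond 25 a tie-corrected normal approximation
with continuity correction takes over.  The cutoff is where exhaustive
enumeration stops being the sensible default and the approximation is
already excellent.

## Protein-level repression curves

SILAC-style tables give each protein a log2 fold change after microRNA
transfection, plus three nested membership flags: transcript carries a
seed match; seed match supported by target prediction; predicted target
additionally associated with alternative splicing.  Violations of the
nesting are rejected as data errors.  Fold changes are drawn as
cumulative curves over the *percent change in expression ratio*,
\((2^{\mathrm{lfc}} - 1)\times 100\) — the standard reading of SILAC
ratios; repression is negative by this convention, and a value of 0 is
neither repressed nor activated.  Each nested set is tested against the
seed-free proteins with the two-sample Kolmogorov–Smirnov test: D is the
exact supremum ECDF difference over pooled points, and P comes from the
asymptotic Kolmogorov series with the
\(\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D\) small-sample
correction.  The exact small-sample KS distribution is not implemented;
the statistic itself is oracle-tested, and the series P is reliable at
the sample sizes these analyses involve (hundreds of proteins).
Medians are reported per set so the direction of a shift is explicit.

## The synthetic-data generator

`simulate_est_dataset()` emulates the isoform structure that the method
exploits: each gene is a 3000-nt reference with a 200-nt cassette exon
carrying a 22-nt MRE; every EST picks an isoform (exon retained with the
tissue's inclusion probability) and a footprint window, uniform in
length between 300 and 800 nt — typical single-pass read lengths — and
uniform in position.  A retained exon yields configuration II when the
window spans the MRE; a skipped exon yields III; windows that miss the
MRE yield configuration I naturally.  The default tissue panel is five
tissues (mixed normal/cancer histology), two libraries of 25 ESTs each,
inclusion probability 0.5.  Splicing regulation is planted by giving a
gene different inclusion probabilities across tissues; ground truth
records exactly the planted sites.  `simulate_protein_table()` plants
repression shifts: background log2 fold changes are Normal(0, 0.3²),
seed-carrying proteins are shifted by −0.5, splicing-regulated ones by a
further −0.5, with set sizes (600, 200, 120, 60).

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: 3′-bias of EST coverage, library-size
imbalance between tissues, sequencing error and chimerism, multiple
cassette exons or mutually exclusive isoform structures, correlated
sites within a gene, and the non-normal inter-set correlation structure
of real random-MRE fractions.

## Validation design and problem sizes

The test suite checks the statistics against independent oracles:
exhaustive hypergeometric enumeration for every 2×2 table with
\(N \le 40\); literal \(2^n\) sign enumeration for the signed-rank test
at \(n \le 12\); brute-force ECDF scans for KS D at \(n \le 12\); and a
per-base reclassification oracle over 1,000 randomized (blocks, MRE)
instances.  Empirical error control uses 500 null simulations (four
tissues, 15 informative ESTs each — 2,000 tissue tables) for the type-I
rate at α = 0.05, and 200 replicates of the planted design (inclusion
0.9 vs 0.1, 30 informative ESTs per side) for power; these sizes give
Monte-Carlo standard errors small enough to bound the rates while
keeping the default test run fast.  For the EST-count checks the
simulator uses footprints equal to the isoform length minus the cassette
exon, so every EST is informative and the per-tissue counts are exact by
design.

## A worked example

```{r example}
cf <- sim_config(
  n_genes = 2,
  inclusion_prob = matrix(c(0.9, 0.1, 0.1, 0.5, 0.5, 0.5), nrow = 2,
                          byrow = TRUE,
                          dimnames = list(NULL, c("embryo", "brain", "liver"))),
  tissues = data.frame(name = c("embryo", "brain", "liver"),
                       histology = "normal", n_libraries = 2L,
                       n_ests = 40L),
  gene_length = 3000L, est_window = c(2800L, 2800L), seed = 1)
sim <- simulate_est_dataset(cf)
fit <- enrich_mre(sim$ests[sim$ests$reference_id == "gene1", ],
                  sim$mre[1, ], sim$libraries)
fit
summary(fit)
```

## Known limitations

* Strand is ignored: inputs must already be oriented to the mRNA sense
  strand, as in UniGene-style clusters.
* Exact matching places sites; polymorphic or edited sites that differ
  from the reference by even one base will not be placed.
* Histology stratification is binary (normal/cancer); finer annotations
  collapse onto it.
* The per-tissue Fisher tests share ESTs through the "all other
  tissues" margin and are not independent; the family-wise false-call
  rate over tissues is characterized by simulation, not by correction.
* EST counts confound expression level with isoform choice when
  libraries are very unevenly sampled across tissues.
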