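# splicemre

Detects **splicing-regulated microRNA recognition elements (MREs)** from
EST evidence.

A microRNA recognition element is a short site on an mRNA through which a
microRNA represses protein output.  When the site sits in or near a
cassette exon, alternative splicing yields two isoform classes: transcripts
that contain the MRE and stay under microRNA control, and MRE-free
transcripts that escape it.  `splicemre` asks, tissue by tissue, whether
the balance between those classes shifts — i.e. whether splicing acts as a
tissue-specific fine-tuning layer on microRNA regulation.  It is aimed at
transcriptomics researchers with reference transcripts (FASTA), spliced
EST/read alignments (BED12), tissue-annotated library tables, and MRE
catalogs with reported repressive ratios.

## What it computes

For an MRE on a reference transcript, each spliced EST alignment takes one
of five configurations: does not span the full site (uninformative); site
inside an exon block (MRE-containing isoform); site inside an inter-block
gap (MRE-free); site split at a junction (counted MRE-free); or anomalous.
Per tissue, the informative counts form the table

|              | MRE-free | MRE-containing |
|--------------|----------|----------------|
| focal tissue | a        | b              |
| all others   | c        | d              |

tested with the Fisher exact test computed from the hypergeometric
distribution (statistic X = a; N = a+b+c+d, K = a+c, n = a+b):

    P(X = k) = C(K, k) C(N−K, n−k) / C(N, n)

`p_left = P(X ≤ a)` flags tissues enriched for MRE-containing isoforms,
`p_right = P(X ≥ a)` for MRE-free isoforms; the two-tailed P uses the
minimum-likelihood rule.  A site is *splicing-regulated* when any tissue
with ≥ 10 informative ESTs reaches `p_twotail < 0.05` (genes need ≥ 10
informative ESTs overall).  Around this core the package merges sites with
≥ 90% overlap into MRE regions and flags regions whose repressive ratio
reaches 30% as highly repressive; compares observed regulated fractions
against randomized 18–22-nt site catalogs with an exact one-sample
Wilcoxon signed-rank test; and quantifies protein-level repression with
cumulative curves of percent expression change, (2^lfc − 1)·100, and
two-sample Kolmogorov–Smirnov tests between nested target sets.  A seeded
synthetic-data generator produces EST libraries and protein tables with
known ground truth.

## Worked example

A reference gene carries an MRE at positions 201–220.  Brain contributes 7
MRE-containing and 3 MRE-free informative ESTs; the other tissues 1 and 6;
two liver ESTs do not span the whole site and are excluded.

```r
library(splicemre)
blocks_cont <- cbind(start = 150L, end = 300L)           # site in exon
blocks_free <- cbind(start = c(100L, 220L), end = c(200L, 300L))  # skipped
blocks <- c(rep(list(blocks_cont), 7), rep(list(blocks_free), 3),
            list(blocks_cont), rep(list(blocks_free), 6),
            list(cbind(start = 300L, end = 400L)),       # no overlap
            list(cbind(start = 100L, end = 210L)))       # partial overlap
libs <- c(rep("libBrain", 10), rep("libColon", 4), rep("libLung", 3),
          rep("libLiver", 2))
ests <- est_set(sprintf("est%02d", seq_along(blocks)),
                rep("g1", length(blocks)), libs, blocks)
libraries <- library_table(
  c("libBrain", "libColon", "libLung", "libLiver"),
  c("brain", "colon", "lung", "liver"), rep("normal", 4))
fit <- enrich_mre(ests, c(200L, 220L), libraries)
summary(fit)
```

```
Tissue-specific splicing enrichment
  informative ESTs: 17 (excluded: 2)
  splicing-regulated: yes (alpha = 0.05, two-tailed)
  significant tissues:
    brain [pooled] (left tail: MRE-containing isoforms enriched)

Per-tissue Fisher exact tests (tested tissues):
 tissue stratum a b c d p_left p_right p_twotail
  brain  pooled 3 7 6 1 0.0364  0.9981   0.04977
```

Brain shows 3 MRE-free of 10 informative ESTs against 6 of 7 elsewhere;
the left tail (P = 0.0364 = 708/19448) says brain is enriched for
MRE-containing isoforms, so brain transcripts remain preferentially
exposed to the microRNA.

Merging a reported VEGF site catalog (bundled, with repressive ratios and
supported tissues) into regions:

```r
vegf <- read_mre_table(system.file("extdata", "vegf_mre_catalog.tsv",
                                   package = "splicemre"))
pipeline_report(merge_regions(vegf))
```

```
MRE region report
  regions: 13;  highly repressive: 9
  supported (any/cancer/normal): 5 / 4 / 2;  supported & highly repressive: 5
```

Thirteen MRE regions, nine highly repressive (max ratio ≥ 30%); all five
regions with tissue support from the enrichment test are highly
repressive.

A command-line wrapper over the same functions is installed at
`system.file("exec", "splicemre", package = "splicemre")` with
subcommands `simulate`, `classify`, `enrich`, `regions`, `nulltest`,
`silac` and `report`.

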