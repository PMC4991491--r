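# xenocomp

Compartment-resolved transcriptomics of patient-derived xenografts
(PDX). A PDX sample contains two transcriptomes — the human tumor and
the mouse stroma recruited by the host — and bulk RNA-seq can separate
them *in silico*: every read pair is aligned against a concatenated
human+mouse reference and kept only if it maps uniquely to one species.
`xenocomp` implements that disambiguation contract and the analyses it
enables, for computational biologists who want to study tumor and
stroma simultaneously from a single sequencing run:

* **Disambiguation & quantification** — seed-and-extend ungapped
  alignment over a two-species k-mer index with the unique-mapping
  filters (≤ 3 mismatches per mate, mismatch/length ratio ≤ 0.10, ties
  discarded as ambiguous); union-mode fragment counting; FPKM on
  exon-union gene length with protein-coding and 400-bp transcript
  filters.
* **Stromal subtyping** — consensus non-negative matrix factorization
  (multiplicative Kullback–Leibler updates, `V ≈ WH`, `W, H ≥ 0`) with
  rank selection by the difference of cophenetic coefficients between
  the actual and a row-permuted matrix, meta-gene driver extraction
  (relative contribution `W[g,f] / Σ_f' W[g,f']`), and chi-squared
  cluster–metadata association.
* **Tumor–stroma crosstalk** — all-against-all Pearson correlation
  between human and mouse profiles on the `log2(FPKM + 1.1)` scale,
  networks thresholded at `|r| > 0.85`, cross-species hub ranking, and
  partner rankings with exact t-based p-values
  (`t = r√(n−2)/√(1−r²)`).
* **Compartment-specific markers** — a calibrated negative-binomial
  Wald differential-expression contract (median-of-ratios
  normalization, moderated moment dispersion), Benjamini–Hochberg FDR,
  hypergeometric signature-overlap tests `P(X ≥ k)`, and triangulation
  of markers significant in tumor-pure platforms but masked by stroma
  in mixed clinical samples.
* **Per-sample classifiers** — host gender from the Y index
  (`1000 · Y-gene counts / all mouse counts`, male if > 10), CAF-marker
  patient-stroma flags (FAP/CSPG4 log2 FPKM > 2 / > 4), and MIF/Ddx6
  hypoxia grouping.
* **Synthetic data with ground truth** — toy two-species genomes with
  controllable ortholog divergence, read mixtures with known species
  labels, and count matrices with planted clusters, cross-species
  couplings, DE genes and host gender, so every stage's recovery is
  measurable.

## Worked example

Simulate a read mixture at 88% human, disambiguate it, and recover the
species proportion:

```r
library(xenocomp)

gen <- make_toy_genomes(n_ortholog_genes = 30, n_private_per_species = 20,
                        divergence = 0.15, seed = 42)
rd  <- simulate_reads(gen, human_proportion = 0.88, n_read_pairs = 20000,
                      error_rate = 0.005, seed = 7)
idx <- build_species_index(gen$fasta, k = 21)
asg <- assign_read_pairs(rd$mate1, rd$mate2, idx)

table(asg$call)
#>    HUMAN    MOUSE UNMAPPED
#>    17517     2419       64
sum(asg$call == "HUMAN") / sum(asg$call %in% c("HUMAN", "MOUSE"))
#> [1] 0.8786617
```

All 17,517 + 2,419 species calls are correct against the simulation
truth (precision 1.0 for both species); the recovered human proportion
0.879 sits within 0.002 of the planted 0.88 (the 64 unmapped pairs are
those with more than three sequencing errors on one mate). A
correlation p-value the same way:

```r
pearson_pvalue(0.37, 79)
#> [1] 0.0007903179
```

The numbered scripts under `analysis/` run the full workflow on
synthetic data — simulation, disambiguation, quantification,
preparation and classifiers, consensus-NMF subtyping, cross-species
networks, and marker analyses — writing tables under `results/`. The
methods vignette (`vignettes/xenocomp-methods.Rmd`) documents the
models, parameter choices, and a known limitation of the
cophenetic-difference rank-selection rule on cleanly clustered
synthetic data.

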