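#!/usr/bin/env Rscript
# Union-mode fragment counting over the toy annotation and filtered FPKM
# for the disambiguated sample, plus the recovered species proportion.

suppressPackageStartupMessages(library(xenocomp))

models <- local({
  cs <- read_species_table("results/simdata/species.tsv")
  gtf <- "results/simdata/toy.gtf"
  hs <- read_gtf(gtf, "HUMAN")
  # the combined GTF holds both species; split by chromosome species
  hs$genes <- hs$genes[cs[hs$genes$chrom] == "HUMAN", ]
  hs$exons <- hs$exons[cs[hs$exons$chrom] == "HUMAN", ]
  mm <- read_gtf(gtf, "MOUSE")
  mm$genes <- mm$genes[cs[mm$genes$chrom] == "MOUSE", ]
  mm$exons <- mm$exons[cs[mm$exons$chrom] == "MOUSE", ]
  combine_gene_models(hs, mm)
})

asg <- read.delim("results/assignments.tsv")
cm <- count_union(asg, models, "pooled_sample")
fp <- compute_fpkm(cm, models, min_transcript_bp = 400, coding_only = TRUE)
write_matrix_tsv(cm$counts, "results/union_counts.tsv")
write_matrix_tsv(fp$values, "results/fpkm.tsv")

cat("Counted", sum(cm$counts), "fragments over", nrow(cm$counts),
    "genes; human proportion of assigned fragments:",
    round(species_proportion(cm, "pooled_sample"), 4), "\n")
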