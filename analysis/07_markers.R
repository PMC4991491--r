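#!/usr/bin/env Rscript
# Subtype differential expression on the simulated cohort, signature
# overlap testing against generated GMT signatures, and the multi-
# platform triangulation of tumor-pure "masked" markers.

suppressPackageStartupMessages(library(xenocomp))
seed <- 20260924

counts <- read_matrix_tsv("results/simdata/counts.tsv")
gene_info <- read.delim("results/simdata/gene_info.tsv")
metadata <- read.delim("results/simdata/metadata.tsv")
truth <- jsonlite::read_json("results/simdata/count_truth.json",
                             simplifyVector = TRUE)

## subtype DE on the human compartment
hum <- gene_info$gene_id[gene_info$species == "HUMAN"]
de <- de_test(counts[hum, ], metadata$subtype)
write.table(de, "results/de_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig_up <- de$gene_id[!is.na(de$fdr) & de$fdr < 0.05 & de$log2_fc > 1.5]
planted <- names(truth$de_genes)
cat(length(sig_up), "genes called over-expressed;",
    sum(sig_up %in% planted), "of", length(planted), "planted DE genes\n")

## hypergeometric overlap against generated signatures
tr <- list(de_genes = unlist(truth$de_genes))
sigs <- make_signatures(tr, gene_info, n_in_signature = 20, n_decoys = 50,
                        seed = seed + 20)
write_gmt(sigs, "results/signatures.gmt")
ov <- lapply(sigs, function(s) {
  r <- hypergeom_overlap(sig_up, s, hum)
  data.frame(k = r$k_overlap, K = r$K_signature, n = r$n_list,
             N = r$N_universe, p_upper = r$p_upper)
})
ovdf <- cbind(signature = names(ov), do.call(rbind, ov))
write.table(ovdf, "results/signature_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(ovdf, row.names = FALSE)

## multi-platform triangulation of masked tumor-pure markers
markers <- 1:30; stromal_too <- 21:30
pdx <- simulate_de_counts(c(6, 6), 600, de_idx = markers, lfc = 3,
                          mu = 150, seed = seed + 30)
cells <- simulate_de_counts(c(6, 6), 600, de_idx = markers, lfc = 3,
                            mu = 150, seed = seed + 31)
tcga <- simulate_de_counts(c(8, 8), 600, de_idx = stromal_too, lfc = 3,
                           mu = 150, seed = seed + 32)
ubcs <- simulate_de_counts(c(8, 8), 600, de_idx = stromal_too, lfc = 3,
                           mu = 150, seed = seed + 33)
tri <- triangulate_markers(
  list(platform_de_set("PDX", "tumor_pure", de_test(pdx$counts, pdx$group)),
       platform_de_set("CellLine", "tumor_pure",
                       de_test(cells$counts, cells$group),
                       sig_thresh = 0.01, sig_on = "p")),
  list(platform_de_set("TCGA", "mixed", de_test(tcga$counts, tcga$group)),
       platform_de_set("UBCS", "mixed", de_test(ubcs$counts, ubcs$group))))
writeLines(tri$masked_markers, "results/masked_markers.txt")
cat("Consensus tumor-pure markers:", length(tri$consensus_pure),
    "; masked in mixed platforms:", length(tri$masked_markers),
    "(planted tumor-only: 20)\n")
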