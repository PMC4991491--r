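#!/usr/bin/env Rscript
# Generates every synthetic input used by the downstream analyses:
# toy two-species genomes with 15%-diverged orthologs, a 20k read-pair
# mixture at 88% human, and a 79-sample count matrix carrying planted
# cluster, coupling, differential-expression and host-gender structure.

suppressPackageStartupMessages(library(xenocomp))
seed <- 20260924
dir.create("results/simdata", recursive = TRUE, showWarnings = FALSE)

gen <- make_toy_genomes(n_ortholog_genes = 30, n_private_per_species = 20,
                        gene_length_bp = 600, divergence = 0.15, seed = seed)
write_fasta(gen$fasta$HUMAN, "results/simdata/human.fa")
write_fasta(gen$fasta$MOUSE, "results/simdata/mouse.fa")
write_gtf(combine_gene_models(gen$models$HUMAN, gen$models$MOUSE),
          "results/simdata/toy.gtf")
write_species_table(gen$chrom_species, "results/simdata/species.tsv")

rd <- simulate_reads(gen, human_proportion = 0.88, n_read_pairs = 20000,
                     read_length = 100, error_rate = 0.005,
                     fragment_length = 300, seed = seed + 1)
write_fastq_pair(rd$mate1, rd$mate2,
                 "results/simdata/reads_1.fastq",
                 "results/simdata/reads_2.fastq")
write.table(rd$truth, "results/simdata/read_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sim <- simulate_counts(n_samples = 79, n_human_genes = 400,
                       n_mouse_genes = 400, planted_k = 3,
                       cluster_strength = 3, n_coupled_pairs = 3,
                       hub_partners = 8, n_de_genes = 30, seed = seed + 2)
write_matrix_tsv(sim$counts$counts, "results/simdata/counts.tsv")
write.table(sim$metadata, "results/simdata/metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$gene_info, "results/simdata/gene_info.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(planted_k = sim$truth$planted_k,
       cluster_of_sample = as.list(sim$truth$cluster_of_sample),
       coupled_pairs = sim$truth$coupled_pairs,
       hub = sim$truth$hub,
       de_genes = as.list(sim$truth$de_genes),
       gender_of_sample = as.list(sim$truth$gender_of_sample)),
  "results/simdata/count_truth.json", auto_unbox = TRUE, digits = NA)

cat("Simulated", length(rd$mate1), "read pairs (",
    round(100 * mean(rd$truth$species == "HUMAN"), 1), "% human ) and a",
    nrow(sim$counts$counts), "gene x", ncol(sim$counts$counts),
    "sample count matrix.\n")
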