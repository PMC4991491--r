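test_that("toy genomes respect divergence limits and determinism", {
  g0 <- make_toy_genomes(n_ortholog_genes = 5, n_private_per_species = 0,
                         gene_length_bp = 500, divergence = 0, seed = 3)
  # divergence 0: ortholog sequences identical
  for (i in 1:5) {
    hex <- g0$models$HUMAN$exons[i, ]
    mex <- g0$models$MOUSE$exons[i, ]
    hs <- substr(g0$fasta$HUMAN[[hex$chrom]], hex$start, hex$end)
    ms <- substr(g0$fasta$MOUSE[[mex$chrom]], mex$start, mex$end)
    expect_identical(hs, ms)
  }
  # equal gene counts with no private genes
  expect_equal(nrow(g0$models$HUMAN$genes), nrow(g0$models$MOUSE$genes))

  expect_error(make_toy_genomes(divergence = 0.7), "divergence")
  expect_error(make_toy_genomes(gene_length_bp = 300), "400")

  g1 <- make_toy_genomes(seed = 11)
  g2 <- make_toy_genomes(seed = 11)
  expect_identical(g1$fasta, g2$fasta)
})

test_that("ortholog Hamming distance concentrates around the divergence rate", {
  gen <- make_toy_genomes(n_ortholog_genes = 10, n_private_per_species = 0,
                          gene_length_bp = 1000, divergence = 0.15, seed = 5)
  for (i in 1:10) {
    hex <- gen$models$HUMAN$exons[i, ]
    mex <- gen$models$MOUSE$exons[i, ]
    hs <- strsplit(substr(gen$fasta$HUMAN[[hex$chrom]], hex$start, hex$end), "")[[1]]
    ms <- strsplit(substr(gen$fasta$MOUSE[[mex$chrom]], mex$start, mex$end), "")[[1]]
    d <- mean(hs != ms)
    # binomial concentration: 0.15 +/- > 3 sd at n = 1000
    expect_gt(d, 0.12)
    expect_lt(d, 0.18)
  }
})

test_that("read simulation honours species proportion, errors and determinism", {
  gen <- make_toy_genomes(n_ortholog_genes = 5, n_private_per_species = 5,
                          seed = 2)
  rd <- simulate_reads(gen, human_proportion = 1.0, n_read_pairs = 200,
                       seed = 4)
  expect_true(all(rd$truth$species == "HUMAN"))

  rd88 <- simulate_reads(gen, human_proportion = 0.88, n_read_pairs = 20000,
                         seed = 4)
  frac <- mean(rd88$truth$species == "HUMAN")
  sd3 <- 3 * sqrt(0.88 * 0.12 / 20000)
  expect_lt(abs(frac - 0.88), sd3)

  # error_rate 0: reads are exact substrings of gene bodies (up to revcomp)
  rd0 <- simulate_reads(gen, n_read_pairs = 50, error_rate = 0, seed = 6)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (i in 1:10) {
    sp <- rd0$truth$species[i]
    ex <- gen$models[[sp]]$exons
    ex <- ex[ex$gene_id == rd0$truth$gene_id[i], ]
    body <- substr(gen$fasta[[sp]][[ex$chrom]], ex$start, ex$end)
    r1 <- rd0$mate1[[i]]
    expect_true(grepl(r1, body, fixed = TRUE) ||
                  grepl(revcomp(r1), body, fixed = TRUE))
  }

  rda <- simulate_reads(gen, n_read_pairs = 100, seed = 9)
  rdb <- simulate_reads(gen, n_read_pairs = 100, seed = 9)
  expect_identical(rda, rdb)
  expect_error(simulate_reads(gen, n_read_pairs = 0), "positive")
})

test_that("simulated counts carry the planted structure and are deterministic", {
  sim <- simulate_counts(n_samples = 20, n_human_genes = 60, n_mouse_genes = 40,
                         planted_k = 3, n_coupled_pairs = 2, n_de_genes = 5,
                         seed = 8)
  expect_s3_class(sim$counts, "CountMatrix")
  expect_equal(dim(sim$counts$counts), c(100, 20))
  expect_equal(length(sim$truth$cluster_of_sample), 20)
  expect_equal(sort(unique(unname(sim$truth$cluster_of_sample))), 1:3)
  expect_equal(nrow(sim$truth$coupled_pairs), 2)
  expect_length(sim$truth$de_genes, 5)

  sim2 <- simulate_counts(n_samples = 20, n_human_genes = 60,
                          n_mouse_genes = 40, planted_k = 3,
                          n_coupled_pairs = 2, n_de_genes = 5, seed = 8)
  expect_identical(sim$counts$counts, sim2$counts$counts)

  expect_error(simulate_counts(n_samples = 3, planted_k = 2), "n_samples")
  expect_error(simulate_counts(planted_k = 1), "planted_k")
})

test_that("all-female simulation leaves Y genes near silent", {
  sim <- simulate_counts(n_samples = 12, n_human_genes = 30, n_mouse_genes = 40,
                         planted_k = 2, n_coupled_pairs = 0, n_de_genes = 0,
                         gender_ratio = 0, seed = 13)
   y <- colSums(sim$counts$counts[c("Eif2s3y", "Ddx3y", "Kdm5d", "Uty"), ])
  lib <- sim$counts$library_size["MOUSE", ]
  expect_true(all(y / lib < 0.001))
})

test_that("planted anti-correlated pair shows up in the log expression", {
  sim <- simulate_counts(n_samples = 79, n_human_genes = 60, n_mouse_genes = 60,
                         planted_k = 2, cluster_strength = 0,
                         n_coupled_pairs = 1, n_de_genes = 0,
                         nb_dispersion = 0.05, seed = 21)
  pair <- sim$truth$coupled_pairs[1, ]
  expect_equal(pair$sign, -1)
  lv <- log2(sim$counts$counts + 1.1)
  r <- cor(lv[pair$human_gene, ], lv[pair$mouse_gene, ])
  expect_lt(r, -0.85)
})

test_that("coupled mean structure matches the planted model at scale", {
  # marginal count means track the planted mean matrix within MC error
  sim <- simulate_counts(n_samples = 60, n_human_genes = 50, n_mouse_genes = 30,
                         planted_k = 2, cluster_strength = 0,
                         n_coupled_pairs = 0, n_de_genes = 10, de_log2fc = 2,
                         nb_dispersion = 0.05, seed = 33)
  de <- names(sim$truth$de_genes)
  grpB <- sim$metadata$subtype == "B"
  obs_fc <- log2(rowMeans(sim$counts$counts[de, grpB]) /
                   rowMeans(sim$counts$counts[de, !grpB]))
  expect_true(all(abs(obs_fc - 2) < 0.6))
})

test_that("signatures are enriched or decoy as requested", {
  sim <- simulate_counts(n_samples = 12, n_human_genes = 100, n_mouse_genes = 30,
                         planted_k = 2, n_coupled_pairs = 0, n_de_genes = 50,
                         seed = 3)
  sigs <- make_signatures(sim$truth, sim$gene_info, n_in_signature = 20,
                          n_decoys = 30, seed = 7)
  de <- names(sim$truth$de_genes)
  expect_length(intersect(sigs$DE_ENRICHED, de), 20)
  expect_length(intersect(sigs$DECOY, de), 0)

  # fixed seed -> identical GMT bytes
  p1 <- tempfile(); p2 <- tempfile()
  write_gmt(sigs, p1)
  write_gmt(make_signatures(sim$truth, sim$gene_info, 20, 30, seed = 7), p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_error(make_signatures(sim$truth, sim$gene_info,
                               n_in_signature = 100), "exceeds")
})
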