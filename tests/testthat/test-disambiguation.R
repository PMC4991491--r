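# Tiny deterministic reference for exact-case tests: two private genes
# plus an identical segment shared across species.
make_tiny_index <- function(k = 15) {
  set.seed(99)
  hgene <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  mgene <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  shared <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  fa <- list(HUMAN = c(hs_1 = paste0(hgene, shared)),
             MOUSE = c(mm_1 = paste0(mgene, shared)))
  list(index = build_species_index(fa, k = k), fa = fa,
       hgene = hgene, mgene = mgene, shared = shared)
}

revcomp1 <- function(s) chartr("ACGT", "TGCA",
                               paste(rev(strsplit(s, "")[[1]]), collapse = ""))

pair_from <- function(seq, start, rl = 60, fl = 150) {
  frag <- substr(seq, start, start + fl - 1)
  list(mate1 = substr(frag, 1, rl),
       mate2 = revcomp1(substr(frag, fl - rl + 1, fl)))
}

test_that("index construction validates input and counts positions", {
  fa <- list(HUMAN = c(hs_1 = strrep("ACGT", 250)),
             MOUSE = c(mm_1 = strrep("TTGCA", 200)))
  idx <- build_species_index(fa, k = 15)
  st <- xenocomp:::.index_stats_cpp(idx$ptr)
  # forward-strand positions only: <= 2 * (1000 - 14)
  expect_lte(st$n_positions, 2 * (1000 - 14))
  expect_error(build_species_index(list(HUMAN = c(c1 = "ACGT"),
                                        MOUSE = c(c1 = "ACGT")), k = 11),
               "duplicate chromosome")
  expect_error(build_species_index(list(HUMAN = c(c1 = ""),
                                        MOUSE = c(c2 = "ACGT")), k = 11),
               "empty")
})

test_that("exact pairs map to their species with zero mismatches", {
  tiny <- make_tiny_index()
  p <- pair_from(tiny$hgene, 10)
  res <- assign_read_pair(p, tiny$index)
  expect_equal(res$call, "HUMAN")
  expect_equal(res$mm1 + res$mm2, 0)
  expect_equal(res$chrom, "hs_1")

  pm <- pair_from(tiny$mgene, 25)
  expect_equal(assign_read_pair(pm, tiny$index)$call, "MOUSE")
})

test_that("pairs from a shared identical segment are ambiguous", {
  tiny <- make_tiny_index()
  p <- pair_from(tiny$shared, 10)
  expect_equal(assign_read_pair(p, tiny$index)$call, "AMBIGUOUS")
})

test_that("mismatch caps follow the per-mate and ratio rules", {
  tiny <- make_tiny_index()
  p <- pair_from(tiny$hgene, 10)
  mutate_at <- function(s, pos) {
    for (i in pos) {
      old <- substr(s, i, i)
      new <- setdiff(c("A", "C", "G", "T"), old)[1]
      substr(s, i, i) <- new
    }
    s
  }
  # 3 mismatches on one mate: still called
  p3 <- p; p3$mate1 <- mutate_at(p$mate1, c(25, 30, 35))
  r3 <- assign_read_pair(p3, tiny$index)
  expect_equal(r3$call, "HUMAN")
  expect_equal(r3$mm1, 3)
  # 4 mismatches confined to one mate: unmapped
  p4 <- p; p4$mate1 <- mutate_at(p$mate1, c(25, 30, 35, 40))
  expect_equal(assign_read_pair(p4, tiny$index)$call, "UNMAPPED")
  # ratio rule: 3+3 over shorter mates exceeds 0.10 when 6/total > 0.10
  pshort <- list(mate1 = substr(p$mate1, 1, 25), mate2 = substr(p$mate2, 1, 25))
  pshort$mate1 <- mutate_at(pshort$mate1, c(5, 10, 17))
  pshort$mate2 <- mutate_at(pshort$mate2, c(5, 10, 17))
  # 6 mismatches / 50 bp = 0.12 > 0.10 -> invalid even though <= 3 per mate
  expect_equal(assign_read_pair(pshort, tiny$index)$call, "UNMAPPED")
})

test_that("a mate shorter than k warns and reports UNMAPPED", {
  tiny <- make_tiny_index()
  p <- pair_from(tiny$hgene, 10)
  p$mate2 <- substr(p$mate2, 1, 10)
  expect_warning(res <- assign_read_pair(p, tiny$index), "shorter than k")
  expect_equal(res$call, "UNMAPPED")
})

test_that("species calls partition the input and ignore read order", {
  gen <- make_toy_genomes(n_ortholog_genes = 6, n_private_per_species = 6,
                          seed = 31)
  rd <- simulate_reads(gen, n_read_pairs = 300, seed = 5)
  idx <- build_species_index(gen$fasta)
  asg <- assign_read_pairs(rd$mate1, rd$mate2, idx)
  expect_setequal(unique(asg$call),
                  intersect(c("HUMAN", "MOUSE", "AMBIGUOUS", "UNMAPPED"),
                            unique(asg$call)))
  expect_equal(nrow(asg), 300)
  # order invariance
  perm <- sample(300)
  asg2 <- assign_read_pairs(rd$mate1[perm], rd$mate2[perm], idx)
  expect_equal(asg2[order(match(asg2$read_id, asg$read_id)), ],
               asg, ignore_attr = TRUE)
})

test_that("union-mode counting follows the single-gene rule", {
  exons <- data.frame(chrom = c("hs_1", "hs_1", "hs_1"),
                      start = c(101, 301, 390), end = c(200, 400, 520),
                      strand = "+", gene_id = c("gA", "gB", "gC"),
                      transcript_id = c("tA", "tB", "tC"))
  gm <- gene_models_from_exons(exons, "HUMAN")
  asg <- data.frame(
    read_id = c("r1", "r2", "r3"),
    call = c("HUMAN", "HUMAN", "HUMAN"),
    chrom = "hs_1",
    start = c(110, 395, 230), end = c(190, 410, 280),
    mm1 = 0, mm2 = 0,
    start1 = c(110, 395, 230), end1 = c(150, 405, 250),
    start2 = c(160, 398, 260), end2 = c(190, 410, 280),
    stringsAsFactors = FALSE)
  cm <- count_union(asg, gm, "s1")
  # r1 inside gA only; r2 overlaps gB and gC -> dropped; r3 intergenic
  expect_equal(cm$counts["gA", 1], 1L)
  expect_equal(cm$counts["gB", 1], 0L)
  expect_equal(cm$counts["gC", 1], 0L)
  # library size counts assigned fragments regardless of feature overlap
  expect_equal(cm$library_size["HUMAN", 1], 3)

  asg_bad <- asg; asg_bad$chrom <- "nope"
  expect_error(count_union(asg_bad, gm, "s1"), "unknown chromosome")
})

test_that("FPKM formula, filters and column identity hold", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      species = "HUMAN",
                      biotype = c("protein_coding", "protein_coding", "lincRNA"),
                      exon_union_length = c(2000L, 500L, 1000L),
                      largest_transcript_length = c(2000L, 399L, 1000L))
  counts <- matrix(c(100L, 10L, 50L), 3, 1,
                   dimnames = list(genes$gene_id, "s1"))
  cm <- new_cm <- structure(
    list(counts = counts,
         gene_species = setNames(genes$species, genes$gene_id),
         library_size = matrix(1e6, 1, 1, dimnames = list("HUMAN", "s1"))),
    class = "CountMatrix")
  fp <- compute_fpkm(cm, genes)
  # 100 fragments, 2 kb gene, 1e6 library -> FPKM 50
  expect_equal(unname(fp$values["g1", 1]), 50)
  # g2 fails the 400 bp rule, g3 the biotype rule
  expect_false("g2" %in% rownames(fp$values))
  expect_false("g3" %in% rownames(fp$values))
  # zero counts give FPKM 0
  counts["g1", 1] <- 0L
  cm$counts <- counts
  expect_equal(unname(compute_fpkm(cm, genes)$values["g1", 1]), 0)

  # column identity: sum FPKM * len / 1e9 * lib = counted fragments
  sim <- simulate_counts(n_samples = 6, n_human_genes = 40, n_mouse_genes = 30,
                         planted_k = 2, n_coupled_pairs = 0, n_de_genes = 0,
                         seed = 12)
  fp2 <- compute_fpkm(sim$counts, sim$gene_info)
  sp <- fp2$gene_species[rownames(fp2$values)]
  for (s in 1:2) {
    for (spec in c("HUMAN", "MOUSE")) {
      lhs <- sum(fp2$values[sp == spec, s] * 1000 / 1e9 *
                   sim$counts$library_size[spec, s])
      rhs <- sum(sim$counts$counts[
        sim$counts$gene_species[rownames(sim$counts$counts)] == spec, s])
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("species proportion comes from assigned fragment totals", {
  lib <- matrix(c(500, 500, 900, 100, 0, 300), 2, 3,
                dimnames = list(c("HUMAN", "MOUSE"), c("a", "b", "c")))
  cm <- structure(list(counts = matrix(0, 1, 3,
                                       dimnames = list("g", c("a", "b", "c"))),
                       gene_species = c(g = "HUMAN"), library_size = lib),
                  class = "CountMatrix")
  expect_equal(species_proportion(cm, "a"), 0.5)
  expect_equal(species_proportion(cm, "b"), 0.9)
  expect_equal(species_proportion(cm, "c"), 0.0)
  lib0 <- lib; lib0[, 1] <- 0
  cm$library_size <- lib0
  expect_error(species_proportion(cm, "a"), "no assigned")
})
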