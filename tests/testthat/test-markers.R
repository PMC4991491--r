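test_that("median-of-ratios size factors behave on constructed cases", {
  m <- matrix(rpois(50 * 4, 100) + 1L, 50, 4)
  expect_equal(size_factors(cbind(m[, 1], m[, 1], m[, 1])), rep(1, 3))
  doubled <- cbind(m[, 1], m[, 1] * 2L)
  sf <- size_factors(doubled)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  # invariant to gene order
  perm <- sample(50)
  expect_equal(size_factors(m[perm, ]), size_factors(m))
  mz <- m; mz[cbind(1:50, rep_len(1:4, 50))] <- 0L
  expect_error(size_factors(mz), "pseudo-reference")
})

test_that("BH FDR matches hand computation and preserves order", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.04, 0.001, 0.9, 0.02)
  f <- bh_fdr(p)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_fdr(p[perm]), f[perm])
  # monotone non-decreasing in p-rank
  expect_true(all(diff(f[order(p)]) >= 0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("hypergeometric overlap matches exhaustive enumeration (N <= 15)", {
  cases <- list(c(k = 3, K = 4, n = 5, N = 10),
                c(k = 0, K = 4, n = 5, N = 10),
                c(k = 2, K = 6, n = 4, N = 12),
                c(k = 5, K = 7, n = 8, N = 15),
                c(k = 1, K = 2, n = 3, N = 8))
  for (cs in cases) {
    expect_equal(hypergeom_upper(cs["k"], cs["K"], cs["n"], cs["N"]),
                 enumerate_hyper_upper(cs["k"], cs["K"], cs["n"], cs["N"]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # N=10, K=4, n=5, k=3 -> 66/252
  expect_equal(hypergeom_upper(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  # complement identity
  for (cs in cases) {
    expect_equal(hypergeom_upper(cs["k"], cs["K"], cs["n"], cs["N"]),
                 1 - phyper(cs["k"] - 1, cs["K"], cs["N"] - cs["K"], cs["n"]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # k = 0 always gives p = 1
  expect_equal(hypergeom_upper(0, 137, 1127, 15984), 1)
})

test_that("overlap test intersects the signature with the universe", {
  uni <- sprintf("g%03d", 1:100)
  lst <- uni[1:20]
  sig <- c(uni[10:24], "not_in_universe")
  res <- hypergeom_overlap(lst, sig, uni)
  expect_equal(res$K_signature, 15)   # foreign gene dropped
  expect_equal(res$k_overlap, 11)
  expect_equal(res$n_list, 20)
  expect_equal(res$N_universe, 100)
  expect_equal(res$p_upper,
               phyper(10, 15, 85, 20, lower.tail = FALSE))
  expect_error(hypergeom_overlap(c(lst, "zzz"), sig, uni), "subset")
  expect_error(hypergeom_overlap(lst, sig, character(0)), "empty")
})

test_that("DE gate, fold-change sign and status labels are correct", {
  sim <- simulate_de_counts(n_per_group = c(4, 4), n_genes = 200,
                            de_idx = 1:20, lfc = 2, mu = 200, seed = 5)
  fpkm <- matrix(10, 200, 8, dimnames = dimnames(sim$counts))
  fpkm[150:200, ] <- 0.5    # gated out
  res <- de_test(sim$counts, sim$group, fpkm = fpkm)
  expect_equal(unique(res$status[150:200]), "low_expression_skipped")
  expect_true(all(is.na(res$fdr[150:200])))
  # sign of log2FC equals sign of normalized mean difference
  sf <- size_factors(sim$counts)
  x <- sweep(sim$counts, 2, sf, `/`)
  d <- rowMeans(x[, sim$group == "g2"]) - rowMeans(x[, sim$group == "g1"])
  tested <- res$status == "tested"
  expect_true(all(sign(res$log2_fc[tested]) == sign(d[tested])))
  # planted genes have strong positive fold change
  expect_true(all(res$log2_fc[1:20] > 1))

  expect_error(de_test(sim$counts, rep("a", 8)), "two groups")
  expect_error(de_test(sim$counts, c("a", rep("b", 7))), ">= 2 samples")
  cnc <- sim$counts; cnc[1, 1] <- 0.5
  expect_error(de_test(cnc, sim$group), "integers")
})

test_that("null DE calibration and power meet their bands", {
  null <- simulate_de_counts(n_per_group = c(5, 5), n_genes = 2000,
                             de_idx = integer(0), mu = 100,
                             dispersion = 0.1, seed = 101)
  res0 <- de_test(null$counts, null$group)
  typeI <- mean(res0$p < 0.05)
  expect_gte(typeI, 0.035)
  expect_lte(typeI, 0.065)

  pow <- simulate_de_counts(n_per_group = c(5, 5), n_genes = 2000,
                            de_idx = 1:200, lfc = 2, mu = 100,
                            dispersion = 0.1, seed = 102)
  resp <- de_test(pow$counts, pow$group)
  hit <- abs(resp$log2_fc[1:200]) > 1.5 & resp$fdr[1:200] < 0.05
  expect_gte(mean(hit), 0.90)
})

test_that("stroma stratification applies strict cutoffs", {
  sc <- c(a = -800, b = -700, c = -600)
  expect_equal(stroma_stratify(names(sc), sc, -700, "<"), "a")
  expect_equal(stroma_stratify(names(sc), sc, -1000, ">"), names(sc))
  expect_warning(out <- stroma_stratify(names(sc), sc, -900, "<"),
                 "no samples")
  expect_length(out, 0)
  expect_error(stroma_stratify(c("a", "zz"), sc, 0, "<"), "zz")
})

test_that("marker triangulation follows the pure/mixed set algebra", {
  mk_records <- function(over, sig_any = character(0)) {
    uni <- sprintf("g%d", 1:10)
    data.frame(gene_id = uni, base_mean = 100,
               log2_fc = ifelse(uni %in% over, 2, 0),
               p = ifelse(uni %in% union(over, sig_any), 0.001, 0.5),
               fdr = ifelse(uni %in% union(over, sig_any), 0.01, 0.8),
               status = "tested", stringsAsFactors = FALSE)
  }
  pure1 <- platform_de_set("p1", "tumor_pure", mk_records(c("g1", "g2", "g3")))
  pure2 <- platform_de_set("p2", "tumor_pure", mk_records(c("g2", "g3", "g4")))
  mixed <- platform_de_set("m1", "mixed", mk_records(character(0), "g3"))
  tri <- triangulate_markers(list(pure1, pure2), list(mixed))
  expect_setequal(tri$consensus_pure, c("g2", "g3"))
  expect_setequal(tri$masked_markers, "g2")
  # masked subset of consensus subset of each pure set
  expect_true(all(tri$masked_markers %in% tri$consensus_pure))

  # empty mixed significance: masked equals consensus
  mixed0 <- platform_de_set("m0", "mixed", mk_records(character(0)))
  tri0 <- triangulate_markers(list(pure1, pure2), list(mixed0))
  expect_setequal(tri0$masked_markers, tri0$consensus_pure)

  bad <- platform_de_set("b", "mixed", mk_records(character(0))[1:5, ])
  expect_error(triangulate_markers(list(pure1), list(bad)), "universe")
})

test_that("triangulation recovers planted tumor-pure markers exactly", {
  # 30 planted tumor markers; 10 of them also carry signal in the mixed
  # platforms (stromal contribution) -> masked set = the other 20
  uni_n <- 600
  markers <- 1:30
  stromal <- 21:30
  pdx <- simulate_de_counts(c(6, 6), uni_n, de_idx = markers, lfc = 3,
                            mu = 150, seed = 11)
  cells <- simulate_de_counts(c(6, 6), uni_n, de_idx = markers, lfc = 3,
                              mu = 150, seed = 12)
  tcga <- simulate_de_counts(c(8, 8), uni_n, de_idx = stromal, lfc = 3,
                             mu = 150, seed = 13)
  ubcs <- simulate_de_counts(c(8, 8), uni_n, de_idx = stromal, lfc = 3,
                             mu = 150, seed = 14)
  sets <- list(
    platform_de_set("PDX", "tumor_pure", de_test(pdx$counts, pdx$group)),
    platform_de_set("CellLine", "tumor_pure",
                    de_test(cells$counts, cells$group),
                    sig_thresh = 0.01, sig_on = "p"))
  mixed <- list(
    platform_de_set("TCGA", "mixed", de_test(tcga$counts, tcga$group)),
    platform_de_set("UBCS", "mixed", de_test(ubcs$counts, ubcs$group)))
  tri <- triangulate_markers(sets, mixed)
  expect_setequal(tri$masked_markers, pdx$de_genes[1:20])
})
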