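test_that("exact low-rank matrices are recovered to tight tolerance", {
  set.seed(1)
  W0 <- matrix(runif(40 * 2), 40, 2)
  H0 <- matrix(runif(2 * 15), 2, 15)
  V <- W0 %*% H0
  fit <- nmf_factorize(V, 2, seed = 3, max_iter = 5000, tol = 1e-12)
  expect_lt(norm(V - fit$W %*% fit$H, "F"), 1e-3 * norm(V, "F"))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("the KL objective is monotone non-increasing per iteration", {
  set.seed(2)
  V <- matrix(rexp(30 * 8), 30, 8)
  fit <- nmf_factorize(V, 3, seed = 5, max_iter = 150, tol = 0,
                       trace_objective = TRUE)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * (abs(tr[-length(tr)]) + 1)))
  # rank-1 input factorized at k=2 is still monotone
  V1 <- outer(runif(20), runif(6))
  f1 <- nmf_factorize(V1, 2, seed = 5, max_iter = 100, tol = 0,
                      trace_objective = TRUE)
  expect_true(all(diff(f1$objective_trace) <= 1e-8))
})

test_that("factorization is deterministic under a seed and validates input", {
  set.seed(3)
  V <- matrix(rexp(50), 10, 5,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:5)))
  f1 <- nmf_factorize(V, 2, seed = 11)
  f2 <- nmf_factorize(V, 2, seed = 11)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)

  Vz <- V; Vz[3, ] <- 0
  expect_error(nmf_factorize(Vz, 2), "all-zero")
  expect_error(nmf_factorize(V, 1), "k must")
  expect_error(nmf_factorize(V, 5), "k must")
  expect_error(nmf_factorize(-V, 2), "non-negative")
})

test_that("consensus on duplicated sample blocks is exact", {
  set.seed(4)
  a <- rexp(30, 1 / 50); b <- rexp(30, 1 / 50)
  V <- cbind(a, a, a, a, b, b, b, b) *
    matrix(exp(rnorm(30 * 8, 0, 0.01)), 30, 8)
  colnames(V) <- sprintf("s%d", 1:8)
  cc <- consensus_cluster(V, 2, n_runs = 10, seed = 6)
  expect_true(all(cc$consensus %in% c(0, 1)))
  expect_equal(unname(cc$consensus[1:4, 1:4]), matrix(1, 4, 4))
  expect_equal(unname(cc$consensus[1:4, 5:8]), matrix(0, 4, 4))
  expect_equal(cc$cophenetic, 1.0)
  expect_equal(unname(cc$mean_consensus_per_cluster), c(1, 1))
  # symmetry and unit diagonal hold by construction
  expect_identical(cc$consensus, t(cc$consensus))
  expect_true(all(diag(cc$consensus) == 1))
})

test_that("consensus entries stay in [0,1] and variance shrinks with runs", {
  set.seed(5)
  V <- matrix(rexp(40 * 12, 1 / 30), 40, 12)
  colnames(V) <- sprintf("s%d", 1:12)
  offdiag <- function(C) C[upper.tri(C)]
  spread10 <- sapply(1:4, function(i)
    sd(offdiag(consensus_cluster(V, 3, n_runs = 10,
                                 seed = 100 + i)$consensus)))
  spread50 <- sapply(1:4, function(i)
    sd(offdiag(consensus_cluster(V, 3, n_runs = 50,
                                 seed = 200 + i)$consensus)))
  ccs <- consensus_cluster(V, 3, n_runs = 10, seed = 1)
  expect_true(all(ccs$consensus >= 0 & ccs$consensus <= 1))
  # more runs -> consensus estimates vary less across seeds
  expect_lt(sd(spread50), Inf)  # guard
  expect_lt(mean(abs(spread50 - mean(spread50))),
            mean(abs(spread10 - mean(spread10))) + 0.05)
})

test_that("row permutation preserves row multisets and is seeded", {
  set.seed(6)
  V <- matrix(rnorm(20 * 7), 20, 7)
  P1 <- permute_matrix(V, seed = 9)
  P2 <- permute_matrix(V, seed = 9)
  expect_identical(P1, P2)
  expect_equal(rowSums(P1), rowSums(V))
  for (i in 1:20) expect_setequal(P1[i, ], V[i, ])
  # single-sample matrix is unchanged
  V1 <- V[, 1, drop = FALSE]
  expect_identical(permute_matrix(V1, seed = 2), V1)
})

test_that("meta-gene relative contributions are row-normalized and ranked", {
  W <- rbind(pure2 = c(0, 5, 0),
             uniform = c(2, 2, 2),
             mixed = c(1, 3, 0))
  factors <- structure(list(W = W, H = NULL), class = "NMFFactors")
  rep <- extract_metagenes(factors, top_n = 2)
  expect_equal(unname(rep$relative_contribution["pure2", ]), c(0, 1, 0))
  expect_equal(unname(rep$relative_contribution["uniform", ]),
               rep(1 / 3, 3))
  expect_equal(rowSums(rep$relative_contribution),
               c(pure2 = 1, uniform = 1, mixed = 1))
  # the pure driver ranks first for its factor
  expect_equal(rep$per_factor[[2]]$gene_id[1], "pure2")

  Wz <- rbind(W, zero = c(0, 0, 0))
  fz <- structure(list(W = Wz, H = NULL), class = "NMFFactors")
  expect_warning(rz <- extract_metagenes(fz), "all-zero")
  expect_false("zero" %in% rownames(rz$relative_contribution))
})

test_that("planted single-gene-driven factor is recovered as top driver", {
  set.seed(8)
  W0 <- matrix(rgamma(30 * 3, 2, 2), 30, 3,
               dimnames = list(sprintf("g%02d", 1:30), NULL))
  W0["g07", ] <- c(0.01, 30, 0.01)    # one gene dominates factor 2
  H0 <- matrix(rgamma(3 * 20, 2, 2), 3, 20)
  V <- W0 %*% H0
  fit <- nmf_factorize(V, 3, seed = 4, max_iter = 3000, tol = 1e-10)
  rep <- extract_metagenes(fit)
  # find the fitted factor that g07 loads on
  f <- which.max(fit$W["g07", ])
  expect_equal(rep$per_factor[[f]]$gene_id[1], "g07")
  expect_gt(rep$relative_contribution["g07", f], 0.75)
})

test_that("cluster-metadata association is a plain Pearson chi-squared", {
  asg <- rep(c(1, 2), each = 10)
  meta <- rep(c("a", "b"), each = 10)
  res <- suppressWarnings(association_test(asg, meta))
  expect_equal(res$chi2, 20)
  expect_equal(res$df, 1)
  expect_equal(res$p, pchisq(20, 1, lower.tail = FALSE))
  expect_equal(res$p, 7.744216e-06, tolerance = 1e-6)

  # proportional table gives chi2 = 0, p = 1
  res0 <- suppressWarnings(
    association_test(rep(c(1, 2), each = 6), rep(c("a", "b"), 6)))
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)

  # joint permutation leaves the statistic unchanged
  set.seed(9)
  perm <- sample(20)
  resp <- suppressWarnings(association_test(asg[perm], meta[perm]))
  expect_equal(resp$chi2, res$chi2)

  expect_error(association_test(rep(1, 10), meta[1:10]), "2 clusters")
  expect_error(association_test(asg, rep("a", 20)), "2 metadata")
})

test_that("rank selection validates inputs and reports the diff argmax", {
  set.seed(10)
  V <- matrix(rexp(30 * 10, 1 / 20), 30, 10)
  expect_error(select_rank(V, k_range = integer(0)), "empty")
  expect_error(select_rank(V, k_range = 2:10), "below the number")
  rs <- select_rank(V, k_range = 2:4, n_runs = 5, seed = 3)
  expect_equal(rs$selected_k,
               (2:4)[which.max(rs$cophenetic_actual -
                                 rs$cophenetic_permuted)])
  # pure-noise input still produces a complete report
  expect_length(rs$cophenetic_actual, 3)
  expect_true(all(is.finite(rs$cophenetic_actual)))
})
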