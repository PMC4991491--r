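#' Non-negative matrix factorization by multiplicative KL updates
#'
#' Factorizes a non-negative matrix V (genes x samples) as W H with
#' W >= 0 (genes x k, the meta-genes) and H >= 0 (k x samples),
#' minimizing the generalized Kullback-Leibler divergence with
#' Brunet-style multiplicative updates.  Initialization is random uniform
#' scaled so that W0 H0 matches the mean of V; the run is deterministic
#' under `seed`.
#'
#' @param V Non-negative numeric matrix without all-zero rows.
#' @param k Factorization rank, 2 <= k < min(dim(V)).
#' @param seed Integer RNG seed.
#' @param max_iter Maximum update iterations.
#' @param tol Relative objective-change convergence tolerance (checked
#'   every `check_every` iterations).
#' @param check_every Convergence-check interval.
#' @param trace_objective Record the objective per iteration (for
#'   monotonicity diagnostics).
#' @param stable_stop When positive, also stop once argmax-H sample
#'   memberships are unchanged over this many consecutive checks
#'   (connectivity-stability rule; used by [consensus_cluster()] where
#'   only the hard memberships feed the consensus matrix).
#' @return An `NMFFactors` list: `W`, `H`, `objective`, `n_iterations`,
#'   `seed`, optionally `objective_trace`.
#' @export
nmf_factorize <- function(V, k, seed = 1, max_iter = 2000, tol = 1e-6,
                          check_every = 10, trace_objective = FALSE,
                          stable_stop = 0) {
  V <- as.matrix(V)
  if (any(V < 0)) stop2("V must be non-negative")
  zero <- rowSums(V) == 0
  if (any(zero))
    stop2("all-zero row(s) in V: ",
          paste(head(rownames(V)[zero] %||% which(zero)), collapse = ", "))
  if (k < 2 || k >= min(dim(V)))
    stop2("k must satisfy 2 <= k < min(dim(V)); got k=", k)
  set.seed(seed)
  W0 <- matrix(runif(nrow(V) * k), nrow(V), k)
  H0 <- matrix(runif(k * ncol(V)), k, ncol(V))
  sc <- sqrt(mean(V) / mean(W0 %*% H0))
  fit <- .nmf_kl_cpp(V, W0 * sc, H0 * sc, as.integer(max_iter), tol,
                     as.integer(check_every), trace_objective,
                     as.integer(stable_stop))
  rownames(fit$W) <- rownames(V)
  colnames(fit$H) <- colnames(V)
  structure(list(W = fit$W, H = fit$H, objective = fit$objective,
                 n_iterations = fit$n_iterations, seed = seed,
                 objective_trace = if (trace_objective) fit$objective_trace),
            class = "NMFFactors")
}

#' Hard cluster membership from NMF coefficients
#'
#' Each sample joins the factor with the maximal H coefficient; ties go
#' to the lowest factor index.
#'
#' @param H Coefficient matrix k x samples.
#' @return Integer vector of factor memberships.
#' @export
nmf_membership <- function(H) apply(H, 2, which.max)

#' Consensus clustering over repeated NMF runs
#'
#' The factorization is repeated `n_runs` times from different random
#' initializations; consensus(i, j) is the fraction of runs assigning
#' samples i and j to the same factor.  Final assignments cut the
#' average-linkage dendrogram of (1 - consensus) into k groups; the
#' cophenetic coefficient is the Pearson correlation between the
#' (1 - consensus) distances and the dendrogram's cophenetic distances.
#'
#' @param V Non-negative matrix (genes x samples).
#' @param k Rank / number of clusters.
#' @param n_runs Number of NMF runs (>= 2).
#' @param seed Integer RNG seed (expanded into per-run seeds).
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @param perturb Per-run input perturbation: `"bootstrap"` (default)
#'   resamples gene rows with replacement before each factorization, so
#'   the consensus measures stability of the sample partition under both
#'   random initialization and gene-level perturbation of the matrix;
#'   `"none"` uses random initializations only.
#' @return A `ConsensusResult`: `k`, `consensus`, `cophenetic`,
#'   `assignments`, `mean_consensus_per_cluster`, `n_runs`.
#' @export
consensus_cluster <- function(V, k, n_runs = 30, seed = 1, max_iter = 500,
                              tol = 1e-5, perturb = c("bootstrap", "none")) {
  if (n_runs < 2) stop2("n_runs must be >= 2")
  perturb <- match.arg(perturb)
  V <- as.matrix(V)
  n <- ncol(V)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1, n_runs)
  C <- matrix(0, n, n)
  for (r in seq_len(n_runs)) {
    Vr <- V
    if (perturb == "bootstrap") {
      set.seed(run_seeds[r])
      Vr <- V[sample.int(nrow(V), replace = TRUE), , drop = FALSE]
    }
    fit <- nmf_factorize(Vr, k, seed = run_seeds[r], max_iter = max_iter,
                         tol = tol, stable_stop = 3)
    m <- nmf_membership(fit$H)
    C <- C + outer(m, m, `==`)
  }
  C <- C / n_runs
  dimnames(C) <- list(colnames(V), colnames(V))
  d <- as.dist(1 - C)
  hc <- hclust(d, method = "average")
  assignments <- cutree(hc, k = k)
  if (all(d == 0)) {
    warning("consensus matrix is all ones; cophenetic reported as 1.0")
    coph <- 1.0
  } else {
    coph <- suppressWarnings(cor(d, cophenetic(hc)))
    if (is.na(coph)) { warning("cophenetic undefined; reported as 1.0"); coph <- 1.0 }
  }
  if (length(unique(assignments)) < k)
    warning("fewer than k clusters realized in the consensus cut")
  mean_cons <- vapply(sort(unique(assignments)), function(cl) {
    idx <- which(assignments == cl)
    if (length(idx) == 1) return(1.0)
    sub <- C[idx, idx]
    mean(sub[upper.tri(sub)])
  }, 0)
  structure(list(k = k, consensus = C, cophenetic = coph,
                 assignments = assignments,
                 mean_consensus_per_cluster =
                   setNames(mean_cons, sort(unique(assignments))),
                 n_runs = n_runs),
            class = "ConsensusResult")
}

#' Permute each gene row independently across samples
#'
#' Destroys sample structure while preserving every gene's marginal
#' distribution (row multisets, hence row sums, are preserved exactly).
#'
#' @param V Matrix.
#' @param seed Integer RNG seed.
#' @return Permuted matrix of the same dimensions.
#' @export
permute_matrix <- function(V, seed = 1) {
  set.seed(seed)
  out <- V
  if (ncol(V) < 2) return(out)
  for (i in seq_len(nrow(V))) out[i, ] <- V[i, sample.int(ncol(V))]
  out
}

#' Select the factorization rank by permutation-calibrated cophenetics
#'
#' For each k in `k_range`, consensus clustering is run on the actual
#' matrix and on a row-permuted matrix; the selected rank maximizes the
#' difference between actual and permuted cophenetic coefficients (ties
#' to the smallest k).
#'
#' @param V Non-negative matrix (genes x samples).
#' @param k_range Candidate ranks.
#' @param n_runs NMF runs per rank per matrix.
#' @param seed Integer RNG seed.
#' @param max_iter,tol,perturb Passed through to [consensus_cluster()].
#' @return A `RankSelection`: `k_range`, `cophenetic_actual`,
#'   `cophenetic_permuted`, `selected_k`.
#' @export
select_rank <- function(V, k_range = 2:11, n_runs = 50, seed = 1,
                        max_iter = 500, tol = 1e-5,
                        perturb = c("bootstrap", "none")) {
  perturb <- match.arg(perturb)
  if (length(k_range) == 0) stop2("k_range is empty")
  if (max(k_range) >= ncol(V))
    stop2("max k_range must be below the number of samples")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 2 * length(k_range) + 1)
  Vp <- permute_matrix(V, seed = seeds[length(seeds)])
  ca <- cp <- setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    ca[i] <- consensus_cluster(V, k_range[i], n_runs, seed = seeds[2 * i - 1],
                               max_iter = max_iter, tol = tol,
                               perturb = perturb)$cophenetic
    cp[i] <- consensus_cluster(Vp, k_range[i], n_runs, seed = seeds[2 * i],
                               max_iter = max_iter, tol = tol,
                               perturb = perturb)$cophenetic
  }
  diff <- ca - cp
  selected_k <- k_range[which.max(diff)]   # which.max takes the first max
  structure(list(k_range = k_range, cophenetic_actual = ca,
                 cophenetic_permuted = cp, cophenetic_diff = diff,
                 selected_k = selected_k),
            class = "RankSelection")
}

#' @export
print.RankSelection <- function(x, ...) {
  cat("RankSelection: selected k =", x$selected_k, "\n")
  print(round(rbind(actual = x$cophenetic_actual,
                    permuted = x$cophenetic_permuted,
                    diff = x$cophenetic_diff), 4))
  invisible(x)
}

#' Rank genes driving each meta-gene
#'
#' The relative contribution of gene g to factor f is
#' W\[g, f\] / sum_f' W\[g, f'\]; per factor, genes are ranked by relative
#' contribution times the gene's maximum loading, and the top `top_n`
#' are reported as driver genes.  All-zero gene rows are excluded with a
#' warning.
#'
#' @param factors An `NMFFactors` object.
#' @param top_n Driver genes per factor.
#' @return A `MetaGeneReport`: per-factor ranked data frames and
#'   `relative_contribution` matrix.
#' @export
extract_metagenes <- function(factors, top_n = 50) {
  W <- factors$W
  zero <- rowSums(W) == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with all-zero loadings excluded")
    W <- W[!zero, , drop = FALSE]
  }
  rel <- W / rowSums(W)
  rowmax <- apply(W, 1, max)
  per_factor <- lapply(seq_len(ncol(W)), function(f) {
    score <- rel[, f] * rowmax
    ord <- order(score, decreasing = TRUE)
    data.frame(gene_id = rownames(W)[ord],
               relative_contribution = rel[ord, f],
               loading = W[ord, f], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  drivers <- lapply(per_factor, function(df) head(df$gene_id, top_n))
  structure(list(relative_contribution = rel, per_factor = per_factor,
                 driver_genes = drivers),
            class = "MetaGeneReport")
}

#' Test association between cluster assignments and a metadata column
#'
#' Pearson chi-squared test on the cluster x category contingency table,
#' without continuity correction.
#'
#' @param assignments Cluster labels per sample.
#' @param metadata_column Categorical covariate per sample.
#' @return List with `chi2`, `df`, `p`, and the contingency `table`.
#' @export
association_test <- function(assignments, metadata_column) {
  tab <- table(assignments, metadata_column)
  if (nrow(tab) < 2) stop2("need >= 2 clusters")
  if (ncol(tab) < 2) stop2("need >= 2 metadata categories")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5))
    warning("expected count < 5 in some cells; chi-squared approximation weak")
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, table = tab)
}
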