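#' All-against-all Pearson correlation between two species' profiles
#'
#' Computes Pearson correlations between expression profiles on the
#' log2(FPKM + offset) scale.  With `scope = "all"` the within-species
#' blocks are included; `"cross_only"` restricts to human-mouse pairs.
#' Constant profiles (undefined r) are excluded with a warning.
#'
#' @param expr_human,expr_mouse LOG2_OFFSET-scale `ExpressionMatrix`
#'   objects (or plain matrices) over an identical ordered sample set.
#' @param scope `"all"` or `"cross_only"`.
#' @return A `CorrelationSet`: list of correlation blocks `hh`, `mm`,
#'   `hm` (NULL where out of scope) plus `n_samples` and `species_of`.
#' @export
pairwise_correlation <- function(expr_human, expr_mouse,
                                 scope = c("all", "cross_only")) {
  scope <- match.arg(scope)
  H <- if (inherits(expr_human, "ExpressionMatrix")) expr_human$values
       else expr_human
  M <- if (inherits(expr_mouse, "ExpressionMatrix")) expr_mouse$values
       else expr_mouse
  if (!identical(colnames(H), colnames(M)))
    stop2("human and mouse matrices disagree on the sample set")
  if (ncol(H) < 3) stop2("need >= 3 samples for correlation")
  drop_constant <- function(X, label) {
    s <- apply(X, 1, sd)
    if (any(s == 0)) {
      warning(sum(s == 0), " constant ", label,
              " profile(s) excluded (undefined correlation)")
      X <- X[s > 0, , drop = FALSE]
    }
    X
  }
  H <- drop_constant(H, "human"); M <- drop_constant(M, "mouse")
  th <- t(H); tm <- t(M)
  hm <- cor(th, tm)
  hh <- if (scope == "all") cor(th) else NULL
  mm <- if (scope == "all") cor(tm) else NULL
  species_of <- c(setNames(rep("HUMAN", nrow(H)), rownames(H)),
                  setNames(rep("MOUSE", nrow(M)), rownames(M)))
  structure(list(hh = hh, mm = mm, hm = hm, n_samples = ncol(H),
                 species_of = species_of, scope = scope),
            class = "CorrelationSet")
}

edge_df <- function(mat, class, symmetric) {
  if (is.null(mat) || length(mat) == 0) return(NULL)
  if (symmetric) {
    idx <- which(upper.tri(mat), arr.ind = TRUE)
  } else {
    idx <- which(matrix(TRUE, nrow(mat), ncol(mat)), arr.ind = TRUE)
  }
  data.frame(gene_a = rownames(mat)[idx[, 1]],
             gene_b = colnames(mat)[idx[, 2]],
             r = mat[idx], edge_class = rep(class, nrow(idx)),
             stringsAsFactors = FALSE)
}

#' Build a thresholded co-expression network
#'
#' Edges connect gene pairs with |r| strictly greater than `threshold`;
#' each edge is labeled human_human, mouse_mouse or cross_species from
#' its endpoint species.  Exact r values are stored so the network can
#' be re-thresholded without recomputation.
#'
#' @param correlations A `CorrelationSet` from [pairwise_correlation()].
#' @param threshold Absolute-correlation threshold (strict).
#' @return A `CorrelationNetwork` with `edges`, `nodes`, `threshold`,
#'   `species_of`, `n_samples`.
#' @export
build_network <- function(correlations, threshold = 0.85) {
  stopifnot(inherits(correlations, "CorrelationSet"))
  all_edges <- rbind(edge_df(correlations$hh, "human_human", TRUE),
                     edge_df(correlations$mm, "mouse_mouse", TRUE),
                     edge_df(correlations$hm, "cross_species", FALSE))
  if (is.null(all_edges))
    all_edges <- data.frame(gene_a = character(0), gene_b = character(0),
                            r = numeric(0), edge_class = character(0),
                            stringsAsFactors = FALSE)
  edges <- all_edges[!is.na(all_edges$r) & abs(all_edges$r) > threshold, ,
                     drop = FALSE]
  rownames(edges) <- NULL
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  structure(list(edges = edges, nodes = nodes, threshold = threshold,
                 species_of = correlations$species_of,
                 n_samples = correlations$n_samples),
            class = "CorrelationNetwork")
}

#' @export
print.CorrelationNetwork <- function(x, ...) {
  cat("CorrelationNetwork: |r| >", x$threshold, "|", length(x$nodes),
      "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) print(table(x$edges$edge_class))
  invisible(x)
}

#' Rank nodes by cross-species degree
#'
#' @param network A `CorrelationNetwork`.
#' @return Data frame of nodes with their count of incident cross-species
#'   edges, ranked descending (ties broken lexicographically).
#' @export
cross_species_hubs <- function(network) {
  e <- network$edges[network$edges$edge_class == "cross_species", ,
                     drop = FALSE]
  deg <- table(c(e$gene_a, e$gene_b))
  degree <- setNames(rep(0L, length(network$nodes)), network$nodes)
  degree[names(deg)] <- as.integer(deg)
  ord <- order(-degree, names(degree))
  data.frame(gene_id = names(degree)[ord],
             species = unname(network$species_of[names(degree)[ord]]),
             cross_degree = unname(degree[ord]),
             rank = seq_along(ord), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rank target-species genes by correlation with a query gene
#'
#' @param expr_query LOG2_OFFSET-scale `ExpressionMatrix` (or matrix)
#'   containing the query gene.
#' @param expr_target Matrix of the target species' profiles over the
#'   same samples.
#' @param query_gene Query gene ID.
#' @param top_fraction Fraction of the ranking returned as the `top`
#'   subset.
#' @param by_abs Rank by |r| instead of signed r.
#' @return A `PartnerRanking` with the full ranking (`partners`), the
#'   `top` subset and `n_samples`.
#' @export
rank_partners <- function(expr_query, expr_target, query_gene,
                          top_fraction = 0.06, by_abs = FALSE) {
  Q <- if (inherits(expr_query, "ExpressionMatrix")) expr_query$values
       else expr_query
  T <- if (inherits(expr_target, "ExpressionMatrix")) expr_target$values
       else expr_target
  if (!query_gene %in% rownames(Q)) stop2("query gene absent: ", query_gene)
  if (!identical(colnames(Q), colnames(T)))
    stop2("query and target matrices disagree on samples")
  if (ncol(Q) < 3) stop2("need >= 3 samples")
  r <- as.vector(cor(Q[query_gene, ], t(T)))
  names(r) <- rownames(T)
  n <- ncol(Q)
  p <- vapply(r, function(ri) pearson_pvalue(ri, n), 0)
  key <- if (by_abs) -abs(r) else -r
  ord <- order(key, names(r))
  partners <- data.frame(gene_id = names(r)[ord], r = unname(r[ord]),
                         p_two_sided = unname(p[ord]),
                         rank = seq_along(ord), row.names = NULL,
                         stringsAsFactors = FALSE)
  n_top <- ceiling(top_fraction * nrow(partners))
  structure(list(query = query_gene, partners = partners,
                 top = head(partners, n_top), n_samples = n,
                 top_fraction = top_fraction),
            class = "PartnerRanking")
}

#' Two-sided p-value of a Pearson correlation
#'
#' Uses the exact t transform t = r sqrt(n-2) / sqrt(1-r^2) with n-2
#' degrees of freedom.
#'
#' @param r Pearson correlation coefficient.
#' @param n Number of samples (>= 3).
#' @return Two-sided p-value; |r| = 1 returns 0.
#' @export
pearson_pvalue <- function(r, n) {
  if (n < 3) stop2("need n >= 3 for a correlation p-value")
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t), df = n - 2)
}
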