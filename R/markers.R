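#' Median-of-ratios size factors
#'
#' The factor of a sample is the median over reference genes (genes with
#' no zero counts) of the ratio of its count to the gene's geometric
#' mean, rescaled so the factors have geometric mean one.
#'
#' @param counts Integer matrix genes x samples.
#' @return Numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  ref <- rowSums(counts == 0) == 0
  if (!any(ref))
    stop2("no gene with all-positive counts; consider a pseudo-reference")
  lg <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, median)
  sf / exp(mean(log(sf)))
}

#' Two-group negative-binomial Wald differential expression
#'
#' Counts are normalized by median-of-ratios size factors; per gene the
#' dispersion is estimated by method of moments pooled across the two
#' groups and shrunk 25% toward the across-gene median (a light
#' moderation that calibrates the test at small group sizes); the Wald
#' statistic log2FC / SE(log2FC) under the NB variance model is referred
#' to a t distribution with n1 + n2 - 2 degrees of freedom.  Genes
#' failing the expression gate (FPKM > `min_fpkm` in at least one
#' sample, when an FPKM matrix is supplied) are reported as
#' `low_expression_skipped` and excluded from BH correction.
#'
#' @param counts Integer matrix genes x samples.
#' @param group_labels Two-level factor (or vector) over samples;
#'   log2 fold changes are second level vs first.
#' @param fpkm Optional FPKM matrix over the same genes used as the
#'   expression gate.
#' @param min_fpkm Gate threshold.
#' @param dispersion_floor Lower bound on the dispersion estimate.
#' @return Data frame of `DERecord`s: `gene_id`, `base_mean`, `log2_fc`,
#'   `p`, `fdr`, `status`.
#' @export
de_test <- function(counts, group_labels, fpkm = NULL, min_fpkm = 1,
                    dispersion_floor = 1e-8) {
  if (any(counts != round(counts)) || any(counts < 0))
    stop2("counts must be non-negative integers")
  group <- factor(group_labels)
  if (nlevels(group) != 2) stop2("exactly two groups required")
  n1 <- sum(group == levels(group)[1]); n2 <- sum(group == levels(group)[2])
  if (min(n1, n2) < 2) stop2("each group needs >= 2 samples")

  sf <- size_factors(counts)
  x <- sweep(counts, 2, sf, `/`)
  g1 <- group == levels(group)[1]
  m1 <- rowMeans(x[, g1, drop = FALSE]); m2 <- rowMeans(x[, !g1, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, var)
  v2 <- apply(x[, !g1, drop = FALSE], 1, var)

  # moment dispersion pooled across groups, moderated toward the
  # across-gene median
  a_raw <- ((n1 - 1) * (v1 - m1) + (n2 - 1) * (v2 - m2)) /
           ((n1 - 1) * m1^2 + (n2 - 1) * m2^2)
  a_raw[!is.finite(a_raw)] <- 0
  a <- pmax(0.75 * a_raw + 0.25 * median(pmax(a_raw, 0)), dispersion_floor)

  lfc <- log2((m2 + 0.5) / (m1 + 0.5))
  var_m1 <- (m1 + a * m1^2) / n1
  var_m2 <- (m2 + a * m2^2) / n2
  se <- sqrt(var_m1 / (m1 + 0.5)^2 + var_m2 / (m2 + 0.5)^2) / log(2)
  z <- lfc / se
  p <- 2 * pt(-abs(z), df = n1 + n2 - 2)

  tested <- rep(TRUE, nrow(counts))
  if (!is.null(fpkm)) {
    fp <- fpkm[match(rownames(counts), rownames(fpkm)), , drop = FALSE]
    tested <- apply(fp, 1, max) > min_fpkm
    tested[is.na(tested)] <- FALSE
  }
  fdr <- rep(NA_real_, nrow(counts))
  fdr[tested] <- bh_fdr(p[tested])
  data.frame(gene_id = rownames(counts),
             base_mean = (n1 * m1 + n2 * m2) / (n1 + n2),
             log2_fc = lfc, p = ifelse(tested, p, NA_real_), fdr = fdr,
             status = ifelse(tested, "tested", "low_expression_skipped"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR
#'
#' Thin validated wrapper around `p.adjust(method = "BH")`; the mapping
#' back to input order is order-preserving.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return FDR values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop2("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Hypergeometric upper-tail signature overlap test
#'
#' Tests whether a gene list drawn from a universe of size N containing
#' K signature genes contains at least k of them:
#' p = P(X >= k) under Hypergeometric(N, K, n).  The signature is
#' intersected with the universe before testing; the list must be a
#' subset of the universe.
#'
#' @param list_genes Character vector (the gene list of interest).
#' @param signature_genes Character vector (the signature).
#' @param universe_genes Character vector (the gene universe), or a
#'   single integer giving the universe size when the list and signature
#'   are already universe-restricted counts.
#' @return An `OverlapResult` list: `k_overlap`, `K_signature`,
#'   `n_list`, `N_universe`, `p_upper`, `overlap_genes`.
#' @export
hypergeom_overlap <- function(list_genes, signature_genes, universe_genes) {
  if (is.numeric(universe_genes) && length(universe_genes) == 1) {
    N <- as.integer(universe_genes)
    sig <- unique(signature_genes)
    lst <- unique(list_genes)
  } else {
    if (length(universe_genes) == 0) stop2("empty universe")
    uni <- unique(universe_genes)
    lst <- unique(list_genes)
    if (!all(lst %in% uni))
      stop2("gene list is not a subset of the universe")
    sig <- intersect(unique(signature_genes), uni)
    N <- length(uni)
  }
  k <- length(intersect(lst, sig))
  K <- length(sig); n <- length(lst)
  if (n > N || K > N) stop2("list or signature larger than universe")
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(k_overlap = k, K_signature = K, n_list = n, N_universe = N,
                 p_upper = p, overlap_genes = intersect(lst, sig)),
            class = "OverlapResult")
}

#' Hypergeometric overlap from printed table cells
#'
#' @param k Observed overlap.
#' @param K Signature size.
#' @param n List size.
#' @param N Universe size.
#' @return Upper-tail p-value P(X >= k).
#' @export
hypergeom_upper <- function(k, K, n, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Stratify samples by an external stromal score
#'
#' @param samples Character vector of sample IDs.
#' @param stromal_scores Named numeric vector of scores.
#' @param cutoff Score cutoff.
#' @param direction `"<"` or `">"` (strict comparisons).
#' @return Character vector of samples satisfying the cutoff.
#' @export
stroma_stratify <- function(samples, stromal_scores, cutoff,
                            direction = c("<", ">")) {
  direction <- match.arg(direction)
  missing <- setdiff(samples, names(stromal_scores))
  if (length(missing))
    stop2("missing stromal score for sample(s): ",
          paste(missing, collapse = ", "))
  sc <- stromal_scores[samples]
  keep <- if (direction == "<") sc < cutoff else sc > cutoff
  out <- samples[keep]
  if (length(out) == 0) warning("no samples satisfy the stromal cutoff")
  out
}

#' Construct a platform DE set
#'
#' Bundles a platform's DE records with its purity class and the
#' significance dialect it uses (`fdr` or `p`).
#'
#' @param platform_name Label.
#' @param purity_class `"tumor_pure"` or `"mixed"`.
#' @param records DE data frame from [de_test()].
#' @param fc_thresh |log2FC| threshold used for over-expression calls.
#' @param sig_thresh Significance threshold.
#' @param sig_on `"fdr"` or `"p"`.
#' @return A `PlatformDESet`.
#' @export
platform_de_set <- function(platform_name, purity_class, records,
                            fc_thresh = 1.5, sig_thresh = 0.05,
                            sig_on = c("fdr", "p")) {
  purity_class <- match.arg(purity_class, c("tumor_pure", "mixed"))
  sig_on <- match.arg(sig_on)
  structure(list(platform_name = platform_name, purity_class = purity_class,
                 records = records, fc_thresh = fc_thresh,
                 sig_thresh = sig_thresh, sig_on = sig_on),
            class = "PlatformDESet")
}

overexpressed_genes <- function(ps) {
  r <- ps$records
  sig <- r[[ps$sig_on]]
  ok <- !is.na(sig) & sig < ps$sig_thresh & r$log2_fc > ps$fc_thresh
  r$gene_id[ok]
}

significant_genes_any_fc <- function(ps) {
  r <- ps$records
  sig <- r[[ps$sig_on]]
  r$gene_id[!is.na(sig) & sig < ps$sig_thresh]
}

#' Triangulate tumor-pure markers masked in mixed samples
#'
#' consensus_pure is the intersection over tumor-pure platforms of genes
#' over-expressed (log2FC above the platform threshold and significant
#' under the platform's dialect); masked_markers removes genes
#' significant in any mixed platform at FDR < `fdr_thresh` regardless of
#' fold-change magnitude — markers whose contrast is obscured by
#' stromal expression in mixed tumor-stroma samples.
#'
#' @param pure_sets List of tumor-pure `PlatformDESet`s.
#' @param mixed_sets List of mixed `PlatformDESet`s.
#' @param fdr_thresh Significance threshold applied to mixed platforms.
#' @return List with `consensus_pure` and `masked_markers` gene sets.
#' @export
triangulate_markers <- function(pure_sets, mixed_sets, fdr_thresh = 0.05) {
  if (length(pure_sets) == 0 || length(mixed_sets) == 0)
    stop2("need at least one pure and one mixed platform")
  uni <- lapply(c(pure_sets, mixed_sets), function(ps) ps$records$gene_id)
  if (length(unique(lapply(uni, sort))) != 1)
    stop2("platforms disagree on the shared gene universe")
  pure_lists <- lapply(pure_sets, overexpressed_genes)
  consensus <- Reduce(intersect, pure_lists)
  mixed_sig <- unique(unlist(lapply(mixed_sets, function(ps) {
    ps$sig_thresh <- fdr_thresh
    significant_genes_any_fc(ps)
  })))
  list(consensus_pure = consensus,
       masked_markers = setdiff(consensus, mixed_sig))
}
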