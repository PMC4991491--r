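new_expression_matrix <- function(values, scale = c("FPKM", "LOG2_OFFSET"),
                                  gene_species = NULL,
                                  filters_applied = character(0)) {
  scale <- match.arg(scale)
  structure(list(values = values, scale = scale,
                 gene_species = gene_species,
                 filters_applied = filters_applied),
            class = "ExpressionMatrix")
}

#' Construct an FPKM-scale ExpressionMatrix from a plain matrix
#'
#' @param values Non-negative numeric matrix (genes x samples).
#' @param gene_species Named vector gene -> species.
#' @param scale `"FPKM"` or `"LOG2_OFFSET"`.
#' @return An `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_species = NULL, scale = "FPKM") {
  new_expression_matrix(values, scale, gene_species)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix [", x$scale, "]: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples", sep = "")
  if (length(x$filters_applied))
    cat("; filters:", paste(x$filters_applied, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Expression-filter thresholds
#'
#' Defaults follow the standard preparation for clustering and
#' cross-species correlation: a gene is kept when its maximum FPKM
#' strictly exceeds 10 (human) or 2 (mouse) in at least one sample and its
#' coefficient of variation exceeds 0.20.
#'
#' @param min_fpkm_human,min_fpkm_mouse Species expression thresholds.
#' @param min_cv Coefficient-of-variation threshold (sd/mean of raw FPKM,
#'   sample sd with n-1 denominator).
#' @param log_offset Offset added before log2 (see [to_nonneg_log()]).
#' @return A `FilterSpec` list.
#' @export
filter_spec <- function(min_fpkm_human = 10, min_fpkm_mouse = 2,
                        min_cv = 0.20, log_offset = 1.1) {
  if (any(c(min_fpkm_human, min_fpkm_mouse, min_cv, log_offset) <= 0))
    stop2("all FilterSpec thresholds must be positive")
  structure(list(min_fpkm_human = min_fpkm_human,
                 min_fpkm_mouse = min_fpkm_mouse,
                 min_cv = min_cv, log_offset = log_offset),
            class = "FilterSpec")
}

#' Retain highly expressed, variable genes
#'
#' @param expr FPKM-scale `ExpressionMatrix`.
#' @param spec A [filter_spec()].
#' @param species Optional species restriction (`"HUMAN"`/`"MOUSE"`); by
#'   default each gene is filtered against its own species threshold.
#' @return Filtered `ExpressionMatrix` (still FPKM scale).
#' @export
filter_genes <- function(expr, spec = filter_spec(), species = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "FPKM") stop2("filter_genes expects an FPKM-scale matrix")
  v <- expr$values
  if (ncol(v) < 2) stop2("coefficient of variation undefined for a single sample")
  sp <- expr$gene_species[rownames(v)]
  if (!is.null(species)) {
    check_species(species)
    keep_sp <- sp == species
    v <- v[keep_sp, , drop = FALSE]
    sp <- sp[keep_sp]
  }
  thr <- ifelse(sp == "HUMAN", spec$min_fpkm_human, spec$min_fpkm_mouse)
  mx <- apply(v, 1, max)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, sd)
  cv <- ifelse(mu > 0, sdv / mu, 0)
  keep <- mx > thr & cv > spec$min_cv          # strict inequalities
  new_expression_matrix(v[keep, , drop = FALSE], "FPKM", sp[keep],
                        c(expr$filters_applied,
                          sprintf("max_fpkm>%g(human)/%g(mouse)",
                                  spec$min_fpkm_human, spec$min_fpkm_mouse),
                          sprintf("cv>%g", spec$min_cv)))
}

#' Non-negative log transform: log2(FPKM + offset)
#'
#' The offset (default 1.1) makes every entry strictly positive so the
#' matrix can be factorized by NMF.
#'
#' @param expr FPKM-scale `ExpressionMatrix`.
#' @param offset Value added before taking log2.
#' @return `ExpressionMatrix` on the LOG2_OFFSET scale.
#' @export
to_nonneg_log <- function(expr, offset = 1.1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "FPKM") stop2("to_nonneg_log expects an FPKM-scale matrix")
  if (any(expr$values < 0)) stop2("negative FPKM input")
  new_expression_matrix(log2(expr$values + offset), "LOG2_OFFSET",
                        expr$gene_species,
                        c(expr$filters_applied,
                          sprintf("log2(x+%g)", offset)))
}

#' Flag samples retaining patient stroma via CAF markers
#'
#' Human FAP or CSPG4 expression above log2 FPKM thresholds flags a sample
#' as retaining patient-derived cancer-associated fibroblasts.  Raw
#' log2(FPKM) is used (FPKM 0 maps to -Inf); `low`/`high` are the
#' low- and high-evidence thresholds.
#'
#' @param expr_human FPKM-scale `ExpressionMatrix` of the human component.
#' @param low,high log2 FPKM thresholds.
#' @param markers Marker gene IDs (default FAP and CSPG4).
#' @return Data frame with per-sample marker levels and
#'   `flag` in none/low_evidence/high_evidence.
#' @export
flag_patient_stroma <- function(expr_human, low = 2.0, high = 4.0,
                                markers = c("FAP", "CSPG4")) {
  stopifnot(inherits(expr_human, "ExpressionMatrix"))
  if (expr_human$scale != "FPKM")
    stop2("flag_patient_stroma expects an FPKM-scale matrix")
  missing <- setdiff(markers, rownames(expr_human$values))
  if (length(missing))
    stop2("marker gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  lv <- log2(expr_human$values[markers, , drop = FALSE])  # 0 -> -Inf
  top <- apply(lv, 2, max)
  flag <- ifelse(top > high, "high_evidence",
                 ifelse(top > low, "low_evidence", "none"))
  data.frame(sample_id = colnames(expr_human$values),
             fap_log2_fpkm = lv[1, ], cspg4_log2_fpkm = lv[2, ],
             flag = flag, row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict host gender from Y-chromosome gene counts
#'
#' Y index = 1000 * (summed counts over the four Y genes) / (total counts
#' over all mouse genes); an index strictly greater than `threshold`
#' calls the host male.
#'
#' @param count_matrix A `CountMatrix` containing the mouse genes.
#' @param y_genes The Y-chromosome reporter genes.
#' @param threshold Y-index cutoff (per-mille units).
#' @return Data frame with `sample_id`, `y_index`, `call`.
#' @export
predict_gender <- function(count_matrix, y_genes = Y_INDEX_GENES,
                           threshold = 10) {
  counts <- count_matrix$counts
  missing <- setdiff(y_genes, rownames(counts))
  if (length(missing))
    stop2("Y gene(s) absent from count matrix: ",
          paste(missing, collapse = ", "))
  mouse <- rownames(counts)[
    count_matrix$gene_species[rownames(counts)] == "MOUSE"]
  tot <- colSums(counts[mouse, , drop = FALSE])
  if (any(tot == 0))
    stop2("zero total mouse counts for sample ",
          colnames(counts)[which(tot == 0)[1]])
  ysum <- colSums(counts[y_genes, , drop = FALSE])
  y_index <- 1000 * ysum / tot
  data.frame(sample_id = colnames(counts), y_index = unname(y_index),
             call = ifelse(y_index > threshold, "male", "female"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group samples by MIF/Ddx6 expression (hypoxia proxy)
#'
#' Samples with high human MIF and low mouse Ddx6 form the putative
#' hypoxic group; low MIF with high Ddx6 the normoxic group; all others
#' are unassigned.  Thresholds are raw log2 FPKM.
#'
#' @param expr_human,expr_mouse FPKM-scale `ExpressionMatrix` objects
#'   sharing a sample set.
#' @param mif_hi,ddx6_lo Thresholds for the MIF-high/Ddx6-low group.
#' @param mif_lo,ddx6_hi Thresholds for the MIF-low/Ddx6-high group.
#' @param mif_gene,ddx6_gene Marker row IDs.
#' @return Data frame with `sample_id`, `group`.
#' @export
hypoxia_grouping <- function(expr_human, expr_mouse, mif_hi = 11.5,
                             ddx6_lo = 1.05, mif_lo = 7.0, ddx6_hi = 1.8,
                             mif_gene = "MIF", ddx6_gene = "Ddx6") {
  if (!mif_gene %in% rownames(expr_human$values))
    stop2("human marker row absent: ", mif_gene)
  if (!ddx6_gene %in% rownames(expr_mouse$values))
    stop2("mouse marker row absent: ", ddx6_gene)
  if (!identical(colnames(expr_human$values), colnames(expr_mouse$values)))
    stop2("human and mouse matrices disagree on samples")
  mif <- log2(expr_human$values[mif_gene, ])
  ddx6 <- log2(expr_mouse$values[ddx6_gene, ])
  group <- ifelse(mif > mif_hi & ddx6 < ddx6_lo, "MIF_high_Ddx6_low",
                  ifelse(mif < mif_lo & ddx6 > ddx6_hi, "MIF_low_Ddx6_high",
                         "unassigned"))
  data.frame(sample_id = colnames(expr_human$values), group = group,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean-expression signature score
#'
#' Per-sample mean of log-scale expression over the signature genes
#' present in the matrix; a simple stand-in where an external stromal
#' score is not available.
#'
#' @param expr LOG2_OFFSET-scale `ExpressionMatrix`.
#' @param signature Character vector of gene IDs.
#' @return Numeric vector of per-sample scores; attribute
#'   `n_missing` counts signature genes absent from the matrix.
#' @export
signature_score <- function(expr, signature) {
  present <- intersect(signature, rownames(expr$values))
  if (length(present) == 0)
    stop2("no signature genes present in the matrix")
  score <- colMeans(expr$values[present, , drop = FALSE])
  attr(score, "n_missing") <- length(setdiff(signature, present))
  score
}
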