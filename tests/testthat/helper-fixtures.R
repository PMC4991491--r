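# Shared fixtures, built in code at test time.

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A two-gene, two-transcript toy GTF (1-based inclusive coordinates).
toy_gtf_lines <- function() {
  attr1 <- 'gene_id "gA"; transcript_id "gA.t1"; gene_biotype "protein_coding";'
  attr2 <- 'gene_id "gA"; transcript_id "gA.t2"; gene_biotype "protein_coding";'
  attr3 <- 'gene_id "gB"; transcript_id "gB.t1"; gene_biotype "lincRNA";'
  c(paste("chr1", "src", "exon", 1, 100, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "src", "exon", 201, 300, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "src", "exon", 1, 100, ".", "+", ".", attr2, sep = "\t"),
    paste("chr1", "src", "exon", 151, 250, ".", "+", ".", attr2, sep = "\t"),
    paste("chr2", "src", "exon", 11, 60, ".", "-", ".", attr3, sep = "\t"))
}

# Brute-force exon-union length by per-base occupancy (oracle).
occupancy_union_length <- function(starts, ends, max_bp = 10000) {
  occ <- logical(max_bp)
  for (i in seq_along(starts)) occ[starts[i]:ends[i]] <- TRUE
  sum(occ)
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
# (oracle for small N).
enumerate_hyper_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # treat items 1..K as signature members
  mean(hits >= k)
}

# Naive double-loop Pearson correlation (oracle).
naive_correlation <- function(A, B) {
  out <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      x <- A[i, ]; y <- B[j, ]
      out[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    }
  }
  dimnames(out) <- list(rownames(A), rownames(B))
  out
}

# Convenience: mouse-side prepared log-expression matrix from a
# simulate_counts() result.
prep_species_log <- function(sim, species, spec = filter_spec()) {
  fp <- compute_fpkm(sim$counts, sim$gene_info)
  sp <- fp$gene_species[rownames(fp$values)]
  em <- expression_matrix(fp$values[sp == species, , drop = FALSE],
                          fp$gene_species[sp == species])
  to_nonneg_log(filter_genes(em, spec))
}
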