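#' Build a seed index over a concatenated two-species reference
#'
#' Every k-mer of every chromosome of both genomes is indexed (reads are
#' matched on both strands at query time).  Chromosome names must be
#' unique across species.
#'
#' @param fasta_by_species List `HUMAN`/`MOUSE` of named chromosome
#'   sequence vectors.
#' @param k Seed length in bp (>= 11; at 15% ortholog divergence a 21-mer
#'   is conserved with probability ~0.03, giving strong species
#'   separation).
#' @return A `SpeciesIndex` object.
#' @export
build_species_index <- function(fasta_by_species, k = 21) {
  check_species(names(fasta_by_species))
  seqs <- unlist(unname(lapply(fasta_by_species, function(x) x)))
  if (length(seqs) == 0 || any(!nzchar(seqs))) stop2("empty FASTA input")
  chrom_species <- unlist(lapply(names(fasta_by_species), function(sp)
    setNames(rep(sp, length(fasta_by_species[[sp]])),
             names(fasta_by_species[[sp]]))))
  if (anyDuplicated(names(chrom_species)))
    stop2("duplicate chromosome name across species: ",
          paste(unique(names(chrom_species)[duplicated(names(chrom_species))]),
                collapse = ", "))
  ptr <- .build_seed_index_cpp(names(chrom_species), unname(toupper(seqs)), k)
  structure(list(ptr = ptr, k = k,
                 chrom_names = names(chrom_species),
                 chrom_species = chrom_species),
            class = "SpeciesIndex")
}

#' @export
print.SpeciesIndex <- function(x, ...) {
  st <- .index_stats_cpp(x$ptr)
  cat("SpeciesIndex: k =", x$k, "|", length(x$chrom_names), "chromosomes |",
      st$n_kmers, "distinct k-mers\n")
  invisible(x)
}

#' Assign read pairs to a species by unique ungapped alignment
#'
#' Candidate loci are seed hits extended ungapped over the full mate.  A
#' locus is valid when each mate has at most `max_mismatch` mismatches,
#' the total mismatch/length ratio is at most `max_mm_ratio`, and the
#' mates land on the same chromosome in forward/reverse orientation within
#' `max_fragment`.  The call is the species of the single best valid
#' locus; ties at the minimum total mismatch count across two or more
#' distinct loci give AMBIGUOUS; no valid locus gives UNMAPPED.
#'
#' @param mate1,mate2 Named character vectors of mate sequences.
#' @param index A `SpeciesIndex`.
#' @param max_mismatch Per-mate mismatch cap.
#' @param max_mm_ratio Cap on total mismatches / total mapped length.
#' @param max_fragment Maximum fragment span in bp.
#' @return Data frame with `read_id`, `call`
#'   (HUMAN/MOUSE/AMBIGUOUS/UNMAPPED), best locus (`chrom`, `start`,
#'   `end`), per-mate mismatches and mate intervals.
#' @export
assign_read_pairs <- function(mate1, mate2, index, max_mismatch = 3,
                              max_mm_ratio = 0.10, max_fragment = 1000) {
  stopifnot(inherits(index, "SpeciesIndex"))
  if (length(mate1) != length(mate2)) stop2("mates differ in length")
  if (any(!nzchar(mate1)) || any(!nzchar(mate2)))
    stop2("empty mate sequence")
  res <- .assign_pairs_cpp(index$ptr, unname(toupper(mate1)),
                           unname(toupper(mate2)),
                           as.integer(max_mismatch), max_mm_ratio,
                           as.integer(max_fragment))
  if (any(res$short_mate))
    warning(sum(res$short_mate), " read pair(s) with a mate shorter than k=",
            index$k, " reported UNMAPPED")
  chrom <- ifelse(is.na(res$chrom_idx), NA_character_,
                  index$chrom_names[res$chrom_idx])
  call <- c("UNMAPPED", "MAPPED", "AMBIGUOUS")[res$status + 1L]
  call[call == "MAPPED"] <- unname(index$chrom_species[chrom[call == "MAPPED"]])
  data.frame(read_id = names(mate1) %||% sprintf("read%06d", seq_along(mate1)),
             call = call, chrom = chrom,
             start = res$start, end = res$end,
             mm1 = res$mm1, mm2 = res$mm2,
             start1 = res$start1, end1 = res$end1,
             start2 = res$start2, end2 = res$end2,
             stringsAsFactors = FALSE)
}

#' @rdname assign_read_pairs
#' @param pair List with elements `mate1` and `mate2` (single sequences).
#' @export
assign_read_pair <- function(pair, index, max_mismatch = 3,
                             max_mm_ratio = 0.10, max_fragment = 1000) {
  df <- assign_read_pairs(setNames(pair$mate1, "read"),
                          setNames(pair$mate2, "read"),
                          index, max_mismatch, max_mm_ratio, max_fragment)
  as.list(df[1, ])
}

new_count_matrix <- function(counts, gene_species, library_size) {
  stopifnot(all(counts >= 0), !is.null(rownames(counts)))
  structure(list(counts = counts, gene_species = gene_species,
                 library_size = library_size),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      sum(x$gene_species[rownames(x$counts)] == "HUMAN"), "human /",
      sum(x$gene_species[rownames(x$counts)] == "MOUSE"), "mouse )\n")
  invisible(x)
}

#' Count fragments per gene in union mode
#'
#' A fragment increments a gene if and only if the union of its two mates'
#' aligned intervals overlaps exons of exactly one gene (strand ignored;
#' the gap between mates is not counted).  Fragments overlapping zero or
#' two or more genes are dropped.  The library size per species is the
#' number of species-assigned fragments, counted or not.
#'
#' @param assignments Data frame from [assign_read_pairs()].
#' @param gene_models Combined `gene_models` for both species.
#' @param sample_id Sample label for the resulting column.
#' @param chrom_species Named vector chromosome -> species (for
#'   validation).
#' @return A single-sample `CountMatrix`.
#' @export
count_union <- function(assignments, gene_models, sample_id,
                        chrom_species = NULL) {
  called <- assignments[assignments$call %in% SPECIES_LEVELS, , drop = FALSE]
  ex <- gene_models$exons
  known <- unique(ex$chrom)
  if (!is.null(chrom_species)) known <- unique(c(known, names(chrom_species)))
  if (nrow(called) && any(!called$chrom %in% known))
    stop2("assignment references unknown chromosome: ",
          paste(unique(setdiff(called$chrom, known)), collapse = ", "))

  gene_ids <- gene_models$genes$gene_id
  counts <- matrix(0L, length(gene_ids), 1,
                   dimnames = list(gene_ids, sample_id))
  if (nrow(called)) {
    # two intervals per fragment (one per mate); gap between mates ignored
    frag <- GenomicRanges::GRanges(
      rep(called$chrom, 2),
      IRanges::IRanges(c(called$start1, called$start2),
                       c(called$end1, called$end2)))
    exr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
    ov <- GenomicRanges::findOverlaps(frag, exr, ignore.strand = TRUE)
    frag_idx <- ((S4Vectors::queryHits(ov) - 1L) %% nrow(called)) + 1L
    hit_gene <- ex$gene_id[S4Vectors::subjectHits(ov)]
    per_frag <- tapply(hit_gene, frag_idx, function(g) unique(g),
                       simplify = FALSE)
    uniq <- vapply(per_frag, length, 0L) == 1L
    tab <- table(unlist(per_frag[uniq]))
    counts[names(tab), 1] <- as.integer(tab)
  }
  gene_species <- setNames(gene_models$genes$species, gene_ids)
  lib <- matrix(c(sum(called$call == "HUMAN"), sum(called$call == "MOUSE")),
                2, 1, dimnames = list(SPECIES_LEVELS, sample_id))
  new_count_matrix(counts, gene_species, lib)
}

#' Combine single-sample CountMatrix columns
#'
#' @param ... `CountMatrix` objects sharing a gene universe.
#' @return A multi-sample `CountMatrix`.
#' @export
cbind_counts <- function(...) {
  xs <- list(...)
  g <- rownames(xs[[1]]$counts)
  for (x in xs) stopifnot(identical(rownames(x$counts), g))
  new_count_matrix(do.call(cbind, lapply(xs, `[[`, "counts")),
                   xs[[1]]$gene_species,
                   do.call(cbind, lapply(xs, `[[`, "library_size")))
}

#' Compute filtered FPKM from union-mode counts
#'
#' FPKM(g, s) = counts(g, s) * 1e9 / (exon_union_length(g) *
#' library_size(s, species(g))).  Genes failing the biotype or
#' transcript-length filter are removed before output.
#'
#' @param count_matrix A `CountMatrix`.
#' @param gene_models `gene_models` covering the count matrix genes, or a
#'   data frame with `gene_id`, `biotype`, `exon_union_length`,
#'   `largest_transcript_length` (a `length` column stands in for both
#'   lengths).
#' @param min_transcript_bp Genes whose largest transcript is shorter are
#'   removed (expression over very short transcripts is overestimated).
#' @param coding_only Keep only protein-coding genes.
#' @return An `ExpressionMatrix` on the FPKM scale.
#' @export
compute_fpkm <- function(count_matrix, gene_models, min_transcript_bp = 400,
                         coding_only = TRUE) {
  genes <- if (inherits(gene_models, "gene_models")) gene_models$genes
           else gene_models
  if (!is.null(genes$length) && is.null(genes$exon_union_length)) {
    genes$exon_union_length <- genes$length
    genes$largest_transcript_length <- genes$length
  }
  counts <- count_matrix$counts
  genes <- genes[match(rownames(counts), genes$gene_id), , drop = FALSE]
  if (anyNA(genes$gene_id))
    stop2("gene models missing for some counted genes")

  keep <- genes$largest_transcript_length >= min_transcript_bp
  if (coding_only) keep <- keep & genes$biotype == "protein_coding"
  counts <- counts[keep, , drop = FALSE]
  genes <- genes[keep, , drop = FALSE]

  sp <- count_matrix$gene_species[rownames(counts)]
  lib <- count_matrix$library_size
  bad <- which(lib == 0, arr.ind = TRUE)
  used_species <- unique(sp)
  bad <- bad[rownames(lib)[bad[, 1]] %in% used_species, , drop = FALSE]
  if (nrow(bad))
    stop2("zero library size for sample ", colnames(lib)[bad[1, 2]],
          ", species ", rownames(lib)[bad[1, 1]], "; FPKM undefined")
  libg <- lib[sp, , drop = FALSE]   # per-gene row of the right species
  fpkm <- counts * 1e9 / (genes$exon_union_length * libg)
  new_expression_matrix(fpkm, scale = "FPKM", gene_species = sp,
                        filters_applied = c(
                          sprintf("largest_transcript>=%dbp", min_transcript_bp),
                          if (coding_only) "protein_coding_only"))
}

#' Human fraction of species-assigned fragments
#'
#' @param count_matrix A `CountMatrix` with per-species library sizes.
#' @param sample_id Sample to report.
#' @return Human assigned fragments / (human + mouse assigned fragments).
#' @export
species_proportion <- function(count_matrix, sample_id) {
  lib <- count_matrix$library_size[, sample_id]
  tot <- lib[["HUMAN"]] + lib[["MOUSE"]]
  if (tot == 0) stop2("no assigned fragments for sample ", sample_id)
  lib[["HUMAN"]] / tot
}
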