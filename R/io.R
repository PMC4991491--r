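#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and sequence identifiers (the first
#' whitespace-delimited token of each header) must be unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop2("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop2("duplicate sequence ID(s) in ", path, ": ",
          paste(unique(dup), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  x <- Biostrings::DNAStringSet(unname(toupper(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read paired FASTQ files
#'
#' @param path1,path2 Paths to the two mate files.
#' @return List with named character vectors `mate1` and `mate2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    out
  }
  m1 <- rd(path1); m2 <- rd(path2)
  if (!identical(names(m1), names(m2)))
    stop2("mate files disagree on read IDs or order")
  list(mate1 = m1, mate2 = m2)
}

#' Write paired reads as two FASTQ files
#'
#' Base qualities are constant ("I"); the simulator models substitution
#' errors directly rather than through quality strings.
#'
#' @param mate1,mate2 Named character vectors of read sequences.
#' @param path1,path2 Output paths.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(mate1, mate2, path1, path2) {
  wr <- function(reads, p) {
    lines <- character(4L * length(reads))
    lines[seq(1, length(lines), 4)] <- paste0("@", names(reads))
    lines[seq(2, length(lines), 4)] <- unname(reads)
    lines[seq(3, length(lines), 4)] <- "+"
    lines[seq(4, length(lines), 4)] <- strrep("I", nchar(reads))
    writeLines(lines, p)
  }
  wr(mate1, path1); wr(mate2, path2)
  invisible(c(path1, path2))
}

#' Read gene models from a GTF file (Ensembl dialect)
#'
#' Exon records are grouped by gene and transcript; per gene the length of
#' the union of all exon intervals and the length of the largest transcript
#' (sum of its exon lengths) are computed.  GTF coordinates are 1-based
#' inclusive; internal interval arithmetic is 0-based half-open.
#'
#' @param path Path to a GTF file.
#' @param species_tag Species of every gene in this file
#'   (`"HUMAN"` or `"MOUSE"`).
#' @return A `gene_models` object: list with `genes` (data frame with
#'   `gene_id`, `species`, `chrom`, `strand`, `biotype`,
#'   `exon_union_length`, `largest_transcript_length`) and `exons`
#'   (data frame of exon intervals with `gene_id`/`transcript_id`).
#' @export
read_gtf <- function(path, species_tag) {
  check_species(species_tag)
  if (!file.exists(path)) stop2("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop2("failed to parse GTF ", path, ": ",
                                           conditionMessage(e)))
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) stop2("no exon records in ", path)
  if (is.null(ex$transcript_id) ||
      any(is.na(ex$transcript_id) | ex$transcript_id == ""))
    stop2("exon record without transcript_id in ", path)
  if (is.null(ex$gene_id) || any(is.na(ex$gene_id) | ex$gene_id == ""))
    stop2("exon record without gene_id in ", path)
  exons <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),   # 1-based inclusive as in file
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id,
    stringsAsFactors = FALSE)
  biotype <- ex$gene_biotype %||% rep(NA_character_, length(ex))
  gene_models_from_exons(exons, species_tag,
                         biotype = tapply(biotype, exons$gene_id, `[`, 1))
}

#' Assemble gene models from an exon table
#'
#' @param exons Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `gene_id`, `transcript_id`.
#' @param species_tag `"HUMAN"` or `"MOUSE"`.
#' @param biotype Optional named vector of gene biotypes (default
#'   `"protein_coding"`).
#' @return A `gene_models` object.
#' @export
gene_models_from_exons <- function(exons, species_tag, biotype = NULL) {
  check_species(species_tag)
  if (any(exons$start > exons$end))
    stop2("exon with start > end for gene ",
          exons$gene_id[which(exons$start > exons$end)[1]])
  gids <- unique(exons$gene_id)
  grl <- GenomicRanges::GRanges(exons$chrom,
                                IRanges::IRanges(exons$start, exons$end))
  red <- GenomicRanges::reduce(S4Vectors::split(grl, exons$gene_id))
  union_len <- vapply(red, function(g) sum(GenomicRanges::width(g)), 0)
  tx_len <- tapply(exons$end - exons$start + 1,
                   list(exons$gene_id, exons$transcript_id), sum)
  largest <- apply(tx_len, 1, max, na.rm = TRUE)
  first <- match(gids, exons$gene_id)
  bt <- if (is.null(biotype)) setNames(rep("protein_coding", length(gids)), gids)
        else biotype
  genes <- data.frame(
    gene_id = gids,
    species = species_tag,
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    biotype = ifelse(is.na(bt[gids]), "protein_coding", bt[gids]),
    exon_union_length = as.integer(union_len[gids]),
    largest_transcript_length = as.integer(largest[gids]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Combine gene models from several species
#'
#' @param ... `gene_models` objects.
#' @return A single `gene_models` object.
#' @export
combine_gene_models <- function(...) {
  xs <- list(...)
  genes <- do.call(rbind, lapply(xs, `[[`, "genes"))
  if (anyDuplicated(genes$gene_id))
    stop2("duplicate gene_id across combined gene models")
  structure(list(genes = genes,
                 exons = do.call(rbind, lapply(xs, `[[`, "exons"))),
            class = "gene_models")
}

#' Write gene models as a GTF file
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  ex <- models$exons
  bt <- setNames(models$genes$biotype, models$genes$gene_id)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                   ex$gene_id, ex$transcript_id, bt[ex$gene_id])
  lines <- paste(ex$chrom, "toy", "exon", ex$start, ex$end, ".",
                 ex$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene signatures in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.  Gene lists
#' are deduplicated preserving first occurrence.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene IDs; each element
#'   carries a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) == 2)
      stop2("GMT line ", i, " has an empty gene list")
    if (length(f) < 3)
      stop2("GMT line ", i, " has fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop2("GMT line ", i, " has an empty gene list")
    attr(genes, "description") <- f[2]
    out[[f[1]]] <- genes
  }
  out
}

#' Write gene signatures in GMT format
#'
#' @param signatures Named list of character vectors (optionally carrying a
#'   `description` attribute).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(names(signatures), function(nm) {
    g <- signatures[[nm]]
    d <- attr(g, "description") %||% nm
    paste(c(nm, d, as.character(g)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a numeric gene-by-sample matrix as TSV
#'
#' First column is `gene_id`; the header row carries sample IDs.  All cells
#' must be present (no missing markers).
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  if (anyNA(mat)) stop2("matrix contains missing values; all cells required")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample matrix TSV
#'
#' @param path Path written by [write_matrix_tsv()].
#' @return Numeric matrix with gene IDs as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyNA(df)) stop2("missing values in matrix TSV ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write the chromosome-to-species sidecar table
#'
#' Two tab-separated columns: `chrom`, `species`.  When no table is given
#' elsewhere, chromosome names prefixed `hs_`/`mm_` fall back to
#' HUMAN/MOUSE.
#'
#' @param path Path to the table.
#' @return Named character vector mapping chromosome to species.
#' @export
read_species_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_species(df$species)
  setNames(df$species, df$chrom)
}

#' @rdname read_species_table
#' @param chrom_species Named character vector (chrom -> species).
#' @export
write_species_table <- function(chrom_species, path) {
  write.table(data.frame(chrom = names(chrom_species),
                         species = unname(chrom_species)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Infer species from chromosome-name prefixes
#'
#' @param chroms Character vector of chromosome names.
#' @return Named character vector mapping each chromosome to a species.
#' @export
species_from_prefix <- function(chroms) {
  sp <- ifelse(startsWith(chroms, "hs_"), "HUMAN",
               ifelse(startsWith(chroms, "mm_"), "MOUSE", NA))
  if (anyNA(sp))
    stop2("cannot infer species for chromosome(s): ",
          paste(chroms[is.na(sp)], collapse = ", "),
          " (expected hs_/mm_ prefix or a species table)")
  setNames(sp, chroms)
}

#' Write a correlation network as an edge-list TSV
#'
#' One row per undirected edge with `node_a < node_b` lexicographically;
#' columns `node_a`, `node_b`, `r`, `edge_class`.
#'
#' @param network A `CorrelationNetwork` (see [build_network()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  e <- network$edges
  swap <- e$gene_a > e$gene_b
  a <- ifelse(swap, e$gene_b, e$gene_a)
  b <- ifelse(swap, e$gene_a, e$gene_b)
  df <- data.frame(node_a = a, node_b = b, r = e$r,
                   edge_class = e$edge_class, stringsAsFactors = FALSE)
  df <- df[order(df$node_a, df$node_b), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV back into a CorrelationNetwork
#'
#' @param path Path written by [write_edge_list()].
#' @param threshold Absolute-correlation threshold recorded on the object.
#' @param species_of Named character vector gene -> species; when NULL the
#'   species is inferred from the stored edge classes where unambiguous.
#' @return A `CorrelationNetwork`.
#' @export
read_edge_list <- function(path, threshold = NA_real_, species_of = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  edges <- data.frame(gene_a = df$node_a, gene_b = df$node_b, r = df$r,
                      edge_class = df$edge_class, stringsAsFactors = FALSE)
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  structure(list(edges = edges, nodes = nodes, threshold = threshold,
                 species_of = species_of),
            class = "CorrelationNetwork")
}

#' Write a run report as JSON
#'
#' @param report Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
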