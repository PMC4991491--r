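#' Synthetic two-species data with known ground truth
#'
#' The generator emulates the statistical structure a compartment-resolved
#' PDX workflow consumes: a mixed human/mouse read population over a
#' concatenated reference, and count matrices carrying planted cluster,
#' cross-species coupling, differential-expression and host-gender
#' structure.  Ground truth is returned alongside every artefact so that
#' recovery can be measured.
#'
#' @name synthetic
NULL

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

mutate_seq <- function(seq, rate) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(b)) < rate
  if (any(hit)) {
    # substitution to one of the three other bases, uniformly
    b[hit] <- vapply(b[hit], function(x) sample(setdiff(BASES, x), 1), "")
  }
  paste(b, collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                "", USE.NAMES = FALSE))
}

#' Generate toy human and mouse genomes with ortholog pairs
#'
#' Each species receives `n_ortholog_genes` orthologous genes plus
#' `n_private_per_species` private genes.  A mouse ortholog is its human
#' counterpart with i.i.d. substitutions at rate `divergence`.  Genes are
#' single-exon, protein-coding, and laid out on chromosomes (`hs_*` /
#' `mm_*`) separated by random intergenic spacers.
#'
#' @param n_ortholog_genes Number of ortholog pairs.
#' @param n_private_per_species Species-private genes per species.
#' @param gene_length_bp Gene length (>= 400 so genes pass the
#'   transcript-length filter).
#' @param divergence Per-base ortholog substitution rate in \[0, 0.5\].
#' @param seed Integer RNG seed.
#' @param genes_per_chrom Genes placed per chromosome.
#' @param spacer_bp Intergenic spacer length.
#' @return List with `fasta` (list `HUMAN`/`MOUSE` of named chromosome
#'   sequences), `models` (list `HUMAN`/`MOUSE` of `gene_models`),
#'   `chrom_species`, and `truth` (ortholog table, parameters).
#' @export
make_toy_genomes <- function(n_ortholog_genes = 30, n_private_per_species = 20,
                             gene_length_bp = 600, divergence = 0.15, seed = 1,
                             genes_per_chrom = 10, spacer_bp = 150) {
  if (divergence < 0 || divergence > 0.5)
    stop2("divergence must be in [0, 0.5]")
  if (gene_length_bp < 400)
    stop2("gene_length_bp must be >= 400 to pass the transcript-length filter")
  set.seed(seed)
  n_genes <- n_ortholog_genes + n_private_per_species

  hs_genes <- vapply(seq_len(n_genes), function(i) random_seq(gene_length_bp), "")
  mm_genes <- character(n_genes)
  if (n_ortholog_genes > 0)
    mm_genes[seq_len(n_ortholog_genes)] <-
      vapply(hs_genes[seq_len(n_ortholog_genes)], mutate_seq, "",
             rate = divergence, USE.NAMES = FALSE)
  if (n_private_per_species > 0)
    mm_genes[n_ortholog_genes + seq_len(n_private_per_species)] <-
      vapply(seq_len(n_private_per_species), function(i)
        random_seq(gene_length_bp), "")

  build_species <- function(gene_seqs, prefix, chrom_prefix) {
    n <- length(gene_seqs)
    gene_ids <- sprintf("%sGENE%04d", prefix, seq_len(n))
    chrom_of <- ceiling(seq_len(n) / genes_per_chrom)
    chroms <- character(max(chrom_of))
    exons <- vector("list", n)
    for (ci in seq_len(max(chrom_of))) {
      idx <- which(chrom_of == ci)
      pieces <- character(0)
      pos <- 0L
      cname <- sprintf("%s%d", chrom_prefix, ci)
      for (g in idx) {
        sp <- random_seq(spacer_bp)
        pieces <- c(pieces, sp, gene_seqs[g])
        start <- pos + spacer_bp + 1L
        end <- start + nchar(gene_seqs[g]) - 1L
        exons[[g]] <- data.frame(chrom = cname, start = start, end = end,
                                 strand = "+", gene_id = gene_ids[g],
                                 transcript_id = paste0(gene_ids[g], ".t1"),
                                 stringsAsFactors = FALSE)
        pos <- end
      }
      pieces <- c(pieces, random_seq(spacer_bp))
      chroms[ci] <- paste(pieces, collapse = "")
      names(chroms)[ci] <- cname
    }
    list(fasta = chroms, exons = do.call(rbind, exons), gene_ids = gene_ids)
  }

  hs <- build_species(hs_genes, "hs", "hs_")
  mm <- build_species(mm_genes, "mm", "mm_")
  models <- list(HUMAN = gene_models_from_exons(hs$exons, "HUMAN"),
                 MOUSE = gene_models_from_exons(mm$exons, "MOUSE"))
  chrom_species <- c(setNames(rep("HUMAN", length(hs$fasta)), names(hs$fasta)),
                     setNames(rep("MOUSE", length(mm$fasta)), names(mm$fasta)))
  orthologs <- if (n_ortholog_genes > 0)
    data.frame(human_gene = hs$gene_ids[seq_len(n_ortholog_genes)],
               mouse_gene = mm$gene_ids[seq_len(n_ortholog_genes)],
               stringsAsFactors = FALSE)
  else data.frame(human_gene = character(0), mouse_gene = character(0))
  list(fasta = list(HUMAN = hs$fasta, MOUSE = mm$fasta),
       models = models,
       chrom_species = chrom_species,
       truth = list(orthologs = orthologs, divergence = divergence,
                    gene_length_bp = gene_length_bp, seed = seed))
}

#' Simulate an unstranded paired-end read mixture from two species
#'
#' Each fragment is drawn from HUMAN with probability `human_proportion`,
#' then uniformly from that species' gene bodies; sequencing errors are
#' i.i.d. substitutions.  Mates are reported in forward /
#' reverse-complement orientation of a randomly oriented fragment.
#'
#' @param genomes Output of [make_toy_genomes()].
#' @param human_proportion Probability a fragment is human.
#' @param n_read_pairs Number of read pairs (> 0).
#' @param read_length Read length (<= `fragment_length`).
#' @param error_rate Per-base substitution error rate.
#' @param fragment_length Fixed fragment length (<= gene length).
#' @param seed Integer RNG seed.
#' @return List with `mate1`, `mate2` (named character vectors) and
#'   `truth` data frame (`read_id`, `species`, `gene_id`).
#' @export
simulate_reads <- function(genomes, human_proportion = 0.88,
                           n_read_pairs = 20000, read_length = 100,
                           error_rate = 0.005, fragment_length = 300,
                           seed = 1) {
  if (n_read_pairs <= 0) stop2("n_read_pairs must be positive")
  if (human_proportion < 0 || human_proportion > 1)
    stop2("human_proportion must be in [0, 1]")
  gene_len <- genomes$truth$gene_length_bp
  if (read_length > fragment_length || fragment_length > gene_len)
    stop2("need read_length <= fragment_length <= gene length")
  set.seed(seed)

  gene_seq <- list()
  for (sp in SPECIES_LEVELS) {
    ex <- genomes$models[[sp]]$exons
    fa <- genomes$fasta[[sp]]
    gene_seq[[sp]] <- setNames(
      substr(fa[ex$chrom], ex$start, ex$end), ex$gene_id)
  }

  species <- ifelse(runif(n_read_pairs) < human_proportion, "HUMAN", "MOUSE")
  read_id <- sprintf("read%06d", seq_len(n_read_pairs))
  mate1 <- character(n_read_pairs); mate2 <- character(n_read_pairs)
  gene_of <- character(n_read_pairs)
  for (i in seq_len(n_read_pairs)) {
    pool <- gene_seq[[species[i]]]
    g <- sample(length(pool), 1)
    gene_of[i] <- names(pool)[g]
    src <- pool[[g]]
    start <- sample(nchar(src) - fragment_length + 1L, 1)
    frag <- substr(src, start, start + fragment_length - 1L)
    if (runif(1) < 0.5) frag <- revcomp(frag)       # unstranded library
    r1 <- substr(frag, 1, read_length)
    r2 <- revcomp(substr(frag, fragment_length - read_length + 1L,
                         fragment_length))
    if (error_rate > 0) {
      r1 <- mutate_seq(r1, error_rate)
      r2 <- mutate_seq(r2, error_rate)
    }
    mate1[i] <- r1; mate2[i] <- r2
  }
  names(mate1) <- read_id; names(mate2) <- read_id
  list(mate1 = mate1, mate2 = mate2,
       truth = data.frame(read_id = read_id, species = species,
                          gene_id = gene_of, stringsAsFactors = FALSE))
}

Y_INDEX_GENES <- c("Eif2s3y", "Ddx3y", "Kdm5d", "Uty")

#' Simulate a two-species count matrix with planted structure
#'
#' Counts are negative binomial (variance mu + alpha * mu^2) around a mean
#' matrix with: `planted_k` sample clusters expressed through mouse-gene
#' blocks (`cluster_strength` = within-cluster log2 elevation); coupled
#' human/mouse gene pairs sharing a per-sample latent factor (negative
#' loading on one member for anti-correlation); an optional human hub gene
#' coupled to several mouse partners; `n_de_genes` human genes elevated by
#' `de_log2fc` in subtype "B"; and the four Y-chromosome genes expressed
#' only in male hosts.  Human genes carry ~`human_fraction` of the library.
#'
#' @param n_samples Number of samples (>= 2 * `planted_k`).
#' @param n_human_genes,n_mouse_genes Genes per species.
#' @param planted_k Number of planted sample clusters (>= 2).
#' @param cluster_strength log2 elevation of a cluster's gene block within
#'   its cluster (0 = no planted structure).
#' @param n_coupled_pairs Cross-species coupled gene pairs (signs alternate
#'   starting anti-correlated).
#' @param hub_partners Mouse partner count of a single human hub gene
#'   (0 disables the hub).
#' @param n_de_genes Human genes differentially expressed in subtype "B".
#' @param de_log2fc Planted log2 fold change.
#' @param nb_dispersion NB dispersion alpha.
#' @param gender_ratio Probability a host is male.
#' @param coupling_strength log2 amplitude of the shared latent factor.
#' @param human_fraction Expected human share of the library.
#' @param seed Integer RNG seed.
#' @return List with `counts` (a `CountMatrix`), `metadata` (data frame),
#'   `gene_info` (gene_id, species, length, biotype), and `truth`.
#' @export
simulate_counts <- function(n_samples = 79, n_human_genes = 2000,
                            n_mouse_genes = 800, planted_k = 3,
                            cluster_strength = 1.0, n_coupled_pairs = 5,
                            hub_partners = 0, n_de_genes = 50, de_log2fc = 2,
                            nb_dispersion = 0.1, gender_ratio = 0.5,
                            coupling_strength = 2.0, human_fraction = 0.88,
                            seed = 1) {
  if (planted_k < 2) stop2("planted_k must be >= 2")
  if (n_samples < 2 * planted_k) stop2("need n_samples >= 2 * planted_k")
  if (n_mouse_genes < 4 + planted_k + n_coupled_pairs + hub_partners)
    stop2("n_mouse_genes too small for the requested planted structure")
  if (n_human_genes < n_coupled_pairs + n_de_genes + 1)
    stop2("n_human_genes too small for the requested planted structure")
  set.seed(seed)

  sample_id <- sprintf("PDX%03d", seq_len(n_samples))
  hs_ids <- sprintf("hsGENE%04d", seq_len(n_human_genes))
  mm_ids <- c(sprintf("mmGENE%04d", seq_len(n_mouse_genes - 4)), Y_INDEX_GENES)
  gene_id <- c(hs_ids, mm_ids)
  species <- c(rep("HUMAN", n_human_genes), rep("MOUSE", n_mouse_genes))

  cluster <- rep_len(seq_len(planted_k), n_samples)
  subtype <- rep_len(c("A", "B"), n_samples)
  gender <- ifelse(runif(n_samples) < gender_ratio, "male", "female")

  base <- rlnorm_safe(n_human_genes + n_mouse_genes, log(80), 1)
  names(base) <- gene_id
  # scale species totals to the requested human library share
  hum <- species == "HUMAN"
  sc <- (human_fraction / (1 - human_fraction)) * sum(base[!hum]) / sum(base[hum])
  base[hum] <- base[hum] * sc

  log2mult <- matrix(0, n_human_genes + n_mouse_genes, n_samples,
                     dimnames = list(gene_id, sample_id))

  # Rank-k mixture structure on the mouse compartment: every sample is a
  # positive combination of k latent cell-type programs with a dominant
  # component given by its cluster (continuous coefficients, not hard
  # blocks — the regime consensus NMF is designed for).  Mouse genes have
  # a "home" program (round-robin); special genes (couplings, hub, Y)
  # stay flat so their planted structure is not confounded.
  mm_regular <- setdiff(mm_ids, Y_INDEX_GENES)
  factor_of <- setNames(rep_len(seq_len(planted_k), length(mm_regular)),
                        mm_regular)
  n_special_mm <- n_coupled_pairs + hub_partners
  struct_mm <- if (length(mm_regular) > n_special_mm)
    mm_regular[(n_special_mm + 1):length(mm_regular)] else character(0)
  if (cluster_strength > 0 && length(struct_mm)) {
    Hlat <- matrix(rgamma(planted_k * n_samples, shape = 2, rate = 2),
                   planted_k, n_samples)
    # a quarter of samples have a mixed stromal phenotype: their dominant
    # program is only moderately elevated, as in hosts recruiting several
    # cell types
    mixed_sample <- seq_len(n_samples) %% 4 == 0
    dom <- ifelse(mixed_sample, 1 + 0.4 * cluster_strength,
                  1 + cluster_strength)
    Hlat[cbind(cluster, seq_len(n_samples))] <-
      dom * rgamma(n_samples, shape = 8, rate = 8)
    Wlat <- matrix(rgamma(length(struct_mm) * planted_k, shape = 1,
                          rate = 10), length(struct_mm), planted_k)
    Wlat[cbind(seq_along(struct_mm), factor_of[struct_mm])] <-
      rgamma(length(struct_mm), shape = 8, rate = 8)
    # balance program masses so no merge of programs is systematically
    # preferred (cell-type programs carry comparable transcriptional mass)
    mass <- colSums(base[struct_mm] * Wlat)
    Wlat <- sweep(Wlat, 2, mean(mass) / mass, `*`)
    mix <- Wlat %*% Hlat
    mix <- mix / rowMeans(mix)            # keep b_g as the base level
    # keep per-sample mouse totals stable (compositional normalization)
    colfac <- colSums(base[struct_mm] * mix) / sum(base[struct_mm])
    mix <- sweep(mix, 2, colfac, `/`)
    log2mult[struct_mm, ] <- log2mult[struct_mm, ] + log2(mix)
  }

  # cross-species coupled pairs: shared standard-normal latent factor
  coupled <- NULL
  used_hs <- character(0); used_mm <- character(0)
  if (n_coupled_pairs > 0) {
    ch <- hs_ids[seq_len(n_coupled_pairs)]
    cm <- mm_regular[seq_len(n_coupled_pairs)]
    sign <- rep_len(c(-1, 1), n_coupled_pairs)
    for (i in seq_len(n_coupled_pairs)) {
      u <- rnorm(n_samples)
      log2mult[ch[i], ] <- log2mult[ch[i], ] + coupling_strength * u
      log2mult[cm[i], ] <- log2mult[cm[i], ] + sign[i] * coupling_strength * u
    }
    coupled <- data.frame(human_gene = ch, mouse_gene = cm, sign = sign,
                          stringsAsFactors = FALSE)
    used_hs <- ch; used_mm <- cm
  }

  # single human hub anti-coupled to several mouse partners
  hub <- NULL
  if (hub_partners > 0) {
    hub_gene <- setdiff(hs_ids, used_hs)[1]
    partners <- setdiff(mm_regular, used_mm)[seq_len(hub_partners)]
    v <- rnorm(n_samples)
    log2mult[hub_gene, ] <- log2mult[hub_gene, ] + coupling_strength * v
    for (p in partners)
      log2mult[p, ] <- log2mult[p, ] - coupling_strength * v
    hub <- list(human_gene = hub_gene, mouse_partners = partners)
    used_hs <- c(used_hs, hub_gene); used_mm <- c(used_mm, partners)
  }

  # subtype-specific differential expression on human genes
  de_genes <- character(0)
  if (n_de_genes > 0) {
    de_genes <- setdiff(hs_ids, used_hs)[seq_len(n_de_genes)]
    log2mult[de_genes, subtype == "B"] <-
      log2mult[de_genes, subtype == "B"] + de_log2fc
  }

  # Y-index genes: high in male hosts, near-zero in female hosts
  y_base <- 6 * median(base[mm_regular])   # male Y index lands ~15-20 per-mille
  base[Y_INDEX_GENES] <- y_base
  log2mult[Y_INDEX_GENES, gender == "female"] <- log2(0.01 / y_base)

  lib_factor <- rlnorm_safe(n_samples, 0, 0.15)
  mu <- sweep(base * 2^log2mult, 2, lib_factor, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))

  gene_species <- setNames(species, gene_id)
  lib <- rbind(HUMAN = colSums(counts[hum, , drop = FALSE]),
               MOUSE = colSums(counts[!hum, , drop = FALSE]))
  cm_obj <- new_count_matrix(counts, gene_species, lib)
  gene_info <- data.frame(gene_id = gene_id, species = species,
                          length = 1000L, biotype = "protein_coding",
                          stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = sample_id,
                         model_id = sample_id,
                         cancer_type = c("lung", "breast", "colon")[
                           rep_len(1:3, n_samples)],
                         provider = "synthetic",
                         mouse_strain = c("NSG", "SCID")[rep_len(1:2, n_samples)],
                         tumor_stage = "primary",
                         subtype = subtype,
                         stringsAsFactors = FALSE)
  truth <- list(planted_k = planted_k,
                cluster_of_sample = setNames(cluster, sample_id),
                coupled_pairs = coupled, hub = hub,
                de_genes = setNames(rep(de_log2fc, length(de_genes)), de_genes),
                gender_of_sample = setNames(gender, sample_id),
                species_proportion = human_fraction,
                cluster_strength = cluster_strength, seed = seed)
  list(counts = cm_obj, metadata = metadata, gene_info = gene_info,
       truth = truth)
}

rlnorm_safe <- function(n, meanlog, sdlog) exp(rnorm(n, meanlog, sdlog))

#' Simulate a simple two-group NB count matrix for DE benchmarking
#'
#' A lean generator for differential-expression calibration and marker
#' triangulation: all genes share mean `mu`; genes in `de_idx` are
#' multiplied by `2^lfc` in group 2.
#'
#' @param n_per_group Samples per group (length-2 vector or scalar).
#' @param n_genes Number of genes.
#' @param de_idx Integer indices (or gene names) of DE genes.
#' @param lfc Planted log2 fold change (group 2 vs group 1).
#' @param mu Baseline NB mean.
#' @param dispersion NB dispersion alpha.
#' @param seed Integer RNG seed.
#' @param gene_ids Optional gene names.
#' @return List with `counts` (matrix), `group` (factor) and `de_genes`.
#' @export
simulate_de_counts <- function(n_per_group = c(5, 5), n_genes = 2000,
                               de_idx = integer(0), lfc = 2, mu = 100,
                               dispersion = 0.1, seed = 1, gene_ids = NULL) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  set.seed(seed)
  n <- sum(n_per_group)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  group <- factor(rep(c("g1", "g2"), n_per_group))
  m <- matrix(mu, n_genes, n, dimnames = list(gene_ids, sprintf("s%03d", 1:n)))
  if (is.character(de_idx)) de_idx <- match(de_idx, gene_ids)
  if (length(de_idx)) m[de_idx, group == "g2"] <- mu * 2^lfc
  counts <- matrix(rnbinom(length(m), mu = m, size = 1 / dispersion),
                   nrow = n_genes, dimnames = dimnames(m))
  list(counts = counts, group = group, de_genes = gene_ids[de_idx])
}

#' Build synthetic GMT signatures from planted DE truth
#'
#' Produces one signature drawn from the planted DE genes (fully enriched)
#' and one pure-decoy signature disjoint from them.
#'
#' @param truth Truth list from [simulate_counts()].
#' @param gene_info Gene table from [simulate_counts()].
#' @param n_in_signature Genes sampled from the planted DE set.
#' @param n_decoys Genes in the decoy signature.
#' @param seed Integer RNG seed.
#' @return Named list of signatures suitable for [write_gmt()].
#' @export
make_signatures <- function(truth, gene_info, n_in_signature = 20,
                            n_decoys = 50, seed = 1) {
  de <- names(truth$de_genes)
  if (n_in_signature > length(de))
    stop2("n_in_signature exceeds the number of planted DE genes (",
          length(de), ")")
  non_de <- setdiff(gene_info$gene_id[gene_info$species == "HUMAN"], de)
  if (n_decoys > length(non_de))
    stop2("n_decoys exceeds the number of available non-DE genes")
  set.seed(seed)
  enriched <- sample(de, n_in_signature)
  decoy <- sample(non_de, n_decoys)
  attr(enriched, "description") <- "planted DE-enriched signature"
  attr(decoy, "description") <- "pure decoy signature"
  list(DE_ENRICHED = enriched, DECOY = decoy)
}
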