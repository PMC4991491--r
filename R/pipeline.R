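PIPELINE_STAGES <- c("simulate", "disambiguate", "quantify", "prep",
                     "cluster", "network", "de", "overlap", "gender")

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected.  One global seed is expanded
#' deterministically into per-stage seeds so stages stay reproducible
#' independently of which stages are enabled.
#'
#' @param output_dir Run directory.
#' @param seed Global integer seed.
#' @param stages Character vector of enabled stages (subset of
#'   simulate, disambiguate, quantify, prep, cluster, network, de,
#'   overlap, gender).
#' @param params Named list of per-stage parameter overrides; allowed
#'   names are the stage names.
#' @return A validated `RunConfig`.
#' @export
run_config <- function(output_dir, seed = 1, stages = PIPELINE_STAGES,
                       params = list()) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop2("unknown stage(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(params), PIPELINE_STAGES)
  if (length(bad)) stop2("unknown config key(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  stage_seeds <- setNames(sample.int(.Machine$integer.max - 1,
                                     length(PIPELINE_STAGES)),
                          PIPELINE_STAGES)
  structure(list(output_dir = output_dir, seed = seed, stages = stages,
                 params = params, stage_seeds = stage_seeds),
            class = "RunConfig")
}

stage_hash <- function(config, stage) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(list(seed = config$seed,
                                   params = config$params[[stage]]),
                              auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

stage_done <- function(config, stage, files) {
  hf <- file.path(config$output_dir, paste0(".", stage, ".hash"))
  file.exists(hf) && identical(readLines(hf)[1], stage_hash(config, stage)) &&
    all(file.exists(file.path(config$output_dir, files)))
}

mark_stage <- function(config, stage) {
  writeLines(stage_hash(config, stage),
             file.path(config$output_dir, paste0(".", stage, ".hash")))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in order — simulate (toy genomes, read
#' mixture, structured count matrix), disambiguate, quantify, prep,
#' cluster, network, de, overlap, gender — writing each stage's
#' artefacts into the run directory and a JSON run report at the end.
#' Re-running with an identical configuration skips stages whose outputs
#' exist and whose parameter hash is unchanged.
#'
#' @param config A [run_config()].
#' @return The run report (named list), invisibly; also written as
#'   `run_report.json` in the run directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  par <- function(stage, name, default) {
    config$params[[stage]][[name]] %||% default
  }
  report <- list(config = list(seed = config$seed, stages = config$stages,
                               params = config$params))
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, files, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    if (stage_done(config, stage, files)) {
      report$stages[[stage]] <<- list(skipped = TRUE, outputs = files)
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e)
      stop2("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
    mark_stage(config, stage)
    report$stages[[stage]] <<- c(list(skipped = FALSE, outputs = files), res)
    invisible(NULL)
  }

  run_stage("simulate", c("human.fa", "mouse.fa", "toy.gtf", "reads_1.fastq",
                          "reads_2.fastq", "counts.tsv", "truth.json"), function() {
    sd <- config$stage_seeds[["simulate"]]
    gen <- make_toy_genomes(
      n_ortholog_genes = par("simulate", "n_ortholog_genes", 30),
      n_private_per_species = par("simulate", "n_private_per_species", 20),
      gene_length_bp = par("simulate", "gene_length_bp", 600),
      divergence = par("simulate", "divergence", 0.15), seed = sd)
    rd <- simulate_reads(gen,
      human_proportion = par("simulate", "human_proportion", 0.88),
      n_read_pairs = par("simulate", "n_read_pairs", 5000),
      read_length = par("simulate", "read_length", 100),
      error_rate = par("simulate", "error_rate", 0.005),
      fragment_length = par("simulate", "fragment_length", 300), seed = sd + 1)
    cnt <- simulate_counts(
      n_samples = par("simulate", "n_samples", 40),
      n_human_genes = par("simulate", "n_human_genes", 400),
      n_mouse_genes = par("simulate", "n_mouse_genes", 200),
      planted_k = par("simulate", "planted_k", 3),
      cluster_strength = par("simulate", "cluster_strength", 1.0),
      n_coupled_pairs = par("simulate", "n_coupled_pairs", 3),
      hub_partners = par("simulate", "hub_partners", 0),
      n_de_genes = par("simulate", "n_de_genes", 30),
      seed = sd + 2)
    write_fasta(gen$fasta$HUMAN, out("human.fa"))
    write_fasta(gen$fasta$MOUSE, out("mouse.fa"))
    write_gtf(combine_gene_models(gen$models$HUMAN, gen$models$MOUSE),
              out("toy.gtf"))
    write_species_table(gen$chrom_species, out("species.tsv"))
    write_fastq_pair(rd$mate1, rd$mate2, out("reads_1.fastq"),
                     out("reads_2.fastq"))
    write_matrix_tsv(cnt$counts$counts, out("counts.tsv"))
    write.table(cnt$metadata, out("metadata.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(cnt$gene_info, out("gene_info.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(read_truth = rd$truth,
           count_truth = cnt$truth[c("planted_k", "de_genes")],
           gender_of_sample = cnt$truth$gender_of_sample),
      out("truth.json"), auto_unbox = TRUE, digits = NA)
    state$gen <- gen; state$reads <- rd; state$sim <- cnt
    list(n_read_pairs = length(rd$mate1),
         n_samples = ncol(cnt$counts$counts))
  })

  needs_sim <- function() {
    if (is.null(state$gen))
      stop2("upstream 'simulate' outputs unavailable; enable the stage")
  }

  run_stage("disambiguate", "assignments.tsv", function() {
    needs_sim()
    idx <- build_species_index(state$gen$fasta,
                               k = par("disambiguate", "seed_length", 21))
    asg <- assign_read_pairs(state$reads$mate1, state$reads$mate2, idx,
      max_mismatch = par("disambiguate", "max_mismatch", 3),
      max_mm_ratio = par("disambiguate", "max_mm_ratio", 0.10))
    write.table(asg, out("assignments.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    state$assignments <- asg
    as.list(table(asg$call))
  })

  run_stage("quantify", c("union_counts.tsv", "fpkm.tsv"), function() {
    needs_sim()
    if (is.null(state$assignments))
      stop2("upstream 'disambiguate' outputs unavailable; enable the stage")
    models <- combine_gene_models(state$gen$models$HUMAN,
                                  state$gen$models$MOUSE)
    cm <- count_union(state$assignments, models, "sample1")
    fp <- compute_fpkm(cm, models,
      min_transcript_bp = par("quantify", "min_transcript_bp", 400),
      coding_only = par("quantify", "coding_only", TRUE))
    write_matrix_tsv(cm$counts, out("union_counts.tsv"))
    write_matrix_tsv(fp$values, out("fpkm.tsv"))
    list(human_proportion = species_proportion(cm, "sample1"))
  })

  sim_expr <- function(species) {
    needs_sim()
    cm <- state$sim$counts
    fp <- compute_fpkm(cm, state$sim$gene_info)
    sp <- fp$gene_species[rownames(fp$values)]
    new_expression_matrix(fp$values[sp == species, , drop = FALSE], "FPKM",
                          fp$gene_species[sp == species])
  }

  run_stage("prep", c("log_expr_mouse.tsv"), function() {
    fs <- filter_spec()
    em <- to_nonneg_log(filter_genes(sim_expr("MOUSE"), fs))
    eh <- to_nonneg_log(filter_genes(sim_expr("HUMAN"), fs))
    write_matrix_tsv(em$values, out("log_expr_mouse.tsv"))
    write_matrix_tsv(eh$values, out("log_expr_human.tsv"))
    state$log_mouse <- em; state$log_human <- eh
    list(n_mouse_genes_kept = nrow(em$values),
         n_human_genes_kept = nrow(eh$values))
  })

  run_stage("cluster", c("rank_selection.json", "assignments_cluster.tsv"),
            function() {
    if (is.null(state$log_mouse)) stop2("enable the 'prep' stage first")
    sd <- config$stage_seeds[["cluster"]]
    rs <- select_rank(state$log_mouse$values,
                      k_range = par("cluster", "k_range", 2:6),
                      n_runs = par("cluster", "n_runs_select", 10), seed = sd)
    cc <- consensus_cluster(state$log_mouse$values, rs$selected_k,
                            n_runs = par("cluster", "n_runs_final", 30),
                            seed = sd + 1)
    jsonlite::write_json(list(k_range = rs$k_range,
                              cophenetic_actual = rs$cophenetic_actual,
                              cophenetic_permuted = rs$cophenetic_permuted,
                              selected_k = rs$selected_k),
                         out("rank_selection.json"), auto_unbox = TRUE,
                         digits = NA)
    write.table(data.frame(sample_id = names(cc$assignments),
                           cluster = cc$assignments),
                out("assignments_cluster.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(selected_k = rs$selected_k, cophenetic = cc$cophenetic)
  })

  run_stage("network", "edges.tsv", function() {
    if (is.null(state$log_mouse)) stop2("enable the 'prep' stage first")
    cs <- pairwise_correlation(state$log_human, state$log_mouse, "all")
    net <- build_network(cs, threshold = par("network", "threshold", 0.85))
    write_edge_list(net, out("edges.tsv"))
    hubs <- cross_species_hubs(net)
    write.table(hubs, out("hubs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(n_edges = nrow(net$edges),
         edge_classes = as.list(table(net$edges$edge_class)))
  })

  run_stage("de", "de_results.tsv", function() {
    needs_sim()
    cm <- state$sim$counts
    hum <- rownames(cm$counts)[cm$gene_species[rownames(cm$counts)] == "HUMAN"]
    res <- de_test(cm$counts[hum, , drop = FALSE],
                   state$sim$metadata$subtype)
    write.table(res, out("de_results.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    state$de <- res
    list(n_significant = sum(res$fdr < 0.05 & abs(res$log2_fc) > 1.5,
                             na.rm = TRUE))
  })

  run_stage("overlap", "overlap.json", function() {
    if (is.null(state$de)) stop2("enable the 'de' stage first")
    sig <- make_signatures(state$sim$truth, state$sim$gene_info,
                           n_in_signature = par("overlap", "n_in_signature", 20),
                           n_decoys = par("overlap", "n_decoys", 50),
                           seed = config$stage_seeds[["overlap"]])
    de_genes <- state$de$gene_id[!is.na(state$de$fdr) & state$de$fdr < 0.05 &
                                   state$de$log2_fc > 1.5]
    res <- lapply(sig, function(s)
      unclass(hypergeom_overlap(de_genes, s, state$de$gene_id))[
        c("k_overlap", "K_signature", "n_list", "N_universe", "p_upper")])
    jsonlite::write_json(res, out("overlap.json"), auto_unbox = TRUE,
                         digits = NA)
    lapply(res, `[[`, "p_upper")
  })

  run_stage("gender", "gender.tsv", function() {
    needs_sim()
    gc <- predict_gender(state$sim$counts)
    write.table(gc, out("gender.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    truth <- state$sim$truth$gender_of_sample[gc$sample_id]
    list(concordance = mean(gc$call == truth))
  })

  write_run_report(report, out("run_report.json"))
  invisible(report)
}
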