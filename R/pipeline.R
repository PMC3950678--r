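#' Pipeline configuration with field-standard defaults
#'
#' Defaults: bonding percentile cutoff `r_cut = 0.90`, Hotelling gate
#' `alpha = 0.05`, module `size_cap = 10`, cis `window = 1e6` bp, linkage
#' `block_cut = 5e5` bp, transitive path length `R = 1`, hill-climbing with 5
#' restarts and parent cap 4, `K = 100` sampled Beta fields, annealing for up
#' to 20000 proposals (T0 = 1, cooling 0.9995, patience 5000).
#'
#' @param ... overrides for any configuration entry.
#' @return named list of parameters (class `PipelineConfig`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    r_cut = 0.90, alpha = 0.05, size_cap = 10L,
    window = 1e6, block_cut = 5e5,
    eta_grid = seq(0.1, 0.9, by = 0.1), K_grid = 1:5, folds = 5L,
    eta = NULL, K_spls = NULL,
    restarts = 5L, max_parents = 4L,
    K = 100L, anneal_iters = 20000L, anneal_T0 = 1,
    anneal_cooling = 0.9995, anneal_patience = 5000L,
    R = 1L, use_eqtls = TRUE,
    seed = 1L, jobs = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Run the four-step causal network reconstruction pipeline
#'
#' Executes module discovery, module-level eQTL mapping, pairwise-module
#' Bayesian subnetwork accumulation, and random-field rank assembly on
#' in-memory inputs. All randomness derives from `config$seed` (per-stage and
#' per-pair sub-seeds), so a rerun with identical inputs and config reproduces
#' identical outputs regardless of `jobs`. With fewer than two modules the
#' pipeline stops gracefully after step 1 with an explanatory message and
#' `NULL` downstream results.
#'
#' @param expr an [expression_matrix].
#' @param geno a [genotype_matrix].
#' @param labels a [phenotype_labels].
#' @param net an [interactome].
#' @param genes a [gene_annotation].
#' @param config a [pipeline_config].
#' @return list with `modules`, `eqtls`, `causation`, `ranks`, `network`,
#'   `major_network`, `config`, `status`.
#' @export
run_pipeline <- function(expr, geno, labels, net, genes,
                         config = pipeline_config()) {
  al <- align_samples(expr, geno, labels)
  expr <- al$expr; geno <- al$geno; labels <- al$labels
  cfg <- config

  modules <- discover_modules(expr, labels, net, r_cut = cfg$r_cut,
                              alpha = cfg$alpha, size_cap = cfg$size_cap)
  message(sprintf("step 1: %d discriminative module(s)", length(modules)))
  if (length(modules) < 2L) {
    message("fewer than two modules; stopping after step 1 ",
            "(no subnetworks can be paired)")
    return(list(modules = modules, eqtls = NULL, causation = NULL,
                ranks = NULL, network = NULL, major_network = NULL,
                config = cfg, status = "stopped_after_step1"))
  }

  eqtl_params <- list(window = cfg$window, block_cut = cfg$block_cut,
                      eta_grid = cfg$eta_grid, K_grid = cfg$K_grid,
                      folds = cfg$folds, eta = cfg$eta, K = cfg$K_spls)
  eqtls <- lapply(seq_along(modules), function(i) {
    if (!cfg$use_eqtls)
      return(structure(list(module_id = modules[[i]]$id,
                            eqtls = data.frame(snp_id = character(),
                                               chrom = character(),
                                               pos = integer(),
                                               block_id = character(),
                                               wilks_p = numeric())),
                       class = "ModuleEqtls"))
    p <- eqtl_params
    p$seed <- derive_seed(cfg$seed, 100L + i)
    map_module_eqtls(modules[[i]], geno, expr, genes, p)
  })
  message(sprintf("step 2: %d eQTL representative(s) over %d module(s)",
                  sum(vapply(eqtls, function(e) nrow(e$eqtls), 0L)),
                  length(modules)))

  C <- accumulate_causation(modules, eqtls, expr, geno,
                            restarts = cfg$restarts,
                            max_parents = cfg$max_parents,
                            seed = derive_seed(cfg$seed, 3L),
                            jobs = cfg$jobs)
  message(sprintf("step 3: causation matrix over %d gene(s), %d count(s)",
                  nrow(C), sum(C)))

  ranks <- infer_ranks(C, K = cfg$K, seed = derive_seed(cfg$seed, 4L),
                       iters = cfg$anneal_iters, T0 = cfg$anneal_T0,
                       cooling = cfg$anneal_cooling,
                       patience = cfg$anneal_patience)
  network <- assemble_global_network(C, ranks)
  major <- major_direction_network(C)
  message(sprintf("step 4: %d oriented edge(s) (%d by major direction)",
                  nrow(network$edges), nrow(major)))
  list(modules = modules, eqtls = eqtls, causation = C, ranks = ranks,
       network = network, major_network = major, config = cfg,
       status = "complete")
}

#' File-based pipeline run with artifact and manifest output
#'
#' Reads the standard input files, runs [run_pipeline], and writes every
#' stage's artifact (modules, eQTLs, causation matrix, ranks, network TSV +
#' SIF) plus a JSON manifest (parameters, seed, runtimes) into `out_dir`.
#'
#' @param expr_path,geno_path,geno_annot_path,labels_path,interactome_path,gene_annot_path
#'   input file paths (see the `read_*` functions for formats).
#' @param out_dir output directory (created if missing).
#' @param config a [pipeline_config].
#' @return the [run_pipeline] result, invisibly.
#' @export
run_pipeline_files <- function(expr_path, geno_path, geno_annot_path,
                               labels_path, interactome_path, gene_annot_path,
                               out_dir, config = pipeline_config()) {
  t0 <- Sys.time()
  expr <- read_expression_matrix(expr_path)
  geno <- read_genotype_matrix(geno_path, geno_annot_path)
  labels <- read_phenotype_labels(labels_path)
  net <- read_interactome(interactome_path)
  genes <- read_gene_annotation(gene_annot_path)
  res <- run_pipeline(expr, geno, labels, net, genes, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_modules(res$modules, file.path(out_dir, "modules.tsv"))
  if (!is.null(res$eqtls))
    write_module_eqtls(res$eqtls, file.path(out_dir, "module_eqtls.tsv"))
  if (!is.null(res$causation))
    write_causation_matrix(res$causation, file.path(out_dir, "causation.tsv"))
  if (!is.null(res$ranks))
    write.table(res$ranks, file.path(out_dir, "ranks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(res$network))
    write_network(res$network, file.path(out_dir, "network.tsv"))
  manifest <- list(
    package = "causanet",
    version = as.character(utils::packageVersion("causanet")),
    status = res$status,
    parameters = unclass(config)[!vapply(config, is.null, TRUE)],
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}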