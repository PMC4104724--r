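## End-to-end orchestration: standardize -> CV for h -> NIPALS fit -> VIP ->
## permutation FDR -> gene selection -> enrichment -> subnetwork -> hubs.
## Driven by a declarative config (YAML file or R list); all outputs are
## plain-text tables plus a run manifest.

default_params <- function() {
  list(h_max = 6L, n_folds = 3L, n_perm = 200L, fdr_threshold = 0.01,
       hub_cutoff = 10L, hub_strict = FALSE, scale_columns = TRUE, seed = 1L)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_invalid("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_invalid("config must be a list or a YAML path")
  config
}

validate_config <- function(config) {
  if (is.null(config$out_dir))
    stop_invalid("config: 'out_dir' is required")
  if (!is.null(config$synthetic)) return(invisible(config))
  inp <- config$inputs
  if (is.null(inp))
    stop_invalid("config: either a 'synthetic' block or an 'inputs' block is required")
  keys <- c("expression", "phenotype", "annotation", "gene_sets", "edges")
  for (key in keys)
    if (is.null(inp[[key]]))
      stop_invalid("config: inputs$%s is missing", key)
  for (key in keys)
    if (!file.exists(inp[[key]]))
      stop_invalid("config: inputs$%s path '%s' does not exist", key, inp[[key]])
  invisible(config)
}

#' Generate a full synthetic study from a config block
#'
#' Expands a `synthetic` config block into an expression cohort, annotation,
#' gene-set collection and interaction graph with planted truth. Hubs are
#' planted among the genes mapped to DE probes so the downstream subnetwork
#' stage has signal to recover.
#'
#' @param syn List of generator parameters (`n_probes`, `n_cases`,
#'   `n_controls`, `n_de`, `effect_size`, `noise_sd`, `n_sets`,
#'   `set_size_min`, `set_size_max`, `n_enriched`, `enrichment_strength`,
#'   `mean_degree`, `n_hubs`, `hub_degree`); missing entries fall back to a
#'   63/20 design.
#' @param seed Integer seed; stage seeds are derived from it.
#' @return List with `expr`, `pheno`, `annotation`, `sets`, `graph`,
#'   `truth`.
#' @export
simulate_study <- function(syn, seed = 1L) {
  syn <- utils::modifyList(
    list(n_probes = 2000L, n_cases = 63L, n_controls = 20L, n_de = 100L,
         effect_size = 1.5, noise_sd = 1.0, direction_bias = 0.5,
         probes_per_gene = 1.2, unannotated_frac = 0,
         n_sets = 50L, set_size_min = 10L, set_size_max = 50L,
         n_enriched = 1L, enrichment_strength = 0.8,
         mean_degree = 2, n_hubs = 3L, hub_degree = 15L),
    syn)
  cohort <- generate_expression(syn$n_probes, syn$n_cases, syn$n_controls,
                                syn$n_de, syn$effect_size, syn$noise_sd,
                                seed = derive_seed(seed, 1L),
                                direction_bias = syn$direction_bias)
  annotation <- generate_annotation(rownames(cohort$expr),
                                    probes_per_gene = syn$probes_per_gene,
                                    unannotated_frac = syn$unannotated_frac,
                                    seed = derive_seed(seed, 2L))
  truth <- cohort$truth
  if (syn$n_enriched > 0L)
    truth$enriched_set_ids <- sprintf("GS%03d", seq_len(syn$n_enriched))
  sets <- generate_gene_sets(annotation, syn$n_sets, syn$set_size_min,
                             syn$set_size_max, truth,
                             enrichment_strength = syn$enrichment_strength,
                             seed = derive_seed(seed, 3L))
  genes <- unique(annotation[nzchar(annotation)])
  de_genes <- unique(annotation[truth$de_probe_ids])
  de_genes <- de_genes[!is.na(de_genes) & nzchar(de_genes)]
  if (syn$n_hubs > 0L && length(de_genes)) {
    set.seed(derive_seed(seed, 4L))
    truth$hub_gene_ids <- sort(sample(de_genes, min(syn$n_hubs, length(de_genes))))
  }
  graph <- generate_interactions(genes, syn$mean_degree,
                                 hub_ids = truth$hub_gene_ids,
                                 hub_degree = syn$hub_degree,
                                 seed = derive_seed(seed, 5L))
  cohort$truth <- truth
  list(expr = cohort$expr, pheno = cohort$pheno, annotation = annotation,
       sets = sets, graph = graph, truth = truth)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cross-validated choice of the number of latent
#' variables, the NIPALS PLS fit, VIP scoring, permutation FDR, gene
#' selection with regulation direction, hypergeometric gene-set enrichment,
#' and hub detection on the interaction subnetwork of selected genes. All
#' result tables, the CV curve, network exports (SIF + GraphML) and a run
#' manifest are written under `out_dir`.
#'
#' @param config A list or path to a YAML file with blocks: `out_dir`;
#'   either `inputs` (paths `expression`, `phenotype`, `annotation`,
#'   `gene_sets`, `edges`) or `synthetic` (see [simulate_study()]); and
#'   `params` (`h_max`, `n_folds`, `n_perm`, `fdr_threshold`, `hub_cutoff`,
#'   `scale_columns`, `seed`).
#' @return Invisibly, a list with all in-memory results (`cv`, `model`,
#'   `vip_table`, `enrichment`, `subnetwork`, `hubs`, `truth` when
#'   synthetic, and the output `paths`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(read_config(config))
  params <- utils::modifyList(default_params(), config$params %||% list())
  seed <- as.integer(params$seed)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  truth <- NULL
  if (!is.null(config$synthetic)) {
    study <- simulate_study(config$synthetic, seed = seed)
    expr <- study$expr; pheno <- study$pheno
    annotation <- study$annotation; sets <- study$sets; graph <- study$graph
    truth <- study$truth
    input_paths <- write_synthetic_inputs(
      list(expr = expr, pheno = pheno, truth = truth),
      annotation, sets, graph, file.path(out_dir, "inputs"))
  } else {
    inp <- config$inputs
    expr <- read_expression(inp$expression)
    pheno <- read_phenotype(inp$phenotype, expr)
    annotation <- read_annotation(inp$annotation)
    sets <- read_gene_sets(inp$gene_sets)
    graph <- read_edge_list(inp$edges)
    input_paths <- unlist(inp)
  }

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop_invalid("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  cv <- stage("choose_h_cv", function()
    choose_h_cv(expr, pheno, h_max = params$h_max, n_folds = params$n_folds,
                seed = derive_seed(seed, 10L),
                scale_columns = params$scale_columns))
  h <- cv$chosen_h

  fdr_res <- stage("permutation_fdr", function()
    permutation_fdr(expr, pheno, h = h, n_perm = params$n_perm,
                    seed = derive_seed(seed, 11L),
                    scale_columns = params$scale_columns))

  vip_table <- stage("select_genes", function()
    select_genes(expr, pheno, fdr_res, fdr_threshold = params$fdr_threshold,
                 annotation = annotation))

  sel_genes <- selected_gene_symbols(vip_table)

  enrichment <- stage("enrich", function() {
    if (!length(sel_genes)) {
      warning("no selected genes; enrichment skipped", call. = FALSE)
      enrich(character(), annotation, sets)
    } else enrich(sel_genes, annotation, sets)
  })

  subnet <- stage("build_subnetwork", function()
    build_subnetwork(sel_genes, graph))
  degrees <- compute_degrees(subnet)
  hubs <- stage("select_hubs", function()
    select_hubs(degrees, cutoff = params$hub_cutoff,
                strict = isTRUE(params$hub_strict)))
  subnet <- annotate_network(subnet, vip_table)

  paths <- c(
    vip_table = write_tsv(vip_table, file.path(out_dir, "vip_table.tsv")),
    cv_curve = write_tsv(cv$curve, file.path(out_dir, "cv_curve.tsv")),
    enrichment = write_tsv(enrichment, file.path(out_dir, "enrichment.tsv")),
    hubs = write_tsv(hubs, file.path(out_dir, "hubs.tsv")),
    network_sif = write_network(subnet, file.path(out_dir, "subnetwork.sif"), "sif"),
    network_graphml = write_network(subnet, file.path(out_dir, "subnetwork.graphml"),
                                    "graphml"))

  rel <- function(paths)               # record paths relative to out_dir
    lapply(as.list(paths), function(p)
      sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out_dir), "/?"),
          "", p))
  manifest <- list(
    package = "plsvip",
    version = as.character(utils::packageVersion("plsvip")),
    params = params,
    chosen_h = h,
    inputs = rel(input_paths),
    input_checksums = lapply(as.list(input_paths), function(p)
      unname(tools::md5sum(p))),
    synthetic = config$synthetic,
    n_probes = nrow(expr), n_samples = ncol(expr),
    n_selected = sum(vip_table$selected),
    outputs = rel(paths))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(cv = cv, fdr = fdr_res, vip_table = vip_table,
                 selected_genes = sel_genes, enrichment = enrichment,
                 subnetwork = subnet, degrees = degrees, hubs = hubs,
                 truth = truth, paths = c(paths, manifest = manifest_path)))
}
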