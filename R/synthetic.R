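## Synthetic cohorts with known ground truth: expression matrices with
## planted differential expression, many-to-one probe annotations, gene-set
## collections with planted enriched sets, and interaction graphs with
## planted hubs. Defaults mirror a 63-case / 20-control peripheral-blood
## case/control design.

#' Generate a two-group expression cohort with planted DE probes
#'
#' Baseline log2 intensities are drawn once per probe (uniform on
#' \[4, 12\], the usual RMA range), i.i.d. Gaussian noise is added on the
#' log2 scale, and `n_de` probes receive a mean shift of `effect_size` in
#' cases. The sign split follows `direction_bias`: a fraction of DE probes
#' are upregulated in cases (default 0.5, the extra probe positive when
#' `n_de` is odd). Samples are ordered cases first, then controls; controls
#' are coded 0 and cases 1.
#'
#' @param n_probes Number of probes.
#' @param n_cases,n_controls Group sizes (defaults 63 and 20).
#' @param n_de Number of differentially expressed probes (`<= n_probes`).
#' @param effect_size Absolute mean shift in log2 units (positive).
#' @param noise_sd Gaussian noise standard deviation (positive, log2 units).
#' @param seed Integer seed; identical arguments + seed give identical
#'   output.
#' @param direction_bias Fraction of DE probes upregulated in cases.
#' @return List with `expr` (probes x samples matrix), `pheno` (named 0/1
#'   vector) and `truth` (a `synthetic_truth` list: `de_probe_ids`,
#'   signed `effect_sizes`, plus empty `enriched_set_ids` / `hub_gene_ids`
#'   slots for the other generators).
#' @export
generate_expression <- function(n_probes, n_cases = 63L, n_controls = 20L,
                                n_de = 0L, effect_size = 1.5, noise_sd = 1.0,
                                seed = 1L, direction_bias = 0.5) {
  n_probes <- check_positive_int(n_probes, "n_probes")
  n_cases <- check_positive_int(n_cases, "n_cases")
  n_controls <- check_positive_int(n_controls, "n_controls")
  n_de <- check_nonneg_int(n_de, "n_de")
  effect_size <- check_positive_real(effect_size, "effect_size")
  noise_sd <- check_positive_real(noise_sd, "noise_sd")
  if (n_cases < 2L || n_controls < 2L)
    stop_invalid("need >= 2 samples per group")
  if (n_de > n_probes)
    stop_invalid("n_de = %d exceeds n_probes = %d", n_de, n_probes)
  if (direction_bias < 0 || direction_bias > 1)
    stop_invalid("direction_bias must lie in [0, 1]")
  set.seed(seed)
  probe_ids <- sprintf("P%05d_at", seq_len(n_probes))
  sample_ids <- c(sprintf("case_%03d", seq_len(n_cases)),
                  sprintf("ctrl_%03d", seq_len(n_controls)))
  n <- n_cases + n_controls
  baseline <- stats::runif(n_probes, 4, 12)
  expr <- matrix(stats::rnorm(n_probes * n, sd = noise_sd), n_probes, n) + baseline
  dimnames(expr) <- list(probe_ids, sample_ids)
  de_idx <- integer(0); effects <- numeric(0)
  if (n_de > 0L) {
    de_idx <- sort(sample.int(n_probes, n_de))
    n_up <- ceiling(n_de * direction_bias)
    signs <- c(rep(1, n_up), rep(-1, n_de - n_up))
    effects <- signs * effect_size
    expr[de_idx, seq_len(n_cases)] <-
      expr[de_idx, seq_len(n_cases)] + effects
  }
  pheno <- stats::setNames(c(rep(1L, n_cases), rep(0L, n_controls)), sample_ids)
  truth <- structure(list(de_probe_ids = probe_ids[de_idx],
                          effect_sizes = stats::setNames(effects, probe_ids[de_idx]),
                          enriched_set_ids = character(),
                          hub_gene_ids = character()),
                     class = "synthetic_truth")
  list(expr = expr, pheno = pheno, truth = truth)
}

#' Generate a many-to-one probe-to-gene annotation
#'
#' Maps `probe_ids` onto roughly `length(probe_ids) / probes_per_gene`
#' gene symbols so that every gene has at least one probe and some genes
#' have several, exercising the probe-collapse rule downstream. A fraction
#' of probes can be left unannotated (empty symbol).
#'
#' @param probe_ids Character vector of probe identifiers.
#' @param probes_per_gene Average probes per gene (default 1.2).
#' @param unannotated_frac Fraction of probes given an empty symbol.
#' @param seed Integer seed.
#' @return Named character vector, probe id -> symbol.
#' @export
generate_annotation <- function(probe_ids, probes_per_gene = 1.2,
                                unannotated_frac = 0, seed = 1L) {
  if (!length(probe_ids)) stop_invalid("probe_ids is empty")
  probes_per_gene <- check_positive_real(probes_per_gene, "probes_per_gene")
  if (probes_per_gene < 1) stop_invalid("probes_per_gene must be >= 1")
  set.seed(seed)
  n_probes <- length(probe_ids)
  n_genes <- max(1L, floor(n_probes / probes_per_gene))
  symbols <- sprintf("GENE%05d", seq_len(n_genes))
  gene_for_probe <- symbols[((seq_len(n_probes) - 1L) %% n_genes) + 1L]
  gene_for_probe <- gene_for_probe[sample.int(n_probes)]
  if (unannotated_frac > 0) {
    drop <- sample.int(n_probes, round(unannotated_frac * n_probes))
    gene_for_probe[drop] <- ""
  }
  stats::setNames(gene_for_probe, probe_ids)
}

#' Generate a gene-set collection with planted enriched sets
#'
#' Builds `n_sets` sets (ids `GS001`, `GS002`, ...) with sizes uniform on
#' \[set_size_min, set_size_max\] over the annotated gene symbols. Sets named
#' in `truth$enriched_set_ids` draw a fraction `enrichment_strength` of
#' their members from the genes mapped to planted DE probes; all other
#' members are uniform draws from the remaining genes.
#'
#' @param probe_annotation Named probe -> symbol vector.
#' @param n_sets Number of sets.
#' @param set_size_min,set_size_max Set size range (inclusive).
#' @param truth A `synthetic_truth`; its `enriched_set_ids` must be a subset
#'   of the generated ids (use e.g. `"GS001"`).
#' @param enrichment_strength Fraction in \[0,1\] of enriched-set members
#'   drawn from DE genes.
#' @param seed Integer seed.
#' @return A `gene_set_collection` (namespace "pathway").
#' @export
generate_gene_sets <- function(probe_annotation, n_sets, set_size_min,
                               set_size_max, truth,
                               enrichment_strength = 0.5, seed = 1L) {
  if (!length(probe_annotation)) stop_invalid("empty probe annotation")
  n_sets <- check_positive_int(n_sets, "n_sets")
  set_size_min <- check_positive_int(set_size_min, "set_size_min")
  set_size_max <- check_positive_int(set_size_max, "set_size_max")
  if (enrichment_strength < 0 || enrichment_strength > 1)
    stop_invalid("enrichment_strength must lie in [0, 1]")
  genes <- unique(probe_annotation[nzchar(probe_annotation)])
  if (set_size_min > set_size_max || set_size_max > length(genes))
    stop_invalid("need set_size_min <= set_size_max <= %d distinct genes",
                 length(genes))
  ids <- sprintf("GS%03d", seq_len(n_sets))
  bad <- setdiff(truth$enriched_set_ids, ids)
  if (length(bad))
    stop_invalid("enriched_set_ids not among generated ids: %s",
                 paste(bad, collapse = ", "))
  de_genes <- unique(probe_annotation[truth$de_probe_ids])
  de_genes <- de_genes[!is.na(de_genes) & nzchar(de_genes)]
  other_genes <- setdiff(genes, de_genes)
  set.seed(seed)
  members <- vector("list", n_sets)
  names(members) <- ids
  sizes <- sample(seq(set_size_min, set_size_max), n_sets, replace = TRUE)
  for (i in seq_len(n_sets)) {
    sz <- sizes[[i]]
    if (ids[[i]] %in% truth$enriched_set_ids && length(de_genes)) {
      n_from_de <- min(round(enrichment_strength * sz), length(de_genes))
      picked <- c(sample(de_genes, n_from_de),
                  sample(other_genes, sz - n_from_de))
    } else {
      picked <- sample(genes, sz)
    }
    members[[i]] <- sort(picked)
  }
  new_gene_set_collection(members,
                          description = stats::setNames(
                            sprintf("synthetic set %d", seq_len(n_sets)), ids),
                          namespace = stats::setNames(rep("pathway", n_sets), ids))
}

#' Generate a random interaction graph with planted hubs
#'
#' Background edges follow an Erdos-Renyi model with expected degree
#' `mean_degree`; each gene in `hub_ids` is then topped up with random extra
#' partners until its degree reaches `hub_degree`. The result is a simple
#' undirected graph (no self-loops or multi-edges).
#'
#' @param gene_ids Character vector of gene symbols (the node set).
#' @param mean_degree Expected background degree (positive real).
#' @param hub_ids Symbols to plant as hubs (subset of `gene_ids`).
#' @param hub_degree Minimum degree for planted hubs
#'   (`< length(gene_ids)`).
#' @param seed Integer seed.
#' @return An undirected [igraph::igraph] graph named by gene symbols.
#' @export
generate_interactions <- function(gene_ids, mean_degree, hub_ids = character(),
                                  hub_degree = 10L, seed = 1L) {
  if (!length(gene_ids)) stop_invalid("gene_ids is empty")
  gene_ids <- toupper(gene_ids)
  hub_ids <- toupper(hub_ids)
  if (mean_degree < 0) stop_invalid("mean_degree must be >= 0")
  bad <- setdiff(hub_ids, gene_ids)
  if (length(bad))
    stop_invalid("hub_ids not in gene_ids: %s", paste(bad, collapse = ", "))
  if (length(hub_ids)) {
    hub_degree <- check_positive_int(hub_degree, "hub_degree")
    if (hub_degree >= length(gene_ids))
      stop_invalid("hub_degree = %d must be < %d genes", hub_degree,
                   length(gene_ids))
  }
  n <- length(gene_ids)
  set.seed(seed)
  p_edge <- min(1, mean_degree / max(1L, n - 1L))
  g <- igraph::sample_gnp(n, p_edge, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = gene_ids)
  for (hub in hub_ids) {
    deg <- igraph::degree(g, hub)
    if (deg >= hub_degree) next
    nbrs <- igraph::V(g)$name[as.integer(igraph::neighbors(g, hub))]
    candidates <- setdiff(gene_ids, c(hub, nbrs))
    extra <- sample(candidates, hub_degree - deg)
    g <- igraph::add_edges(g, as.vector(rbind(hub, extra)))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a complete synthetic input bundle
#'
#' Emits every generated object in the formats the readers consume:
#' expression TSV, phenotype TSV, annotation TSV, gene sets GMT, interaction
#' SIF, and a truth JSON sidecar.
#'
#' @param cohort Output of [generate_expression()].
#' @param annotation Named probe -> symbol vector.
#' @param sets A `gene_set_collection`.
#' @param graph An [igraph::igraph] interaction graph.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_synthetic_inputs <- function(cohort, annotation, sets, graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             edges = file.path(dir, "interactions.sif"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$expr, paths[["expression"]])
  write_phenotype(cohort$pheno, paths[["phenotype"]])
  write_annotation(annotation, paths[["annotation"]])
  write_gene_sets(sets, paths[["gene_sets"]])
  write_network(graph, paths[["edges"]], dialect = "sif")
  truth <- cohort$truth
  jsonlite::write_json(list(de_probe_ids = truth$de_probe_ids,
                            effect_sizes = as.list(truth$effect_sizes),
                            enriched_set_ids = truth$enriched_set_ids,
                            hub_gene_ids = truth$hub_gene_ids),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
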