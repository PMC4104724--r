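## Readers and writers for every external representation the pipeline touches.
## All files are UTF-8, tab-delimited text. Expression files follow the GEO
## series-matrix convention: probes as rows, samples as columns, first column
## holds the probe identifier.

#' Validate an expression matrix
#'
#' Checks the container invariants used throughout the package: a numeric
#' probes x samples matrix on the log2 scale with unique probe and sample
#' identifiers, no missing values, at least 2 probes and 4 samples.
#'
#' @param x Numeric matrix with probe identifiers as rownames and sample
#'   identifiers as colnames.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid("expression data must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_invalid("expression matrix must carry probe rownames and sample colnames")
  if (nrow(x) < 2L || ncol(x) < 4L)
    stop_invalid("expression matrix needs >= 2 probes and >= 4 samples (got %d x %d)",
                 nrow(x), ncol(x))
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop_invalid("duplicated probe id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop_invalid("duplicated sample id(s): %s", paste(unique(dup), collapse = ", "))
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop_invalid("missing value at probe '%s', sample '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]])
  }
  invisible(x)
}

#' Read a probe-level expression matrix
#'
#' Tab-delimited text with a header row of sample identifiers and the probe
#' identifier in the first column. Row and column order are preserved.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, probes x samples, with dimnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L)
    stop_invalid("expression file '%s' needs a probe column plus >= 1 sample", path)
  probes <- df[[1L]]
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    stop_invalid("expression file '%s': duplicated probe id(s): %s",
                 path, paste(dup, collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) , arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop_invalid("expression file '%s': non-numeric or blank cell at probe '%s', sample '%s' (value '%s')",
                 path, probes[i], colnames(vals)[j], vals[i, j])
  }
  dimnames(num) <- list(probes, colnames(vals))
  validate_expression(num)
  num
}

#' Write an expression matrix
#'
#' @param expr Numeric matrix, probes x samples, with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary phenotype table and align it to an expression matrix
#'
#' Two tab-separated columns, `sample_id` and `label`, labels in \{0, 1\}
#' (0 = control, 1 = case). Rows may be in any order; the result is reordered
#' to the expression matrix's sample order.
#'
#' @param path Path to the phenotype TSV.
#' @param expr Expression matrix whose sample order defines the alignment.
#' @return Named integer vector of 0/1 labels, names = sample ids, in
#'   `colnames(expr)` order.
#' @export
read_phenotype <- function(path, expr) {
  validate_expression(expr)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L)
    stop_invalid("phenotype file '%s' needs columns sample_id and label", path)
  ids <- df[[1L]]
  labels <- suppressWarnings(as.integer(df[[2L]]))
  bad <- is.na(labels) | !(labels %in% c(0L, 1L))
  if (any(bad))
    stop_invalid("phenotype file '%s': label outside {0,1} for sample(s) %s",
                 path, paste(ids[bad], collapse = ", "))
  missing <- setdiff(colnames(expr), ids)
  if (length(missing))
    stop_invalid("phenotype file '%s' lacks sample(s): %s",
                 path, paste(missing, collapse = ", "))
  y <- labels[match(colnames(expr), ids)]
  names(y) <- colnames(expr)
  validate_phenotype(y, expr)
  y
}

#' @rdname read_phenotype
#' @param y Named 0/1 integer vector to validate against `expr`.
#' @export
validate_phenotype <- function(y, expr) {
  if (!all(names(y) == colnames(expr)))
    stop_invalid("phenotype sample order does not match expression matrix")
  if (!all(y %in% c(0L, 1L)))
    stop_invalid("phenotype labels must be 0 (control) or 1 (case)")
  if (length(unique(y)) < 2L)
    stop_invalid("phenotype must contain both classes (all labels are %d)", y[1L])
  invisible(y)
}

#' Write a phenotype table
#' @param y Named 0/1 vector (names = sample ids).
#' @param path Output path.
#' @export
write_phenotype <- function(y, path) {
  utils::write.table(data.frame(sample_id = names(y), label = as.integer(y)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Two tab-separated columns: probe id and gene symbol. An empty symbol marks
#' an unannotated probe and is retained. Symbols are upper-cased on load so
#' that set and graph operations are case-consistent.
#'
#' @param path Path to the annotation TSV (with header).
#' @return Named character vector, probe id -> gene symbol ("" if unannotated).
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "",
                          na.strings = character())
  if (ncol(df) < 2L)
    stop_invalid("annotation file '%s' needs columns probe_id and symbol", path)
  probes <- df[[1L]]
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    stop_invalid("annotation file '%s': duplicated probe row(s): %s",
                 path, paste(dup, collapse = ", "))
  ann <- toupper(trimws(df[[2L]]))
  names(ann) <- probes
  ann
}

#' Write a probe-to-gene annotation table
#' @param ann Named character vector (probe id -> symbol).
#' @param path Output path.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(data.frame(probe_id = names(ann), symbol = unname(ann)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, `set_id TAB description TAB
#' member...`. Member symbols are upper-cased and deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with `members` (named list of
#'   character vectors), `description` and `namespace` (named character
#'   vectors). The namespace tag defaults to "pathway" and can be embedded in
#'   the description field as `namespace:text`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  members <- list(); descr <- character(); nspace <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop_invalid("GMT file '%s': line %d has %d field(s), need >= 3",
                   path, i, length(f))
    id <- f[[1L]]
    if (id %in% names(members))
      stop_invalid("GMT file '%s': duplicate set id '%s' (line %d)", path, id, i)
    d <- f[[2L]]
    ns <- "pathway"
    if (grepl("^(pathway|GO):", d)) {
      ns <- sub(":.*$", "", d)
      d <- sub("^[^:]*:", "", d)
    }
    members[[id]] <- unique(toupper(f[-(1:2)]))
    descr[[id]] <- d
    nspace[[id]] <- ns
  }
  new_gene_set_collection(members, descr, nspace)
}

#' Construct a gene-set collection
#' @param members Named list of character vectors of gene symbols.
#' @param description Optional named character vector of free-text labels.
#' @param namespace Optional named character vector; "pathway" or "GO".
#' @return A `gene_set_collection` object.
#' @export
new_gene_set_collection <- function(members, description = NULL, namespace = NULL) {
  ids <- names(members) %||% character()
  if (length(members) && (!length(ids) || anyDuplicated(ids)))
    stop_invalid("gene set ids must be unique and non-empty")
  members <- lapply(members, function(m) unique(toupper(m)))
  if (is.null(description)) description <- stats::setNames(ids, ids)
  if (is.null(namespace)) namespace <- stats::setNames(rep("pathway", length(ids)), ids)
  structure(list(members = members,
                 description = description[ids],
                 namespace = namespace[ids]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d distinct genes\n",
              length(x$members), length(unique(unlist(x$members)))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$members)

#' Write a gene-set collection in GMT format
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  ids <- names(sets$members)
  lines <- vapply(ids, function(id) {
    paste(c(id, paste0(sets$namespace[[id]], ":", sets$description[[id]]),
            sets$members[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction network from an edge list
#'
#' Accepts SIF lines (`node relation node ...`) or a plain two-column TSV of
#' symbol pairs. Self-loops are dropped (with a message reporting the count)
#' and duplicate edges are collapsed; symbols are upper-cased.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph::igraph] graph.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pairs <- matrix(character(), ncol = 2L)
  singles <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1L]]
    f <- toupper(f)
    if (length(f) == 1L) {
      singles <- c(singles, f)          # SIF allows isolated nodes
    } else if (length(f) == 2L) {
      pairs <- rbind(pairs, f)
    } else {
      # SIF: source relation target1 target2 ...
      pairs <- rbind(pairs, cbind(f[[1L]], f[-(1:2)]))
    }
  }
  loops <- pairs[, 1L] == pairs[, 2L]
  if (any(loops))
    message(sprintf("read_edge_list: dropped %d self-loop(s)", sum(loops)))
  pairs <- pairs[!loops, , drop = FALSE]
  nodes <- unique(c(singles, as.vector(t(pairs))))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(pairs))
    g <- igraph::add_edges(g, as.vector(t(pairs)))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Export an interaction network for Cytoscape
#'
#' Writes the graph as SIF (`node pp node`, isolated nodes on their own line)
#' or GraphML. Node attributes present on the graph (e.g. `degree`,
#' `direction`) are carried into the GraphML dialect.
#'
#' @param graph An undirected [igraph::igraph] graph with a `name` vertex
#'   attribute.
#' @param path Output path.
#' @param dialect "sif" or "graphml".
#' @export
write_network <- function(graph, path, dialect = c("sif", "graphml")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(graph, "igraph"))
  if (dialect == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  lines <- if (nrow(el)) paste(el[, 1L], "pp", el[, 2L], sep = "\t") else character()
  iso <- setdiff(igraph::V(graph)$name,
                 if (nrow(el)) unique(as.vector(el)) else character())
  writeLines(c(lines, iso), path)
  invisible(path)
}
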