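## Hypergeometric over-representation of selected genes in gene sets.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' k members of a K-gene set when sampling n genes without replacement from a
#' universe of N. Computed with `phyper` on the complementary tail, which
#' accumulates the mass in a numerically stable way.
#'
#' @param N Universe size.
#' @param K Number of set members in the universe.
#' @param n Number of selected genes in the universe.
#' @param k Observed overlap.
#' @return The p-value P(X >= k); exactly 1 when k = 0.
#' @export
hypergeom_upper <- function(N, K, n, k) {
  N <- check_nonneg_int(N, "N"); K <- check_nonneg_int(K, "K")
  n <- check_nonneg_int(n, "n"); k <- check_nonneg_int(k, "k")
  if (K > N || n > N)
    stop_invalid("need K <= N and n <= N (got N=%d, K=%d, n=%d)", N, K, n)
  if (k > min(K, n))
    stop_invalid("k = %d exceeds min(K, n) = %d", k, min(K, n))
  if (k == 0L) return(1)
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' For each namespace in the collection the universe is the set of annotated
#' genes that appear in at least one set of that namespace; `n` is the count
#' of selected genes inside that universe. Each set with a nonzero overlap
#' gets an upper-tail hypergeometric p-value and a per-namespace
#' Benjamini-Hochberg q-value. Sets with k = 0 are dropped (their
#' over-representation is untestable).
#'
#' @param selected_genes Character vector of selected gene symbols.
#' @param annotation Named probe -> symbol vector ("" = unannotated); the
#'   annotated genes define which collection members are measurable.
#' @param sets A `gene_set_collection`.
#' @return data.frame: set_id, description, namespace, N, K, n, k, p_value,
#'   q_value, sorted by ascending p_value.
#' @export
enrich <- function(selected_genes, annotation, sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (length(sets$members) == 0L)
    stop_invalid("empty gene-set collection")
  selected_genes <- unique(toupper(selected_genes))
  annotated <- unique(annotation[nzchar(annotation)])
  rows <- list()
  for (ns in unique(sets$namespace)) {
    ids <- names(sets$members)[sets$namespace == ns]
    ns_genes <- unique(unlist(sets$members[ids], use.names = FALSE))
    universe <- intersect(annotated, ns_genes)
    N <- length(universe)
    sel_u <- intersect(selected_genes, universe)
    n <- length(sel_u)
    if (n == 0L) {
      warning(sprintf("enrich: no selected gene maps into the '%s' universe", ns),
              call. = FALSE)
      next
    }
    ns_rows <- lapply(ids, function(id) {
      memb <- intersect(sets$members[[id]], universe)
      K <- length(memb)
      k <- length(intersect(sel_u, memb))
      if (k == 0L) return(NULL)
      data.frame(set_id = id,
                 description = unname(sets$description[[id]]),
                 namespace = ns, N = N, K = K, n = n, k = k,
                 p_value = hypergeom_upper(N, K, n, k),
                 stringsAsFactors = FALSE)
    })
    ns_df <- do.call(rbind, ns_rows)
    if (is.null(ns_df)) next
    ns_df$q_value <- stats::p.adjust(ns_df$p_value, method = "BH")
    rows[[ns]] <- ns_df
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_id = character(), description = character(),
                      namespace = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
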