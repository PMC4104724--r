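## Gene scoring by VIP, latent-variable selection by cross-validated
## prediction accuracy, and significance by pooled label-permutation FDR.

#' Variable importance in projection
#'
#' VIP_j = sqrt( p * sum_k Cor^2(y, t_k) w_kj^2 / sum_k Cor^2(y, t_k) ),
#' where w_k are the unit-norm NIPALS weight vectors and Cor is the Pearson
#' correlation of the phenotype with the k-th x-score. Because each w_k has
#' unit norm, sum_j VIP_j^2 = p identically.
#'
#' @param model A `pls_model`.
#' @param pheno Named 0/1 vector aligned with the model's samples.
#' @return Named numeric vector of VIP scores (one per retained probe).
#' @export
compute_vip <- function(model, pheno) {
  stopifnot(inherits(model, "pls_model"))
  r2 <- latent_correlations(model, pheno)
  tot <- sum(r2)
  if (tot < .Machine$double.eps)
    stop_invalid("all latent scores uncorrelated with phenotype; VIP undefined")
  p <- length(model$probe_ids)
  vip <- sqrt(p * as.numeric(model$W^2 %*% r2) / tot)
  names(vip) <- model$probe_ids
  vip
}

## Folds and label permutations are drawn in sample-ID-sorted space so that
## reordering samples (with their labels) leaves fold membership and the
## permutation null distribution unchanged.
make_stratified_folds <- function(pheno, n_folds, seed) {
  ord <- order(names(pheno))
  fold_c <- integer(length(pheno))       # folds in canonical (sorted) order
  pheno_c <- pheno[ord]
  set.seed(seed)
  for (cl in sort(unique(pheno_c))) {
    idx <- which(pheno_c == cl)
    if (length(idx) < n_folds)
      stop_invalid("class %s has %d sample(s), fewer than %d folds",
                   cl, length(idx), n_folds)
    fold_c[idx] <- (sample(seq_along(idx)) %% n_folds) + 1L
  }
  fold <- integer(length(pheno))
  fold[ord] <- fold_c
  fold
}

#' Choose the number of latent variables by cross-validation
#'
#' Stratified k-fold cross-validation of prediction accuracy. For each fold
#' a PLS model with `h_max` components is fitted on the training split, and
#' every h in 1..h_max is evaluated by truncating the model to its first h
#' components; the chosen h is the smallest one attaining the maximum mean
#' accuracy across folds.
#'
#' @param expr Expression matrix (probes x samples).
#' @param pheno Named 0/1 vector aligned with `colnames(expr)`.
#' @param h_max Largest candidate number of latent variables.
#' @param n_folds Number of folds (default 3).
#' @param seed Integer seed controlling fold assignment.
#' @param scale_columns Passed to [standardize()].
#' @return A `cv_curve`: data.frame `curve` (h, accuracy), `chosen_h`,
#'   `n_folds`, `seed`.
#' @export
choose_h_cv <- function(expr, pheno, h_max, n_folds = 3L, seed = 1L,
                        scale_columns = TRUE) {
  validate_expression(expr)
  validate_phenotype(pheno, expr)
  h_max <- check_positive_int(h_max, "h_max")
  n_folds <- check_positive_int(n_folds, "n_folds")
  n <- ncol(expr)
  if (h_max > min(n - 2L, nrow(expr)))
    stop_invalid("h_max = %d exceeds min(n-2, p) = %d", h_max,
                 min(n - 2L, nrow(expr)))
  fold <- make_stratified_folds(pheno, n_folds, seed)
  correct <- matrix(0, n_folds, h_max)
  sizes <- integer(n_folds)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    expr_tr <- expr[, !test, drop = FALSE]
    data_tr <- standardize(expr_tr, pheno[!test], scale_columns = scale_columns)
    fit <- nipals_fit(data_tr, h_max)
    expr_te <- expr[, test, drop = FALSE]
    for (h in seq_len(h_max)) {
      pred <- predict(fit, expr_te, ncomp = h)
      correct[f, h] <- sum(pred$class == pheno[test])
    }
    sizes[f] <- sum(test)
  }
  acc <- colSums(correct) / sum(sizes)   # pooled over folds
  fold_acc <- colMeans(correct / sizes)  # mean of per-fold accuracies
  chosen <- which(fold_acc >= max(fold_acc) - 1e-12)[1L]
  structure(list(curve = data.frame(h = seq_len(h_max),
                                    accuracy = fold_acc,
                                    pooled_accuracy = acc),
                 chosen_h = as.integer(chosen),
                 n_folds = n_folds, seed = seed),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("cv_curve: chosen h = %d (accuracy %.3f, %d folds)\n",
              x$chosen_h, x$curve$accuracy[x$chosen_h], x$n_folds))
  invisible(x)
}

#' Permutation-based FDR for VIP scores
#'
#' Refits the full PLS model (same h, same standardization policy) on
#' `n_perm` random label permutations, recomputing VIP each time to build a
#' pooled null distribution. The FDR of probe i is the pooled exceedance
#' count over all probes and permutations, divided by `n_perm * p`:
#'
#'   FDR_i = \[ sum_j sum_i' Bool(VIP_i'j > VIP_i) / n_perm \] / p
#'
#' with strict inequality (ties are not exceedances). Permuted refits that
#' fail (e.g. rank deficiency) are redrawn, with a message reporting the
#' count. A conventional tail-ratio estimator (pooled null exceedance rate
#' divided by the observed exceedance rate) is available via
#' `estimator = "tail_ratio"` for comparison; the pooled form is the
#' default.
#'
#' @param expr Expression matrix (probes x samples).
#' @param pheno Named 0/1 vector aligned with `colnames(expr)`.
#' @param h Number of latent variables (typically the CV choice), held fixed
#'   across permutations.
#' @param n_perm Number of label permutations (default 10000; small values
#'   such as 100-200 are adequate for testing).
#' @param seed Integer seed; permutations are drawn as successive
#'   `sample(n)` calls after `set.seed(seed)`.
#' @param scale_columns Passed to [standardize()].
#' @param estimator "pooled" (default) or "tail_ratio".
#' @return A `vip_fdr` list: `probe_ids` (retained probes), `vip` (observed
#'   VIP), `fdr` (per-probe estimate in \[0,1\]), `h`, `n_perm`,
#'   `n_redrawn`.
#' @export
permutation_fdr <- function(expr, pheno, h, n_perm = 10000L, seed = 1L,
                            scale_columns = TRUE,
                            estimator = c("pooled", "tail_ratio")) {
  estimator <- match.arg(estimator)
  n_perm <- check_positive_int(n_perm, "n_perm")
  data <- standardize(expr, pheno, scale_columns = scale_columns)
  fit <- nipals_fit(data, h)
  vip_obs <- compute_vip(fit, pheno)
  p <- length(vip_obs)
  n <- ncol(expr)
  n_redrawn <- 0L
  ord <- order(names(pheno))           # canonical sample order for permuting
  set.seed(seed)
  j <- 0L
  null_chunks <- vector("list", n_perm)
  while (j < n_perm) {
    perm <- sample(n)
    y_perm <- pheno
    y_perm[ord] <- pheno[ord][perm]    # permute labels in canonical space
    res <- tryCatch({
      d <- standardize(expr, y_perm, scale_columns = scale_columns)
      f <- nipals_fit(d, h)
      compute_vip(f, y_perm)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_perm)
        stop_invalid("permutation refits keep failing (h = %d too large?)", h)
      next
    }
    j <- j + 1L
    null_chunks[[j]] <- res
  }
  if (n_redrawn > 0L)
    message(sprintf("permutation_fdr: redrew %d failed permutation(s)", n_redrawn))
  null_vip <- unlist(null_chunks, use.names = FALSE)
  # exceedance count per probe: number of null VIPs strictly greater
  srt <- sort(null_vip)
  n_null <- length(srt)                       # n_perm * p, exact
  exceed <- n_null - findInterval(vip_obs, srt)   # strict: > vip_obs, ties excluded
  fdr <- switch(estimator,
    pooled = (exceed / n_perm) / p,
    tail_ratio = {
      obs_ge <- vapply(vip_obs, function(v) sum(vip_obs >= v), numeric(1L))
      pmin(1, (exceed / n_null) / (obs_ge / p))
    })
  fdr <- pmin(pmax(fdr, 0), 1)
  structure(list(probe_ids = names(vip_obs), vip = unname(vip_obs),
                 fdr = unname(fdr), h = h, n_perm = n_perm,
                 n_redrawn = n_redrawn, estimator = estimator),
            class = "vip_fdr")
}

#' Select differentially expressed probes
#'
#' Flags probes with FDR strictly below the threshold and assigns a
#' regulation direction from the sign of (case mean - control mean) of the
#' log2 expression values. Output rows are sorted by ascending FDR, then
#' descending VIP.
#'
#' @param expr Expression matrix (probes x samples) the FDR was computed on.
#' @param pheno Named 0/1 vector aligned with `colnames(expr)`.
#' @param fdr_result A `vip_fdr` object from [permutation_fdr()].
#' @param fdr_threshold Selection threshold in (0, 1\]; strict inequality
#'   `fdr < fdr_threshold` (default 0.01).
#' @param annotation Optional named probe -> symbol vector; adds a `gene`
#'   column.
#' @return A data.frame (`vip_table`): probe_id, gene (if annotated), vip,
#'   fdr, selected, direction ("up"/"down" in cases).
#' @export
select_genes <- function(expr, pheno, fdr_result, fdr_threshold = 0.01,
                         annotation = NULL) {
  stopifnot(inherits(fdr_result, "vip_fdr"))
  if (length(fdr_threshold) != 1L || !is.numeric(fdr_threshold) ||
      fdr_threshold <= 0 || fdr_threshold > 1)
    stop_invalid("fdr_threshold must lie in (0, 1]")
  probes <- fdr_result$probe_ids
  case_mean <- rowMeans(expr[probes, pheno == 1L, drop = FALSE])
  ctrl_mean <- rowMeans(expr[probes, pheno == 0L, drop = FALSE])
  tab <- data.frame(probe_id = probes,
                    vip = fdr_result$vip,
                    fdr = fdr_result$fdr,
                    selected = fdr_result$fdr < fdr_threshold,
                    direction = ifelse(case_mean >= ctrl_mean, "up", "down"),
                    log2_diff = unname(case_mean - ctrl_mean),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation))
    tab$gene <- unname(annotation[tab$probe_id])
  tab <- tab[order(tab$fdr, -tab$vip, tab$probe_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("vip_table", "data.frame")
  tab
}

#' Map selected probes to gene symbols
#'
#' A gene counts as differentially expressed if any of its probes is
#' selected (probes map many-to-one onto symbols).
#'
#' @param vip_table Output of [select_genes()] (must carry a `gene` column
#'   or `annotation` must be given).
#' @param annotation Optional named probe -> symbol vector.
#' @return Character vector of unique, non-empty selected gene symbols.
#' @export
selected_gene_symbols <- function(vip_table, annotation = NULL) {
  genes <- if (!is.null(vip_table$gene)) vip_table$gene
           else if (!is.null(annotation)) unname(annotation[vip_table$probe_id])
           else stop_invalid("no annotation available to map probes to genes")
  sel <- genes[vip_table$selected]
  unique(sel[!is.na(sel) & nzchar(sel)])
}
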