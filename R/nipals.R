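## PLS via the NIPALS iteration, single binary response.
##
## The model seeks latent variables t_k = X w_k maximizing covariance with
## response scores u_k, extracted one at a time with deflation of both X and
## y. Variables are probes (columns of the n x p design matrix obtained by
## transposing the probes-x-samples expression matrix).

#' Center (and optionally scale) expression data for PLS
#'
#' Transposes the probes x samples matrix into the n x p design orientation,
#' mean-centers every probe column, optionally scales each to unit variance,
#' and mean-centers the 0/1 phenotype. Zero-variance probes cannot be scaled
#' and carry no class information, so they are dropped with a message.
#'
#' @param expr Expression matrix, probes x samples (log2 scale).
#' @param pheno Named 0/1 vector aligned with `colnames(expr)`.
#' @param scale_columns Scale probe columns to unit variance (default TRUE).
#'   Without scaling, high-variance probes dominate the weight vectors
#'   w = X'u regardless of their association with the phenotype.
#' @return A `pls_standardized` list: `X` (n x p centered/scaled design),
#'   `y` (centered response), `center`, `scale`, `y_mean`, `probe_ids`
#'   (retained probes), `dropped` (zero-variance probe ids).
#' @export
standardize <- function(expr, pheno, scale_columns = TRUE) {
  validate_expression(expr)
  validate_phenotype(pheno, expr)
  if (min(table(pheno)) < 2L)
    stop_invalid("need >= 2 samples in each class")
  X <- t(expr)                       # n x p
  ctr <- colMeans(X)
  X <- sweep(X, 2L, ctr, "-")
  sds <- sqrt(colSums(X^2) / (nrow(X) - 1L))
  keep <- sds > 1e-12
  if (!any(keep))
    stop_invalid("all probes have zero variance")
  if (!all(keep))
    message(sprintf("standardize: dropped %d zero-variance probe(s): %s",
                    sum(!keep), paste(colnames(X)[!keep], collapse = ", ")))
  X <- X[, keep, drop = FALSE]
  sds <- sds[keep]
  ctr <- ctr[keep]
  if (scale_columns) {
    X <- sweep(X, 2L, sds, "/")
  } else {
    sds <- rep(1, length(sds))
    names(sds) <- colnames(X)
  }
  y_mean <- mean(pheno)
  structure(list(X = X, y = as.numeric(pheno) - y_mean,
                 center = ctr, scale = sds, y_mean = y_mean,
                 probe_ids = colnames(X),
                 sample_ids = rownames(X),
                 dropped = names(keep)[!keep],
                 scale_columns = scale_columns),
            class = "pls_standardized")
}

#' Fit a PLS model by NIPALS
#'
#' Extracts `h` latent variables. For each component: initialize u0 = y;
#' iterate w = X'u0, w = w/||w||; t = Xw; c = y't, c = c/|c|; u = yc until
#' ||u - u0|| < tol; then deflate X <- X - t(t'X)/(t't) and
#' y <- y - t(t'y)/(t't). With a single response the iteration converges in
#' one pass since y' X X' y >= 0. The sign of each weight vector is fixed so
#' its largest-magnitude entry is positive; VIP is invariant to this choice.
#'
#' @param data A `pls_standardized` object from [standardize()].
#' @param h Number of latent variables, `1 <= h <= min(n-1, p)`.
#' @param tol Convergence tolerance on the Euclidean norm of `u - u0`.
#' @param max_iter Iteration cap per component.
#' @return A `pls_model`: weights `W` (p x h, unit-norm columns), x-scores
#'   `T` (n x h, mutually orthogonal), x-loadings `P`, y-loadings `q`,
#'   y-scores `U`, regression coefficients `coefficients` (standardized
#'   scale) with `y_mean` intercept, the standardization parameters, and
#'   per-component iteration counts.
#' @export
nipals_fit <- function(data, h, tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(data, "pls_standardized"))
  h <- check_positive_int(h, "h")
  tol <- check_positive_real(tol, "tol")
  X <- data$X
  y <- data$y
  n <- nrow(X); p <- ncol(X)
  if (h > min(n - 1L, p))
    stop_invalid("h = %d exceeds min(n-1, p) = %d", h, min(n - 1L, p))
  W <- matrix(0, p, h); Tm <- matrix(0, n, h); P <- matrix(0, p, h)
  U <- matrix(0, n, h)
  q <- numeric(h); iters <- integer(h)
  eps <- .Machine$double.eps
  for (k in seq_len(h)) {
    u0 <- y
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter)
        stop_invalid("NIPALS did not converge for component %d within %d iterations",
                     k, max_iter)
      w <- crossprod(X, u0)[, 1L]
      nw <- sqrt(sum(w^2))
      if (nw < eps * p)
        stop_invalid("rank deficiency at component %d: only %d component(s) extractable",
                     k, k - 1L)
      w <- w / nw
      t_k <- (X %*% w)[, 1L]
      tt <- sum(t_k^2)
      if (tt < eps * n)
        stop_invalid("rank deficiency at component %d: only %d component(s) extractable",
                     k, k - 1L)
      cc <- sum(y * t_k)
      cc <- if (abs(cc) < eps) 1 else cc / abs(cc)   # |c| = 1 after normalization
      u <- y * cc
      if (sqrt(sum((u - u0)^2)) < tol) break
      u0 <- u
    }
    # deterministic sign: largest-|w| entry positive
    flip <- if (w[which.max(abs(w))] < 0) -1 else 1
    w <- flip * w; t_k <- flip * t_k
    tt <- sum(t_k^2)
    p_k <- crossprod(X, t_k)[, 1L] / tt
    q_k <- sum(y * t_k) / tt
    X <- X - tcrossprod(t_k, p_k)
    y <- y - t_k * q_k
    W[, k] <- w; Tm[, k] <- t_k; P[, k] <- p_k; U[, k] <- u * flip
    q[k] <- q_k; iters[k] <- it
  }
  rownames(W) <- rownames(P) <- data$probe_ids
  rownames(Tm) <- rownames(U) <- data$sample_ids
  # beta = W (P'W)^{-1} q maps standardized X to fitted centered y
  beta <- tryCatch(
    W %*% solve(crossprod(P, W), q),
    error = function(e) stop_invalid("singular P'W while forming coefficients: %s",
                                     conditionMessage(e)))
  structure(list(h = h, W = W, T = Tm, P = P, U = U, q = q,
                 coefficients = beta[, 1L],
                 center = data$center, scale = data$scale,
                 y_mean = data$y_mean, probe_ids = data$probe_ids,
                 scale_columns = data$scale_columns,
                 iterations = iters),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent variable(s), %d probes, %d samples\n",
              x$h, length(x$probe_ids), nrow(x$T)))
  invisible(x)
}

#' Predict phenotype from a fitted PLS model
#'
#' Applies the stored centering/scaling to the new samples, accumulates the
#' latent-variable regression (equivalently the coefficient vector), and adds
#' back the response mean. Samples with a continuous score >= 0.5 are called
#' class 1 (the response is 0/1 coded, so 0.5 is the midpoint).
#'
#' @param object A `pls_model`.
#' @param expr_new Expression matrix (probes x samples) whose probes must
#'   include every probe retained by the model.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return A data.frame with `sample_id`, `score` (continuous) and `class`
#'   (0/1).
#' @export
predict.pls_model <- function(object, expr_new, ncomp = object$h, ...) {
  ncomp <- check_positive_int(ncomp, "ncomp")
  if (ncomp > object$h)
    stop_invalid("ncomp = %d exceeds fitted components (%d)", ncomp, object$h)
  missing <- setdiff(object$probe_ids, rownames(expr_new))
  if (length(missing))
    stop_invalid("new data lacks %d model probe(s): %s", length(missing),
                 paste(utils::head(missing, 5L), collapse = ", "))
  X <- t(expr_new[object$probe_ids, , drop = FALSE])
  X <- sweep(X, 2L, object$center, "-")
  X <- sweep(X, 2L, object$scale, "/")
  if (ncomp == object$h) {
    beta <- object$coefficients
  } else {
    idx <- seq_len(ncomp)
    beta <- (object$W[, idx, drop = FALSE] %*%
               solve(crossprod(object$P[, idx, drop = FALSE],
                               object$W[, idx, drop = FALSE]),
                     object$q[idx]))[, 1L]
  }
  score <- (X %*% beta)[, 1L] + object$y_mean
  data.frame(sample_id = rownames(X), score = unname(score),
             class = as.integer(score >= 0.5), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Squared correlation of each latent score with the phenotype
#'
#' Returns Cor^2(y, t_k) for k = 1..h, the per-component weights used in the
#' VIP statistic (Pearson correlation).
#'
#' @param model A `pls_model` fitted on the same samples as `pheno`.
#' @param pheno Named 0/1 vector aligned with the model's samples.
#' @return Numeric vector of length h, entries in \[0, 1\].
#' @export
latent_correlations <- function(model, pheno) {
  stopifnot(inherits(model, "pls_model"))
  if (length(pheno) != nrow(model$T))
    stop_invalid("phenotype length %d != %d model samples",
                 length(pheno), nrow(model$T))
  vapply(seq_len(model$h), function(k) {
    t_k <- model$T[, k]
    if (stats::sd(t_k) < .Machine$double.eps)
      stop_invalid("latent score %d has zero variance", k)
    stats::cor(as.numeric(pheno), t_k)^2
  }, numeric(1L))
}
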