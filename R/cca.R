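#' Canonical correlation analysis of two feature blocks
#'
#' Finds paired linear projections of two blocks measured on the same samples
#' that maximize the correlation between the projected scores. The problem
#' is solved as the generalized eigenproblem
#' `C_AA^-1 C_AB C_BB^-1 C_AB' phi_a = lambda^2 phi_a` on mean-centered
#' blocks, with the within-block covariances stabilized by a relative ridge
#' (`C + ridge * (trace(C)/D) * I`) so collinear questionnaire items do not
#' make the problem singular. Weight vectors are scaled to unit canonical
#' variance (`phi' C phi = 1`, sample n-1 convention) and the number of
#' canonical dimensions is `min(rank(A), rank(B))`.
#'
#' Signs are fixed for reproducibility: every canonical pair satisfies
#' `cor(a_hat_k, b_hat_k) >= 0` and the largest-magnitude weight in `phi_a`
#' is positive.
#'
#' @param block_a,block_b Numeric matrices or tibbles (the `participant` and
#'   `strawberry` key columns are dropped) with the same rows in sample-key
#'   order; at least 3 rows.
#' @param ridge Nonnegative relative ridge added to both within-block
#'   covariances; default `1e-8`.
#' @param scale Standardize columns (z-score) before the analysis; off by
#'   default since CCA is affine-invariant in the full-rank case.
#' @return An object of class `taste_cca`: projection matrices
#'   `projection_a` (`D_a x D_cca`), `projection_b`, `canonical_correlations`
#'   (descending, in `[0, 1]`), canonical feature matrices
#'   `canonical_features_a`/`_b` (`n x D_cca`, unit sample variance),
#'   Bartlett `p_values` per dimension, and the preprocessing record
#'   (`column_means`, `column_scale`, `ridge`).
#' @examples
#' a <- matrix(rnorm(60), 20, 3)
#' b <- matrix(rnorm(40), 20, 2)
#' fit_cca(a, b)
#' @export
fit_cca <- function(block_a, block_b, ridge = 1e-8, scale = FALSE) {
  A <- if (is.matrix(block_a)) block_a else feature_matrix_values(block_a)
  B <- if (is.matrix(block_b)) block_b else feature_matrix_values(block_b)
  if (is.null(colnames(A))) colnames(A) <- paste0("a", seq_len(ncol(A)))
  if (is.null(colnames(B))) colnames(B) <- paste0("b", seq_len(ncol(B)))
  n <- nrow(A)
  if (nrow(B) != n) abort("blocks must have the same number of rows")
  if (n < 3) abort("fit_cca() needs at least 3 samples")
  if (ridge < 0) abort("ridge must be nonnegative")

  center_scale <- function(X) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sc <- NULL
    if (isTRUE(scale)) {
      sc <- apply(Xc, 2, stats::sd)
      if (any(sc == 0)) abort("cannot standardize a constant column")
      Xc <- sweep(Xc, 2, sc, `/`)
    }
    list(x = Xc, mean = mu, scale = sc)
  }
  pa <- center_scale(A); pb <- center_scale(B)
  Ac <- pa$x; Bc <- pb$x
  rank_a <- qr(Ac)$rank; rank_b <- qr(Bc)$rank
  if (rank_a == 0 || rank_b == 0) abort("rank-0 block: no variation to correlate")
  d_cca <- min(rank_a, rank_b)

  Caa <- crossprod(Ac) / (n - 1)
  Cbb <- crossprod(Bc) / (n - 1)
  Cab <- crossprod(Ac, Bc) / (n - 1)
  reg <- function(C) C + diag(ridge * mean(diag(C)), ncol(C))
  Caa_r <- reg(Caa); Cbb_r <- reg(Cbb)

  inv_sqrt <- function(S) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    keep <- e$values > 1e-12 * max(e$values)
    V <- e$vectors[, keep, drop = FALSE]
    V %*% (t(V) / sqrt(e$values[keep]))
  }
  Wa <- inv_sqrt(Caa_r)
  M <- Wa %*% Cab %*% solve(Cbb_r, t(Cab)) %*% Wa
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  idx <- seq_len(d_cca)
  lambda <- sqrt(pmax(eig$values[idx], 0))
  lambda <- pmin(lambda, 1)

  Phi_a <- Wa %*% eig$vectors[, idx, drop = FALSE]
  Phi_b <- solve(Cbb_r, t(Cab) %*% Phi_a)
  bnorm <- sqrt(pmax(colSums(Phi_b * (Cbb_r %*% Phi_b)), 0))
  bnorm[bnorm < 1e-30] <- 1
  Phi_b <- sweep(Phi_b, 2, bnorm, `/`)

  A_hat <- Ac %*% Phi_a
  B_hat <- Bc %*% Phi_b
  for (k in idx) {
    ck <- sum(A_hat[, k] * B_hat[, k])
    if (ck < 0) {                       # enforce cor(a_hat, b_hat) >= 0
      Phi_b[, k] <- -Phi_b[, k]; B_hat[, k] <- -B_hat[, k]
    }
    w <- Phi_a[, k]
    if (w[which.max(abs(w))] < 0) {     # fix overall sign, preserving the pair
      Phi_a[, k] <- -Phi_a[, k]; A_hat[, k] <- -A_hat[, k]
      Phi_b[, k] <- -Phi_b[, k]; B_hat[, k] <- -B_hat[, k]
    }
  }
  dn <- paste0("cc", idx)
  dimnames(Phi_a) <- list(colnames(A), dn)
  dimnames(Phi_b) <- list(colnames(B), dn)
  colnames(A_hat) <- colnames(B_hat) <- dn

  out <- structure(
    list(projection_a = Phi_a, projection_b = Phi_b,
         canonical_correlations = lambda,
         canonical_features_a = A_hat, canonical_features_b = B_hat,
         p_values = NULL, significance = "bartlett",
         column_means = list(a = pa$mean, b = pb$mean),
         column_scale = list(a = pa$scale, b = pb$scale),
         n = n, d_a = ncol(A), d_b = ncol(B), d_cca = d_cca, ridge = ridge),
    class = "taste_cca"
  )
  out$p_values <- canonical_significance(out)
  out
}

#' @export
print.taste_cca <- function(x, ...) {
  cat("<taste_cca>", x$n, "samples,", x$d_a, "x", x$d_b, "variables,",
      x$d_cca, "canonical dimensions\n")
  print(tidy(x), n = x$d_cca)
  invisible(x)
}

#' @export
tidy.taste_cca <- function(x, ...) {
  tibble::tibble(
    dimension = seq_len(x$d_cca),
    canonical_correlation = x$canonical_correlations,
    p_value = x$p_values
  )
}

#' @export
glance.taste_cca <- function(x, ...) {
  tibble::tibble(n = x$n, d_a = x$d_a, d_b = x$d_b, d_cca = x$d_cca,
                 ridge = x$ridge, significance = x$significance)
}

#' Cross-loadings of raw variables on the opposite canonical feature
#'
#' The interpretation device of the second analysis stage: the Pearson
#' correlation of each raw variable in one block with the k-th canonical
#' feature of the *opposite* block. A large absolute cross-loading marks the
#' raw variable as driving the canonical pair.
#'
#' @param result A [fit_cca()] object.
#' @param raw_block The raw data of one block (matrix or tibble, key columns
#'   dropped), same rows the fit used.
#' @param side Which block `raw_block` is: `"a"` or `"b"`.
#' @param dimension Canonical dimension `k` (default 1, the headline pair).
#' @return A tibble `variable`, `loading`, one row per raw column.
#' @export
cross_loadings <- function(result, raw_block, side = c("a", "b"), dimension = 1) {
  stopifnot(inherits(result, "taste_cca"))
  side <- match.arg(side)
  if (dimension < 1 || dimension > result$d_cca) {
    abort("dimension must lie in 1..D_cca")
  }
  X <- if (is.matrix(raw_block)) raw_block else feature_matrix_values(raw_block)
  if (nrow(X) != result$n) abort("raw block rows do not match the fitted samples")
  opposite <- if (side == "a") result$canonical_features_b else result$canonical_features_a
  feat <- opposite[, dimension]
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("x", seq_len(ncol(X)))
  tibble::tibble(
    variable = vars,
    loading = purrr::map_dbl(seq_len(ncol(X)), \(j) pearson(X[, j], feat))
  )
}

#' Bartlett's sequential significance test for canonical correlations
#'
#' Tests, for each dimension `k`, the null that canonical correlations `k`
#' and beyond are all zero, via the chi-square approximation to Wilks'
#' lambda: `Lambda_k = prod_{j >= k} (1 - lambda_j^2)`, statistic
#' `-(n - 1 - (D_a + D_b + 1)/2) * ln(Lambda_k)` on
#' `(D_a - k + 1)(D_b - k + 1)` degrees of freedom. A canonical correlation
#' of exactly 1 gives `p = 0` by convention.
#'
#' @param result A [fit_cca()] object.
#' @param n,d_a,d_b Sample size and block widths; default those of the fit.
#' @return Numeric vector of p-values, one per canonical dimension.
#' @export
canonical_significance <- function(result, n = result$n,
                                   d_a = result$d_a, d_b = result$d_b) {
  stopifnot(inherits(result, "taste_cca"))
  lambda <- result$canonical_correlations
  purrr::map_dbl(seq_along(lambda), function(k) {
    lam <- lambda[k:length(lambda)]
    if (any(lam >= 1 - 1e-12)) return(0)
    wilks <- prod(1 - lam^2)
    stat <- -(n - 1 - (d_a + d_b + 1) / 2) * log(wilks)
    df <- (d_a - k + 1) * (d_b - k + 1)
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  })
}

#' Permutation significance for canonical correlations
#'
#' Distribution-free alternative to [canonical_significance()]: refits the
#' CCA with the rows of `block_b` permuted and reports, per dimension,
#' `p = (1 + #{permuted lambda_k >= observed lambda_k}) / (n_perm + 1)`.
#' Seeded and reproducible.
#'
#' @param block_a,block_b The two blocks, as in [fit_cca()].
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @param ridge Passed to [fit_cca()].
#' @return A tibble `dimension`, `canonical_correlation`, `p_value`.
#' @export
permutation_significance <- function(block_a, block_b, n_perm = 999, seed = 1,
                                     ridge = 1e-8) {
  if (n_perm < 99) abort("n_perm must be at least 99")
  observed <- fit_cca(block_a, block_b, ridge = ridge)
  lambda <- observed$canonical_correlations
  B <- if (is.matrix(block_b)) block_b else feature_matrix_values(block_b)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  exceed <- numeric(length(lambda))
  for (i in seq_len(n_perm)) {
    perm <- fit_cca(block_a, B[sample(nrow(B)), , drop = FALSE], ridge = ridge)
    lp <- perm$canonical_correlations
    m <- min(length(lp), length(lambda))
    exceed[seq_len(m)] <- exceed[seq_len(m)] + (lp[seq_len(m)] >= lambda[seq_len(m)])
  }
  tibble::tibble(
    dimension = seq_along(lambda),
    canonical_correlation = lambda,
    p_value = (1 + exceed) / (n_perm + 1)
  )
}

#' Bar chart of canonical correlations
#'
#' @param object A [fit_cca()] object.
#' @param alpha Significance level annotated on the bars.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taste_cca <- function(object, alpha = 0.05, ...) {
  df <- tidy(object) |>
    dplyr::mutate(significant = .data$p_value < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$dimension),
                                   y = .data$canonical_correlation,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey70"),
                               name = paste0("p < ", alpha)) +
    ggplot2::labs(x = "canonical feature", y = "canonical correlation") +
    ggplot2::theme_minimal()
}

#' Bar chart of cross-loadings
#'
#' @param loadings Tibble from [cross_loadings()].
#' @return A ggplot.
#' @export
plot_cross_loadings <- function(loadings) {
  loadings <- dplyr::mutate(loadings,
                            variable = factor(.data$variable, levels = .data$variable))
  ggplot2::ggplot(loadings, ggplot2::aes(x = .data$variable, y = .data$loading)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "cross-loading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
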