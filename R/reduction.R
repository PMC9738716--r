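#' Fit PCA on an fNIRS feature table
#'
#' Column-centered principal component analysis of the per-sample feature
#' table, used as the study's only noise-handling step before correlation
#' and CCA. Components are deterministic up to sign; the sign is fixed so
#' each component's largest-magnitude loading is positive. Columns are
#' centered but not rescaled by default (the five statistics share units per
#' chromophore); set `scale = TRUE` for per-column z-scoring.
#'
#' @param features Tibble from [build_feature_matrix()] (key columns are
#'   ignored) or a numeric matrix, rows = samples.
#' @param scale Standardize columns before the eigendecomposition.
#' @return An object of class `taste_pca` with elements `rotation`
#'   (orthonormal loadings), `sdev`, `explained_ratio` (descending),
#'   `column_means`, `column_scale`, `n`.
#' @export
fit_pca <- function(features, scale = FALSE) {
  x <- if (is.matrix(features)) features else feature_matrix_values(features)
  if (nrow(x) < 2) abort("fit_pca() needs at least 2 rows")
  if (anyNA(x)) abort("fit_pca() does not accept missing values")
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var <= 0) abort("all feature columns are constant: zero total variance")
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  # sign convention: largest-|loading| entry of each component positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rotation <- sweep(pc$rotation, 2, flip, `*`)
  ev <- pc$sdev^2
  structure(
    list(rotation = rotation, sdev = pc$sdev,
         explained_ratio = ev / sum(ev),
         column_means = pc$center,
         column_scale = if (isTRUE(scale)) pc$scale else NULL,
         n = nrow(x)),
    class = "taste_pca"
  )
}

#' @export
print.taste_pca <- function(x, ...) {
  d90 <- select_dimension(x, 0.90)
  cat("<taste_pca>", length(x$explained_ratio), "components fitted on", x$n, "samples;",
      d90, "components reach 90% cumulative variance\n")
  invisible(x)
}

#' Smallest dimension reaching a cumulative-variance threshold
#'
#' The study's selection rule: keep the fewest leading components whose
#' cumulative contribution rate reaches the threshold (90% by default, which
#' selected 9 dimensions in the packaged study).
#'
#' @param result A [fit_pca()] object.
#' @param threshold Cumulative explained-variance fraction in (0, 1].
#' @return Integer dimension `d`.
#' @examples
#' \dontrun{select_dimension(fit_pca(features), 0.90)}
#' @export
select_dimension <- function(result, threshold = 0.90) {
  stopifnot(inherits(result, "taste_pca"))
  if (length(threshold) != 1 || threshold <= 0 || threshold > 1) {
    abort("threshold must lie in (0, 1]")
  }
  cum <- cumsum(result$explained_ratio)
  d <- which(cum >= threshold - 1e-12)[1]
  if (is.na(d)) d <- length(cum)   # numerical shortfall: keep everything
  as.integer(d)
}

#' Project features onto retained principal components
#'
#' Centers (and, if fitted so, rescales) the feature columns and projects
#' them onto the leading `d` component directions, yielding the
#' low-dimensional brain scores used by both analyses.
#'
#' @param result A [fit_pca()] object.
#' @param features Feature tibble or matrix with the fitted columns.
#' @param d Number of components to keep; default the 90% rule via
#'   [select_dimension()].
#' @return A tibble of scores with columns `d1` .. `d<d>` (plus
#'   `participant`, `strawberry` when present in `features`).
#' @export
pca_transform <- function(result, features, d = select_dimension(result)) {
  stopifnot(inherits(result, "taste_pca"))
  x <- if (is.matrix(features)) features else feature_matrix_values(features)
  if (ncol(x) != nrow(result$rotation)) {
    abort("feature columns do not match the fitted PCA")
  }
  xc <- sweep(x, 2, result$column_means)
  if (!is.null(result$column_scale)) xc <- sweep(xc, 2, result$column_scale, `/`)
  scores <- xc %*% result$rotation[, seq_len(d), drop = FALSE]
  colnames(scores) <- paste0("d", seq_len(d))
  out <- tibble::as_tibble(scores)
  if (!is.matrix(features) && all(c("participant", "strawberry") %in% names(features))) {
    out <- dplyr::bind_cols(features[c("participant", "strawberry")], out)
  }
  out
}

#' @export
predict.taste_pca <- function(object, newdata, d = select_dimension(object), ...) {
  pca_transform(object, newdata, d)
}

#' @export
tidy.taste_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained_ratio),
    sdev = x$sdev,
    explained_ratio = x$explained_ratio,
    cumulative = cumsum(x$explained_ratio)
  )
}

#' @export
glance.taste_pca <- function(x, threshold = 0.90, ...) {
  tibble::tibble(
    n = x$n,
    n_features = nrow(x$rotation),
    d_selected = select_dimension(x, threshold),
    threshold = threshold
  )
}

#' Scree plot of a fitted PCA
#'
#' @param object A [fit_pca()] object.
#' @param threshold Cumulative-variance threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taste_pca <- function(object, threshold = 0.90, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$explained_ratio), fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "principal component", y = "explained variance fraction",
                  title = "PCA of fNIRS epoch features") +
    ggplot2::theme_minimal()
}
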