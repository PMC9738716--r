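#' Pearson correlation coefficient
#'
#' Product-moment correlation of two stacked sample vectors. Constant input
#' is an explicit error (the correlation is undefined), never `NaN`.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) abort("pearson() needs vectors of equal length")
  if (length(a) < 3) abort("pearson() needs at least 3 observations")
  if (anyNA(a) || anyNA(b)) abort("pearson() does not accept missing values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("correlation undefined for constant input")
  }
  stats::cor(a, b)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Tests the null of zero correlation with the exact t statistic
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' `|r| = 1` returns `p = 0` by convention.
#'
#' @param r Correlation coefficient.
#' @param n Sample size (>= 3).
#' @return Two-sided p-value in `[0, 1]`.
#' @export
pearson_pvalue <- function(r, n) {
  if (n < 3) abort("pearson_pvalue() needs n >= 3")
  if (abs(r) > 1 + 1e-12) abort("|r| cannot exceed 1")
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Correlation screen of taste against every other variable
#'
#' The first analysis stage: Pearson correlation (with two-sided t-test
#' p-values) between the stacked VAS taste vector and every questionnaire
#' item, every retained brain PCA score, and every individual-information
#' variable. Questionnaire and individual rows are computable from the
#' tables alone; brain rows need the PCA scores.
#'
#' @param tables A [study_tables()] object with at least the VAS block.
#' @param brain_scores Optional score tibble from [pca_transform()]
#'   (columns `participant`, `strawberry`, `d1` ..).
#' @return A tibble with one row per variable: `variable`, `block`
#'   (`"questionnaire"`, `"brain"`, `"individual"`), `r`, `p`, `n`, ordered
#'   by block then catalogue/dimension order.
#' @examples
#' correlate_taste_vs_all(study_fixtures())
#' @export
correlate_taste_vs_all <- function(tables, brain_scores = NULL) {
  stopifnot(inherits(tables, "study_tables"))
  v <- stack_column(tables$vas, "vas")
  n <- length(v)
  one_row <- function(variable, block, b) {
    r <- pearson(v, b)
    tibble::tibble(variable = variable, block = block, r = r,
                   p = pearson_pvalue(r, n), n = n)
  }

  q_rows <- NULL
  if (!is.null(tables$questionnaire)) {
    items <- if (!is.null(tables$items)) tables$items$item else
      sort(unique(tables$questionnaire$item))
    q_rows <- purrr::map_dfr(items, function(it) {
      resp <- tables$questionnaire |>
        dplyr::filter(.data$item == it) |>
        dplyr::select("participant", "strawberry", "response")
      one_row(it, "questionnaire", stack_column(resp, "response"))
    })
  }

  b_rows <- NULL
  if (!is.null(brain_scores)) {
    dcols <- grep("^d[0-9]+$", names(brain_scores), value = TRUE)
    dcols <- dcols[order(as.integer(sub("^d", "", dcols)))]
    b_rows <- purrr::map_dfr(dcols, function(dc) {
      one_row(dc, "brain", stack_column(brain_scores, dc))
    })
  }

  i_rows <- NULL
  if (!is.null(tables$individual)) {
    ind_vars <- c(sugar_content = "sugar_content", acidity = "acidity",
                  `sugar-to-acid ratio` = "sugar_acid_ratio", size = "size_indicator")
    i_rows <- purrr::map2_dfr(names(ind_vars), ind_vars, function(label, colname) {
      one_row(label, "individual", stack_column(tables$individual, colname))
    })
  }

  dplyr::bind_rows(q_rows, b_rows, i_rows)
}

#' Bar chart of a correlation screen
#'
#' Mirrors the study's presentation: one bar per variable, height `|r|`,
#' colored by data block.
#'
#' @param report Tibble from [correlate_taste_vs_all()].
#' @param value `"r"` (absolute correlation) or `"p"`.
#' @return A ggplot.
#' @export
plot_correlation_report <- function(report, value = c("r", "p")) {
  value <- match.arg(value)
  report <- dplyr::mutate(report, variable = factor(.data$variable, levels = .data$variable))
  y <- if (value == "r") abs(report$r) else report$p
  ggplot2::ggplot(report, ggplot2::aes(x = .data$variable, y = y, fill = .data$block)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = if (value == "r") "|r| with taste (VAS)" else "p-value",
                  title = "Correlation between taste and other data") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
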