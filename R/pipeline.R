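package_provenance <- function(seed = NULL, extra = list()) {
  c(list(package = "tastecca",
         version = as.character(utils::packageVersion("tastecca")),
         seed = seed),
    extra)
}

write_csv_provenance <- function(df, path, provenance) {
  header <- paste0("# ", paste(names(provenance), unlist(provenance),
                               sep = "=", collapse = " "))
  writeLines(c(header, readr::format_csv(df)), path)
  invisible(path)
}

#' Run the correlation-screen analysis
#'
#' First analysis stage over a study: Pearson correlation of taste (VAS)
#' against every questionnaire item, brain PCA score, and
#' individual-information variable, with two-sided t-test p-values. The
#' individual and questionnaire rows need only the tables; brain rows are
#' included when scores are supplied.
#'
#' @param tables A [study_tables()] object.
#' @param brain_scores Optional PCA score tibble from [pca_transform()].
#' @param out_dir Optional output directory (created if missing); writes
#'   `analysis1_report.csv` and `analysis1_report.json`, both carrying a
#'   provenance header.
#' @param seed Recorded in provenance only (the analysis is deterministic).
#' @return The correlation report tibble (see [correlate_taste_vs_all()]).
#' @export
run_analysis1 <- function(tables, brain_scores = NULL, out_dir = NULL, seed = NULL) {
  report <- correlate_taste_vs_all(tables, brain_scores)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- package_provenance(seed, list(analysis = "analysis1"))
    write_csv_provenance(report, file.path(out_dir, "analysis1_report.csv"), prov)
    jsonlite::write_json(list(provenance = prov, report = report),
                         file.path(out_dir, "analysis1_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Run the canonical-correlation analysis
#'
#' Second analysis stage: PCA-reduce the fNIRS features with the
#' cumulative-variance rule, then fit three CCAs pairing the brain scores
#' with taste (VAS), the questionnaire items, and the individual
#' information. For a 19-item questionnaire study with 9 retained brain
#' dimensions the three fits have 1, 9, and 4 canonical dimensions. First-
#' dimension cross-loadings identify the raw variables driving each pair.
#'
#' @param tables A [study_tables()] object (taste required; questionnaire
#'   and individual pairs are fitted when their blocks are present).
#' @param features fNIRS feature table from [build_feature_matrix()], or a
#'   [generate_study()] object in place of both arguments.
#' @param pca_threshold Cumulative-variance threshold for
#'   [select_dimension()].
#' @param ridge Ridge stabilizer for [fit_cca()].
#' @param significance `"bartlett"` (default) or `"permutation"`.
#' @param n_perm,seed Permutation count and seed (permutation method only;
#'   `seed` is recorded in provenance either way).
#' @param out_dir Optional output directory; per-pair JSON results plus CSVs
#'   of weights, canonical features, and cross-loadings.
#' @return An object of class `analysis2`: list with `pca`, `scores`,
#'   per-pair `taste_cca` fits (`taste`, `questionnaire`, `individual`) and
#'   first-dimension `cross_loadings` tibbles.
#' @export
run_analysis2 <- function(tables, features = NULL, pca_threshold = 0.90,
                          ridge = 1e-8, significance = c("bartlett", "permutation"),
                          n_perm = 999, seed = 1, out_dir = NULL) {
  significance <- match.arg(significance)
  if (inherits(tables, "synthetic_study")) {
    study <- tables
    tables <- study$tables
    if (is.null(features)) features <- build_feature_matrix(study$recordings)
  }
  stopifnot(inherits(tables, "study_tables"))
  if (is.null(features)) {
    abort("analysis 2 requires fNIRS features (brain block absent)")
  }

  pca <- fit_pca(features)
  d <- select_dimension(pca, pca_threshold)
  scores <- pca_transform(pca, features, d)
  brain <- feature_matrix_values(scores)

  taste <- matrix(stack_column(tables$vas, "vas"), ncol = 1,
                  dimnames = list(NULL, "vas"))

  questionnaire_block <- NULL
  if (!is.null(tables$questionnaire)) {
    items <- if (!is.null(tables$items)) tables$items$item else
      sort(unique(tables$questionnaire$item))
    questionnaire_block <- do.call(cbind, lapply(items, function(it) {
      resp <- tables$questionnaire |>
        dplyr::filter(.data$item == it) |>
        dplyr::select("participant", "strawberry", "response")
      stack_column(resp, "response")
    }))
    colnames(questionnaire_block) <- items
  }

  individual_block <- NULL
  if (!is.null(tables$individual)) {
    ind_vars <- c(sugar_content = "sugar_content", acidity = "acidity",
                  `sugar-to-acid ratio` = "sugar_acid_ratio", size = "size_indicator")
    individual_block <- do.call(cbind, lapply(ind_vars, function(cn) {
      stack_column(tables$individual, cn)
    }))
    colnames(individual_block) <- names(ind_vars)
  }

  fit_pair <- function(other_block) {
    if (is.null(other_block)) return(NULL)
    fit <- fit_cca(other_block, brain, ridge = ridge)
    if (significance == "permutation") {
      perm <- permutation_significance(other_block, brain, n_perm = n_perm,
                                       seed = seed, ridge = ridge)
      fit$p_values <- perm$p_value
      fit$significance <- "permutation"
    }
    fit
  }
  fits <- list(taste = fit_pair(taste),
               questionnaire = fit_pair(questionnaire_block),
               individual = fit_pair(individual_block))
  loadings <- list(
    questionnaire = if (!is.null(fits$questionnaire))
      cross_loadings(fits$questionnaire, questionnaire_block, side = "a", dimension = 1),
    individual = if (!is.null(fits$individual))
      cross_loadings(fits$individual, individual_block, side = "a", dimension = 1)
  )

  result <- structure(
    list(pca = pca, scores = scores, d_selected = d,
         taste = fits$taste, questionnaire = fits$questionnaire,
         individual = fits$individual, cross_loadings = loadings,
         pca_threshold = pca_threshold, ridge = ridge,
         significance = significance),
    class = "analysis2"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- package_provenance(seed, list(
      analysis = "analysis2", pca_threshold = pca_threshold, ridge = ridge,
      significance = significance, d_selected = d))
    write_csv_provenance(scores, file.path(out_dir, "brain_scores.csv"), prov)
    for (pair in c("taste", "questionnaire", "individual")) {
      fit <- result[[pair]]
      if (is.null(fit)) next
      jsonlite::write_json(
        list(provenance = prov, pair = pair,
             canonical_correlations = fit$canonical_correlations,
             p_values = fit$p_values, d_cca = fit$d_cca),
        file.path(out_dir, paste0("analysis2_", pair, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      weights <- dplyr::bind_rows(
        tibble::as_tibble(fit$projection_a, rownames = "variable") |>
          dplyr::mutate(block = pair, .before = 1),
        tibble::as_tibble(fit$projection_b, rownames = "variable") |>
          dplyr::mutate(block = "brain", .before = 1)
      )
      write_csv_provenance(weights,
                           file.path(out_dir, paste0("analysis2_", pair, "_weights.csv")), prov)
      feats <- dplyr::bind_cols(
        scores[c("participant", "strawberry")],
        stats::setNames(tibble::as_tibble(fit$canonical_features_a),
                        paste0(pair, "_", colnames(fit$canonical_features_a))),
        stats::setNames(tibble::as_tibble(fit$canonical_features_b),
                        paste0("brain_", colnames(fit$canonical_features_b)))
      )
      write_csv_provenance(feats,
                           file.path(out_dir, paste0("analysis2_", pair, "_features.csv")), prov)
    }
    for (pair in c("questionnaire", "individual")) {
      if (is.null(loadings[[pair]])) next
      write_csv_provenance(loadings[[pair]],
                           file.path(out_dir, paste0("analysis2_", pair, "_crossloadings.csv")),
                           prov)
    }
  }
  result
}

#' @export
print.analysis2 <- function(x, ...) {
  cat("<analysis2> brain scores:", x$d_selected, "PCA dimensions (threshold",
      x$pca_threshold, ")\n")
  for (pair in c("taste", "questionnaire", "individual")) {
    if (is.null(x[[pair]])) next
    lam <- x[[pair]]$canonical_correlations
    cat(sprintf("  brain x %-13s D_cca = %d, first canonical correlation %.3f (p = %.3f)\n",
                pair, x[[pair]]$d_cca, lam[1], x[[pair]]$p_values[1]))
  }
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Materializes a [generate_study()] result in the layout the other pipeline
#' stages read: one long-format study CSV, one trace CSV per
#' (participant, strawberry, chromophore), and a JSON sidecar with the event
#' markers, ground truth, and configuration.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if missing).
#' @return The generated `synthetic_study`, invisibly.
#' @export
make_synthetic <- function(config = synthetic_config(), out_dir) {
  study <- generate_study(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- package_provenance(config$seed, list(analysis = "synthetic_study"))
  write_study_csv(study$tables, file.path(out_dir, "study.csv"),
                  provenance = paste(names(prov), unlist(prov), sep = "=", collapse = " "))
  markers <- list()
  for (key in names(study$recordings)) {
    rec <- study$recordings[[key]]
    long <- as_tibble(rec)
    for (chrom in c("oxy", "deoxy")) {
      write_csv_provenance(
        dplyr::filter(long, .data$chromophore == chrom),
        file.path(out_dir, sprintf("trace_%s_%s.csv", key, chrom)), prov)
    }
    markers[[key]] <- list(participant = rec$participant, strawberry = rec$strawberry,
                           sampling_rate = rec$sampling_rate,
                           bite_onset_s = rec$bite_onset_s,
                           swallow_end_s = rec$swallow_end_s)
  }
  jsonlite::write_json(
    list(provenance = prov, markers = markers,
         truth = list(latent = study$truth$latent,
                      responsive_channels = study$truth$responsive_channels,
                      planted = study$truth$planted),
         config = unclass(config)),
    file.path(out_dir, "study_meta.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(study)
}

#' Read a synthetic study back from disk
#'
#' Inverse of [make_synthetic()].
#'
#' @param dir Directory written by [make_synthetic()].
#' @return A `synthetic_study` object (the `config` element is the stored
#'   configuration list).
#' @export
read_study_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "study_meta.json"), simplifyVector = TRUE)
  tables <- read_study_csv(file.path(dir, "study.csv"))
  keys <- names(meta$markers)
  recordings <- purrr::map(keys, function(key) {
    m <- meta$markers[[key]]
    long <- dplyr::bind_rows(
      readr::read_csv(file.path(dir, sprintf("trace_%s_oxy.csv", key)),
                      comment = "#", show_col_types = FALSE, progress = FALSE),
      readr::read_csv(file.path(dir, sprintf("trace_%s_deoxy.csv", key)),
                      comment = "#", show_col_types = FALSE, progress = FALSE)
    )
    wide <- long |>
      dplyr::mutate(trace = chan_col(.data$channel, .data$chromophore)) |>
      dplyr::select("time_s", "trace", "value") |>
      tidyr::pivot_wider(names_from = "trace", values_from = "value") |>
      dplyr::arrange(.data$time_s)
    values <- as.matrix(dplyr::select(wide, -"time_s"))
    fnirs_recording(time_s = wide$time_s, values = values,
                    sampling_rate = m$sampling_rate,
                    bite_onset_s = m$bite_onset_s, swallow_end_s = m$swallow_end_s,
                    participant = m$participant, strawberry = m$strawberry)
  })
  names(recordings) <- keys
  structure(
    list(tables = tables, recordings = recordings,
         truth = list(latent = tibble::as_tibble(meta$truth$latent),
                      responsive_channels = meta$truth$responsive_channels,
                      planted = meta$truth$planted),
         config = meta$config),
    class = "synthetic_study"
  )
}
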