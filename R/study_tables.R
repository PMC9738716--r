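#' Sample key: the shared row order of all stacked vectors
#'
#' Every length-`4P` stacked vector in the analysis orders its elements
#' strawberry-block by strawberry-block (s1, s2, s3, s4), participants
#' `1..P` within each block, so element `(s_rank - 1) * P + p` belongs to
#' participant `p` eating strawberry `s`.
#'
#' @param n_participants Number of participants `P` (19 in the packaged study).
#' @return A tibble with columns `row`, `participant`, `strawberry`, one row
#'   per (participant, strawberry) sample, sorted by `row`.
#' @examples
#' sample_key(3)
#' @export
sample_key <- function(n_participants) {
  stopifnot(is.numeric(n_participants), length(n_participants) == 1, n_participants >= 1)
  P <- as.integer(n_participants)
  tibble::tibble(
    row = seq_len(4L * P),
    participant = rep(seq_len(P), times = 4L),
    strawberry = rep(strawberry_levels, each = P)
  )
}

#' Load a packaged study table
#'
#' The tasting study's printed data ship with the package: the visual analog
#' scale (VAS) taste scores in millimetres for 19 participants x 4
#' strawberries, the per-strawberry composition measurements (sugar content,
#' acidity, sugar-to-acid ratio), and the 19-item questionnaire catalogue
#' (the responses themselves were never published and are not packaged).
#'
#' @param name One of `"vas_table1"`, `"individual_table3"`,
#'   `"questionnaire_catalogue"`.
#' @return A tibble. For `vas_table1`: columns `participant`, `strawberry`,
#'   `vas`. For `individual_table3`: `participant`, `strawberry`,
#'   `sugar_content`, `acidity`, `sugar_acid_ratio`, `size_indicator`
#'   (1 = large, 0 = small). For `questionnaire_catalogue`: `item`, `factor`,
#'   `prompt`.
#' @examples
#' load_fixture("vas_table1")
#' @export
load_fixture <- function(name = c("vas_table1", "individual_table3", "questionnaire_catalogue")) {
  if (length(name) != 1 || !name %in% c("vas_table1", "individual_table3", "questionnaire_catalogue")) {
    abort(paste0("unknown fixture name: ", paste(name, collapse = ", ")))
  }
  file <- switch(name,
    vas_table1 = "vas_table1.csv",
    individual_table3 = "individual_table3.csv",
    questionnaire_catalogue = "questionnaire_items.csv"
  )
  path <- system.file("extdata", file, package = "tastecca", mustWork = TRUE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  switch(name,
    vas_table1 = {
      out <- raw |>
        dplyr::select("participant", "strawberry", vas = "value")
      validate_vas(out)
      out
    },
    individual_table3 = {
      out <- raw |>
        tidyr::pivot_wider(names_from = "variable", values_from = "value") |>
        dplyr::mutate(size_indicator = unname(strawberry_size_indicator[.data$strawberry])) |>
        dplyr::select("participant", "strawberry", "sugar_content", "acidity",
                      "sugar_acid_ratio", "size_indicator")
      validate_individual(out)
      out
    },
    questionnaire_catalogue = tibble::as_tibble(raw)
  )
}

#' Bundle the study's data tables
#'
#' A `study_tables` object holds the three tabular blocks of a tasting study
#' sharing one (participant, strawberry) sample layout: VAS taste scores,
#' questionnaire responses (optional; 5-point Likert), and per-strawberry
#' individual information. All downstream stacking inherits the [sample_key()]
#' row order.
#'
#' @param vas Tibble with columns `participant`, `strawberry`, `vas`
#'   (millimetres, 0-100), complete over `P` participants x 4 strawberries.
#' @param individual Optional tibble with `participant`, `strawberry`,
#'   `sugar_content`, `acidity`, `sugar_acid_ratio`, `size_indicator`.
#' @param questionnaire Optional tibble with `participant`, `strawberry`,
#'   `item`, `response` (integer 1..5), complete over items x samples.
#' @param items Questionnaire item catalogue (`item`, `factor`, `prompt`);
#'   defaults to the packaged 19-item catalogue when responses are supplied.
#' @return An object of class `study_tables`: a list with elements `vas`,
#'   `individual`, `questionnaire`, `items`, `n_participants`.
#' @examples
#' study_tables(load_fixture("vas_table1"), load_fixture("individual_table3"))
#' @export
study_tables <- function(vas, individual = NULL, questionnaire = NULL, items = NULL) {
  validate_vas(vas)
  P <- length(unique(vas$participant))
  if (!is.null(individual)) validate_individual(individual, P)
  if (!is.null(questionnaire)) {
    if (is.null(items)) items <- load_fixture("questionnaire_catalogue")
    validate_questionnaire(questionnaire, P, items)
  }
  structure(
    list(vas = vas, individual = individual, questionnaire = questionnaire,
         items = items, n_participants = P),
    class = "study_tables"
  )
}

#' @export
print.study_tables <- function(x, ...) {
  cat("<study_tables>", x$n_participants, "participants x 4 strawberries\n")
  cat("  vas:          ", nrow(x$vas), "scores\n")
  cat("  individual:   ", if (is.null(x$individual)) "absent" else paste(nrow(x$individual), "rows"), "\n")
  cat("  questionnaire:", if (is.null(x$questionnaire)) "absent" else
    paste(nrow(x$questionnaire), "responses,", length(unique(x$questionnaire$item)), "items"), "\n")
  invisible(x)
}

#' The packaged tasting study
#'
#' Convenience wrapper returning a [study_tables()] object built from the
#' packaged VAS and composition fixtures plus the questionnaire catalogue.
#' Questionnaire responses are `NULL` (never published).
#'
#' @return A `study_tables` object.
#' @export
study_fixtures <- function() {
  st <- study_tables(load_fixture("vas_table1"), load_fixture("individual_table3"))
  st$items <- load_fixture("questionnaire_catalogue")
  st
}

check_complete_grid <- function(df, P, what) {
  key <- sample_key(P)
  found <- dplyr::distinct(df, .data$participant, .data$strawberry)
  missing <- dplyr::anti_join(key[c("participant", "strawberry")], found,
                              by = c("participant", "strawberry"))
  if (nrow(missing) > 0) {
    abort(paste0(what, " table incomplete: missing ", nrow(missing),
                 " (participant, strawberry) cells, e.g. participant ",
                 missing$participant[1], " ", missing$strawberry[1]))
  }
  extra <- dplyr::anti_join(found, key[c("participant", "strawberry")],
                            by = c("participant", "strawberry"))
  if (nrow(extra) > 0) {
    abort(paste0(what, " table has cells outside the 1..P x s1..s4 grid"))
  }
  invisible(TRUE)
}

validate_vas <- function(vas, P = length(unique(vas$participant))) {
  stopifnot(all(c("participant", "strawberry", "vas") %in% names(vas)))
  if (anyDuplicated(vas[c("participant", "strawberry")])) {
    abort("duplicate (participant, strawberry) rows in VAS table")
  }
  check_complete_grid(vas, P, "VAS")
  if (anyNA(vas$vas) || any(vas$vas < 0 | vas$vas > 100)) {
    abort("VAS values must lie in [0, 100] millimetres with no missing cells")
  }
  invisible(TRUE)
}

validate_individual <- function(ind, P = length(unique(ind$participant))) {
  needed <- c("participant", "strawberry", "sugar_content", "acidity",
              "sugar_acid_ratio", "size_indicator")
  stopifnot(all(needed %in% names(ind)))
  if (anyDuplicated(ind[c("participant", "strawberry")])) {
    abort("duplicate (participant, strawberry) rows in individual-information table")
  }
  check_complete_grid(ind, P, "individual-information")
  if (any(ind$sugar_content <= 0) || any(ind$acidity <= 0)) {
    abort("sugar_content and acidity must be positive percentages")
  }
  expected_size <- unname(strawberry_size_indicator[ind$strawberry])
  if (!all(ind$size_indicator == expected_size)) {
    abort("size_indicator must be 1 for s1/s3 (large) and 0 for s2/s4 (small)")
  }
  # printed one-decimal rounding of the ratio column leaves up to ~0.15 slack
  dev <- abs(ind$sugar_acid_ratio - ind$sugar_content / ind$acidity)
  if (any(dev > 0.15)) {
    abort("sugar_acid_ratio inconsistent with sugar_content / acidity (deviation > 0.15)")
  }
  invisible(TRUE)
}

validate_questionnaire <- function(q, P, items) {
  stopifnot(all(c("participant", "strawberry", "item", "response") %in% names(q)))
  if (anyDuplicated(q[c("participant", "strawberry", "item")])) {
    abort("duplicate (participant, strawberry, item) questionnaire responses")
  }
  if (anyNA(q$response) || any(q$response %% 1 != 0) || any(q$response < 1 | q$response > 5)) {
    abort("questionnaire responses must be integers on the 5-point Likert scale 1..5")
  }
  per_item <- table(q$item)
  if (!setequal(names(per_item), items$item) || any(per_item != 4L * P)) {
    abort("questionnaire table incomplete: every catalogue item needs one response per sample")
  }
  invisible(TRUE)
}

#' Stack a table column into the shared sample order
#'
#' Flattens one variable of a study table into the length-`4P` vector used by
#' the correlation and CCA stages: strawberry blocks s1..s4 concatenated,
#' participants 1..P within each block (see [sample_key()]).
#'
#' @param table A tibble with `participant`, `strawberry`, and the requested
#'   variable column (e.g. the `vas` component of a [study_tables()] object).
#' @param variable Column name to stack.
#' @return Numeric vector of length `4P`.
#' @examples
#' stack_column(load_fixture("vas_table1"), "vas")[1]   # participant 1, s1
#' @export
stack_column <- function(table, variable) {
  stopifnot(all(c("participant", "strawberry") %in% names(table)))
  if (!variable %in% names(table)) {
    abort(paste0("no column '", variable, "' in table"))
  }
  if (anyNA(table[[variable]])) abort("missing cells in column to stack")
  P <- length(unique(table$participant))
  check_complete_grid(table, P, variable)
  ordered <- table |>
    dplyr::mutate(.s_rank = match(.data$strawberry, strawberry_levels)) |>
    dplyr::arrange(.data$.s_rank, .data$participant)
  ordered[[variable]]
}

#' Rebuild a (participant, strawberry) table from a stacked vector
#'
#' Inverse of [stack_column()].
#'
#' @param x Numeric vector of length `4P` in [sample_key()] order.
#' @param n_participants `P`.
#' @param name Name for the value column.
#' @return A tibble `participant`, `strawberry`, `<name>`.
#' @export
unstack_column <- function(x, n_participants, name = "value") {
  P <- as.integer(n_participants)
  if (length(x) != 4L * P) abort("stacked vector length must be 4 * n_participants")
  out <- sample_key(P)[c("participant", "strawberry")]
  out[[name]] <- x
  out
}

#' Mean and sample standard deviation of a column
#'
#' The summary convention of the study tables: arithmetic mean and the
#' n-1-denominator (sample) standard deviation, which reproduces the printed
#' summary rows of the packaged tables.
#'
#' @param x Numeric vector, length >= 2.
#' @return A one-row tibble with columns `mean` and `sd`.
#' @examples
#' vas <- load_fixture("vas_table1")
#' mean_sd(vas$vas[vas$strawberry == "s1"])
#' @export
mean_sd <- function(x) {
  if (length(x) < 2 || anyNA(x)) abort("mean_sd() needs at least two non-missing values")
  tibble::tibble(mean = mean(x), sd = stats::sd(x))
}

# ---- long-format CSV I/O -----------------------------------------------------

individual_csv_vars <- c("sugar_content", "acidity", "sugar_acid_ratio", "size")

#' Read a study from a long-format CSV
#'
#' One CSV holds every tabular block in the long dialect
#' `participant,strawberry,variable,value`: `variable` is `vas` for taste
#' scores, a catalogue item id (`Q1-1` .. `Q4-4`) for questionnaire
#' responses, or one of `sugar_content`, `acidity`, `sugar_acid_ratio`,
#' `size` for individual information. `size` rows are optional (derived from
#' the strawberry type when absent). Lines starting `#` are ignored.
#'
#' @param path CSV file path.
#' @param items Questionnaire catalogue used to recognise item variables.
#' @return A [study_tables()] object.
#' @export
read_study_csv <- function(path, items = load_fixture("questionnaire_catalogue")) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  needed <- c("participant", "strawberry", "variable", "value")
  if (!all(needed %in% names(raw))) {
    abort("study CSV needs columns participant, strawberry, variable, value")
  }
  if (!all(raw$strawberry %in% strawberry_levels)) {
    abort("strawberry must be one of s1, s2, s3, s4")
  }
  if (anyDuplicated(raw[c("participant", "strawberry", "variable")])) {
    abort("duplicate (participant, strawberry, variable) rows in study CSV")
  }
  vas <- raw |>
    dplyr::filter(.data$variable == "vas") |>
    dplyr::select("participant", "strawberry", vas = "value")
  if (nrow(vas) == 0) abort("study CSV contains no 'vas' rows")

  q <- raw |> dplyr::filter(.data$variable %in% items$item)
  questionnaire <- NULL
  if (nrow(q) > 0) {
    questionnaire <- q |>
      dplyr::select("participant", "strawberry", item = "variable", response = "value")
  }

  ind_long <- raw |> dplyr::filter(.data$variable %in% individual_csv_vars)
  individual <- NULL
  if (nrow(ind_long) > 0) {
    individual <- ind_long |>
      tidyr::pivot_wider(names_from = "variable", values_from = "value")
    if (!"size" %in% names(individual)) {
      individual$size <- unname(strawberry_size_indicator[individual$strawberry])
    }
    individual <- dplyr::rename(individual, size_indicator = "size")
  }

  unknown <- setdiff(unique(raw$variable), c("vas", items$item, individual_csv_vars))
  if (length(unknown) > 0) {
    abort(paste0("unknown study variables: ", paste(unknown, collapse = ", ")))
  }
  study_tables(vas, individual = individual, questionnaire = questionnaire, items = items)
}

#' Write a study to a long-format CSV
#'
#' Inverse of [read_study_csv()]; write-then-read reproduces every cell.
#'
#' @param tables A [study_tables()] object.
#' @param path Output CSV path.
#' @param provenance Optional character scalar written as a leading `#` comment.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(tables, path, provenance = NULL) {
  stopifnot(inherits(tables, "study_tables"))
  long <- dplyr::bind_rows(
    tables$vas |>
      dplyr::transmute(.data$participant, .data$strawberry, variable = "vas", value = .data$vas),
    if (!is.null(tables$questionnaire)) {
      tables$questionnaire |>
        dplyr::transmute(.data$participant, .data$strawberry,
                         variable = .data$item, value = as.numeric(.data$response))
    },
    if (!is.null(tables$individual)) {
      tables$individual |>
        dplyr::rename(size = "size_indicator") |>
        tidyr::pivot_longer(dplyr::all_of(individual_csv_vars),
                            names_to = "variable", values_to = "value") |>
        dplyr::select("participant", "strawberry", "variable", "value")
    }
  )
  lines <- character(0)
  if (!is.null(provenance)) lines <- paste0("# ", provenance)
  writeLines(c(lines, readr::format_csv(long)), path)
  invisible(path)
}
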