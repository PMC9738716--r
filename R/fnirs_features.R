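#' Construct an fNIRS recording
#'
#' A recording holds the multichannel oxy-/deoxy-hemoglobin time series of one
#' eating task, with event markers delimiting the bite-to-swallow epoch.
#'
#' @param time_s Sample times in seconds (strictly increasing, regular grid).
#' @param values Numeric matrix, one row per time point, one column per
#'   (channel, chromophore) named `ch01_oxy` .. `ch20_deoxy`.
#' @param sampling_rate Hz.
#' @param bite_onset_s,swallow_end_s Event markers in seconds; must satisfy
#'   `bite_onset_s < swallow_end_s` and lie within the trace.
#' @param participant,strawberry Sample identity.
#' @return An object of class `fnirs_recording`.
#' @export
fnirs_recording <- function(time_s, values, sampling_rate,
                            bite_onset_s, swallow_end_s,
                            participant, strawberry) {
  stopifnot(is.matrix(values), nrow(values) == length(time_s))
  if (bite_onset_s >= swallow_end_s) {
    abort("swallow_end_s must come after bite_onset_s")
  }
  if (bite_onset_s < min(time_s) || swallow_end_s > max(time_s)) {
    abort("epoch markers lie outside the recorded trace")
  }
  structure(
    list(time_s = time_s, values = values, sampling_rate = sampling_rate,
         bite_onset_s = bite_onset_s, swallow_end_s = swallow_end_s,
         participant = participant, strawberry = strawberry),
    class = "fnirs_recording"
  )
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat("<fnirs_recording> participant", x$participant, x$strawberry, "-",
      ncol(x$values), "traces,", length(x$time_s), "samples at",
      x$sampling_rate, "Hz; epoch", sprintf("[%.2f, %.2f] s", x$bite_onset_s, x$swallow_end_s), "\n")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.fnirs_recording <- function(x, ...) {
  long <- tibble::as_tibble(x$values) |>
    dplyr::mutate(time_s = x$time_s) |>
    tidyr::pivot_longer(-"time_s", names_to = "trace", values_to = "value") |>
    tidyr::separate_wider_regex("trace", c("ch", channel = "\\d+", "_", chromophore = ".*"))
  long |>
    dplyr::transmute(time_s = .data$time_s, channel = as.integer(.data$channel),
                     chromophore = .data$chromophore, value = .data$value)
}

#' Extract the eating epoch from one trace
#'
#' Returns the samples whose time lies in the closed interval
#' `[bite_onset_s, swallow_end_s]` for one channel/chromophore.
#'
#' @param recording An [fnirs_recording()].
#' @param channel Channel id 1..20.
#' @param chromophore `"oxy"` or `"deoxy"`.
#' @return Numeric vector of epoch samples (length >= 2).
#' @export
extract_epoch <- function(recording, channel, chromophore = c("oxy", "deoxy")) {
  stopifnot(inherits(recording, "fnirs_recording"))
  chromophore <- match.arg(chromophore)
  col <- chan_col(channel, chromophore)
  if (!col %in% colnames(recording$values)) {
    abort(paste0("no trace for channel ", channel, " / ", chromophore))
  }
  keep <- recording$time_s >= recording$bite_onset_s &
    recording$time_s <= recording$swallow_end_s
  out <- recording$values[keep, col]
  if (length(out) < 2) abort("epoch contains fewer than 2 samples")
  out
}

epoch_stat_names <- c("mean", "std", "rms", "max", "min")

#' Epoch summary statistics
#'
#' The five per-trace statistics of the eating epoch: mean, sample (n-1)
#' standard deviation, root-mean-square, maximum and minimum.
#'
#' @param series Numeric vector with at least 2 samples.
#' @return A one-row tibble with columns `mean`, `std`, `rms`, `max`, `min`.
#' @examples
#' epoch_statistics(c(1, -1, 1, -1))
#' @export
epoch_statistics <- function(series) {
  if (length(series) < 2 || anyNA(series)) {
    abort("epoch_statistics() needs at least two non-missing samples")
  }
  tibble::tibble(
    mean = mean(series),
    std = stats::sd(series),
    rms = sqrt(mean(series^2)),
    max = max(series),
    min = min(series)
  )
}

# Fixed 200-column layout: statistic (mean, std, rms, max, min) slowest,
# then channel 1..20, then chromophore (oxy, deoxy).
feature_column_names <- function() {
  traces <- as.vector(t(outer(1:20, c("oxy", "deoxy"), chan_col)))
  as.vector(t(outer(epoch_stat_names, traces, paste, sep = "_")))
}

#' Build the per-sample fNIRS feature matrix
#'
#' Converts each recording's eating epoch into the 200-dimensional feature
#' vector (5 statistics x 20 channels x 2 chromophores) and assembles all
#' samples into one table in [sample_key()] row order. Epochs may have
#' different lengths across recordings.
#'
#' @param recordings List of [fnirs_recording()] objects, one per
#'   (participant, strawberry) sample, in any order.
#' @return A tibble with `participant`, `strawberry` and 200 feature columns
#'   named `<statistic>_ch<channel>_<chromophore>`, rows in sample-key order.
#' @export
build_feature_matrix <- function(recordings) {
  stopifnot(length(recordings) > 0, all(purrr::map_lgl(recordings, inherits, "fnirs_recording")))
  ids <- purrr::map_dfr(recordings, \(r) tibble::tibble(participant = r$participant,
                                                        strawberry = r$strawberry))
  if (anyDuplicated(ids)) abort("duplicate recordings for the same (participant, strawberry)")
  P <- length(unique(ids$participant))
  key <- sample_key(P)
  matched <- dplyr::left_join(key, dplyr::mutate(ids, idx = dplyr::row_number()),
                              by = c("participant", "strawberry"))
  if (anyNA(matched$idx)) {
    abort("missing recordings: every (participant, strawberry) sample needs one")
  }
  cols <- feature_column_names()
  rows <- purrr::map(matched$idx, function(i) {
    r <- recordings[[i]]
    keep <- r$time_s >= r$bite_onset_s & r$time_s <= r$swallow_end_s
    epoch <- r$values[keep, , drop = FALSE]
    if (nrow(epoch) < 2) abort("epoch contains fewer than 2 samples")
    stats5 <- rbind(
      colMeans(epoch),
      apply(epoch, 2, stats::sd),
      sqrt(colMeans(epoch^2)),
      apply(epoch, 2, max),
      apply(epoch, 2, min)
    )
    rownames(stats5) <- epoch_stat_names
    out <- as.vector(t(stats5))          # per-statistic blocks of 40 traces
    names(out) <- as.vector(t(outer(epoch_stat_names, colnames(epoch), paste, sep = "_")))
    out[cols]
  })
  features <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(key[c("participant", "strawberry")], features)
}

#' Drop key columns from a feature table
#'
#' @param features Tibble with `participant`, `strawberry` plus numeric columns.
#' @return Numeric matrix of the feature columns.
#' @export
feature_matrix_values <- function(features) {
  as.matrix(dplyr::select(features, -dplyr::any_of(c("participant", "strawberry"))))
}
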