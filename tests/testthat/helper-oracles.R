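# Independent oracles and fixture builders used across the suite.

# Direct evaluation of the product-moment correlation from its defining sums.
brute_pearson <- function(a, b) {
  am <- sum(a) / length(a)
  bm <- sum(b) / length(b)
  sum((a - am) * (b - bm)) /
    (sqrt(sum((a - am)^2)) * sqrt(sum((b - bm)^2)))
}

# Unit direction grids at a fixed angular step: all of S^0 / half of S^1 /
# half of S^2 (antipodal directions give the same |correlation|).
unit_directions <- function(d, step_deg = 1) {
  if (d == 1) return(matrix(1, 1, 1))
  if (d == 2) {
    ang <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
    return(rbind(cos(ang), sin(ang)))
  }
  if (d == 3) {
    th <- seq(0, 180, by = step_deg) * pi / 180      # polar
    ph <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
    g <- expand.grid(th = th, ph = ph)
    return(rbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th)))
  }
  stop("grid oracle supports at most 3 columns")
}

# Exhaustive grid maximization of the projected Pearson correlation between
# two blocks; the brute-force reference for the first canonical correlation.
grid_max_cancor <- function(A, B, step_deg = 1, chunk = 20000L) {
  row_standardize <- function(S) {
    S <- S - rowMeans(S)
    S / pmax(sqrt(rowSums(S^2)), 1e-300)
  }
  Sa <- row_standardize(t(A %*% unit_directions(ncol(A), step_deg)))
  Sb <- row_standardize(t(B %*% unit_directions(ncol(B), step_deg)))
  best <- 0
  for (start in seq(1, nrow(Sa), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(Sa))
    best <- max(best, abs(Sa[rows, , drop = FALSE] %*% t(Sb)))
  }
  best
}

# Minimal single-trace recording on a regular grid.
make_test_recording <- function(values, sampling_rate = 10,
                                bite_onset_s = NULL, swallow_end_s = NULL,
                                participant = 1, strawberry = "s1") {
  if (is.vector(values)) {
    values <- matrix(values, ncol = 1, dimnames = list(NULL, "ch01_oxy"))
  }
  t <- (seq_len(nrow(values)) - 1) / sampling_rate
  fnirs_recording(
    time_s = t, values = values, sampling_rate = sampling_rate,
    bite_onset_s = bite_onset_s %||% min(t),
    swallow_end_s = swallow_end_s %||% max(t),
    participant = participant, strawberry = strawberry
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Full 40-trace random recording for one sample.
make_random_recording <- function(participant, strawberry, n_t = 30, seed = 1) {
  set.seed(seed)
  cols <- as.vector(outer(1:20, c("oxy", "deoxy"),
                          function(ch, cr) sprintf("ch%02d_%s", ch, cr)))
  values <- matrix(rnorm(n_t * 40), n_t, 40, dimnames = list(NULL, cols))
  t <- (seq_len(n_t) - 1) / 10
  fnirs_recording(time_s = t, values = values, sampling_rate = 10,
                  bite_onset_s = t[5], swallow_end_s = t[n_t - 4],
                  participant = participant, strawberry = strawberry)
}
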