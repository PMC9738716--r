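#' Configuration for a synthetic tasting study
#'
#' Defines the generative model used to emulate the tasting experiment: a
#' latent "taste" value per (participant, strawberry) sample drives the VAS
#' score, the sugar-to-acid ratio, the reward- and cultural-factor
#' questionnaire items, and an epoch-locked hemodynamic response on a subset
#' of fNIRS channels. All cross-block links are expressed as target Pearson
#' correlations on the latent (pre-discretization, pre-clipping) scale.
#'
#' @param n_participants Participants `P`; the study has `4P` samples.
#' @param latent_taste_sd Standard deviation of the latent taste variable
#'   (arbitrary units; rescales brain response amplitudes via `brain_gain`).
#' @param link_vas Target correlation of the VAS score with latent taste.
#' @param link_reward Target correlation of reward-factor items with the VAS.
#' @param link_cultural Target correlation of cultural-factor items with the
#'   brain latent (identified with latent taste).
#' @param link_ratio Target correlation of the sugar-to-acid ratio with
#'   latent taste.
#' @param brain_gain Peak hemodynamic response amplitude per unit latent
#'   taste on responsive channels.
#' @param channel_subset Responsive channel ids (subset of 1..20).
#' @param sampling_rate Trace sampling rate in Hz.
#' @param epoch_seconds Nominal bite-to-swallow epoch duration in seconds;
#'   each recording jitters it by +-20% to mimic per-participant eating-time
#'   differences.
#' @param noise_sd White-noise standard deviation added to every trace sample.
#' @param drift_amp Amplitude of a slow (60 s period) sinusoidal baseline
#'   drift with random phase per channel.
#' @param seed Integer seed; the whole study is a deterministic function of it.
#' @return An object of class `synthetic_config` (a named list).
#' @export
synthetic_config <- function(n_participants = 19,
                             latent_taste_sd = 1,
                             link_vas = 0.6,
                             link_reward = 0.6,
                             link_cultural = 0.5,
                             link_ratio = 0,
                             brain_gain = 1,
                             channel_subset = 1:6,
                             sampling_rate = 10,
                             epoch_seconds = 6,
                             noise_sd = 0.3,
                             drift_amp = 0.2,
                             seed = 1) {
  cfg <- list(
    n_participants = as.integer(n_participants), latent_taste_sd = latent_taste_sd,
    link_vas = link_vas, link_reward = link_reward, link_cultural = link_cultural,
    link_ratio = link_ratio, brain_gain = brain_gain,
    channel_subset = as.integer(channel_subset), sampling_rate = sampling_rate,
    epoch_seconds = epoch_seconds, noise_sd = noise_sd, drift_amp = drift_amp,
    seed = as.integer(seed)
  )
  links <- c(cfg$link_vas, cfg$link_reward, cfg$link_cultural, cfg$link_ratio)
  if (any(abs(links) > 1)) abort("correlation targets must lie in [-1, 1]")
  if (cfg$n_participants < 1) abort("n_participants must be >= 1")
  if (cfg$sampling_rate <= 0 || cfg$epoch_seconds <= 0) {
    abort("sampling_rate and epoch_seconds must be positive")
  }
  if (cfg$noise_sd < 0 || cfg$drift_amp < 0 || cfg$latent_taste_sd <= 0) {
    abort("noise_sd, drift_amp must be >= 0 and latent_taste_sd > 0")
  }
  if (length(cfg$channel_subset) == 0 || !all(cfg$channel_subset %in% 1:20)) {
    abort("channel_subset must be a nonempty subset of 1..20")
  }
  check_link_feasibility(cfg)
  structure(cfg, class = "synthetic_config")
}

# Assemble the implied correlation matrix over (latent, vas, ratio, cultural,
# reward) and reject non-PSD targets rather than repairing them.
check_link_feasibility <- function(cfg) {
  lv <- cfg$link_vas; lr <- cfg$link_reward; lc <- cfg$link_cultural; li <- cfg$link_ratio
  R <- diag(5)
  rownames(R) <- colnames(R) <- c("latent", "vas", "ratio", "cultural", "reward")
  R["latent", "vas"] <- R["vas", "latent"] <- lv
  R["latent", "ratio"] <- R["ratio", "latent"] <- li
  R["latent", "cultural"] <- R["cultural", "latent"] <- lc
  R["vas", "reward"] <- R["reward", "vas"] <- lr
  R["vas", "ratio"] <- R["ratio", "vas"] <- lv * li
  R["vas", "cultural"] <- R["cultural", "vas"] <- lv * lc
  R["latent", "reward"] <- R["reward", "latent"] <- lv * lr
  R["ratio", "cultural"] <- R["cultural", "ratio"] <- li * lc
  R["ratio", "reward"] <- R["reward", "ratio"] <- li * lv * lr
  R["cultural", "reward"] <- R["reward", "cultural"] <- lc * lv * lr
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    abort("infeasible correlation combination: implied correlation matrix is not positive semi-definite")
  }
  invisible(R)
}

# Counter-based substream seeds so per-recording streams are reproducible
# independently of generation order.
substream_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in idx) h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  as.integer(h)
}

chan_col <- function(channel, chromophore) sprintf("ch%02d_%s", channel, chromophore)

# Smooth unimodal hemodynamic-like kernel over the epoch, peak scaled to 1.
response_kernel <- function(t, onset, epoch_len) {
  x <- t - onset
  k <- ifelse(x >= 0, stats::dgamma(x, shape = 3, scale = epoch_len / 6), 0)
  peak <- stats::dgamma(2 * epoch_len / 6, shape = 3, scale = epoch_len / 6)
  k / peak
}

#' Generate one synthetic fNIRS trace
#'
#' Simulates a single channel/chromophore trace for one eating task: 4 s
#' pre-epoch baseline, the bite-to-swallow epoch, 4 s post-epoch, at the
#' configured sampling rate. Responsive channels (in `config$channel_subset`)
#' carry a smooth gamma-shaped epoch-locked response of peak amplitude
#' `brain_gain * latent` (sign flipped for the deoxy chromophore); all
#' channels carry white noise and a slow sinusoidal drift.
#'
#' @param latent Latent taste value of the sample (in `latent_taste_sd` units).
#' @param config A [synthetic_config()].
#' @param channel Channel id 1..20.
#' @param chromophore `"oxy"` or `"deoxy"`.
#' @param epoch_len Epoch length in seconds; defaults to `config$epoch_seconds`.
#' @param seed Stream seed; defaults to `config$seed`.
#' @return A tibble `time_s`, `value` with attributes `bite_onset_s` and
#'   `swallow_end_s`.
#' @export
generate_fnirs_trace <- function(latent, config, channel,
                                 chromophore = c("oxy", "deoxy"),
                                 epoch_len = config$epoch_seconds,
                                 seed = config$seed) {
  chromophore <- match.arg(chromophore)
  if (!channel %in% 1:20) abort("channel must be in 1..20")
  pre <- 4; post <- 4
  t <- seq(0, pre + epoch_len + post, by = 1 / config$sampling_rate)
  sign_c <- if (chromophore == "oxy") 1 else -1
  responsive <- channel %in% config$channel_subset
  signal <- if (responsive) {
    sign_c * config$brain_gain * latent * response_kernel(t, pre, epoch_len)
  } else {
    rep(0, length(t))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 97L, channel, match(chromophore, c("oxy", "deoxy"))))
  phase <- runif(1, 0, 2 * pi)
  drift <- config$drift_amp * sin(2 * pi * t / 60 + phase)
  value <- signal + drift + rnorm(length(t), 0, config$noise_sd)
  out <- tibble::tibble(time_s = t, value = value)
  attr(out, "bite_onset_s") <- pre
  attr(out, "swallow_end_s") <- pre + epoch_len
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Build the full 20-channel x 2-chromophore recording for one sample.
make_recording <- function(latent, cfg, participant, strawberry, sample_index) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(cfg$seed, 2L, sample_index))
  pre <- 4; post <- 4
  epoch_len <- cfg$epoch_seconds * runif(1, 0.8, 1.2)
  t <- seq(0, pre + epoch_len + post, by = 1 / cfg$sampling_rate)
  n_t <- length(t)
  kernel <- response_kernel(t, pre, epoch_len)
  cols <- as.vector(outer(1:20, c("oxy", "deoxy"), chan_col))
  values <- matrix(0, n_t, length(cols), dimnames = list(NULL, cols))
  for (ch in 1:20) {
    for (chrom in c("oxy", "deoxy")) {
      sign_c <- if (chrom == "oxy") 1 else -1
      amp <- if (ch %in% cfg$channel_subset) sign_c * cfg$brain_gain * latent else 0
      phase <- runif(1, 0, 2 * pi)
      values[, chan_col(ch, chrom)] <-
        amp * kernel +
        cfg$drift_amp * sin(2 * pi * t / 60 + phase) +
        rnorm(n_t, 0, cfg$noise_sd)
    }
  }
  fnirs_recording(time_s = t, values = values, sampling_rate = cfg$sampling_rate,
                  bite_onset_s = pre, swallow_end_s = pre + epoch_len,
                  participant = participant, strawberry = strawberry)
}

#' Generate a complete synthetic tasting study
#'
#' Draws latent taste per sample, then VAS, composition, questionnaire
#' responses and fNIRS recordings with the configured cross-block
#' correlations. Sugar content is drawn near the packaged study's means and
#' acidity is derived as sugar/ratio so the ratio column is exactly
#' consistent. Questionnaire items are discretized to the 1..5 Likert scale
#' by equal-probability thresholds on a latent Gaussian. Deterministic given
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_study`: list with `tables`
#'   ([study_tables()]), `recordings` (named list of `fnirs_recording`,
#'   keys `p<participant>_<strawberry>`), `truth` (tibble of per-sample
#'   latent values plus the planted links and responsive channels), and
#'   `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  P <- cfg$n_participants
  n <- 4L * P
  key <- sample_key(P)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(cfg$seed, 1L))

  z <- rnorm(n)                               # standardized latent taste
  mix <- function(rho, anchor) rho * anchor + sqrt(1 - rho^2) * rnorm(n)

  vas_z <- mix(cfg$link_vas, z)
  vas <- pmin(100, pmax(0, 65 + 15 * vas_z))

  ratio_z <- mix(cfg$link_ratio, z)
  ratio <- pmax(5, 16 + 2.5 * ratio_z)
  sugar <- pmax(5, rnorm(n, 9.9, 1.2))
  acidity <- sugar / ratio

  items <- load_fixture("questionnaire_catalogue")
  likert_cuts <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  q_long <- purrr::map_dfr(seq_len(nrow(items)), function(i) {
    fac <- items$factor[i]
    item_z <- switch(fac,
      reward = mix(cfg$link_reward, vas_z),
      cultural = mix(cfg$link_cultural, z),
      rnorm(n)
    )
    tibble::tibble(participant = key$participant, strawberry = key$strawberry,
                   item = items$item[i],
                   response = as.integer(findInterval(item_z, likert_cuts) + 1L))
  })

  tables <- study_tables(
    vas = tibble::tibble(participant = key$participant, strawberry = key$strawberry, vas = vas),
    individual = tibble::tibble(
      participant = key$participant, strawberry = key$strawberry,
      sugar_content = sugar, acidity = acidity, sugar_acid_ratio = ratio,
      size_indicator = unname(strawberry_size_indicator[key$strawberry])
    ),
    questionnaire = q_long,
    items = items
  )

  latent <- cfg$latent_taste_sd * z
  recordings <- purrr::map(seq_len(n), function(j) {
    make_recording(latent[j], cfg, key$participant[j], key$strawberry[j], j)
  })
  names(recordings) <- paste0("p", key$participant, "_", key$strawberry)

  truth <- list(
    latent = tibble::tibble(participant = key$participant,
                            strawberry = key$strawberry, latent = latent),
    responsive_channels = cfg$channel_subset,
    planted = list(brain_vas = cfg$link_vas, vas = cfg$link_vas,
                   reward = cfg$link_reward, cultural = cfg$link_cultural,
                   ratio = cfg$link_ratio)
  )
  structure(list(tables = tables, recordings = recordings, truth = truth, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", x$config$n_participants, "participants x 4 strawberries,",
      length(x$recordings), "recordings (seed", x$config$seed, ")\n")
  invisible(x)
}
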