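test_that("study generation is a deterministic function of the seed", {
  cfg <- synthetic_config(n_participants = 4, seed = 11)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_equal(s1$tables$vas, s2$tables$vas)
  expect_equal(s1$tables$questionnaire, s2$tables$questionnaire)
  expect_equal(s1$recordings[["p2_s3"]]$values, s2$recordings[["p2_s3"]]$values)

  s3 <- generate_study(synthetic_config(n_participants = 4, seed = 12))
  expect_false(isTRUE(all.equal(s1$tables$vas$vas, s3$tables$vas$vas)))
})

test_that("planted correlations are recovered empirically at large n", {
  study <- generate_study(synthetic_config(n_participants = 125, seed = 3,
                                           link_vas = 0.9))
  v <- stack_column(study$tables$vas, "vas")
  z <- stack_column(study$truth$latent, "latent")
  expect_lt(abs(cor(v, z) - 0.9), 0.05)

  # ratio link
  study_r <- generate_study(synthetic_config(n_participants = 125, seed = 4,
                                             link_ratio = 0.7))
  ratio <- stack_column(study_r$tables$individual, "sugar_acid_ratio")
  z_r <- stack_column(study_r$truth$latent, "latent")
  expect_lt(abs(cor(ratio, z_r) - 0.7), 0.07)
})

test_that("zero links give near-zero cross-block correlations", {
  study <- generate_study(synthetic_config(
    n_participants = 125, seed = 9,
    link_vas = 0, link_reward = 0, link_cultural = 0, link_ratio = 0))
  n <- 500
  v <- stack_column(study$tables$vas, "vas")
  z <- stack_column(study$truth$latent, "latent")
  ratio <- stack_column(study$tables$individual, "sugar_acid_ratio")
  q_mean <- study$tables$questionnaire |>
    dplyr::summarise(m = mean(response), .by = c(participant, strawberry))
  qm <- stack_column(q_mean, "m")
  for (r in c(cor(v, z), cor(v, ratio), cor(v, qm), cor(ratio, z), cor(qm, z))) {
    expect_lt(abs(r), 3 / sqrt(n))
  }
})

test_that("questionnaire responses are valid 5-level Likert with planted structure", {
  study <- generate_study(synthetic_config(n_participants = 50, seed = 21,
                                           link_reward = 0.8, link_cultural = 0))
  q <- study$tables$questionnaire
  expect_true(all(q$response %in% 1:5))
  # equal-probability discretization keeps levels roughly balanced
  expect_true(all(table(q$response) > 0.1 * nrow(q) / 5))
  # reward items track the VAS
  v <- stack_column(study$tables$vas, "vas")
  items <- study$tables$items
  r_by_item <- vapply(items$item, function(it) {
    resp <- q[q$item == it, c("participant", "strawberry", "response")]
    cor(v, stack_column(resp, "response"))
  }, numeric(1))
  expect_gt(mean(abs(r_by_item[items$factor == "reward"])),
            mean(abs(r_by_item[items$factor != "reward"])) + 0.2)
})

test_that("noiseless traces expose the epoch-locked response structure", {
  cfg <- synthetic_config(noise_sd = 0, drift_amp = 0, seed = 1)

  flat <- generate_fnirs_trace(0, cfg, channel = 1, chromophore = "oxy")
  expect_true(all(flat$value == 0))

  t1 <- generate_fnirs_trace(1, cfg, channel = 1, chromophore = "oxy")
  t2 <- generate_fnirs_trace(2, cfg, channel = 1, chromophore = "oxy")
  in_epoch <- t1$time_s >= attr(t1, "bite_onset_s") & t1$time_s <= attr(t1, "swallow_end_s")
  expect_equal(mean(t2$value[in_epoch]), 2 * mean(t1$value[in_epoch]))
  expect_gt(mean(t1$value[in_epoch]), 0)

  deoxy <- generate_fnirs_trace(1, cfg, channel = 1, chromophore = "deoxy")
  expect_equal(mean(deoxy$value[in_epoch]), -mean(t1$value[in_epoch]))

  # channels outside the responsive subset carry no signal
  off <- generate_fnirs_trace(5, cfg, channel = 20, chromophore = "oxy")
  expect_true(all(off$value == 0))
})

test_that("generated recordings carry valid markers and jittered epochs", {
  cfg <- synthetic_config(n_participants = 3, seed = 6)
  study <- generate_study(cfg)
  for (rec in study$recordings) {
    expect_lt(rec$bite_onset_s, rec$swallow_end_s)
    expect_gte(rec$bite_onset_s, min(rec$time_s))
    expect_lte(rec$swallow_end_s, max(rec$time_s))
    len <- rec$swallow_end_s - rec$bite_onset_s
    expect_gte(len, 0.8 * cfg$epoch_seconds - 1e-9)
    expect_lte(len, 1.2 * cfg$epoch_seconds + 1e-9)
  }
})

test_that("configuration validation rejects invalid parameters", {
  expect_error(synthetic_config(link_vas = 1.2), "\\[-1, 1\\]")
  expect_error(synthetic_config(channel_subset = integer(0)), "channel_subset")
  expect_error(synthetic_config(channel_subset = 25), "channel_subset")
  expect_error(synthetic_config(sampling_rate = 0), "positive")
  expect_error(synthetic_config(latent_taste_sd = 0), "latent_taste_sd")
})
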