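test_that("packaged fixtures reproduce the printed cells and summaries", {
  vas <- load_fixture("vas_table1")
  expect_equal(vas$vas[vas$participant == 2 & vas$strawberry == "s2"], 10)
  expect_equal(vas$vas[vas$participant == 1 & vas$strawberry == "s1"], 88)
  expect_true(all(vas$vas >= 0 & vas$vas <= 100))

  col_means <- vapply(c("s1", "s2", "s3", "s4"),
                      function(s) mean(vas$vas[vas$strawberry == s]), numeric(1))
  expect_equal(unname(round(col_means)), c(70, 61, 69, 62))
  s1 <- mean_sd(vas$vas[vas$strawberry == "s1"])
  expect_equal(round(s1$sd), 15)
  expect_equal(round(s1$mean), 70)

  ind <- load_fixture("individual_table3")
  expect_equal(ind$sugar_content[ind$participant == 1 & ind$strawberry == "s3"], 14.7)
  sugar_means <- vapply(c("s1", "s2", "s3", "s4"),
                        function(s) mean(ind$sugar_content[ind$strawberry == s]), numeric(1))
  expect_equal(unname(round(sugar_means[1:2], 2)), c(9.27, 9.64))
  expect_equal(unname(round(sugar_means[3:4], 1)), c(10.8, 10.0))
  # ratio column consistent with sugar/acidity up to printed rounding
  expect_true(all(abs(ind$sugar_acid_ratio - ind$sugar_content / ind$acidity) <= 0.15))

  cat <- load_fixture("questionnaire_catalogue")
  expect_equal(nrow(cat), 19)
  expect_equal(as.vector(table(cat$factor)[c("reward", "cultural", "information", "appearance")]),
               c(5L, 5L, 5L, 4L))
  expect_error(load_fixture("no_such_table"), "unknown fixture")
})

test_that("stack_column follows the sample-key order and inverts cleanly", {
  vas <- load_fixture("vas_table1")
  v <- stack_column(vas, "vas")
  expect_length(v, 76)
  expect_equal(v[1], 88)    # participant 1, s1
  expect_equal(v[20], 77)   # participant 1, s2
  key <- sample_key(19)
  expect_equal(key$row, (match(key$strawberry, c("s1", "s2", "s3", "s4")) - 1) * 19 + key$participant)

  ind <- load_fixture("individual_table3")
  expect_equal(stack_column(ind, "size_indicator"),
               rep(c(1, 0, 1, 0), each = 19))

  const <- dplyr::mutate(vas, cc = 7)
  expect_equal(stack_column(const, "cc"), rep(7, 76))

  # shuffled row order does not change the stacked result
  shuffled <- vas[sample(nrow(vas)), ]
  expect_equal(stack_column(shuffled, "vas"), v)

  # stack then unstack is the identity
  back <- unstack_column(v, 19, "vas")
  expect_equal(dplyr::arrange(back, participant, strawberry),
               dplyr::arrange(vas, participant, strawberry))

  expect_error(stack_column(vas[-1, ], "vas"), "incomplete")
  expect_error(stack_column(vas, "nope"), "no column")
})

test_that("mean_sd uses the sample denominator and rejects tiny input", {
  expect_equal(mean_sd(c(3, 3, 3))$sd, 0)
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  expect_equal(mean_sd(x)$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  expect_error(mean_sd(5), "at least two")
})

test_that("study CSV round-trips and rejects malformed input", {
  tables <- study_fixtures()
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(tables, path, provenance = "round-trip test")
  back <- read_study_csv(path)
  expect_equal(back$vas, tables$vas)
  expect_equal(back$individual, tables$individual)

  # questionnaire responses survive the round trip too
  study <- generate_study(synthetic_config(n_participants = 3, seed = 5))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(study$tables, path2)
  back2 <- read_study_csv(path2)
  expect_equal(
    dplyr::arrange(back2$questionnaire, participant, strawberry, item),
    dplyr::arrange(study$tables$questionnaire, participant, strawberry, item)
  )

  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  bad_range <- raw
  bad_range$value[bad_range$variable == "vas"][1] <- 101
  p3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad_range, p3)
  expect_error(read_study_csv(p3), "\\[0, 100\\]")

  missing_cell <- raw[-which(raw$variable == "vas")[1], ]
  p4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(missing_cell, p4)
  expect_error(read_study_csv(p4), "incomplete")

  dup <- rbind(raw, raw[1, ])
  p5 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dup, p5)
  expect_error(read_study_csv(p5), "duplicate")
})

test_that("table validation enforces the grid, ranges, and size pattern", {
  ind <- load_fixture("individual_table3")
  bad_size <- dplyr::mutate(ind, size_indicator = 1 - size_indicator)
  expect_error(study_tables(load_fixture("vas_table1"), bad_size), "size_indicator")
  bad_ratio <- dplyr::mutate(ind, sugar_acid_ratio = sugar_acid_ratio + 1)
  expect_error(study_tables(load_fixture("vas_table1"), bad_ratio), "inconsistent")
})
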