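test_that("toy long-format table parses into a normalised dataset", {
  shuffled <- make_toy_dataset()[c(3, 1, 4, 2), ]
  ds <- gap_dataset(shuffled)
  expect_s3_class(ds, "gap_dataset")
  expect_equal(nrow(ds), 4)
  expect_equal(n_subjects(ds), 2)
  expect_equal(ds$subject_id, c("A", "A", "B", "B"))
  expect_equal(ds$rank, c(1, 2, 1, 2))
})

test_that("invariant violations are rejected with the subject named", {
  toy <- as.data.frame(make_toy_dataset())

  bad_rank <- toy
  bad_rank$rank[2] <- 3  # subject A has ranks 1,3
  expect_error(gap_dataset(bad_rank), "rank-sequence.*subject A")

  bad_gap <- toy
  bad_gap$gap_weeks[3] <- 0
  expect_error(gap_dataset(bad_gap), "nonpositive-gap")

  bad_cov <- toy
  bad_cov$age_onset[2] <- 25  # varies within subject A
  expect_error(gap_dataset(bad_cov), "covariate-not-fixed")

  expect_error(gap_dataset(toy[, -3]), "missing required column")
})

test_that("validate_gap_data reports every violation without stopping", {
  toy <- as.data.frame(make_toy_dataset())
  toy$event[1] <- 0           # censored at rank 1 of 2 for subject A
  toy$gap_weeks[4] <- -2      # nonpositive gap for subject B
  rep <- validate_gap_data(toy)
  expect_true("censored-not-last" %in% rep$rule[rep$subject_id == "A"])
  expect_true("nonpositive-gap" %in% rep$rule[rep$subject_id == "B"])

  all_censored <- toy[3:4, ]
  all_censored$event <- 0
  rep2 <- validate_gap_data(all_censored)
  expect_true("censored-not-last" %in% rep2$rule)

  expect_equal(nrow(validate_gap_data(make_toy_dataset())), 0)
})

test_that("write then read reproduces the dataset field-for-field", {
  set.seed(7)
  ds <- random_small_dataset(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gap_data(ds, path)
  back <- read_gap_data(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))

  # header-only file for an empty dataset
  empty <- ds[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_gap_data(empty, path2)
  expect_equal(length(readLines(path2)), 1L)
})

test_that("reading drops subjects with missing covariates, with warning", {
  toy <- as.data.frame(make_toy_dataset())
  toy$head_injury[toy$subject_id == "B"] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(toy, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_warning(ds <- read_gap_data(path), "excluding 1 subject.*B")
  expect_equal(unique(ds$subject_id), "A")

  expect_error(read_gap_data(withr::local_tempfile()), "not found")
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject_id,rank\nA,1", path3)
  expect_error(read_gap_data(path3), "missing column.*gap_weeks")
})

test_that("gap times are built from admission histories correctly", {
  g <- build_gap_times("A", 0, admissions = c(10, 20),
                       discharges = c(14, 25), followup_end_week = 40)
  expect_equal(g$gap_weeks, c(10, 6, 15))
  expect_equal(g$event, c(1, 1, 0))
  expect_equal(g$rank, 1:3)

  # follow-up ends at the last discharge: no censored tail
  g2 <- build_gap_times("A", 0, admissions = 10, discharges = 14,
                        followup_end_week = 14)
  expect_equal(g2$gap_weeks, 10)
  expect_equal(g2$event, 1)

  expect_error(build_gap_times("A", 0, admissions = c(10, 14),
                               discharges = c(14, 18),
                               followup_end_week = 30),
               "zero-length gap")
  expect_error(build_gap_times("A", 12, admissions = 10, discharges = 14,
                               followup_end_week = 30), "onset_week")
})

test_that("gaps plus hospital stays partition the follow-up window", {
  set.seed(11)
  for (i in 1:25) {
    n_stay <- sample(1:5, 1)
    adm <- cumsum(stats::runif(n_stay, 1, 20))
    dis <- adm + stats::runif(n_stay, 0.5, 6)
    if (n_stay > 1) {
      # enforce increasing non-overlapping stays
      for (j in 2:n_stay) {
        if (adm[j] <= dis[j - 1]) {
          delta <- dis[j - 1] - adm[j] + stats::runif(1, 0.5, 2)
          adm[j:n_stay] <- adm[j:n_stay] + delta
          dis[j:n_stay] <- dis[j:n_stay] + delta
        }
      }
    }
    fu <- dis[n_stay] + stats::runif(1, 0, 10)
    g <- build_gap_times("X", 0, adm, dis, fu)
    expect_equal(sum(g$gap_weeks) + sum(dis - adm), fu,
                 tolerance = 1e-12)
  }
})

test_that("relapse cross-tab matches hand counts and normalises", {
  # three male, no-family-history subjects with 3, 3, 4 relapses
  rows <- do.call(rbind, lapply(1:3, function(j) {
    k <- c(3, 3, 4)[j]
    data.frame(subject_id = paste0("S", j), rank = 1:k,
               gap_weeks = rep(5, k), event = rep(1, k),
               age_onset = 20, gender = 1, marital = 0, mode_onset = 0,
               head_injury = 0, family_history = 0)
  }))
  ds <- gap_dataset(rows)
  tab <- relapse_frequency_table(ds, c("family_history", "gender"))
  row3 <- tab[tab$family_history == "No" & tab$gender == "Male" &
                tab$relapses == "3", ]
  row4 <- tab[tab$family_history == "No" & tab$gender == "Male" &
                tab$relapses == "4", ]
  expect_equal(row3$n, 2)
  expect_equal(row3$pct, 200 / 3, tolerance = 1e-10)
  expect_equal(row4$n, 1)
  expect_equal(row4$pct, 100 / 3, tolerance = 1e-10)

  # marginal total equals the number of subjects; rows sum to 100%
  expect_equal(sum(tab$n), n_subjects(ds))
  key <- paste(tab$family_history, tab$gender)
  sums <- tapply(tab$pct, key, sum)
  expect_true(all(abs(sums[is.finite(sums)] - 100) < 1e-9))

  # empty strata kept as zero rows, not dropped
  expect_true(any(tab$family_history == "Yes" & tab$n == 0))

  expect_error(relapse_frequency_table(ds, "age_onset"), "unknown stratum")
  empty <- relapse_frequency_table(ds[0, ])
  expect_equal(nrow(empty), 0)
})
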