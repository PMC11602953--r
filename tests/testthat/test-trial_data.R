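test_that("loader handles completers, off-flags and error cases", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path)
  d <- load_trial_csv(path)
  expect_s3_class(d, "trial_data")
  expect_equal(d$deviation_visit, c(2L, 2L))   # D = S = J for completers
  expect_equal(d$last_study_visit, c(2L, 2L))
  expect_equal(d$n_visits, 2L)

  # outcome at visits 1,2 then blank, off-flag from visit 3 -> D = 2, S = 2
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,arm,visit,outcome,baseline,offtrt",
               "a,reference,1,1,5,0", "a,reference,2,2,5,0",
               "a,reference,3,,5,1",
               "b,active,1,3,6,0", "b,active,2,4,6,0", "b,active,3,5,6,0"),
             p2)
  d2 <- load_trial_csv(p2)
  expect_equal(d2$deviation_visit, c(2L, 3L))
  expect_equal(d2$last_study_visit, c(2L, 3L))

  # unknown arm label
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,arm,visit,outcome,baseline",
               "a,placebo,1,1,5", "a,placebo,2,1,5",
               "b,active,1,1,5", "b,active,2,1,5"), p3)
  expect_error(load_trial_csv(p3), "unknown arm label")

  # duplicate (subject, visit)
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,arm,visit,outcome,baseline",
               "a,reference,1,1,5", "a,reference,1,2,5", "a,reference,2,1,5",
               "b,active,1,1,5", "b,active,2,1,5"), p4)
  expect_error(load_trial_csv(p4), "duplicate")
})

test_that("constructor enforces S >= D and monotone missingness after S", {
  y <- rbind(c(1, 2, NA), c(1, 2, 3))
  expect_error(trial_data(y, c(0, 1), c(1, 1), deviation_visit = c(3, 3),
                          last_study_visit = c(1, 3)),
               "S < D")
  expect_error(trial_data(rbind(c(1, 2, 3), c(1, 2, 3)), c(0, 1), c(1, 1),
                          deviation_visit = c(2, 3),
                          last_study_visit = c(2, 3)),
               "after last_study_visit")
  # interim missing before S is accepted
  d <- trial_data(rbind(c(1, NA, 3), c(1, 2, 3)), c(0, 1), c(1, 1))
  expect_equal(d$last_study_visit, c(3L, 3L))
})

test_that("CSV round trip reproduces values and missingness exactly", {
  gt <- covered_fixture(seed = 3, n = c(25, 25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(gt$data, path)
  d2 <- load_trial_csv(path)
  expect_identical(is.na(d2$outcomes), is.na(gt$data$outcomes))
  expect_equal(d2$outcomes, gt$data$outcomes, ignore_attr = TRUE)
  expect_equal(d2$deviation_visit, gt$data$deviation_visit)
  expect_equal(d2$baseline, gt$data$baseline)
  expect_equal(d2$arm, gt$data$arm)
})

test_that("derive_patterns produces the defined covariates", {
  y <- matrix(rnorm(8), 2, 4)
  d <- trial_data(y, c(1, 0), c(1, 2), deviation_visit = c(2L, 4L),
                  last_study_visit = c(4L, 4L))
  pv <- derive_patterns(d, core_spec("J2R"))
  expect_equal(pv$off_t[1:4], c(0L, 0L, 1L, 1L))
  expect_equal(pv$pattern[1:4], c(1L, 2L, 2L, 2L))
  expect_equal(pv$j2r_factor[1:4],
               c("active", "active", "reference", "reference"))
  # off_t = 1 exactly when visit > D; pattern non-decreasing, constant after D
  expect_true(all(pv$off_t == as.integer(pv$visit > rep(d$deviation_visit, each = 4))))
  expect_true(all(diff(pv$pattern[1:4]) >= 0))
  # idempotent / deterministic in (D, T, J, core)
  expect_identical(pv, derive_patterns(d, core_spec("J2R")))

  # CIR: trtbyvis at visit 4 for an active patient with D = 2 encodes
  # mu[0,4] + mu[1,2] - mu[0,2]
  pv_cir <- derive_patterns(d, core_spec("CIR"))
  w <- pv_cir$trtbyvis[4, ]
  expect_equal(unname(w["mu[0,4]"]), 1)
  expect_equal(unname(w["mu[1,2]"]), 1)
  expect_equal(unname(w["mu[0,2]"]), -1)
  expect_equal(sum(w != 0), 3)
})

test_that("pattern_summary satisfies the per-visit partition identity", {
  for (seed in 1:4) {
    gt <- covered_fixture(seed = seed, n = c(30, 35))
    ps <- pattern_summary(gt$data)
    vc <- ps$visit_counts
    for (a in unique(vc$arm)) {
      na <- sum(gt$data$arm == (a == "active"))
      expect_true(all(vc$on[vc$arm == a] + vc$off_obs[vc$arm == a] +
                        vc$off_miss[vc$arm == a] == na))
    }
    # stratum counts sum to arm totals
    pat <- ps$patterns
    expect_equal(sum(pat$count[pat$arm == "reference"]),
                 sum(gt$data$arm == 0L))
    expect_equal(sum(pat$count[pat$arm == "active"]),
                 sum(gt$data$arm == 1L))
    # counts match the generator-side bookkeeping
    D <- gt$data$deviation_visit
    for (r in seq_len(nrow(pat))) {
      sel <- gt$data$arm == (pat$arm[r] == "active") & D == pat$deviation_visit[r]
      expect_lte(pat$count[r], sum(sel))
    }
  }
})

test_that("all-completer data give one stratum per arm with sample means", {
  y <- matrix(rnorm(20), 5, 4)
  d <- trial_data(y, c(0, 0, 1, 1, 1), baseline = rnorm(5))
  ps <- pattern_summary(d)
  expect_equal(nrow(ps$patterns), 2L)
  expect_equal(unlist(ps$patterns[ps$patterns$arm == "reference",
                                  paste0("mean_v", 1:4)], use.names = FALSE),
               colMeans(y[1:2, ]))
  # strata with zero observed values report NA, not zero
  y2 <- y; y2[5, 3:4] <- NA
  d2 <- trial_data(y2, c(0, 0, 1, 1, 1), baseline = rnorm(5),
                   deviation_visit = c(4L, 4L, 4L, 4L, 2L))
  ps2 <- pattern_summary(d2)
  stop_row <- ps2$patterns$group == "stop"
  expect_true(all(is.na(ps2$patterns[stop_row, c("mean_v3", "mean_v4")])))
})

test_that("merge_observed_off_treatment restores exactly the observed cells", {
  gt <- covered_fixture(seed = 2, n = c(20, 20))
  d <- gt$data
  imp <- d
  imp$outcomes[] <- 99
  merged <- merge_observed_off_treatment(imp, d)
  obs <- !is.na(d$outcomes)
  expect_identical(merged$outcomes[obs], d$outcomes[obs])
  expect_true(all(merged$outcomes[!obs] == 99))
  # fully observed original -> identity
  full <- trial_data(matrix(1:8, 2, 4), c(0, 1), c(1, 2))
  imp2 <- full; imp2$outcomes[] <- 0
  expect_equal(merge_observed_off_treatment(imp2, full)$outcomes, full$outcomes)
  # shape mismatch
  expect_error(merge_observed_off_treatment(imp2, d), "shape mismatch")
})

test_that("merging observed off-treatment data above the reference mean raises the estimate", {
  # construct data where off-treatment actives sit well above what J2R
  # would impute for them: merged analysis must give a larger difference
  cfg <- synthetic_config(n_per_arm = c(50, 50), J = 3,
                          mu = rbind(c(0, 0, 0), c(3, 4, 5)),
                          Sigma = diag(3) + 1,
                          dev_hazard = rbind(c(0, 0), c(0.5, 0.3)),
                          q_stop = c(0, 0),  # deviators all observed
                          off_rule = "mar_truth",  # stay on own profile
                          baseline_coef = rep(0, 3))
  gt <- generate_trial(cfg, seed = 8)
  d <- gt$data
  g <- fast_gibbs(seed = 4, K = 80)
  only <- run_classic_rbi(d, core_spec("J2R"), merge_back = FALSE, gibbs = g)
  merged <- run_classic_rbi(d, core_spec("J2R"), merge_back = TRUE, gibbs = g)
  expect_gt(merged$estimate, only$estimate)
})
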