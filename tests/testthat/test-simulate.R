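test_that("the default study has the right shape and is seed-deterministic", {
  cfg <- default_config()
  t1 <- generate_study(cfg, 14)
  expect_equal(nrow(t1$estimates), 1950L)  # 10 x 65 x 3
  expect_equal(nrow(t1$predictions), 65L)
  expect_equal(length(participants(t1)), 10L)
  t2 <- generate_study(cfg, 14)
  expect_identical(t1$estimates, t2$estimates)
  expect_identical(t1$predictions, t2$predictions)
  expect_identical(t1$likert, t2$likert)
  t3 <- generate_study(cfg, 15)
  expect_false(identical(t1$estimates, t3$estimates))
  # generate_study validates internally: every invariant holds by construction
  expect_silent(validate_study_table(t1))
})

test_that("adding participants does not perturb existing participants' data", {
  small <- generate_study(simulation_config(n_participants = 4L, n_images = 12L), 6)
  large <- generate_study(simulation_config(n_participants = 6L, n_images = 12L), 6)
  keep <- large$estimates$participant_id %in% participants(small)
  expect_identical(small$estimates, large$estimates[keep, ])
})

test_that("a zero-error model always contains the truth in its predicted bin", {
  cfg <- simulation_config(model_error = list(core_sd_weeks = 0, gross_sd_weeks = 0,
                                              gross_prob = 0))
  img <- sample_images(cfg, 99)
  expect_true(all(
    woar:::in_bin(img$images$true_ga_weeks, img$predictions$bin_lo_weeks,
                  img$predictions$bin_hi_weeks, 42)
  ))
  expect_equal(nrow(img$predictions), 65L)
})

test_that("degenerate advice weights pin the Weight of Advice", {
  cfg <- simulation_config(n_participants = 1L, n_images = 30L,
                           population = list(resid_sd = 0))
  img <- sample_images(cfg, 5)
  prof <- sample_profile(cfg, "p01", seed = 1, index = 1L)
  prof$bias_weeks <- 0
  prof$noise_sd_weeks <- 0
  prof$helpfulness_shift <- 0
  prof$confusion_sd_weeks <- 0

  prof$advice_weight <- 1
  full <- simulate_participant(prof, img$images, img$predictions, cfg, seed = 2)
  s2 <- full[full$stage == 2, ]
  m <- img$predictions$point_weeks[match(s2$image_id, img$predictions$image_id)]
  expect_equal(s2$estimate_weeks, m)

  prof$advice_weight <- 0
  none <- simulate_participant(prof, img$images, img$predictions, cfg, seed = 2)
  expect_equal(none[none$stage == 2, ]$estimate_weeks,
               none[none$stage == 1, ]$estimate_weeks)
})

test_that("mean WoA is monotone in the advice weight on a shared noise stream", {
  cfg <- simulation_config(n_participants = 1L, n_images = 40L)
  img <- sample_images(cfg, 11)
  prof <- sample_profile(cfg, "p01", seed = 3, index = 1L)
  prof$helpfulness_shift <- 0
  prof$confusion_sd_weeks <- 0
  woas <- vapply(seq(0, 1, by = 0.1), function(w) {
    prof$advice_weight <- w
    recs <- simulate_participant(prof, img$images, img$predictions, cfg, seed = 4)
    tbl <- study_table(recs, img$predictions, bin_scheme = cfg$bin_scheme)
    mean_woa(tbl, "p01", 2)$mean_woa
  }, numeric(1))
  expect_true(all(diff(woas) >= -1e-9))
})

test_that("the stratified cohort carries the configured type and helped shares", {
  tbl <- generate_study(default_config(), 23)
  prof <- attr(tbl, "profiles")
  expect_equal(nrow(prof), 10L)
  expect_equal(sum(prof$helped), 5L)                    # half the cohort
  expect_equal(sum(prof$advice_weight > 0.6), 6L)       # strong advice-takers
  expect_true(all(prof$noise_sd_weeks > 0))
  expect_true(all(prof$advice_weight >= 0 & prof$advice_weight <= 1))
})

test_that("explanations improve helped and worsen hindered readers in expectation", {
  d_helped <- c(); d_hindered <- c()
  for (s in 61:70) {
    tbl <- generate_study(default_config(), s)
    prof <- attr(tbl, "profiles")
    d <- vapply(prof$participant_id, function(p) delta_mae(tbl, p, 2, 3),
                numeric(1))
    d_helped <- c(d_helped, d[prof$helped])
    d_hindered <- c(d_hindered, d[!prof$helped])
  }
  expect_lt(mean(d_helped), 0)
  expect_gt(mean(d_hindered), 0)
  # the sceptical readers who are helped see the largest gains, since their
  # advice weight has the most room to grow
  expect_gt(mean(d_helped < 0), 0.7)
})

test_that("questionnaire responses track the latent helped flag", {
  agree <- 0L; total <- 0L
  for (s in 81:90) {
    tbl <- generate_study(default_config(), s)
    prof <- attr(tbl, "profiles")
    lik <- tbl$likert
    hr <- lik[lik$item_id == "explanations_helpful", ]
    hr <- hr[match(prof$participant_id, hr$participant_id), ]
    agree <- agree + sum((hr$value >= 4) == prof$helped)
    total <- total + nrow(prof)
  }
  expect_equal(agree, total)  # rating >= 4 iff helped, by construction
  # trust timepoints all present
  tbl <- generate_study(default_config(), 81)
  expect_setequal(unique(tbl$likert$timepoint),
                  c("pre_study", "post_stage2", "post_stage3", "post_study"))
})

test_that("config JSON round-trips through the reader and writer", {
  cfg <- simulation_config(n_participants = 5L,
                           population = list(strong_w_mean = 0.8),
                           seed = 77L)
  path <- withr::local_tempfile(fileext = ".json")
  write_config_json(cfg, path)
  back <- read_config_json(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(read_config_json("no/such/config.json"), "not found")
  # invalid values are rejected on read
  bad <- cfg; bad$helped_fraction <- 2
  class(bad) <- "simulation_config"
  path2 <- withr::local_tempfile(fileext = ".json")
  out <- unclass(bad); out$bin_scheme <- list(lo = cfg$bin_scheme$lo, hi = cfg$bin_scheme$hi)
  jsonlite::write_json(out, path2, auto_unbox = TRUE, digits = NA)
  expect_error(read_config_json(path2), "helped_fraction")
})
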