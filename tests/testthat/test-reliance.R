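test_that("weight of advice reproduces the canonical advice-taking semantics", {
  expect_equal(weight_of_advice(20, 25, 30)$value, 0.5)   # averaged with advice
  expect_equal(weight_of_advice(20, 30, 30)$value, 1.0)   # adopted the advice
  expect_equal(weight_of_advice(20, 20, 30)$value, 0.0)   # ignored the advice
  expect_equal(weight_of_advice(20, 18, 30)$value, -0.2)  # moved away
  expect_gt(weight_of_advice(20, 32, 30)$value, 1)        # overshot
  near <- weight_of_advice(29.5, 30, 30)
  expect_true(near$excluded)
  expect_true(is.na(near$value))
  # the exclusion covers the zero-denominator case
  expect_true(weight_of_advice(30, 31, 30)$excluded)
})

test_that("WoA is invariant to translation and positive scaling of all inputs", {
  set.seed(11)
  for (i in 1:200) {
    prior <- runif(1, 13, 42); post <- runif(1, 13, 42); m <- runif(1, 13, 42)
    shift <- runif(1, -5, 5); scale <- runif(1, 0.5, 3)
    base <- weight_of_advice(prior, post, m)
    shifted <- weight_of_advice(prior + shift, post + shift, m + shift)
    expect_equal(shifted$value, base$value, tolerance = 1e-9)
    scaled <- weight_of_advice(prior * scale, post * scale, m * scale)
    if (!base$excluded && !scaled$excluded) {
      expect_equal(scaled$value, base$value, tolerance = 1e-9)
    }
  }
})

test_that("mean WoA averages non-excluded images and flags the all-excluded case", {
  # adopting the model everywhere gives mean WoA 1
  adopt <- mini_study(truth = c(25, 30, 35), est1 = c(20, 24, 28),
                      est2 = c(27, 30.5, 34.5), m = c(27, 30.5, 34.5))
  expect_equal(mean_woa(adopt, "p01", 2)$mean_woa, 1)
  # unchanged estimates give mean WoA 0
  keep <- mini_study(truth = c(25, 30, 35), est1 = c(20, 24, 28),
                     est2 = c(20, 24, 28), m = c(27, 30.5, 34.5))
  expect_equal(mean_woa(keep, "p01", 2)$mean_woa, 0)
  # WoA 0.5 and 1.0 plus one excluded image average to 0.75
  mix <- mini_study(truth = c(25, 30, 35), est1 = c(20, 20, 29.5),
                    est2 = c(25, 30, 30), m = c(30, 30, 30))
  res <- mean_woa(mix, "p01", 2)
  expect_equal(res$mean_woa, 0.75)
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$n_used, 2L)
  # every image excluded: undefined mean, not a number
  allex <- mini_study(truth = c(25, 30), est1 = c(29.6, 30.2), est2 = c(30, 30),
                      m = c(30, 30))
  expect_true(is.na(mean_woa(allex, "p01", 2)$mean_woa))
  expect_equal(mean_woa(allex, "p01", 2)$n_excluded, 2L)
})

test_that("the stage-3 prior defaults to stage 1 but can be switched to stage 2", {
  tbl <- mini_study(truth = 30, est1 = 20, est2 = 26, est3 = 28, m = 30)
  expect_equal(mean_woa(tbl, "p01", 3)$mean_woa, (20 - 28) / (20 - 30))
  expect_equal(mean_woa(tbl, "p01", 3, prior_stage = 2)$mean_woa,
               (26 - 28) / (26 - 30))
  expect_error(mean_woa(tbl, "p01", 2, prior_stage = 2), "precede")
})

test_that("reliance typing matches its definitions on worked cases including ties", {
  lab <- function(y, p1, p2, m) as.character(classify_reliance(y, p1, p2, m)$label)
  expect_equal(lab(30, 20, 26, 29), "appropriate")  # relied, model better
  expect_equal(lab(30, 20, 20, 29), "under")        # kept own, model better
  expect_equal(lab(20, 20, 25, 29), "over")         # relied, model worse
  expect_equal(lab(20, 24, 23, 30), "appropriate")  # kept own, model worse
  # ties resolve to no-reliance / model-not-better, hence appropriate
  expect_equal(lab(30, 20, 20, 40), "appropriate")
  cls <- classify_reliance(30, 20, 26, 29)
  expect_equal(cls$delta1, 9); expect_equal(cls$delta2, 3)
  expect_equal(cls$eps_m, 1); expect_equal(cls$eps_p1, 10)
})

test_that("reliance typing agrees with the literal oracle on a random grid", {
  set.seed(21)
  y <- sample(13:42, 4000, replace = TRUE)
  p1 <- sample(13:42, 4000, replace = TRUE)
  p2 <- sample(13:42, 4000, replace = TRUE)
  m <- sample(13:42, 4000, replace = TRUE)
  got <- as.character(classify_reliance(y, p1, p2, m)$label)
  expect_equal(got, reliance_oracle(y, p1, p2, m))
})

test_that("structural label constraints hold on random inputs", {
  set.seed(31)
  y <- runif(500, 13, 42); p1 <- runif(500, 13, 42); m <- runif(500, 13, 42)
  # unchanged estimate can never be over-reliance
  expect_false(any(classify_reliance(y, p1, p1, m)$label == "over"))
  # adopting the model (from elsewhere) can never be under-reliance
  keep <- abs(p1 - m) > 1e-6
  expect_false(any(classify_reliance(y[keep], p1[keep], m[keep], m[keep])$label == "under"))
})

test_that("reliance proportions count labels and conserve mass", {
  # four images engineered to app, app, under, over
  tbl <- mini_study(
    truth = c(30, 20, 30, 20),
    est1 = c(20, 24, 20, 20),
    est2 = c(26, 23, 20, 25),
    m = c(29, 30, 29, 29)
  )
  pr <- reliance_proportions(tbl, "p01", 2)
  expect_equal(pr$p_appropriate, 0.5)
  expect_equal(pr$p_under, 0.25)
  expect_equal(pr$p_over, 0.25)
  expect_equal(pr$n, 4L)
  expect_equal(pr$p_appropriate + pr$p_under + pr$p_over, 1)
  # all-appropriate study
  all_app <- mini_study(truth = c(30, 35), est1 = c(20, 25), est2 = c(26, 31),
                        m = c(29, 34))
  pr2 <- reliance_proportions(all_app, "p01", 2)
  expect_equal(pr2$p_appropriate, 1)
})

test_that("agreement uses half-open bins with a closed last bin", {
  # bin [18,20): 19 agrees, 20 does not
  tbl <- mini_study(truth = c(19, 19, 19, 19),
                    est1 = c(15, 15, 15, 15),
                    est2 = c(19, 20, 18, 17.9),
                    m = c(19, 19, 19, 19))
  expect_equal(agreement(tbl, "p01", 2), 0.5)  # 19 and 18 in, 20 and 17.9 out
  # last bin [38,42] is closed at 42
  last <- mini_study(truth = 40, est1 = 30, est2 = 42, m = 40)
  expect_equal(agreement(last, "p01", 2), 1)
  # 3 of 4 agreeing
  tbl2 <- mini_study(truth = rep(25, 4), est1 = rep(20, 4),
                     est2 = c(24.5, 25.9, 24.1, 30), m = rep(25, 4))
  expect_equal(agreement(tbl2, "p01", 2), 0.75)
})

test_that("log ratios behave like natural logs and respect the fold reading", {
  expect_equal(log_ratio(0.6, 0.2), log(3), tolerance = 1e-9)
  expect_equal(log_ratio(0.3, 0.3), 0)
  expect_equal(log_ratio(0.2, 0.6), -log(3), tolerance = 1e-9)
  expect_warning(out <- log_ratio(0, 0), "undefined")
  expect_true(is.na(out))
  # the natural base keeps the prose reading of typical study values honest
  expect_gt(exp(1.21), 3)
  expect_equal(exp(0.65), 2, tolerance = 0.05)
  # Haldane smoothing keeps ratios finite when a category is empty
  pr <- haldane_proportions(c(10L, 5L, 0L))
  expect_true(all(is.finite(log_ratio(pr[1], pr[3]))))
  expect_equal(sum(pr), 1)
})

test_that("the per-participant reliance summary is complete and consistent", {
  tbl <- generate_study(simulation_config(n_participants = 3L, n_images = 20L), 5)
  rs <- reliance_summary(tbl)
  expect_equal(nrow(rs), 3L * 2L)
  expect_true(all(abs(rs$p_appropriate + rs$p_under + rs$p_over - 1) < 1e-9))
  expect_true(all(rs$agreement >= 0 & rs$agreement <= 1))
  expect_true(all(rs$n == 20L))
})
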