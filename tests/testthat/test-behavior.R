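test_that("go bias is the accuracy difference between the two win stimuli", {
  tr <- policy_trials(go_rate_go_win = 0.9, go_rate_nogo_win = 0.3)
  expect_equal(go_bias(tr), 0.9 - 0.7)
  tr2 <- policy_trials(go_rate_go_win = 0.8, go_rate_nogo_win = 0.2)
  expect_equal(go_bias(tr2), 0)
  only_go <- tr[tr$stimulus == "go_win", ]
  expect_error(go_bias(only_go), "both")
})

test_that("exclusion rules match the stated thresholds and are idempotent", {
  cohort <- rbind(
    policy_trials(pid = "good", go_rate_go_win = 0.9, go_rate_nogo_win = 0.1),
    policy_trials(pid = "perfect", go_rate_go_win = 1, go_rate_nogo_win = 0),
    # 55% incorrect overall (accuracy 0.45 across the two win stimuli)
    policy_trials(pid = "inaccurate", go_rate_go_win = 0.5,
                  go_rate_nogo_win = 0.6),
    # fine overall but 20% on one stimulus
    policy_trials(pid = "one_bad", go_rate_go_win = 1,
                  go_rate_nogo_win = 0.8))
  sm <- summarize_participants(cohort)
  res <- apply_exclusions(sm)
  expect_setequal(res$kept$participant_id, c("good", "perfect"))
  expect_setequal(res$excluded$participant_id, c("inaccurate", "one_bad"))
  expect_match(res$excluded$reason[res$excluded$participant_id == "inaccurate"],
               ">=50%")
  expect_match(res$excluded$reason[res$excluded$participant_id == "one_bad"],
               "<30%")
  again <- apply_exclusions(res$kept)
  expect_equal(again$kept, res$kept)
  expect_equal(nrow(again$excluded), 0)
})

test_that("per-stimulus accuracy uses the hc decoy but never the lc decoy", {
  # hc decoy with only 20% go -> excluded even though win stimuli are fine
  tr <- policy_trials(pid = "hc_bad", go_rate_go_win = 1,
                      go_rate_nogo_win = 0, go_rate_decoy = 0.2,
                      condition = "hc")
  res <- apply_exclusions(summarize_participants(tr))
  expect_equal(res$excluded$participant_id, "hc_bad")
  # same decoy policy in lc is not an exclusion reason (optimal undefined)
  tr_lc <- policy_trials(pid = "lc_ok", go_rate_go_win = 1,
                         go_rate_nogo_win = 0, go_rate_decoy = 0.2,
                         condition = "lc")
  expect_equal(nrow(apply_exclusions(summarize_participants(tr_lc))$excluded),
               0)
})

test_that("bias and variance match their definitions", {
  tr <- make_trials(rep("go_win", 4), c("go", "go", "nogo", "go"))
  tr$optimal_action <- c("go", "nogo", "nogo", "go")
  bv <- bias_variance(tr)
  expect_equal(bv[["bias"]], 0.25)
  expect_equal(bv[["variance"]], 0.75 * 0.25)

  all_opt <- make_trials(c("go_win", "nogo_win"), c("go", "nogo"))
  expect_equal(bias_variance(all_opt)[["bias"]], 0)

  # variance equals p(1-p) for the session go rate (identity oracle)
  for (seed in 1:5) {
    set.seed(seed)
    acts <- sample(c("go", "nogo"), 30, replace = TRUE)
    tr <- make_trials(rep("go_win", 30), acts)
    p <- mean(acts == "go")
    expect_equal(bias_variance(tr)[["variance"]], p * (1 - p),
                 tolerance = 1e-12)
  }

  # bias skips undefined-optimal trials; variance keeps them unless asked
  mix <- make_trials(c("go_win", "decoy_lc", "decoy_lc"),
                     c("go", "go", "go"))
  expect_equal(bias_variance(mix)[["bias"]], 0)
  expect_equal(bias_variance(mix)[["variance"]], 0)
  no_decoy <- bias_variance(mix, include_decoy = FALSE)
  expect_equal(no_decoy[["variance"]], 0)
  only_decoy <- make_trials("decoy_lc", "go")
  expect_error(bias_variance(only_decoy), "defined optimal")
})

test_that("weight-quantile analysis is aligned, consistent and monotone", {
  co <- simulate_cohort(30, adaptive_spec(), "exp1", "lc", seed = 19)
  one <- go_bias_by_weight_quantile(co$trials, co$weights, 1)
  overall <- mean(per_participant(co$trials, go_bias))
  expect_equal(one$mean_go_bias, overall, tolerance = 1e-12)

  q <- go_bias_by_weight_quantile(co$trials, co$weights, 5)
  expect_equal(nrow(q), 5)
  expect_true(all(q$n_participants >= 25))
  expect_gt(cor(q$quantile, q$mean_go_bias, method = "spearman"), 0)

  # constant weights: bins are balanced and statistically indistinguishable
  fx <- model_spec("fixed", beta = 3, w_fixed = 0.5)
  cf <- simulate_cohort(30, fx, "exp1", "lc", seed = 20)
  q2 <- go_bias_by_weight_quantile(cf$trials, cf$weights, 2)
  expect_lt(abs(q2$mean_go_bias[1] - q2$mean_go_bias[2]),
            3 * sqrt(sum(q2$sem^2)))

  expect_error(
    go_bias_by_weight_quantile(co$trials[1:3, ], co$weights, 5),
    "fewer trials")
  bad_w <- co$weights; bad_w$trial <- bad_w$trial + 1000
  expect_error(go_bias_by_weight_quantile(co$trials, bad_w, 5),
               "not aligned")
})

test_that("go-bias timecourse pairs within-stimulus indices correctly", {
  # deterministic all-go agent: go bias is 1 - 0 at every index, slope 0
  tr <- policy_trials(pid = "allgo", n_per = 40, go_rate_go_win = 1,
                      go_rate_nogo_win = 1, go_rate_decoy = 1)
  tc <- go_bias_timecourse(tr, window = 1)
  expect_equal(tc$series$mean_go_bias, rep(1, 40))
  expect_equal(tc$slopes$slope, 0)
  expect_equal(tc$series$smoothed, tc$series$mean_go_bias)

  # hand-built two-index session: k pairing independent of interleaving
  tr2 <- make_trials(c("go_win", "nogo_win", "nogo_win", "go_win"),
                     c("go", "nogo", "go", "nogo"))
  s <- go_bias_timecourse(tr2, window = 1)$series
  expect_equal(s$mean_go_bias, c(1 - 1, 0 - 0))

  unbal <- make_trials(c("go_win", "go_win", "nogo_win"),
                       c("go", "go", "nogo"))
  expect_error(go_bias_timecourse(unbal), "unequal")

  # smoothing window averages neighbours
  x <- c(1, 0, 1, 0, 1)
  expect_equal(pavarb:::moving_average(x, 3),
               c(0.5, 2 / 3, 1 / 3, 2 / 3, 0.5))
})

test_that("group statistics detect design and handle identical groups", {
  mk <- function(pid, cond, g_go, g_ng)
    policy_trials(pid = pid, condition = cond, go_rate_go_win = g_go,
                  go_rate_nogo_win = g_ng)
  # mirrored groups: identical distribution of measures -> d = 0, p = 1
  tr <- rbind(mk("l1", "lc", 0.9, 0.1), mk("l2", "lc", 0.7, 0.3),
              mk("h1", "hc", 0.9, 0.1), mk("h2", "hc", 0.7, 0.3))
  gs <- group_stats(tr)
  expect_equal(gs$design, "between")
  gb <- gs$tests[gs$tests$measure == "go_bias", ]
  expect_equal(gb$cohens_d, 0)
  expect_equal(gb$p, 1, tolerance = 1e-9)

  # within-subject sessions are detected as paired
  co <- simulate_cohort(6, adaptive_spec(), "exp2", seed = 44)
  gs2 <- group_stats(co$trials)
  expect_equal(gs2$design, "paired")
  expect_equal(nrow(gs2$tests), 3)

  expect_error(group_stats(mk("a", "lc", 1, 0)), "both conditions")
})
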