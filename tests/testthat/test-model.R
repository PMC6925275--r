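test_that("state initialization sets priors, counters and the initial weight", {
  spec <- adaptive_spec()
  st <- init_state(spec, c("go_win", "nogo_win", "decoy_lc"))
  expect_true(all(st$theta_s == 0.5))
  expect_true(all(st$theta_sa == 0.5))
  expect_true(all(st$eta_s == 2))
  expect_equal(state_weight(st, spec), 0.6224593, tolerance = 1e-6)

  flat <- model_spec("adaptive", L0 = 0)
  expect_equal(state_weight(init_state(flat, "go_win"), flat), 0.5)

  two <- model_spec("adaptive", theta0_u = 0.3, theta0_c = 0.7)
  st2 <- init_state(two, c("go_win", "nogo_win"))
  expect_true(all(st2$theta_s == 0.3))
  expect_true(all(st2$theta_sa == 0.7))
})

test_that("model specs validate their parameters", {
  expect_error(model_spec("fixed", beta = 3), "w_fixed")
  expect_error(model_spec("fixed", beta = 3, w_fixed = 1.2), "w_fixed")
  expect_error(model_spec("adaptive", w_fixed = 0.5), "no w_fixed")
  expect_error(model_spec("adaptive", theta0_u = 0))
  expect_error(model_spec("adaptive", eta0_c = 0))
})

test_that("mean updates follow the running-average closed form exactly", {
  spec <- adaptive_spec()
  st <- init_state(spec, "go_win")
  st <- update_means(st, "go_win", "go", 1)
  expect_equal(unname(st$eta_s["go_win"]), 3)
  expect_equal(unname(st$theta_s["go_win"]), 0.5 + 0.5 / 3, tolerance = 1e-12)
  st <- update_means(st, "go_win", "go", 1)
  expect_equal(unname(st$theta_s["go_win"]), 0.75, tolerance = 1e-12)
  # untouched entries stay at the prior
  expect_equal(unname(st$theta_sa["go_win", "nogo"]), 0.5)

  # closed-form oracle: theta_n = (eta0*theta0 + sum r) / (eta0 + n)
  for (seed in 1:5) {
    set.seed(seed)
    theta0 <- runif(1, 0.1, 0.9); eta0 <- runif(1, 0.5, 10)
    r <- rbinom(50, 1, 0.6)
    sp <- model_spec("adaptive", theta0_u = theta0, eta0_u = eta0,
                     theta0_c = theta0, eta0_c = eta0)
    st <- init_state(sp, "go_win")
    for (i in seq_along(r)) {
      st <- update_means(st, "go_win", "go", r[i])
      expect_equal(unname(st$theta_s["go_win"]),
                   (eta0 * theta0 + sum(r[1:i])) / (eta0 + i),
                   tolerance = 1e-12)
    }
  }
  expect_error(update_means(st, "go_win", "go", 2), "0 or 1")
})

test_that("log-odds updates equal the predictive log ratio", {
  spec <- adaptive_spec()
  st <- init_state(spec, "go_win")
  st$theta_s["go_win"] <- 0.5
  st$theta_sa["go_win", "go"] <- 0.8
  up <- update_logodds(st, "go_win", "go", 1)
  expect_equal(up$L - st$L, -0.4700036, tolerance = 1e-6)   # ln(0.625)
  dn <- update_logodds(st, "go_win", "go", 0)
  expect_equal(dn$L - st$L, 0.9162907, tolerance = 1e-6)    # ln(2.5)
  st$theta_sa["go_win", "go"] <- 0.5
  expect_equal(update_logodds(st, "go_win", "go", 1)$L, st$L)
  expect_equal(update_logodds(st, "go_win", "go", 0)$L, st$L)
})

test_that("action values mix the two controllers by the weight", {
  spec <- adaptive_spec()        # w = plogis(0.5)
  st <- init_state(spec, "go_win")
  st$theta_s["go_win"] <- 0.5
  st$theta_sa["go_win", "go"] <- 0.8
  v <- action_values(st, "go_win", spec)
  expect_equal(unname(v["go"]), 0.6132622, tolerance = 1e-6)
  expect_equal(unname(v["nogo"]), (1 - 0.6224593) * 0.5, tolerance = 1e-6)

  inst <- model_spec("fixed", w_fixed = 0)
  vi <- action_values(st, "go_win", inst)
  expect_equal(unname(vi["go"]), 0.8)
  expect_equal(unname(vi["nogo"]), 0.5)

  pav <- model_spec("fixed", w_fixed = 1)
  expect_equal(unname(action_values(st, "go_win", pav)["nogo"]), 0)
})

test_that("softmax choice probabilities are calibrated and shift-invariant", {
  expect_equal(choice_probability(c(go = 0.6, nogo = 0.4), 2),
               0.5986877, tolerance = 1e-6)
  expect_equal(choice_probability(c(go = 0.9, nogo = 0.1), 0), 0.5)
  expect_equal(choice_probability(c(go = 0.7, nogo = 0.7), 5), 0.5)
  expect_equal(choice_probability(c(go = 0.6, nogo = 0.4), 2),
               choice_probability(c(go = 10.6, nogo = 10.4), 2))
})

test_that("step composes log-odds then mean updates; fixed variant skips L", {
  spec <- adaptive_spec()
  st <- init_state(spec, "go_win")
  st$theta_sa["go_win", "go"] <- 0.7   # make dL nonzero
  manual <- update_means(update_logodds(st, "go_win", "go", 1),
                         "go_win", "go", 1)
  expect_identical(step_state(st, "go_win", "go", 1, spec), manual)

  fx <- model_spec("fixed", w_fixed = 0.3)
  st <- init_state(fx, "go_win")
  for (r in rbinom(20, 1, 0.5)) st <- step_state(st, "go_win", "go", r, fx)
  expect_equal(st$L, fx$L0)
})

test_that("C and R session walks agree to machine precision", {
  cfg1 <- build_task_config("exp1", "lc", seed = 21)
  cfg2 <- build_task_config("exp2", seed = 22)
  specs <- list(adaptive_spec(),
                model_spec("adaptive", beta = 1.3, theta0_u = 0.3,
                           eta0_u = 5, theta0_c = 0.7, eta0_c = 0.8),
                model_spec("fixed", beta = 2, w_fixed = 0.8))
  for (spec in specs) {
    for (cfg in list(cfg1, cfg2)) {
      sim <- simulate_agent(spec, cfg, seed = 33)
      a <- session_trace(spec, sim$trials)
      b <- pavarb:::session_trace_r(spec, sim$trials)
      expect_equal(a$loglik, b$loglik, tolerance = 1e-12)
      expect_equal(a$w, b$w, tolerance = 1e-12)
      expect_equal(a$p_go, b$p_go, tolerance = 1e-12)
    }
  }
})

test_that("session log-likelihood has the right fixed points and guards", {
  cfg <- build_task_config("exp1", "hc", seed = 5)
  sim <- simulate_agent(adaptive_spec(), cfg, seed = 5)
  zero_beta <- model_spec("adaptive", beta = 0)
  expect_equal(session_loglik(zero_beta, sim$trials), 120 * log(0.5))

  # first-trial probability chains action_values and choice_probability
  spec <- adaptive_spec()
  one <- sim$trials[1, ]
  st <- init_state(spec, one$stimulus)
  p <- choice_probability(action_values(st, one$stimulus, spec), spec$beta)
  expect_equal(session_loglik(spec, one),
               log(if (one$action == "go") p else 1 - p))

  mixed <- rbind(sim$trials, transform(sim$trials, participant_id = "other"))
  expect_error(session_loglik(spec, mixed), "multiple participants")
  expect_error(session_loglik(spec, sim$trials[c(2, 1), ]), "sorted")
  expect_error(session_loglik(spec, sim$trials[0, ]), "no trials")
})

test_that("simulation is deterministic and weights stay in (0,1)", {
  cfg <- build_task_config("exp2", seed = 14)
  spec <- adaptive_spec()
  a <- simulate_agent(spec, cfg, seed = 8)
  b <- simulate_agent(spec, cfg, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$trials$action,
                         simulate_agent(spec, cfg, seed = 9)$trials$action))
  expect_true(all(a$weights$w > 0 & a$weights$w < 1))
  # weight monotone in L
  L <- seq(-5, 5, length.out = 50)
  expect_true(all(diff(plogis(L)) > 0))

  fx <- model_spec("fixed", w_fixed = 0.25)
  wf <- simulate_agent(fx, cfg, seed = 8)$weights$w
  expect_true(all(wf == 0.25))
})

test_that("controllability drives the weight in the predicted directions", {
  spec <- adaptive_spec()
  # action-independent rewards (LC decoy alone): L drifts upward
  set.seed(77)
  st <- init_state(spec, "decoy_lc")
  for (i in 1:10000) {
    a <- sample(c("go", "nogo"), 1)
    r <- rbinom(1, 1, 0.5)
    st <- step_state(st, "decoy_lc", a, r, spec)
  }
  expect_gt(st$L, spec$L0)
  expect_gt(plogis(st$L), 0.9)

  # strongly action-dependent rewards: weight collapses toward 0
  set.seed(78)
  st <- init_state(spec, "go_win")
  for (i in 1:10000) {
    a <- sample(c("go", "nogo"), 1)
    r <- rbinom(1, 1, if (a == "go") 0.9 else 0.1)
    st <- step_state(st, "go_win", a, r, spec)
  }
  expect_lt(plogis(st$L), 0.01)
})

test_that("exp2 blocks reset the learner state", {
  spec <- adaptive_spec()
  cfg <- build_task_config("exp2", seed = 31)
  sim <- simulate_agent(spec, cfg, seed = 31)
  tr <- session_trace(spec, sim$trials)
  first_of_block2 <- which(sim$trials$block == 1)[1]
  expect_equal(tr$w[first_of_block2], plogis(spec$L0))
  expect_equal(sim$weights$w[first_of_block2], plogis(spec$L0))
})
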