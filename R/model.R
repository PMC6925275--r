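# Pavlovian and instrumental Beta-Bernoulli learners, controllability
# inference, value integration, softmax choice, and forward simulation.
#
# The Pavlovian (uncontrollable-environment) learner tracks a posterior mean
# reward rate per stimulus, theta_s; the instrumental (controllable) learner
# tracks one per stimulus-action pair, theta_sa. Both use the incremental
# running-average rule delta-theta = (r - theta) / eta with the counter eta
# initialized to the prior confidence eta0 and incremented on every
# observation, so theta after n observations equals
# (eta0 * theta0 + sum r) / (eta0 + n). The arbitrator maintains the log
# posterior odds L that the environment is uncontrollable, updated each trial
# by the log ratio of the two learners' one-step predictive probabilities for
# the observed reward; w = sigmoid(L) mixes the controllers' action values.

THETA_EPS <- 1e-6  # clip predictive means before taking logs

#' Specify an arbitration model
#'
#' The adaptive variant updates the Pavlovian weight `w = plogis(L)` from
#' trial-wise predictive log-odds; the fixed variant holds `w` constant at
#' `w_fixed`. Both share the inverse temperature `beta` and one
#' (`theta0`, `eta0`) prior pair per internal environment model:
#' `_u` for the uncontrollable (Pavlovian, stimulus-only) learner and `_c`
#' for the controllable (instrumental, stimulus-action) learner.
#'
#' @param variant `"adaptive"` or `"fixed"`.
#' @param beta inverse temperature, `>= 0`.
#' @param theta0_u,eta0_u prior mean in (0,1) and prior confidence > 0 for
#'   the Pavlovian learner.
#' @param theta0_c,eta0_c prior mean and confidence for the instrumental
#'   learner.
#' @param w_fixed Pavlovian weight in `[0, 1]`; required for the fixed
#'   variant, must be absent for the adaptive variant.
#' @param L0 initial log-odds of the uncontrollable environment
#'   (default 0.5, i.e. initial weight `plogis(0.5)` ~= 0.622).
#' @return A `pavarb_model` list.
#' @export
#' @examples
#' model_spec("adaptive", beta = 3)
#' model_spec("fixed", beta = 3, w_fixed = 0.9)
model_spec <- function(variant = c("adaptive", "fixed"), beta = 3,
                       theta0_u = 0.5, eta0_u = 2,
                       theta0_c = 0.5, eta0_c = 2,
                       w_fixed = NULL, L0 = 0.5) {
  variant <- match.arg(variant)
  stopifnot(beta >= 0, eta0_u > 0, eta0_c > 0,
            theta0_u > 0, theta0_u < 1, theta0_c > 0, theta0_c < 1,
            is.finite(L0))
  if (variant == "fixed") {
    if (is.null(w_fixed) || w_fixed < 0 || w_fixed > 1)
      stop_config("fixed variant requires w_fixed in [0, 1]")
  } else if (!is.null(w_fixed)) {
    stop_config("adaptive variant takes no w_fixed")
  }
  structure(list(variant = variant, beta = beta,
                 theta0_u = theta0_u, eta0_u = eta0_u,
                 theta0_c = theta0_c, eta0_c = eta0_c,
                 w_fixed = w_fixed, L0 = L0),
            class = "pavarb_model")
}

#' Initialize learner state
#'
#' Pavlovian means start at `theta0_u` with counters `eta0_u`; instrumental
#' means at `theta0_c` with counters `eta0_c`, independently per
#' stimulus-action pair; the log-odds start at `L0`.
#'
#' @param spec a [model_spec()].
#' @param stimuli character vector of stimulus ids present in the session.
#' @return A `pavarb_state` list with `theta_s`, `eta_s` (named by stimulus),
#'   `theta_sa`, `eta_sa` (stimulus x action matrices), and `L`.
#' @export
init_state <- function(spec, stimuli) {
  stopifnot(inherits(spec, "pavarb_model"), length(stimuli) > 0)
  n <- length(stimuli)
  sa <- matrix(spec$theta0_c, n, 2, dimnames = list(stimuli, ACTIONS))
  eta_sa <- matrix(spec$eta0_c, n, 2, dimnames = list(stimuli, ACTIONS))
  structure(list(theta_s = setNames(rep(spec$theta0_u, n), stimuli),
                 eta_s = setNames(rep(spec$eta0_u, n), stimuli),
                 theta_sa = sa, eta_sa = eta_sa,
                 L = spec$L0),
            class = "pavarb_state")
}

#' Current Pavlovian weight of a state
#'
#' `plogis(L)` for the adaptive variant, `w_fixed` for the fixed variant.
#'
#' @param state a `pavarb_state`.
#' @param spec the owning [model_spec()].
#' @return Weight in `(0, 1)` (adaptive) or `[0, 1]` (fixed).
#' @export
state_weight <- function(state, spec) {
  if (spec$variant == "fixed") spec$w_fixed else plogis(state$L)
}

#' Update posterior means after an observed reward
#'
#' Increments the stimulus counter and applies the running-average delta for
#' the Pavlovian mean; does the same for the instrumental mean of the chosen
#' (stimulus, action) pair only. All other entries are untouched.
#'
#' @param state a `pavarb_state`.
#' @param s stimulus id.
#' @param a action taken, `"go"` or `"nogo"`.
#' @param r reward, 0 or 1.
#' @return Updated state.
#' @export
update_means <- function(state, s, a, r) {
  if (!r %in% c(0, 1)) stop_config("reward must be 0 or 1")
  state$eta_s[s] <- state$eta_s[s] + 1
  state$theta_s[s] <- state$theta_s[s] +
    (r - state$theta_s[s]) / state$eta_s[s]
  state$eta_sa[s, a] <- state$eta_sa[s, a] + 1
  state$theta_sa[s, a] <- state$theta_sa[s, a] +
    (r - state$theta_sa[s, a]) / state$eta_sa[s, a]
  state
}

#' Update the controllability log-odds
#'
#' Adds the log ratio of the Pavlovian and instrumental one-step predictive
#' probabilities of the observed reward:
#' `dL = r * log(theta_s / theta_sa) + (1 - r) * log((1-theta_s)/(1-theta_sa))`.
#' Must be called with the means as they stood *before* this trial's
#' [update_means()] (prequential one-step prediction). Means are clipped to
#' `[1e-6, 1 - 1e-6]` before the logs as a guard for degenerate priors.
#'
#' @inheritParams update_means
#' @return Updated state.
#' @export
update_logodds <- function(state, s, a, r) {
  th_s <- min(max(state$theta_s[s], THETA_EPS), 1 - THETA_EPS)
  th_sa <- min(max(state$theta_sa[s, a], THETA_EPS), 1 - THETA_EPS)
  dL <- if (r == 1) log(th_s / th_sa) else log((1 - th_s) / (1 - th_sa))
  state$L <- state$L + dL
  state
}

#' Integrated action values for a stimulus
#'
#' `V(s, go) = w * theta_s + (1 - w) * theta_s,go` and
#' `V(s, nogo) = (1 - w) * theta_s,nogo`: the Pavlovian value of No-Go is 0
#' (reward expectation invigorates action only).
#'
#' @param state a `pavarb_state`.
#' @param s stimulus id.
#' @param spec the owning [model_spec()].
#' @return Named numeric `c(go = , nogo = )`.
#' @export
action_values <- function(state, s, spec) {
  w <- state_weight(state, spec)
  c(go = w * unname(state$theta_s[s]) + (1 - w) * state$theta_sa[s, "go"],
    nogo = (1 - w) * state$theta_sa[s, "nogo"])
}

#' Softmax Go probability
#'
#' `P(go) = 1 / (1 + exp(-beta * (V_go - V_nogo)))`; invariant to adding a
#' constant to both values.
#'
#' @param values named numeric with elements `go` and `nogo`.
#' @param beta inverse temperature `>= 0`.
#' @return Probability of a Go response.
#' @export
choice_probability <- function(values, beta) {
  stopifnot(beta >= 0)
  plogis(beta * (values[["go"]] - values[["nogo"]]))
}

#' Advance the learner by one trial
#'
#' For the adaptive variant the log-odds update (from pre-update means) runs
#' first, then the mean updates; the fixed variant skips the log-odds update.
#'
#' @inheritParams update_means
#' @param spec the owning [model_spec()].
#' @return Updated state.
#' @export
step_state <- function(state, s, a, r, spec) {
  if (spec$variant == "adaptive") state <- update_logodds(state, s, a, r)
  update_means(state, s, a, r)
}

trials_to_codes <- function(trials) {
  list(stim = match(trials$stimulus, STIMULI),
       action = as.integer(trials$action == "go"),
       reward = as.integer(trials$reward),
       block = as.integer(trials$block))
}

check_single_session <- function(trials) {
  if (nrow(trials) == 0) stop_config("no trials")
  if (length(unique(trials$participant_id)) > 1)
    stop_config("trials mix multiple participants")
  if (is.unsorted(trials$trial, strictly = TRUE))
    stop_config("trials must be strictly sorted by trial index")
  invisible(trials)
}

#' Session log-likelihood of observed choices
#'
#' Total `sum(log P(a_t | s_t))` for one participant's session with the
#' learner state evolved trial by trial ([step_state()]); state (means and
#' log-odds) is re-initialized at each block boundary, since each block
#' introduces new stimuli. Computed in C; [session_trace()] exposes the
#' per-trial weights and Go probabilities, and the pure-R evolution via
#' [step_state()] serves as the reference implementation in the test suite.
#'
#' @param spec a [model_spec()].
#' @param trials single-participant trial data.frame sorted by `trial`.
#' @return Scalar log-likelihood (`<= 0`).
#' @export
session_loglik <- function(spec, trials) {
  session_trace(spec, trials)$loglik
}

#' Per-trial trace of the model over a session
#'
#' @inheritParams session_loglik
#' @return List with `loglik`, and per-trial vectors `w` (Pavlovian weight
#'   used on that trial) and `p_go` (model Go probability).
#' @export
session_trace <- function(spec, trials) {
  check_single_session(trials)
  cd <- trials_to_codes(trials)
  arb_session_cpp(cd$stim, cd$action, cd$reward, cd$block,
                  spec$beta, spec$theta0_u, spec$eta0_u,
                  spec$theta0_c, spec$eta0_c, spec$L0,
                  spec$variant == "adaptive", spec$w_fixed %||% 0.5)
}

# Pure-R session walk; reference ("oracle") path for the C implementation.
session_trace_r <- function(spec, trials) {
  check_single_session(trials)
  loglik <- 0
  w <- p_go <- numeric(nrow(trials))
  state <- NULL
  cur_block <- -1L
  for (i in seq_len(nrow(trials))) {
    if (trials$block[i] != cur_block) {
      cur_block <- trials$block[i]
      state <- init_state(spec, STIMULI)
    }
    s <- trials$stimulus[i]
    w[i] <- state_weight(state, spec)
    p_go[i] <- choice_probability(action_values(state, s, spec), spec$beta)
    p_act <- if (trials$action[i] == "go") p_go[i] else 1 - p_go[i]
    loglik <- loglik + log(max(p_act, 1e-300))
    state <- step_state(state, s, trials$action[i], trials$reward[i], spec)
  }
  list(loglik = loglik, w = w, p_go = p_go)
}

#' Simulate one agent on the task
#'
#' Samples a trial sequence from the config, then on each trial draws the
#' action from the model's softmax policy, draws the reward from the task
#' contingencies, and steps the learner. Deterministic given `seed`.
#'
#' @param spec a [model_spec()].
#' @param config a [build_task_config()].
#' @param seed integer seed for the agent's action and outcome draws.
#' @param participant_id id recorded in the trial log.
#' @return List with `trials` (trial data.frame) and `weights` (data.frame
#'   `participant_id, trial, w` of the per-trial Pavlovian weight).
#' @export
simulate_agent <- function(spec, config, seed = 0, participant_id = "sim01") {
  seq_df <- sample_trial_sequence(config)
  n <- nrow(seq_df)
  with_seed(derive_seed(seed, "agent"), {
    action <- character(n)
    reward <- integer(n)
    w <- numeric(n)
    optimal <- character(n)
    state <- NULL
    cur_block <- -1L
    for (i in seq_len(n)) {
      if (seq_df$block[i] != cur_block) {
        cur_block <- seq_df$block[i]
        state <- init_state(spec, STIMULI)
      }
      s <- seq_df$stimulus[i]
      st_spec <- config$contingencies[[s]]
      w[i] <- state_weight(state, spec)
      p_go <- choice_probability(action_values(state, s, spec), spec$beta)
      action[i] <- if (runif(1) < p_go) "go" else "nogo"
      reward[i] <- sample_outcome(st_spec, action[i])
      optimal[i] <- st_spec$optimal_action
      state <- step_state(state, s, action[i], reward[i], spec)
    }
    trials <- data.frame(participant_id = participant_id,
                         experiment = config$experiment,
                         condition = seq_df$condition,
                         block = seq_df$block,
                         trial = seq_df$trial,
                         stimulus = seq_df$stimulus,
                         action = action,
                         reward = reward,
                         optimal_action = optimal,
                         stringsAsFactors = FALSE)
    list(trials = trials,
         weights = data.frame(participant_id = participant_id,
                              trial = seq_df$trial, w = w,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate a cohort of agents
#'
#' One agent per row of `design`; per-agent seeds are derived from `seed`
#' and the participant id, so cohort membership and order never perturb an
#' individual agent's stream.
#'
#' @param n number of agents.
#' @param spec a [model_spec()] shared by all agents.
#' @param experiment `"exp1"` or `"exp2"`.
#' @param condition for exp1, `"lc"` or `"hc"` (recycled over agents);
#'   ignored for exp2.
#' @param seed integer cohort seed.
#' @param id_prefix participant id prefix.
#' @param trials_per_stimulus passed to [build_task_config()].
#' @param contingencies passed to [build_task_config()].
#' @return List with stacked `trials` and `weights` data.frames.
#' @export
simulate_cohort <- function(n, spec, experiment, condition = NULL, seed = 0,
                            id_prefix = "sim", trials_per_stimulus = 40,
                            contingencies = default_contingencies()) {
  ids <- sprintf("%s%03d", id_prefix, seq_len(n))
  out <- lapply(seq_len(n), function(i) {
    cfg <- build_task_config(experiment, condition,
                             seed = derive_seed(seed, "task", ids[i]),
                             trials_per_stimulus = trials_per_stimulus,
                             contingencies = contingencies)
    simulate_agent(spec, cfg, seed = derive_seed(seed, "sim", ids[i]),
                   participant_id = ids[i])
  })
  list(trials = do.call(rbind, lapply(out, `[[`, "trials")),
       weights = do.call(rbind, lapply(out, `[[`, "weights")))
}
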