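# Shared fixtures: small hand-built trial frames and canonical model specs.

adaptive_spec <- function(...) model_spec("adaptive", beta = 3, ...)

# Build a minimal valid trial frame from parallel vectors.
make_trials <- function(stimulus, action, reward = 0L, condition = "lc",
                        pid = "p1", block = 0L, experiment = "exp1") {
  n <- length(stimulus)
  cont <- default_contingencies()
  data.frame(participant_id = pid, experiment = experiment,
             condition = rep_len(condition, n), block = rep_len(block, n),
             trial = seq_len(n) - 1L, stimulus = stimulus,
             action = action, reward = as.integer(rep_len(reward, n)),
             optimal_action = unname(vapply(stimulus,
                                            function(s) cont[[s]]$optimal_action,
                                            character(1))),
             stringsAsFactors = FALSE, row.names = NULL)
}

# A balanced session where the participant takes `action_go_win` on every
# go_win trial etc.; rewards irrelevant for accuracy-based tests.
policy_trials <- function(pid = "p1", n_per = 10, go_rate_go_win = 1,
                          go_rate_nogo_win = 0, go_rate_decoy = 0.5,
                          condition = "lc") {
  decoy <- if (condition == "lc") "decoy_lc" else "decoy_hc"
  stim <- rep(c("go_win", "nogo_win", decoy), each = n_per)
  n_go <- function(rate) round(rate * n_per)
  act <- c(rep(c("go", "nogo"), c(n_go(go_rate_go_win),
                                  n_per - n_go(go_rate_go_win))),
           rep(c("go", "nogo"), c(n_go(go_rate_nogo_win),
                                  n_per - n_go(go_rate_nogo_win))),
           rep(c("go", "nogo"), c(n_go(go_rate_decoy),
                                  n_per - n_go(go_rate_decoy))))
  make_trials(stim, act, condition = condition, pid = pid)
}

per_participant <- function(trials, fn) {
  vapply(split(trials, trials$participant_id), fn, numeric(1))
}
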