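# Go/No-Go task with a controllability manipulation: stimuli, contingencies,
# trial sequences, outcome sampling, and trial CSV I/O.

STIMULI <- c("go_win", "nogo_win", "decoy_lc", "decoy_hc")
ACTIONS <- c("go", "nogo")
CONDITIONS <- c("lc", "hc")
EXPERIMENTS <- c("exp1", "exp2")

#' Reward contingencies for one stimulus
#'
#' A stimulus is defined by its reward probability under each action. The
#' optimal action is the one with the higher reward probability; when the two
#' probabilities are equal the outcome is action-independent and the optimal
#' action is undefined (the operational meaning of low controllability for
#' the decoy).
#'
#' @param stimulus_id one of `"go_win"`, `"nogo_win"`, `"decoy_lc"`,
#'   `"decoy_hc"`.
#' @param p_reward_go,p_reward_nogo reward probabilities in `[0, 1]` for Go
#'   and No-Go responses.
#' @return A `pavarb_stimulus` list with fields `stimulus_id`, `p_reward_go`,
#'   `p_reward_nogo`, `optimal_action` (`"go"`, `"nogo"` or `"undefined"`).
#' @export
#' @examples
#' stimulus_spec("decoy_lc", 0.5, 0.5)$optimal_action  # "undefined"
stimulus_spec <- function(stimulus_id, p_reward_go, p_reward_nogo) {
  if (!stimulus_id %in% STIMULI)
    stop_config("unknown stimulus '%s'", stimulus_id)
  if (!is.numeric(p_reward_go) || p_reward_go < 0 || p_reward_go > 1 ||
      !is.numeric(p_reward_nogo) || p_reward_nogo < 0 || p_reward_nogo > 1)
    stop_config("reward probabilities must lie in [0, 1]")
  optimal <- if (p_reward_go > p_reward_nogo) "go"
             else if (p_reward_go < p_reward_nogo) "nogo"
             else "undefined"
  structure(list(stimulus_id = stimulus_id,
                 p_reward_go = p_reward_go,
                 p_reward_nogo = p_reward_nogo,
                 optimal_action = optimal),
            class = "pavarb_stimulus")
}

#' Default task contingencies
#'
#' Go-to-Win rewards Go 75% of the time, No-Go-to-Win rewards No-Go 75% of
#' the time; the complementary action is rewarded 25% of the time. The low
#' control decoy rewards either action 50% of the time (action-independent);
#' the high control decoy rewards Go 80% and No-Go 20% of the time.
#' All four probabilities can be overridden via the `contingencies` argument
#' of [build_task_config()].
#'
#' @return Named list of [stimulus_spec()] objects.
#' @export
default_contingencies <- function() {
  list(go_win   = stimulus_spec("go_win",   0.75, 0.25),
       nogo_win = stimulus_spec("nogo_win", 0.25, 0.75),
       decoy_lc = stimulus_spec("decoy_lc", 0.50, 0.50),
       decoy_hc = stimulus_spec("decoy_hc", 0.80, 0.20))
}

#' Build a task configuration
#'
#' Experiment 1 is a between-subjects session of 120 trials (three stimuli,
#' 40 each, randomly interleaved) where `condition` selects which decoy the
#' participant sees. Experiment 2 is a within-subject session of 240 trials:
#' two 120-trial blocks, one per decoy condition, block order randomized by
#' `seed`.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param condition `"lc"` or `"hc"`; required for exp1, ignored for exp2.
#' @param seed integer seed for sequence generation and block-order
#'   randomization.
#' @param trials_per_stimulus trials per stimulus per block (default 40).
#' @param contingencies list of stimulus specs, see
#'   [default_contingencies()].
#' @return A `pavarb_task_config` list with fields `experiment`,
#'   `block_conditions` (condition of each block), `trials_per_stimulus`,
#'   `n_trials`, `seed`, `contingencies`.
#' @export
#' @examples
#' cfg <- build_task_config("exp1", "lc", seed = 1)
#' cfg$n_trials  # 120
build_task_config <- function(experiment, condition = NULL, seed = 0,
                              trials_per_stimulus = 40,
                              contingencies = default_contingencies()) {
  if (!is.character(experiment) || !experiment %in% EXPERIMENTS)
    stop_config("unknown experiment '%s' (use 'exp1' or 'exp2')",
                as.character(experiment)[1])
  stopifnot(trials_per_stimulus >= 1)
  if (experiment == "exp1") {
    if (is.null(condition) || !condition %in% CONDITIONS)
      stop_config("exp1 requires condition 'lc' or 'hc'")
    block_conditions <- condition
  } else {
    block_conditions <- with_seed(derive_seed(seed, "block_order"),
                                  sample(CONDITIONS))
  }
  n_blocks <- length(block_conditions)
  structure(list(experiment = experiment,
                 block_conditions = block_conditions,
                 trials_per_stimulus = trials_per_stimulus,
                 n_trials = 3L * trials_per_stimulus * n_blocks,
                 seed = as.integer(seed),
                 contingencies = contingencies),
            class = "pavarb_task_config")
}

block_stimuli <- function(condition) {
  c("go_win", "nogo_win", if (condition == "lc") "decoy_lc" else "decoy_hc")
}

#' Sample a trial sequence
#'
#' Within each block every stimulus appears exactly `trials_per_stimulus`
#' times, uniformly shuffled under the config seed. Deterministic: the same
#' config yields the same sequence.
#'
#' @param config a [build_task_config()] object.
#' @return data.frame with columns `block` (0-based), `trial` (0-based
#'   within-session), `condition`, `stimulus`.
#' @export
sample_trial_sequence <- function(config) {
  stopifnot(inherits(config, "pavarb_task_config"))
  blocks <- lapply(seq_along(config$block_conditions), function(b) {
    cond <- config$block_conditions[b]
    stim <- rep(block_stimuli(cond), each = config$trials_per_stimulus)
    stim <- with_seed(derive_seed(config$seed, "sequence", b), sample(stim))
    data.frame(block = b - 1L, condition = cond, stimulus = stim,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out$trial <- seq_len(nrow(out)) - 1L
  out[, c("block", "trial", "condition", "stimulus")]
}

#' Sample a binary reward outcome
#'
#' Bernoulli draw with probability `p_reward_go` if the action is Go, else
#' `p_reward_nogo`. Uses the current RNG stream; wrap in [with_seed()] or
#' `set.seed()` for reproducibility.
#'
#' @param spec a [stimulus_spec()].
#' @param action `"go"` or `"nogo"` (vectorized).
#' @return Integer vector of 0/1 rewards, one per action.
#' @export
sample_outcome <- function(spec, action) {
  stopifnot(inherits(spec, "pavarb_stimulus"), all(action %in% ACTIONS))
  p <- ifelse(action == "go", spec$p_reward_go, spec$p_reward_nogo)
  as.integer(runif(length(action)) < p)
}

TRIAL_COLUMNS <- c("participant_id", "experiment", "condition", "block",
                   "trial", "stimulus", "action", "reward", "optimal_action")

validate_trials <- function(trials, file = NULL) {
  where <- if (is.null(file)) "trials" else sprintf("'%s'", file)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols) > 0)
    stop_config("%s: missing column(s) %s", where,
                paste(missing_cols, collapse = ", "))
  bad <- which(!trials$stimulus %in% STIMULI)
  if (length(bad) > 0)
    stop_config("%s: unknown stimulus '%s' at row %d", where,
                trials$stimulus[bad[1]], bad[1])
  bad <- which(!trials$action %in% ACTIONS)
  if (length(bad) > 0)
    stop_config("%s: unknown action '%s' at row %d", where,
                trials$action[bad[1]], bad[1])
  bad <- which(!trials$reward %in% c(0L, 1L))
  if (length(bad) > 0)
    stop_config("%s: non-binary reward at row %d", where, bad[1])
  bad <- which((trials$stimulus == "decoy_lc" & trials$condition != "lc") |
               (trials$stimulus == "decoy_hc" & trials$condition != "hc"))
  if (length(bad) > 0)
    stop_config("%s: decoy stimulus does not match condition at row %d",
                where, bad[1])
  invisible(trials)
}

#' Write trial records to CSV
#'
#' Schema: `participant_id,experiment,condition,block,trial,stimulus,action,
#' reward,optimal_action`; one row per trial, UTF-8, comma-separated.
#'
#' @param trials trial data.frame.
#' @param path output file path.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trial records from CSV
#'
#' Validates the schema and invariants (binary rewards, known stimulus and
#' action labels, decoy consistent with condition); errors name the first
#' offending row.
#'
#' @param path CSV file path.
#' @return Trial data.frame (possibly zero rows).
#' @export
read_trials <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE,
                     colClasses = c(participant_id = "character"))
  if (nrow(trials) == 0) {
    missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
    if (length(missing_cols) > 0)
      stop_config("'%s': missing column(s) %s", path,
                  paste(missing_cols, collapse = ", "))
    return(trials[, TRIAL_COLUMNS])
  }
  trials$reward <- suppressWarnings(as.integer(trials$reward))
  trials$reward[is.na(trials$reward)] <- -1L
  validate_trials(trials, file = path)
  trials[, TRIAL_COLUMNS]
}
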