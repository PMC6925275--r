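# Behavioral analyses: accuracy and exclusion filters, Go bias, Go bias by
# Pavlovian-weight quantile and by trial, bias-variance decomposition of
# choice behavior, and group statistics.
#
# "Accuracy" always means the fraction of trials on which the taken action
# equals the optimal action, computed only over trials whose optimal action
# is defined -- the low control decoy rewards both actions equally, so those
# trials carry no notion of correctness and are excluded from every accuracy
# (and from the bias numerator), though not from the variance.

acc_defined <- function(trials) {
  ok <- trials$optimal_action != "undefined"
  if (!any(ok)) return(NA_real_)
  mean(trials$action[ok] == trials$optimal_action[ok])
}

stim_accuracy <- function(trials, stim) {
  sub <- trials[trials$stimulus == stim, , drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  acc_defined(sub)
}

#' Per-participant behavioral summaries
#'
#' @param trials multi-participant trial data.frame.
#' @return data.frame with one row per participant: overall accuracy,
#'   per-stimulus accuracies (NA where the optimal action is undefined or
#'   the stimulus is absent), Go bias, and the bias and variance of choice
#'   behavior.
#' @export
summarize_participants <- function(trials) {
  validate_trials(trials)
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(pid) {
    tr <- trials[trials$participant_id == pid, , drop = FALSE]
    bv <- bias_variance(tr)
    data.frame(participant_id = pid,
               condition = paste(sort(unique(tr$condition)), collapse = "+"),
               n_trials = nrow(tr),
               accuracy = acc_defined(tr),
               acc_go_win = stim_accuracy(tr, "go_win"),
               acc_nogo_win = stim_accuracy(tr, "nogo_win"),
               acc_decoy_hc = stim_accuracy(tr, "decoy_hc"),
               go_bias = go_bias(tr),
               bias = bv[["bias"]], variance = bv[["variance"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply participant exclusion rules
#'
#' A participant is excluded if they made the incorrect action on at least
#' 50% of all (defined-optimal) trials, or if their accuracy on any single
#' stimulus with a defined optimal action fell below 30%. Idempotent.
#'
#' @param summaries data.frame from [summarize_participants()].
#' @return List with `kept` and `excluded` data.frames; `excluded` carries a
#'   `reason` column.
#' @export
apply_exclusions <- function(summaries) {
  acc_cols <- intersect(c("acc_go_win", "acc_nogo_win", "acc_decoy_hc"),
                        names(summaries))
  reason <- character(nrow(summaries))
  for (i in seq_len(nrow(summaries))) {
    r <- character(0)
    if (!is.na(summaries$accuracy[i]) && summaries$accuracy[i] <= 0.5)
      r <- c(r, "incorrect on >=50% of trials")
    accs <- unlist(summaries[i, acc_cols])
    if (any(!is.na(accs) & accs < 0.3))
      r <- c(r, "<30% accuracy on a stimulus")
    reason[i] <- paste(r, collapse = "; ")
  }
  excluded <- summaries[reason != "", , drop = FALSE]
  excluded$reason <- reason[reason != ""]
  list(kept = summaries[reason == "", , drop = FALSE], excluded = excluded)
}

#' Go bias of a session
#'
#' Accuracy on Go-to-Win trials (fraction of Go responses) minus accuracy on
#' No-Go-to-Win trials (fraction of No-Go responses). Zero under purely
#' instrumental control; positive values index Pavlovian influence.
#'
#' @param trials trial data.frame containing both stimulus types.
#' @return Scalar in `[-1, 1]`.
#' @export
go_bias <- function(trials) {
  a_go <- stim_accuracy(trials, "go_win")
  a_nogo <- stim_accuracy(trials, "nogo_win")
  if (is.na(a_go) || is.na(a_nogo))
    stop_config("go_bias needs both go_win and nogo_win trials")
  a_go - a_nogo
}

#' Go bias by within-participant Pavlovian-weight quantile
#'
#' Each participant's trials are ranked by that participant's own per-trial
#' weight `w` and split into `n_quantiles` equal-count bins (rank-based, so
#' ties and constant weights still yield balanced bins); the Go bias is
#' computed within each bin and averaged across participants. With
#' `n_quantiles = 1` this reduces to the overall [go_bias()].
#'
#' @param trials multi-participant trial data.frame.
#' @param weights data.frame `participant_id, trial, w` aligned to `trials`.
#' @param n_quantiles number of weight bins (default 5).
#' @return data.frame `quantile, mean_go_bias, sem, n_participants`.
#' @export
go_bias_by_weight_quantile <- function(trials, weights, n_quantiles = 5) {
  stopifnot(n_quantiles >= 1)
  key_t <- paste(trials$participant_id, trials$trial)
  key_w <- paste(weights$participant_id, weights$trial)
  idx <- match(key_t, key_w)
  if (anyNA(idx)) stop_config("weights are not aligned to trials")
  trials$w <- weights$w[idx]
  ids <- unique(trials$participant_id)
  per <- matrix(NA_real_, length(ids), n_quantiles)
  for (i in seq_along(ids)) {
    tr <- trials[trials$participant_id == ids[i], , drop = FALSE]
    if (nrow(tr) < n_quantiles)
      stop_config("participant %s has fewer trials than quantiles", ids[i])
    bin <- ceiling(n_quantiles * rank(tr$w, ties.method = "first") / nrow(tr))
    for (q in seq_len(n_quantiles)) {
      sub <- tr[bin == q, , drop = FALSE]
      a_go <- stim_accuracy(sub, "go_win")
      a_nogo <- stim_accuracy(sub, "nogo_win")
      if (!is.na(a_go) && !is.na(a_nogo)) per[i, q] <- a_go - a_nogo
    }
  }
  data.frame(
    quantile = seq_len(n_quantiles),
    mean_go_bias = colMeans(per, na.rm = TRUE),
    sem = apply(per, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
    }),
    n_participants = colSums(!is.na(per)))
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  vapply(seq_along(x), function(i) {
    j <- max(1, i - half):min(length(x), i + half)
    mean(x[j], na.rm = TRUE)
  }, numeric(1))
}

#' Go-bias timecourse over within-stimulus trial index
#'
#' For presentation index `k` (the k-th Go-to-Win and k-th No-Go-to-Win
#' trial within a block), the trial-level Go bias is
#' `I[Go on k-th go_win] - I[No-Go on k-th nogo_win]` per participant
#' (averaged over blocks for two-block sessions). Returns the cohort mean
#' and SEM per `k`, a centered moving-average smooth for display, and each
#' participant's OLS slope of the trial-level Go bias on `log(k)` together
#' with the one-sample t-test on those slopes.
#'
#' @param trials multi-participant trial data.frame with equal numbers of
#'   go_win and nogo_win trials per block.
#' @param window moving-average window in trials (default 5; 1 = no
#'   smoothing).
#' @return List with `series` (data.frame `k, mean_go_bias, sem, smoothed`),
#'   `slopes` (data.frame `participant_id, slope`), and `slope_test`
#'   (`htest` of mean slope against 0).
#' @export
go_bias_timecourse <- function(trials, window = 5) {
  ids <- unique(trials$participant_id)
  per <- list()
  slopes <- numeric(length(ids))
  for (i in seq_along(ids)) {
    tr <- trials[trials$participant_id == ids[i], , drop = FALSE]
    pts_k <- integer(0); pts_gb <- numeric(0)
    acc <- NULL
    for (b in sort(unique(tr$block))) {
      blk <- tr[tr$block == b, , drop = FALSE]
      blk <- blk[order(blk$trial), , drop = FALSE]
      go_tr <- blk[blk$stimulus == "go_win", , drop = FALSE]
      ng_tr <- blk[blk$stimulus == "nogo_win", , drop = FALSE]
      if (nrow(go_tr) != nrow(ng_tr))
        stop_config("participant %s block %d: unequal go_win/nogo_win counts",
                    ids[i], b)
      gb <- as.numeric(go_tr$action == "go") -
            as.numeric(ng_tr$action == "nogo")
      pts_k <- c(pts_k, seq_along(gb)); pts_gb <- c(pts_gb, gb)
      acc <- if (is.null(acc)) gb else acc + gb
    }
    per[[i]] <- acc / length(unique(tr$block))
    slopes[i] <- unname(coef(lm(pts_gb ~ log(pts_k)))[2])
  }
  kmax <- max(lengths(per))
  mat <- t(vapply(per, function(v) c(v, rep(NA_real_, kmax - length(v))),
                  numeric(kmax)))
  mean_gb <- colMeans(mat, na.rm = TRUE)
  sem <- apply(mat, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  })
  list(series = data.frame(k = seq_len(kmax), mean_go_bias = mean_gb,
                           sem = sem,
                           smoothed = moving_average(mean_gb, window)),
       slopes = data.frame(participant_id = ids, slope = slopes,
                           stringsAsFactors = FALSE),
       slope_test = safe_t_test(slopes))
}

#' Bias and variance of choice behavior
#'
#' Bias is the mean of `I[a_t = Go] - I[a*_t = Go]` over trials whose
#' optimal action `a*` is defined; positive values mean responding Go more
#' often than optimal. Variance is the mean squared deviation of `I[a_t=Go]`
#' from the participant's own average Go rate over *all* trials, which
#' equals `p(1-p)` for Go rate `p`.
#'
#' @param trials single-participant trial data.frame.
#' @param include_decoy if `FALSE`, decoy trials are dropped before the
#'   variance (the bias never sees undefined-optimal trials). Default `TRUE`:
#'   the variance runs over all trials as defined.
#' @return Named numeric `c(bias = , variance = )`.
#' @export
bias_variance <- function(trials, include_decoy = TRUE) {
  if (!include_decoy)
    trials <- trials[!trials$stimulus %in% c("decoy_lc", "decoy_hc"), ,
                     drop = FALSE]
  if (nrow(trials) == 0) stop_config("no trials")
  is_go <- as.numeric(trials$action == "go")
  ok <- trials$optimal_action != "undefined"
  if (!any(ok)) stop_config("no trials with a defined optimal action")
  bias <- mean(is_go[ok] - as.numeric(trials$optimal_action[ok] == "go"))
  variance <- mean((is_go - mean(is_go))^2)
  c(bias = bias, variance = variance)
}

# t.test that degrades gracefully when the data are constant: a zero-spread,
# zero-difference comparison is reported as t = 0, p = 1 rather than an error.
safe_t_test <- function(x, y = NULL) {
  degenerate <- function() {
    est <- if (is.null(y)) mean(x) else mean(x) - mean(y)
    structure(list(statistic = c(t = if (est == 0) 0 else sign(est) * Inf),
                   parameter = c(df = NA_real_),
                   p.value = if (est == 0) 1 else 0,
                   estimate = est, method = "degenerate t-test"),
              class = "htest")
  }
  tt <- tryCatch(if (is.null(y)) t.test(x) else t.test(x, y),
                 error = function(e) NULL)
  if (is.null(tt) || !is.finite(tt$statistic)) degenerate() else tt
}

cohens_d_pooled <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
             (length(x) + length(y) - 2))
  if (sp == 0) 0 else (mean(x) - mean(y)) / sp
}

#' Group statistics across controllability conditions
#'
#' Computes per-(participant, condition) Go bias, bias and variance and
#' compares the low and high control conditions: Welch two-sample t-tests
#' when each participant saw one condition (between-subjects), paired
#' t-tests when each saw both (within-subject). Cohen's d uses the pooled
#' SD (between) or the SD of the paired differences (within). Optionally
#' correlates each participant's mean adaptive weight with their fitted
#' fixed weight.
#'
#' @param trials multi-participant trial data.frame covering both
#'   conditions.
#' @param weights optional adaptive-model weight timeseries
#'   (`participant_id, trial, w`).
#' @param fits optional [fit_cohort()] data.frame containing fixed-variant
#'   rows with a `w_fixed` column.
#' @return A `pavarb_group_stats` list: `design` (`"between"`/`"paired"`),
#'   `measures` (per participant-condition data.frame), `tests` (one row per
#'   measure: means, t, df, p, cohens_d), and optionally `w_correlation`.
#' @export
group_stats <- function(trials, weights = NULL, fits = NULL) {
  validate_trials(trials)
  key <- unique(trials[, c("participant_id", "condition")])
  per_cond <- table(key$participant_id)
  if (length(unique(trials$condition)) < 2)
    stop_config("group_stats needs both conditions")
  design <- if (all(per_cond == 2)) "paired" else "between"
  rows <- lapply(seq_len(nrow(key)), function(i) {
    tr <- trials[trials$participant_id == key$participant_id[i] &
                 trials$condition == key$condition[i], , drop = FALSE]
    bv <- bias_variance(tr)
    data.frame(participant_id = key$participant_id[i],
               condition = key$condition[i],
               go_bias = go_bias(tr), bias = bv[["bias"]],
               variance = bv[["variance"]], stringsAsFactors = FALSE)
  })
  measures <- do.call(rbind, rows)
  tests <- lapply(c("go_bias", "bias", "variance"), function(m) {
    lc <- measures[measures$condition == "lc", ]
    hc <- measures[measures$condition == "hc", ]
    if (design == "paired") {
      lc <- lc[order(lc$participant_id), ]
      hc <- hc[order(hc$participant_id), ]
      stopifnot(identical(lc$participant_id, hc$participant_id))
      d <- lc[[m]] - hc[[m]]
      tt <- safe_t_test(d)
      cd <- if (sd(d) == 0) 0 else mean(d) / sd(d)
    } else {
      if (nrow(lc) < 2 || nrow(hc) < 2)
        stop_config("each condition group needs at least 2 participants")
      tt <- safe_t_test(lc[[m]], hc[[m]])
      cd <- cohens_d_pooled(lc[[m]], hc[[m]])
    }
    data.frame(measure = m, mean_lc = mean(lc[[m]]), mean_hc = mean(hc[[m]]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, cohens_d = cd, stringsAsFactors = FALSE)
  })
  out <- list(design = design, measures = measures,
              tests = do.call(rbind, tests))
  if (!is.null(weights) && !is.null(fits)) {
    mean_w <- tapply(weights$w, weights$participant_id, mean)
    fx <- fits[fits$variant == "fixed", , drop = FALSE]
    common <- intersect(names(mean_w), fx$participant_id)
    if (length(common) >= 3) {
      out$w_correlation <- cor(mean_w[common],
                               fx$w_fixed[match(common, fx$participant_id)])
    }
  }
  structure(out, class = "pavarb_group_stats")
}

#' @export
print.pavarb_group_stats <- function(x, ...) {
  cat("Group comparison (", x$design, " design, LC vs HC)\n", sep = "")
  tab <- x$tests
  tab[, -1] <- round(tab[, -1], 4)
  print(tab, row.names = FALSE)
  if (!is.null(x$w_correlation))
    cat("cor(mean adaptive w, fitted w_fixed) =",
        round(x$w_correlation, 3), "\n")
  invisible(x)
}
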