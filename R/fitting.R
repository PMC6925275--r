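# Per-participant maximum-likelihood estimation of the adaptive (5 free
# parameters) and fixed (6) arbitration models, with unconstrained
# transforms, seeded multistart, and a BIC/AIC evidence approximation for
# group-level model selection.

# Transform bounds (guard rails after the unconstrained reparametrization):
# beta in (0, 50], eta0 in (0.1, 100], theta0 in [0.01, 0.99], w in [0, 1].
.tr_beta <- function(x) exp(pmin(pmax(x, log(1e-4)), log(50)))
.tr_eta <- function(x) exp(pmin(pmax(x, log(0.1)), log(100)))
.tr_theta <- function(x) 0.01 + 0.98 * plogis(x)
.tr_w <- function(x) plogis(x)

param_names <- function(variant) {
  c("beta", "theta0_u", "eta0_u", "theta0_c", "eta0_c",
    if (variant == "fixed") "w_fixed")
}

transform_params <- function(x, variant) {
  p <- c(beta = .tr_beta(x[1]),
         theta0_u = .tr_theta(x[2]), eta0_u = .tr_eta(x[3]),
         theta0_c = .tr_theta(x[4]), eta0_c = .tr_eta(x[5]))
  if (variant == "fixed") p <- c(p, w_fixed = .tr_w(x[6]))
  p
}

spec_from_params <- function(p, variant, L0 = 0.5) {
  model_spec(variant, beta = p[["beta"]],
             theta0_u = p[["theta0_u"]], eta0_u = p[["eta0_u"]],
             theta0_c = p[["theta0_c"]], eta0_c = p[["eta0_c"]],
             w_fixed = if (variant == "fixed") p[["w_fixed"]], L0 = L0)
}

random_start <- function(variant) {
  x <- c(rnorm(1, 1, 0.7),              # log beta, centered on beta ~ e
         rnorm(1, 0, 1), rnorm(1, 0.7, 0.7),
         rnorm(1, 0, 1), rnorm(1, 0.7, 0.7))
  if (variant == "fixed") x <- c(x, rnorm(1, 0, 1.5))
  x
}

#' Fitting settings
#'
#' @param n_restarts number of seeded random restarts of the optimizer.
#' @param seed base seed for the restart draws.
#' @param evidence `"bic"` (default) or `"aic"` log-evidence approximation.
#' @param maxit maximum BFGS iterations per restart.
#' @param L0 initial log-odds, held fixed (not a free parameter).
#' @return Settings list for [fit_participant()] / [fit_cohort()].
#' @export
fit_settings <- function(n_restarts = 10, seed = 1,
                         evidence = c("bic", "aic"), maxit = 500, L0 = 0.5) {
  list(n_restarts = n_restarts, seed = seed,
       evidence = match.arg(evidence), maxit = maxit, L0 = L0)
}

#' Fit one participant by multistart maximum likelihood
#'
#' Maximizes [session_loglik()] over the model's free parameters using BFGS
#' on an unconstrained reparametrization (log for `beta` and `eta0`, logistic
#' for `theta0` and `w_fixed`), keeping the best of `n_restarts` seeded
#' random starts. Deterministic given the settings seed.
#'
#' @param trials single-participant trial data.frame.
#' @param variant `"adaptive"` or `"fixed"`.
#' @param settings a [fit_settings()] list.
#' @return A `pavarb_fit` list: `participant_id`, `variant`, `params` (named,
#'   natural scale), `loglik`, `n_params`, `n_trials`, `evidence`,
#'   `converged`, `n_restarts_used`.
#' @export
fit_participant <- function(trials, variant = c("adaptive", "fixed"),
                            settings = fit_settings()) {
  variant <- match.arg(variant)
  check_single_session(trials)
  pid <- trials$participant_id[1]
  cd <- trials_to_codes(trials)
  adaptive <- variant == "adaptive"
  negll <- function(x) {
    p <- transform_params(x, variant)
    -arb_session_cpp(cd$stim, cd$action, cd$reward, cd$block,
                     p[["beta"]], p[["theta0_u"]], p[["eta0_u"]],
                     p[["theta0_c"]], p[["eta0_c"]], settings$L0,
                     adaptive, if (adaptive) 0.5 else p[["w_fixed"]])$loglik
  }
  best <- NULL
  n_ok <- 0L
  with_seed(derive_seed(settings$seed, "fit", pid, variant), {
    for (k in seq_len(settings$n_restarts)) {
      x0 <- random_start(variant)
      res <- tryCatch(
        optim(x0, negll, method = "BFGS",
              control = list(maxit = settings$maxit)),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$value)) next
      n_ok <- n_ok + 1L
      if (is.null(best) || res$value < best$value) best <- res
    }
  })
  if (is.null(best)) {
    return(structure(list(participant_id = pid, variant = variant,
                          params = setNames(rep(NA_real_,
                                                length(param_names(variant))),
                                            param_names(variant)),
                          loglik = NA_real_,
                          n_params = length(param_names(variant)),
                          n_trials = nrow(trials), evidence = NA_real_,
                          converged = FALSE, n_restarts_used = 0L),
                     class = "pavarb_fit"))
  }
  params <- transform_params(best$par, variant)
  fit <- structure(list(participant_id = pid, variant = variant,
                        params = params, loglik = -best$value,
                        n_params = length(params), n_trials = nrow(trials),
                        evidence = NA_real_, converged = TRUE,
                        n_restarts_used = n_ok),
                   class = "pavarb_fit")
  if (fit$n_trials >= 2)
    fit$evidence <- log_evidence(fit, type = settings$evidence)
  fit
}

#' Approximate log model evidence of a fit
#'
#' BIC convention (default): `loglik - n_params/2 * log(n_trials)`;
#' AIC alternative: `loglik - n_params`. Used as per-subject input to
#' random-effects Bayesian model selection ([bms()]).
#'
#' @param fit a `pavarb_fit`.
#' @param type `"bic"` or `"aic"`.
#' @return Scalar approximate log evidence (`<= loglik` for `n_trials > 1`).
#' @export
log_evidence <- function(fit, type = c("bic", "aic")) {
  type <- match.arg(type)
  if (!isTRUE(fit$converged)) stop_config("fit did not converge")
  if (fit$n_trials < 2) stop_config("evidence needs at least 2 trials")
  if (type == "bic") fit$loglik - fit$n_params / 2 * log(fit$n_trials)
  else fit$loglik - fit$n_params
}

fit_to_row <- function(fit) {
  p <- as.list(fit$params)
  data.frame(participant_id = fit$participant_id, variant = fit$variant,
             beta = p$beta %||% NA_real_,
             theta0_u = p$theta0_u %||% NA_real_,
             eta0_u = p$eta0_u %||% NA_real_,
             theta0_c = p$theta0_c %||% NA_real_,
             eta0_c = p$eta0_c %||% NA_real_,
             w_fixed = p$w_fixed %||% NA_real_,
             loglik = fit$loglik, evidence = fit$evidence,
             n_params = fit$n_params, n_trials = fit$n_trials,
             converged = fit$converged, stringsAsFactors = FALSE)
}

#' Fit every participant under one or more model variants
#'
#' Per-participant seeds are derived from the settings seed and the
#' participant id, so results are independent of participant order.
#' Participants with zero trials are skipped with a warning.
#'
#' @param trials multi-participant trial data.frame.
#' @param variants character vector of variants to fit.
#' @param settings a [fit_settings()] list.
#' @return data.frame with one row per (participant, variant), columns
#'   `participant_id, variant, beta, theta0_u, eta0_u, theta0_c, eta0_c,
#'   w_fixed, loglik, evidence, n_params, n_trials, converged`.
#' @export
fit_cohort <- function(trials, variants = c("adaptive", "fixed"),
                       settings = fit_settings()) {
  ids <- unique(trials$participant_id)
  rows <- list()
  for (pid in ids) {
    tr <- trials[trials$participant_id == pid, , drop = FALSE]
    tr <- tr[order(tr$trial), , drop = FALSE]
    if (nrow(tr) == 0) {
      warning(sprintf("participant %s has no trials; skipped", pid))
      next
    }
    for (v in variants) {
      rows[[length(rows) + 1]] <- fit_to_row(fit_participant(tr, v, settings))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build evidence matrix from cohort fits
#'
#' @param fits data.frame from [fit_cohort()].
#' @return participants x models matrix of log evidences, rownames
#'   participant ids, colnames variants.
#' @export
evidence_matrix <- function(fits) {
  ids <- sort(unique(fits$participant_id))
  variants <- sort(unique(fits$variant))
  m <- matrix(NA_real_, length(ids), length(variants),
              dimnames = list(ids, variants))
  for (i in seq_len(nrow(fits)))
    m[fits$participant_id[i], fits$variant[i]] <- fits$evidence[i]
  if (anyNA(m))
    stop_config("missing or non-finite evidence for participant %s",
                ids[which(rowSums(is.na(m)) > 0)[1]])
  m
}
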