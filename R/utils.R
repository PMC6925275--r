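#' @useDynLib pavarb, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim plogis qlogis quantile rbinom runif rnorm rgamma
#'   pbeta sd var cor t.test lm coef setNames
#' @importFrom utils read.csv write.csv
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state so that library code never perturbs the user's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a deterministic sub-stream seed
#'
#' Hashes a base seed together with one or more labels (stage names,
#' participant ids, block indices) into a new 31-bit seed. Adding a new
#' stage with its own label never perturbs the streams of existing stages.
#'
#' @param seed integer base seed.
#' @param ... labels (coerced to character) identifying the sub-stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate", "p01")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (lab in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 131 + code) %% m
    }
    h <- (h * 131 + 7) %% m
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
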