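# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded package functions never perturb the
#' caller's random number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# z-score within subgroups; a zero-variance subgroup contributes zeros so a
# degenerate covariate simply carries no effect (documented generator rule).
group_zscore <- function(x, group) {
  out <- numeric(length(x))
  for (g in unique(group)) {
    i <- group == g
    s <- stats::sd(x[i])
    out[i] <- if (is.na(s) || s == 0) 0 else (x[i] - mean(x[i])) / s
  }
  out
}

assert_prob_vector <- function(p, field) {
  if (any(!is.finite(p)) || any(p < 0))
    stop(sprintf("invalid sim_spec field '%s': probabilities must be finite and non-negative", field),
         call. = FALSE)
  if (abs(sum(p) - 1) > 1e-12)
    stop(sprintf("invalid sim_spec field '%s': probabilities must sum to 1 (got %.15f)", field, sum(p)),
         call. = FALSE)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
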