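#' @keywords internal
"_PACKAGE"

# Condition helpers: every user-facing contract violation raises a classed
# error so callers (and tests) can discriminate failure modes.
bs_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "biosumm_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

bs_invalid <- function(msg) bs_error("biosumm_invalid_parameter", msg)
bs_empty <- function(msg) bs_error("biosumm_empty_input", msg)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded package internals never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Cosine similarity; zero vectors contribute 0 by convention.
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Half-up rounding (round(2.5) -> 3), independent of IEC 60559 banker's
# rounding, so sentence budgets are stable across platforms.
round_half_up <- function(x) floor(x + 0.5)
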