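#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds R's generator, evaluates `expr`, and
#' restores the previous state on exit. All stochastic code in the package
#' funnels through this so that a single integer seed makes a whole run
#' reproducible.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit signed range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12345L) %% 2147483629)
}

abort_ht <- function(msg, class) {
  stop(structure(class = c(class, "handtrack_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
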