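#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_songeval <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "songeval_error")))
}

assert_that <- function(ok, msg, class = "songeval_validation_error") {
  if (!isTRUE(ok)) stop_songeval(msg, class)
  invisible(TRUE)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals never perturb user-level random streams.
#' A `NULL` seed evaluates `expr` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Percentile with an explicit convention.  "linear" is the classic
# interpolate-between-closest-ranks estimate (quantile type 7);
# "nearest_rank" is the ceiling(p*n) order statistic (type 1).
percentile <- function(x, p, method = c("linear", "nearest_rank")) {
  method <- match.arg(method)
  type <- if (method == "linear") 7L else 1L
  unname(stats::quantile(x, probs = p, type = type, names = FALSE))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == floor(x)

# Spearman rank correlation without the cor.test machinery (ties allowed).
spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}
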