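# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Seeded operations must not perturb the global
# stream; everything stochastic in the package funnels through here.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# Stable per-stage seed derived from a global seed and a stage name, so that
# adding a stage never perturbs another stage's draws. Kept below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

stop_param <- function(...) {
  stop(structure(class = c("phowaves_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_param(name, " must not be NULL")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(name, " must be a finite numeric scalar")
  if (x < lower || x > upper)
    stop_param(name, " must be in [", lower, ", ", upper, "]")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
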