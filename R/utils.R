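#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed without touching the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

not_evaluable <- function(msg) {
  structure(class = c("ith_not_evaluable", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

stop_not_evaluable <- function(msg) stop(not_evaluable(msg))

# NA-tolerant wrapper: not-evaluable conditions become NA, real errors propagate
eval_or_na <- function(expr) {
  tryCatch(expr, ith_not_evaluable = function(e) NA_real_)
}
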