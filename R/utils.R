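# Internal helpers shared across modules.

# Run `expr` under a local RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

abort_param <- function(msg, class = "crossproteo_param_error") {
  rlang::abort(msg, class = class)
}

abort_validation <- function(msg, class = "crossproteo_validation_error") {
  rlang::abort(msg, class = class)
}

# round-half-up to integer percent (printed convention: 689/777 -> 89)
percent_int <- function(num, den) {
  if (den == 0) return(NA_real_)
  floor(100 * num / den + 0.5)
}
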