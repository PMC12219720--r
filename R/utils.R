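# Internal helpers shared across modules.

#' Derive a component sub-seed from the master seed
#'
#' Every stochastic generator in the package consumes a sub-seed obtained from
#' the single integer master seed by a fixed scheme, so that components can be
#' regenerated independently yet the whole scenario is a pure function of one
#' seed. The scheme is `(master + 10007 * index) mod (2^31 - 1)`, with `index`
#' a small fixed per-component offset.
#'
#' @param master integer master seed.
#' @param index non-negative integer component offset.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
sub_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(index))
  as.integer((as.double(master) + 10007 * as.double(index)) %% (2^31 - 1))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Population (divide-by-n) variance; NA-free input expected.
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
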