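#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the previous global RNG
#' state afterwards, so seeded helpers do not perturb the caller's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible substream seed
#'
#' One master seed drives a whole simulated screen; per-plate (and
#' per-replicate) streams are derived by a documented counter scheme so any
#' single plate can be regenerated in isolation:
#' `seed_k = (master * 48271 + k) mod (2^31 - 1)`, with `k` a small
#' non-negative counter (e.g. `(rep - 1) * n_plates + plate`). The multiplier
#' is the classical MINSTD constant; all arithmetic stays exact in doubles
#' and the result always fits a 32-bit R integer.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer counter.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), all(index >= 0))
  m <- 2147483647
  as.integer(((master %% m) * 48271 + index) %% m)
}
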