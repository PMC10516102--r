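# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Derive a stage seed from a master seed
#'
#' Every stochastic pipeline stage draws its seed deterministically from the
#' master seed and the stage name, so stages can be re-run in isolation and
#' whole runs are reproducible. Stays below 2^31.
#'
#' @param master integer master seed.
#' @param stage stage name (character).
#' @return a single integer seed.
#' @export
deriveSeed <- function(master, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1977326743
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647L)
}

# Interior (non-NA, non-zero) cells of a mask raster, as a logical matrix.
maskInterior <- function(mask) {
  v <- mask@values
  !is.na(v) & v != 0
}
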