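`%||%` <- function(x, y) if (is.null(x)) y else x

# machine epsilon used inside logarithms of texture formulas
.EPS <- 2.220446e-16

# run code with a local RNG state derived from a seed, restoring afterwards
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}
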