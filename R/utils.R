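## Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Clamp numeric values into [lo, hi].
clampNum <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopfmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnfmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Empty detections / annotations prototypes keep rbind() well-typed.
emptyDetections <- function() {
  data.frame(label = character(), L = double(), T = double(),
             R = double(), B = double(), score = double(),
             stringsAsFactors = FALSE)
}

emptyToothBoxes <- function() {
  data.frame(tooth = integer(), L = double(), T = double(),
             R = double(), B = double(), stringsAsFactors = FALSE)
}
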