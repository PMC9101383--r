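# Shared helpers: classed conditions, decibel conversions, seeded RNG scopes.

ssm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "soundscapemap_error")))
}

ssm_warn <- function(msg, class = "soundscapemap_warning") {
  warning(warningCondition(msg, class = c(class, "soundscapemap_warning")))
}

#' Convert linear amplitude to decibels
#'
#' @param x Linear amplitude (magnitude), non-negative.
#' @param ref Reference amplitude; `x = ref` maps to 0 dB.
#' @return `20 * log10(x / ref)`.
#' @export
amp_to_db <- function(x, ref = 1) 20 * log10(x / ref)

#' Convert a dBFS level to linear amplitude
#'
#' @param db Level in dB relative to full scale (0 dBFS = amplitude 1).
#' @return Linear amplitude `10^(db / 20)`.
#' @export
dbfs_to_amp <- function(db) 10^(db / 20)

#' Root-mean-square amplitude
#'
#' @param x Numeric vector of samples.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) sqrt(mean(x^2))

# Evaluate `expr` under a local RNG state seeded with `seed` (NULL = use the
# current stream). Restores the caller's RNG state afterwards so library code
# never perturbs user-level reproducibility.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

`%||%` <- function(a, b) if (is.null(a)) b else a
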