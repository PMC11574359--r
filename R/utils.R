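# Internal helpers: seeding and input checks.

# Boltzmann constant, J/K (SI exact).
.kB <- 1.380649e-23

#' Derive a reproducible substream seed
#'
#' All stochastic stages of the pipeline draw their seed from a single master
#' seed through this deterministic hash, so that individual stages (population
#' sampling, labelling, detection, track simulation, vesiculation) are
#' independently reproducible. The result is always a valid 32-bit integer
#' seed.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @param index Optional integer index (e.g. replicate number).
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, "tracks")
#' derive_seed(1, "tracks", index = 2)
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.double(seed)) * 48271 + h * 10007 + as.double(index) * 7919) %%
    2147483647)
}

# Run `expr` under `seed` (when non-NULL) without disturbing the caller's RNG
# state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}
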