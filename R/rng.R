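#' Derive a reproducible substream seed from a root seed
#'
#' Splits one root seed into independent, reproducible substream seeds by a
#' counter-based Lehmer mixing scheme. The same `(root_seed, index, purpose)`
#' triple always yields the same seed, so every trajectory (and every
#' per-sample perturbation draw) can be regenerated in isolation, independent
#' of the order in which samples are evaluated or batched.
#'
#' @param root_seed Integer root seed for a whole run.
#' @param index Non-negative integer counter (e.g. the sample index).
#' @param purpose Small integer separating different uses of the same counter
#'   (0 = trajectory noise, 1 = perturbation draw, ...).
#' @return An integer seed in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' rng_substream(42, 0)
#' rng_substream(42, 1)
#' @export
rng_substream <- function(root_seed, index, purpose = 0L) {
  m <- 2147483647 # 2^31 - 1; all arithmetic stays exact in doubles
  a <- 48271
  s <- (abs(as.numeric(root_seed)) %% (m - 1)) + 1
  for (k in c(as.numeric(index), as.numeric(purpose), 1)) {
    s <- ((s + (abs(k) %% (m - 1))) %% (m - 1)) + 1
    s <- (a * s) %% m
    s <- (a * s) %% m
    s <- (a * s) %% m
  }
  as.integer(s)
}

#' Reproducible random-number stream handle
#'
#' Returns a self-contained generator handle whose draws are a deterministic
#' function of `(root_seed, stream_index)` and do not disturb (nor depend on)
#' the global random state. Streams with different indices are effectively
#' independent.
#'
#' @inheritParams rng_substream
#' @param stream_index Non-negative integer identifying the stream.
#' @return An object of class `sdemc_rng` with function elements `runif(n)`,
#'   `rnorm(n, mean, sd)` and `sample_int(n, size)`.
#' @examples
#' s <- rng_stream(42, 0)
#' s$runif(3)
#' @export
rng_stream <- function(root_seed, stream_index) {
  seed <- rng_substream(root_seed, stream_index)
  state <- local({
    old <- get0(".Random.seed", globalenv())
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
    st
  })
  draw <- function(fn) {
    function(...) {
      old <- get0(".Random.seed", globalenv())
      assign(".Random.seed", state, globalenv())
      out <- fn(...)
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, globalenv())
      }
      out
    }
  }
  structure(
    list(
      seed = seed,
      runif = draw(stats::runif),
      rnorm = draw(stats::rnorm),
      sample_int = draw(function(n, size) sample.int(n, size))
    ),
    class = "sdemc_rng"
  )
}

# Evaluate `code` under `seed` and restore the caller's random state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
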