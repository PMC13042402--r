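# internal: run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# internal: softplus, numerically stable for large arguments
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

# internal: stopifnot with a friendlier message
check_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
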