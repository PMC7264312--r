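# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the RNG stream untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Normal draws truncated to [lower, upper] by rejection; sd = 0 degenerates
# to the mean. Used for anthropometrics and per-stage EE targets.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower <= upper)
  if (sd == 0) {
    return(rep(mean, n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

check_number <- function(x, what, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite and numeric.", what))
  }
  bad <- if (allow_zero) x < min else x <= min
  if (any(bad)) {
    abort(sprintf("`%s` must be %s %s.", what,
                  if (allow_zero) ">=" else ">", format(min)))
  }
  invisible(x)
}
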