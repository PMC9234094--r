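# Internal helpers shared across modules.

# Round half away from zero at `digits` decimals (base round() is half-even,
# which disagrees with how surveillance tables are usually typeset).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a locally seeded, fully specified RNG, restoring the
# caller's RNG state afterwards. Pinning kind/normal/sample keeps output
# byte-identical across R versions and sessions.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

check_probability <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`", name, "` must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
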