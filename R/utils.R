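#' @keywords internal
"_PACKAGE"

# Evaluate expr under a temporary RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a distinct child seed from a base seed (kept inside 32-bit range).
child_seed <- function(seed, k) {
  (as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647
}
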