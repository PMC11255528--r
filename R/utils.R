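# Evaluate code under a given seed, restoring the caller's RNG state.
# seed = NULL evaluates in the current RNG stream.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

fmt_date <- function(d) {
  out <- format(d, "%Y-%m-%d")
  out[is.na(d)] <- ""
  out
}
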