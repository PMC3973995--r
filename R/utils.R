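# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed (if any) is restored afterwards, so library calls never
# perturb user-level randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# substr on 0-based half-open [start, end) offsets, the package's native
# span convention.
slice_span <- function(text, start, end) {
  substr(text, start + 1L, end)
}

# rbind a list of data.frames that may be empty/NULL; returns `proto`
# (a zero-row data.frame) when nothing remains.
rbind_df <- function(lst, proto = NULL) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0L, lst)
  if (length(lst) == 0L) {
    return(proto)
  }
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two half-open spans overlap iff each starts before the other ends.
spans_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

new_df <- function(...) data.frame(..., stringsAsFactors = FALSE)
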