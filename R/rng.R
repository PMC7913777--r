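# Reproducible noise streams. One user-facing seed drives all noise draws
# through L'Ecuyer-CMRG substreams indexed by a counter, so the draws for
# scan k do not change when scans are added before or after it.

#' @noRd
with_substream_noise <- function(seed, stream, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(stream)) s <- parallel::nextRNGSubStream(s)
  assign(".Random.seed", s, envir = globalenv())
  stats::rnorm(n)
}
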