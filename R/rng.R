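#' Derive a reproducible substream seed
#'
#' All stochastic stages of a run (genome build, historical phase, recent
#' phase, trait sampling, phenotype noise) draw their own seed from one
#' master seed plus a stage label, so any stage can be replayed in
#' isolation and replicates never share streams.
#'
#' @param master integer master seed.
#' @param label character stage label, e.g. `"historical"`.
#' @param replicate optional replicate index folded into the stream.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, label, replicate = 0L) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  x <- (as.numeric(master) %% 2147483647) * 48271 +
    h * 7919 + as.numeric(replicate) * 104729
  as.integer(x %% 2147483647)
}

with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}
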