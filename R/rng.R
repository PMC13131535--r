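#' Derive a named RNG stream seed from a master seed
#'
#' One master seed fans out to independent named streams (build, stimulus,
#' pools, optimizer, targets) so each component of a run is reproducible in
#' isolation.  The derived seed is a deterministic 31-bit hash of the master
#' seed and the stream name.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
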