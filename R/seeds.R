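#' Derive a reproducible child seed from a master seed
#'
#' Integer mixing used everywhere a substream is needed (per-subject,
#' per-session, per-split, per-backend), so that datasets and grid runs are
#' reproducible from a single master seed and insertion-order independent.
#' The mix is done in double precision (exact below 2^53) and reduced mod
#' 2^31 - 1 so the result is always a valid 32-bit seed.
#'
#' @param master integer master seed.
#' @param ... further integer indices identifying the substream.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- (as.double(master) %% 2147483647) + 1
  mults <- c(40503, 9973, 69069, 33797, 30269)
  for (i in seq_along(idx)) {
    m <- mults[((i - 1) %% length(mults)) + 1]
    h <- (h * 48271 + (as.double(idx[i]) + 1) * m) %% 2147483647
    h <- (h * 16807 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

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
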