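#' Mean Earth radius (km) used throughout
#'
#' Fixed at the IUGG mean radius 6371.0088 km so that haversine distances and
#' the equal-area projection are reproducible across platforms.
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

#' Derive a reproducible sub-stream seed
#'
#' Maps a master seed and a stage label to a deterministic 32-bit integer so
#' that every stochastic stage of a run draws from its own stream. Changing
#' the label decorrelates streams; the same (seed, label) pair always yields
#' the same sub-seed.
#'
#' @param seed integer master seed.
#' @param label character stage label.
#' @return a single integer in `[1, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "world") != derive_seed(1, "occurrences")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 1000003
  as.integer(((abs(seed) %% 1046527) * 2053 + h * 97) %% 2147483629 + 1)
}

# first element or default
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf formatting, no call in message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# condensed lower-triangle vector of a symmetric matrix / dist input
condensed <- function(d) {
  m <- as.matrix(d)
  m[lower.tri(m)]
}
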