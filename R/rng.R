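#' Counter-based uniform random generator
#'
#' A pure, stateless generator in the Random123 family: the value is a fixed
#' avalanche mixing function (Threefry-2x64 structure, two 4-round
#' add-xor-rotate blocks) of a 128-bit key and a 64-bit counter. Identical
#' `(key, counter)` always give the identical value, so random streams can be
#' keyed per `(seed, gid, purpose)` and are independent of cell-group
#' partitioning, call order, and checkpoint boundaries.
#'
#' @param key integer vector of length 4 (the stream identity).
#' @param counter non-negative whole number(s); vectorized.
#' @return numeric vector in `[0, 1)`, same length as `counter`.
#' @examples
#' counter_rng(c(1L, 2L, 3L, 4L), 0:4)
#' @export
counter_rng <- function(key, counter) {
  key <- as.integer(key)
  if (length(key) != 4 || anyNA(key))
    nc_stop("nc_parameter_error", "counter_rng: key must be 4 integers")
  counter_rng_cpp(key, as.numeric(counter))
}

# Stream keys: (seed, gid, purpose, salt). Purpose codes keep streams for
# different uses of the same cell disjoint.
.nc_purpose <- c(netstim = 11L, branching = 23L)

make_stream_key <- function(seed, gid, purpose) {
  p <- .nc_purpose[[purpose]]
  c(as.integer(seed), as.integer(gid), p, 1013904223L)
}
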