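# Centralized coordinate conversions.
#
# Convention used throughout the package:
#   * point features (SNPs, CpGs) carry 1-based positions `pos`;
#   * interval tracks (BED) are 0-based half-open [start, end) internally.
# A 1-based point p corresponds to the half-open interval [p - 1, p).

#' Convert a 1-based point position to a 0-based half-open interval
#'
#' @param pos Integer vector of 1-based positions.
#' @return A two-column matrix (`start`, `end`) with `end = start + 1`.
#' @export
pos1_to_bed0 <- function(pos) {
  pos <- as.integer(pos)
  if (any(pos < 1L, na.rm = TRUE)) mk_stop("1-based positions must be >= 1")
  cbind(start = pos - 1L, end = pos)
}

#' Convert a single-base 0-based half-open interval back to a 1-based point
#'
#' @param start,end Integer vectors with `end == start + 1`.
#' @return Integer vector of 1-based positions.
#' @export
bed0_to_pos1 <- function(start, end) {
  if (any(end - start != 1L)) mk_stop("not single-base intervals")
  as.integer(start) + 1L
}

# Does the 1-based point pos fall inside the 0-based half-open [start, end)?
point_in_bed0 <- function(pos, start, end) {
  p0 <- pos - 1L
  p0 >= start & p0 < end
}
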