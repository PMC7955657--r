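#' Jaccard distance between sequence intervals
#'
#' Distance between two regions of the same sequence, defined as
#' `1 - |a intersect b| / |a union b|` where `|.|` counts residues and
#' intervals are 1-based and inclusive. The union of two disjoint intervals
#' counts only residues inside either interval, never the gap between them,
#' so the distance is exactly 1 when the intervals share no residue and 0
#' when they coincide. It is a metric (the Jaccard distance on residue sets).
#'
#' All arguments are vectorized and recycled.
#'
#' @param a_start,a_end,b_start,b_end Interval endpoints (1-based, inclusive,
#'   `start <= end`).
#' @param a_seq,b_seq Optional sequence identifiers; if both are given they
#'   must match element-wise (regions on different sequences are not
#'   comparable).
#' @return Numeric vector of distances in `[0, 1]`.
#' @export
#' @examples
#' region_distance(1, 100, 1, 100)    # 0
#' region_distance(1, 100, 200, 300)  # 1
#' region_distance(1, 100, 51, 150)   # 1 - 50/150
region_distance <- function(a_start, a_end, b_start, b_end,
                            a_seq = NULL, b_seq = NULL) {
  if (!is.null(a_seq) && !is.null(b_seq) && any(a_seq != b_seq))
    stop("region_distance(): regions lie on different sequences")
  if (any(a_start < 1L) || any(b_start < 1L) ||
      any(a_end < a_start) || any(b_end < b_start))
    stop("region_distance(): invalid interval (need 1 <= start <= end)")
  la <- a_end - a_start + 1
  lb <- b_end - b_start + 1
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
  1 - inter / (la + lb - inter)
}

## Number of residues shared by two intervals (vectorized; 0 if disjoint).
interval_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
}

## Full pairwise distance matrix for one set of intervals on one sequence.
## O(n^2) memory; intended for per-query sets (hundreds of alignments).
pairwise_region_distance <- function(s, e) {
  n <- length(s)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  S <- matrix(s, n, n)
  E <- matrix(e, n, n)
  inter <- pmin(E, t(E)) - pmax(S, t(S)) + 1
  inter[inter < 0] <- 0
  len <- e - s + 1
  uni <- outer(len, len, "+") - inter
  1 - inter / uni
}
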