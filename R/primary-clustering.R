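#' Local densities of alignments on one query
#'
#' The density of an alignment is the number of alignments of the same query
#' (itself included, so densities are at least 1) whose query regions lie at
#' Jaccard distance strictly below `mu1`.
#'
#' @param aln Alignment table for one query, already deduplicated with
#'   [dedup_same_search()].
#' @param mu1 Density radius in `(0, 1)`.
#' @return Integer vector of densities, parallel to the rows of `aln`.
#' @export
local_densities <- function(aln, mu1 = 0.2) {
  D <- pairwise_region_distance(aln$qstart, aln$qend)
  as.integer(rowSums(D < mu1))
}

## delta_i = min distance to a denser point, with density ties resolved by
## rank order: points are ordered by (density desc, input index asc) and
## delta is the minimum distance to any point earlier in that order. The
## first point (the designated density maximum) gets delta = 1, the
## metric's maximum. For distinct densities this is exactly the minimum
## distance to a strictly denser point; for tied densities it designates
## one representative per co-located group instead of letting every tied
## point claim delta = 1.
dpc_delta <- function(D, rho) {
  n <- length(rho)
  delta <- numeric(n)
  if (n == 0L) return(delta)
  ord <- order(-rho, seq_len(n))
  delta[ord[1L]] <- 1
  if (n == 1L) return(delta)
  for (k in 2:n) {
    i <- ord[k]
    delta[i] <- min(D[i, ord[seq_len(k - 1L)]])
  }
  delta
}

#' Score and rank alignments by gamma = rho * delta
#'
#' Computes, for every alignment of a query, the DPC separation `delta`
#' (minimum query-region distance to any denser alignment, density ties
#' resolved by rank order; 1 for the density maximum) and the peak score
#' `gamma = rho * delta`, and returns the scores together with the
#' decreasing-gamma ranking.
#'
#' @param aln Alignment table for one query (deduplicated).
#' @param rho Densities from [local_densities()]; computed if missing.
#' @param mu1 Density radius, used only when `rho` is missing.
#' @return A `data.table` with one row per alignment (input order) and
#'   columns `rho`, `delta`, `gamma`, `rank` (1 = highest gamma; ties broken
#'   by input order).
#' @export
gamma_ranking <- function(aln, rho = NULL, mu1 = 0.2) {
  D <- pairwise_region_distance(aln$qstart, aln$qend)
  if (is.null(rho)) rho <- as.integer(rowSums(D < mu1))
  delta <- dpc_delta(D, rho)
  gamma <- rho * delta
  ord <- order(-gamma, seq_along(gamma))
  rank <- integer(length(gamma))
  rank[ord] <- seq_along(ord)
  data.table::data.table(rho = rho, delta = delta, gamma = gamma, rank = rank)
}

#' Select density peaks by the gamma-gap rule
#'
#' Scans the ranked gamma sequence for multiplicative gaps of at least
#' `10^delta_exp` between consecutive values. Zero-gamma entries (points
#' co-located with a denser point) can never be peaks and are excluded from
#' the ratio scan. Let `g` be the last gap position among the non-zero
#' entries: if `g <= g_max`, the `g - 1` alignments ranked above the gap are
#' the peaks; if the last gap falls beyond `g_max`, or no ratio reaches the
#' threshold, no peaks are returned. As a degenerate-data fallback, when no
#' finite ratio reaches the threshold but the gamma sequence collapses
#' exactly to zero after its first `K <= g_max - 1` entries, the drop to
#' zero is itself treated as the gap and all `K` non-zero entries become
#' peaks (an infinite ratio trivially exceeds any threshold).
#'
#' @param gamma_sorted Numeric vector of gamma values sorted decreasingly.
#' @param delta_exp Gap exponent (threshold ratio is `10^delta_exp`).
#' @param g_max Maximum admissible gap index.
#' @return Number of peaks (0 when the query is to be skipped); the peaks
#'   are the first `k` entries of the ranked sequence.
#' @export
select_gap_peaks <- function(gamma_sorted, delta_exp = 0.5, g_max = 20L) {
  if (is.unsorted(rev(gamma_sorted))) gamma_sorted <- sort(gamma_sorted, decreasing = TRUE)
  nz <- gamma_sorted[gamma_sorted > 0]
  K <- length(nz)
  if (K == 0L) return(0L)
  had_zero <- length(gamma_sorted) > K
  thr <- 10^delta_exp
  if (K >= 2L) {
    ratios <- nz[-K] / nz[-1L]          # ratios[s-1] = gamma_{s-1}/gamma_s
    qual <- which(ratios >= thr) + 1L   # gap positions s in 2..K
  } else {
    qual <- integer(0)
  }
  if (length(qual)) {
    g <- max(qual)
    if (g > g_max) return(0L)
    return(g - 1L)
  }
  if (had_zero && K + 1L <= g_max) return(K)
  0L
}

#' Assign alignments to primary-cluster peaks
#'
#' Every alignment joins the nearest peak provided the query-region distance
#' to it is strictly below `mu1`; alignments at distance `>= mu1` from every
#' peak are discarded. Ties on the nearest distance are broken in favour of
#' the higher-ranked (larger gamma) peak. Each peak belongs to its own
#' cluster (distance 0 to itself).
#'
#' @param aln Alignment table for one query (deduplicated).
#' @param peak_idx Row indices of the peaks in `aln`, ordered by decreasing
#'   gamma (rank order).
#' @param mu1 Assignment radius.
#' @return Integer vector, parallel to the rows of `aln`: the 1-based index
#'   into `peak_idx` of the assigned peak, or `NA` for discarded alignments.
#' @export
assign_primary <- function(aln, peak_idx, mu1 = 0.2) {
  n <- nrow(aln)
  if (length(peak_idx) == 0L) return(rep(NA_integer_, n))
  Dp <- vapply(peak_idx, function(p)
    region_distance(aln$qstart, aln$qend,
                    aln$qstart[p], aln$qend[p]),
    numeric(n))
  Dp <- matrix(Dp, nrow = n)
  nearest <- apply(Dp, 1L, which.min)       # first minimum = highest-ranked
  dmin <- Dp[cbind(seq_len(n), nearest)]
  ifelse(dmin < mu1, as.integer(nearest), NA_integer_)
}

#' Primary clustering of an alignment table
#'
#' Runs, independently for every query: same-search-sequence deduplication,
#' density estimation, gamma ranking, gamma-gap peak selection and
#' nearest-peak assignment. Queries for which the gap rule finds no peaks
#' contribute no clusters (they are skipped, not errors).
#'
#' @param aln Alignment table (all queries) as from [read_alignment_table()].
#' @param params [clustering_params()] list.
#' @return A `data.table` of primary-cluster members, one row per clustered
#'   alignment: `cluster_id` (globally unique integer), `query_id`,
#'   `peak_rank` (gamma rank of the cluster's peak within its query), `peak`
#'   (logical: is this row the peak alignment), plus the alignment columns
#'   `aln_id`, `search_id`, `qstart`, `qend`, `sstart`, `send`, `evalue`.
#' @export
primary_clustering <- function(aln, params = clustering_params()) {
  queries <- group_by_query(aln)
  out <- vector("list", length(queries))
  next_id <- 1L
  for (qi in seq_along(queries)) {
    q <- dedup_same_search(queries[[qi]], params$mu1)
    if (nrow(q) == 0L) next
    D <- pairwise_region_distance(q$qstart, q$qend)
    rho <- as.integer(rowSums(D < params$mu1))
    delta <- dpc_delta(D, rho)
    gamma <- rho * delta
    ord <- order(-gamma, seq_along(gamma))
    k <- select_gap_peaks(gamma[ord], params$delta_exp, params$g_max)
    if (k == 0L) next
    peak_idx <- ord[seq_len(k)]
    Dp <- D[, peak_idx, drop = FALSE]
    nearest <- apply(Dp, 1L, which.min)
    dmin <- Dp[cbind(seq_len(nrow(q)), nearest)]
    assigned <- which(dmin < params$mu1)
    if (length(assigned) == 0L) next
    memb <- q[assigned]
    local_cluster <- nearest[assigned]
    memb[, cluster_id := next_id + local_cluster - 1L]
    memb[, peak_rank := local_cluster]
    ## the peak row of a cluster is the row that is its own nearest peak
    memb[, peak := assigned == peak_idx[local_cluster]]
    next_id <- next_id + k
    out[[qi]] <- memb
  }
  res <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(res) == 0L)
    return(data.table::data.table(cluster_id = integer(), query_id = character(),
                                  peak_rank = integer(), peak = logical(),
                                  aln_id = integer(), search_id = character(),
                                  qstart = integer(), qend = integer(),
                                  sstart = integer(), send = integer(),
                                  evalue = numeric()))
  ## drop empty clusters' ids are impossible (a peak always self-assigns);
  ## renumber densely for downstream convenience
  res[, cluster_id := match(cluster_id, unique(cluster_id))]
  data.table::setcolorder(res, c("cluster_id", "query_id", "peak_rank", "peak",
                                 "aln_id", "search_id", "qstart", "qend",
                                 "sstart", "send", "evalue"))
  res[]
}
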