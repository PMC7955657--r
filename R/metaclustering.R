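#' Distance between two primary clusters
#'
#' Primary clusters are compared through the search-sequence regions of
#' their member alignments: `D = 1 - M / min(N_c, N_c0)`, where `M` counts
#' one-to-one matched alignment pairs (one from each cluster) that lie on
#' the same search sequence with search-region Jaccard distance below
#' `mu_d`. Each alignment contributes to at most one counted pair; matching
#' is greedy over qualifying pairs sorted by increasing distance (ties by
#' member order), a deterministic approximation of the maximum bipartite
#' matching. The result is symmetric and clamped to `[0, 1]`; it is small
#' when the two clusters share many overlapping search regions.
#'
#' @param c1,c2 Member tables of two primary clusters (rows of the
#'   [primary_clustering()] output for one `cluster_id` each); must be
#'   non-empty.
#' @param mu_d Search-region distance radius.
#' @return The distance, a scalar in `[0, 1]`.
#' @export
primary_cluster_distance <- function(c1, c2, mu_d = 0.2) {
  if (nrow(c1) == 0L || nrow(c2) == 0L)
    stop("primary_cluster_distance(): empty cluster")
  M <- 0L
  shared <- intersect(unique(c1$search_id), unique(c2$search_id))
  for (sid in shared) {
    i <- which(c1$search_id == sid)
    j <- which(c2$search_id == sid)
    pairs <- expand.grid(i = i, j = j, KEEP.OUT.ATTRS = FALSE)
    d <- region_distance(c1$sstart[pairs$i], c1$send[pairs$i],
                         c2$sstart[pairs$j], c2$send[pairs$j])
    ok <- d < mu_d
    if (!any(ok)) next
    pairs <- pairs[ok, , drop = FALSE]
    d <- d[ok]
    ord <- order(d, pairs$i, pairs$j)
    used_i <- logical(max(pairs$i)); used_j <- logical(max(pairs$j))
    for (k in ord) {
      pi <- pairs$i[k]; pj <- pairs$j[k]
      if (!used_i[pi] && !used_j[pj]) {
        used_i[pi] <- TRUE; used_j[pj] <- TRUE
        M <- M + 1L
      }
    }
  }
  max(0, min(1, 1 - M / min(nrow(c1), nrow(c2))))
}

## Greedy one-to-one match count for one (cluster pair, search sequence)
## group; `mi`, `mj` are member indices and the rows arrive sorted by
## (distance, mi, mj). Same greedy as primary_cluster_distance().
greedy_match_count <- function(mi, mj) {
  used_i <- unique(mi); used_j <- unique(mj)
  ui <- logical(length(used_i)); uj <- logical(length(used_j))
  ii <- match(mi, used_i); jj <- match(mj, used_j)
  m <- 0L
  for (k in seq_along(ii)) {
    if (!ui[ii[k]] && !uj[jj[k]]) {
      ui[ii[k]] <- TRUE; uj[jj[k]] <- TRUE
      m <- m + 1L
    }
  }
  m
}

## Sparse pairwise distances between all primary clusters.
## Returns dt(ci, cj, D) for ci < cj restricted to pairs with at least one
## matched search region (all absent pairs have D = 1), plus the cluster
## sizes. Cluster indices are positions in sort(unique(cluster_id)).
pc_pair_distances <- function(members, mu_d = 0.2) {
  cl <- sort(unique(members$cluster_id))
  m <- data.table::data.table(
    ci = match(members$cluster_id, cl),
    sid = match(members$search_id, unique(members$search_id)),
    sstart = members$sstart, send = members$send
  )
  m[, midx := seq_len(.N), by = ci]
  Nc <- m[, .N, by = ci][order(ci), N]
  empty <- list(pairs = data.table::data.table(ci = integer(), cj = integer(),
                                               D = numeric()),
                sizes = Nc, cluster_ids = cl)
  setkey(m, sid)
  pairs <- m[m, on = "sid", allow.cartesian = TRUE,
             .(sid, ci = ci, cj = i.ci, mi = midx, mj = i.midx,
               as = sstart, ae = send, bs = i.sstart, be = i.send)]
  pairs <- pairs[ci < cj]
  if (nrow(pairs) == 0L) return(empty)
  pairs[, d := region_distance(as, ae, bs, be)]
  pairs <- pairs[d < mu_d]
  if (nrow(pairs) == 0L) return(empty)
  pairs[, n_pairs := .N, by = .(ci, cj, sid)]
  singles <- pairs[n_pairs == 1L, .(m = .N), by = .(ci, cj)]
  multi <- pairs[n_pairs > 1L]
  if (nrow(multi)) {
    data.table::setorder(multi, ci, cj, sid, d, mi, mj)
    multi_m <- multi[, .(m = greedy_match_count(mi, mj)), by = .(ci, cj, sid)]
    multi_m <- multi_m[, .(m = sum(m)), by = .(ci, cj)]
    Mtab <- data.table::rbindlist(list(singles, multi_m))
    Mtab <- Mtab[, .(m = sum(m)), by = .(ci, cj)]
  } else {
    Mtab <- singles
  }
  Mtab[, D := pmax(0, pmin(1, 1 - m / pmin(Nc[ci], Nc[cj])))]
  list(pairs = Mtab[, .(ci, cj, D)], sizes = Nc, cluster_ids = cl)
}

#' Metacluster density peaks among primary clusters
#'
#' Computes, for every primary cluster, its density `rho_c` (the number of
#' *other* clusters at distance below `mu2`; self excluded) and separation
#' `delta_c` (minimum distance to any denser cluster, density ties resolved
#' by rank order as in the primary round; 1 for the global density
#' maximum). Peaks are the clusters with `delta_c == 1` and `rho_c > 1`:
#' dense clusters with no overlap at all to any denser cluster.
#'
#' @param members Primary-cluster member table from [primary_clustering()].
#' @param params [clustering_params()] list (`mu_d`, `mu2` are used).
#' @param pd Optional precomputed result of the internal sparse pairwise
#'   distance step (for reuse across stages).
#' @return A list with `cluster_ids` (sorted unique ids), `rho`, `delta`
#'   (parallel numeric vectors) and `peaks` (indices into `cluster_ids`,
#'   ordered by decreasing `rho`, ties by index).
#' @export
metacluster_peaks <- function(members, params = clustering_params(), pd = NULL) {
  if (nrow(members) == 0L)
    return(list(cluster_ids = integer(), rho = integer(), delta = numeric(),
                peaks = integer(), pd = NULL))
  if (is.null(pd)) pd <- pc_pair_distances(members, params$mu_d)
  ncl <- length(pd$cluster_ids)
  close_pairs <- pd$pairs[D < params$mu2]
  rho <- tabulate(c(close_pairs$ci, close_pairs$cj), nbins = ncl)
  delta <- dpc_delta_sparse(pd$pairs, rho, ncl)
  peaks <- which(delta == 1 & rho > 1)
  peaks <- peaks[order(-rho[peaks], peaks)]
  list(cluster_ids = pd$cluster_ids, rho = rho, delta = delta,
       peaks = peaks, pd = pd)
}

## delta over a sparse distance list (absent pairs have distance 1), with
## the same rank-order tie resolution as dpc_delta(): delta_c is the
## minimum distance to any cluster earlier in the (rho desc, index asc)
## order, 1 for the first cluster and whenever no earlier cluster shares
## any matched search region.
dpc_delta_sparse <- function(pairs, rho, n) {
  delta <- rep(1, n)
  if (n == 0L) return(delta)
  pos <- integer(n)                      # rank position of each cluster
  ord <- order(-rho, seq_len(n))
  pos[ord] <- seq_len(n)
  if (nrow(pairs)) {
    long <- data.table::data.table(a = c(pairs$ci, pairs$cj),
                                   b = c(pairs$cj, pairs$ci),
                                   D = c(pairs$D, pairs$D))
    earlier <- long[pos[b] < pos[a], .(dmin = min(D)), by = a]
    delta[earlier$a] <- pmin(1, earlier$dmin)
  }
  delta[ord[1L]] <- 1
  delta
}

#' Assign primary clusters to metacluster peaks
#'
#' Every primary cluster joins the nearest peak provided the distance is
#' strictly below `mu2`; clusters at distance `>= mu2` from every peak are
#' discarded. Ties are broken in favour of the denser peak (then the lower
#' cluster index). A peak belongs to its own metacluster.
#'
#' @param members Primary-cluster member table.
#' @param peaks_info Result of [metacluster_peaks()].
#' @param params [clustering_params()] list.
#' @return Integer vector parallel to `peaks_info$cluster_ids`: the index of
#'   the assigned peak within `peaks_info$peaks` (1-based), `NA` for
#'   discarded clusters.
#' @export
assign_to_metaclusters <- function(members, peaks_info,
                                   params = clustering_params()) {
  ncl <- length(peaks_info$cluster_ids)
  assign <- rep(NA_integer_, ncl)
  peaks <- peaks_info$peaks
  if (length(peaks) == 0L) return(assign)
  pairs <- peaks_info$pd$pairs
  long <- data.table::data.table(a = c(pairs$ci, pairs$cj),
                                 b = c(pairs$cj, pairs$ci),
                                 D = c(pairs$D, pairs$D))
  long <- long[b %in% peaks]
  long[, prio := match(b, peaks)]
  data.table::setorder(long, a, D, prio)
  best <- long[!duplicated(a)]
  best <- best[D < params$mu2]
  assign[best$a] <- best$prio
  assign[peaks] <- seq_along(peaks)   # a peak is its own metacluster (D = 0)
  assign
}

#' Merge redundant metaclusters
#'
#' The distance between two metaclusters is the average of the pairwise
#' primary-cluster distances across them (pairs never observed to share a
#' search region count as distance 1). All metacluster pairs with distance
#' below `merge_threshold` are merged transitively (connected components of
#' the below-threshold graph), pooling their primary clusters. Setting
#' `merge_doubled = TRUE` in the parameters uses twice the mean instead.
#'
#' @param assign Assignment vector from [assign_to_metaclusters()].
#' @param peaks_info Result of [metacluster_peaks()].
#' @param params [clustering_params()] list.
#' @return Integer vector like `assign` but with merged metacluster labels
#'   (dense, 1-based, relabelled in decreasing order of metacluster size in
#'   primary clusters).
#' @export
merge_metaclusters <- function(assign, peaks_info,
                               params = clustering_params()) {
  k <- max(c(0L, assign), na.rm = TRUE)
  if (k <= 1L) return(assign)
  pairs <- peaks_info$pd$pairs
  sizes <- tabulate(assign, nbins = k)
  ## cross sums of observed distances per metacluster pair
  pp <- data.table::data.table(ma = assign[pairs$ci], mb = assign[pairs$cj],
                               D = pairs$D)
  pp <- pp[!is.na(ma) & !is.na(mb) & ma != mb]
  if (nrow(pp)) {
    pp[, `:=`(lo = pmin(ma, mb), hi = pmax(ma, mb))]
    agg <- pp[, .(s = sum(D), n = .N), by = .(lo, hi)]
  } else {
    agg <- data.table::data.table(lo = integer(), hi = integer(),
                                  s = numeric(), n = integer())
  }
  grid <- data.table::CJ(lo = seq_len(k), hi = seq_len(k))[lo < hi]
  grid <- agg[grid, on = c("lo", "hi")]
  grid[is.na(s), `:=`(s = 0, n = 0L)]
  grid[, tot := sizes[lo] * sizes[hi]]
  grid <- grid[tot > 0L]
  grid[, dmc := (s + (tot - n)) / tot]
  if (isTRUE(params$merge_doubled)) grid[, dmc := 2 * dmc]
  edges <- grid[dmc < params$merge_threshold]
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges$lo[e]); rb <- find(edges$hi[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  merged <- ifelse(is.na(assign), NA_integer_, roots[assign])
  ## dense relabel by decreasing size (primary-cluster count), ties by root
  tab <- table(factor(merged, levels = sort(unique(roots))))
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  relabel <- integer(max(as.integer(names(tab))))
  relabel[as.integer(names(tab))[ord]] <- seq_along(ord)
  ifelse(is.na(merged), NA_integer_, relabel[merged])
}

#' Metacluster a primary-cluster table
#'
#' Runs the full second DPC round: sparse pairwise primary-cluster
#' distances, density-peak selection, nearest-peak assignment and transitive
#' merging.
#'
#' @param members Primary-cluster member table from [primary_clustering()].
#' @param params [clustering_params()] list.
#' @return A list with `mc_of_cluster` (a `data.table` mapping `cluster_id`
#'   to `mc_id`; discarded clusters are absent), `mc_members` (the
#'   metacluster member table: `mc_id`, `search_id`, `sstart`, `send`,
#'   `query_id`, `cluster_id`, `aln_id`, one row per member alignment),
#'   and the intermediate `rho`, `delta`, `peaks` diagnostics.
#' @export
metacluster <- function(members, params = clustering_params()) {
  pk <- metacluster_peaks(members, params)
  if (length(pk$cluster_ids) == 0L || length(pk$peaks) == 0L) {
    return(list(mc_of_cluster = data.table::data.table(cluster_id = integer(),
                                                       mc_id = integer()),
                mc_members = empty_mc_members(),
                rho = pk$rho, delta = pk$delta, peaks = pk$peaks))
  }
  assign0 <- assign_to_metaclusters(members, pk, params)
  assign <- merge_metaclusters(assign0, pk, params)
  map <- data.table::data.table(cluster_id = pk$cluster_ids, mc_id = assign)
  map <- map[!is.na(mc_id)]
  mc_members <- members[map, on = "cluster_id",
                        .(mc_id = i.mc_id, search_id, sstart, send,
                          query_id, cluster_id, aln_id)]
  data.table::setorder(mc_members, mc_id, cluster_id, aln_id)
  list(mc_of_cluster = map, mc_members = mc_members,
       rho = pk$rho, delta = pk$delta, peaks = pk$peaks)
}

empty_mc_members <- function() {
  data.table::data.table(mc_id = integer(), search_id = character(),
                         sstart = integer(), send = integer(),
                         query_id = character(), cluster_id = integer(),
                         aln_id = integer())
}
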