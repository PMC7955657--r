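#' Clustering parameters
#'
#' Collects every tunable parameter of the two-round clustering pipeline in a
#' single validated list. Defaults are the reference values used throughout
#' the package documentation:
#'
#' * `evalue_max = 0.1` — strict upper bound on alignment E-values at read
#'   time (`evalue < evalue_max` is kept).
#' * `mu1 = 0.2` — neighbourhood radius of the query-interval Jaccard
#'   distance used for primary-cluster densities and assignment.
#' * `delta_exp = 0.5` — the gamma-gap exponent: a drop of at least
#'   `10^delta_exp` between consecutive ranked gamma values marks the
#'   boundary between density peaks and the bulk.
#' * `g_max = 20` — maximum admissible index for the gamma gap, capping the
#'   number of primary clusters per query.
#' * `mu_d = 0.2` — search-interval Jaccard radius used when counting shared
#'   search regions between primary clusters (and when filtering members).
#' * `mu2 = 0.9` — density/assignment radius for the metacluster round.
#' * `merge_threshold = 0.9` — metacluster pairs with average cross-cluster
#'   distance below this are merged (transitively).
#' * `merge_doubled = FALSE` — if `TRUE`, use twice the mean cross distance
#'   (the literal prefactor variant) instead of the plain mean.
#' * `min_size = 100` — metaclusters with fewer member regions are dropped.
#' * `member_cap = 5000` — random subsample cap on members per metacluster.
#' * `member_identity = 0.95`, `seed_identity = 0.60` — greedy
#'   redundancy-reduction identity thresholds for members and seed sets.
#' * `seed_cap = 1000` — cap on seed-set size.
#' * `rng_seed = 1` — seed for every random choice (subsampling).
#'
#' @param evalue_max,mu1,delta_exp,g_max,mu_d,mu2,merge_threshold,merge_doubled,min_size,member_cap,member_identity,seed_identity,seed_cap,rng_seed
#'   See description.
#' @return A named list of class `peakfam_params`.
#' @export
#' @examples
#' p <- clustering_params(mu1 = 0.25)
#' p$mu1
clustering_params <- function(evalue_max = 0.1,
                              mu1 = 0.2,
                              delta_exp = 0.5,
                              g_max = 20L,
                              mu_d = 0.2,
                              mu2 = 0.9,
                              merge_threshold = 0.9,
                              merge_doubled = FALSE,
                              min_size = 100L,
                              member_cap = 5000L,
                              member_identity = 0.95,
                              seed_identity = 0.60,
                              seed_cap = 1000L,
                              rng_seed = 1L) {
  p <- list(evalue_max = evalue_max, mu1 = mu1, delta_exp = delta_exp,
            g_max = as.integer(g_max), mu_d = mu_d, mu2 = mu2,
            merge_threshold = merge_threshold, merge_doubled = merge_doubled,
            min_size = as.integer(min_size),
            member_cap = as.integer(member_cap),
            member_identity = member_identity,
            seed_identity = seed_identity,
            seed_cap = as.integer(seed_cap),
            rng_seed = as.integer(rng_seed))
  stopifnot(p$evalue_max > 0,
            p$mu1 > 0, p$mu1 < 1,
            p$delta_exp > 0,
            p$g_max >= 1L,
            p$mu_d > 0, p$mu_d < 1,
            p$mu2 > 0, p$mu2 <= 1,
            p$merge_threshold > 0, p$merge_threshold <= 1,
            p$min_size >= 1L, p$member_cap >= 1L, p$seed_cap >= 1L,
            p$member_identity > 0, p$member_identity <= 1,
            p$seed_identity > 0, p$seed_identity <= 1)
  class(p) <- "peakfam_params"
  p
}

#' @export
print.peakfam_params <- function(x, ...) {
  cat("peakfam clustering parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
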