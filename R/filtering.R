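#' Filter metacluster member regions
#'
#' A metacluster is a collection of search-sequence regions; outlier members
#' that do not overlap any other member are noise. A member region is
#' retained iff at least one *other* member of the same metacluster lies on
#' the same search sequence at Jaccard distance below `mu_d`. The partner
#' relation is symmetric, so a single pass suffices and every retained
#' region keeps a retained partner.
#'
#' @param mc_members Metacluster member table (from [metacluster()]).
#' @param mu_d Search-region distance radius.
#' @return The retained subset of `mc_members`, original order.
#' @export
filter_member_regions <- function(mc_members, mu_d = 0.2) {
  if (nrow(mc_members) == 0L) return(mc_members)
  m <- mc_members[, .(mc_id, search_id, sstart, send)]
  m[, member_id := seq_len(.N)]
  j <- m[m, on = c("mc_id", "search_id"), allow.cartesian = TRUE,
         .(member_id, other = i.member_id,
           d = region_distance(sstart, send, i.sstart, i.send))]
  j <- j[member_id != other & d < mu_d]
  keep <- sort(unique(j$member_id))
  mc_members[keep]
}

#' Reduce redundancy and cap metacluster membership
#'
#' Applies, in order: (a) when sequences are supplied, greedy identity-based
#' redundancy reduction of member regions at `member_identity` (members
#' sorted longest-first; a region is dropped when it is at least
#' `member_identity` identical, over the shorter region length, to an
#' already retained one on comparison of their subsequences); (b) removal of
#' metaclusters with fewer than `min_size` members; (c) a uniform random
#' subsample down to `member_cap` members per metacluster, using
#' `rng_seed` so runs are reproducible. When no sequences are available the
#' identity step is skipped with a message.
#'
#' @param mc_members Metacluster member table (ideally already filtered with
#'   [filter_member_regions()]).
#' @param sequences Optional [Biostrings::AAStringSet] (or `XStringSet`)
#'   named by sequence id, used for the identity step.
#' @param params [clustering_params()] list.
#' @return The reduced member table.
#' @export
reduce_and_cap_members <- function(mc_members, sequences = NULL,
                                   params = clustering_params()) {
  if (nrow(mc_members) == 0L) return(mc_members)
  m <- data.table::copy(mc_members)
  if (!is.null(sequences)) {
    missing <- setdiff(unique(m$search_id), names(sequences))
    if (length(missing))
      stop("reduce_and_cap_members(): no sequence for region(s) on: ",
           paste(head(missing, 3L), collapse = ", "))
    keep_rows <- unlist(lapply(split(seq_len(nrow(m)), m$mc_id), function(rows) {
      rows[identity_reduce(m[rows], sequences, params$member_identity)]
    }), use.names = FALSE)
    m <- m[sort(keep_rows)]
  } else {
    message("reduce_and_cap_members(): no sequences supplied; ",
            "identity-based redundancy reduction skipped")
  }
  sizes <- m[, .N, by = mc_id]
  m <- m[mc_id %in% sizes[N >= params$min_size, mc_id]]
  if (nrow(m) == 0L) return(m)
  with_seed(params$rng_seed, {
    m <- m[, if (.N > params$member_cap)
      .SD[sort(sample.int(.N, params$member_cap))] else .SD,
      by = mc_id]
  })
  m[]
}

## Greedy longest-first identity reduction of the member regions of one
## metacluster. Returns the positions (within `mem`) retained. Identity is
## the best ungapped-diagonal match count divided by the shorter region
## length: adequate for near-duplicate removal and fast enough for
## desk-scale runs; an external CD-HIT pass is a drop-in alternative on the
## exported member table.
identity_reduce <- function(mem, sequences, identity) {
  n <- nrow(mem)
  if (n <= 1L) return(seq_len(n))
  subs <- as.character(Biostrings::subseq(
    sequences[mem$search_id], start = mem$sstart, end = mem$send))
  lens <- nchar(subs)
  ord <- order(-lens, seq_len(n))
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (k in kept) {
      if (ungapped_identity(subs[i], subs[k]) >= identity) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  sort(kept)
}

## Best ungapped-diagonal fractional identity between two strings, computed
## over the shorter length.
ungapped_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  best <- 0L
  for (off in 0:(lb - la)) {
    best <- max(best, sum(av == bv[(off + 1L):(off + la)]))
    if (best == la) break
  }
  best / la
}

#' Export a metacluster seed set as FASTA records
#'
#' Extracts the member-region subsequences of one metacluster, reduces
#' redundancy at `seed_identity`, caps the set at `seed_cap` records
#' (seeded random choice when exceeded) and returns them named
#' `"<seq_id>/<start>-<end>"`. The result is suitable as input to external
#' multiple-alignment (e.g. MUSCLE) and profile-HMM (HMMER) construction.
#'
#' @param mc_members Member table rows of a single metacluster.
#' @param sequences [Biostrings::AAStringSet] named by sequence id.
#' @param params [clustering_params()] list (`seed_identity`, `seed_cap`,
#'   `rng_seed`).
#' @return An `AAStringSet` of seed subsequences.
#' @export
export_seed_set <- function(mc_members, sequences,
                            params = clustering_params()) {
  if (length(unique(mc_members$mc_id)) > 1L)
    stop("export_seed_set(): members of a single metacluster expected")
  if (nrow(mc_members) == 0L) return(Biostrings::AAStringSet())
  missing <- setdiff(unique(mc_members$search_id), names(sequences))
  if (length(missing))
    stop("export_seed_set(): no sequence for: ",
         paste(head(missing, 3L), collapse = ", "))
  too_long <- mc_members$send >
    Biostrings::width(sequences[mc_members$search_id])
  if (any(too_long))
    stop("export_seed_set(): region beyond sequence length for ",
         mc_members$search_id[which(too_long)[1L]])
  keep <- identity_reduce(mc_members, sequences, params$seed_identity)
  mem <- mc_members[keep]
  if (nrow(mem) > params$seed_cap) {
    with_seed(params$rng_seed,
              mem <- mem[sort(sample.int(nrow(mem), params$seed_cap))])
  }
  out <- Biostrings::subseq(sequences[mem$search_id],
                            start = mem$sstart, end = mem$send)
  names(out) <- sprintf("%s/%d-%d", mem$search_id, mem$sstart, mem$send)
  out
}
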