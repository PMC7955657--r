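#' Run the full clustering pipeline
#'
#' Executes, in order: alignment reading (when `alignments` is a path) and
#' E-value filtering, grouping by query, same-search deduplication, primary
#' clustering, metaclustering, metacluster merging, member-region filtering,
#' identity reduction (when sequences are available), minimum-size pruning
#' and member capping. Per-stage counts are collected in a run manifest.
#'
#' @param alignments Alignment table (as from [read_alignment_table()] or
#'   [simulate_alignments()]) or a path to an outfmt-6 file.
#' @param params [clustering_params()] list.
#' @param sequences Optional `AAStringSet` of search sequences for the
#'   identity-reduction step.
#' @param filter If `FALSE`, stop after metacluster merging and report raw
#'   metacluster membership (used e.g. by the robustness protocol, which
#'   compares assignments before filtering).
#' @return A list of class `peakfam_run`: `primary` (primary-cluster member
#'   table), `mc_members` (final metacluster member table), `mc_of_cluster`
#'   (primary-cluster to metacluster map), `manifest` (parameters, seed and
#'   per-stage counts).
#' @export
run_cluster <- function(alignments, params = clustering_params(),
                        sequences = NULL, filter = TRUE) {
  input_digest <- NA_character_
  if (is.character(alignments) && length(alignments) == 1L) {
    input_digest <- unname(tools::md5sum(alignments))
    alignments <- read_alignment_table(alignments, params$evalue_max)
  } else {
    alignments <- data.table::as.data.table(alignments)
    alignments <- alignments[evalue < params$evalue_max]
    if (!"aln_id" %in% names(alignments))
      alignments[, aln_id := seq_len(.N)]
  }
  n_aln <- nrow(alignments)
  primary <- primary_clustering(alignments, params)
  n_queries <- length(unique(alignments$query_id))
  n_clustered_queries <- length(unique(primary$query_id))
  mcs <- metacluster(primary, params)
  mm <- mcs$mc_members
  n_mc_raw <- length(unique(mm$mc_id))
  n_members_raw <- nrow(mm)
  if (filter && nrow(mm)) {
    mm <- filter_member_regions(mm, params$mu_d)
    mm <- suppressMessages(reduce_and_cap_members(mm, sequences, params))
  }
  manifest <- list(
    tool = "peakfam",
    version = as.character(utils::packageVersion("peakfam")),
    params = unclass(params),
    input_digest = input_digest,
    counts = list(
      alignments = n_aln,
      queries = n_queries,
      queries_clustered = n_clustered_queries,
      queries_skipped = n_queries - n_clustered_queries,
      primary_clusters = length(unique(primary$cluster_id)),
      metaclusters_raw = n_mc_raw,
      members_raw = n_members_raw,
      metaclusters = length(unique(mm$mc_id)),
      members = nrow(mm)
    ),
    filtered = filter
  )
  structure(list(primary = primary, mc_members = mm,
                 mc_of_cluster = mcs$mc_of_cluster,
                 manifest = manifest),
            class = "peakfam_run")
}

#' @export
print.peakfam_run <- function(x, ...) {
  cn <- x$manifest$counts
  cat("peakfam run:\n")
  cat(sprintf("  %d alignments on %d queries (%d clustered, %d skipped)\n",
              cn$alignments, cn$queries, cn$queries_clustered,
              cn$queries_skipped))
  cat(sprintf("  %d primary clusters -> %d metaclusters (%d members%s)\n",
              cn$primary_clusters, cn$metaclusters, cn$members,
              if (isTRUE(x$manifest$filtered)) ", filtered" else ", unfiltered"))
  invisible(x)
}

#' Write a run manifest
#'
#' @param run A `peakfam_run`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  yaml::write_yaml(run$manifest, path)
  invisible(path)
}

## Metacluster label per alignment id (pre-filter membership).
mc_labels_of <- function(run) {
  setNames(run$mc_members$mc_id, run$mc_members$aln_id)
}

#' Default robustness perturbations
#'
#' One run per parameter and direction: `mu1`, `mu2` and `delta_exp`, each
#' scaled by 0.9 and 1.1.
#'
#' @param params Base [clustering_params()].
#' @return Named list of parameter-override lists.
#' @export
robustness_perturbations <- function(params = clustering_params()) {
  list(mu1_down = list(mu1 = 0.9 * params$mu1),
       mu1_up = list(mu1 = 1.1 * params$mu1),
       mu2_down = list(mu2 = 0.9 * params$mu2),
       mu2_up = list(mu2 = min(1, 1.1 * params$mu2)),
       delta_down = list(delta_exp = 0.9 * params$delta_exp),
       delta_up = list(delta_exp = 1.1 * params$delta_exp))
}

#' Robustness of the metaclustering to parameter perturbations
#'
#' Re-runs the clustering under each perturbed parameter set and compares
#' the assignment of alignments to metaclusters (before the filtering step)
#' against the reference run. For each run the report gives the number of
#' metaclustered alignments, the percentage of the reference run's
#' metaclustered alignments that are still metaclustered, and the NMI over
#' the alignments metaclustered by both runs.
#'
#' @param alignments Alignment table or path.
#' @param params Reference [clustering_params()].
#' @param perturbations Named list of parameter-override lists; default
#'   [robustness_perturbations()].
#' @return A `data.frame` with one row per run (including the reference):
#'   `run`, `n_metaclustered`, `pct_common`, `nmi`.
#' @export
run_robustness <- function(alignments, params = clustering_params(),
                           perturbations = robustness_perturbations(params)) {
  stopifnot(length(perturbations) >= 1L)
  ref <- run_cluster(alignments, params, filter = FALSE)
  ref_lab <- mc_labels_of(ref)
  rows <- list(data.frame(run = "reference",
                          n_metaclustered = length(ref_lab),
                          pct_common = 100, nmi = 1,
                          stringsAsFactors = FALSE))
  for (nm in names(perturbations)) {
    p <- params
    over <- perturbations[[nm]]
    p[names(over)] <- over
    p <- do.call(clustering_params, p[setdiff(names(p), character(0))])
    alt <- run_cluster(alignments, p, filter = FALSE)
    alt_lab <- mc_labels_of(alt)
    common <- intersect(names(ref_lab), names(alt_lab))
    nmi <- if (length(common))
      clustering_nmi(ref_lab[common], alt_lab[common]) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      run = nm,
      n_metaclustered = length(alt_lab),
      pct_common = 100 * length(common) / max(1L, length(ref_lab)),
      nmi = nmi, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
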