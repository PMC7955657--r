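mk_cluster <- function(cid, sids, sstart, send, qid = paste0("Q", cid)) {
  n <- length(sids)
  data.table::data.table(
    cluster_id = cid, query_id = qid, peak_rank = 1L,
    peak = c(TRUE, rep(FALSE, n - 1L)), aln_id = seq_len(n),
    search_id = sids, qstart = 1L, qend = 101L,
    sstart = as.integer(sstart), send = as.integer(send), evalue = 1e-10)
}

test_that("primary-cluster distance: identical, disjoint and capped matching", {
  c1 <- mk_cluster(1L, c("X", "Y", "Z"), 10, 110)
  expect_equal(primary_cluster_distance(c1, c1, 0.2), 0)
  c2 <- mk_cluster(2L, c("U", "V"), 10, 110)
  expect_equal(primary_cluster_distance(c1, c2, 0.2), 1)  # no shared search id
  ## one-to-one matching caps the pair count at the smaller cluster size
  a <- mk_cluster(1L, "X", 1, 100)
  b <- mk_cluster(2L, c("X", "X"), c(1, 5), c(100, 104))
  expect_equal(primary_cluster_distance(a, b, 0.2), 0)    # M = 1 = min size
  expect_error(primary_cluster_distance(a[0], b, 0.2), "empty")
})

test_that("metacluster peaks: dense trio wins, isolated and sparse fail rho > 1", {
  trio <- lapply(1:3, function(i) mk_cluster(i, c("X", "Y", "Z"), 10, 110))
  iso <- mk_cluster(4L, c("A", "B", "C"), 10, 110)
  members <- data.table::rbindlist(c(trio, list(iso)))
  pk <- metacluster_peaks(members, clustering_params())
  expect_equal(pk$rho, c(2L, 2L, 2L, 0L))
  expect_equal(pk$delta[1], 1)
  expect_equal(pk$peaks, 1L)
  ## a single cluster can never be a peak
  pk1 <- metacluster_peaks(trio[[1]], clustering_params())
  expect_length(pk1$peaks, 0L)
})

test_that("assignment joins the nearest peak below mu2, else discards", {
  ## two well-populated families and one stray cluster
  famA <- lapply(1:3, function(i) mk_cluster(i, c("X", "Y", "Z", "W"), 10, 110))
  famB <- lapply(4:6, function(i) mk_cluster(i, c("P", "Q", "R", "T"), 200, 300))
  stray <- mk_cluster(7L, c("N1", "N2"), 50, 150)
  members <- data.table::rbindlist(c(famA, famB, list(stray)))
  params <- clustering_params()
  pk <- metacluster_peaks(members, params)
  assign <- assign_to_metaclusters(members, pk, params)
  expect_length(pk$peaks, 2L)
  expect_equal(assign[1:3], rep(assign[1], 3L))
  expect_equal(assign[4:6], rep(assign[4], 3L))
  expect_false(assign[1] == assign[4])
  expect_true(is.na(assign[7]))              # no shared search regions
})

test_that("merging is transitive over the below-threshold graph", {
  params <- clustering_params()
  fake_pk <- function(pairs) list(pd = list(pairs = pairs))
  ## chain: A-B at 0.5, B-C at 0.5, A-C at 0.95 -> one component
  chain <- data.table::data.table(ci = c(1L, 2L, 1L), cj = c(2L, 3L, 3L),
                                  D = c(0.5, 0.5, 0.95))
  merged <- merge_metaclusters(c(1L, 2L, 3L), fake_pk(chain), params)
  expect_equal(merged, c(1L, 1L, 1L))
  ## all cross distances 1: nothing merges
  far <- data.table::data.table(ci = integer(), cj = integer(), D = numeric())
  merged2 <- merge_metaclusters(c(1L, 2L, 3L), fake_pk(far), params)
  expect_equal(sort(unique(merged2)), 1:3)
  ## identical metaclusters (all cross distances 0) collapse into one
  dup <- data.table::data.table(ci = 1L, cj = 2L, D = 0)
  merged3 <- merge_metaclusters(c(1L, 2L), fake_pk(dup), params)
  expect_equal(merged3, c(1L, 1L))
  ## the doubled-prefactor variant is stricter: 2 * 0.5 >= 0.9 keeps A, B apart
  params2 <- clustering_params(merge_doubled = TRUE)
  merged4 <- merge_metaclusters(c(1L, 2L, 3L), fake_pk(chain), params2)
  expect_equal(length(unique(merged4)), 3L)
})

test_that("metacluster round matches the brute-force oracle on random clusters", {
  params <- clustering_params()
  for (seed in 1:8) {
    clusters <- random_primary_clusters(sample(8:25, 1), seed = seed)
    members <- data.table::rbindlist(clusters)
    bf <- bf_metacluster(clusters, params$mu_d, params$mu2,
                         params$merge_threshold)
    pk <- metacluster_peaks(members, params)
    expect_equal(pk$rho, bf$rho)
    expect_equal(pk$delta, bf$delta, tolerance = 1e-12)
    expect_identical(pk$peaks, bf$peaks)
    ## pairwise distances agree between sparse path and direct computation
    for (r in seq_len(min(nrow(pk$pd$pairs), 20L))) {
      i <- pk$pd$pairs$ci[r]; j <- pk$pd$pairs$cj[r]
      expect_equal(pk$pd$pairs$D[r],
                   bf_pc_distance(clusters[[i]], clusters[[j]], params$mu_d),
                   tolerance = 1e-12)
    }
    assign <- assign_to_metaclusters(members, pk, params)
    expect_identical(assign, bf$assign)
    merged <- merge_metaclusters(assign, pk, params)
    expect_identical(merged, bf$merged)
  }
})

test_that("member filtering keeps exactly the regions with a close same-sequence partner", {
  mm <- data.table::data.table(
    mc_id = 1L,
    search_id = c("X", "X", "Y", "X", "X"),
    sstart = c(10L, 12L, 50L, 300L, 500L),
    send = c(100L, 102L, 150L, 400L, 600L),
    query_id = "q", cluster_id = 1L, aln_id = 1:5)
  kept <- filter_member_regions(mm, 0.2)
  ## rows 1-2 partner each other; the lone Y region and the two disjoint
  ## X regions are removed
  expect_equal(kept$aln_id, 1:2)
  ## symmetry: every retained region keeps a retained partner
  for (i in seq_len(nrow(kept))) {
    others <- kept[-i][search_id == kept$search_id[i]]
    expect_true(nrow(others) > 0 &&
                  any(region_distance(kept$sstart[i], kept$send[i],
                                      others$sstart, others$send) < 0.2))
  }
})

test_that("min-size pruning and the member cap behave as configured", {
  mk_mm <- function(mc, n) data.table::data.table(
    mc_id = mc, search_id = sprintf("s%d_%d", mc, seq_len(n)),
    sstart = 1L, send = 100L, query_id = "q", cluster_id = mc,
    aln_id = seq_len(n))
  mm <- data.table::rbindlist(list(mk_mm(1L, 120L), mk_mm(2L, 99L)))
  params <- clustering_params(min_size = 100L, member_cap = 50L, rng_seed = 5L)
  red <- suppressMessages(reduce_and_cap_members(mm, NULL, params))
  expect_equal(unique(red$mc_id), 1L)          # the 99-member MC is dropped
  expect_equal(nrow(red), 50L)                 # capped
  red2 <- suppressMessages(reduce_and_cap_members(mm, NULL, params))
  expect_identical(red, red2)                  # seeded sampling reproducible
})

test_that("identity reduction drops near-duplicates when sequences are given", {
  seqs <- Biostrings::AAStringSet(c(
    A = paste(rep("ACDEFGHIKL", 12), collapse = ""),
    B = paste(rep("ACDEFGHIKL", 12), collapse = ""),
    C = paste(rep("MNPQRSTVWY", 12), collapse = "")))
  mm <- data.table::data.table(
    mc_id = 1L, search_id = c("A", "B", "C"),
    sstart = c(1L, 1L, 1L), send = c(100L, 100L, 100L),
    query_id = "q", cluster_id = 1L, aln_id = 1:3)
  params <- clustering_params(min_size = 1L, member_identity = 0.95)
  red <- reduce_and_cap_members(mm, seqs, params)
  ## A and B are identical over the region; C is unrelated
  expect_equal(sort(red$search_id), c("A", "C"))
  mm_bad <- data.table::copy(mm)[1, search_id := "ZZ"]
  expect_error(reduce_and_cap_members(mm_bad, seqs, params), "ZZ")
})

test_that("seed-set export writes subsequences, reduces redundancy and caps", {
  seqs <- Biostrings::AAStringSet(c(
    A = paste(rep("ACDEFGHIKL", 15), collapse = ""),
    B = paste(rep("ACDEFGHIKL", 15), collapse = ""),
    C = paste(rep("MNPQRSTVWY", 15), collapse = "")))
  mm <- data.table::data.table(
    mc_id = 1L, search_id = c("A", "B", "C"),
    sstart = c(11L, 11L, 21L), send = c(110L, 110L, 120L),
    query_id = "q", cluster_id = 1L, aln_id = 1:3)
  params <- clustering_params(seed_identity = 0.6, seed_cap = 2L)
  out <- export_seed_set(mm, seqs, params)
  ## exact duplicate removed at 60% identity, then capped at 2
  expect_lte(length(out), 2L)
  expect_true(all(grepl("^[ABC]/\\d+-\\d+$", names(out))))
  expect_equal(as.character(out[["C/21-120"]]),
               substr(as.character(seqs[["C"]]), 21, 120))
  mm_oob <- data.table::copy(mm)[1, send := 999L]
  expect_error(export_seed_set(mm_oob, seqs, params), "beyond sequence length")
})
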