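ann_row <- function(seq_id, fam, clan, start, end, ev) {
  data.frame(seq_id = seq_id, family_id = fam, clan_id = clan,
             start = start, end = end, evalue = ev,
             stringsAsFactors = FALSE)
}

test_that("overlap resolution keeps the lowest-E-value annotation, no nesting", {
  ann <- rbind(ann_row("p", "A", "cA", 10, 258, 1e-50),
               ann_row("p", "B", "cB", 200, 300, 1e-10))
  res <- resolve_annotation_overlaps(ann)
  expect_equal(res$family_id, "A")
  ## non-overlapping annotations are both kept
  ann2 <- rbind(ann_row("p", "A", "cA", 10, 100, 1e-5),
                ann_row("p", "B", "cB", 200, 300, 1e-4))
  expect_equal(nrow(resolve_annotation_overlaps(ann2)), 2L)
  ## nesting resolved as plain overlap: the outer, stronger hit wins
  ann3 <- rbind(ann_row("p", "A", "cA", 50, 60, 1e-5),
                ann_row("p", "B", "cB", 10, 100, 1e-20))
  expect_equal(resolve_annotation_overlaps(ann3)$family_id, "B")
})

q5bh58 <- rbind(ann_row("Q5BH58", "PF02190", "CL0178", 10, 258, 1e-50),
                ann_row("Q5BH58", "PF00004", "CL0023", 482, 625, 1e-60),
                ann_row("Q5BH58", "PF05362", "CL0178", 706, 915, 1e-40))

test_that("GTA assignment reproduces the two-domain worked example", {
  res <- resolve_annotation_overlaps(q5bh58)
  g <- gta_of_region("Q5BH58", 132, 567, res)
  expect_equal(g$family, c("PF02190", "PF00004"))
  expect_equal(g$clan, c("CL0178", "CL0023"))
  expect_equal(g$covered, c(10, 625))
  ## a 1-residue overlap is enough for inclusion
  g1 <- gta_of_region("Q5BH58", 258, 260, res)
  expect_equal(g1$family, "PF02190")
  ## unannotated region: empty GTA
  g0 <- gta_of_region("Q5BH58", 300, 400, res)
  expect_length(g0$family, 0L)
  expect_null(g0$covered)
  ## annotations on other sequences never leak into a region's GTA
  multi <- resolve_annotation_overlaps(
    rbind(q5bh58, ann_row("OTHER", "PF99999", "CL9999", 100, 600, 1e-80)))
  g2 <- gta_of_region("Q5BH58", 132, 567, multi)
  expect_equal(g2$family, c("PF02190", "PF00004"))
})

test_that("dominant architecture is the modal GTA with deterministic ties", {
  gtas <- c(rep(list(c("A", "B")), 5), rep(list("A"), 3),
            rep(list(character(0)), 2))
  expect_equal(dominant_architecture(gtas), c("A", "B"))
  ## lexicographic tie-break among non-empty architectures
  expect_equal(dominant_architecture(list("A", "A", "B", "B")), "A")
  expect_equal(dominant_architecture(list("A")), "A")
  ## empty never beats a non-empty architecture on a tie
  expect_equal(dominant_architecture(c(list(character(0)), list("Z"))), "Z")
  expect_warning(da <- dominant_architecture(list(character(0), character(0))),
                 "unannotated")
  expect_length(da, 0L)
})

test_that("consistency ladder counts the worked member mix correctly", {
  clan_gtas <- c(rep(list(c("X", "Y")), 6), rep(list("X"), 2),
                 list(character(0)), list(c("X", "Z")))
  fam_gtas <- clan_gtas  # one family per clan in this toy setup
  cs <- consistency_scores(fam_gtas, clan_gtas, c("X", "Y"), c("X", "Y"))
  expect_equal(cs$pct_dac, 60)
  expect_equal(cs$pct_dacf, 90)   # fewer-clans members include the empty GTA
  expect_equal(cs$pct_dacfa, 100) # X_Z keeps one DA clan, adds one extra
  ## order violation: Y_X is not an order-preserving subsequence of X_Y
  cs2 <- consistency_scores(list(c("Y", "X")), list(c("Y", "X")),
                            c("X", "Y"), c("X", "Y"))
  expect_equal(cs2$pct_dacf, 0)
  expect_equal(cs2$pct_dacfa, 0)  # no extra clan either
  ## members with only non-DA clans never count in the ladder beyond 0
  cs3 <- consistency_scores(list("Q"), list("Q"), c("X", "Y"), c("X", "Y"))
  expect_equal(cs3$pct_dacfa, 0)
})

test_that("consistency ladder is monotone on randomized configurations", {
  set.seed(42)
  clans <- LETTERS[1:6]
  for (rep in 1:200) {
    n <- sample(3:30, 1)
    gtas <- lapply(seq_len(n), function(i) {
      k <- sample(0:3, 1)
      if (k == 0) character(0) else sample(clans, k)
    })
    da <- suppressWarnings(dominant_architecture(gtas))
    if (length(da) == 0L) next
    cs <- consistency_scores(gtas, gtas, da, da)
    expect_lte(cs$pct_daf, cs$pct_dac + 1e-9)
    expect_lte(cs$pct_dac, cs$pct_dacf + 1e-9)
    expect_lte(cs$pct_dacf, cs$pct_dacfa + 1e-9)
    expect_lte(cs$pct_dacfa, 100 + 1e-9)
  }
})

test_that("boundary scores reproduce the worked residue arithmetic", {
  ## member region (132,567) against covered interval (10,625)
  bs <- boundary_scores(132, 567, 10, 625)
  expect_equal(bs$f_red, 180 / 616)
  expect_equal(bs$f_ext, 0)
  ## S == P: both zero, category equivalent
  bs2 <- boundary_scores(50, 150, 50, 150)
  expect_equal(c(bs2$f_red, bs2$f_ext), c(0, 0))
  expect_equal(bs2$category, "equivalent")
  ## category thresholds at 0.2
  expect_equal(boundary_category(0.47, 0.05), "extended")
  expect_equal(boundary_category(0.1, 0.3), "reduced")
  expect_equal(boundary_category(0.3, 0.3), "shifted")
  expect_equal(boundary_category(0.19, 0.19), "equivalent")
  ## empty reference intervals are skipped with a warning
  expect_warning(bs3 <- boundary_scores(c(1, 1), c(10, 10), c(1, NA), c(10, NA)),
                 "skipped")
  expect_equal(bs3$f_red, 0)
})

test_that("boundary scores stay in [0,1] with the expected zero cases", {
  set.seed(9)
  for (rep in 1:100) {
    s <- sample(1:500, 2); p <- sample(1:500, 2)
    bs <- boundary_scores(min(s), max(s), min(p), max(p))
    expect_gte(bs$f_red, 0); expect_lte(bs$f_red, 1)
    expect_gte(bs$f_ext, 0); expect_lte(bs$f_ext, 1)
    if (min(s) >= min(p) && max(s) <= max(p)) expect_equal(bs$f_ext, 0)
    if (min(p) >= min(s) && max(p) <= max(s)) expect_equal(bs$f_red, 0)
  }
})

test_that("coverage curve ranks metaclusters greedily and counts regions once", {
  ref <- data.frame(seq_id = paste0("p", 1:4),
                    start = c(1, 1, 1, 1), end = c(100, 100, 100, 100))
  hits <- data.frame(
    mc_id = c("MC1", "MC1", "MC1", "MC2", "MC2", "MC3"),
    seq_id = c("p1", "p2", "p3", "p1", "p4", "p4"),
    start = c(1, 1, 10, 1, 1, 1),
    end = c(100, 90, 89, 100, 80, 100))
  cv75 <- coverage_curve(ref, hits, fraction = 0.75)
  ## MC1 covers p1,p2,p3 at 75%; MC2 then adds only p4 (p1 already counted)
  expect_equal(cv75$mc_id[1], "MC1")
  expect_equal(cv75$n_new, c(3L, 1L))
  expect_equal(cv75$cum_fraction, c(0.75, 1))
  expect_true(!is.unsorted(cv75$cum_fraction))
  expect_true(all(diff(cv75$n_new) <= 0))
  ## 100% coverage is stricter: the 80/100 and 90/100 hits no longer count
  cv100 <- coverage_curve(ref, hits, fraction = 1)
  expect_equal(sum(cv100$n_new), 2L)  # p1 (MC1 or MC2) and p4 (MC3)
  ## no hits: empty curve
  expect_equal(nrow(coverage_curve(ref, hits[0, ], 0.75)), 0L)
})

test_that("coverage honours E-value thresholds when present", {
  ref <- data.frame(seq_id = "p1", start = 1, end = 100)
  hits <- data.frame(mc_id = "MC1", seq_id = "p1", start = 1, end = 100,
                     seq_evalue = c(0.5), dom_evalue = c(1e-5))
  expect_equal(nrow(coverage_curve(ref, hits, 0.75)), 0L)
  hits$seq_evalue <- 1e-5
  expect_equal(nrow(coverage_curve(ref, hits, 0.75)), 1L)
})

test_that("domtblout parsing extracts ids, envelopes and E-values", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  lines <- c(
    "# comment line",
    paste("seq1 - 500 MC1 - 120 1e-20 55.0 0.1 1 2 2e-21 1e-18 30.0 0.2",
          "5 110 10 118 8 120 0.9 desc text"),
    paste("seq2 - 400 MC2 - 120 5e-03 15.0 0.1 1 1 4e-03 2e-02 10.0 0.2",
          "1 100 20 119 18 120 0.8 more desc"))
  writeLines(lines, f)
  h <- read_domtblout(f)
  expect_equal(h$seq_id, c("seq1", "seq2"))
  expect_equal(h$mc_id, c("MC1", "MC2"))
  expect_equal(h$start, c(8L, 18L))
  expect_equal(h$end, c(120L, 120L))
  expect_equal(h$seq_evalue, c(1e-20, 5e-3))
  expect_equal(h$dom_evalue, c(1e-18, 2e-2))
})

test_that("NMI: identity, label invariance, symmetry and near-zero independence", {
  expect_equal(clustering_nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(clustering_nmi(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  a <- sample(1:4, 200, replace = TRUE)
  b <- sample(1:3, 200, replace = TRUE)
  expect_equal(clustering_nmi(a, b), clustering_nmi(b, a))
  expect_equal(clustering_nmi(a, b), bf_nmi(a, b), tolerance = 1e-12)
  ## both single-class partitions: NMI = 1 by convention
  expect_equal(clustering_nmi(rep(1, 5), rep("x", 5)), 1)
  ## NA labels restrict the comparison to commonly clustered items
  expect_equal(clustering_nmi(c(1, 1, 2, NA), c(1, 1, NA, 2)), 1)
  expect_error(clustering_nmi(c(NA, NA), c(1, 2)), "no items")
  set.seed(123)
  x <- sample(1:2, 10000, replace = TRUE)
  y <- sample(1:2, 10000, replace = TRUE)
  expect_lt(abs(clustering_nmi(x, y)), 0.01)
})

test_that("metacluster report aggregates sizes, lengths, LC fraction and scores", {
  res <- resolve_annotation_overlaps(q5bh58)
  mm <- data.table::data.table(
    mc_id = 7L, search_id = "Q5BH58",
    sstart = c(101L, 1L), send = c(200L, 200L),
    query_id = "q", cluster_id = 1L, aln_id = 1:2)
  rep1 <- report_metacluster(mm, res)
  expect_equal(rep1$size, 2L)
  expect_equal(rep1$avg_length, 150)
  expect_equal(rep1$sdl, 50)              # population SD
  expect_true(is.na(rep1$lc_fraction))    # no mask supplied
  expect_equal(rep1$da_family, "PF02190")
  expect_equal(rep1$pct_daf, 100)
  mask <- data.frame(seq_id = "Q5BH58", start = 1, end = 30)
  rep2 <- report_metacluster(mm, res, mask = mask)
  expect_equal(rep2$lc_fraction, 30 / 300)
})
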