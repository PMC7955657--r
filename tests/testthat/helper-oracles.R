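# Brute-force reference implementations, written independently of the
# package internals (explicit residue sets and double loops) so they can
# serve as oracles for the vectorized/sparse production code.

## Jaccard distance by explicit residue-set enumeration.
bf_region_distance <- function(a1, a2, b1, b2) {
  A <- seq.int(a1, a2)
  B <- seq.int(b1, b2)
  1 - length(intersect(A, B)) / length(union(A, B))
}

## Scalar double loop; overlap/union by counting (spot-checked against the
## residue-set version in the tests).
bf_dist_matrix <- function(qs, qe) {
  n <- length(qs)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ov <- min(qe[i], qe[j]) - max(qs[i], qs[j]) + 1
    if (ov < 0) ov <- 0
    un <- (qe[i] - qs[i] + 1) + (qe[j] - qs[j] + 1) - ov
    D[i, j] <- 1 - ov / un
  }
  D
}

bf_rho <- function(D, mu1) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) sum(D[i, ] < mu1), integer(1))
}

## Rank-order delta: minimum distance to any point earlier in the
## (rho desc, index asc) order; 1 for the first point.
bf_delta <- function(D, rho) {
  n <- length(rho)
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  for (k in seq_len(n)) {
    i <- ord[k]
    if (k == 1L) {
      delta[i] <- 1
    } else {
      best <- Inf
      for (k2 in seq_len(k - 1L)) best <- min(best, D[i, ord[k2]])
      delta[i] <- best
    }
  }
  delta
}

## Gamma-gap peak count: literal scan over ratios of the ranked non-zero
## gamma values; the collapse to exact zero after K entries acts as an
## infinite ratio only when no finite ratio qualifies.
bf_gap_peaks <- function(gamma_sorted, delta_exp, g_max) {
  nz <- gamma_sorted[gamma_sorted > 0]
  K <- length(nz)
  if (K == 0L) return(0L)
  thr <- 10^delta_exp
  g <- 0L
  if (K >= 2L) {
    for (s in 2:K) if (nz[s - 1L] / nz[s] >= thr) g <- s
  }
  if (g > 0L) {
    if (g > g_max) return(0L)
    return(g - 1L)
  }
  if (length(gamma_sorted) > K && K + 1L <= g_max) return(K)
  0L
}

bf_assign_primary <- function(D, peak_idx, mu1) {
  n <- nrow(D)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    dbest <- Inf; pbest <- NA_integer_
    for (p in seq_along(peak_idx)) {
      if (D[i, peak_idx[p]] < dbest) { dbest <- D[i, peak_idx[p]]; pbest <- p }
    }
    if (!is.na(pbest) && dbest < mu1) out[i] <- pbest
  }
  out
}

## Distance between two primary clusters: greedy one-to-one matching of
## same-search-sequence pairs below mu_d, pairs sorted by (distance, i, j).
bf_pc_distance <- function(c1, c2, mu_d) {
  cand <- NULL
  for (i in seq_len(nrow(c1))) for (j in seq_len(nrow(c2))) {
    if (c1$search_id[i] == c2$search_id[j]) {
      d <- bf_region_distance(c1$sstart[i], c1$send[i],
                              c2$sstart[j], c2$send[j])
      if (d < mu_d) cand <- rbind(cand, data.frame(i = i, j = j, d = d))
    }
  }
  M <- 0L
  if (!is.null(cand)) {
    cand <- cand[order(cand$d, cand$i, cand$j), ]
    ui <- rep(FALSE, nrow(c1)); uj <- rep(FALSE, nrow(c2))
    for (k in seq_len(nrow(cand))) {
      if (!ui[cand$i[k]] && !uj[cand$j[k]]) {
        ui[cand$i[k]] <- TRUE; uj[cand$j[k]] <- TRUE; M <- M + 1L
      }
    }
  }
  max(0, min(1, 1 - M / min(nrow(c1), nrow(c2))))
}

## Full brute-force metacluster round on a list of cluster member tables.
bf_metacluster <- function(clusters, mu_d, mu2, merge_threshold) {
  k <- length(clusters)
  Dm <- matrix(1, k, k); diag(Dm) <- 0
  for (a in seq_len(k)) for (b in seq_len(k)) if (a != b)
    Dm[a, b] <- bf_pc_distance(clusters[[a]], clusters[[b]], mu_d)
  rho <- vapply(seq_len(k), function(a) sum(Dm[a, -a] < mu2), integer(1))
  ord <- order(-rho, seq_len(k))
  delta <- numeric(k)
  for (p in seq_len(k)) {
    a <- ord[p]
    delta[a] <- if (p == 1L) 1 else min(Dm[a, ord[seq_len(p - 1L)]])
  }
  peaks <- which(delta == 1 & rho > 1)
  peaks <- peaks[order(-rho[peaks], peaks)]
  assign <- rep(NA_integer_, k)
  for (a in seq_len(k)) {
    if (length(peaks) == 0L) break
    dp <- Dm[a, peaks]
    best <- which.min(dp)
    if (dp[best] < mu2) assign[a] <- best
  }
  if (length(peaks)) assign[peaks] <- seq_along(peaks)
  ## merge: mean cross-pair distance, connected components below threshold
  nmc <- length(peaks)
  if (nmc >= 2L) {
    grp <- seq_len(nmc)
    repeat {
      changed <- FALSE
      for (a in seq_len(nmc - 1L)) for (b in (a + 1L):nmc) {
        ia <- which(assign == a); ib <- which(assign == b)
        if (!length(ia) || !length(ib)) next
        dmc <- mean(Dm[ia, ib, drop = FALSE])
        if (dmc < merge_threshold && grp[b] != grp[a]) {
          grp[grp == grp[b]] <- grp[a]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    ## relabel merged groups by decreasing pooled size then group id
    merged <- ifelse(is.na(assign), NA_integer_, grp[assign])
    sizes <- table(factor(merged, levels = sort(unique(grp))))
    lab_order <- order(-as.integer(sizes), as.integer(names(sizes)))
    relabel <- integer(max(as.integer(names(sizes))))
    relabel[as.integer(names(sizes))[lab_order]] <- seq_along(lab_order)
    merged <- ifelse(is.na(merged), NA_integer_, relabel[merged])
  } else {
    merged <- assign
  }
  list(D = Dm, rho = rho, delta = delta, peaks = peaks,
       assign = assign, merged = merged)
}

## Independent NMI computation: explicit class-pair loops, log base 2.
bf_nmi <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a)
  ca <- unique(a); cb <- unique(b)
  H <- function(x, cls) {
    p <- vapply(cls, function(c) sum(x == c) / n, numeric(1))
    -sum(p * log2(p))
  }
  I <- 0
  for (x in ca) for (y in cb) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) I <- I + pxy * log2(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  ha <- H(a, ca); hb <- H(b, cb)
  if (ha + hb == 0) return(1)
  2 * I / (ha + hb)
}

# --- fixture generators -----------------------------------------------------

## Random per-query alignment set: a few co-located groups plus stragglers.
random_query_set <- function(n, seed, qlen = 600L) {
  set.seed(seed)
  n_groups <- sample(1:4, 1L)
  centers <- sort(sample(seq(50L, qlen - 150L), n_groups))
  rows <- lapply(seq_len(n), function(i) {
    if (runif(1) < 0.85) {
      g <- sample(n_groups, 1L)
      st <- max(1L, centers[g] + sample(-15:15, 1L))
      en <- min(qlen, st + 80L + sample(-20:20, 1L))
    } else {
      st <- sample(seq_len(qlen - 60L), 1L)
      en <- min(qlen, st + sample(40:160, 1L))
    }
    data.frame(query_id = "Q1", search_id = sprintf("S%03d", sample(1:60, 1L)),
               qstart = st, qend = en, sstart = st, send = en,
               evalue = 10^runif(1, -40, -2), stringsAsFactors = FALSE)
  })
  out <- data.table::as.data.table(do.call(rbind, rows))
  out[, aln_id := seq_len(.N)]
  out[]
}

## Random set of primary clusters over a pool of search sequences.
random_primary_clusters <- function(n_clusters, seed) {
  set.seed(seed)
  n_fam <- sample(2:4, 1L)
  fam_sids <- lapply(seq_len(n_fam), function(f)
    sprintf("S%d_%02d", f, seq_len(sample(6:12, 1L))))
  fam_region <- lapply(seq_len(n_fam), function(f) c(30L, 130L))
  clusters <- lapply(seq_len(n_clusters), function(ci) {
    f <- sample(n_fam, 1L)
    sids <- sample(fam_sids[[f]], sample(3:6, 1L))
    st <- fam_region[[f]][1L] + sample(-5:5, length(sids), replace = TRUE)
    en <- fam_region[[f]][2L] + sample(-5:5, length(sids), replace = TRUE)
    data.table::data.table(
      cluster_id = ci, query_id = sprintf("Q%03d", ci), peak_rank = 1L,
      peak = c(TRUE, rep(FALSE, length(sids) - 1L)),
      aln_id = seq_along(sids), search_id = sids,
      qstart = 1L, qend = 101L, sstart = pmax(1L, st), send = en,
      evalue = 1e-10)
  })
  clusters
}

## Tiny clean two-architecture simulation for fast end-to-end tests.
tiny_clean_config <- function(seed = 7L, n_proteins = 40L) {
  synthetic_config(n_families = 2L,
                   architectures = list("F1", c("F1", "F2")),
                   arch_freqs = c(1, 1),
                   n_proteins = n_proteins,
                   detection_prob = 1, boundary_jitter_sd = 0,
                   noise_alignment_rate = 0, rng_seed = seed)
}
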