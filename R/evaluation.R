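#' Resolve overlapping domain annotations
#'
#' Reference domain annotations on a protein can overlap (including nested
#' domains). The resolution rule keeps, greedily in ascending E-value order
#' (ties by input order), every annotation whose region shares no residue
#' with an already kept annotation on the same sequence; losing annotations
#' are removed entirely. Nesting is deliberately not handled: a domain
#' nested inside a stronger-scoring one disappears.
#'
#' @param ann `data.frame`/`data.table` with columns `seq_id`, `family_id`,
#'   `clan_id`, `start`, `end`, `evalue`. For families without a clan, use
#'   the family id as `clan_id`.
#' @return A `data.table` of the retained annotations, ordered by sequence
#'   and start position.
#' @export
resolve_annotation_overlaps <- function(ann) {
  ann <- data.table::as.data.table(ann)
  if (nrow(ann) == 0L) return(ann)
  ann[, .input_order := seq_len(.N)]
  keep_idx <- ann[, {
    o <- order(evalue, .input_order)
    kept <- integer(0)
    for (i in o) {
      if (!length(kept) ||
          all(interval_overlap(start[i], end[i], start[kept], end[kept]) == 0))
        kept <- c(kept, i)
    }
    .(row = .I[kept])
  }, by = seq_id]$row
  out <- ann[sort(keep_idx)]
  out[, .input_order := NULL]
  data.table::setorder(out, seq_id, start)
  out[]
}

#' Ground-truth architecture of a sequence region
#'
#' The ground-truth architecture (GTA) of a region is the ordered list of
#' resolved reference families overlapping it by at least one residue,
#' ordered by position along the sequence. The covered interval spans from
#' the start of the first overlapping family to the end of the last one,
#' including every residue between them; it is empty iff no family
#' overlaps.
#'
#' @param seq_id,start,end The region.
#' @param resolved Resolved annotations from [resolve_annotation_overlaps()].
#' @return A list with `family` (character vector of family ids), `clan`
#'   (parallel clan ids) and `covered` (`c(start, end)` or `NULL`).
#' @export
#' @examples
#' ann <- data.frame(seq_id = "Q5BH58",
#'                   family_id = c("PF02190", "PF00004", "PF05362"),
#'                   clan_id = c("CL0178", "CL0023", "CL0178"),
#'                   start = c(10, 482, 706), end = c(258, 625, 915),
#'                   evalue = c(1e-30, 1e-40, 1e-20))
#' gta_of_region("Q5BH58", 132, 567, resolve_annotation_overlaps(ann))
gta_of_region <- function(seq_id, start, end, resolved) {
  a <- as.data.frame(resolved)
  a <- a[a$seq_id == seq_id, , drop = FALSE]
  if (nrow(a)) {
    hit <- interval_overlap(start, end, a$start, a$end) > 0
    a <- a[hit, , drop = FALSE]
  }
  if (nrow(a) == 0L)
    return(list(family = character(0), clan = character(0), covered = NULL))
  a <- a[order(a$start), ]
  list(family = a$family_id, clan = a$clan_id,
       covered = c(a$start[1L], a$end[nrow(a)]))
}

gta_string <- function(labels) paste(labels, collapse = "_")

#' Dominant architecture of a metacluster
#'
#' The modal GTA among the members. Empty GTAs (unannotated members) take
#' part in the counting but never win a tie against a non-empty GTA; ties
#' among non-empty GTAs are broken lexicographically.
#'
#' @param gtas List of character vectors (one GTA per member; may be
#'   zero-length for unannotated members).
#' @return Character vector of labels of the dominant architecture
#'   (zero-length when all members are unannotated, with a warning).
#' @export
dominant_architecture <- function(gtas) {
  stopifnot(length(gtas) >= 1L)
  keys <- vapply(gtas, gta_string, character(1))
  tab <- table(keys)
  best <- names(tab)[tab == max(tab)]
  if (length(best) > 1L && "" %in% best && any(best != ""))
    best <- best[best != ""]
  da <- sort(best)[1L]
  if (da == "") {
    warning("dominant_architecture(): all members unannotated; empty DA")
    return(character(0))
  }
  strsplit(da, "_", fixed = TRUE)[[1L]]
}

## Is `x` an order-preserving subsequence of `da`? Repeats are matched
## greedily left-to-right. The empty vector is a subsequence of anything.
is_subsequence <- function(x, da) {
  if (length(x) == 0L) return(TRUE)
  if (length(x) > length(da)) return(FALSE)
  j <- 1L
  for (el in da) {
    if (el == x[j]) {
      j <- j + 1L
      if (j > length(x)) return(TRUE)
    }
  }
  FALSE
}

#' Member-consistency percentages of a metacluster
#'
#' Compares member GTAs with the dominant architecture (DA) and returns the
#' cumulative consistency ladder:
#' * `pct_daf` — percent of members whose family-level GTA equals the
#'   family-level DA;
#' * `pct_dac` — percent whose clan-level GTA equals the clan-level DA
#'   ("DA members");
#' * `pct_dacf` — `pct_dac` plus members whose clan GTA is a proper
#'   order-preserving subsequence of the DA clans (members lacking any
#'   annotation count here);
#' * `pct_dacfa` — `pct_dacf` plus members whose clan GTA features at least
#'   one non-DA clan while retaining at least one DA clan.
#'
#' The ladder `pct_daf <= pct_dac <= pct_dacf <= pct_dacfa <= 100` always
#' holds.
#'
#' @param fam_gtas,clan_gtas Lists of character vectors: the family-level
#'   and clan-level GTA of each member.
#' @param da_family,da_clan The dominant architecture at the two levels
#'   (character vectors); `da_clan` must be non-empty.
#' @return Named list `pct_daf`, `pct_dac`, `pct_dacf`, `pct_dacfa` plus the
#'   logical class masks `dac_member` (DA members) and `order_violation`
#'   (members counted in `pct_dacfa` whose DA clans appear out of order).
#' @export
consistency_scores <- function(fam_gtas, clan_gtas, da_family, da_clan) {
  stopifnot(length(da_clan) >= 1L, length(fam_gtas) == length(clan_gtas))
  n <- length(clan_gtas)
  daf <- vapply(fam_gtas, identical, logical(1), y = da_family)
  dac <- vapply(clan_gtas, identical, logical(1), y = da_clan)
  fewer <- !dac & vapply(clan_gtas, function(g)
    all(g %in% da_clan) && is_subsequence(g, da_clan), logical(1))
  extra <- !dac & !fewer & vapply(clan_gtas, function(g)
    any(g %in% da_clan) && any(!(g %in% da_clan)), logical(1))
  viol <- extra & vapply(clan_gtas, function(g)
    !is_subsequence(g[g %in% da_clan], da_clan), logical(1))
  list(pct_daf = 100 * sum(daf) / n,
       pct_dac = 100 * sum(dac) / n,
       pct_dacf = 100 * (sum(dac) + sum(fewer)) / n,
       pct_dacfa = 100 * (sum(dac) + sum(fewer) + sum(extra)) / n,
       dac_member = dac,
       order_violation = viol)
}

#' Boundary agreement between member regions and their reference coverage
#'
#' For every DA member with region `S` and reference-covered interval `P`:
#' `F_red = |P \ (S ∩ P)| / |P|` (fraction of the reference interval the
#' member misses) and `F_ext = |S \ (S ∩ P)| / |S|` (fraction of the member
#' extending beyond the reference interval), with residue counts on
#' 1-based inclusive intervals. The metacluster-level scores are the means
#' over DA members, and the qualitative category applies 0.2 thresholds:
#' `equivalent` (both < 0.2), `reduced` (`f_ext < 0.2`, `f_red >= 0.2`),
#' `extended` (`f_ext >= 0.2`, `f_red < 0.2`), `shifted` (both >= 0.2).
#'
#' @param s_start,s_end Member region endpoints (DA members).
#' @param p_start,p_end Covered-interval endpoints; `NA` entries (empty
#'   coverage) are skipped with a warning.
#' @return List with per-member `f_red_i`, `f_ext_i`, the means `f_red`,
#'   `f_ext` and the `category`.
#' @export
boundary_scores <- function(s_start, s_end, p_start, p_end) {
  ok <- !(is.na(p_start) | is.na(p_end))
  if (!all(ok))
    warning("boundary_scores(): ", sum(!ok),
            " member(s) with empty reference interval skipped")
  s_start <- s_start[ok]; s_end <- s_end[ok]
  p_start <- p_start[ok]; p_end <- p_end[ok]
  inter <- interval_overlap(s_start, s_end, p_start, p_end)
  lp <- p_end - p_start + 1
  ls <- s_end - s_start + 1
  f_red_i <- (lp - inter) / lp
  f_ext_i <- (ls - inter) / ls
  f_red <- mean(f_red_i)
  f_ext <- mean(f_ext_i)
  list(f_red_i = f_red_i, f_ext_i = f_ext_i,
       f_red = f_red, f_ext = f_ext,
       category = boundary_category(f_ext, f_red))
}

#' @rdname boundary_scores
#' @param f_ext,f_red Metacluster-level mean scores.
#' @export
boundary_category <- function(f_ext, f_red) {
  if (f_ext < 0.2 && f_red < 0.2) "equivalent"
  else if (f_ext < 0.2) "reduced"
  else if (f_red < 0.2) "extended"
  else "shifted"
}

#' Cumulative coverage of reference regions by metacluster profile hits
#'
#' A reference region is covered by a metacluster when at least one of the
#' metacluster's profile hits on the same sequence overlaps at least
#' `fraction` of the region's residues. Metaclusters are ranked greedily by
#' decreasing marginal contribution (ties by metacluster id), and the curve
#' reports the cumulative fraction of reference regions covered, each
#' region counted once even when covered by several metaclusters. When the
#' hit table carries E-value columns, hits are pre-filtered at
#' `seq_evalue < 0.01` and `dom_evalue < 0.03`.
#'
#' @param ref `data.frame` of reference regions: `seq_id`, `start`, `end`.
#' @param hits `data.frame` of profile hits: `mc_id`, `seq_id`, `start`,
#'   `end`, optionally `seq_evalue` and `dom_evalue` (see
#'   [read_domtblout()]).
#' @param fraction Coverage fraction threshold, e.g. `0.75` or `1.0`.
#' @return A `data.table` with one row per contributing metacluster:
#'   `rank`, `mc_id`, `n_new` (newly covered regions), `cum_covered`,
#'   `cum_fraction`.
#' @export
coverage_curve <- function(ref, hits, fraction = 0.75) {
  ref <- data.table::as.data.table(ref)
  hits <- data.table::as.data.table(hits)
  nref <- nrow(ref)
  out <- data.table::data.table(rank = integer(), mc_id = character(),
                                n_new = integer(), cum_covered = integer(),
                                cum_fraction = numeric())
  if (nref == 0L || nrow(hits) == 0L) return(out)
  if ("seq_evalue" %in% names(hits)) hits <- hits[seq_evalue < 0.01]
  if ("dom_evalue" %in% names(hits)) hits <- hits[dom_evalue < 0.03]
  if (nrow(hits) == 0L) return(out)
  ref[, rid := seq_len(.N)]
  cand <- hits[ref, on = "seq_id", allow.cartesian = TRUE, nomatch = NULL,
               .(mc_id, rid = i.rid,
                 ovl = interval_overlap(start, end, i.start, i.end),
                 rlen = i.end - i.start + 1)]
  cov <- unique(cand[ovl >= fraction * rlen, .(mc_id = as.character(mc_id), rid)])
  if (nrow(cov) == 0L) return(out)
  covered <- rep(FALSE, nref)
  rank <- 0L
  repeat {
    marg <- cov[!covered[rid], .N, by = mc_id]
    if (nrow(marg) == 0L || max(marg$N) == 0L) break
    data.table::setorder(marg, -N, mc_id)
    pick <- marg$mc_id[1L]
    new <- cov[mc_id == pick & !covered[rid], unique(rid)]
    covered[new] <- TRUE
    rank <- rank + 1L
    out <- rbind(out, data.table::data.table(
      rank = rank, mc_id = pick, n_new = length(new),
      cum_covered = sum(covered), cum_fraction = sum(covered) / nref))
    cov <- cov[mc_id != pick]
    if (nrow(cov) == 0L) break
  }
  out[]
}

#' Summary report for one metacluster against a reference annotation
#'
#' Aggregates, for one metacluster: size, mean and population standard
#' deviation of member-region lengths, dominant architectures at family and
#' clan level, the consistency ladder, boundary scores and category over DA
#' members, the number of extra (non-DA) clans present in at least
#' `extra_clan_min_frac` of members, and (when a low-complexity mask is
#' supplied) the fraction of member residues falling in masked intervals.
#'
#' @param mc_members Member table rows of a single metacluster (columns
#'   `search_id`, `sstart`, `send`).
#' @param resolved Resolved reference annotations.
#' @param mask Optional `data.frame` of masked (e.g. low-complexity)
#'   intervals: `seq_id`, `start`, `end`.
#' @param extra_clan_min_frac Presence threshold for the extra-clan count.
#' @return A one-row `data.frame` (`MCReport`): `mc_id`, `size`,
#'   `avg_length`, `sdl`, `lc_fraction` (`NA` without a mask), `da_family`,
#'   `da_clan` (underscore-joined strings), the four percentages, `f_red`,
#'   `f_ext`, `category`, `extra_clans`, `order_violations`.
#' @export
report_metacluster <- function(mc_members, resolved, mask = NULL,
                               extra_clan_min_frac = 0.05) {
  stopifnot(nrow(mc_members) >= 1L)
  mc_id <- if ("mc_id" %in% names(mc_members)) mc_members$mc_id[1L] else NA
  n <- nrow(mc_members)
  gtas <- lapply(seq_len(n), function(i)
    gta_of_region(mc_members$search_id[i], mc_members$sstart[i],
                  mc_members$send[i], resolved))
  fam <- lapply(gtas, `[[`, "family")
  clan <- lapply(gtas, `[[`, "clan")
  da_family <- suppressWarnings(dominant_architecture(fam))
  da_clan <- suppressWarnings(dominant_architecture(clan))
  lens <- mc_members$send - mc_members$sstart + 1
  avg_length <- mean(lens)
  sdl <- sqrt(mean((lens - avg_length)^2))   # population SD
  lc_fraction <- NA_real_
  if (!is.null(mask)) {
    mask <- as.data.frame(mask)
    masked <- vapply(seq_len(n), function(i) {
      mm <- mask[mask$seq_id == mc_members$search_id[i], , drop = FALSE]
      if (nrow(mm) == 0L) return(0)
      sum(interval_overlap(mc_members$sstart[i], mc_members$send[i],
                           mm$start, mm$end))
    }, numeric(1))
    lc_fraction <- sum(masked) / sum(lens)
  }
  if (length(da_clan) == 0L) {
    return(data.frame(mc_id = mc_id, size = n, avg_length = avg_length,
                      sdl = sdl, lc_fraction = lc_fraction,
                      da_family = "", da_clan = "",
                      pct_daf = NA_real_, pct_dac = NA_real_,
                      pct_dacf = NA_real_, pct_dacfa = NA_real_,
                      f_red = NA_real_, f_ext = NA_real_,
                      category = NA_character_, extra_clans = NA_integer_,
                      order_violations = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  cs <- consistency_scores(fam, clan, da_family, da_clan)
  dam <- which(cs$dac_member)
  if (length(dam)) {
    pcov <- t(vapply(gtas[dam], function(g)
      if (is.null(g$covered)) c(NA_real_, NA_real_) else as.numeric(g$covered),
      numeric(2)))
    bs <- suppressWarnings(
      boundary_scores(mc_members$sstart[dam], mc_members$send[dam],
                      pcov[, 1L], pcov[, 2L]))
    f_red <- bs$f_red; f_ext <- bs$f_ext; category <- bs$category
  } else {
    f_red <- NA_real_; f_ext <- NA_real_; category <- NA_character_
  }
  extra_tab <- table(unlist(lapply(clan, function(g) unique(setdiff(g, da_clan)))))
  extra_clans <- sum(extra_tab >= extra_clan_min_frac * n)
  data.frame(mc_id = mc_id, size = n, avg_length = avg_length, sdl = sdl,
             lc_fraction = lc_fraction,
             da_family = gta_string(da_family), da_clan = gta_string(da_clan),
             pct_daf = cs$pct_daf, pct_dac = cs$pct_dac,
             pct_dacf = cs$pct_dacf, pct_dacfa = cs$pct_dacfa,
             f_red = f_red, f_ext = f_ext, category = category,
             extra_clans = extra_clans,
             order_violations = sum(cs$order_violation),
             stringsAsFactors = FALSE)
}

#' Read a HMMER per-domain hit table (domtblout)
#'
#' Parses the whitespace-delimited `--domtblout` format of `hmmsearch` /
#' `hmmscan`, returning the columns the coverage analysis consumes: the
#' target sequence, the query profile (interpreted as the metacluster id),
#' the envelope coordinates and the sequence- and domain-level E-values.
#'
#' @param path Path to a domtblout file (comment lines starting with `#`
#'   are skipped).
#' @return A `data.table` with columns `seq_id`, `mc_id`, `start`, `end`
#'   (envelope), `seq_evalue`, `dom_evalue`.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) stop("domtblout not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.table::data.table(seq_id = character(), mc_id = character(),
                                  start = integer(), end = integer(),
                                  seq_evalue = numeric(),
                                  dom_evalue = numeric()))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(fields) < 22L)
  if (length(bad))
    stop("domtblout ", path, ": line ", bad[1L], " has fewer than 22 fields")
  data.table::data.table(
    seq_id = vapply(fields, `[[`, character(1), 1L),
    mc_id = vapply(fields, `[[`, character(1), 4L),
    start = as.integer(vapply(fields, `[[`, character(1), 20L)),
    end = as.integer(vapply(fields, `[[`, character(1), 21L)),
    seq_evalue = as.numeric(vapply(fields, `[[`, character(1), 7L)),
    dom_evalue = as.numeric(vapply(fields, `[[`, character(1), 13L))
  )
}
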