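#' Configuration for the synthetic proteome/alignment simulator
#'
#' Describes a planted-truth multi-domain proteome and the statistical model
#' of the BLAST-like alignment table derived from it. Proteins are
#' concatenations of family domains (drawn from the architecture list) and
#' random linkers; every ordered pair of domain instances of the same
#' family yields an alignment with probability `detection_prob`, with
#' endpoints jittered by a rounded Gaussian of SD `boundary_jitter_sd`
#' residues. Spurious alignments between unrelated random regions arrive at
#' a Poisson rate of `noise_alignment_rate` per protein, and
#' `span_prob` controls the chance that a pair of adjacent same-architecture
#' domain blocks is emitted as a single spanning alignment (to exercise the
#' clustering's architecture-joining behaviour). E-values are sampled (the
#' pipeline only thresholds and ranks them), log10-uniform in
#' `evalue_log10_range` for homologous alignments and in
#' `noise_evalue_log10_range` for noise; `super_threshold_rate` adds rows
#' with E-value above the 0.1 cutoff to exercise the reader's filter.
#'
#' @param n_families Number of families (`F1`, `F2`, ...).
#' @param family_length_range Min/max family domain length (residues).
#' @param architectures List of character vectors of family ids; default:
#'   each family alone.
#' @param arch_freqs Relative frequencies of the architectures.
#' @param n_proteins Number of proteins.
#' @param linker_length_range Min/max linker length (residues).
#' @param fragment_fraction Fraction of proteins truncated at a uniform
#'   position.
#' @param detection_prob Probability a homologous ordered domain pair yields
#'   an alignment.
#' @param boundary_jitter_sd Gaussian SD (residues) of endpoint jitter.
#' @param noise_alignment_rate Spurious alignments per protein (Poisson
#'   mean).
#' @param span_prob Probability that an adjacent-domain block pair is
#'   emitted as one spanning alignment.
#' @param mutation_rate Per-residue substitution rate of a domain instance
#'   relative to its family consensus.
#' @param evalue_log10_range,noise_evalue_log10_range log10 E-value sampling
#'   ranges.
#' @param super_threshold_rate Above-cutoff rows per protein (Poisson mean).
#' @param rng_seed Integer seed; identical configuration and seed give
#'   byte-identical output.
#' @return A validated list of class `peakfam_synth_config`.
#' @export
synthetic_config <- function(n_families = 3L,
                             family_length_range = c(80L, 120L),
                             architectures = NULL,
                             arch_freqs = NULL,
                             n_proteins = 100L,
                             linker_length_range = c(20L, 60L),
                             fragment_fraction = 0,
                             detection_prob = 1,
                             boundary_jitter_sd = 0,
                             noise_alignment_rate = 0,
                             span_prob = 0,
                             mutation_rate = 0.1,
                             evalue_log10_range = c(-50, -2),
                             noise_evalue_log10_range = c(-3, -1),
                             super_threshold_rate = 0,
                             rng_seed = 1L) {
  fams <- sprintf("F%d", seq_len(n_families))
  if (is.null(architectures)) architectures <- as.list(fams)
  if (is.null(arch_freqs)) arch_freqs <- rep(1, length(architectures))
  unknown <- setdiff(unlist(architectures), fams)
  if (length(unknown))
    stop("synthetic_config(): architecture references unknown family: ",
         paste(unknown, collapse = ", "))
  cfg <- list(n_families = as.integer(n_families), families = fams,
              family_length_range = as.integer(family_length_range),
              architectures = architectures,
              arch_freqs = arch_freqs / sum(arch_freqs),
              n_proteins = as.integer(n_proteins),
              linker_length_range = as.integer(linker_length_range),
              fragment_fraction = fragment_fraction,
              detection_prob = detection_prob,
              boundary_jitter_sd = boundary_jitter_sd,
              noise_alignment_rate = noise_alignment_rate,
              span_prob = span_prob,
              mutation_rate = mutation_rate,
              evalue_log10_range = evalue_log10_range,
              noise_evalue_log10_range = noise_evalue_log10_range,
              super_threshold_rate = super_threshold_rate,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$n_families >= 1L, cfg$n_proteins >= 1L,
            all(cfg$family_length_range > 0L),
            all(cfg$linker_length_range >= 0L),
            cfg$fragment_fraction >= 0, cfg$fragment_fraction <= 1,
            cfg$detection_prob >= 0, cfg$detection_prob <= 1,
            cfg$span_prob >= 0, cfg$span_prob <= 1,
            cfg$boundary_jitter_sd >= 0, cfg$noise_alignment_rate >= 0,
            cfg$mutation_rate >= 0, cfg$mutation_rate <= 1)
  class(cfg) <- "peakfam_synth_config"
  cfg
}

#' Benchmark configuration: three families, two-domain architecture
#'
#' The default end-to-end benchmark: three families (`F1`, `F2`, `F3`) of
#' 80--120 residues arranged in the architectures `-F1-`, `-F1-F2-` and
#' `-F3-` with equal frequencies over 300 proteins; homologous domain pairs
#' are detected with probability 0.9, alignment endpoints carry Gaussian
#' jitter of SD 3 residues and spurious alignments arrive at a rate of 0.1
#' per protein. The single-family architecture `-F1-` alongside `-F1-F2-`
#' gives the clustering the evidence it needs to separate F1 from F2; F3 is
#' an independent single-domain family.
#'
#' @param rng_seed Integer seed.
#' @param ... Overrides forwarded to [synthetic_config()].
#' @return A `peakfam_synth_config`.
#' @export
benchmark_config <- function(rng_seed = 1L, ...) {
  defaults <- list(n_families = 3L,
                   architectures = list("F1", c("F1", "F2"), "F3"),
                   arch_freqs = c(1, 1, 1),
                   n_proteins = 300L,
                   detection_prob = 0.9,
                   boundary_jitter_sd = 3,
                   noise_alignment_rate = 0.1,
                   mutation_rate = 0.1,
                   rng_seed = rng_seed)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(synthetic_config, defaults)
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

random_aa <- function(n) paste(sample(AA_ALPHABET20, n, replace = TRUE),
                               collapse = "")

mutate_seq <- function(consensus, rate) {
  if (rate == 0) return(consensus)
  ch <- strsplit(consensus, "")[[1L]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- sample(AA_ALPHABET20, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

#' Simulate a planted-truth proteome
#'
#' Generates protein sequences as domain/linker concatenations according to
#' the configuration and records the planted annotations exactly. Domain
#' instances are per-family consensus sequences with point mutations, so
#' identity-based redundancy reduction operates meaningfully. A
#' `fragment_fraction` of proteins is truncated at a uniform position, with
#' planted annotations clipped to the remaining length (and dropped when
#' fully cut away).
#'
#' @param config A [synthetic_config()].
#' @return List with `sequences` (named `AAStringSet`), `truth` (a
#'   `data.table` of planted annotations: `seq_id`, `family_id`, `clan_id`
#'   (= family id; the planted families are clanless), `start`, `end`,
#'   `evalue`), and `config`.
#' @export
simulate_proteome <- function(config) {
  with_seed(config$rng_seed, {
    flr <- config$family_length_range
    fam_len <- setNames(
      sample(seq(flr[1L], flr[2L]), config$n_families, replace = TRUE),
      config$families)
    consensus <- setNames(
      vapply(fam_len, random_aa, character(1)), config$families)
    llr <- config$linker_length_range
    seqs <- character(config$n_proteins)
    ids <- sprintf("P%04d", seq_len(config$n_proteins))
    truth <- vector("list", config$n_proteins)
    arch_idx <- sample.int(length(config$architectures), config$n_proteins,
                           replace = TRUE, prob = config$arch_freqs)
    for (p in seq_len(config$n_proteins)) {
      arch <- config$architectures[[arch_idx[p]]]
      pos <- 0L
      parts <- character(0)
      rows <- list()
      for (f in arch) {
        lk <- sample(seq(llr[1L], llr[2L]), 1L)
        parts <- c(parts, random_aa(lk))
        pos <- pos + lk
        dom <- mutate_seq(consensus[[f]], config$mutation_rate)
        parts <- c(parts, dom)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          seq_id = ids[p], family_id = f, clan_id = f,
          start = pos + 1L, end = pos + fam_len[[f]],
          evalue = 10^runif(1, -60, -20))
        pos <- pos + fam_len[[f]]
      }
      lk <- sample(seq(llr[1L], llr[2L]), 1L)
      parts <- c(parts, random_aa(lk))
      seqs[p] <- paste(parts, collapse = "")
      tr <- data.table::rbindlist(rows)
      if (config$fragment_fraction > 0 &&
          runif(1) < config$fragment_fraction) {
        cut <- sample.int(nchar(seqs[p]), 1L)
        seqs[p] <- substr(seqs[p], 1L, cut)
        tr <- tr[start <= cut]
        tr[, end := pmin(end, cut)]
      }
      truth[[p]] <- tr
    }
    ss <- Biostrings::AAStringSet(seqs)
    names(ss) <- ids
    list(sequences = ss, truth = data.table::rbindlist(truth),
         config = config)
  })
}

jitter_clip <- function(start, end, sd, len) {
  if (sd > 0) {
    start <- start + round(rnorm(length(start), 0, sd))
    end <- end + round(rnorm(length(end), 0, sd))
  }
  start <- pmax(1L, pmin(as.integer(start), len))
  end <- pmax(1L, pmin(as.integer(end), len))
  sw <- start > end
  if (any(sw)) { tmp <- start[sw]; start[sw] <- end[sw]; end[sw] <- tmp }
  list(start = start, end = end)
}

#' Simulate a BLAST-like alignment table from a planted proteome
#'
#' For every ordered pair of distinct domain instances of the same family,
#' an alignment is emitted with probability `detection_prob`; its query and
#' search regions are the planted instance regions perturbed by rounded
#' Gaussian jitter and clipped to the protein. Adjacent same-architecture
#' domain block pairs may be emitted as single spanning alignments with
#' probability `span_prob`. Spurious (noise) alignments link random
#' unrelated regions at a Poisson rate per protein, and
#' `super_threshold_rate` adds rows with E-values above the standard 0.1
#' cutoff. The simulation is seeded from `config$rng_seed` (offset from the
#' proteome stream so the two draws are independent).
#'
#' @param proteome Result of [simulate_proteome()].
#' @param config The same configuration (defaults to `proteome$config`).
#' @return A `data.table` shaped like [read_alignment_table()] output, with
#'   extra provenance columns `q_family`, `s_family` (planted family of the
#'   two regions; `NA` for noise) and `type`
#'   (`"homolog"`, `"span"`, `"noise"`, `"super"`).
#' @export
simulate_alignments <- function(proteome, config = proteome$config) {
  truth <- proteome$truth
  plen <- setNames(Biostrings::width(proteome$sequences),
                   names(proteome$sequences))
  with_seed(config$rng_seed + 7919L, {
    out <- list()
    ## homologous pairs
    for (f in config$families) {
      inst <- truth[family_id == f]
      ni <- nrow(inst)
      if (ni < 2L) next
      pr <- data.table::CJ(i = seq_len(ni), j = seq_len(ni))[i != j]
      pr <- pr[runif(nrow(pr)) < config$detection_prob]
      if (nrow(pr) == 0L) next
      q <- jitter_clip(inst$start[pr$i], inst$end[pr$i],
                       config$boundary_jitter_sd, plen[inst$seq_id[pr$i]])
      s <- jitter_clip(inst$start[pr$j], inst$end[pr$j],
                       config$boundary_jitter_sd, plen[inst$seq_id[pr$j]])
      out[[length(out) + 1L]] <- data.table::data.table(
        query_id = inst$seq_id[pr$i], search_id = inst$seq_id[pr$j],
        qstart = q$start, qend = q$end, sstart = s$start, send = s$end,
        evalue = 10^runif(nrow(pr), config$evalue_log10_range[1L],
                          config$evalue_log10_range[2L]),
        q_family = f, s_family = f, type = "homolog")
    }
    ## spanning alignments over adjacent same-architecture domain blocks
    if (config$span_prob > 0) {
      ## adjacent domain pairs per protein, spanning first start to next end
      blk <- truth[, if (.N > 1L)
        .(f1 = family_id[-.N], f2 = family_id[-1L],
          start = start[-.N], end = end[-1L]), by = seq_id]
      if (nrow(blk)) {
        blk[, key := paste(f1, f2)]
        for (kk in unique(blk$key)) {
          bi <- blk[key == kk]
          nb <- nrow(bi)
          if (nb < 2L) next
          pr <- data.table::CJ(i = seq_len(nb), j = seq_len(nb))[i != j]
          pr <- pr[runif(nrow(pr)) < config$span_prob]
          if (nrow(pr) == 0L) next
          q <- jitter_clip(bi$start[pr$i], bi$end[pr$i],
                           config$boundary_jitter_sd, plen[bi$seq_id[pr$i]])
          s <- jitter_clip(bi$start[pr$j], bi$end[pr$j],
                           config$boundary_jitter_sd, plen[bi$seq_id[pr$j]])
          out[[length(out) + 1L]] <- data.table::data.table(
            query_id = bi$seq_id[pr$i], search_id = bi$seq_id[pr$j],
            qstart = q$start, qend = q$end, sstart = s$start, send = s$end,
            evalue = 10^runif(nrow(pr), config$evalue_log10_range[1L],
                              config$evalue_log10_range[2L]),
            q_family = bi$f1[pr$i], s_family = bi$f1[pr$j], type = "span")
        }
      }
    }
    ## noise alignments
    n_noise <- rpois(1L, config$noise_alignment_rate * config$n_proteins)
    if (n_noise > 0L) {
      ids <- names(proteome$sequences)
      qid <- sample(ids, n_noise, replace = TRUE)
      sid <- sample(ids, n_noise, replace = TRUE)
      ln_q <- sample(30:80, n_noise, replace = TRUE)
      ln_s <- sample(30:80, n_noise, replace = TRUE)
      qs <- pmax(1L, floor(runif(n_noise) * pmax(1L, plen[qid] - ln_q)) + 1L)
      ss <- pmax(1L, floor(runif(n_noise) * pmax(1L, plen[sid] - ln_s)) + 1L)
      out[[length(out) + 1L]] <- data.table::data.table(
        query_id = qid, search_id = sid,
        qstart = as.integer(qs), qend = as.integer(pmin(qs + ln_q - 1L, plen[qid])),
        sstart = as.integer(ss), send = as.integer(pmin(ss + ln_s - 1L, plen[sid])),
        evalue = 10^runif(n_noise, config$noise_evalue_log10_range[1L],
                          config$noise_evalue_log10_range[2L]),
        q_family = NA_character_, s_family = NA_character_, type = "noise")
    }
    ## above-cutoff rows, to exercise the reader's E-value filter
    n_sup <- rpois(1L, config$super_threshold_rate * config$n_proteins)
    if (n_sup > 0L) {
      ids <- names(proteome$sequences)
      qid <- sample(ids, n_sup, replace = TRUE)
      sid <- sample(ids, n_sup, replace = TRUE)
      qs <- sample(1:50, n_sup, replace = TRUE)
      out[[length(out) + 1L]] <- data.table::data.table(
        query_id = qid, search_id = sid,
        qstart = as.integer(qs), qend = as.integer(pmin(qs + 39L, plen[qid])),
        sstart = 1L, send = as.integer(pmin(40L, plen[sid])),
        evalue = runif(n_sup, 0.1, 5),
        q_family = NA_character_, s_family = NA_character_, type = "super")
    }
    aln <- data.table::rbindlist(out)
    if (nrow(aln) == 0L) {
      aln <- cbind(empty_alignments(),
                   data.table::data.table(q_family = character(),
                                          s_family = character(),
                                          type = character()))
      return(aln)
    }
    aln[, aln_id := seq_len(.N)]
    data.table::setcolorder(aln, c("aln_id", "query_id", "search_id",
                                   "qstart", "qend", "sstart", "send",
                                   "evalue", "q_family", "s_family", "type"))
    aln[]
  })
}

#' Planted family label of sequence regions
#'
#' Labels each region with the planted family of the annotation it overlaps
#' most (in residues); `NA` when the region overlaps no planted annotation.
#'
#' @param regions `data.frame` with `seq_id`, `start`, `end`.
#' @param truth Planted-truth annotation table.
#' @return Character vector of family labels.
#' @export
planted_labels <- function(regions, truth) {
  regions <- data.table::as.data.table(regions)
  regions[, rid := seq_len(.N)]
  j <- truth[regions, on = "seq_id", allow.cartesian = TRUE,
             .(rid = i.rid, family_id,
               ovl = interval_overlap(start, end, i.start, i.end))]
  j <- j[ovl > 0]
  lab <- rep(NA_character_, nrow(regions))
  if (nrow(j)) {
    data.table::setorder(j, rid, -ovl, family_id)
    j <- j[!duplicated(rid)]
    lab[j$rid] <- j$family_id
  }
  lab
}

#' Write a synthetic fixture to disk
#'
#' Emits `proteins.fasta`, `annotations.tsv` (evaluation-module dialect:
#' `seq_id`, `family_id`, `clan_id`, `start`, `end`, `evalue`),
#' `alignments.tsv` (BLAST outfmt 6) and `manifest.yml` (configuration and
#' seed) under `out_dir`.
#'
#' @param proteome Result of [simulate_proteome()].
#' @param alignments Result of [simulate_alignments()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(proteome, alignments, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(out_dir, "proteins.fasta"),
             annotations = file.path(out_dir, "annotations.tsv"),
             alignments = file.path(out_dir, "alignments.tsv"),
             manifest = file.path(out_dir, "manifest.yml"))
  Biostrings::writeXStringSet(proteome$sequences, paths[["fasta"]])
  data.table::fwrite(proteome$truth, paths[["annotations"]], sep = "\t")
  write_alignment_table(alignments, paths[["alignments"]])
  cfg <- proteome$config
  cfg$architectures <- vapply(cfg$architectures, paste, character(1),
                              collapse = "+")
  yaml::write_yaml(unclass(cfg), paths[["manifest"]])
  invisible(paths)
}
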