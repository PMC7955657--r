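#' Read a tabular local-alignment file (BLAST outfmt 6)
#'
#' Reads a BLAST tabular file (`-outfmt 6`: `qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), consuming only
#' the query/subject identifiers, the alignment envelope coordinates and the
#' E-value. Rows are kept when `evalue < evalue_max` (strict inequality).
#' Coordinates are normalized so that `start <= end` on both sequences
#' (minus-strand style rows are flipped); no other coordinate is altered and
#' row order is preserved.
#'
#' @param path Path to a whitespace/tab separated alignment table with at
#'   least 11 columns in outfmt-6 order. A zero-length file yields an empty
#'   table, not an error.
#' @param evalue_max Strict E-value cutoff (default 0.1).
#' @param drop_self If `TRUE`, rows where the query aligns to itself over the
#'   identical coordinates (`query_id == search_id`, equal envelopes) are
#'   dropped. Default keeps them.
#' @return A `data.table` with columns `aln_id` (input row number among
#'   retained rows is *not* used: `aln_id` numbers the retained rows in input
#'   order), `query_id`, `search_id`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`.
#' @export
read_alignment_table <- function(path, evalue_max = 0.1, drop_self = FALSE) {
  if (!file.exists(path)) stop("alignment table not found: ", path)
  if (file.size(path) == 0L) return(empty_alignments())
  raw <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = "character", fill = TRUE)
  if (ncol(raw) < 11L)
    stop("alignment table ", path, ": expected >= 11 outfmt-6 columns, got ",
         ncol(raw))
  aln <- data.table::data.table(
    query_id  = raw[[1L]],
    search_id = raw[[2L]],
    qstart    = suppressWarnings(as.integer(raw[[7L]])),
    qend      = suppressWarnings(as.integer(raw[[8L]])),
    sstart    = suppressWarnings(as.integer(raw[[9L]])),
    send      = suppressWarnings(as.integer(raw[[10L]])),
    evalue    = suppressWarnings(as.numeric(raw[[11L]]))
  )
  bad <- which(is.na(aln$qstart) | is.na(aln$qend) | is.na(aln$sstart) |
                 is.na(aln$send) | is.na(aln$evalue) |
                 pmin(aln$qstart, aln$qend, aln$sstart, aln$send) <= 0L |
                 aln$evalue < 0)
  if (length(bad))
    stop("alignment table ", path, ": malformed record at line ", bad[1L],
         " (non-numeric or non-positive coordinate, or negative E-value)")
  aln <- normalize_alignment_coords(aln)
  aln <- aln[evalue < evalue_max]
  if (drop_self)
    aln <- aln[!(query_id == search_id & qstart == sstart & qend == send)]
  aln[, aln_id := seq_len(.N)]
  data.table::setcolorder(aln, c("aln_id", "query_id", "search_id",
                                 "qstart", "qend", "sstart", "send", "evalue"))
  aln[]
}

empty_alignments <- function() {
  data.table::data.table(aln_id = integer(), query_id = character(),
                         search_id = character(), qstart = integer(),
                         qend = integer(), sstart = integer(),
                         send = integer(), evalue = numeric())
}

normalize_alignment_coords <- function(aln) {
  sw <- aln$qstart > aln$qend
  if (any(sw)) {
    tmp <- aln$qstart[sw]; aln$qstart[sw] <- aln$qend[sw]; aln$qend[sw] <- tmp
  }
  sw <- aln$sstart > aln$send
  if (any(sw)) {
    tmp <- aln$sstart[sw]; aln$sstart[sw] <- aln$send[sw]; aln$send[sw] <- tmp
  }
  aln
}

#' Write alignments back to a BLAST outfmt-6 table
#'
#' Emits the 12-column outfmt-6 dialect. Only the columns the pipeline
#' consumes (ids, envelope coordinates, E-value) are meaningful on re-read;
#' percent identity, lengths, mismatches, gap opens and bit scores are filled
#' with placeholders so the file stays structurally valid for other outfmt-6
#' consumers.
#'
#' @param aln Alignment table as returned by [read_alignment_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(aln, path) {
  out <- data.table::data.table(
    qseqid = aln$query_id, sseqid = aln$search_id,
    pident = "100.0",
    length = aln$qend - aln$qstart + 1L,
    mismatch = 0L, gapopen = 0L,
    qstart = aln$qstart, qend = aln$qend,
    sstart = aln$sstart, send = aln$send,
    evalue = formatC(aln$evalue, digits = 17, format = "g"),
    bitscore = round(pmax(0, -10 * log10(aln$evalue + 1e-300)), 1)
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Split alignments into per-query sets
#'
#' @param aln Alignment table.
#' @return Named list of `data.table`s, one per distinct `query_id`, in
#'   order of first appearance; every row of the input appears in exactly
#'   one element.
#' @export
group_by_query <- function(aln) {
  if (nrow(aln) == 0L) return(list())
  split(aln, by = "query_id", sorted = FALSE)
}

#' Deduplicate same-search-sequence alignments on one query
#'
#' Two alignments of the same query against the same search sequence whose
#' query regions lie closer than `mu1` are considered duplicates of the same
#' underlying match: only the one with the lowest E-value is retained.
#' Resolution is greedy in ascending E-value order (ties broken by input
#' order), so a retained alignment suppresses all same-search-sequence
#' alignments within `mu1` of it; for any two retained alignments with equal
#' `search_id` the query-region distance is therefore `>= mu1`.
#'
#' @param aln Alignment table for a single query.
#' @param mu1 Query-region distance radius in `(0, 1)`.
#' @return The retained subset, in the original row order.
#' @export
dedup_same_search <- function(aln, mu1 = 0.2) {
  stopifnot(mu1 > 0, mu1 < 1)
  n <- nrow(aln)
  if (n <= 1L) return(aln)
  if (length(unique(aln$query_id)) > 1L)
    stop("dedup_same_search(): alignments must share a single query_id")
  keep <- rep(TRUE, n)
  dup_sids <- aln[, .N, by = search_id][N > 1L, search_id]
  for (sid in dup_sids) {
    idx <- which(aln$search_id == sid)
    ord <- idx[order(aln$evalue[idx], idx)]
    kept <- integer(0)
    for (i in ord) {
      if (length(kept) &&
          any(region_distance(aln$qstart[i], aln$qend[i],
                              aln$qstart[kept], aln$qend[kept]) < mu1)) {
        keep[i] <- FALSE
      } else {
        kept <- c(kept, i)
      }
    }
  }
  aln[keep]
}
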