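#' Exact and splice-aware read mapping
#'
#' Desk-scale mapping with the two modes the survey needs: exact paired-end
#' placement of trimmed reads (no mismatch, indel, or splicing within a
#' read), and splice-aware single-end split mapping of untrimmed reads
#' against small two-gene references. Exactness is strict: an `N` base never
#' matches anything.
#'
#' @name mapper
NULL

#' Trim read pairs
#'
#' Two trimming modes feed the two mapping stages:
#' \describe{
#'   \item{`five_prime_30`}{both mates are cut to their 5'-most 30 bases,
#'     increasing the effective span of the pair.}
#'   \item{`dual_17`}{each mate (length >= 34) yields a synthetic pair of
#'     its first 17 bases and the reverse complement of its last 17 bases,
#'     mimicking the opposite-strand mate convention; read id provenance is
#'     kept in `orig_id`/`orig_mate` so the original read can be recovered.}
#' }
#' Too-short reads are skipped; the skip count is attached as attribute
#' `"skipped"`.
#'
#' @param pairs data.frame with `read_id`, `seq1`, `seq2` (and optional
#'   quality columns).
#' @param mode `"five_prime_30"` or `"dual_17"`.
#' @return data.frame of trimmed pairs; for `dual_17` one row per input
#'   mate with columns `read_id`, `orig_id`, `orig_mate`, `seq1`, `seq2`.
#' @export
trim_reads <- function(pairs, mode = c("five_prime_30", "dual_17")) {
  mode <- match.arg(mode)
  if (mode == "five_prime_30") {
    ok <- nchar(pairs$seq1) >= 30L & nchar(pairs$seq2) >= 30L
    out <- pairs[ok, , drop = FALSE]
    out$seq1 <- substr(out$seq1, 1L, 30L)
    out$seq2 <- substr(out$seq2, 1L, 30L)
    if (!is.null(out$qual1)) out$qual1 <- substr(out$qual1, 1L, 30L)
    if (!is.null(out$qual2)) out$qual2 <- substr(out$qual2, 1L, 30L)
    attr(out, "skipped") <- sum(!ok)
    return(out)
  }
  reads <- data.frame(
    orig_id = rep(pairs$read_id, 2L),
    orig_mate = rep(c(1L, 2L), each = nrow(pairs)),
    seq = c(pairs$seq1, pairs$seq2), stringsAsFactors = FALSE)
  ok <- nchar(reads$seq) >= 34L
  skipped <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  if (nrow(reads) == 0L) {
    out <- data.frame(read_id = character(0), orig_id = character(0),
                      orig_mate = integer(0), seq1 = character(0),
                      seq2 = character(0), stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  L <- nchar(reads$seq)
  out <- data.frame(
    read_id = paste0(reads$orig_id, ":", reads$orig_mate),
    orig_id = reads$orig_id, orig_mate = reads$orig_mate,
    seq1 = substr(reads$seq, 1L, 17L),
    seq2 = revcomp(substring(reads$seq, L - 16L, L)),
    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Build a k-mer index over a set of reference sequences
#'
#' Every position `0..L-k` of every contig is indexed; duplicate k-mers keep
#' all their positions.
#'
#' @param genome named character vector of contig sequences.
#' @param k k-mer size (>= 4, <= shortest contig). Defaults to 17 so the
#'   shortest query the pipeline produces is a single-k-mer lookup.
#' @return a `kmer_index` object.
#' @export
build_index <- function(genome, k = 17L) {
  k <- as.integer(k)
  if (k < 4L) stop_fmt("k must be >= 4")
  if (k > min(nchar(genome))) stop_fmt("k (%d) exceeds shortest contig length", k)
  tabs <- lapply(names(genome), function(cn) {
    s <- genome[[cn]]
    starts <- seq_len(nchar(s) - k + 1L)
    data.table::data.table(kmer = substring(s, starts, starts + k - 1L),
                           contig = cn, pos = starts - 1L)
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  structure(list(k = k, table = dt,
                 lengths = vapply(genome, nchar, integer(1))),
            class = "kmer_index")
}

# exact placements of a vector of reads on one strand sense; `seqs` are the
# query strings as they should appear on the '+' strand of the reference
exact_hits <- function(index, genome, seqs, ids, strand) {
  keep <- nchar(seqs) >= index$k & !grepl("N", seqs, fixed = TRUE)
  if (!any(keep)) return(NULL)
  q <- data.table::data.table(kmer = substr(seqs[keep], 1L, index$k),
                              qi = which(keep))
  cand <- index$table[q, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(cand) == 0L) return(NULL)
  len <- nchar(seqs)[cand$qi]
  fits <- cand$pos + len <= index$lengths[cand$contig]
  cand <- cand[fits]; len <- len[fits]
  if (nrow(cand) == 0L) return(NULL)
  ref <- substring(genome[cand$contig], cand$pos + 1L, cand$pos + len)
  hit <- ref == seqs[cand$qi]
  if (!any(hit)) return(NULL)
  data.frame(read_id = ids[cand$qi[hit]], contig = cand$contig[hit],
             start = cand$pos[hit], end = cand$pos[hit] + len[hit],
             strand = strand, stringsAsFactors = FALSE)
}

#' Map single-end reads exactly
#'
#' Places each read wherever it matches the reference exactly, on both
#' strands. Reads containing `N` are never placed.
#'
#' @param index a [build_index()] result.
#' @param genome the indexed reference.
#' @param reads data.frame with `read_id` and `seq`.
#' @return data.frame of placements `read_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `unique` (exactly one placement for
#'   that read).
#' @export
map_reads_exact <- function(index, genome, reads) {
  fwd <- exact_hits(index, genome, reads$seq, reads$read_id, "+")
  rev <- exact_hits(index, genome, revcomp(reads$seq), reads$read_id, "-")
  out <- rbind(fwd, rev)
  if (is.null(out))
    return(data.frame(read_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), unique = logical(0)))
  counts <- table(out$read_id)
  out$unique <- counts[out$read_id] == 1L
  out[order(out$read_id, out$contig, out$start), , drop = FALSE]
}

#' Map read pairs exactly (paired-end mode)
#'
#' Each mate is placed independently wherever it matches exactly on either
#' strand; all mate-1 x mate-2 placement combinations are reported, with
#' `unique` true for a mate with exactly one placement. No insert-size or
#' orientation constraint is applied.
#'
#' @inheritParams map_reads_exact
#' @param pairs data.frame with `read_id`, `seq1`, `seq2`.
#' @return data.frame of per-mate placements: `read_id`, `mate` (1 or 2),
#'   `contig`, `start`, `end`, `strand`, `unique`.
#' @export
map_pairs_exact <- function(index, genome, pairs) {
  m1 <- map_reads_exact(index, genome,
                        data.frame(read_id = pairs$read_id, seq = pairs$seq1))
  m2 <- map_reads_exact(index, genome,
                        data.frame(read_id = pairs$read_id, seq = pairs$seq2))
  if (nrow(m1)) m1$mate <- 1L
  if (nrow(m2)) m2$mate <- 2L
  out <- rbind(m1, m2)
  out[, c("read_id", "mate", "contig", "start", "end", "strand", "unique")]
}

#' Exact placements of one read pair
#'
#' Convenience wrapper returning every combination of mate placements for a
#' single pair.
#'
#' @inheritParams map_pairs_exact
#' @param pair one-row data.frame with `read_id`, `seq1`, `seq2`.
#' @return list of pair alignments, each a list with `mate1` and `mate2`
#'   placement rows; empty list when either mate is unmapped.
#' @export
map_pair_exact <- function(index, genome, pair) {
  pl <- map_pairs_exact(index, genome, pair[1L, , drop = FALSE])
  p1 <- pl[pl$mate == 1L, , drop = FALSE]
  p2 <- pl[pl$mate == 2L, , drop = FALSE]
  if (nrow(p1) == 0L || nrow(p2) == 0L) return(list())
  combos <- expand.grid(i = seq_len(nrow(p1)), j = seq_len(nrow(p2)))
  lapply(seq_len(nrow(combos)), function(r)
    list(mate1 = p1[combos$i[r], ], mate2 = p2[combos$j[r], ]))
}

common_prefix_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq)) neq[1L] - 1L else n
}

str_rev <- function(x) {
  vapply(x, function(s) rawToChar(rev(charToRaw(s))), "", USE.NAMES = FALSE)
}

# all occurrences (0-based) of `pat` in `subject`
find_all <- function(pat, subject) {
  m <- gregexpr(pat, subject, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Build a two-gene reference for spliced and fusion-point mapping
#'
#' Extracts each gene's span plus `flank` from the genome into a local
#' contig named after the gene, shifts the gene model into local
#' coordinates, and pre-builds the k-mer indexes used by split and exact
#' mapping.
#'
#' @param genome wild-type genome.
#' @param models named list of `gene_model`.
#' @param gene5,gene3 partner gene ids.
#' @param flank flanking sequence (nt) to include, default 1 kb.
#' @return a `pair_reference` list with `genome` (two local contigs),
#'   `models` (local coordinates), `offsets` (local-to-genomic shifts),
#'   and prebuilt indexes.
#' @export
build_pair_reference <- function(genome, models, gene5, gene3, flank = 1000L) {
  shift_model <- function(m, off) {
    ex <- m$exons; ex$start <- ex$start - off; ex$end <- ex$end - off
    cds <- m$cds
    if (!is.null(cds)) { cds$start <- cds$start - off; cds$end <- cds$end - off }
    dom <- m$domains
    if (!is.null(dom)) { dom$start <- dom$start - off; dom$end <- dom$end - off }
    gene_model(m$gene_id, m$gene_id, m$strand, ex, cds = cds, domains = dom)
  }
  take <- function(gid) {
    m <- models[[gid]]
    if (is.null(m)) stop_fmt("unknown gene '%s'", gid)
    sp <- model_span(m)
    start <- max(0L, sp$start - flank)
    end <- min(nchar(genome[[sp$contig]]), sp$end + flank)
    list(seq = seq_slice(genome[[sp$contig]], start, end),
         offset = start, model = shift_model(m, start), contig = sp$contig)
  }
  a <- take(gene5); b <- take(gene3)
  ref_genome <- stats::setNames(c(a$seq, b$seq), c(gene5, gene3))
  structure(list(
    genome = ref_genome,
    models = stats::setNames(list(a$model, b$model), c(gene5, gene3)),
    offsets = stats::setNames(c(a$offset, b$offset), c(gene5, gene3)),
    source_contigs = stats::setNames(c(a$contig, b$contig), c(gene5, gene3)),
    index17 = build_index(ref_genome, 17L),
    index8 = build_index(ref_genome, 8L)),
    class = "pair_reference")
}

# maximal exact prefix/suffix placements of `read` in `ref$genome`
max_prefix_hits <- function(ref, read, anchor_k = 8L) {
  L <- nchar(read)
  anchor <- substr(read, 1L, anchor_k)
  out <- list()
  for (cn in names(ref$genome)) {
    s <- ref$genome[[cn]]
    for (p in find_all(anchor, s)) {
      len <- common_prefix_len(read, substr(s, p + 1L, p + L))
      out[[length(out) + 1L]] <- data.frame(contig = cn, pos = p, len = len)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

max_suffix_hits <- function(ref, read, anchor_k = 8L) {
  L <- nchar(read)
  anchor <- substr(read, L - anchor_k + 1L, L)
  rread <- str_rev(read)
  out <- list()
  for (cn in names(ref$genome)) {
    s <- ref$genome[[cn]]
    for (p in find_all(anchor, s)) {
      hi <- p + anchor_k           # suffix match ends here (exclusive)
      lo <- max(0L, hi - L)
      len <- common_prefix_len(rread, str_rev(substr(s, lo + 1L, hi)))
      out[[length(out) + 1L]] <- data.frame(contig = cn, end = hi, len = len)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Splice-aware single-end mapping against a two-gene reference
#'
#' Decomposes the read into at most two exact segments. Same-contig
#' decompositions whose reference gap matches an annotated intron (segment
#' ends at annotated exon boundaries) are preferred, then unannotated gaps
#' of at least `min_gap`, then chimeric decompositions with segments in the
#' two different genes (annotated chimeric junctions rank with annotated
#' introns). Among equals the smallest gap wins. Both read orientations are
#' tried.
#'
#' @param ref a [build_pair_reference()] object.
#' @param read read sequence (character scalar).
#' @param min_segment minimum exact segment length, default 8.
#' @param min_gap minimum unannotated intron length, default 20.
#' @return `NULL` when no decomposition exists, else a list with `strand`,
#'   `chimeric`, `annotated`, `gap`, and `segments` (data.frame `contig`,
#'   `rstart`, `rend`, `qstart`, `qend`; query coordinates refer to the
#'   oriented read).
#' @export
map_single_spliced <- function(ref, read, min_segment = 8L, min_gap = 20L) {
  boundaries <- lapply(ref$models, function(m)
    list(ends = sort(unique(m$exons$end)), starts = sort(unique(m$exons$start))))
  try_orient <- function(seq, strand) {
    L <- nchar(seq)
    if (L < 2L * min_segment) return(NULL)
    P <- max_prefix_hits(ref, seq)
    if (is.null(P)) return(NULL)
    full <- P[P$len == L, , drop = FALSE]
    if (nrow(full)) {
      p <- full[1L, ]
      return(list(strand = strand, chimeric = FALSE, annotated = FALSE, gap = 0L,
                  segments = data.frame(contig = p$contig, rstart = p$pos,
                                        rend = p$pos + L, qstart = 0L, qend = L)))
    }
    S <- max_suffix_hits(ref, seq)
    if (is.null(S)) return(NULL)
    best <- NULL
    for (i in seq_len(nrow(P))) for (j in seq_len(nrow(S))) {
      pref <- P$len[i]; suf <- S$len[j]
      if (pref < min_segment || suf < min_segment) next
      x_lo <- max(min_segment, L - suf)
      x_hi <- min(pref, L - min_segment)
      if (x_lo > x_hi) next
      a <- P$pos[i]; bend <- S$end[j]
      same <- P$contig[i] == S$contig[j]
      gap <- if (same) bend - a - L else NA_integer_
      if (same && gap < 1L) next
      # annotated split: segment 1 ends at an exon end, segment 2 starts at
      # an exon start, for some admissible split x
      bd1 <- boundaries[[P$contig[i]]]$ends
      bd2 <- boundaries[[S$contig[j]]]$starts
      xs <- bd1[bd1 - a >= x_lo & bd1 - a <= x_hi] - a
      ann_x <- NA_integer_
      for (x in xs) {
        seg2start <- bend - suf + (x - (L - suf))
        if (seg2start %in% bd2) { ann_x <- x; break }
      }
      annotated <- !is.na(ann_x)
      if (!annotated && same && gap < min_gap) next
      if (!annotated && !same) next
      x <- if (annotated) ann_x else x_hi
      cand <- list(strand = strand, chimeric = !same, annotated = annotated,
                   gap = gap,
                   segments = data.frame(
                     contig = c(P$contig[i], S$contig[j]),
                     rstart = c(a, bend - suf + (x - (L - suf))),
                     rend = c(a + x, bend),
                     qstart = c(0L, x), qend = c(x, L)))
      rank <- function(c) c(!c$annotated, if (is.na(c$gap)) Inf else c$gap)
      if (is.null(best) ||
          isTRUE(rank(cand)[1L] < rank(best)[1L]) ||
          (rank(cand)[1L] == rank(best)[1L] && rank(cand)[2L] < rank(best)[2L]))
        best <- cand
    }
    best
  }
  res <- try_orient(read, "+")
  if (!is.null(res) && res$annotated) return(res)
  res_rev <- try_orient(revcomp(read), "-")
  pick <- function(a, b) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    ra <- c(!a$annotated, if (is.na(a$gap)) Inf else a$gap)
    rb <- c(!b$annotated, if (is.na(b$gap)) Inf else b$gap)
    if (rb[1L] < ra[1L] || (rb[1L] == ra[1L] && rb[2L] < ra[2L])) b else a
  }
  pick(res, res_rev)
}
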