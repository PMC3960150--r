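#' Breakpoint evidence: coverage, junction reads, fusion-point mapping
#'
#' The per-candidate evidence stack: per-nucleotide coverage with exon-level
#' discontinuity detection, chimeric splice-junction read counting,
#' DNA-level fusion-point read recovery via dual-17-nt trimmed pairs, and
#' split-read breakpoint resolution with micro-homology. A short identical
#' sequence shared by the two partners at the breakpoint (micro-homology)
#' makes the exact break coordinate ambiguous within an interval of that
#' length; the resolver reports the homology length and the two
#' truth-containing break intervals.
#'
#' @name breakpoint
NULL

#' Per-base coverage over a region
#'
#' @param placements alignment placements (`contig`, `start`, `end`).
#' @param contig region contig.
#' @param start,end region bounds (0-based half-open).
#' @return integer vector of length `end - start`; element i is the number
#'   of aligned segments covering base `start + i - 1`.
#' @export
compute_coverage <- function(placements, contig, start, end) {
  L <- end - start
  delta <- numeric(L + 1L)
  p <- placements[placements$contig == contig & placements$end > start &
                    placements$start < end, , drop = FALSE]
  if (nrow(p)) {
    s <- pmax(p$start, start) - start
    e <- pmin(p$end, end) - start
    ds <- table(s + 1L); de <- table(e + 1L)
    delta[as.integer(names(ds))] <- delta[as.integer(names(ds))] + as.numeric(ds)
    delta[as.integer(names(de))] <- delta[as.integer(names(de))] - as.numeric(de)
  }
  as.integer(cumsum(delta)[seq_len(L)])
}

#' Locate an abrupt coverage discontinuity between exons
#'
#' Mean depth is computed per exon (in transcription order); the first
#' inter-exon boundary where one side's mean is at least `min_depth` and
#' the other side's mean falls below `side / ratio` is reported as the
#' suspected break intron.
#'
#' @param placements alignment placements used for coverage.
#' @param model the gene's `gene_model`.
#' @param ratio fold drop that counts as a discontinuity (default 10).
#' @param min_depth minimal mean depth of the expressed side (default 5).
#' @return 1-based intron index (in transcription order) of the first
#'   discontinuity, or `NA_integer_` if none.
#' @export
locate_discontinuity <- function(placements, model, ratio = 10, min_depth = 5) {
  ex <- model$exons
  if (nrow(ex) < 2L) stop_fmt("need >= 2 exons")
  means <- vapply(seq_len(nrow(ex)), function(i)
    mean(compute_coverage(placements, model$contig, ex$start[i], ex$end[i])),
    numeric(1))
  for (i in seq_len(length(means) - 1L)) {
    a <- means[i]; b <- means[i + 1L]
    if ((a >= min_depth && b < a / ratio) || (b >= min_depth && a < b / ratio))
      return(i)
  }
  NA_integer_
}

#' Count reads spanning a chimeric splice junction
#'
#' Reads are split-mapped against the two-gene reference with
#' [map_single_spliced()]; a read is counted when its two segments end at
#' the 5' junction exon end and start at the 3' junction exon start, with
#' at least `min_overhang` exact bases on each side.
#'
#' @param reads data.frame with `read_id` and `seq` (untrimmed reads).
#' @param ref a [build_pair_reference()] object.
#' @param junction list with `contig5`, `end5`, `contig3`, `start3`: the
#'   junction exon boundaries in local pair-reference coordinates.
#' @param min_overhang minimum exact overhang on each side, default 8.
#' @return list with `count`, `min_overhang_observed`, `read_ids`.
#' @export
find_junction_reads <- function(reads, ref, junction, min_overhang = 8L) {
  hits <- character(0)
  overhangs <- integer(0)
  # a read crossing the junction with min_overhang exact bases on each side
  # necessarily contains this window verbatim (exact mapping) — cheap screen
  window <- paste0(
    seq_slice(ref$genome[[junction$contig5]],
              junction$end5 - min_overhang, junction$end5),
    seq_slice(ref$genome[[junction$contig3]],
              junction$start3, junction$start3 + min_overhang))
  screen <- grepl(window, reads$seq, fixed = TRUE) |
    grepl(revcomp(window), reads$seq, fixed = TRUE)
  reads <- reads[screen, , drop = FALSE]
  for (i in seq_len(nrow(reads))) {
    al <- map_single_spliced(ref, reads$seq[i], min_segment = min_overhang)
    if (is.null(al) || nrow(al$segments) != 2L) next
    s <- al$segments
    crosses <- s$contig[1L] == junction$contig5 && s$rend[1L] == junction$end5 &&
      s$contig[2L] == junction$contig3 && s$rstart[2L] == junction$start3
    if (!crosses) next
    oh <- min(s$qend - s$qstart)
    if (oh < min_overhang) next
    hits <- c(hits, reads$read_id[i])
    overhangs <- c(overhangs, oh)
  }
  list(count = length(hits),
       min_overhang_observed = if (length(overhangs)) min(overhangs) else NA_integer_,
       read_ids = hits)
}

point_in <- function(pos_start, pos_end, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(FALSE, length(pos_start)))
  vapply(seq_along(pos_start), function(i)
    any(intervals$start < pos_end[i] & intervals$end > pos_start[i]), logical(1))
}

# full containment: the aligned end must lie inside the interval, not merely
# touch it — an exonic 17-mer that pokes a coincidental base into the intron
# is an exonic (spliced) read, not intronic evidence
contained_in <- function(pos_start, pos_end, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(FALSE, length(pos_start)))
  vapply(seq_along(pos_start), function(i)
    any(intervals$start <= pos_start[i] & pos_end[i] <= intervals$end), logical(1))
}

#' Recover DNA-level fusion-point candidate reads
#'
#' Each original read is trimmed to its two 17-nt ends ([trim_reads()]
#' `dual_17` mode) and the resulting synthetic pair is mapped exactly on
#' the two-gene reference. The original read is retained when (1) its two
#' ends align to different genes, (2) either end aligns wholly within a
#' suspected break intron (an exonic end that merely touches the intron by
#' a coincidental base is spliced-transcript evidence, not intronic), and
#' (3) neither end aligns to a masked (repeat-annotated) region.
#'
#' @param reads data.frame with `read_id`, `seq`, and an `origin` tag
#'   (`rnaseq`, `exome_tumor`, `exome_normal`).
#' @param ref a [build_pair_reference()] object.
#' @param suspected named list (by gene id) of data.frames `start`, `end`:
#'   suspected break introns in local pair-reference coordinates.
#' @param repeats optional data.frame `contig`, `start`, `end` of masked
#'   intervals in local pair-reference coordinates.
#' @return subset of `reads` passing all three criteria.
#' @export
map_fusion_point_reads <- function(reads, ref, suspected, repeats = NULL) {
  if (nrow(reads) == 0L) return(reads[0L, , drop = FALSE])
  L <- nchar(reads$seq)
  pairs17 <- data.frame(read_id = reads$read_id,
                        seq1 = substr(reads$seq, 1L, 17L),
                        seq2 = revcomp(substring(reads$seq, L - 16L, L)),
                        stringsAsFactors = FALSE)
  ok <- nchar(reads$seq) >= 34L
  pairs17 <- pairs17[ok, , drop = FALSE]
  pl <- map_pairs_exact(ref$index17, ref$genome, pairs17)
  pl_by_read <- split(pl, factor(pl$read_id, levels = pairs17$read_id))
  keep <- vapply(pairs17$read_id, function(id) {
    p <- pl_by_read[[id]]
    p1 <- p[p$mate == 1L, , drop = FALSE]
    p2 <- p[p$mate == 2L, , drop = FALSE]
    if (nrow(p1) == 0L || nrow(p2) == 0L) return(FALSE)
    # (1) some placement combination puts the two ends in different genes
    diff_gene <- any(outer(p1$contig, p2$contig, "!="))
    if (!diff_gene) return(FALSE)
    # (2) either end aligns wholly within a suspected break intron
    in_intron <- FALSE
    for (g in names(suspected)) {
      sub <- p[p$contig == g, , drop = FALSE]
      if (nrow(sub) && any(contained_in(sub$start, sub$end, suspected[[g]])))
        in_intron <- TRUE
    }
    if (!in_intron) return(FALSE)
    # (3) neither end aligns to a masked region
    if (!is.null(repeats) && nrow(repeats)) {
      for (g in unique(p$contig)) {
        sub <- p[p$contig == g, , drop = FALSE]
        msk <- repeats[repeats$contig == g, , drop = FALSE]
        if (nrow(msk) && any(point_in(sub$start, sub$end, msk))) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  reads[ok, , drop = FALSE][keep, , drop = FALSE]
}

#' Resolve the DNA-level breakpoint and its micro-homology
#'
#' Each candidate read is decomposed into its longest exact prefix within
#' the 5' gene region and longest exact suffix within the 3' gene region
#' (both orientations tried). The overlap of the two maximal extensions
#' defines the micro-homology length `h` and the two break intervals of
#' width `h` (each containing the true break). Per-read calls are
#' aggregated by majority, ties going to the widest interval; supporting
#' reads are tallied by origin and the somatic flag is set when tumor
#' support exists without normal-exome support.
#'
#' @param cand_reads candidate reads (`read_id`, `seq`, `origin`) from
#'   [map_fusion_point_reads()].
#' @param ref a [build_pair_reference()] for the gene pair (gene5 first).
#' @param min_support minimal supporting reads to call a fusion point,
#'   default 2.
#' @return a `breakpoint_call` list: `gene5`, `gene3`, `break5`, `break3`
#'   (genomic 0-based intervals of width `homology`), `homology`,
#'   `support` (reads by source), `somatic`, `n_reads`.
#' @export
resolve_breakpoint <- function(cand_reads, ref, min_support = 2L) {
  if (nrow(cand_reads) == 0L) stop_fmt("no confident fusion point: no candidate reads")
  g5 <- names(ref$genome)[1L]; g3 <- names(ref$genome)[2L]
  s5 <- ref$genome[[g5]]; s3 <- ref$genome[[g3]]
  origins <- cand_reads$origin %||% rep("unknown", nrow(cand_reads))
  calls <- list()
  for (i in seq_len(nrow(cand_reads))) {
    for (orient in c("+", "-")) {
      read <- if (orient == "+") cand_reads$seq[i] else revcomp(cand_reads$seq[i])
      L <- nchar(read)
      if (L < 34L) next
      best <- NULL
      for (p in find_all(substr(read, 1L, 17L), s5)) {
        pref <- common_prefix_len(read, substr(s5, p + 1L, p + L))
        for (q in find_all(substr(read, L - 16L, L), s3)) {
          hi <- q + 17L
          lo <- max(0L, hi - L)
          suf <- common_prefix_len(str_rev(read), str_rev(substr(s3, lo + 1L, hi)))
          if (pref + suf < L) next
          h <- pref + suf - L
          cand <- list(h = h,
                       b5 = c(p + L - suf, p + pref),
                       b3 = c(hi - suf, hi - suf + h))
          if (is.null(best) || cand$h < best$h) best <- cand
        }
      }
      if (!is.null(best)) {
        calls[[length(calls) + 1L]] <-
          data.frame(read_id = cand_reads$read_id[i],
                     origin = origins[i],
                     h = best$h, b5s = best$b5[1L], b5e = best$b5[2L],
                     b3s = best$b3[1L], b3e = best$b3[2L],
                     stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (!length(calls))
    stop_fmt("no confident fusion point: no read decomposes into two exact segments")
  calls <- do.call(rbind, calls)
  key <- paste(calls$h, calls$b5s, calls$b3s)
  tab <- sort(table(key), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {  # ties -> widest interval
    hs <- calls$h[match(top, key)]
    top <- top[which.max(hs)]
  }
  sup <- calls[key == top, , drop = FALSE]
  if (nrow(sup) < min_support)
    stop_fmt("no confident fusion point: support %d below minimum %d", nrow(sup), min_support)
  one <- sup[1L, ]
  off5 <- ref$offsets[[g5]]; off3 <- ref$offsets[[g3]]
  support <- c(tumor_rna = sum(sup$origin == "rnaseq"),
               tumor_exome = sum(sup$origin == "exome_tumor"),
               normal_exome = sum(sup$origin == "exome_normal"))
  structure(list(
    gene5 = g5, gene3 = g3,
    break5 = c(one$b5s + off5, one$b5e + off5),
    break3 = c(one$b3s + off3, one$b3e + off3),
    homology = one$h, support = support,
    somatic = support[["normal_exome"]] == 0L &&
      (support[["tumor_rna"]] + support[["tumor_exome"]]) > 0L,
    n_reads = nrow(sup)), class = "breakpoint_call")
}
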