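#' Discordant read pairs and fusion-candidate scoring
#'
#' A discordant read pair is a paired-end fragment whose two mates map
#' uniquely to two different genes. Candidate gene pairs are scored with
#' expression-normalized support statistics:
#' \describe{
#'   \item{SPER}{discordant-pair support per million mapped pairs,
#'     `inter / M * 1e6`.}
#'   \item{DASPER}{SPER minus the expression-based expectation: with
#'     `p_G = intra_G / M` (floored at `1/M`), the expected discordant
#'     count for pair (A,B) is `D_tot * p_A p_B / sum(p_X p_Y)` over all
#'     candidates, and DASPER = SPER - expected/M * 1e6.}
#'   \item{RESPER}{SPER relative to the mean SPER over all candidates in
#'     the sample.}
#' }
#' All three are invariant under proportional scaling of the counts.
#'
#' @name fusion-scoring
NULL

assign_genes <- function(placements, models) {
  spans <- do.call(rbind, lapply(models, function(m) {
    sp <- model_span(m)
    data.frame(gene = m$gene_id, contig = sp$contig, start = sp$start,
               end = sp$end, stringsAsFactors = FALSE)
  }))
  if (nrow(placements) == 0L) return(character(0))
  q <- GenomicRanges::GRanges(placements$contig,
                              IRanges::IRanges(placements$start + 1L, placements$end))
  s <- GenomicRanges::GRanges(spans$contig, IRanges::IRanges(spans$start + 1L, spans$end))
  ov <- GenomicRanges::findOverlaps(q, s, select = "first")
  ifelse(is.na(ov), NA_character_, spans$gene[ov])
}

#' Collect discordant read pairs and per-gene read counts
#'
#' A pair is discordant iff both mates map uniquely and their enclosing
#' genes differ. Uniquely mapped mates of non-discordant pairs that overlap
#' a gene increment that gene's intra count; mates outside any gene, or
#' with multiple placements, are left unassigned.
#'
#' @param placements per-mate placements from [map_pairs_exact()].
#' @param models named list of `gene_model`.
#' @return list with `discordant` (data.frame `read_id`, `gene_m1`,
#'   `gene_m2`), `intra` (named integer, reads per gene), and `stats`
#'   (mate bookkeeping: `mapped_mates`, `unassigned_mates`,
#'   `mapped_pairs`).
#' @export
collect_discordant_pairs <- function(placements, models) {
  uniq <- placements[placements$unique, , drop = FALSE]
  uniq$gene <- assign_genes(uniq, models)
  g1 <- uniq[uniq$mate == 1L, c("read_id", "gene")]
  g2 <- uniq[uniq$mate == 2L, c("read_id", "gene")]
  both <- merge(g1, g2, by = "read_id", suffixes = c("_m1", "_m2"))
  disc <- both[!is.na(both$gene_m1) & !is.na(both$gene_m2) &
                 both$gene_m1 != both$gene_m2, , drop = FALSE]
  disc_mates <- paste0(rep(disc$read_id, 2L), ":", rep(1:2, each = nrow(disc)))
  uniq_key <- paste0(uniq$read_id, ":", uniq$mate)
  intra_mates <- uniq[!is.na(uniq$gene) & !(uniq_key %in% disc_mates), , drop = FALSE]
  intra <- stats::setNames(integer(length(models)), names(models))
  tab <- table(intra_mates$gene)
  intra[names(tab)] <- as.integer(tab)
  mapped_mates <- length(unique(paste0(placements$read_id, ":", placements$mate)))
  m1_ids <- unique(placements$read_id[placements$mate == 1L])
  m2_ids <- unique(placements$read_id[placements$mate == 2L])
  mapped_pairs <- length(intersect(m1_ids, m2_ids))
  unassigned <- mapped_mates - sum(intra) - 2L * nrow(disc)
  list(discordant = disc, intra = intra,
       stats = list(mapped_mates = mapped_mates, unassigned_mates = unassigned,
                    mapped_pairs = mapped_pairs))
}

#' Classify the geometry of a candidate gene pair
#'
#' @param geneA,geneB gene ids.
#' @param models named list of `gene_model`.
#' @return one of `"inter"` (different contigs), `"read-through"` (adjacent,
#'   same strand), `"cis"` (adjacent, opposite strands), `"intra"` (same
#'   contig, not adjacent). Adjacent means no annotated gene lies between
#'   the two on their contig.
#' @export
classify_fusion_type <- function(geneA, geneB, models) {
  ma <- models[[geneA]]; mb <- models[[geneB]]
  if (is.null(ma) || is.null(mb)) stop_fmt("unknown gene in pair %s,%s", geneA, geneB)
  sa <- model_span(ma); sb <- model_span(mb)
  if (sa$contig != sb$contig) return("inter")
  on_contig <- Filter(function(m) model_span(m)$contig == sa$contig, models)
  ord <- names(on_contig)[order(vapply(on_contig, function(m) model_span(m)$start, numeric(1)))]
  adjacent <- abs(match(geneA, ord) - match(geneB, ord)) == 1L
  if (!adjacent) return("intra")
  if (sa$strand == sb$strand) "read-through" else "cis"
}

#' Aggregate discordant pairs into fusion candidates
#'
#' Pairs are grouped by unordered gene pair; the reported 5'/3' orientation
#' is the majority mate-1 gene, ties broken lexicographically.
#'
#' @param disc discordant pairs from [collect_discordant_pairs()].
#' @param intra named per-gene read counts.
#' @param models named list of `gene_model`.
#' @param sample_id sample label carried into the candidate table.
#' @return data.frame with one row per candidate: `gene1`, `gene2`,
#'   `sample`, `fusion_type`, `inter_reads`, `intra_reads_1`,
#'   `intra_reads_2`.
#' @export
make_candidates <- function(disc, intra, models, sample_id = "sample1") {
  if (nrow(disc) == 0L)
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      sample = character(0), fusion_type = character(0),
                      inter_reads = integer(0), intra_reads_1 = integer(0),
                      intra_reads_2 = integer(0), stringsAsFactors = FALSE))
  key <- ifelse(disc$gene_m1 < disc$gene_m2,
                paste(disc$gene_m1, disc$gene_m2, sep = "\r"),
                paste(disc$gene_m2, disc$gene_m1, sep = "\r"))
  rows <- lapply(split(disc, key), function(d) {
    pair <- sort(c(d$gene_m1[1L], d$gene_m2[1L]))
    votes_first <- sum(d$gene_m1 == pair[1L])
    g1 <- if (votes_first * 2L >= nrow(d)) pair[1L] else pair[2L]
    g2 <- setdiff(pair, g1)
    data.frame(gene1 = g1, gene2 = g2, sample = sample_id,
               fusion_type = classify_fusion_type(g1, g2, models),
               inter_reads = nrow(d),
               intra_reads_1 = unname(intra[g1]),
               intra_reads_2 = unname(intra[g2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score fusion candidates (SPER, DASPER, RESPER)
#'
#' @param candidates candidate table from [make_candidates()].
#' @param M total mapped pairs in the sample.
#' @return the candidate table with `SPER`, `DASPER`, `RESPER` columns.
#' @export
score_candidates <- function(candidates, M) {
  if (M <= 0) stop_fmt("total mapped pairs M must be positive")
  if (nrow(candidates) == 0L) {
    candidates$SPER <- candidates$DASPER <- candidates$RESPER <- numeric(0)
    return(candidates)
  }
  sper <- candidates$inter_reads / M * 1e6
  p1 <- pmax(candidates$intra_reads_1, 1L) / M
  p2 <- pmax(candidates$intra_reads_2, 1L) / M
  d_tot <- sum(candidates$inter_reads)
  w <- p1 * p2
  expected <- d_tot * w / sum(w)
  candidates$SPER <- sper
  candidates$DASPER <- sper - expected / M * 1e6
  candidates$RESPER <- sper / mean(sper)
  candidates
}

#' Filter and sort scored candidates
#'
#' Retains candidates with `DASPER > dasper` and `RESPER > resper` (strict
#' inequalities) and sorts by RESPER descending; ties are broken by
#' `inter_reads` descending, then by gene-pair name.
#'
#' @param candidates scored candidate table.
#' @param dasper,resper score thresholds, both defaulting to 1.0.
#' @return filtered, sorted candidate table.
#' @export
threshold_filter <- function(candidates, dasper = 1.0, resper = 1.0) {
  keep <- candidates$DASPER > dasper & candidates$RESPER > resper
  out <- candidates[keep, , drop = FALSE]
  pair <- paste(out$gene1, out$gene2)
  out <- out[order(-out$RESPER, -out$inter_reads, pair), , drop = FALSE]
  rownames(out) <- NULL
  out
}
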