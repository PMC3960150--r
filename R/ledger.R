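#' Candidate exclusion ledger
#'
#' Scored candidates are passed through a staged rule set that mirrors how
#' a fusion survey triages its top candidates: previously reported fusions
#' are set aside as known; candidates whose partners sit inside or near a
#' high-level amplicon are excluded as likely passenger by-products of the
#' amplification; adjacent same-strand pairs joined by an annotated
#' transcript are excluded as misannotation artifacts; fusions that break
#' the 3' partner's reading frame are excluded; candidates with no
#' chimeric junction-spanning reads are excluded. Everything else is
#' retained.
#'
#' @name candidate-ledger
NULL

#' Estimate copy number from exome coverage
#'
#' Mean per-base depth is computed in fixed windows; each window's fold is
#' its mean depth divided by the genome-wide median window depth.
#'
#' @param placements exome read placements (from [map_pairs_exact()] or
#'   [map_reads_exact()]).
#' @param genome the reference the placements refer to.
#' @param window window size in bp (default 10 kb).
#' @return data.frame `contig`, `start`, `end`, `fold`.
#' @export
estimate_copy_number <- function(placements, genome, window = 10000L) {
  if (nrow(placements) == 0L) stop_fmt("insufficient coverage: no aligned reads")
  rows <- lapply(names(genome), function(cn) {
    L <- nchar(genome[[cn]])
    starts <- seq(0L, L - 1L, by = window)
    ends <- pmin(starts + window, L)
    p <- placements[placements$contig == cn, , drop = FALSE]
    depth <- numeric(L)
    if (nrow(p)) {
      delta <- numeric(L + 1L)
      ds <- table(pmax(p$start, 0L) + 1L)
      de <- table(pmin(p$end, L) + 1L)
      delta[as.integer(names(ds))] <- delta[as.integer(names(ds))] + as.numeric(ds)
      delta[as.integer(names(de))] <- delta[as.integer(names(de))] - as.numeric(de)
      depth <- cumsum(delta)[seq_len(L)]
    }
    means <- vapply(seq_along(starts), function(i)
      mean(depth[(starts[i] + 1L):ends[i]]), numeric(1))
    data.frame(contig = cn, start = starts, end = ends, mean_depth = means,
               stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, rows)
  med <- stats::median(track$mean_depth)
  if (med <= 0) stop_fmt("insufficient coverage: median window depth is zero")
  track$fold <- track$mean_depth / med
  track[, c("contig", "start", "end", "fold")]
}

#' Flag a candidate as amplicon-associated
#'
#' @param gene1,gene2 candidate partner gene ids.
#' @param models named list of `gene_model`.
#' @param track copy-number track from [estimate_copy_number()].
#' @param radius distance (bp) around each gene span to search, default 1 Mb.
#' @param fold_threshold minimal window fold counted as amplification,
#'   default 3.0 (splits high-level 6-12-fold amplicons from tolerated
#'   sub-2-fold gains).
#' @return logical: does either gene's span, expanded by `radius`, overlap
#'   a window with fold at or above the threshold?
#' @export
flag_amplicon <- function(gene1, gene2, models, track, radius = 1e6,
                          fold_threshold = 3.0) {
  hot <- track[track$fold >= fold_threshold, , drop = FALSE]
  if (nrow(hot) == 0L) return(FALSE)
  any(vapply(c(gene1, gene2), function(g) {
    sp <- model_span(models[[g]])
    any(hot$contig == sp$contig & hot$start < sp$end + radius &
          hot$end > sp$start - radius)
  }, logical(1)))
}

#' Flag a candidate as an annotation artifact
#'
#' An adjacent same-strand pair is a suspected misannotation when the
#' annotation set carries a transcript joining the two gene ids (supplied
#' as a joining-transcript table, standing in for EST evidence).
#'
#' @param geneA,geneB candidate partner gene ids.
#' @param models named list of `gene_model`.
#' @param joining data.frame with columns `gene_a`, `gene_b` listing gene
#'   pairs spanned by a single annotated transcript.
#' @return logical.
#' @export
flag_misannotation <- function(geneA, geneB, models, joining) {
  if (classify_fusion_type(geneA, geneB, models) != "read-through") return(FALSE)
  if (is.null(joining) || nrow(joining) == 0L) return(FALSE)
  any((joining$gene_a == geneA & joining$gene_b == geneB) |
        (joining$gene_a == geneB & joining$gene_b == geneA))
}

#' Check reading-frame preservation across a fusion junction
#'
#' The junction is in frame when the summed 5'-side CDS length modulo 3
#' complements the start phase of the first 3'-side CDS interval, i.e. the
#' 3' partner's native codons (and hence its named domains) are preserved.
#' Retained domains are the 3' partner's domains lying wholly downstream of
#' the junction, reported only for in-frame fusions.
#'
#' @param fused a fused `gene_model` carrying `junction_exon5` (number of
#'   retained 5'-partner exons) and CDS phases.
#' @return list with `in_frame`, `junction_phase` (phase of the first 3'
#'   CDS interval), and `retained_domains` (character vector).
#' @export
check_frame <- function(fused) {
  if (is.null(fused$cds)) stop_fmt("no coding model for '%s'", fused$gene_id)
  j <- fused$junction_exon5
  if (is.null(j)) stop_fmt("fused model lacks junction bookkeeping")
  ex5 <- fused$exons[seq_len(j), , drop = FALSE]
  in5 <- vapply(seq_len(nrow(fused$cds)), function(i)
    any(ex5$start <= fused$cds$start[i] & fused$cds$end[i] <= ex5$end), logical(1))
  len5 <- sum(fused$cds$end[in5] - fused$cds$start[in5])
  cds3 <- fused$cds[!in5, , drop = FALSE]
  if (nrow(cds3) == 0L) stop_fmt("no coding model downstream of the junction")
  p3 <- cds3$phase[1L]
  in_frame <- (len5 %% 3L) == ((3L - p3) %% 3L)
  retained <- character(0)
  if (in_frame && !is.null(fused$domains)) {
    j3_start <- min(cds3$start)
    keep <- fused$domains$start >= j3_start
    retained <- fused$domains$name[keep]
  }
  list(in_frame = in_frame, junction_phase = p3, retained_domains = retained)
}

#' Apply the staged exclusion rules to scored candidates
#'
#' Rules are applied in order: known fusion (set aside), amplicon,
#' misannotation, off-frame, no junction reads; a candidate passing all
#' rules is retained. A candidate triggering several rules is excluded
#' whichever order is used; the reported reason is the first in the stated
#' order.
#'
#' @param candidates scored candidate table (needs `gene1`, `gene2`,
#'   `sample`).
#' @param evidence list with elements keyed by `"gene1:gene2:sample"`:
#'   `known` (character vector of known `"gene1:gene2"` pairs),
#'   `amplicon` (named logical), `misannotation` (named logical),
#'   `in_frame` (named logical), `junction_reads` (named integer). Every
#'   candidate must be covered by each named element.
#' @return data.frame: the candidates plus `status`
#'   (`retained`/`excluded`/`set_aside_known`) and `reason`.
#' @export
apply_ledger <- function(candidates, evidence) {
  if (nrow(candidates) == 0L) {
    candidates$status <- candidates$reason <- character(0)
    return(candidates)
  }
  key <- paste(candidates$gene1, candidates$gene2, candidates$sample, sep = ":")
  pair <- paste(candidates$gene1, candidates$gene2, sep = ":")
  need <- function(field) {
    v <- evidence[[field]]
    miss <- setdiff(key, names(v))
    if (length(miss))
      stop_fmt("missing %s evidence for candidate %s", field, miss[1L])
    v[key]
  }
  known <- pair %in% (evidence$known %||% character(0))
  amplicon <- need("amplicon")
  misann <- need("misannotation")
  in_frame <- need("in_frame")
  jreads <- need("junction_reads")
  status <- rep("retained", nrow(candidates))
  reason <- rep("", nrow(candidates))
  set <- function(cond, st, rs) {
    hit <- cond & status == "retained" & reason == ""
    status[hit] <<- st; reason[hit] <<- rs
  }
  set(known, "set_aside_known", "known fusion")
  set(amplicon, "excluded", "amplicon")
  set(misann, "excluded", "misannotation")
  set(!in_frame, "excluded", "off-frame")
  set(jreads == 0L, "excluded", "no junction reads")
  candidates$status <- status
  candidates$reason <- reason
  candidates
}

#' Worked exclusion-ledger example from a published GBM survey
#'
#' Loads the bundled top-20 fusion-candidate table from a glioblastoma
#' RNA-seq fusion survey (with the evidence labels the survey reported:
#' amplicon association, misannotation, frame status, junction-read
#' support, known-fusion status) and runs it through [apply_ledger()].
#'
#' @return list with `candidates` (the encoded table), `ledger` (the
#'   [apply_ledger()] output), and summary counts: `n_after_primary`
#'   (candidates left after the known-fusion set-aside and the amplicon and
#'   misannotation exclusions), `n_final` (retained after all rules), and
#'   `final_pairs`.
#' @export
gbm_survey_example <- function() {
  path <- system.file("extdata", "gbm_top20_candidates.tsv",
                      package = "fusionsurvey", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(sample = "character"))
  key <- paste(tab$gene1, tab$gene2, tab$sample, sep = ":")
  evidence <- list(
    known = unique(paste(tab$gene1, tab$gene2, sep = ":")[tab$evidence == "known"]),
    amplicon = stats::setNames(tab$evidence == "amplicon", key),
    misannotation = stats::setNames(tab$evidence == "misannotation", key),
    in_frame = stats::setNames(tab$evidence != "off_frame", key),
    junction_reads = stats::setNames(ifelse(tab$evidence == "no_junction", 0L, 1L), key))
  ledger <- apply_ledger(tab, evidence)
  primary <- c("known fusion", "amplicon", "misannotation")
  list(candidates = tab, ledger = ledger,
       n_after_primary = sum(!ledger$reason %in% primary),
       n_final = sum(ledger$status == "retained"),
       final_pairs = paste(ledger$gene1[ledger$status == "retained"],
                           ledger$gene2[ledger$status == "retained"], sep = ":"))
}
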