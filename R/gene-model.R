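#' Gene models
#'
#' A gene model is a list with fields:
#' \describe{
#'   \item{gene_id}{unique identifier}
#'   \item{contig, strand}{location; strand is `"+"` or `"-"`}
#'   \item{exons}{data.frame `start`, `end` (0-based half-open, genomic
#'     coordinates) in transcription order: ascending start for `"+"`
#'     genes, descending for `"-"` genes}
#'   \item{cds}{optional data.frame `start`, `end`, `phase` — exonic
#'     sub-intervals in transcription order; `phase` is the number of bases
#'     at the 5' end of the interval that complete the codon begun in the
#'     previous CDS interval (GFF convention, in `0:2`)}
#'   \item{domains}{optional data.frame `name`, `start`, `end` — named CDS
#'     sub-intervals such as "transmembrane" or "kinase"}
#' }
#'
#' @name gene-model
NULL

#' Construct and validate a gene model
#'
#' @param gene_id gene identifier.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame `start`, `end` in transcription order.
#' @param cds optional CDS data.frame `start`, `end`, `phase`.
#' @param domains optional domain data.frame `name`, `start`, `end`.
#' @return a validated `gene_model` list.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds = NULL, domains = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- data.frame(start = as.integer(exons$start), end = as.integer(exons$end))
  if (any(exons$end <= exons$start)) stop_fmt("gene '%s': exon with end <= start", gene_id)
  ord <- order(exons$start)
  if (any(exons$start[ord][-1L] < exons$end[ord][-nrow(exons)]))
    stop_fmt("gene '%s': overlapping exons", gene_id)
  expected <- if (strand == "+") order(exons$start) else order(-exons$start)
  if (!identical(expected, seq_len(nrow(exons))))
    stop_fmt("gene '%s': exons not in transcription order for strand %s", gene_id, strand)
  if (!is.null(cds)) {
    cds <- data.frame(start = as.integer(cds$start), end = as.integer(cds$end),
                      phase = as.integer(cds$phase))
    if (any(!cds$phase %in% 0:2)) stop_fmt("gene '%s': CDS phase outside 0:2", gene_id)
    within <- vapply(seq_len(nrow(cds)), function(i)
      any(exons$start <= cds$start[i] & cds$end[i] <= exons$end), logical(1))
    if (!all(within)) stop_fmt("gene '%s': CDS interval outside exons", gene_id)
  }
  if (!is.null(domains)) {
    domains <- data.frame(name = as.character(domains$name),
                          start = as.integer(domains$start),
                          end = as.integer(domains$end))
    if (is.null(cds)) stop_fmt("gene '%s': domains require a CDS", gene_id)
    within <- vapply(seq_len(nrow(domains)), function(i)
      any(cds$start <= domains$start[i] & domains$end[i] <= cds$end), logical(1))
    if (!all(within)) stop_fmt("gene '%s': domain interval outside CDS", gene_id)
  }
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons, cds = cds, domains = domains),
            class = "gene_model")
}

#' Genomic span of a gene model
#'
#' @param model a `gene_model`.
#' @return list with `contig`, `start`, `end`, `strand` (0-based half-open).
#' @export
model_span <- function(model) {
  list(contig = model$contig, start = min(model$exons$start),
       end = max(model$exons$end), strand = model$strand)
}

#' Spliced transcript sequence (mRNA, 5' to 3')
#'
#' Concatenates exon sequences in transcription order, reverse-complementing
#' minus-strand genes.
#'
#' @param genome named character vector of contigs.
#' @param model a `gene_model`.
#' @return character scalar.
#' @export
splice_transcript <- function(genome, model) {
  seq <- genome[[model$contig]]
  parts <- seq_slice(seq, model$exons$start, model$exons$end)
  if (model$strand == "-") parts <- revcomp(parts)
  paste(parts, collapse = "")
}

#' Unspliced pre-mRNA sequence (5' to 3')
#'
#' @inheritParams splice_transcript
#' @return character scalar spanning the gene including introns.
#' @export
unspliced_transcript <- function(genome, model) {
  sp <- model_span(model)
  s <- seq_slice(genome[[model$contig]], sp$start, sp$end)
  if (model$strand == "-") s <- revcomp(s)
  s
}

#' Summed exonic length of a gene model
#'
#' @param model a `gene_model`.
#' @return integer scalar.
#' @export
exonic_length <- function(model) {
  sum(model$exons$end - model$exons$start)
}

#' Read gene models from a GTF file
#'
#' GTF coordinates (1-based inclusive) are converted to internal 0-based
#' half-open intervals; exon and CDS rows are ordered in transcription order
#' (reversed relative to genomic order for minus-strand genes). Optional
#' `domain` feature rows with a `domain_id` attribute populate the model's
#' named domains.
#'
#' @param path GTF file path.
#' @return named list of `gene_model` objects.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop_fmt("GTF file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop_fmt("malformed GTF '%s': %s", path, conditionMessage(e)))
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   phase = if ("phase" %in% names(S4Vectors::mcols(gr)))
                     as.integer(gr$phase) else NA_integer_,
                   gene_id = as.character(gr$gene_id),
                   domain_id = if ("domain_id" %in% names(S4Vectors::mcols(gr)))
                     as.character(gr$domain_id) else NA_character_,
                   stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-")))
    stop_fmt("GTF '%s': unknown strand '%s'", path, df$strand[!df$strand %in% c("+", "-")][1L])
  models <- lapply(split(df, df$gene_id), function(g) {
    strand <- g$strand[1L]
    tx_order <- function(d) d[order(if (strand == "+") d$start else -d$start), , drop = FALSE]
    ex <- tx_order(g[g$type == "exon", c("start", "end")])
    cds <- g[g$type == "CDS", c("start", "end", "phase")]
    cds <- if (nrow(cds)) tx_order(cds) else NULL
    dom <- g[g$type == "domain", c("domain_id", "start", "end")]
    dom <- if (nrow(dom)) {
      names(dom)[1L] <- "name"
      dom[order(dom$start), , drop = FALSE]
    } else NULL
    gene_model(g$gene_id[1L], g$contig[1L], strand, ex, cds = cds, domains = dom)
  })
  models[order(vapply(models, function(m) min(m$exons$start), integer(1)))]
}

#' Write gene models to a GTF file
#'
#' @param models list of `gene_model` objects.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- data.frame(type = "exon", start = m$exons$start, end = m$exons$end,
                     phase = NA_integer_, domain_id = NA_character_)
    cd <- if (!is.null(m$cds))
      data.frame(type = "CDS", start = m$cds$start, end = m$cds$end,
                 phase = m$cds$phase, domain_id = NA_character_)
    dm <- if (!is.null(m$domains))
      data.frame(type = "domain", start = m$domains$start, end = m$domains$end,
                 phase = NA_integer_, domain_id = m$domains$name)
    out <- rbind(ex, cd, dm)
    out$contig <- m$contig
    out$strand <- m$strand
    out$gene_id <- m$gene_id
    out
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$contig, df$start, df$type), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand,
    source = "fusionsurvey", type = df$type, score = NA_real_,
    phase = df$phase, gene_id = df$gene_id)
  if (any(!is.na(df$domain_id))) gr$domain_id <- df$domain_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
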