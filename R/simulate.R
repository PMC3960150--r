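#' Synthetic reference, fusion, read, and cohort generators
#'
#' Every generator is a pure function of its configuration and seed: the
#' caller's RNG state is saved and restored, and identical inputs produce
#' byte-identical outputs. The generators emulate the data a fusion survey
#' consumes: a multi-gene genome with stranded multi-exon gene models and CDS
#' phase bookkeeping, a somatic DNA-level fusion joining a 5' partner's
#' leading exons to a 3' partner's trailing exons (with configurable
#' junction micro-homology), RNA-seq fragments dominated by spliced mRNA
#' with a small pre-mRNA fraction, exome fragments restricted to exons plus
#' flanks, and cohort expression matrices with planted outliers and
#' signature-shifted samples.
#'
#' @name simgen
NULL

#' Simulation configuration
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes to place on the reference contig.
#' @param exons_per_gene exon count per gene.
#' @param exon_len,intron_len,intergenic_len length ranges (2-vectors) for
#'   exons, introns and intergenic gaps, in nucleotides.
#' @param read_len read length (nt).
#' @param insert_mean,insert_sd fragment insert-size distribution.
#' @param n_pairs read pairs per simulated sample.
#' @param premrna_fraction probability a fragment is drawn from the
#'   unspliced pre-mRNA instead of the mature transcript.
#' @param exome_flank exon flank (nt) captured by the exome protocol.
#' @param expression_weights optional named per-gene sampling weights.
#' @param base_error per-base substitution error rate.
#' @param kinase_genes gene ids whose trailing exons receive named
#'   "transmembrane" and "kinase" domains.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 8L, exons_per_gene = 4L,
                       exon_len = c(150L, 300L), intron_len = c(300L, 600L),
                       intergenic_len = c(400L, 800L), read_len = 76L,
                       insert_mean = 200, insert_sd = 20, n_pairs = 2000L,
                       premrna_fraction = 0.01, exome_flank = 100L,
                       expression_weights = NULL, base_error = 0,
                       kinase_genes = NULL) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
              intergenic_len = as.integer(intergenic_len),
              read_len = as.integer(read_len), insert_mean = insert_mean,
              insert_sd = insert_sd, n_pairs = as.integer(n_pairs),
              premrna_fraction = premrna_fraction,
              exome_flank = as.integer(exome_flank),
              expression_weights = expression_weights,
              base_error = base_error, kinase_genes = kinase_genes)
  with(cfg, {
    if (n_genes < 1L || exons_per_gene < 2L) stop_fmt("need >= 1 gene with >= 2 exons")
    if (any(c(exon_len, intron_len, intergenic_len, read_len) <= 0L))
      stop_fmt("all lengths must be positive")
    if (premrna_fraction < 0 || premrna_fraction > 1)
      stop_fmt("premrna_fraction must be a probability")
    if (insert_mean < read_len)
      stop_fmt("insert_mean (%s) below read length (%d) is infeasible", insert_mean, read_len)
  })
  cfg
}

cum_phases <- function(lens) {
  cum <- c(0L, cumsum(lens))[seq_along(lens)]
  as.integer((3L - cum %% 3L) %% 3L)
}

#' Generate a reference genome and gene models
#'
#' Genes are laid left to right on one contig with alternating strands (so
#' both strands are represented), every exon coding with cumulative CDS
#' phases. Genes listed in `kinase_genes` get a "transmembrane" domain on
#' their second-to-last exon and a "kinase" domain on their last exon (in
#' transcription order).
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector) and `models`
#'   (named list of `gene_model`).
#' @export
make_reference <- function(config) {
  with_seed(config$seed, {
    rlen <- function(rng) sample(seq(rng[1L], rng[2L]), 1L)
    models <- vector("list", config$n_genes)
    pos <- 0L
    strands <- rep(c("+", "-"), length.out = config$n_genes)
    for (i in seq_len(config$n_genes)) {
      pos <- pos + rlen(config$intergenic_len)
      ex_starts <- integer(config$exons_per_gene)
      ex_ends <- integer(config$exons_per_gene)
      for (j in seq_len(config$exons_per_gene)) {
        if (j > 1L) pos <- pos + rlen(config$intron_len)
        ex_starts[j] <- pos
        pos <- pos + rlen(config$exon_len)
        ex_ends[j] <- pos
      }
      exons <- data.frame(start = ex_starts, end = ex_ends)
      strand <- strands[i]
      if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
      lens <- exons$end - exons$start
      cds <- data.frame(start = exons$start, end = exons$end, phase = cum_phases(lens))
      gid <- paste0("g", i)
      domains <- NULL
      if (gid %in% (config$kinase_genes %||% character(0))) {
        k <- nrow(exons)
        domains <- data.frame(name = c("transmembrane", "kinase"),
                              start = c(exons$start[k - 1L], exons$start[k]),
                              end = c(exons$end[k - 1L], exons$end[k]))
        domains <- domains[order(domains$start), , drop = FALSE]
      }
      models[[i]] <- gene_model(gid, "chr1", strand, exons, cds = cds, domains = domains)
    }
    pos <- pos + rlen(config$intergenic_len)
    genome <- c(chr1 = random_dna(pos))
    names(models) <- vapply(models, `[[`, "", "gene_id")
    list(genome = genome, models = models)
  })
}

#' Describe a fusion event to plant
#'
#' @param gene5,gene3 ids of the 5' and 3' partner genes.
#' @param intron5,intron3 1-based index (in transcription order) of the
#'   intron carrying the DNA break in each partner.
#' @param homology micro-homology length `h >= 0`: the `h` bases immediately
#'   5' of each break are made identical between the partners, so the exact
#'   break coordinate is ambiguous within an interval of width `h`.
#' @param somatic logical; a somatic event is absent from the matched
#'   normal genome.
#' @return a `fusion_spec` list.
#' @export
fusion_spec <- function(gene5, gene3, intron5 = 2L, intron3 = 1L,
                        homology = 0L, somatic = TRUE) {
  stopifnot(homology >= 0L)
  list(gene5 = gene5, gene3 = gene3, intron5 = as.integer(intron5),
       intron3 = as.integer(intron3), homology = as.integer(homology),
       somatic = isTRUE(somatic))
}

intron_interval <- function(model, idx) {
  if (model$strand != "+") stop_fmt("fusion construction requires '+'-strand partners")
  if (idx < 1L || idx >= nrow(model$exons))
    stop_fmt("gene '%s' has no intron %d", model$gene_id, idx)
  c(model$exons$end[idx], model$exons$start[idx + 1L])
}

#' Plant a DNA-level fusion and derive the fused gene model
#'
#' Constructs a tumor genome that carries an extra contig (`"fusion"`)
#' joining the 5' partner's sequence through its break intron to the 3'
#' partner's sequence from its break intron onward. Break positions are
#' chosen inside the requested introns such that exactly `h` bases
#' immediately 5' of the two breaks are identical (and the flanking bases
#' differ), giving the junction a micro-homology of exactly `h`. The
#' wild-type contigs are retained in the tumor genome, mimicking a
#' heterozygous somatic rearrangement.
#'
#' @param genome wild-type genome.
#' @param models wild-type gene models.
#' @param fspec a [fusion_spec()].
#' @return list with `tumor_genome`, `fused_model` (on contig `"fusion"`,
#'   with `junction_exon5` recording the count of retained 5'-partner
#'   exons), and `truth` (exact break coordinates, homology, fused
#'   transcript sequence).
#' @export
apply_fusion <- function(genome, models, fspec) {
  m5 <- models[[fspec$gene5]]; m3 <- models[[fspec$gene3]]
  if (is.null(m5) || is.null(m3)) stop_fmt("unknown fusion partner gene")
  h <- fspec$homology
  i5 <- intron_interval(m5, fspec$intron5)
  i3 <- intron_interval(m3, fspec$intron3)
  if (h > min(i5[2L] - i5[1L], i3[2L] - i3[1L]))
    stop_fmt("micro-homology %d exceeds flanking intron length", h)
  s5 <- genome[[m5$contig]]; s3 <- genome[[m3$contig]]
  pad <- 10L
  b5_range <- seq(i5[1L] + pad, i5[2L] - pad)
  b3_lo <- i3[1L] + pad; b3_hi <- i3[2L] - pad
  mid <- ceiling(length(b5_range) / 2)
  scan_order <- b5_range[order(abs(seq_along(b5_range) - mid))]
  found <- NULL
  intron3_seq <- seq_slice(s3, i3[1L], i3[2L])
  for (b5 in scan_order) {
    ctx <- seq_slice(s5, b5 - h, b5)
    if (h > 0L) {
      hits <- gregexpr(ctx, intron3_seq, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      b3s <- i3[1L] + (hits - 1L) + h
    } else {
      b3s <- seq(b3_lo, b3_hi)
    }
    b3s <- b3s[b3s >= b3_lo & b3s <= b3_hi]
    for (b3 in b3s) {
      fwd_stop <- seq_slice(s3, b3, b3 + 1L) != seq_slice(s5, b5, b5 + 1L)
      back_stop <- seq_slice(s3, b3 - h - 1L, b3 - h) != seq_slice(s5, b5 - h - 1L, b5 - h)
      if (fwd_stop && back_stop) { found <- c(b5, b3); break }
    }
    if (!is.null(found)) break
  }
  if (is.null(found))
    stop_fmt("could not construct a junction with micro-homology %d in the requested introns", h)
  b5 <- found[1L]; b3 <- found[2L]
  sp5 <- model_span(m5); sp3 <- model_span(m3)
  left <- seq_slice(s5, sp5$start, b5)
  right <- seq_slice(s3, b3, sp3$end)
  fusion_seq <- paste0(left, right)
  jt <- b5 - sp5$start  # tumor-contig coordinate where the 3' side begins
  shift3 <- jt - b3
  keep5 <- seq_len(fspec$intron5)
  keep3 <- seq(fspec$intron3 + 1L, nrow(m3$exons))
  ex <- rbind(
    data.frame(start = m5$exons$start[keep5] - sp5$start,
               end = m5$exons$end[keep5] - sp5$start),
    data.frame(start = m3$exons$start[keep3] + shift3,
               end = m3$exons$end[keep3] + shift3))
  pick_cds <- function(cds, exons_kept, shift) {
    if (is.null(cds)) return(NULL)
    keep <- vapply(seq_len(nrow(cds)), function(i)
      any(exons_kept$start <= cds$start[i] & cds$end[i] <= exons_kept$end), logical(1))
    out <- cds[keep, , drop = FALSE]
    out$start <- out$start + shift; out$end <- out$end + shift
    out
  }
  cds <- rbind(pick_cds(m5$cds, m5$exons[keep5, ], -sp5$start),
               pick_cds(m3$cds, m3$exons[keep3, ], shift3))
  dom <- NULL
  if (!is.null(m3$domains)) {
    keep <- m3$domains$start >= min(m3$exons$start[keep3])
    if (any(keep)) {
      dom <- m3$domains[keep, , drop = FALSE]
      dom$start <- dom$start + shift3; dom$end <- dom$end + shift3
    }
  }
  fused <- gene_model(paste0(fspec$gene5, "-", fspec$gene3), "fusion", "+",
                      ex, cds = cds, domains = dom)
  fused$junction_exon5 <- length(keep5)
  tumor <- c(genome, fusion = fusion_seq)
  jx_mrna <- sum(m5$exons$end[keep5] - m5$exons$start[keep5])
  truth <- list(spec = fspec, break5 = b5, break3 = b3,
                contig5 = m5$contig, contig3 = m3$contig,
                junction_tumor = jt, junction_mrna = jx_mrna,
                homology = h,
                fused_transcript = splice_transcript(tumor, fused))
  list(tumor_genome = tumor, fused_model = fused, truth = truth)
}

apply_base_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1L]]
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

draw_fragments <- function(templates, tpl_idx, config) {
  n <- length(tpl_idx)
  rl <- config$read_len
  lens <- nchar(templates)[tpl_idx]
  insert <- pmax(rl, round(stats::rnorm(n, config$insert_mean, config$insert_sd)))
  insert <- pmin(insert, lens)
  start <- floor(stats::runif(n, 0, lens - insert + 1))
  frag <- substring(templates[tpl_idx], start + 1L, start + insert)
  mate1 <- substr(frag, 1L, rl)
  mate2 <- revcomp(substring(frag, insert - rl + 1L, insert))
  flip <- stats::runif(n) < 0.5
  tmp <- mate1[flip]; mate1[flip] <- mate2[flip]; mate2[flip] <- tmp
  list(start = start, insert = insert,
       mate1 = apply_base_errors(mate1, config$base_error),
       mate2 = apply_base_errors(mate2, config$base_error),
       flipped = flip)
}

#' Simulate paired-end RNA-seq reads
#'
#' Each fragment is drawn from a transcript chosen proportionally to its
#' expression weight; with probability `premrna_fraction` the unspliced
#' pre-mRNA is the template. Insert sizes are normal, truncated below at the
#' read length and above at the template length. The library is unstranded:
#' mates are swapped with probability one half. Genes whose mature
#' transcript is shorter than the read length are skipped with a warning.
#'
#' @param genome genome the models refer to (tumor genome when a fused
#'   model is included).
#' @param models named list of `gene_model` (may include a fused model).
#' @param config a [sim_config()]; `expression_weights` selects per-gene
#'   abundance (default: equal weights).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `pairs` (data.frame `read_id`, `seq1`, `seq2`,
#'   `origin`) and `truth` (template gene, template kind, fragment
#'   coordinates, junction-spanning flags when a `junction` attribute is
#'   supplied via a fused model's truth).
#' @export
simulate_rnaseq <- function(genome, models, config, seed = config$seed) {
  weights <- config$expression_weights %||%
    stats::setNames(rep(1, length(models)), names(models))
  weights <- weights[names(models)]
  weights[is.na(weights)] <- 0
  if (sum(weights) <= 0) stop_fmt("expression weights must sum to a positive value")
  mrna <- vapply(models, function(m) splice_transcript(genome, m), "")
  premrna <- vapply(models, function(m) unspliced_transcript(genome, m), "")
  short <- nchar(mrna) < config$read_len
  if (any(short & weights > 0)) {
    warning(sprintf("skipping %d gene(s) with transcript shorter than the read length",
                    sum(short & weights > 0)))
    weights[short] <- 0
  }
  with_seed(seed, {
    n <- config$n_pairs
    gene_idx <- sample.int(length(models), n, replace = TRUE, prob = weights)
    pre <- stats::runif(n) < config$premrna_fraction
    pre <- pre & nchar(premrna)[gene_idx] >= config$read_len
    templates <- ifelse(pre, premrna[gene_idx], mrna[gene_idx])
    fr <- draw_fragments(templates, seq_len(n), config)
    ids <- sprintf("rna%05d", seq_len(n))
    pairs <- data.frame(read_id = ids, seq1 = fr$mate1, seq2 = fr$mate2,
                        origin = "rnaseq", stringsAsFactors = FALSE)
    truth <- data.frame(read_id = ids, gene = names(models)[gene_idx],
                        template = ifelse(pre, "premrna", "mrna"),
                        tstart = fr$start, insert = fr$insert,
                        flipped = fr$flipped, stringsAsFactors = FALSE)
    list(pairs = pairs, truth = truth)
  })
}

#' Capture windows of the exome protocol
#'
#' @param models named list of `gene_model`.
#' @param flank flank length (nt) added to both sides of every exon.
#' @param genome genome, used to clip windows at contig ends.
#' @return data.frame `contig`, `start`, `end` of merged windows.
#' @export
exome_windows <- function(models, flank, genome) {
  win <- do.call(rbind, lapply(models, function(m)
    data.frame(contig = m$contig,
               start = pmax(0L, m$exons$start - flank),
               end = pmin(nchar(genome[[m$contig]]), m$exons$end + flank))))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    win$contig, IRanges::IRanges(win$start + 1L, win$end)))
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Simulate paired-end exome reads
#'
#' Fragments are drawn uniformly from the capture windows (exons plus
#' `exome_flank` on the supplied genome, merged across overlaps), fully
#' contained in a window. For a somatic fusion the caller passes the tumor
#' genome and models for `tissue = "tumor"` and the wild-type genome and
#' models for `tissue = "normal"`.
#'
#' @inheritParams simulate_rnaseq
#' @param tissue `"tumor"` or `"normal"`; tags read ids and origin.
#' @return list with `pairs` and `truth` (window and fragment coordinates).
#' @export
simulate_exome <- function(genome, models, config, tissue = c("tumor", "normal"),
                           seed = config$seed) {
  tissue <- match.arg(tissue)
  win <- exome_windows(models, config$exome_flank, genome)
  templates <- seq_slice(genome[win$contig], win$start, win$end)
  with_seed(seed + ifelse(tissue == "tumor", 101L, 202L), {
    n <- config$n_pairs
    w_idx <- sample.int(nrow(win), n, replace = TRUE, prob = win$end - win$start)
    fr <- draw_fragments(templates, w_idx, config)
    ids <- sprintf("ex%s%05d", substr(tissue, 1, 1), seq_len(n))
    pairs <- data.frame(read_id = ids, seq1 = fr$mate1, seq2 = fr$mate2,
                        origin = paste0("exome_", tissue), stringsAsFactors = FALSE)
    truth <- data.frame(read_id = ids, contig = win$contig[w_idx],
                        gstart = win$start[w_idx] + fr$start,
                        insert = fr$insert, flipped = fr$flipped,
                        stringsAsFactors = FALSE)
    list(pairs = pairs, truth = truth)
  })
}

#' Simulate a cohort expression matrix
#'
#' Produces a log2-scale genes-by-samples matrix: baseline values are
#' `N(baseline, noise_sd)`; samples in `activated` are shifted by
#' `direction * log2(fold)` on the signature genes; samples in
#' `outlier_samples` receive `outlier_shift` on `outlier_gene`.
#'
#' @param n_samples,n_genes matrix dimensions; genes are named `g1..gN`,
#'   samples `s1..sM`.
#' @param signature optional data.frame `gene`, `direction` (+1/-1).
#' @param activated sample names (or indices) shifted along the signature.
#' @param fold linear fold change applied to signature genes.
#' @param noise_sd log2-scale noise standard deviation.
#' @param baseline log2-scale baseline mean.
#' @param outlier_samples,outlier_gene,outlier_shift planted single-gene
#'   expression outliers.
#' @param seed RNG seed.
#' @return numeric matrix (genes x samples) on log2 scale.
#' @export
simulate_cohort_expression <- function(n_samples, n_genes, signature = NULL,
                                       activated = character(0), fold = 2,
                                       noise_sd = 0.5, baseline = 6,
                                       outlier_samples = character(0),
                                       outlier_gene = NULL, outlier_shift = 6,
                                       seed = 1L) {
  with_seed(seed, {
    genes <- paste0("g", seq_len(n_genes))
    samples <- paste0("s", seq_len(n_samples))
    m <- matrix(stats::rnorm(n_genes * n_samples, baseline, noise_sd),
                nrow = n_genes, dimnames = list(genes, samples))
    if (is.numeric(activated)) activated <- samples[activated]
    if (!is.null(signature) && length(activated) && fold != 1) {
      sig_gene <- as.character(signature$gene)
      m[sig_gene, activated] <- m[sig_gene, activated] +
        signature$direction * log2(fold)
    }
    if (is.numeric(outlier_samples)) outlier_samples <- samples[outlier_samples]
    if (length(outlier_samples) && !is.null(outlier_gene))
      m[outlier_gene, outlier_samples] <- m[outlier_gene, outlier_samples] + outlier_shift
    m
  })
}
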