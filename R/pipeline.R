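#' Pipeline orchestration
#'
#' Three stage-groups tie the modules together: the survey (trim, exact
#' paired-end mapping, discordant-pair collection, scoring, thresholding),
#' the exclusion ledger, and per-candidate validation (coverage
#' discontinuity, junction reads, fusion-point mapping, breakpoint
#' resolution, frame check, somatic status). All stages are deterministic
#' given config and seed.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Collects file paths, thresholds (every printed survey default is
#' surfaced: DASPER/RESPER cutoffs 1.0, trim lengths 30/17 nt, 1 kb gene
#' flanks, 1 Mb amplicon radius), and the seed.
#'
#' @param genome,gtf,fq1,fq2 input paths.
#' @param repeats,joining,known_fusions optional evidence paths.
#' @param dasper,resper score thresholds.
#' @param flank gene flank (nt) for pair references.
#' @param radius,fold_threshold amplicon rule parameters.
#' @param min_overhang junction-read overhang.
#' @param ratio,min_depth discontinuity parameters.
#' @param min_support minimal fusion-point support.
#' @param seed integer seed.
#' @param sample_id sample label.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genome = NULL, gtf = NULL, fq1 = NULL, fq2 = NULL,
                            repeats = NULL, joining = NULL, known_fusions = NULL,
                            dasper = 1.0, resper = 1.0, flank = 1000L,
                            radius = 1e6, fold_threshold = 3.0,
                            min_overhang = 8L, ratio = 10, min_depth = 5,
                            min_support = 2L, seed = 1L, sample_id = "sample1") {
  cfg <- as.list(environment())
  stopifnot(dasper > 0, resper > 0, flank > 0, radius > 0, fold_threshold > 0,
            min_overhang > 0, ratio > 0, min_depth > 0, min_support > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys match [pipeline_config()] arguments.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

check_input <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop_fmt("survey stage: missing %s file '%s'", what, path %||% "(unset)")
  path
}

write_manifest <- function(path, inputs, params) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    parameters = params)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the fusion survey stage
#'
#' Trims reads to their 5'-most 30 nt, maps them exactly in paired-end
#' mode, collects discordant pairs, scores candidates, and applies the
#' DASPER/RESPER thresholds. Stage read counts are logged to stderr and a
#' run manifest (input hashes and parameters) accompanies the outputs.
#'
#' @param config a [pipeline_config()] with `genome`, `gtf`, `fq1`, `fq2`.
#' @param outdir optional output directory for `candidates.tsv` and
#'   `manifest.json`.
#' @return invisible list with `candidates` (filtered, sorted), `scored`
#'   (all scored candidates), `stats`, and `intra` counts.
#' @export
run_survey <- function(config, outdir = NULL) {
  genome <- read_fasta(check_input(config$genome, "genome FASTA"))
  models <- read_gtf(check_input(config$gtf, "annotation GTF"))
  pairs <- read_fastq_pairs(check_input(config$fq1, "FASTQ mate 1"),
                            check_input(config$fq2, "FASTQ mate 2"))
  message(sprintf("survey: %d input pairs", nrow(pairs)))
  trimmed <- trim_reads(pairs, "five_prime_30")
  message(sprintf("survey: %d pairs after trimming (%d skipped)",
                  nrow(trimmed), attr(trimmed, "skipped")))
  index <- build_index(genome, 17L)
  placements <- map_pairs_exact(index, genome, trimmed)
  coll <- collect_discordant_pairs(placements, models)
  message(sprintf("survey: %d mapped pairs, %d discordant",
                  coll$stats$mapped_pairs, nrow(coll$discordant)))
  cands <- make_candidates(coll$discordant, coll$intra, models, config$sample_id)
  scored <- if (nrow(cands)) score_candidates(cands, coll$stats$mapped_pairs) else cands
  filtered <- if (nrow(scored))
    threshold_filter(scored, config$dasper, config$resper)
  else scored
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(filtered, file.path(outdir, "candidates.tsv"))
    write_manifest(file.path(outdir, "manifest.json"),
                   list(genome = config$genome, gtf = config$gtf,
                        fq1 = config$fq1, fq2 = config$fq2),
                   list(dasper = config$dasper, resper = config$resper,
                        seed = config$seed, sample_id = config$sample_id))
  }
  invisible(list(candidates = filtered, scored = scored,
                 stats = coll$stats, intra = coll$intra,
                 placements = placements))
}

#' Run the exclusion-ledger stage
#'
#' @param candidates scored candidate table.
#' @param evidence evidence bundle, see [apply_ledger()].
#' @param out_path optional TSV path; retained candidates are listed first.
#' @return the ledger data.frame.
#' @export
run_ledger <- function(candidates, evidence, out_path = NULL) {
  ledger <- apply_ledger(candidates, evidence)
  ord <- order(ledger$status != "retained")
  ledger <- ledger[ord, , drop = FALSE]
  rownames(ledger) <- NULL
  if (!is.null(out_path)) write_tsv(ledger, out_path)
  ledger
}

# virtual fused model (transcript bookkeeping only) joining the 5' partner
# through intron `i5` to the 3' partner after intron `i3`
fuse_models <- function(m5, m3, i5, i3) {
  take <- function(m, idx) {
    ex <- m$exons[idx, , drop = FALSE]
    cds <- m$cds
    if (!is.null(cds)) {
      keep <- vapply(seq_len(nrow(cds)), function(i)
        any(ex$start <= cds$start[i] & cds$end[i] <= ex$end), logical(1))
      cds <- cds[keep, , drop = FALSE]
    }
    dom <- m$domains
    if (!is.null(dom)) {
      keep <- vapply(seq_len(nrow(dom)), function(i)
        any(ex$start <= dom$start[i] & dom$end[i] <= ex$end), logical(1))
      dom <- if (any(keep)) dom[keep, , drop = FALSE] else NULL
    }
    list(ex = ex, cds = cds, dom = dom)
  }
  part5 <- take(m5, seq_len(i5))
  part3 <- take(m3, seq(i3 + 1L, nrow(m3$exons)))
  # lay exons head-to-tail on a virtual contig with 100-nt gaps; for
  # minus-strand sources use exon lengths in transcription order
  lay <- function(parts, pos0) {
    shift_tab <- list(); pos <- pos0
    ex_out <- NULL
    for (i in seq_len(nrow(parts$ex))) {
      len <- parts$ex$end[i] - parts$ex$start[i]
      shift <- pos - parts$ex$start[i]
      ex_out <- rbind(ex_out, data.frame(start = pos, end = pos + len))
      shift_tab[[i]] <- c(parts$ex$start[i], parts$ex$end[i], shift)
      pos <- pos + len + 100L
    }
    remap <- function(tab) {
      if (is.null(tab)) return(NULL)
      out <- tab
      for (i in seq_len(nrow(tab))) {
        for (s in shift_tab) {
          if (tab$start[i] >= s[1L] && tab$end[i] <= s[2L]) {
            out$start[i] <- tab$start[i] + s[3L]
            out$end[i] <- tab$end[i] + s[3L]
            break
          }
        }
      }
      out
    }
    list(ex = ex_out, cds = remap(parts$cds), dom = remap(parts$dom), pos = pos)
  }
  l5 <- lay(part5, 0L)
  l3 <- lay(part3, l5$pos)
  fused <- gene_model(paste0(m5$gene_id, "-", m3$gene_id), "virtual", "+",
                      rbind(l5$ex, l3$ex),
                      cds = rbind(l5$cds, l3$cds),
                      domains = rbind(l5$dom, l3$dom))
  fused$junction_exon5 <- i5
  fused
}

explode_pairs <- function(pairs, origin) {
  data.frame(read_id = c(paste0(pairs$read_id, "/1"), paste0(pairs$read_id, "/2")),
             seq = c(pairs$seq1, pairs$seq2),
             origin = origin, stringsAsFactors = FALSE)
}

#' Run the per-candidate validation stage
#'
#' For a retained candidate gene pair, assembles the evidence stack:
#' per-exon coverage discontinuity in both partners, chimeric
#' splice-junction reads, DNA-level fusion-point reads (dual-17 trimming,
#' repeat masking), breakpoint resolution with micro-homology, somatic
#' status from matched exome reads, and the reading-frame report. When no
#' fusion-point read survives, the DNA/RNA level is reported as
#' `"undetermined"` (junction evidence only).
#'
#' @param genome wild-type genome.
#' @param models wild-type gene models.
#' @param gene5,gene3 candidate partner gene ids (5' first).
#' @param rna_pairs tumor RNA-seq pairs (data.frame `read_id`, `seq1`,
#'   `seq2`).
#' @param exome_tumor_pairs,exome_normal_pairs optional exome pairs.
#' @param repeats optional masked intervals (`contig`, `start`, `end`,
#'   genomic coordinates).
#' @param config a [pipeline_config()] supplying thresholds.
#' @param intron5,intron3 optional break-intron overrides; by default the
#'   suspected introns are located from the coverage discontinuity.
#' @param out_path optional JSON report path.
#' @return a validation report list.
#' @export
run_validation <- function(genome, models, gene5, gene3, rna_pairs,
                           exome_tumor_pairs = NULL, exome_normal_pairs = NULL,
                           repeats = NULL, config = pipeline_config(),
                           intron5 = NULL, intron3 = NULL, out_path = NULL) {
  m5 <- models[[gene5]]; m3 <- models[[gene3]]
  if (is.null(m5) || is.null(m3)) stop_fmt("validation stage: unknown gene pair")
  index <- build_index(genome, 17L)
  trimmed <- trim_reads(rna_pairs, "five_prime_30")
  placements <- map_pairs_exact(index, genome, trimmed)
  upl <- placements[placements$unique, , drop = FALSE]
  d5 <- locate_discontinuity(upl, m5, config$ratio, config$min_depth)
  d3 <- locate_discontinuity(upl, m3, config$ratio, config$min_depth)
  i5 <- intron5 %||% d5
  i3 <- intron3 %||% d3
  ref <- build_pair_reference(genome, models, gene5, gene3, config$flank)
  junction_count <- 0L
  junction <- NULL
  frame <- NULL
  if (!is.na(i5) && !is.na(i3)) {
    lm5 <- ref$models[[gene5]]; lm3 <- ref$models[[gene3]]
    junction <- list(contig5 = gene5, end5 = lm5$exons$end[i5],
                     contig3 = gene3, start3 = lm3$exons$start[i3 + 1L])
    jr <- find_junction_reads(explode_pairs(rna_pairs, "rnaseq"), ref, junction,
                              config$min_overhang)
    junction_count <- jr$count
    frame <- check_frame(fuse_models(m5, m3, i5, i3))
  }
  singles <- explode_pairs(rna_pairs, "rnaseq")
  if (!is.null(exome_tumor_pairs))
    singles <- rbind(singles, explode_pairs(exome_tumor_pairs, "exome_tumor"))
  if (!is.null(exome_normal_pairs))
    singles <- rbind(singles, explode_pairs(exome_normal_pairs, "exome_normal"))
  suspected <- list()
  local_intron <- function(m, i) {
    if (is.na(i) || i < 1L || i >= nrow(m$exons)) return(NULL)
    if (m$strand == "+")
      data.frame(start = m$exons$end[i], end = m$exons$start[i + 1L])
    else
      data.frame(start = m$exons$end[i + 1L], end = m$exons$start[i])
  }
  suspected[[gene5]] <- local_intron(ref$models[[gene5]], i5)
  suspected[[gene3]] <- local_intron(ref$models[[gene3]], i3)
  local_repeats <- NULL
  if (!is.null(repeats) && nrow(repeats)) {
    rows <- lapply(names(ref$genome), function(g) {
      src <- ref$source_contigs[[g]]; off <- ref$offsets[[g]]
      r <- repeats[repeats$contig == src, , drop = FALSE]
      if (!nrow(r)) return(NULL)
      data.frame(contig = g, start = r$start - off, end = r$end - off)
    })
    local_repeats <- do.call(rbind, rows)
  }
  cand <- map_fusion_point_reads(singles, ref, suspected, local_repeats)
  bp <- NULL
  bp_note <- NULL
  if (nrow(cand)) {
    bp <- tryCatch(resolve_breakpoint(cand, ref, config$min_support),
                   error = function(e) { bp_note <<- conditionMessage(e); NULL })
  }
  level <- if (!is.null(bp)) "DNA"
  else if (junction_count > 0L) "undetermined"
  else "none"
  report <- list(
    gene5 = gene5, gene3 = gene3,
    discontinuity = list(gene5_intron = d5, gene3_intron = d3),
    junction_reads = junction_count,
    fusion_point_reads = nrow(cand),
    breakpoint = bp, breakpoint_note = bp_note,
    frame = frame, level = level,
    somatic = if (!is.null(bp)) bp$somatic else NA)
  if (!is.null(out_path)) {
    out <- report
    out$breakpoint <- if (!is.null(bp)) unclass(bp) else NULL
    jsonlite::write_json(out, out_path, auto_unbox = TRUE, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' Write a complete synthetic dataset to disk
#'
#' Generates a reference genome and annotation, optionally plants a fusion,
#' simulates tumor RNA-seq and tumor/normal exome read pairs, and writes
#' everything as plain-text files (FASTA, GTF, paired FASTQ, BED, TSV).
#' Default expression weights emulate the promoter-swap situation a fusion
#' survey targets: the fused gene is highly expressed (weight 20, a
#' promoter-swap level of over-expression), the
#' wild-type 3' partner nearly silent (weight 0.05), all other genes 1.
#' Decoy masked intervals (one per intergenic gap, 150 nt) are written as
#' `repeats.bed`.
#'
#' @param config a [sim_config()].
#' @param fspec optional [fusion_spec()].
#' @param outdir output directory.
#' @return invisible list with the in-memory objects (`genome`, `models`,
#'   `fusion`, `rna`, `exome_tumor`, `exome_normal`) and file paths.
#' @export
simulate_dataset <- function(config, fspec = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(config)
  genome <- ref$genome; models <- ref$models
  fusion <- NULL
  tumor_genome <- genome
  tumor_models <- models
  weights <- config$expression_weights
  if (!is.null(fspec)) {
    fusion <- apply_fusion(genome, models, fspec)
    tumor_genome <- fusion$tumor_genome
    tumor_models <- c(models, stats::setNames(list(fusion$fused_model),
                                              fusion$fused_model$gene_id))
    if (is.null(weights)) {
      weights <- stats::setNames(rep(1, length(tumor_models)), names(tumor_models))
      weights[fspec$gene3] <- 0.05
      weights[fusion$fused_model$gene_id] <- 20
    }
  }
  cfg_rna <- config
  cfg_rna$expression_weights <- weights
  rna <- simulate_rnaseq(tumor_genome, tumor_models, cfg_rna)
  exome_tumor <- simulate_exome(tumor_genome, tumor_models, config, "tumor")
  normal_genome <- if (!is.null(fspec) && fspec$somatic) genome else tumor_genome
  normal_models <- if (!is.null(fspec) && fspec$somatic) models else tumor_models
  exome_normal <- simulate_exome(normal_genome, normal_models, config, "normal")
  spans <- t(vapply(models, function(m)
    c(min(m$exons$start), max(m$exons$end)), numeric(2)))
  gaps <- data.frame(contig = "chr1",
                     start = spans[-nrow(spans), 2L],
                     end = spans[-1L, 1L])
  mid <- floor((gaps$start + gaps$end) / 2)
  repeats <- data.frame(contig = gaps$contig, start = mid - 75L, end = mid + 75L)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gtf = file.path(outdir, "genes.gtf"),
    tumor_genome = file.path(outdir, "tumor_genome.fa"),
    tumor_gtf = file.path(outdir, "tumor_genes.gtf"),
    rna = file.path(outdir, c("tumor_rna_1.fq", "tumor_rna_2.fq")),
    exome_tumor = file.path(outdir, c("tumor_exome_1.fq", "tumor_exome_2.fq")),
    exome_normal = file.path(outdir, c("normal_exome_1.fq", "normal_exome_2.fq")),
    repeats = file.path(outdir, "repeats.bed"),
    truth = file.path(outdir, "truth.tsv"))
  write_fasta(genome, paths$genome)
  write_gtf(models, paths$gtf)
  write_fasta(tumor_genome, paths$tumor_genome)
  write_gtf(tumor_models, paths$tumor_gtf)
  write_fastq(rna$pairs, paths$rna[1L], paths$rna[2L])
  write_fastq(exome_tumor$pairs, paths$exome_tumor[1L], paths$exome_tumor[2L])
  write_fastq(exome_normal$pairs, paths$exome_normal[1L], paths$exome_normal[2L])
  write_bed(repeats, paths$repeats)
  truth_tab <- if (!is.null(fusion))
    data.frame(gene5 = fspec$gene5, gene3 = fspec$gene3,
               break5 = fusion$truth$break5, break3 = fusion$truth$break3,
               homology = fusion$truth$homology,
               junction_mrna = fusion$truth$junction_mrna,
               somatic = fspec$somatic)
  else data.frame(gene5 = character(0), gene3 = character(0))
  write_tsv(truth_tab, paths$truth)
  invisible(list(genome = genome, models = models, fusion = fusion,
                 tumor_genome = tumor_genome, tumor_models = tumor_models,
                 rna = rna, exome_tumor = exome_tumor,
                 exome_normal = exome_normal, repeats = repeats,
                 paths = paths))
}
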