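# shared fixtures and independent oracles

rand_genome <- function(len, seed, name = "chr1") {
  set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""), name)
}

# brute-force exact placements of a read on both strands (mapping oracle)
naive_scan <- function(genome, seq) {
  out <- NULL
  for (cn in names(genome)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seq else revcomp(seq)
      m <- gregexpr(q, genome[[cn]], fixed = TRUE)[[1L]]
      if (m[1L] == -1L) next
      out <- rbind(out, data.frame(contig = cn, start = as.integer(m) - 1L,
                                   end = as.integer(m) - 1L + nchar(seq),
                                   strand = strand, stringsAsFactors = FALSE))
    }
  }
  out
}

# cached small fusion dataset shared across tests
.fixture_env <- new.env()
fixture_fusion_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    # exome_flank 300 emulates a fusion point fortuitously captured along
    # with the adjacent exons, the situation that yields DNA-level evidence
    cfg <- sim_config(seed = 101, n_genes = 6, n_pairs = 1200,
                      premrna_fraction = 0.05, exome_flank = 300L)
    .fixture_env$ds <- simulate_dataset(
      cfg, fusion_spec("g1", "g3", intron5 = 2, intron3 = 1, homology = 2),
      outdir = file.path(tempdir(), "fixture_ds"))
    .fixture_env$cfg <- cfg
  }
  .fixture_env$ds
}
fixture_config <- function() { fixture_fusion_dataset(); .fixture_env$cfg }

# toy coding gene pair engineered so the frame oracle is decisive: 5'-partner
# CDS uses only C/G (no stop codon can form in any frame); the 3' partner
# carries a 9-mer whose +1/+2 frame readings contain TAA but whose native
# frame does not, placed at a native codon boundary downstream of every
# possible junction
make_toy_coding_pair <- function(seed) {
  set.seed(seed)
  cg_codons <- function(n) paste(sample(c("C", "G"), 3L * n, replace = TRUE),
                                 collapse = "")
  n5 <- sample(2:4, 1L); n3 <- sample(2:4, 1L)
  len5 <- sample(4:9, n5, replace = TRUE)          # codons per exon
  extra5 <- sample(0:2, 1L)                        # make exon lengths non-multiples of 3
  build_gene <- function(id, exon_seqs, pos0 = 0L) {
    pos <- pos0
    exons <- NULL
    seqs <- character(0)
    for (s in exon_seqs) {
      exons <- rbind(exons, data.frame(start = pos, end = pos + nchar(s)))
      seqs <- c(seqs, s)
      pos <- pos + nchar(s) + 50L
    }
    lens <- exons$end - exons$start
    cum <- c(0L, cumsum(lens))[seq_along(lens)]
    cds <- data.frame(start = exons$start, end = exons$end,
                      phase = (3L - cum %% 3L) %% 3L)
    list(model = gene_model(id, "toy", "+", exons, cds = cds),
         seqs = seqs, next_pos = pos)
  }
  ex5 <- vapply(len5, cg_codons, "")
  # shift exon boundaries off codon boundaries
  if (extra5 > 0L) ex5[1L] <- substr(ex5[1L], 1L, nchar(ex5[1L]) - extra5)
  g5 <- build_gene("t5", ex5)
  i5 <- sample(seq_len(n5 - 1L), 1L)
  i3 <- sample(seq_len(n3 - 1L), 1L)
  len3 <- sample(4:9, n3, replace = TRUE)
  ex3 <- vapply(len3, cg_codons, "")
  # plant the frame sentinel at the first codon boundary of the first exon
  # retained after any junction (exon i3 + 1)
  cum3 <- c(0L, cumsum(nchar(ex3)))[seq_along(ex3)]
  p <- (3L - cum3[i3 + 1L] %% 3L) %% 3L
  tgt <- ex3[i3 + 1L]
  ex3[i3 + 1L] <- paste0(substr(tgt, 1L, p), "CTAAATAAC",
                         substr(tgt, p + 1L, nchar(tgt)))
  g3 <- build_gene("t3", ex3, pos0 = g5$next_pos + 200L)
  contig <- paste(rep("T", g3$next_pos + 50L), collapse = "")
  list(m5 = g5$model, m3 = g3$model, i5 = i5, i3 = i3,
       cds5 = g5$seqs, cds3 = ex3)
}

# direct-translation frame oracle: translate the fused CDS and look for a
# premature stop before the 3' CDS end
translation_in_frame <- function(toy) {
  fused_cds <- paste0(paste(toy$cds5[seq_len(toy$i5)], collapse = ""),
                      paste(toy$cds3[seq(toy$i3 + 1L, length(toy$cds3))],
                            collapse = ""))
  n_cod <- nchar(fused_cds) %/% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(fused_cds, 1L, 3L * n_cod)),
    if.fuzzy.codon = "X"))
  !grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))
}

# rank-based AUROC of scores against binary labels
auroc <- function(scores, labels) {
  r <- rank(scores)
  pos <- labels == 1
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}
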