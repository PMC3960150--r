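test_that("the reference generator is deterministic and structurally sound", {
  cfg <- sim_config(seed = 9, n_genes = 3)
  a <- make_reference(cfg)
  b <- make_reference(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fasta(a$genome, file.path(d1, "g.fa")); write_gtf(a$models, file.path(d1, "m.gtf"))
  write_fasta(b$genome, file.path(d2, "g.fa")); write_gtf(b$models, file.path(d2, "m.gtf"))
  expect_identical(readLines(file.path(d1, "g.fa")), readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "m.gtf"))[-(1:3)],
                   readLines(file.path(d2, "m.gtf"))[-(1:3)])

  expect_length(a$models, 3L)
  expect_setequal(vapply(a$models, `[[`, "", "strand"), c("+", "-"))

  # every exon's sequence appears at its interval in the genome
  for (m in a$models) {
    for (i in seq_len(nrow(m$exons))) {
      s <- substr(a$genome[[m$contig]], m$exons$start[i] + 1L, m$exons$end[i])
      expect_identical(regexpr(s, a$genome[[m$contig]], fixed = TRUE) > 0, TRUE)
      expect_identical(nchar(s), m$exons$end[i] - m$exons$start[i])
    }
  }
})

test_that("planted fusions carry exactly the requested micro-homology", {
  ref <- make_reference(sim_config(seed = 21, n_genes = 6))
  g <- ref$genome[["chr1"]]
  for (h in c(0L, 2L, 5L)) {
    fus <- apply_fusion(ref$genome, ref$models,
                        fusion_spec("g1", "g3", 2, 1, homology = h))
    b5 <- fus$truth$break5; b3 <- fus$truth$break3
    if (h > 0)
      expect_identical(substr(g, b5 - h + 1L, b5), substr(g, b3 - h + 1L, b3))
    # flanking bases differ, so the ambiguity is exactly h
    expect_false(substr(g, b5 + 1L, b5 + 1L) == substr(g, b3 + 1L, b3 + 1L))
    expect_false(substr(g, b5 - h, b5 - h) == substr(g, b3 - h, b3 - h))
    # tumor contig joins the two wild-type sides at the junction
    jt <- fus$truth$junction_tumor
    fc <- fus$tumor_genome[["fusion"]]
    sp5 <- model_span(ref$models$g1)
    expect_identical(substr(fc, 1L, jt), substr(g, sp5$start + 1L, b5))
  }
})

test_that("the fused transcript equals an independent splice of the fused model", {
  ref <- make_reference(sim_config(seed = 33, n_genes = 6))
  fus <- apply_fusion(ref$genome, ref$models,
                      fusion_spec("g1", "g3", 2, 1, homology = 2))
  # independent splicing: concatenate exon substrings straight off the contig
  fc <- fus$tumor_genome[["fusion"]]
  ex <- fus$fused_model$exons
  manual <- paste(substring(fc, ex$start + 1L, ex$end), collapse = "")
  expect_identical(fus$truth$fused_transcript, manual)
  # and equals the wild-type leading/trailing exon concatenation
  g <- ref$genome[["chr1"]]
  m1 <- ref$models$g1; m3 <- ref$models$g3
  manual2 <- paste0(
    paste(substring(g, m1$exons$start[1:2] + 1L, m1$exons$end[1:2]), collapse = ""),
    paste(substring(g, m3$exons$start[2:4] + 1L, m3$exons$end[2:4]), collapse = ""))
  expect_identical(fus$truth$fused_transcript, manual2)
})

test_that("RNA-seq simulation respects templates, weights, and coverage expectations", {
  cfg <- sim_config(seed = 13, n_genes = 3, n_pairs = 600, premrna_fraction = 0)
  ref <- make_reference(cfg)
  rna <- simulate_rnaseq(ref$genome, ref$models, cfg)
  expect_identical(nrow(rna$pairs), 600L)
  expect_true(all(rna$truth$template == "mrna"))
  # premrna_fraction = 0: no read contains intron-only sequence of g1
  m <- ref$models$g1
  intron <- substr(ref$genome[["chr1"]], m$exons$end[1] + 20L, m$exons$start[2] - 20L)
  hits <- grepl(intron, rna$pairs$seq1, fixed = TRUE) |
    grepl(intron, rna$pairs$seq2, fixed = TRUE)
  expect_false(any(hits))

  # one-hot weights: every fragment drawn from that gene
  cfg1 <- cfg
  cfg1$expression_weights <- c(g1 = 0, g2 = 1, g3 = 0)
  rna1 <- simulate_rnaseq(ref$genome, ref$models, cfg1)
  expect_true(all(rna1$truth$gene == "g2"))

  # coverage at a mid-transcript position: expected reads ~ 2*N*readlen/L_eff
  cfg2 <- sim_config(seed = 14, n_genes = 1, n_pairs = 2000,
                     premrna_fraction = 0, insert_sd = 0)
  ref2 <- make_reference(cfg2)
  tx <- splice_transcript(ref2$genome, ref2$models$g1)
  L <- nchar(tx); rl <- cfg2$read_len
  rna2 <- simulate_rnaseq(ref2$genome, ref2$models, cfg2)
  pos <- floor(L / 2)
  ins <- rna2$truth$insert
  covered <- (rna2$truth$tstart < pos & pos <= rna2$truth$tstart + rl) |
    (rna2$truth$tstart + ins - rl < pos & pos <= rna2$truth$tstart + ins)
  lambda <- 2000 * 2 * rl / (L - cfg2$insert_mean + 1)
  expect_lt(abs(sum(covered) - lambda), 3 * sqrt(lambda))
})

test_that("exome simulation stays inside capture windows and sees somatic junctions", {
  cfg <- sim_config(seed = 15, n_genes = 4, n_pairs = 800, exome_flank = 0L,
                    insert_mean = 80, insert_sd = 5)
  ref <- make_reference(cfg)
  ex <- simulate_exome(ref$genome, ref$models, cfg, "tumor")
  win <- exome_windows(ref$models, 0L, ref$genome)
  inside <- vapply(seq_len(nrow(ex$truth)), function(i) {
    any(win$start <= ex$truth$gstart[i] &
          ex$truth$gstart[i] + ex$truth$insert[i] <= win$end)
  }, logical(1))
  expect_true(all(inside))

  # somatic fusion: junction-overlapping reads in tumor exome, absent in normal
  ds <- fixture_fusion_dataset()
  jt <- ds$fusion$truth$junction_tumor
  fc <- ds$tumor_genome[["fusion"]]
  window <- substr(fc, jt - 15L, jt + 16L)
  in_tumor <- any(grepl(window, ds$exome_tumor$pairs$seq1, fixed = TRUE) |
                    grepl(window, ds$exome_tumor$pairs$seq2, fixed = TRUE) |
                    grepl(revcomp(window), ds$exome_tumor$pairs$seq1, fixed = TRUE) |
                    grepl(revcomp(window), ds$exome_tumor$pairs$seq2, fixed = TRUE))
  in_normal <- any(grepl(window, ds$exome_normal$pairs$seq1, fixed = TRUE) |
                     grepl(window, ds$exome_normal$pairs$seq2, fixed = TRUE) |
                     grepl(revcomp(window), ds$exome_normal$pairs$seq1, fixed = TRUE) |
                     grepl(revcomp(window), ds$exome_normal$pairs$seq2, fixed = TRUE))
  expect_true(in_tumor)
  expect_false(in_normal)

  # exome read starts are uniform across a window (chi-square GOF)
  w1 <- exome_windows(ref$models, 0L, ref$genome)[1L, ]
  starts <- ex$truth$gstart[ex$truth$gstart >= w1$start &
                              ex$truth$gstart < w1$end]
  if (length(starts) >= 40L) {
    span <- range(starts)
    cuts <- seq(span[1L], span[2L] + 1L, length.out = 5L)
    counts <- table(cut(starts, cuts, include.lowest = TRUE))
    p <- suppressWarnings(stats::chisq.test(counts)$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("cohort expression simulation plants exactly what it promises", {
  m0 <- simulate_cohort_expression(12, 5, noise_sd = 0, seed = 2)
  expect_true(all(m0 == m0[1L, 1L]))

  sig <- data.frame(gene = c("g1", "g2"), direction = c(1L, -1L))
  m1 <- simulate_cohort_expression(12, 5, signature = sig, activated = 1:3,
                                   fold = 1, noise_sd = 0, seed = 2)
  expect_identical(m1, m0)

  m2 <- simulate_cohort_expression(12, 5, signature = sig, activated = 1:3,
                                   fold = 4, noise_sd = 0, seed = 2)
  expect_equal(m2["g1", "s1"] - m0["g1", "s1"], log2(4))
  expect_equal(m2["g2", "s2"] - m0["g2", "s2"], -log2(4))
  expect_identical(m2["g3", ], m0["g3", ])
})

test_that("junction-spanning read counts in the FASTQ match the truth table", {
  ds <- fixture_fusion_dataset()
  jx <- ds$fusion$truth$junction_mrna
  tx <- ds$fusion$truth$fused_transcript
  rl <- 76L
  window <- substr(tx, jx - rl + 2L, jx + rl - 1L)  # any junction-crossing read sits here
  fid <- ds$fusion$fused_model$gene_id
  tr <- ds$rna$truth
  crosses <- tr$gene == fid & tr$template == "mrna" &
    ((tr$tstart < jx & tr$tstart + rl > jx) |
       (tr$tstart + tr$insert - rl < jx & tr$tstart + tr$insert > jx))
  found <- vapply(which(tr$gene == fid), function(i) {
    s1 <- ds$rna$pairs$seq1[i]; s2 <- ds$rna$pairs$seq2[i]
    any(c(grepl(s1, window, fixed = TRUE), grepl(revcomp(s1), window, fixed = TRUE),
          grepl(s2, window, fixed = TRUE), grepl(revcomp(s2), window, fixed = TRUE)))
  }, logical(1))
  expect_identical(sum(found), sum(crosses))
})
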