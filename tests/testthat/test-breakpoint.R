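test_that("coverage computation matches brute-force per-base counting", {
  pl <- data.frame(read_id = c("a", "b"), mate = 1L, contig = "c1",
                   start = c(10L, 25L), end = c(40L, 55L), strand = "+",
                   unique = TRUE)
  cov <- compute_coverage(pl, "c1", 0L, 60L)
  expect_identical(sum(cov), 60L)  # two 30-nt segments
  expect_identical(cov[11], 1L)    # base 10
  expect_identical(cov[30], 2L)    # overlap
  expect_identical(cov[60], 0L)

  set.seed(3)
  for (rep in 1:5) {
    n <- 30
    s <- sample(0:170, n, replace = TRUE)
    pl <- data.frame(read_id = sprintf("r%d", 1:n), mate = 1L, contig = "c1",
                     start = s, end = s + sample(5:30, n, replace = TRUE),
                     strand = "+", unique = TRUE)
    cov <- compute_coverage(pl, "c1", 0L, 200L)
    brute <- vapply(0:199, function(p) sum(pl$start <= p & p < pl$end), integer(1))
    expect_identical(cov, brute)
  }
})

test_that("coverage discontinuities are located at the break intron", {
  model <- gene_model("g", "c1", "+",
                      data.frame(start = c(0L, 200L, 400L, 600L),
                                 end = c(100L, 300L, 500L, 700L)))
  tile <- function(lo, hi) {
    s <- seq(lo, hi - 30L, by = 2L)
    data.frame(read_id = sprintf("t%d", seq_along(s)), mate = 1L, contig = "c1",
               start = s, end = s + 30L, strand = "+", unique = TRUE)
  }
  # exons 1-2 high, exons 3-4 silent -> boundary after exon 2
  pl <- rbind(tile(0L, 100L), tile(200L, 300L))
  expect_identical(locate_discontinuity(pl, model), 2L)
  # uniform -> none
  expect_true(is.na(locate_discontinuity(tile(0L, 700L), model)))
  # all zero -> none
  expect_true(is.na(locate_discontinuity(pl[0, ], model)))
})

test_that("junction reads are counted only when they truly bridge the fusion", {
  ds <- fixture_fusion_dataset()
  ref <- build_pair_reference(ds$genome, ds$models, "g1", "g3", 1000L)
  junction <- list(contig5 = "g1", end5 = ref$models$g1$exons$end[2],
                   contig3 = "g3", start3 = ref$models$g3$exons$start[2])
  tx <- ds$fusion$truth$fused_transcript
  jx <- ds$fusion$truth$junction_mrna
  reads <- data.frame(
    read_id = c("span38", "span8rc", "inside", "wildtype"),
    seq = c(substr(tx, jx - 37, jx + 38),
            revcomp(substr(tx, jx - 67, jx + 8)),
            substr(tx, jx + 1, jx + 76),
            substr(ds$genome[["chr1"]], 101, 176)))
  jr <- find_junction_reads(reads, ref, junction, min_overhang = 8L)
  expect_setequal(jr$read_ids, c("span38", "span8rc"))
  expect_identical(jr$min_overhang_observed, 8L)

  # a read with a 7-nt overhang falls below the minimum
  short <- data.frame(read_id = "span7", seq = substr(tx, jx - 6, jx + 69))
  expect_identical(find_junction_reads(short, ref, junction, 8L)$count, 0L)

  # wild-type sample: no junction reads at all
  wt <- simulate_rnaseq(ds$genome, ds$models, fixture_config(), seed = 77)
  singles <- data.frame(read_id = paste0(wt$pairs$read_id, "/1"),
                        seq = wt$pairs$seq1)
  expect_identical(find_junction_reads(singles, ref, junction, 8L)$count, 0L)
})

test_that("junction-read counts scale linearly with junction coverage", {
  ds <- fixture_fusion_dataset()
  ref <- build_pair_reference(ds$genome, ds$models, "g1", "g3", 1000L)
  junction <- list(contig5 = "g1", end5 = ref$models$g1$exons$end[2],
                   contig3 = "g3", start3 = ref$models$g3$exons$start[2])
  tx <- ds$fusion$truth$fused_transcript
  jx <- ds$fusion$truth$junction_mrna
  depths <- c(10L, 20L, 40L)
  counts <- vapply(depths, function(d) {
    offs <- seq(-60L, 0L, length.out = d)
    reads <- data.frame(read_id = sprintf("d%d_%d", d, seq_len(d)),
                        seq = substring(tx, jx + offs - 7L, jx + offs + 68L))
    find_junction_reads(reads, ref, junction, 8L)$count
  }, integer(1))
  fit <- stats::lm(counts ~ 0 + depths)
  expect_lt(abs(stats::coef(fit)[[1]] - 1), 0.15)
})

test_that("fusion-point read recovery applies all three criteria", {
  ds <- fixture_fusion_dataset()
  ref <- build_pair_reference(ds$genome, ds$models, "g1", "g3", 1000L)
  tr <- ds$fusion$truth
  g5m <- ds$models$g1; g3m <- ds$models$g3
  off5 <- ref$offsets[["g1"]]; off3 <- ref$offsets[["g3"]]
  suspected <- list(
    g1 = data.frame(start = g5m$exons$end[2] - off5,
                    end = g5m$exons$start[3] - off5),
    g3 = data.frame(start = g3m$exons$end[1] - off3,
                    end = g3m$exons$start[2] - off3))
  fc <- ds$tumor_genome[["fusion"]]
  jt <- tr$junction_tumor
  reads <- data.frame(
    read_id = c("junction", "left_only", "exonic"),
    seq = c(substr(fc, jt - 37, jt + 38),            # crosses the DNA junction
            substr(fc, jt - 99, jt - 24),            # both 17-mers in the 5' intron
            substr(ds$genome[["chr1"]],
                   g5m$exons$start[1] + 1, g5m$exons$start[1] + 76)),
    origin = "exome_tumor")
  kept <- map_fusion_point_reads(reads, ref, suspected)
  expect_identical(kept$read_id, "junction")

  # a decoy mask over the junction-side intron removes the read
  masked <- data.frame(contig = "g1",
                       start = suspected$g1$start, end = suspected$g1$end)
  kept2 <- map_fusion_point_reads(reads, ref, suspected, masked)
  expect_identical(nrow(kept2), 0L)
})

test_that("breakpoint resolution recovers the planted micro-homology exactly", {
  ref0 <- make_reference(sim_config(seed = 55, n_genes = 4))
  for (h in c(0L, 2L)) {
    fus <- apply_fusion(ref0$genome, ref0$models,
                        fusion_spec("g1", "g3", 2, 1, homology = h))
    ref <- build_pair_reference(ref0$genome, ref0$models, "g1", "g3", 1000L)
    fc <- fus$tumor_genome[["fusion"]]
    jt <- fus$truth$junction_tumor
    offs <- seq(-58L, -18L, by = 10L)
    reads <- data.frame(read_id = sprintf("h%d_%d", h, seq_along(offs)),
                        seq = substring(fc, jt + offs + 1L, jt + offs + 76L),
                        origin = "exome_tumor")
    bp <- resolve_breakpoint(reads, ref)
    expect_identical(bp$homology, h)
    expect_identical(diff(bp$break5), h)
    expect_identical(diff(bp$break3), h)
    expect_true(bp$break5[1] <= fus$truth$break5 &&
                  fus$truth$break5 <= bp$break5[2])
    expect_true(bp$break3[1] <= fus$truth$break3 &&
                  fus$truth$break3 <= bp$break3[2])
    expect_true(bp$somatic)
  }

  # candidate reads from the normal exome only -> not somatic
  fus <- apply_fusion(ref0$genome, ref0$models,
                      fusion_spec("g1", "g3", 2, 1, homology = 0L))
  ref <- build_pair_reference(ref0$genome, ref0$models, "g1", "g3", 1000L)
  fc <- fus$tumor_genome[["fusion"]]
  jt <- fus$truth$junction_tumor
  reads <- data.frame(read_id = c("n1", "n2"),
                      seq = substring(fc, jt + c(-50L, -30L) + 1L,
                                      jt + c(-50L, -30L) + 76L),
                      origin = "exome_normal")
  bp <- resolve_breakpoint(reads, ref)
  expect_false(bp$somatic)

  # wild-type reads never decompose across the two genes
  wt_reads <- data.frame(read_id = "w",
                         seq = substr(ref0$genome[["chr1"]], 1001, 1076),
                         origin = "rnaseq")
  expect_error(resolve_breakpoint(wt_reads, ref), "no confident fusion point")
})
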