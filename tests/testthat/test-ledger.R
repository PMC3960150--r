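test_that("copy-number folds are 1 under uniform coverage and recover amplification", {
  g <- rand_genome(20000, seed = 31)
  # uniform tiling: one 100-nt read every 50 bases
  starts <- seq(0L, 19900L, by = 50L)
  pl <- data.frame(read_id = sprintf("u%04d", seq_along(starts)), mate = 1L,
                   contig = "chr1", start = starts, end = starts + 100L,
                   strand = "+", unique = TRUE)
  track <- estimate_copy_number(pl, g, window = 2000L)
  expect_true(all(abs(track$fold - 1) < 0.05))

  # an 8x-weighted region stands out
  amp <- seq(6000L, 7900L, by = 50L)
  amp_pl <- do.call(rbind, replicate(7, data.frame(
    read_id = "a", mate = 1L, contig = "chr1", start = amp, end = amp + 100L,
    strand = "+", unique = TRUE), simplify = FALSE))
  track2 <- estimate_copy_number(rbind(pl, amp_pl), g, window = 2000L)
  hot <- track2$fold[track2$start == 6000L]
  expect_gt(hot, 7); expect_lt(hot, 9)

  expect_error(estimate_copy_number(pl[0, ], g), "insufficient coverage")
})

test_that("amplicon flagging respects the radius and fold threshold", {
  models <- list(
    gNear = gene_model("gNear", "c1", "+",
                       data.frame(start = 500000L, end = 501000L)),
    gFar = gene_model("gFar", "c1", "+",
                      data.frame(start = 3000000L, end = 3001000L)),
    gOther = gene_model("gOther", "c2", "+",
                        data.frame(start = 0L, end = 1000L)))
  track <- data.frame(contig = "c1", start = 0L, end = 10000L, fold = 8)
  expect_true(flag_amplicon("gNear", "gOther", models, track))   # 0.5 Mb away
  expect_false(flag_amplicon("gFar", "gOther", models, track))   # ~3 Mb away
  mild <- track; mild$fold <- 1.8
  expect_false(flag_amplicon("gNear", "gOther", models, mild))   # sub-threshold gain
})

test_that("misannotation flagging needs adjacency, same strand, and a joining transcript", {
  mk <- function(id, contig, start, strand = "+") {
    ex <- data.frame(start = start, end = start + 500L)
    gene_model(id, contig, strand, ex)
  }
  models <- list(gA = mk("gA", "c1", 0L), gB = mk("gB", "c1", 1000L),
                 gC = mk("gC", "c1", 2000L, "-"), gD = mk("gD", "c2", 0L))
  joining <- data.frame(gene_a = "gA", gene_b = "gB")
  expect_true(flag_misannotation("gA", "gB", models, joining))
  expect_true(flag_misannotation("gB", "gA", models, joining))
  expect_false(flag_misannotation("gB", "gC", models, joining))  # opposite strands
  expect_false(flag_misannotation("gA", "gD", models, joining))  # different contigs
  expect_false(flag_misannotation("gB", "gC", models, NULL))
})

test_that("frame checks follow CDS length and phase arithmetic", {
  # 5' CDS length 300, 3' junction exon phase 0 -> in frame
  m5 <- gene_model("f5", "c", "+",
                   data.frame(start = c(0L, 400L), end = c(300L, 700L)),
                   cds = data.frame(start = c(0L, 400L), end = c(300L, 700L),
                                    phase = c(0L, 0L)))
  m3 <- gene_model("f3", "c", "+",
                   data.frame(start = c(2000L, 2400L), end = c(2300L, 2700L)),
                   cds = data.frame(start = c(2000L, 2400L), end = c(2300L, 2700L),
                                    phase = c(0L, 0L)),
                   domains = data.frame(name = "kinase", start = 2400L, end = 2700L))
  fr <- check_frame(fuse_models(m5, m3, 1L, 1L))
  expect_true(fr$in_frame)
  expect_identical(fr$retained_domains, "kinase")

  # one extra 5' nucleotide shifts the frame
  m5b <- m5
  m5b$exons$end[1] <- 301L
  m5b$cds$end[1] <- 301L
  frb <- check_frame(fuse_models(m5b, m3, 1L, 1L))
  expect_false(frb$in_frame)
  expect_identical(frb$retained_domains, character(0))

  expect_error(check_frame(gene_model("x", "c", "+",
                                      data.frame(start = 0L, end = 9L))),
               "no coding model")
})

test_that("frame verdicts agree with direct translation on random toy fusions", {
  n_inframe <- 0L
  for (seed in 1:200) {
    toy <- make_toy_coding_pair(seed)
    fr <- check_frame(fuse_models(toy$m5, toy$m3, toy$i5, toy$i3))
    expect_identical(fr$in_frame, translation_in_frame(toy),
                     info = sprintf("seed %d", seed))
    n_inframe <- n_inframe + fr$in_frame
  }
  expect_gt(n_inframe, 20L)
  expect_lt(n_inframe, 180L)
})

test_that("the staged ledger partitions candidates and is order-robust", {
  ex <- gbm_survey_example()
  led <- ex$ledger
  expect_identical(nrow(led), 20L)
  expect_setequal(unique(led$status), c("retained", "excluded", "set_aside_known"))
  expect_identical(sum(led$status == "retained") + sum(led$status == "excluded") +
                     sum(led$status == "set_aside_known"), 20L)
  expect_identical(led$reason[led$status == "retained"], rep("", 3L))

  # a candidate triggering several rules is excluded regardless of order,
  # with the first-listed reason reported
  cand <- data.frame(gene1 = "x", gene2 = "y", sample = "s",
                     stringsAsFactors = FALSE)
  key <- "x:y:s"
  ev <- list(known = character(0),
             amplicon = stats::setNames(TRUE, key),
             misannotation = stats::setNames(TRUE, key),
             in_frame = stats::setNames(FALSE, key),
             junction_reads = stats::setNames(0L, key))
  out <- apply_ledger(cand, ev)
  expect_identical(out$status, "excluded")
  expect_identical(out$reason, "amplicon")

  ev$amplicon[] <- FALSE
  expect_identical(apply_ledger(cand, ev)$reason, "misannotation")
  ev$misannotation[] <- FALSE
  expect_identical(apply_ledger(cand, ev)$reason, "off-frame")
  ev$in_frame[] <- TRUE
  expect_identical(apply_ledger(cand, ev)$reason, "no junction reads")

  ev$junction_reads <- stats::setNames(1L, "other:key:s")
  expect_error(apply_ledger(cand, ev), "missing junction_reads")

  expect_identical(nrow(apply_ledger(cand[0, ], ev)), 0L)
})
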