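#' Transcript quantity, outlier expression, and pathway activity
#'
#' RPKM quantification (reads per kilobase of exon model per million mapped
#' reads), robust single-gene outlier-sample detection, directional
#' signature derivation from a treated-versus-control comparison, and
#' nearest-template pathway-activity scoring: the cosine similarity, in
#' `[-1, 1]`, between a sample's cohort-standardized expression over the
#' signature genes and the signature's direction vector. Positive scores
#' indicate relative activation of the pathway, negative scores relative
#' inactivation.
#'
#' @name expression-pathway
NULL

#' Compute RPKM
#'
#' `RPKM_g = 1e9 * c_g / (L_g * N)` with `c_g` the read count, `L_g` the
#' summed exon length, and `N` the total mapped reads.
#'
#' @param counts named integer vector of per-gene read counts.
#' @param lengths named integer vector of summed exonic lengths (nt).
#' @param N total mapped reads.
#' @return named numeric vector of RPKM values.
#' @export
compute_rpkm <- function(counts, lengths, N) {
  if (N <= 0) stop_fmt("total mapped reads N must be positive")
  lengths <- lengths[names(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop_fmt("missing or non-positive exonic length")
  1e9 * counts / (lengths * N)
}

#' Count uniquely mapped reads per gene
#'
#' @param placements per-mate placements from [map_pairs_exact()].
#' @param models named list of `gene_model`.
#' @return named integer vector (one entry per model).
#' @export
count_reads_per_gene <- function(placements, models) {
  uniq <- placements[placements$unique, , drop = FALSE]
  gene <- assign_genes(uniq, models)
  out <- stats::setNames(integer(length(models)), names(models))
  tab <- table(gene[!is.na(gene)])
  out[names(tab)] <- as.integer(tab)
  out
}

#' Detect outlier samples for one gene
#'
#' A sample is an outlier when its value exceeds both the background level
#' and `median + k * MAD` across the cohort; the MAD is floored at
#' `0.1 * median + eps` so all-but-outlier-zero cohorts remain callable.
#'
#' @param values named numeric vector: one gene's values across >= 10
#'   samples.
#' @param background background expression level (default 1.0, suited to
#'   the RPKM scale; for array data use e.g. the cohort's 95th percentile).
#' @param k MAD multiplier, default 5.
#' @return names (or indices) of the outlier samples.
#' @export
detect_outlier_samples <- function(values, background = 1.0, k = 5) {
  if (length(values) < 10L) stop_fmt("need >= 10 samples")
  med <- stats::median(values)
  madv <- max(stats::mad(values), 0.1 * med + 1e-8)
  out <- values > background & values > med + k * madv
  if (is.null(names(values))) which(out) else names(values)[out]
}

#' Derive a directional expression signature
#'
#' Compares a treated profile to the mean of control profiles on linear
#' scale: a gene enters the signature when its ratio is at least
#' `fold_cutoff` (direction +1) or at most `1/fold_cutoff` (direction -1),
#' boundaries inclusive. Excluded genes (e.g. the receptor driving the
#' treatment response) are removed last.
#'
#' @param treated named numeric vector (linear scale).
#' @param controls numeric matrix (genes x controls) or vector, same gene
#'   space as `treated`.
#' @param fold_cutoff fold-change cutoff, default 2.
#' @param exclude gene ids to drop from the signature.
#' @return data.frame `gene`, `direction` (+1/-1).
#' @export
derive_signature <- function(treated, controls, fold_cutoff = 2,
                             exclude = character(0)) {
  if (is.vector(controls)) controls <- matrix(controls, ncol = 1L,
                                              dimnames = list(names(controls), NULL))
  if (!identical(sort(names(treated)), sort(rownames(controls))))
    stop_fmt("treated and control profiles cover different gene spaces")
  ctrl <- rowMeans(controls)[names(treated)]
  ratio <- treated / ctrl
  up <- ratio >= fold_cutoff
  down <- ratio <= 1 / fold_cutoff
  sig <- data.frame(gene = names(treated)[up | down],
                    direction = ifelse(up[up | down], 1L, -1L),
                    stringsAsFactors = FALSE)
  sig <- sig[!sig$gene %in% exclude, , drop = FALSE]
  rownames(sig) <- NULL
  sig
}

#' Nearest-template pathway-activity scores
#'
#' Each signature gene is z-scored across the cohort; a sample's activity
#' is the cosine similarity between its z-vector over the signature genes
#' and the signature's direction vector. Scores are exactly bounded in
#' `[-1, 1]`. Signature genes missing from the matrix are dropped with a
#' warning; fewer than 3 remaining genes is an error.
#'
#' @param mat numeric matrix (genes x samples) on log scale.
#' @param signature data.frame `gene`, `direction`.
#' @return named numeric vector of per-sample activity scores.
#' @export
score_activity <- function(mat, signature) {
  if (ncol(mat) < 2L) stop_fmt("need >= 2 samples for cohort standardization")
  present <- signature$gene %in% rownames(mat)
  if (any(!present))
    warning(sprintf("dropping %d signature gene(s) absent from the matrix",
                    sum(!present)))
  sig <- signature[present, , drop = FALSE]
  if (nrow(sig) < 3L) stop_fmt("template too small: %d gene(s) present", nrow(sig))
  sub <- mat[sig$gene, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1L, stats::sd)
  sdv[sdv == 0] <- 1  # constant genes contribute zero signal
  z <- (sub - mu) / sdv
  dir <- sig$direction
  dnorm <- sqrt(sum(dir^2))
  scores <- vapply(seq_len(ncol(z)), function(j) {
    v <- z[, j]
    vn <- sqrt(sum(v^2))
    if (vn == 0) return(0)
    sum(v * dir) / (vn * dnorm)
  }, numeric(1))
  scores <- pmin(pmax(scores, -1), 1)
  stats::setNames(scores, colnames(mat))
}

#' Permutation significance for activity scores
#'
#' Optional extension to the cosine activity score: a permutation p-value
#' from shuffling the signature's gene assignment within the matrix.
#'
#' @inheritParams score_activity
#' @param n_perm number of shuffles, default 1000.
#' @param seed RNG seed.
#' @return data.frame `sample`, `score`, `p_value`.
#' @export
score_activity_significance <- function(mat, signature, n_perm = 1000L, seed = 1L) {
  obs <- score_activity(mat, signature)
  genes <- rownames(mat)
  with_seed(seed, {
    null_max <- replicate(n_perm, {
      perm <- signature
      perm$gene <- sample(genes, nrow(signature))
      suppressWarnings(score_activity(mat, perm))
    })
    p <- vapply(seq_along(obs), function(i)
      (1 + sum(null_max[i, ] >= obs[i])) / (n_perm + 1), numeric(1))
    data.frame(sample = names(obs), score = unname(obs), p_value = p,
               stringsAsFactors = FALSE)
  })
}
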