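#' Genomes, FASTA/FASTQ input and output, bedGraph emission
#'
#' A genome is represented as a named character vector: one uppercase
#' nucleotide string per contig over the alphabet `{A,C,G,T,N}`. All internal
#' coordinates in this package are 0-based half-open; conversion to the
#' 1-based conventions of GTF happens only inside the readers/writers.
#'
#' @name genome-io
NULL

validate_genome <- function(genome) {
  if (length(genome) == 0L) stop_fmt("genome has no contigs")
  nm <- names(genome)
  if (is.null(nm) || any(!nzchar(nm))) stop_fmt("genome contigs must be named")
  if (anyDuplicated(nm)) stop_fmt("duplicate contig name '%s'", nm[duplicated(nm)][1L])
  if (any(!nzchar(genome))) stop_fmt("contig '%s' has empty sequence", nm[!nzchar(genome)][1L])
  bad <- gsub("[ACGTN]", "", genome)
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1L]
    stop_fmt("illegal character '%s' in contig '%s'", substr(bad[i], 1, 1), nm[i])
  }
  invisible(genome)
}

#' Read a FASTA file into a genome
#'
#' Sequences are uppercased; any character outside `{A,C,G,T,N}` is a format
#' error naming the offending character and record.
#'
#' @param path FASTA file path.
#' @return named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop_fmt("malformed FASTA '%s': %s", path, conditionMessage(e)))
  genome <- toupper(as.character(set))
  names(genome) <- sub("\\s.*$", "", names(set))
  validate_genome(genome)
  genome
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  validate_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path, format = "fasta")
  invisible(path)
}

#' Read one FASTQ file
#'
#' @param path FASTQ path.
#' @return data.frame with columns `read_id`, `seq`, `qual` (possibly 0 rows).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTQ file not found: %s", path)
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L)
    stop_fmt("truncated FASTQ '%s': %d lines is not a multiple of 4", path, n_lines)
  if (n_lines == 0L)
    return(data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop_fmt("malformed FASTQ '%s': %s", path, conditionMessage(e)))
  data.frame(read_id = sub("\\s.*$", "", names(set)),
             seq = toupper(as.character(set)),
             qual = as.character(S4Vectors::mcols(set)$qualities),
             stringsAsFactors = FALSE)
}

#' Read a pair of mate FASTQ files
#'
#' Mate files must be index-aligned: record i of both files carries the same
#' read id.
#'
#' @param path1,path2 mate-1 and mate-2 FASTQ paths.
#' @return data.frame with columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  m1 <- read_fastq(path1)
  m2 <- read_fastq(path2)
  if (nrow(m1) != nrow(m2))
    stop_fmt("mate files differ in record count (%d vs %d)", nrow(m1), nrow(m2))
  id1 <- sub("/[12]$", "", m1$read_id)
  id2 <- sub("/[12]$", "", m2$read_id)
  if (any(id1 != id2)) {
    i <- which(id1 != id2)[1L]
    stop_fmt("read id mismatch between mate files at record %d: '%s' vs '%s'",
             i, m1$read_id[i], m2$read_id[i])
  }
  data.frame(read_id = id1, seq1 = m1$seq, qual1 = m1$qual,
             seq2 = m2$seq, qual2 = m2$qual, stringsAsFactors = FALSE)
}

#' Write read pairs as two mate FASTQ files
#'
#' @param pairs data.frame with columns `read_id`, `seq1`, `seq2` and
#'   optionally `qual1`, `qual2` (defaulting to uniform "I").
#' @param path1,path2 output mate FASTQ paths.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq <- function(pairs, path1, path2) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  q1 <- pairs$qual1 %||% strrep("I", nchar(pairs$seq1))
  q2 <- pairs$qual2 %||% strrep("I", nchar(pairs$seq2))
  if (nrow(pairs) == 0L) {
    file.create(path1); file.create(path2)
    return(invisible(c(path1, path2)))
  }
  write_one(pairs$seq1, q1, paste0(pairs$read_id, "/1"), path1)
  write_one(pairs$seq2, q2, paste0(pairs$read_id, "/2"), path2)
  invisible(c(path1, path2))
}

#' Write a per-base depth vector as bedGraph
#'
#' Adjacent equal-depth runs are merged into single 0-based half-open lines;
#' zero-depth runs are omitted.
#'
#' @param depths non-negative integer vector of per-base depths.
#' @param contig contig name the depths refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(depths, contig, path) {
  if (any(depths < 0)) stop_fmt("negative depth at position %d", which(depths < 0)[1L] - 1L)
  r <- rle(as.integer(depths))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values > 0L
  gr <- GenomicRanges::GRanges(
    seqnames = rep(contig, sum(keep)),
    ranges = IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
    score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read masked intervals from a BED file
#'
#' @param path BED file of masked (e.g. repeat-annotated) intervals.
#' @return data.frame with columns `contig`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' @param intervals data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$contig,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
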