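#' Construct a ReadSet
#'
#' A ReadSet is a data.frame with one row per read (a mate of a pair).
#' Mates of a pair share \code{id} and are distinguished by \code{mate}.
#' Qualities are phred+33 encoded strings of the same length as the
#' sequence. Extra columns (sample label, truth provenance from the
#' generator) are carried along untouched.
#'
#' @param id character read/template identifiers.
#' @param mate integer, 1 or 2.
#' @param seq DNA strings over \code{{A,C,G,T,N}}.
#' @param qual phred+33 quality strings, same width as \code{seq}.
#' @param sample_id sample label per read.
#' @param ... further per-read columns (recycled by data.frame rules).
#' @return a \code{ReadSet} (classed data.frame).
#' @export
read_set <- function(id, mate, seq, qual, sample_id = "S1", ...) {
  rs <- data.frame(id = as.character(id), mate = as.integer(mate),
                   seq = as.character(seq), qual = as.character(qual),
                   sample_id = as.character(sample_id), ...,
                   stringsAsFactors = FALSE)
  validate_read_set(rs)
  class(rs) <- c("ReadSet", "data.frame")
  rs
}

validate_read_set <- function(rs) {
  stopifnot(all(c("id", "mate", "seq", "qual", "sample_id") %in% names(rs)))
  if (nrow(rs) == 0L) return(invisible(rs))
  if (!all(rs$mate %in% c(1L, 2L)))
    stop_domain("ReadSet: mate must be 1 or 2")
  if (any(nchar(rs$seq) != nchar(rs$qual)))
    stop_domain("ReadSet: sequence and quality lengths differ")
  qr <- range(unlist(phred_decode(rs$qual[seq_len(min(nrow(rs), 1000L))])))
  if (qr[1] < 0 || qr[2] > 60)
    stop_domain("ReadSet: qualities outside [0, 60]")
  invisible(rs)
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d reads, %d templates, samples: %s\n",
              nrow(x), length(unique(x$id)),
              paste(unique(x$sample_id), collapse = ", ")))
  invisible(x)
}

#' Read a FASTQ file into a ReadSet
#'
#' Mate numbers are recovered from trailing \code{/1} / \code{/2} on the
#' record ids (defaulting to 1 when absent).
#'
#' @param path FASTQ file (optionally gzipped).
#' @param sample_id sample label attached to all reads.
#' @return a [read_set()].
#' @export
read_fastq <- function(path, sample_id = "S1") {
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(x = x, qual = as.character(S4Vectors::mcols(x)$qualities))
  }, error = function(e) stop_domain("malformed FASTQ in '", path, "': ",
                                     conditionMessage(e)))
  x <- parsed$x
  ids <- names(x)
  qual <- parsed$qual
  bad <- which(Biostrings::width(x) != nchar(qual, type = "bytes"))
  if (length(bad))
    stop_domain("malformed FASTQ in '", path, "': record ", bad[1],
                " has mismatched sequence/quality lengths")
  mate <- rep(1L, length(ids))
  has_mate <- grepl("/[12]$", ids)
  mate[has_mate] <- as.integer(sub("^.*/", "", ids[has_mate]))
  ids[has_mate] <- sub("/[12]$", "", ids[has_mate])
  read_set(id = ids, mate = mate, seq = as.character(x), qual = qual,
           sample_id = sample_id)
}

#' Write a ReadSet to FASTQ
#'
#' @param rs a ReadSet.
#' @param path output path (gzipped when it ends in .gz).
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(rs, path) {
  x <- Biostrings::DNAStringSet(rs$seq)
  names(x) <- paste0(rs$id, "/", rs$mate)
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(rs$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Trim reads at the 3' end
#'
#' Applies, to a fixpoint: exact adapter trimming (full adapter occurrence,
#' or a suffix of the read matching an adapter prefix), removal of terminal
#' poly-G runs of at least \code{min_polyg} bases, and removal of trailing
#' bases with quality below \code{trim_q}. Templates where either mate drops
#' below \code{min_len} are discarded together.
#'
#' @param rs a ReadSet.
#' @param trim_q phred threshold for 3' quality trimming (default 10).
#' @param adapters character vector of adapter sequences (may be empty).
#' @param min_polyg minimum terminal G-run length to strip (default 10).
#' @param min_len minimum surviving mate length (default 30).
#' @return trimmed ReadSet; attribute \code{n_dropped_templates} counts
#'   discarded templates.
#' @export
trim_reads <- function(rs, trim_q = 10, adapters = character(),
                       min_polyg = 10, min_len = 30) {
  validate_read_set(rs)
  if (nrow(rs) == 0L) return(rs)
  tr <- trim_reads_cpp(rs$seq, rs$qual, as.integer(trim_q),
                       as.character(adapters), as.integer(min_polyg), 5L)
  out <- rs
  out$seq <- tr$seq
  out$qual <- tr$qual
  short <- unique(out$id[nchar(out$seq) < min_len])
  dropped <- length(short)
  if (dropped > 0) out <- out[!out$id %in% short, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ReadSet", "data.frame")
  attr(out, "n_dropped_templates") <- dropped
  out
}

#' Expected fold coverage from read counts
#'
#' @param n_reads number of reads.
#' @param read_len mean read length (bp).
#' @param genome_size haploid genome size (bp).
#' @return fold coverage \code{n_reads * read_len / genome_size}.
#' @export
expected_coverage <- function(n_reads, read_len, genome_size) {
  if (any(genome_size <= 0)) stop_domain("genome_size must be > 0")
  if (any(n_reads <= 0) || any(read_len <= 0))
    stop_domain("n_reads and read_len must be > 0")
  n_reads * read_len / genome_size
}
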