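#' Canonical k-mer counting
#'
#' Exact counts of canonical k-mers (lexicographic minimum of a k-mer and
#' its reverse complement) over a read set. k-mers containing N are
#' skipped. Exact hashing, no sketching: the pipeline targets desk-scale
#' genomes where this is affordable and fully testable.
#'
#' @param reads a [read_set()].
#' @param k odd k-mer length (default 25).
#' @return a \code{KmerTable}: list with \code{k}, \code{counts}
#'   (data.table kmer/count) and \code{total_kmers}.
#' @export
count_kmers <- function(reads, k = 25L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 3L || k > 99L)
    stop_domain("k must be odd and in [3, 99]")
  if (all(nchar(reads$seq) < k)) {
    warning("k exceeds every read length; empty k-mer table")
    kt <- list(k = k,
               counts = data.table::data.table(kmer = character(),
                                               count = integer()),
               total_kmers = 0L)
    class(kt) <- "KmerTable"
    return(kt)
  }
  km <- extract_kmers(reads$seq, k)
  km[, kmer := canonical_kmer(kmer)]
  counts <- km[, .(count = .N), by = kmer]
  data.table::setkey(counts, kmer)
  kt <- list(k = k, counts = counts, total_kmers = sum(counts$count))
  class(kt) <- "KmerTable"
  kt
}

# data.table(read_row, kmer) of all k-mers free of non-ACGT characters
extract_kmers <- function(seqs, k) {
  L <- nchar(seqs)
  use <- which(L >= k)
  nk <- L[use] - k + 1L
  starts <- sequence(nk)
  rr <- rep(use, nk)
  km <- substring(rep(seqs[use], nk), starts, starts + k - 1L)
  dt <- data.table::data.table(read_row = rr, kmer = km)
  dt[!grepl("[^ACGT]", kmer)]
}

#' @noRd
canonical_kmer <- function(x) {
  pmin(x, revcomp(x))
}

#' @export
print.KmerTable <- function(x, ...) {
  cat(sprintf("KmerTable: k=%d, %d distinct canonical k-mers, %d total\n",
              x$k, nrow(x$counts), x$total_kmers))
  invisible(x)
}

#' k-mer coverage histogram
#'
#' @param table a [count_kmers()] table.
#' @param max_bin counts above this are pooled into the final bin.
#' @return data.frame \code{count} / \code{n_kmers}; the sum of
#'   \code{n_kmers} equals the number of distinct canonical k-mers.
#' @export
kmer_histogram <- function(table, max_bin = 10000L) {
  cc <- pmin(table$counts$count, as.integer(max_bin))
  if (length(cc) == 0L)
    return(data.frame(count = integer(), n_kmers = integer()))
  tab <- table(cc)
  data.frame(count = as.integer(names(tab)), n_kmers = as.integer(tab))
}

#' Write a k-mer histogram as two-column TSV
#' @param hist a [kmer_histogram()] result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_kmer_histogram <- function(hist, path) {
  utils::write.table(hist, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Low-copy read filter by k-mer coverage band
#'
#' A read is kept iff at least \code{min_frac} of its (N-free) k-mers have
#' a pooled-table count inside \code{band}. Reads shorter than k are
#' rejected. The table is normally built from the merged multi-sample pool
#' so the band is expressed in pooled-coverage units.
#'
#' @param reads a [read_set()].
#' @param table a [count_kmers()] table built from the same pool.
#' @param band integer pair \code{c(low, high)}, inclusive.
#' @param min_frac minimum in-band k-mer fraction (default 0.9).
#' @return list of ReadSets \code{kept} and \code{rejected}
#'   (kept + rejected == input, exactly).
#' @export
filter_low_copy_reads <- function(reads, table, band = c(10L, 40L),
                                  min_frac = 0.9) {
  k <- table$k
  n <- nrow(reads)
  frac <- rep(-1, n)  # reads shorter than k (or all-N k-mers) auto-reject
  km <- extract_kmers(reads$seq, k)
  if (nrow(km)) {
    km[, kmer := canonical_kmer(kmer)]
    km <- table$counts[km, on = "kmer"]
    km[is.na(count), count := 0L]
    fr <- km[, .(frac = mean(count >= band[1] & count <= band[2])),
             by = read_row]
    frac[fr$read_row] <- fr$frac
  }
  keep <- frac >= min_frac
  kept <- reads[keep, , drop = FALSE]
  rejected <- reads[!keep, , drop = FALSE]
  rownames(kept) <- rownames(rejected) <- NULL
  class(kept) <- class(rejected) <- c("ReadSet", "data.frame")
  list(kept = kept, rejected = rejected)
}

#' Re-pair a filtered read set
#'
#' Splits reads into templates with both mates present (paired) and
#' singletons, mirroring pair repair after per-read filtering.
#'
#' @param kept a [read_set()].
#' @return list of ReadSets \code{paired} and \code{singletons};
#'   their union is the input.
#' @export
repair_pairs <- function(kept) {
  key <- paste(kept$id, kept$mate)
  if (anyDuplicated(key)) stop_domain("duplicate read id + mate")
  tab <- table(kept$id)
  both <- names(tab)[tab == 2L]
  paired <- kept[kept$id %in% both, , drop = FALSE]
  singletons <- kept[!kept$id %in% both, , drop = FALSE]
  rownames(paired) <- rownames(singletons) <- NULL
  class(paired) <- class(singletons) <- c("ReadSet", "data.frame")
  list(paired = paired, singletons = singletons)
}
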