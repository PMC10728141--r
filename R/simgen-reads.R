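#' Simulate paired-end reads from a sequence set
#'
#' Uniform fragment sampling with Gaussian insert sizes, substitution-only
#' sequencing error and flat base qualities (optionally with a fixed
#' low-quality 3' ramp for testing quality trimming). Every read carries
#' truth provenance (origin contig, 0-based start, strand).
#'
#' @param seqs named character vector of source sequences.
#' @param coverage target fold coverage per source sequence.
#' @param read_len read length in bp (default 150, "2 x 150" layout).
#' @param insert_mean,insert_sd fragment length distribution (bp).
#' @param err substitution error rate per base.
#' @param seed RNG seed.
#' @param sample_id sample label.
#' @param base_q flat base quality (phred).
#' @param ramp optional \code{c(len, q)}: the last \code{len} bases of every
#'   read get quality \code{q}.
#' @return a [read_set()] with provenance columns \code{origin_contig},
#'   \code{origin_start}, \code{origin_strand}.
#' @export
simulate_reads <- function(seqs, coverage, read_len = 150L,
                           insert_mean = 300, insert_sd = 30, err = 0.002,
                           seed = 1L, sample_id = "S1", base_q = 37L,
                           ramp = NULL) {
  if (coverage <= 0) stop_domain("coverage must be > 0")
  if (any(nchar(seqs) < read_len))
    stop_domain("read_len exceeds a source sequence length")
  with_seed(seed, {
    out <- vector("list", length(seqs))
    counter <- 0L
    for (ci in seq_along(seqs)) {
      s <- seqs[[ci]]
      L <- nchar(s)
      n_pairs <- max(1L, round(coverage * L / (2 * read_len)))
      flen <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                        read_len), L)
      start <- floor(runif(n_pairs) * (L - flen + 1))  # 0-based
      fwd <- runif(n_pairs) < 0.5
      left <- substring(s, start + 1L, start + read_len)
      right <- revcomp(substring(s, start + flen - read_len + 1L,
                                 start + flen))
      r1 <- ifelse(fwd, left, right)
      r2 <- ifelse(fwd, right, left)
      ids <- sprintf("%s_r%07d", sample_id, counter + seq_len(n_pairs))
      counter <- counter + n_pairs
      o1_start <- ifelse(fwd, start, start + flen - read_len)
      o2_start <- ifelse(fwd, start + flen - read_len, start)
      o1_strand <- ifelse(fwd, "+", "-")
      o2_strand <- ifelse(fwd, "-", "+")
      out[[ci]] <- data.frame(
        id = rep(ids, 2L), mate = rep(c(1L, 2L), each = n_pairs),
        seq = c(r1, r2),
        origin_contig = names(seqs)[ci],
        origin_start = c(o1_start, o2_start),
        origin_strand = c(o1_strand, o2_strand),
        stringsAsFactors = FALSE)
    }
    rs <- do.call(rbind, out)
    if (err > 0) {
      nb <- nrow(rs) * read_len
      hits <- which(runif(nb) < err)
      if (length(hits)) {
        ridx <- (hits - 1L) %/% read_len + 1L
        bpos <- (hits - 1L) %% read_len + 1L
        by_read <- split(bpos, ridx)
        for (k in seq_along(by_read)) {
          i <- as.integer(names(by_read)[k])
          rs$seq[i] <- mutate_bases(rs$seq[i], by_read[[k]])
        }
      }
    }
    qv <- rep(as.integer(base_q), read_len)
    if (!is.null(ramp)) {
      stopifnot(length(ramp) == 2)
      qv[(read_len - ramp[1] + 1):read_len] <- as.integer(ramp[2])
    }
    qual <- intToUtf8(qv + 33L)
    read_set(id = rs$id, mate = rs$mate, seq = rs$seq,
             qual = rep(qual, nrow(rs)), sample_id = sample_id,
             origin_contig = rs$origin_contig,
             origin_start = rs$origin_start,
             origin_strand = rs$origin_strand)
  })
}
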