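# Shared lazily-built fixtures. The "toy study" reproduces the study
# conditions at desk scale (200 kb genome, 75% repeats, four ~5x haploid
# samples) with error-free reads and a substitution-only sister reference,
# so that caller/filter correctness is separable from error modelling.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

toy_study <- function() {
  fixture("toy_study", function() {
    g <- generate_genome(size = 2e5, repeat_fraction = 0.75,
                         divergence = 0.02, indel_rate = 0, seed = 101)
    hap <- sample_haploids(g, n = 4, snp_density = 1 / 200, seed = 102)
    reads <- do.call(rbind, lapply(1:4, function(i)
      simulate_reads(hap$haploids[i], 5, err = 0, seed = 110 + i,
                     sample_id = names(hap$haploids)[i])))
    class(reads) <- c("ReadSet", "data.frame")
    kt <- count_kmers(reads, 25)
    fl <- filter_low_copy_reads(reads, kt)
    aln_silver <- seed_map(reads, g$silver_ref)
    raw_silver <- pileup_call(aln_silver, g$silver_ref)
    filt_silver <- filter_variants(raw_silver, pipeline_config())
    am <- anchor_contigs(g$draft_contigs, g$silver_ref)
    list(genome = g, hap = hap, reads = reads, kmer_table = kt,
         filtered_reads = fl, aln_silver = aln_silver,
         raw_silver = raw_silver, filt_silver = filt_silver,
         anchors = am)
  })
}

# fraction of reads whose origin midpoint lies in a set of intervals
frac_reads_in <- function(rs, bed) {
  mid <- rs$origin_start + floor(nchar(rs$seq) / 2)
  hit <- logical(nrow(rs))
  for (i in seq_len(nrow(bed)))
    hit <- hit | (mid >= bed$start[i] & mid < bed$end[i])
  mean(hit)
}

# membership of positions in intervals
pos_in <- function(pos, bed) {
  hit <- logical(length(pos))
  for (i in seq_len(nrow(bed)))
    hit <- hit | (pos >= bed$start[i] & pos < bed$end[i])
  hit
}

# per-sample depth at given reference positions (0-based), from alignments
sample_depths_at <- function(aln, ref, pos0) {
  samples <- sort(unique(aln$sample_id))
  out <- sapply(samples, function(s) {
    dp <- depth_profile(aln[aln$sample_id == s, , drop = FALSE], ref)
    dp$profiles[[1]][pos0 + 1L]
  })
  matrix(out, ncol = length(samples), dimnames = list(NULL, samples))
}

# naive independent suffix-array/LCP oracle over the same terminated text:
# terminators encoded as low code-point characters ordered by string index
naive_suffix_oracle <- function(seqs) {
  m <- length(seqs)
  stopifnot(m < 200)
  term <- vapply(seq_len(m), intToUtf8, character(1))
  text <- unlist(lapply(seq_len(m), function(j)
    c(strsplit(seqs[j], "")[[1]], term[j])))
  n <- length(text)
  suff <- vapply(seq_len(n), function(i)
    paste(text[i:n], collapse = ""), character(1))
  o <- order(suff, method = "radix")
  lcp <- integer(n)
  for (r in 2:n) {
    a <- suff[o[r - 1]]; b <- suff[o[r]]
    l <- 0L
    while (l < nchar(a) && l < nchar(b) &&
           substr(a, l + 1, l + 1) == substr(b, l + 1, l + 1)) l <- l + 1L
    lcp[r] <- l
  }
  list(sa = o - 1L, lcp = lcp)
}
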