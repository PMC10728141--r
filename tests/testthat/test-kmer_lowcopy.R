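# independent canonical-k-mer oracle built on Biostrings
oracle_kmers <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    km <- substring(s, 1:(L - k + 1), k:L)
    km <- km[!grepl("[^ACGT]", km)]
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(km)))
    out <- c(out, ifelse(km <= rc, km, rc))
  }
  out
}

mk_reads <- function(seqs) {
  read_set(id = sprintf("r%03d", seq_along(seqs)), mate = 1L, seq = seqs,
           qual = strrep("I", nchar(seqs)))
}

test_that("canonical k-mer counts match enumeration on small reads", {
  rs <- mk_reads("ACGTACGT")
  kt <- count_kmers(rs, 5)
  oracle <- sort(table(oracle_kmers("ACGTACGT", 5)))
  got <- sort(table(rep(kt$counts$kmer, kt$counts$count)))
  expect_equal(as.vector(got), as.vector(oracle))
  expect_equal(names(got), names(oracle))
  expect_equal(kt$total_kmers, 4L)
})

test_that("a read and its reverse complement double every count", {
  s <- gametoSNP:::random_dna(80)
  kt1 <- count_kmers(mk_reads(s), 25)
  kt2 <- count_kmers(mk_reads(c(s, revcomp(s))), 25)
  merged <- merge(kt1$counts, kt2$counts, by = "kmer")
  expect_equal(nrow(merged), nrow(kt1$counts))
  expect_equal(merged$count.y, 2L * merged$count.x)
})

test_that("k-mers containing N are skipped; k beyond read length warns", {
  kt <- count_kmers(mk_reads("ACGTNACGTACGT"), 5)
  expect_false(any(grepl("N", kt$counts$kmer)))
  expect_warning(kt0 <- count_kmers(mk_reads("ACGT"), 7), "read length")
  expect_equal(nrow(kt0$counts), 0L)
  expect_error(count_kmers(mk_reads("ACGT"), 4), "odd")
})

test_that("histogram conserves distinct k-mers and pools the tail", {
  kt <- list(k = 5L,
             counts = data.table::data.table(
               kmer = c("AAAAA", "AAAAC", "AAAAG"),
               count = c(3L, 3L, 1L)),
             total_kmers = 7L)
  class(kt) <- "KmerTable"
  h <- kmer_histogram(kt)
  expect_equal(h, data.frame(count = c(1L, 3L), n_kmers = c(1L, 2L)))
  expect_equal(sum(h$n_kmers), nrow(kt$counts))
  hp <- kmer_histogram(kt, max_bin = 2L)
  expect_equal(hp, data.frame(count = 1:2, n_kmers = c(1L, 2L)))
  empty <- kt; empty$counts <- kt$counts[0]
  expect_equal(nrow(kmer_histogram(empty)), 0L)
})

test_that("histogram mode sits at the k-mer coverage of unique sequence", {
  g <- generate_genome(size = 5e4, repeat_fraction = 0, dup_share = 0,
                       divergence = 0, seed = 21)
  rs <- simulate_reads(g$truth, coverage = 20, err = 0, seed = 22)
  kt <- count_kmers(rs, 25)
  h <- kmer_histogram(kt)
  h <- h[h$count > 3, ]                      # ignore the error/edge spike
  mode <- h$count[which.max(h$n_kmers)]
  expected <- 20 * (150 - 25 + 1) / 150      # k-mer coverage, ~16.8
  expect_lt(abs(mode - expected), 2.5)
})

test_that("high-copy repeats put secondary histogram mass at copy x coverage", {
  unit <- gametoSNP:::random_dna(1000)
  genome <- c(gen = paste0(gametoSNP:::random_dna(30000),
                           strrep(unit, 50),
                           gametoSNP:::random_dna(5000)))
  rs <- simulate_reads(genome, coverage = 20, err = 0, seed = 23)
  kt <- count_kmers(rs, 25)
  h <- kmer_histogram(kt, max_bin = 5000)
  target <- 50 * 20 * (150 - 25 + 1) / 150   # ~840
  high <- h[h$count > 0.5 * target, ]
  expect_gt(sum(high$n_kmers), 500)          # ~1000 distinct repeat k-mers
  wmode <- sum(high$count * high$n_kmers) / sum(high$n_kmers)
  expect_lt(abs(wmode - target) / target, 0.25)
})

test_that("band filter keeps in-band reads and rejects out-of-band reads", {
  reads <- mk_reads(c(gametoSNP:::random_dna(60), gametoSNP:::random_dna(60)))
  km1 <- oracle_kmers(reads$seq[1], 25)
  km2 <- oracle_kmers(reads$seq[2], 25)
  kt <- list(k = 25L,
             counts = data.table::data.table(
               kmer = c(unique(km1), unique(km2)),
               count = c(rep(20L, length(unique(km1))),
                         rep(1000L, length(unique(km2))))),
             total_kmers = 0L)
  class(kt) <- "KmerTable"
  data.table::setkey(kt$counts, kmer)
  fl <- filter_low_copy_reads(reads, kt, band = c(10, 40), min_frac = 0.9)
  expect_equal(fl$kept$id, "r001")
  expect_equal(fl$rejected$id, "r002")
})

test_that("filter conserves reads and is monotone in band and fraction", {
  g <- generate_genome(size = 6e4, seed = 24)
  rs <- simulate_reads(g$truth, coverage = 8, err = 0.002, seed = 25)
  kt <- count_kmers(rs, 25)
  fl <- filter_low_copy_reads(rs, kt, band = c(4, 16))
  expect_equal(nrow(fl$kept) + nrow(fl$rejected), nrow(rs))
  expect_equal(sort(c(fl$kept$id, fl$rejected$id)), sort(rs$id))
  wider <- filter_low_copy_reads(rs, kt, band = c(2, 32))
  expect_true(all(fl$kept$id %in% wider$kept$id))
  looser <- filter_low_copy_reads(rs, kt, band = c(4, 16), min_frac = 0.5)
  expect_true(all(fl$kept$id %in% looser$kept$id))
})

test_that("keep/reject decisions match a naive per-read recount", {
  g <- generate_genome(size = 5e4, repeat_fraction = 0.6, seed = 26)
  rs <- simulate_reads(g$truth, coverage = 6, err = 0.002, seed = 27)
  kt <- count_kmers(rs, 25)
  fl <- filter_low_copy_reads(rs, kt, band = c(3, 12), min_frac = 0.9)
  counts <- table(oracle_kmers(rs$seq, 25))
  naive_keep <- vapply(rs$seq, function(s) {
    km <- oracle_kmers(s, 25)
    if (length(km) == 0) return(FALSE)
    cc <- as.integer(counts[km])
    mean(cc >= 3 & cc <= 12) >= 0.9
  }, logical(1), USE.NAMES = FALSE)
  key <- paste(rs$id, rs$mate)
  expect_setequal(key[naive_keep], paste(fl$kept$id, fl$kept$mate))
})

test_that("pair repair partitions reads exactly", {
  rs <- read_set(id = c("a", "a", "b", "c", "c"), mate = c(1, 2, 1, 1, 2),
                 seq = rep("ACGTACGT", 5), qual = rep(strrep("I", 8), 5))
  rp <- repair_pairs(rs)
  expect_setequal(unique(rp$paired$id), c("a", "c"))
  expect_equal(rp$singletons$id, "b")
  expect_equal(nrow(rp$paired) + nrow(rp$singletons), nrow(rs))
  dup <- rbind(rs, rs[1, ])
  class(dup) <- c("ReadSet", "data.frame")
  expect_error(repair_pairs(dup), "duplicate")
})
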