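test_that("eBWT of a single tiny read matches hand enumeration", {
  idx <- build_ebwt("ACG", include_rc = FALSE)
  # suffixes of "ACG$": "$", "ACG$", "CG$", "G$" in sorted order
  expect_equal(idx$sa, c(3L, 0L, 1L, 2L))
  expect_equal(ebwt_chars(idx), c("G", "$", "A", "C"))
  expect_error(build_ebwt(character(0)), "empty")
})

test_that("eBWT symbols are a permutation of the text symbols", {
  set.seed(41)
  seqs <- vapply(1:20, function(i) gametoSNP:::random_dna(60), character(1))
  idx <- build_ebwt(seqs, include_rc = TRUE)
  expect_equal(sort(table(ebwt_chars(idx))),
               sort(table(strsplit(idx$text_str, "")[[1]])))
  expect_equal(length(idx$sa), length(idx$lcp))
  expect_equal(length(idx$sa), length(idx$tvec))
})

test_that("suffix and LCP arrays equal a naive sort oracle", {
  set.seed(42)
  seqs <- vapply(1:50, function(i) gametoSNP:::random_dna(100), character(1))
  idx <- build_ebwt(seqs, include_rc = FALSE)
  oracle <- naive_suffix_oracle(seqs)
  expect_equal(idx$sa, oracle$sa)
  expect_equal(idx$lcp, oracle$lcp)
})

test_that("LF-stepping inverts the eBWT back to every input string", {
  set.seed(43)
  seqs <- vapply(1:30, function(i)
    gametoSNP:::random_dna(sample(40:120, 1)), character(1))
  idx <- build_ebwt(seqs, include_rc = TRUE)
  expect_equal(invert_ebwt(idx), c(seqs, revcomp(seqs)))
})

test_that("identical reads form unanimous clusters yielding no candidates", {
  seqs <- rep(gametoSNP:::random_dna(80), 10)
  idx <- build_ebwt(seqs, include_rc = FALSE)
  cl <- detect_clusters(idx, min_context = 20, min_size = 4)
  expect_gt(nrow(cl), 0)
  cand <- call_snps_from_clusters(idx, cl, min_allele_support = 4)
  expect_equal(nrow(cand), 0L)
})

test_that("two read groups differing at one base yield one biallelic event", {
  set.seed(44)
  s <- gametoSNP:::random_dna(81)
  p <- 41L
  s2 <- s
  base <- substr(s, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  substr(s2, p, p) <- alt
  idx <- build_ebwt(c(rep(s, 6), rep(s2, 6)), include_rc = FALSE)
  cl <- detect_clusters(idx, min_context = 20, min_size = 4)
  cand <- call_snps_from_clusters(idx, cl, min_allele_support = 4)
  expect_equal(nrow(cand), 1L)
  expect_setequal(c(cand$allele_a, cand$allele_b), c(base, alt))
  expect_equal(cand$support_a + cand$support_b, 12L)
  expect_equal(cand$right_ctx, substr(s, p + 1, p + 40))
})

test_that("clusters equal a brute-force scan of the naive suffix order", {
  set.seed(45)
  seqs <- vapply(1:30, function(i) gametoSNP:::random_dna(80), character(1))
  seqs[16:30] <- seqs[1:15]   # create depth so clusters exist
  idx <- build_ebwt(seqs, include_rc = FALSE)
  cl <- detect_clusters(idx, min_context = 20, min_size = 4)
  oracle <- naive_suffix_oracle(seqs)
  t <- 20L
  runs <- rle(oracle$lcp >= t)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths + 1L >= 4L
  expect_equal(cl$lo, (starts - 1L)[keep])
  expect_equal(cl$hi, ends[keep])
})

test_that("calls are invariant to read input order", {
  set.seed(46)
  g <- generate_genome(size = 5e4, repeat_fraction = 0, dup_share = 0,
                       divergence = 0, seed = 47)
  hap <- sample_haploids(g, n = 2, snp_density = 1 / 400, seed = 48,
                         fst = 0)
  reads <- do.call(rbind, lapply(1:2, function(i)
    simulate_reads(hap$haploids[i], 8, err = 0, seed = 49 + i,
                   sample_id = names(hap$haploids)[i])))
  idx1 <- build_ebwt(reads$seq)
  sh <- sample(nrow(reads))
  idx2 <- build_ebwt(reads$seq[sh])
  cl1 <- detect_clusters(idx1); cl2 <- detect_clusters(idx2)
  c1 <- call_snps_from_clusters(idx1, cl1, min_allele_support = 3)
  c2 <- call_snps_from_clusters(idx2, cl2, min_allele_support = 3)
  key <- function(x) sort(paste(x$right_ctx, x$allele_a, x$allele_b,
                                x$support_a, x$support_b))
  expect_equal(key(c1), key(c2))
})

test_that("planted SNPs between two haploid sets are recovered accurately", {
  g <- generate_genome(size = 5e4, repeat_fraction = 0, dup_share = 0,
                       divergence = 0, seed = 51)
  hap <- sample_haploids(g, n = 2, snp_density = 1 / 300, seed = 52,
                         fst = 0)
  cov_per_set <- 10
  reads <- do.call(rbind, lapply(1:2, function(i)
    simulate_reads(hap$haploids[i], cov_per_set, err = 0, seed = 53 + i,
                   sample_id = names(hap$haploids)[i])))
  idx <- build_ebwt(reads$seq)
  cl <- detect_clusters(idx)
  cand <- call_snps_from_clusters(idx, cl,
                                  min_allele_support = ceiling(cov_per_set / 4))
  vs <- anchor_to_reference(cand, g$truth)
  ts <- hap$truth_snps
  diff_sites <- ts$pos[xor(ts$H1, ts$H2)]
  expect_gt(length(diff_sites), 50)
  expect_gte(mean(diff_sites %in% vs$pos), 0.90)   # recall
  expect_gte(mean(vs$pos %in% diff_sites), 0.95)   # precision
})

test_that("anchoring places candidates and handles strand and repeats", {
  set.seed(54)
  left <- gametoSNP:::random_dna(60)
  ctx <- gametoSNP:::random_dna(30)
  right <- gametoSNP:::random_dna(60)
  ref_fwd <- c(chr = paste0(left, "A", ctx, right))
  cand <- data.frame(allele_a = "A", allele_b = "G", support_a = 6L,
                     support_b = 6L, right_ctx = ctx, left_a = "",
                     left_b = "", stringsAsFactors = FALSE)
  vs <- anchor_to_reference(cand, ref_fwd)
  expect_equal(nrow(vs), 1L)
  expect_equal(vs$pos, 60L)      # the base left of the context
  expect_equal(vs$ref, "A")
  expect_equal(vs$alt, "G")

  # reverse-strand-only match: alleles complemented, position correct
  ref_rc <- c(chr = as.character(revcomp(ref_fwd)))
  vs2 <- anchor_to_reference(cand, ref_rc)
  expect_equal(nrow(vs2), 1L)
  expect_equal(vs2$pos, nchar(ref_rc[[1]]) - 1L - 60L)
  expect_equal(vs2$ref, "T")
  expect_equal(vs2$alt, "C")

  # repeated context: multi-hit, dropped and counted
  ref_rep <- c(chr = paste0(left, "A", ctx, right, "C", ctx))
  vs3 <- anchor_to_reference(cand, ref_rep)
  expect_equal(nrow(vs3), 0L)
  expect_equal(unname(attr(vs3, "anchor_stats")["multi_hit"]), 1L)
})
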