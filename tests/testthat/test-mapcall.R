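mk_ref <- function(seq) c(ref1 = seq)

test_that("error-free reads from unique sequence map at their true spots", {
  g <- generate_genome(size = 5e4, repeat_fraction = 0, dup_share = 0,
                       divergence = 0, seed = 31)
  rs <- simulate_reads(g$truth, coverage = 3, err = 0, seed = 32)
  names(g$truth) <- "ref1"
  aln <- seed_map(rs, g$truth)
  expect_equal(nrow(aln), nrow(rs))
  m <- match(paste(aln$id, aln$mate), paste(rs$id, rs$mate))
  expect_true(all(aln$start == rs$origin_start[m]))
  expect_true(all(aln$strand == rs$origin_strand[m]))
  expect_true(all(aln$mapq == 60))
  expect_true(all(aln$nm == 0))
})

test_that("reads from exact repeats get MAPQ 0", {
  unit <- gametoSNP:::random_dna(3000)
  ref <- mk_ref(paste0(gametoSNP:::random_dna(2000), unit,
                       gametoSNP:::random_dna(2000), unit,
                       gametoSNP:::random_dna(2000)))
  read <- substr(unit, 1001, 1150)
  rs <- read_set("rep1", 1L, read, strrep("I", 150))
  aln <- seed_map(rs, ref)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$mapq, 0L)
})

test_that("mapping with sequencing error stays within 5 bp of truth", {
  g <- generate_genome(size = 5e4, repeat_fraction = 0, dup_share = 0,
                       divergence = 0, seed = 33)
  rs <- simulate_reads(g$truth, coverage = 6, err = 0.002, seed = 34)
  aln <- seed_map(rs, g$truth)
  expect_gte(nrow(aln) / nrow(rs), 0.99)
  m <- match(paste(aln$id, aln$mate), paste(rs$id, rs$mate))
  expect_gte(mean(abs(aln$start - rs$origin_start[m]) <= 5), 0.99)
})

test_that("anchor-region subsetting picks exactly the overlapping reads", {
  aln <- data.frame(id = c("a", "b", "c"), mate = 1L, sample_id = "H1",
                    contig = "s1", start = c(100L, 500L, 190L),
                    strand = "+", mapq = 60L, cigar = "10M", nm = 0L,
                    seq = strrep("A", 10), qual = strrep("I", 10),
                    stringsAsFactors = FALSE)
  reads <- read_set(c("a", "b", "c"), 1L, rep(strrep("A", 10), 3),
                    rep(strrep("I", 10), 3))
  bed <- data.frame(contig = "s1", start = 0L, end = 200L)
  sub <- subset_reads_by_anchor_regions(aln, bed, reads)
  expect_setequal(sub$ids, c("a", "c"))   # c overlaps by exactly 10 bp
  bed2 <- data.frame(contig = "s1", start = 195L, end = 200L)
  sub2 <- subset_reads_by_anchor_regions(aln, bed2, reads)
  expect_equal(sub2$ids, "c")             # 1-bp-scale overlap suffices
  expect_warning(
    subset_reads_by_anchor_regions(aln, data.frame(contig = "nope",
                                                   start = 0L, end = 5L),
                                   reads),
    "absent")
})

test_that("maximum-depth mask equals direct per-position comparison", {
  dp <- list(profiles = list(c1 = rep(7L, 100)), d = 7)
  class(dp) <- "DepthProfile"
  expect_equal(nrow(max_depth_mask(dp)), 0L)  # 7 < 7 + 4*sqrt(7)

  prof <- c(rep(7L, 40), rep(100L, 10), rep(7L, 50))
  dp2 <- list(profiles = list(c1 = prof), d = mean(prof))
  class(dp2) <- "DepthProfile"
  mask <- max_depth_mask(dp2)
  thr <- mean(prof) + 4 * sqrt(mean(prof))
  naive <- which(prof > thr) - 1L
  got <- unlist(lapply(seq_len(nrow(mask)),
                       function(i) mask$start[i]:(mask$end[i] - 1L)))
  expect_equal(got, naive)

  set.seed(35)
  prof3 <- rpois(500, 7) + rbinom(500, 1, 0.05) * 50L
  dp3 <- list(profiles = list(c1 = prof3), d = mean(prof3))
  class(dp3) <- "DepthProfile"
  mask3 <- max_depth_mask(dp3)
  thr3 <- mean(prof3) + 4 * sqrt(mean(prof3))
  got3 <- unlist(lapply(seq_len(nrow(mask3)),
                        function(i) mask3$start[i]:(mask3$end[i] - 1L)))
  expect_equal(sort(got3), which(prof3 > thr3) - 1L)
  expect_error(max_depth_mask(list(profiles = list(), d = 0)), "empty")
})

# four-sample pileup fixture: exact reads from ref with planted alleles
pileup_fixture <- function(alt_samples = c("H2", "H3"), snp_pos = 60L,
                           depth_each = 10L) {
  ref <- mk_ref(gametoSNP:::random_dna(200))
  aln <- list()
  for (s in paste0("H", 1:4)) {
    hseq <- ref[[1]]
    if (s %in% alt_samples) {
      b <- substr(hseq, snp_pos + 1, snp_pos + 1)
      substr(hseq, snp_pos + 1, snp_pos + 1) <- setdiff(c("A", "C", "G", "T"),
                                                        b)[1]
    }
    starts <- round(seq(0, 80, length.out = depth_each))
    aln[[s]] <- data.frame(id = sprintf("%s_%02d", s, seq_along(starts)),
                           mate = 1L, sample_id = s, contig = "ref1",
                           start = starts, strand = "+", mapq = 60L,
                           cigar = "120M", nm = 0L,
                           seq = substring(hseq, starts + 1, starts + 120),
                           qual = strrep("I", 120), stringsAsFactors = FALSE)
  }
  list(ref = ref, aln = do.call(rbind, aln))
}

test_that("pileup emits nothing when every sample matches the reference", {
  fx <- pileup_fixture(alt_samples = character(0))
  vs <- pileup_call(fx$aln, fx$ref)
  expect_equal(nrow(vs), 0L)
})

test_that("a planted 2/4 SNP is called with AF 0.5 and sane per-sample data", {
  fx <- pileup_fixture(alt_samples = c("H2", "H3"))
  vs <- pileup_call(fx$aln, fx$ref)
  expect_equal(nrow(vs), 1L)
  expect_equal(vs$pos, 60L)
  expect_equal(vs$af, 0.5)
  expect_equal(unname(vs$calls[1, c("H2", "H3")] != vs$ref), c(TRUE, TRUE))
  expect_true(all(vs$depths[1, ] >= 5))
  expect_true(all(vs$gqs[1, ] >= 15))
  expect_equal(vs$mq, 60)
  # AF is recomputable from the per-sample calls
  called <- !is.na(vs$calls[1, ])
  expect_equal(vs$af, mean(vs$calls[1, called] != vs$ref))
})

test_that("filter cascade applies its rules in order with attrition log", {
  cfg <- pipeline_config()
  mk_vs <- function(depths_row, calls_row, minor_row, mq = 60,
                    gqs_row = rep(40, 4)) {
    variant_set("c1", 10L, "A", "G", af = mean(calls_row != "A"), mq = mq,
                method = "silver",
                calls = matrix(calls_row, 1, 4,
                               dimnames = list(NULL, paste0("H", 1:4))),
                depths = matrix(depths_row, 1, 4),
                gqs = matrix(gqs_row, 1, 4),
                minor = matrix(minor_row, 1, 4))
  }
  ok <- mk_vs(c(10, 10, 10, 10), c("A", "G", "G", "A"), c(0, 0, 0, 0))
  expect_equal(nrow(filter_variants(ok, cfg)), 1L)

  shallow <- mk_vs(c(4, 10, 10, 10), c("A", "G", "G", "A"), c(0, 0, 0, 0))
  out <- filter_variants(shallow, cfg)
  expect_equal(nrow(out), 0L)
  expect_equal(unname(attr(out, "attrition")["depth"]), 1L)

  het <- mk_vs(c(12, 10, 10, 10), c("A", "G", "G", "A"), c(6, 0, 0, 0))
  out <- filter_variants(het, cfg)
  expect_equal(unname(attr(out, "attrition")["het"]), 1L)

  lowmq <- mk_vs(c(10, 10, 10, 10), c("A", "G", "G", "A"), c(0, 0, 0, 0),
                 mq = 20)
  expect_equal(unname(attr(filter_variants(lowmq, cfg), "attrition")["mq"]),
               1L)

  fixed <- mk_vs(c(10, 10, 10, 10), c("G", "G", "G", "G"), c(0, 0, 0, 0))
  expect_equal(unname(attr(filter_variants(fixed, cfg),
                           "attrition")["polymorphic"]), 1L)
})

test_that("filtering is idempotent and attrition sums to the input size", {
  fx <- toy_study()
  filt1 <- fx$filt_silver
  att <- attr(filt1, "attrition")
  # every record carries exactly one tag: removals + retained = input
  expect_equal(unname(sum(att)), nrow(fx$raw_silver))
  filt2 <- filter_variants(filt1, pipeline_config())
  expect_equal(nrow(filt2), nrow(filt1))
  expect_equal(filt2$pos, filt1$pos)
})

test_that("with four called haploids the AF rule removes nothing", {
  fx <- toy_study()
  raw <- fx$raw_silver
  att <- attr(filter_variants(raw, pipeline_config()), "attrition")
  expect_equal(unname(att["af"]), 0L)
})

test_that("greedy spacing filter matches definition and brute force", {
  vs <- variant_set(rep("c1", 3), c(100L, 120L, 180L), "A", "G")
  out <- spacing_filter(vs, 50)
  expect_equal(out$pos, c(100L, 180L))
  one <- variant_set("c1", 5L, "A", "G")
  expect_equal(nrow(spacing_filter(one, 50)), 1L)

  set.seed(36)
  pos <- sort(sample.int(5000, 50))
  vs2 <- variant_set(rep("c1", 50), pos, "A", "G")
  got <- spacing_filter(vs2, 50)$pos
  keep <- logical(50); last <- -Inf
  for (i in 1:50) if (pos[i] - last >= 50) { keep[i] <- TRUE; last <- pos[i] }
  expect_equal(got, pos[keep])

  unsorted <- vs2[c(2, 1, 3:50), ]
  class(unsorted) <- c("VariantSet", "data.frame")
  expect_error(spacing_filter(unsorted, 50), "sorted")
})

test_that("anchor-region read subsetting reduces draft depth inflation", {
  fx <- toy_study()
  g <- fx$genome
  aln_all <- seed_map(fx$reads, g$draft_contigs)
  dp_all <- depth_profile(aln_all, g$draft_contigs)
  bed <- anchored_regions(fx$anchors)
  sub <- subset_reads_by_anchor_regions(fx$aln_silver, bed, fx$reads)
  aln_sub <- seed_map(sub$reads, g$draft_contigs)
  dp_sub <- depth_profile(aln_sub, g$draft_contigs)
  pooled_cov <- 4 * 5
  expect_lt(frac_above_depth(dp_sub, pooled_cov),
            frac_above_depth(dp_all, pooled_cov))
})
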