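test_that("amplicon genotype calling handles clear and ambiguous counts", {
  rc <- matrix(c(50L, 1L, 0L), 1, 3)
  ac <- matrix(c(0L, 1L, 0L), 1, 3)
  gm <- call_amplicon_genotypes(rc, ac, err = 0.01)
  expect_equal(unname(gm$geno[1, 1]), 0L)        # 50 ref / 0 alt
  expect_true(is.na(gm$geno[1, 2]))              # depth 2: posterior < 0.95
  expect_true(is.na(gm$geno[1, 3]))              # zero depth
  expect_error(call_amplicon_genotypes(-rc, ac), "negative")
})

test_that("genotype concordance with truth reaches 99% at depth 21", {
  pop <- build_clone_population(20, 8, 8, 0, n_loci = 150, seed = 71)
  amp <- simulate_amplicons(pop, mean_depth = 21, err = 0.01,
                            dropout = 0.02, seed = 72)
  gm <- call_amplicon_genotypes(amp$ref, amp$alt, err = 0.01,
                                clone_labels = pop$individuals$labelled_genet)
  conc <- mean(gm$geno == pop$geno, na.rm = TRUE)
  expect_gte(conc, 0.99)
})

test_that("polymorphism test separates variable from monomorphic loci", {
  set.seed(73)
  n <- 50
  depth <- rep(30L, n)
  # all homozygous reference with clean reads: no evidence of variation
  p_mono <- polymorphism_test(depth, rbinom(n, depth, 0.01), err = 0.01)
  expect_gt(p_mono, 0.001)
  # half dosage 0, half dosage 2 at depth 30: overwhelming evidence
  alt <- c(rbinom(n / 2, 30, 0.01), rbinom(n / 2, 30, 0.99))
  p_poly <- polymorphism_test(rep(30L, n) - alt, alt, err = 0.01)
  expect_lt(p_poly, 1e-10)
  # truth-monomorphic loci are flagged at >= 95%
  rc <- matrix(30L, 40, 200)
  ac <- matrix(rbinom(40 * 200, 30, 0.01), 40, 200)
  rc <- rc - ac
  flagged <- !variable_loci(rc, ac, err = 0.01)
  expect_gte(mean(flagged), 0.95)
  expect_true(is.na(polymorphism_test(rep(0L, 20), rep(0L, 20))))
})

test_that("panel filters use the stated inclusive boundaries and log attrition", {
  set.seed(74)
  n <- 40
  g <- matrix(rbinom(n * 4, 2, 0.4), n, 4)
  g[seq_len(ceiling(0.15 * n)), 1] <- NA       # exactly 15% missing
  g[, 2] <- c(1L, rep(0L, n - 1))              # MAF = 1/80 < 0.05
  g[, 3] <- rep(c(0L, 1L, 2L, 1L), n / 4)      # healthy locus
  g[, 4] <- rep(c(0L, 2L, 1L, 1L), n / 4)
  gm <- genotype_matrix(g)
  out <- filter_panel(gm)
  att <- attr(out, "attrition")
  expect_equal(unname(att["locus_missing"]), 1L)
  expect_gte(unname(att["maf"]), 1L)
  expect_equal(ncol(gm$geno),
               unname(att["locus_missing"] + att["maf"] +
                        att["loci_retained"]))
  # MAF exactly 0.05 is dropped (inclusive boundary)
  g2 <- cbind(matrix(rep(c(0L, 1L, 2L, 1L), 10), 40, 3),
              c(rep(1L, 4), rep(0L, 36)))     # p = 4/80 = 0.05
  out2 <- filter_panel(genotype_matrix(g2), min_maf = 0.05)
  expect_equal(unname(attr(out2, "attrition")["maf"]), 1L)
})

test_that("a panel built to the study's attrition keeps 169 of 193 loci", {
  set.seed(75)
  n <- 342
  keep <- matrix(rbinom(n * 169, 2, 0.4), n, 169)
  drop_miss <- matrix(rbinom(n * 14, 2, 0.4), n, 14)
  drop_miss[seq_len(60), ] <- NA               # ~18% missing
  drop_maf <- matrix(rbinom(n * 10, 2, 0.01), n, 10)
  gm <- genotype_matrix(cbind(keep, drop_miss, drop_maf))
  expect_equal(ncol(gm$geno), 193L)
  out <- filter_panel(gm)
  expect_equal(ncol(out$geno), 169L)
  expect_equal(nrow(out$geno), 342L)
  expect_equal(round(100 * ncol(out$geno) / 193, 1), 87.6)
})

test_that("the heterozygosity CI filter excludes only loci above 0.5", {
  n <- 342
  all_het <- matrix(1L, n, 1)
  half_het <- matrix(rep(c(1L, 0L), n / 2), n, 1)
  gm <- genotype_matrix(cbind(all_het, half_het))
  hc <- het_ci_filter(gm)
  expect_equal(hc$excluded, "L0001")
  expect_equal(hc$kept, "L0002")
})

test_that("under Hardy-Weinberg the het filter type-I error stays at alpha", {
  set.seed(76)
  n <- 342
  m <- 1000
  p <- runif(m, 0.2, 0.8)
  g <- vapply(p, function(pp) rbinom(n, 2, pp), integer(n))
  gm <- genotype_matrix(g)
  hc <- het_ci_filter(gm, alpha = 0.05)
  expect_lte(length(hc$excluded) / m, 0.05)
})

test_that("mismatch percentages for pairs and trios follow the definition", {
  a <- rep(0L, 100); b <- a; b[1:5] <- 1L
  expect_equal(mismatch_percent(a, a), 0)
  expect_equal(mismatch_percent(a, b), 0.05)
  c_ <- a; c_[6:8] <- 2L
  expect_equal(mismatch_percent(a, b, c_), 0.08)
  expect_error(mismatch_percent(c(NA, 1L), c(1L, NA)), "non-missing")
  # trio mismatch >= max pairwise mismatch, across random trios
  set.seed(77)
  for (i in 1:20) {
    g <- matrix(rbinom(300, 2, 0.4), 3, 100)
    g[matrix(runif(300) < 0.05, 3, 100)] <- NA
    tri <- mismatch_percent(g[1, ], g[2, ], g[3, ])
    prs <- c(mismatch_percent(g[1, ], g[2, ]),
             mismatch_percent(g[1, ], g[3, ]),
             mismatch_percent(g[2, ], g[3, ]))
    expect_gte(tri + 1e-9, max(prs) * (1 - 0.06))  # joint-locus sets differ
  }
  expect_equal(mismatch_gap(8.8, 46.6), 37.8)
})

test_that("ramet and unrelated mismatch distributions are disjoint", {
  pop <- build_clone_population(20, 8, 8, 0, n_loci = 150, seed = 78)
  amp <- simulate_amplicons(pop, mean_depth = 21, err = 0.01, seed = 79)
  gm <- call_amplicon_genotypes(amp$ref, amp$alt,
                                clone_labels = pop$individuals$labelled_genet)
  prof <- mismatch_profile(gm, n_groups = 50, seed = 80)
  s <- prof$summary
  expect_lt(s["ramet_pair", "max"], s["unrelated_pair", "min"])
  expect_lt(s["ramet_trio", "max"], s["unrelated_trio", "min"])
  expect_true(all(prof$gap > 0))
  tiny <- genotype_matrix(matrix(0L, 4, 10), rep(c("a", "b"), 2))
  expect_error(mismatch_profile(tiny), "fewer genets")
})

test_that("identity analysis recovers genets, mislabels and conflicts", {
  pop <- build_clone_population(20, 8, 8, 0, n_loci = 150, seed = 81)
  amp <- simulate_amplicons(pop, mean_depth = 21, err = 0.01, seed = 82)
  gm <- call_amplicon_genotypes(amp$ref, amp$alt,
                                clone_labels = pop$individuals$labelled_genet)
  id <- identity_analysis(gm)
  expect_equal(id$assignments$inferred, id$assignments$labelled)
  expect_equal(nrow(id$mislabels), 0L)

  mis <- build_clone_population(20, 8, 8, 3, n_unrelated_mislabels = 1,
                                n_loci = 150, seed = 83)
  amp2 <- simulate_amplicons(mis, mean_depth = 21, err = 0.01, seed = 84)
  gm2 <- call_amplicon_genotypes(amp2$ref, amp2$alt,
                                 clone_labels = mis$individuals$labelled_genet)
  id2 <- identity_analysis(gm2)
  expect_equal(sort(id2$mislabels$ind_id), sort(mis$mislabels$ind_id))
  got <- id2$mislabels[order(id2$mislabels$ind_id), ]
  want <- mis$mislabels[order(mis$mislabels$ind_id), ]
  expect_equal(got$class, want$class)
  reass <- got$class == "reassigned"
  expect_equal(got$inferred[reass], want$true_genet[reass])

  # two labelled multi-ramet genets with identical genotypes -> conflict
  g <- rbind(matrix(rep(rbinom(50, 2, 0.5), 6), 6, 50, byrow = TRUE),
             matrix(rbinom(150, 2, 0.5), 3, 50, byrow = TRUE))
  gmx <- genotype_matrix(g, c(rep("gA", 3), rep("gB", 3), "gC", "gD", "gE"))
  idx <- identity_analysis(gmx)
  expect_gt(length(idx$conflicts), 0)
})

test_that("the GRM matches its definition and algebraic identities", {
  g <- matrix(c(0L, 1L, 2L, 1L,
                0L, 1L, 2L, 1L,
                2L, 0L, 1L, 0L), 3, 4, byrow = TRUE)
  gm <- genotype_matrix(g)
  G <- grm(gm)
  # hand oracle: explicit double loop over the definition
  p <- colMeans(g) / 2
  denom <- 2 * sum(p * (1 - p))
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    oracle[i, j] <- sum((g[i, ] - 2 * p) * (g[j, ] - 2 * p)) / denom
  expect_equal(unname(G$G), oracle, tolerance = 1e-12)
  # identical individuals: off-diagonal equals the diagonals
  expect_equal(G$G[1, 2], G$G[1, 1])
  expect_equal(G$G[1, 2], G$G[2, 2])
  expect_error(grm(genotype_matrix(matrix(2L, 3, 4))), "monomorphic")
})

test_that("the GRM is invariant to locus and individual permutations", {
  set.seed(85)
  g <- matrix(rbinom(50 * 30, 2, 0.4), 50, 30)
  gm <- genotype_matrix(g)
  G1 <- grm(gm)$G
  lp <- sample(30); ip <- sample(50)
  G2 <- grm(genotype_matrix(g[, lp]))$G
  expect_equal(unname(G1), unname(G2))
  G3 <- grm(genotype_matrix(g[ip, ]))$G
  expect_equal(unname(G1[ip, ip]), unname(G3))
})

test_that("ramet blocks exceed unrelated relatedness; 50 loci suffice", {
  pop <- build_clone_population(15, 5, 5, 0, n_loci = 113, seed = 86)
  amp <- simulate_amplicons(pop, mean_depth = 21, err = 0.01, seed = 87)
  gm <- call_amplicon_genotypes(amp$ref, amp$alt,
                                clone_labels = pop$individuals$labelled_genet)
  G <- grm(gm)$G
  same <- outer(gm$indiv$clone, gm$indiv$clone, "==")
  diag(same) <- NA
  within <- G[same & !is.na(same)]
  between <- G[!same & !is.na(same)]
  expect_gt(min(within), max(between))
  # identity assignment from a random 50-locus subset matches the full panel
  set.seed(88)
  sub <- sample(ncol(gm$geno), 50)
  id_full <- identity_analysis(gm)
  id_sub <- identity_analysis(genotype_matrix(gm$geno[, sub],
                                              gm$indiv$clone))
  expect_equal(id_sub$assignments$inferred, id_full$assignments$inferred)
})

test_that("half-sib families show ~0.25 genomic relatedness", {
  set.seed(89)
  m <- 113
  p <- runif(m, 0.2, 0.8)
  n_fam <- 60
  draw_gamete <- function(geno) rbinom(m, 1, geno / 2)
  sires <- matrix(rbinom(n_fam * m, 2, rep(p, each = n_fam)), n_fam, m,
                  byrow = FALSE)
  offspring <- matrix(0L, 2 * n_fam, m)
  for (f in seq_len(n_fam)) {
    sire <- rbinom(m, 2, p)
    for (k in 1:2) {
      dam <- rbinom(m, 2, p)
      offspring[2 * (f - 1) + k, ] <- draw_gamete(sire) + draw_gamete(dam)
    }
  }
  gm <- genotype_matrix(offspring)
  G <- grm(gm, p = p)$G
  hs <- vapply(seq_len(n_fam), function(f) G[2 * f - 1, 2 * f],
               numeric(1))
  expect_lt(abs(mean(hs) - 0.25), 0.08)
})
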