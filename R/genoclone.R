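#' Construct a GenotypeMatrix
#'
#' Individuals x loci dosage matrix with cells in {0, 1, 2, NA}. Carries
#' per-individual clone labels and exposes per-locus allele frequency,
#' observed heterozygosity and missingness through accessors.
#'
#' @param geno integer matrix (individuals x loci; NA = missing).
#' @param clone_labels labelled genet per individual (rownames order).
#' @return a \code{GenotypeMatrix}.
#' @export
genotype_matrix <- function(geno, clone_labels = NULL) {
  stopifnot(is.matrix(geno))
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop_domain("genotypes must be 0/1/2/NA")
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("I%04d", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("L%04d", seq_len(ncol(geno)))
  if (is.null(clone_labels)) clone_labels <- rownames(geno)
  gm <- list(geno = geno,
             indiv = data.frame(ind_id = rownames(geno),
                                clone = as.character(clone_labels),
                                stringsAsFactors = FALSE))
  class(gm) <- "GenotypeMatrix"
  gm
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Per-locus alt allele frequency (non-missing cells)
#' @param gm a GenotypeMatrix.
#' @return numeric vector of frequencies.
#' @export
locus_freq <- function(gm) colMeans(gm$geno, na.rm = TRUE) / 2

#' Per-locus observed heterozygosity
#' @param gm a GenotypeMatrix.
#' @return fraction of heterozygous calls among non-missing cells.
#' @export
locus_het <- function(gm) colMeans(gm$geno == 1L, na.rm = TRUE)

#' Per-locus missing fraction
#' @param gm a GenotypeMatrix.
#' @return numeric vector.
#' @export
locus_missing <- function(gm) colMeans(is.na(gm$geno))

#' Call genotypes from amplicon allele read counts
#'
#' Genotype likelihoods are binomial in the alt-read count with alt-read
#' probabilities \code{err}, 0.5 and \code{1 - err} for dosages 0, 1, 2.
#' The prior is Hardy-Weinberg at a first-pass allele-frequency estimate
#' (pooled alt-read fraction per locus). A cell is set to the MAP
#' genotype when its posterior exceeds \code{min_posterior}, otherwise
#' missing; zero-depth cells are missing.
#'
#' @param ref_counts,alt_counts individuals x loci count matrices.
#' @param err per-read allele error rate (in (0, 0.05]).
#' @param min_posterior posterior probability needed to call (0.95).
#' @param min_depth minimum reads for a call; below it the frequency
#'   prior alone could push an uninformative cell past the posterior
#'   cutoff (default 3).
#' @param clone_labels optional labelled genet per individual.
#' @return a [genotype_matrix()].
#' @export
call_amplicon_genotypes <- function(ref_counts, alt_counts, err = 0.01,
                                    min_posterior = 0.95, min_depth = 3L,
                                    clone_labels = NULL) {
  if (any(ref_counts < 0) || any(alt_counts < 0))
    stop_domain("negative read counts")
  if (err <= 0 || err > 0.05) stop_domain("err must be in (0, 0.05]")
  depth <- ref_counts + alt_counts
  n <- nrow(depth); m <- ncol(depth)
  p_hat <- colSums(alt_counts) / pmax(colSums(depth), 1L)
  p_hat <- pmin(pmax(p_hat, 1e-4), 1 - 1e-4)
  prior <- rbind((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  p_g <- c(err, 0.5, 1 - err)
  geno <- matrix(NA_integer_, n, m, dimnames = dimnames(depth))
  for (g in 0:2) {
    lk <- dbinom(alt_counts, depth, p_g[g + 1L])
    assign(paste0("L", g), lk)
  }
  post <- array(0, c(n, m, 3L))
  for (g in 0:2)
    post[, , g + 1L] <- get(paste0("L", g)) *
      matrix(prior[g + 1L, ], n, m, byrow = TRUE)
  tot <- post[, , 1L] + post[, , 2L] + post[, , 3L]
  for (g in 0:2) post[, , g + 1L] <- post[, , g + 1L] / tot
  map_g <- apply(post, c(1, 2), which.max) - 1L
  map_p <- pmax(post[, , 1L], post[, , 2L], post[, , 3L])
  ok <- depth >= min_depth & map_p > min_posterior
  geno[ok] <- map_g[ok]
  genotype_matrix(geno, clone_labels)
}

#' Likelihood-ratio test for a truly variable locus
#'
#' Compares a polymorphic read-level model (each individual at its
#' best-supported dosage) against a monomorphic one (all individuals
#' dosage 0 or all dosage 2, alt reads arising only at error rate
#' \code{err}); 2*log LR is referred to a 1-df chi-square. Loci that do
#' not reject are flagged non-variable.
#'
#' @param ref_counts,alt_counts per-individual read counts at one locus.
#' @param err per-read error rate.
#' @return p-value (small = truly variable). \code{NA} when fewer than
#'   10 individuals have reads.
#' @export
polymorphism_test <- function(ref_counts, alt_counts, err = 0.01) {
  depth <- ref_counts + alt_counts
  use <- depth > 0L
  if (sum(use) < 10L) return(NA_real_)
  a <- alt_counts[use]; d <- depth[use]
  p_g <- c(err, 0.5, 1 - err)
  ll_free <- sum(apply(vapply(p_g, function(p) dbinom(a, d, p, log = TRUE),
                              numeric(length(a))), 1, max))
  ll_mono <- max(sum(dbinom(a, d, err, log = TRUE)),
                 sum(dbinom(a, d, 1 - err, log = TRUE)))
  stat <- 2 * (ll_free - ll_mono)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Flag non-variable loci of a count matrix
#' @param ref_counts,alt_counts individuals x loci count matrices.
#' @param err per-read error rate.
#' @param alpha p-value threshold (default 0.001).
#' @return logical vector: TRUE where the locus is truly variable.
#' @export
variable_loci <- function(ref_counts, alt_counts, err = 0.01,
                          alpha = 0.001) {
  p <- vapply(seq_len(ncol(ref_counts)), function(j)
    polymorphism_test(ref_counts[, j], alt_counts[, j], err), numeric(1))
  !is.na(p) & p < alpha
}

#' Panel filtering: locus missingness, MAF, individual missingness
#'
#' Fixed order: drop loci with missing fraction >= \code{max_locus_missing}
#' (boundary inclusive); drop loci with minor allele frequency
#' <= \code{min_maf} (boundary inclusive); drop individuals with missing
#' fraction > \code{max_indiv_missing}. Attrition per rule is recorded.
#'
#' @param gm a GenotypeMatrix.
#' @param max_locus_missing locus missing-data bound (default 0.15).
#' @param min_maf MAF bound (default 0.05).
#' @param max_indiv_missing individual missing-data bound (default 0.20).
#' @return filtered GenotypeMatrix with attribute \code{attrition}.
#' @export
filter_panel <- function(gm, max_locus_missing = 0.15, min_maf = 0.05,
                         max_indiv_missing = 0.20) {
  g <- gm$geno
  n0_loci <- ncol(g); n0_ind <- nrow(g)
  miss <- colMeans(is.na(g))
  drop_miss <- miss >= max_locus_missing
  g <- g[, !drop_miss, drop = FALSE]
  if (ncol(g) == 0L) stop_domain("locus-missingness filter removed all loci")
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_maf <- maf <= min_maf
  g <- g[, !drop_maf, drop = FALSE]
  if (ncol(g) == 0L) stop_domain("MAF filter removed all loci")
  imiss <- rowMeans(is.na(g))
  drop_ind <- imiss > max_indiv_missing
  g <- g[!drop_ind, , drop = FALSE]
  if (nrow(g) == 0L) stop_domain("individual-missingness filter removed all individuals")
  out <- genotype_matrix(g, gm$indiv$clone[!drop_ind])
  attr(out, "attrition") <- c(locus_missing = sum(drop_miss),
                              maf = sum(drop_maf),
                              indiv_missing = sum(drop_ind),
                              loci_retained = ncol(g),
                              indiv_retained = nrow(g))
  out
}

#' Exclude loci with heterozygosity significantly above 0.5
#'
#' 0.5 is the theoretical maximum of the population mean heterozygosity
#' at a biallelic locus under Hardy-Weinberg; loci whose Wilson score
#' interval for the heterozygote fraction lies entirely above it indicate
#' collapsed paralogs. A locus is excluded iff the lower bound of its
#' (1 - alpha) interval exceeds 0.5.
#'
#' @param gm a GenotypeMatrix.
#' @param alpha two-sided interval level (default 0.05).
#' @return list of locus-id vectors \code{kept} and \code{excluded}.
#' @export
het_ci_filter <- function(gm, alpha = 0.05) {
  g <- gm$geno
  lower <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    n <- sum(!is.na(x))
    if (n == 0L) return(0)
    h <- sum(x == 1L, na.rm = TRUE)
    stats::prop.test(h, n, conf.level = 1 - alpha,
                     correct = FALSE)$conf.int[1]
  }, numeric(1))
  excl <- lower > 0.5
  list(kept = colnames(g)[!excl], excluded = colnames(g)[excl])
}

#' Percentage of mismatching loci between two or three genotype vectors
#'
#' Pairs: fraction of loci, among those non-missing in both, where the
#' genotypes differ. Trios: fraction of loci non-missing in all three
#' where the three genotypes are not all identical (hence trio mismatch
#' >= any within-trio pairwise mismatch).
#'
#' @param a,b,c genotype vectors on an identical locus panel.
#' @return mismatch fraction.
#' @export
mismatch_percent <- function(a, b, c = NULL) {
  if (is.null(c)) {
    use <- !is.na(a) & !is.na(b)
    if (!any(use)) stop_domain("no jointly non-missing locus")
    return(mean(a[use] != b[use]))
  }
  use <- !is.na(a) & !is.na(b) & !is.na(c)
  if (!any(use)) stop_domain("no jointly non-missing locus")
  mean(!(a[use] == b[use] & b[use] == c[use]))
}

#' Gap between ramet and unrelated mismatch regimes
#' @param ramet_max maximum mismatch among ramet groups (fraction or %).
#' @param unrelated_min minimum mismatch among unrelated groups.
#' @return \code{unrelated_min - ramet_max}.
#' @export
mismatch_gap <- function(ramet_max, unrelated_min) {
  unrelated_min - ramet_max
}

#' Mismatch profile of ramet groups versus randomized unrelated groups
#'
#' Computes the mismatch for every within-clone pair and trio and for
#' \code{n_groups} seeded random unrelated pairs and trios (members drawn
#' from distinct genets), and reports the range per group plus the gap
#' \code{min(unrelated) - max(ramet)} separately for pairs and trios.
#'
#' @param gm a GenotypeMatrix.
#' @param clone_map labelled genet per individual (defaults to the
#'   GenotypeMatrix clone labels).
#' @param n_groups number of random unrelated pairs/trios.
#' @param seed RNG seed.
#' @return list with \code{profile} (long table of group mismatches),
#'   \code{summary} (min/max per kind) and \code{gap} (pairs, trios).
#' @export
mismatch_profile <- function(gm, clone_map = NULL, n_groups = 83L,
                             seed = 1L) {
  g <- gm$geno
  if (is.null(clone_map)) clone_map <- gm$indiv$clone
  genets <- split(seq_len(nrow(g)), clone_map)
  if (length(genets) < 3L) stop_domain("fewer genets than group size")
  rows <- list()
  for (gn in names(genets)) {
    idx <- genets[[gn]]
    if (length(idx) >= 2L) {
      prs <- utils::combn(idx, 2L)
      for (k in seq_len(ncol(prs)))
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "ramet_pair",
          mismatch = mismatch_percent(g[prs[1, k], ], g[prs[2, k], ]))
    }
    if (length(idx) >= 3L) {
      tri <- utils::combn(idx, 3L)
      for (k in seq_len(ncol(tri)))
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "ramet_trio",
          mismatch = mismatch_percent(g[tri[1, k], ], g[tri[2, k], ],
                                      g[tri[3, k], ]))
    }
  }
  with_seed(seed, {
    for (k in seq_len(n_groups)) {
      gs <- sample(names(genets), 2L)
      i <- vapply(gs, function(x) sample(rep(genets[[x]], 2L), 1L), integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "unrelated_pair",
        mismatch = mismatch_percent(g[i[1], ], g[i[2], ]))
      gs <- sample(names(genets), 3L)
      i <- vapply(gs, function(x) sample(rep(genets[[x]], 2L), 1L), integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "unrelated_trio",
        mismatch = mismatch_percent(g[i[1], ], g[i[2], ], g[i[3], ]))
    }
  })
  profile <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(profile$mismatch, profile$kind),
                                function(v) data.frame(min = min(v),
                                                       max = max(v))))
  gap <- c(
    pairs = if (all(c("ramet_pair", "unrelated_pair") %in% rownames(summ)))
      mismatch_gap(summ["ramet_pair", "max"], summ["unrelated_pair", "min"])
    else NA_real_,
    trios = if (all(c("ramet_trio", "unrelated_trio") %in% rownames(summ)))
      mismatch_gap(summ["ramet_trio", "max"], summ["unrelated_trio", "min"])
    else NA_real_)
  list(profile = profile, summary = summ, gap = gap)
}

# pairwise mismatch matrix over jointly non-missing loci
mismatch_matrix <- function(g) {
  n <- nrow(g)
  M <- !is.na(g)
  joint <- M %*% t(M)
  eq <- matrix(0, n, n)
  for (d in 0:2) {
    I <- (g == d) & M
    I[is.na(I)] <- FALSE
    eq <- eq + I %*% t(I)
  }
  mm <- 1 - eq / pmax(joint, 1)
  mm[joint == 0] <- NA
  diag(mm) <- 0
  dimnames(mm) <- list(rownames(g), rownames(g))
  mm
}

#' Fuzzy identity analysis and mislabel detection
#'
#' Individuals are grouped into inferred genets by single-linkage
#' clustering of pairwise mismatch at threshold \code{max_mismatch}
#' (chosen inside the empirical gap between the ramet and unrelated
#' mismatch regimes). Each inferred genet takes the majority label of its
#' members; individuals whose label disagrees are reported as mislabels,
#' classed \code{"reassigned"} (they joined another labelled genet) or
#' \code{"unrelated"} (singleton group). A linkage chain that merges two
#' labelled genets with more than two ramets each is reported as a
#' conflict rather than silently merged.
#'
#' @param gm a GenotypeMatrix.
#' @param max_mismatch fuzzy-match threshold (default 0.10).
#' @return list: \code{assignments} (ind, labelled, inferred genet),
#'   \code{mislabels} (with class), \code{conflicts}.
#' @export
identity_analysis <- function(gm, max_mismatch = 0.10) {
  g <- gm$geno
  lab <- gm$indiv$clone
  mm <- mismatch_matrix(g)
  if (anyNA(mm)) stop_domain("undefined mismatch (no shared loci) between some individuals")
  if (nrow(g) < 2L) stop_domain("need >= 2 individuals")
  hc <- hclust(as.dist(mm), method = "single")
  grp <- cutree(hc, h = max_mismatch)
  inferred <- character(length(grp))
  conflicts <- character(0)
  for (k in unique(grp)) {
    i <- which(grp == k)
    labs <- lab[i]
    tab <- sort(table(labs), decreasing = TRUE)
    maj <- names(tab)[1L]
    if (length(i) == 1L && sum(lab == labs) > 1L) {
      # singleton that failed to join the other ramets of its labelled
      # genet: matches nothing in the population
      inferred[i] <- paste0("singleton:", rownames(g)[i])
    } else {
      inferred[i] <- maj
    }
    big <- names(tab)[tab > 2L]
    if (length(big) > 1L)
      conflicts <- c(conflicts, paste(big, collapse = "+"))
  }
  assignments <- data.frame(ind_id = rownames(g), labelled = lab,
                            inferred = inferred, stringsAsFactors = FALSE)
  sizes <- table(grp)
  mis <- assignments[assignments$labelled != assignments$inferred, ,
                     drop = FALSE]
  if (nrow(mis)) {
    mis$class <- ifelse(startsWith(mis$inferred, "singleton:"),
                        "unrelated", "reassigned")
  } else {
    mis$class <- character(0)
  }
  rownames(mis) <- NULL
  list(assignments = assignments, mislabels = mis, conflicts = conflicts)
}

#' VanRaden genomic relatedness matrix
#'
#' \code{G = Z Z' / (2 * sum(p_i (1 - p_i)))} with Z the dosage matrix
#' column-centred by \code{2 p_i}; missing cells are mean-imputed per
#' locus (centred value 0). Allele frequencies are computed on all
#' individuals (including ramets) unless supplied.
#'
#' @param gm a GenotypeMatrix (post het-CI filtering).
#' @param p optional per-locus alt allele frequencies.
#' @return a \code{RelatednessMatrix}: list with symmetric \code{G},
#'   \code{p} and locus ids.
#' @export
grm <- function(gm, p = NULL) {
  g <- gm$geno
  if (is.null(p)) p <- colMeans(g, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop_domain("all loci monomorphic; GRM undefined")
  Z <- sweep(g, 2, 2 * p)
  Z[is.na(Z)] <- 0
  G <- Z %*% t(Z) / denom
  out <- list(G = G, p = p, loci = colnames(g))
  class(out) <- "RelatednessMatrix"
  out
}

#' @export
print.RelatednessMatrix <- function(x, ...) {
  cat(sprintf("RelatednessMatrix: %d x %d from %d loci\n",
              nrow(x$G), ncol(x$G), length(x$loci)))
  invisible(x)
}
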