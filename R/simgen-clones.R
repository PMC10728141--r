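#' Build a synthetic clonal orchard population
#'
#' Genets (genetic individuals) receive Hardy-Weinberg diploid genotypes at
#' a panel of loci; each genet is represented by one, two or three ramets
#' (grafted copies with identical true genotypes). Optionally plants
#' mislabels: ramets whose true genotype belongs to another genet
#' ("reassigned" truth) or to no genet at all ("unrelated" truth).
#'
#' @param n_trio genets with three ramets.
#' @param n_duo genets with two ramets.
#' @param n_single genets with a single ramet.
#' @param n_mislabels total planted mislabels.
#' @param n_unrelated_mislabels how many of the mislabels are injected
#'   unrelated genotypes (the rest are swaps into another genet).
#' @param n_loci number of biallelic loci.
#' @param p optional per-locus alt allele frequencies (default U(0.1,0.9)).
#' @param seed RNG seed.
#' @return a \code{ClonePopulation}: \code{individuals} (id, labelled and
#'   true genet), \code{geno} (individuals x loci dosage matrix),
#'   \code{loci} (id, p), \code{ramet_structure}, \code{mislabels},
#'   \code{genets}.
#' @export
build_clone_population <- function(n_trio, n_duo, n_single, n_mislabels = 0,
                                   n_unrelated_mislabels = 0, n_loci = 200L,
                                   p = NULL, seed = 1L) {
  if (any(c(n_trio, n_duo, n_single, n_mislabels) < 0))
    stop_domain("counts must be >= 0")
  n_ind <- 3L * n_trio + 2L * n_duo + n_single
  if (n_mislabels > n_ind) stop_domain("more mislabels than individuals")
  if (n_unrelated_mislabels > n_mislabels)
    stop_domain("n_unrelated_mislabels exceeds n_mislabels")
  n_genet <- n_trio + n_duo + n_single
  with_seed(seed, {
    if (is.null(p)) p <- runif(n_loci, 0.1, 0.9)
    n_loci <- length(p)
    genet_ids <- sprintf("G%03d", seq_len(n_genet))
    gg <- matrix(rbinom(n_genet * n_loci, 2L, rep(p, each = n_genet)),
                 n_genet, n_loci, dimnames = list(genet_ids, NULL))
    ramets <- rep(c(3L, 2L, 1L), c(n_trio, n_duo, n_single))
    names(ramets) <- genet_ids
    ind_genet <- rep(genet_ids, ramets)
    ind_ids <- sprintf("I%04d", seq_len(n_ind))
    geno <- gg[ind_genet, , drop = FALSE]
    rownames(geno) <- ind_ids
    individuals <- data.frame(ind_id = ind_ids, labelled_genet = ind_genet,
                              true_genet = ind_genet,
                              stringsAsFactors = FALSE)
    mis <- data.frame(ind_id = character(), true_genet = character(),
                      labelled_genet = character(), class = character(),
                      stringsAsFactors = FALSE)
    if (n_mislabels > 0) {
      # plant at most one mislabel per genet, inside multi-ramet genets so
      # the remaining ramets still identify the labelled genet
      pool_genets <- genet_ids[ramets >= 3L]
      if (length(pool_genets) < n_mislabels)
        pool_genets <- genet_ids[ramets >= 2L]
      if (length(pool_genets) < n_mislabels)
        stop_domain("not enough multi-ramet genets to plant mislabels")
      vg <- sample(pool_genets, n_mislabels)
      victims <- vapply(vg, function(x)
        sample(rep(ind_ids[ind_genet == x], 2L), 1L), character(1))
      unrelated <- victims[seq_len(n_unrelated_mislabels)]
      swapped <- setdiff(victims, unrelated)
      for (v in unrelated) {
        i <- match(v, ind_ids)
        geno[i, ] <- rbinom(n_loci, 2L, p)
        individuals$true_genet[i] <- "unrelated"
        mis <- rbind(mis, data.frame(ind_id = v, true_genet = "unrelated",
                                     labelled_genet = individuals$labelled_genet[i],
                                     class = "unrelated"))
      }
      multi <- genet_ids[ramets >= 2L]
      for (v in swapped) {
        i <- match(v, ind_ids)
        target <- sample(setdiff(multi, individuals$labelled_genet[i]), 1)
        geno[i, ] <- gg[target, ]
        individuals$true_genet[i] <- target
        mis <- rbind(mis, data.frame(ind_id = v, true_genet = target,
                                     labelled_genet = individuals$labelled_genet[i],
                                     class = "reassigned"))
      }
    }
    pop <- list(individuals = individuals, geno = geno,
                loci = data.frame(locus_id = sprintf("L%04d", seq_len(n_loci)),
                                  p = p, stringsAsFactors = FALSE),
                ramet_structure = ramets, mislabels = mis,
                genets = data.frame(genet_id = genet_ids,
                                    pool = "Ambrolauri",
                                    stringsAsFactors = FALSE))
    colnames(pop$geno) <- pop$loci$locus_id
    class(pop) <- "ClonePopulation"
    pop
  })
}

#' @export
print.ClonePopulation <- function(x, ...) {
  cat(sprintf(
    "ClonePopulation: %d individuals, %d genets, %d loci, %d mislabels\n",
    nrow(x$individuals), length(x$ramet_structure), nrow(x$loci),
    nrow(x$mislabels)))
  invisible(x)
}

#' Simulate targeted amplicon read counts for a clone population
#'
#' Per-cell depth is negative-binomially dispersed around the mean; alt
#' read counts are binomial around the dosage with sequencing error
#' \code{err}; a \code{dropout} fraction of cells gets zero depth.
#'
#' @param pop a [build_clone_population()] result.
#' @param loci indices (or locus ids) of loci to amplify; default all.
#' @param mean_depth mean coverage depth per cell (default 21).
#' @param err per-read allele error rate.
#' @param dropout fraction of individual x locus cells with zero depth.
#' @param dispersion negative-binomial size parameter.
#' @param seed RNG seed.
#' @return list of individuals x loci matrices \code{ref}, \code{alt}.
#' @export
simulate_amplicons <- function(pop, loci = NULL, mean_depth = 21, err = 0.01,
                               dropout = 0.02, dispersion = 8, seed = 1L) {
  g <- pop$geno
  if (!is.null(loci)) g <- g[, loci, drop = FALSE]
  n <- nrow(g); m <- ncol(g)
  with_seed(seed, {
    depth <- matrix(stats::rnbinom(n * m, mu = mean_depth, size = dispersion),
                    n, m, dimnames = dimnames(g))
    if (dropout > 0)
      depth[matrix(runif(n * m) < dropout, n, m)] <- 0L
    p_alt <- matrix(c(err, 0.5, 1 - err)[g + 1L], n, m)
    alt <- matrix(rbinom(n * m, as.vector(depth), as.vector(p_alt)),
                  n, m, dimnames = dimnames(g))
    list(ref = depth - alt, alt = alt)
  })
}
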