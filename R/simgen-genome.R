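#' Generate a synthetic repeat-rich genome with a diverged sister reference
#'
#' Emulates the study system at desk scale: a genome dominated by high-copy
#' repeat families, interspersed single-copy ("low-copy") regions plus a
#' small class of 2-copy duplicated segments (the "1-2x" regions a low-copy
#' draft assembly collapses), a diverged related-species reference copy, and
#' a fragmented noisy draft assembly of the low-copy regions. All components
#' are truth-labelled so downstream calls can be scored.
#'
#' @param size genome size in bp (>= 50 kb).
#' @param repeat_fraction fraction of the genome in high-copy repeats.
#' @param n_repeat_families number of repeat families.
#' @param divergence substitutions/site between the genome and the sister
#'   reference (0-0.1).
#' @param frag_n50 target N50 of the draft contigs (bp).
#' @param seed RNG seed (fixed seed gives byte-identical output).
#' @param dup_share fraction of non-repeat sequence present in two copies.
#' @param copy_divergence substitutions/site between copies of a repeat
#'   family or duplicated segment.
#' @param indel_rate short indels/site in the sister reference (lengths
#'   1-3 bp); defaults to \code{divergence / 50}.
#' @param draft_noise substitution noise in draft contigs (default 0.002).
#' @return a \code{SyntheticGenome} list; see Details.
#' @details Fields: \code{truth} (named sequence), \code{silver_ref},
#'   \code{draft_contigs}, \code{segments} (typed interval table),
#'   \code{lowcopy_intervals} (unique + collapsed-duplicate copy A, the
#'   regions the draft covers), \code{lowcopy12_intervals} (all 1-2x
#'   sequence, i.e. including the second duplicate copies),
#'   \code{unique_intervals},
#'   \code{contigs_truth} (draft contig origins), \code{silver_subs},
#'   \code{silver_indels}, \code{params}.
#' @export
generate_genome <- function(size = 2e5, repeat_fraction = 0.75,
                            n_repeat_families = 3, divergence = 0.02,
                            frag_n50 = 600, seed = 1L, dup_share = 0.3,
                            copy_divergence = 0.01, indel_rate = NULL,
                            draft_noise = 0.002) {
  if (repeat_fraction >= 1) stop_domain("repeat_fraction must be < 1")
  if (repeat_fraction < 0) stop_domain("repeat_fraction must be >= 0")
  if (size < 5e4) stop_domain("size must be >= 50 kb")
  if (divergence < 0 || divergence > 0.1)
    stop_domain("divergence must be in [0, 0.1]")
  if (is.null(indel_rate)) indel_rate <- divergence / 50
  with_seed(seed, {
    rep_budget <- round(repeat_fraction * size)
    nonrep <- size - rep_budget
    dup_total <- round(dup_share * nonrep / 2)  # bases per copy
    uniq_total <- nonrep - 2 * dup_total

    segs <- list()
    # repeat families: tandem + dispersed copies of a few units
    fams <- list()
    if (rep_budget > 0) {
      fam_budget <- rep(rep_budget %/% n_repeat_families, n_repeat_families)
      fam_budget[1] <- fam_budget[1] + rep_budget %% n_repeat_families
      for (f in seq_len(n_repeat_families)) {
        ulen <- min(sample(500:2000, 1), max(fam_budget[f] %/% 2L, 100L))
        unit <- random_dna(ulen)
        # full copies plus one truncated copy so the family budget is met
        # exactly and the realized composition matches the target
        lens <- rep(ulen, fam_budget[f] %/% ulen)
        rest <- fam_budget[f] - sum(lens)
        if (rest > 0) lens <- c(lens, rest)
        copies <- vapply(lens, function(l) {
          cp <- substr(unit, 1L, l)
          nmut <- rbinom(1, l, copy_divergence)
          mutate_bases(cp, sample.int(l, nmut))
        }, character(1))
        fams[[f]] <- list(unit = unit, n_copies = length(lens))
        for (cp in copies)
          segs[[length(segs) + 1L]] <- list(seq = cp, type = "repeat",
                                            family = f, partner = NA_integer_)
      }
    }
    # unique low-copy pieces (~2-5 kb)
    left <- uniq_total
    while (left > 0) {
      l <- min(left, sample(2000:5000, 1))
      if (left - l < 500) l <- left
      segs[[length(segs) + 1L]] <- list(seq = random_dna(l), type = "unique",
                                        family = NA_integer_,
                                        partner = NA_integer_)
      left <- left - l
    }
    # duplicated segments, two diverged copies each
    left <- dup_total
    pair_id <- 0L
    while (left > 0) {
      l <- min(left, sample(1000:2000, 1))
      if (left - l < 500) l <- left
      pair_id <- pair_id + 1L
      a <- random_dna(l)
      b <- mutate_bases(a, sample.int(l, rbinom(1, l, copy_divergence)))
      segs[[length(segs) + 1L]] <- list(seq = a, type = "dupA",
                                        family = NA_integer_, partner = pair_id)
      segs[[length(segs) + 1L]] <- list(seq = b, type = "dupB",
                                        family = NA_integer_, partner = pair_id)
      left <- left - l
    }
    segs <- segs[sample.int(length(segs))]
    lens <- vapply(segs, function(s) nchar(s$seq), integer(1))
    ends <- cumsum(lens)
    starts <- ends - lens
    truth <- paste(vapply(segs, `[[`, character(1), "seq"), collapse = "")
    segments <- data.frame(
      start = starts, end = ends,
      type = vapply(segs, `[[`, character(1), "type"),
      family = vapply(segs, function(s) as.integer(s$family), integer(1)),
      partner = vapply(segs, function(s) as.integer(s$partner), integer(1)),
      stringsAsFactors = FALSE)

    lc <- segments[segments$type %in% c("unique", "dupA"), c("start", "end")]
    uq <- segments[segments$type == "unique", c("start", "end")]
    lc12 <- segments[segments$type %in% c("unique", "dupA", "dupB"),
                     c("start", "end")]
    lc <- data.frame(contig = "genome1", lc, row.names = NULL)
    uq <- data.frame(contig = "genome1", uq, row.names = NULL)
    lc12 <- data.frame(contig = "genome1", lc12, row.names = NULL)

    # sister-species reference: substitutions + rare short indels
    n_sub <- rbinom(1, size, divergence)
    sub_pos <- sort(sample.int(size, n_sub))  # 1-based
    silver <- mutate_bases(truth, sub_pos)
    n_ind <- rbinom(1, size, indel_rate)
    ind_pos <- sort(sample.int(size - 10L, n_ind))
    ind_len <- if (n_ind) sample(1:3, n_ind, replace = TRUE) else integer()
    ind_ins <- if (n_ind) runif(n_ind) < 0.5 else logical()
    if (n_ind > 0) {
      ch <- strsplit(silver, "", fixed = TRUE)[[1]]
      pieces <- character(0)
      prev <- 1L
      for (i in seq_len(n_ind)) {
        p <- ind_pos[i]
        if (ind_ins[i]) {
          pieces <- c(pieces, paste(ch[prev:p], collapse = ""),
                      random_dna(ind_len[i]))
          prev <- p + 1L
        } else {
          pieces <- c(pieces, paste(ch[prev:p], collapse = ""))
          prev <- p + 1L + ind_len[i]
        }
      }
      pieces <- c(pieces, paste(ch[prev:length(ch)], collapse = ""))
      silver <- paste(pieces, collapse = "")
    }
    silver_indels <- data.frame(truth_pos = ind_pos,
                                shift = ifelse(ind_ins, 1L, -1L) * ind_len)

    # draft assembly: fragments of the low-copy intervals with base noise
    ctg_seq <- character(0)
    ctg_truth <- list()
    for (i in seq_len(nrow(lc))) {
      s <- lc$start[i]; e <- lc$end[i]
      pos <- s
      while (e - pos >= 100) {
        l <- round(runif(1, 0.5, 1.5) * frag_n50)
        l <- min(l, e - pos)
        if (e - pos - l < 100) l <- e - pos
        frag <- substr(truth, pos + 1L, pos + l)
        nmut <- rbinom(1, l, draft_noise)
        mut_at <- sample.int(l, nmut)
        frag <- mutate_bases(frag, mut_at)
        ctg_seq <- c(ctg_seq, frag)
        ctg_truth[[length(ctg_truth) + 1L]] <-
          data.frame(src_start = pos, src_end = pos + l, n_noise = nmut)
        pos <- pos + l
      }
    }
    names(ctg_seq) <- sprintf("ctg%05d", seq_along(ctg_seq))
    contigs_truth <- do.call(rbind, ctg_truth)
    contigs_truth <- data.frame(contig = names(ctg_seq), contigs_truth,
                                row.names = NULL)

    g <- list(truth = c(genome1 = truth),
              silver_ref = c(genome1 = silver),
              draft_contigs = ctg_seq,
              segments = segments,
              lowcopy_intervals = lc,
              lowcopy12_intervals = lc12,
              unique_intervals = uq,
              repeat_families = fams,
              contigs_truth = contigs_truth,
              silver_subs = sub_pos - 1L,
              silver_indels = silver_indels,
              params = list(size = size, repeat_fraction = repeat_fraction,
                            divergence = divergence, frag_n50 = frag_n50,
                            copy_divergence = copy_divergence,
                            draft_noise = draft_noise, seed = seed))
    realized <- sum(segments$end - segments$start)
    stopifnot(realized == size ||
                abs(realized - size) / size < 0.02)
    class(g) <- "SyntheticGenome"
    g
  })
}

#' @export
print.SyntheticGenome <- function(x, ...) {
  cat(sprintf(
    "SyntheticGenome: %d bp (%.0f%% repeat), %d draft contigs, silver ref %d bp\n",
    nchar(x$truth), 100 * realized_repeat_fraction(x),
    length(x$draft_contigs), nchar(x$silver_ref)))
  invisible(x)
}

#' Realized high-copy repeat fraction of a synthetic genome
#' @param genome a SyntheticGenome.
#' @return fraction of genome bases inside planted repeat copies.
#' @export
realized_repeat_fraction <- function(genome) {
  s <- genome$segments
  sum((s$end - s$start)[s$type == "repeat"]) / nchar(genome$truth)
}

#' Convert truth-genome coordinates to sister-reference coordinates
#'
#' Accounts for the short indels introduced when deriving the sister
#' reference; identity when the genome was generated without indels.
#'
#' @param genome a SyntheticGenome.
#' @param pos 0-based truth positions.
#' @return 0-based positions on \code{silver_ref}.
#' @export
truth_to_silver <- function(genome, pos) {
  ind <- genome$silver_indels
  if (nrow(ind) == 0L) return(pos)
  vapply(pos, function(p) {
    p + sum(ind$shift[ind$truth_pos <= p])
  }, numeric(1))
}

#' Sample haploid megagametophyte genomes with planted SNPs
#'
#' Plants truth SNPs on the genome at the requested density with
#' Balding-Nichols differentiated allele frequencies between two gene
#' pools, then draws one allele per haploid individual (megagametophytes
#' carry a single allele per locus).
#'
#' @param genome a SyntheticGenome.
#' @param n number of haploid individuals (>= 2).
#' @param pool_assignment pool label per individual (two pools).
#' @param snp_density SNPs per bp (default 1/200).
#' @param seed RNG seed.
#' @param fst differentiation of the pool split (default 0.1).
#' @return list with \code{haploids} (named sequences), \code{truth_snps}
#'   (0-based \code{pos}, \code{ref}, \code{alt}, pool frequencies, one
#'   logical carrier column per haploid), and \code{pool}.
#' @export
sample_haploids <- function(genome, n = 4, pool_assignment = NULL,
                            snp_density = 1 / 200, seed = 1L, fst = 0.1) {
  if (n < 2) stop_domain("need at least 2 haploids")
  if (is.null(pool_assignment))
    pool_assignment <- rep(c("A", "B"), length.out = n)
  stopifnot(length(pool_assignment) == n)
  truth <- genome$truth[[1]]
  L <- nchar(truth)
  with_seed(seed, {
    pos <- which(runif(L) < snp_density)  # 1-based
    m <- length(pos)
    ch <- strsplit(truth, "", fixed = TRUE)[[1]]
    ref <- ch[pos]
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1), USE.NAMES = FALSE)
    p0 <- runif(m, 0.1, 0.9)
    bn <- function(p) {
      if (fst <= 0) return(p)
      rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
    }
    pA <- bn(p0); pB <- bn(p0)
    carriers <- matrix(FALSE, m, n)
    pools <- unique(pool_assignment)
    for (i in seq_len(n)) {
      p <- if (pool_assignment[i] == pools[1]) pA else pB
      carriers[, i] <- runif(m) < p
    }
    ids <- sprintf("H%d", seq_len(n))
    colnames(carriers) <- ids
    haploids <- vapply(seq_len(n), function(i) {
      hc <- ch
      hc[pos[carriers[, i]]] <- alt[carriers[, i]]
      paste(hc, collapse = "")
    }, character(1))
    names(haploids) <- ids
    truth_snps <- data.frame(pos = pos - 1L, ref = ref, alt = alt,
                             p_A = pA, p_B = pB, stringsAsFactors = FALSE)
    truth_snps <- cbind(truth_snps, as.data.frame(carriers))
    list(haploids = haploids, truth_snps = truth_snps,
         pool = stats::setNames(pool_assignment, ids))
  })
}
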