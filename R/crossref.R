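#' Anchor draft contigs to a reference
#'
#' Seed hits vote for a candidate reference window and strand; the contig
#' is then aligned to the winning window (Needleman-Wunsch, global-local)
#' and the gapless blocks of the alignment become anchors. Contigs whose
#' second-best placement is nearly as well supported as the best are
#' ambiguous (repeats) and dropped. Anchors shorter than \code{min_len}
#' or below \code{min_identity} are discarded.
#'
#' @param contigs named character vector of draft contigs.
#' @param ref named reference sequences.
#' @param min_len minimum anchor length in bp (default 100).
#' @param min_identity minimum anchor identity (default 0.9).
#' @param seed_len seed length for placement voting (default 15).
#' @return an \code{AnchorMap}: data.frame of anchors (contig interval,
#'   reference interval, strand, identity; all 0-based half-open, blocks
#'   gapless so interval lengths match exactly). Attribute
#'   \code{n_ambiguous} counts dropped multi-placement contigs.
#' @export
anchor_contigs <- function(contigs, ref, min_len = 100L, min_identity = 0.9,
                           seed_len = 15L) {
  idx <- ref_seed_index(ref, seed_len)
  anchors <- list()
  n_ambiguous <- 0L
  for (ci in seq_along(contigs)) {
    cseq <- contigs[[ci]]
    L <- nchar(cseq)
    if (L < seed_len) next
    best <- NULL
    votes <- list()
    for (strand in c("+", "-")) {
      q <- if (strand == "+") cseq else revcomp(cseq)
      off <- seq.int(1L, L - seed_len + 1L, by = 10L)
      dt <- data.table::data.table(
        offset = off, seed = substring(q, off, off + seed_len - 1L))
      hits <- idx[dt, on = "seed", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hits) == 0L) next
      hits[, diag := hit_pos - (offset - 1L)]
      hits[, diagbin := round(diag / 50)]
      v <- hits[, .(n = .N, diag0 = as.integer(round(stats::median(diag)))),
                by = .(contig, diagbin)]
      v[, strand := strand]
      votes[[strand]] <- v
    }
    votes <- data.table::rbindlist(votes)
    if (nrow(votes) == 0L) next
    data.table::setorder(votes, -n)
    # merge adjacent diagonal bins of the same placement before ranking
    top <- votes[1L]
    rival <- votes[!(contig == top$contig & strand == top$strand &
                       abs(diagbin - top$diagbin) <= 1L)]
    if (nrow(rival) && rival$n[1L] >= 0.8 * top$n) {
      n_ambiguous <- n_ambiguous + 1L
      next
    }
    cg <- top$contig
    q <- if (top$strand == "+") cseq else revcomp(cseq)
    ws <- max(0L, top$diag0 - 50L)                 # 0-based window start
    we <- min(nchar(ref[[cg]]), top$diag0 + L + 50L)
    window <- substr(ref[[cg]], ws + 1L, we)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(window),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3),
      gapOpening = 6, gapExtension = 3)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    sub_start0 <- ws + BiocGenerics::start(Biostrings::subject(pa)) - 1L
    blocks <- alignment_blocks(ap, as_, sub_start0)
    if (nrow(blocks) == 0L) next
    blocks <- blocks[blocks$len >= min_len & blocks$identity >= min_identity,
                     , drop = FALSE]
    if (nrow(blocks) == 0L) next
    if (top$strand == "-") {
      # convert query coords (on the rc contig) back to contig coords
      qs <- blocks$q_start; qe <- blocks$q_end
      blocks$q_start <- L - qe
      blocks$q_end <- L - qs
    }
    anchors[[length(anchors) + 1L]] <- data.frame(
      contig = names(contigs)[ci], c_start = blocks$q_start,
      c_end = blocks$q_end, ref = cg, r_start = blocks$r_start,
      r_end = blocks$r_end, strand = top$strand,
      identity = blocks$identity, stringsAsFactors = FALSE)
  }
  if (length(anchors) == 0L) {
    am <- data.frame(contig = character(), c_start = integer(),
                     c_end = integer(), ref = character(),
                     r_start = integer(), r_end = integer(),
                     strand = character(), identity = numeric(),
                     stringsAsFactors = FALSE)
  } else {
    am <- do.call(rbind, anchors)
    rownames(am) <- NULL
  }
  class(am) <- c("AnchorMap", "data.frame")
  attr(am, "n_ambiguous") <- n_ambiguous
  am
}

# gapless blocks of an alignment given aligned pattern/subject strings;
# coordinates 0-based half-open (q on the aligned query, r on the ref)
alignment_blocks <- function(ap, as_, sub_start0) {
  gap <- ap == "-" | as_ == "-"
  qpos <- cumsum(ap != "-")  # 1-based query coordinate at each column
  rpos <- cumsum(as_ != "-")
  if (all(gap)) return(data.frame())
  r <- rle(gap)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  ok <- which(!r$values)
  out <- lapply(ok, function(k) {
    cs <- s[k]; ce <- e[k]
    len <- ce - cs + 1L
    ident <- mean(ap[cs:ce] == as_[cs:ce])
    data.frame(q_start = qpos[cs] - 1L, q_end = qpos[ce],
               r_start = sub_start0 + rpos[cs] - 1L,
               r_end = sub_start0 + rpos[ce],
               len = len, identity = ident)
  })
  do.call(rbind, out)
}

#' Merged BED of anchored reference regions
#' @param anchor_map an [anchor_contigs()] map.
#' @return BED data.frame (contig/start/end, 0-based half-open, merged).
#' @export
anchored_regions <- function(anchor_map) {
  if (nrow(anchor_map) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    anchor_map$ref,
    IRanges::IRanges(start = anchor_map$r_start + 1L,
                     end = anchor_map$r_end)))
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
}

#' Lift contig positions to reference coordinates
#'
#' Linear offset inside the covering gapless anchor; \code{NA} when no
#' anchor covers the position. Reverse-strand anchors flip the offset
#' (allele complementation is the caller's responsibility, see
#' [lift_variants()]).
#'
#' @param anchor_map an [anchor_contigs()] map.
#' @param contig contig ids (recycled).
#' @param pos 0-based contig positions.
#' @return data.frame ref/pos/strand (NA rows where unanchored).
#' @export
lift_position <- function(anchor_map, contig, pos) {
  n <- max(length(contig), length(pos))
  contig <- rep_len(as.character(contig), n)
  pos <- rep_len(as.integer(pos), n)
  out <- data.frame(ref = rep(NA_character_, n), pos = rep(NA_integer_, n),
                    strand = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (nrow(anchor_map) == 0L) return(out)
  for (i in seq_len(n)) {
    a <- anchor_map[anchor_map$contig == contig[i] &
                      anchor_map$c_start <= pos[i] &
                      anchor_map$c_end > pos[i], , drop = FALSE]
    if (nrow(a) == 0L) next
    a <- a[1L, ]
    if (a$strand == "+") {
      out$pos[i] <- a$r_start + (pos[i] - a$c_start)
    } else {
      out$pos[i] <- a$r_start + (a$c_end - 1L - pos[i])
    }
    out$ref[i] <- a$ref
    out$strand[i] <- a$strand
  }
  out
}

#' Lift a VariantSet through an anchor map
#'
#' Positions are lifted with [lift_position()]; alleles are complemented
#' for reverse-strand anchors. Unanchored records are dropped (counted in
#' attribute \code{n_unanchored}).
#'
#' @param vars a VariantSet in contig coordinates.
#' @param anchor_map an [anchor_contigs()] map.
#' @return lifted VariantSet in reference coordinates.
#' @export
lift_variants <- function(vars, anchor_map) {
  lifted <- lift_position(anchor_map, vars$contig, vars$pos)
  keep <- !is.na(lifted$pos)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  ref <- vars$ref[keep]; alt <- vars$alt[keep]
  neg <- lifted$strand[keep] == "-"
  ref[neg] <- comp(ref[neg]); alt[neg] <- comp(alt[neg])
  out <- variant_set(lifted$ref[keep], lifted$pos[keep], ref, alt,
                     af = vars$af[keep], mq = vars$mq[keep],
                     method = vars$method[keep])
  attr(out, "n_unanchored") <- sum(!keep)
  out
}

#' Intersect two variant sets
#'
#' Default mode matches on position and (order- and strand-normalised)
#' alleles; \code{mode = "position"} matches on coordinates only. The
#' partition is exact: \code{shared + a_only == a}.
#'
#' @param a,b VariantSets on the same coordinate system.
#' @param mode \code{"position+alleles"} (default) or \code{"position"}.
#' @return list of VariantSets \code{shared}, \code{a_only}, \code{b_only}
#'   (records taken from \code{a} for \code{shared}).
#' @export
intersect_variant_sets <- function(a, b, mode = c("position+alleles",
                                                  "position")) {
  mode <- match.arg(mode)
  keyfun <- function(v) {
    if (mode == "position") return(paste(v$contig, v$pos))
    comp <- function(x) chartr("ACGT", "TGCA", x)
    pair <- paste(pmin(v$ref, v$alt), pmax(v$ref, v$alt))
    pair_rc <- paste(pmin(comp(v$ref), comp(v$alt)),
                     pmax(comp(v$ref), comp(v$alt)))
    paste(v$contig, v$pos, pmin(pair, pair_rc))
  }
  ka <- keyfun(a); kb <- keyfun(b)
  sel <- ka %in% kb
  subset_vs <- function(v, i) {
    out <- v[i, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("VariantSet", "data.frame")
    out
  }
  list(shared = subset_vs(a, sel), a_only = subset_vs(a, !sel),
       b_only = subset_vs(b, !(kb %in% ka)))
}

#' Indirect cross-reference intersection
#'
#' Reproduces the two-reference intersection that cannot be done directly:
#' draft contigs are anchored to the sister reference, and the
#' reference-based call set is restricted to the anchored regions
#' (\code{mode = "region"}, the default bookkeeping). The stricter
#' \code{mode = "lift"} additionally lifts the contig-based calls and
#' requires position + allele agreement.
#'
#' @param ref_vars VariantSet on the sister reference.
#' @param contig_vars VariantSet on the draft contigs.
#' @param anchor_map an [anchor_contigs()] map (contigs -> reference).
#' @param mode \code{"region"} or \code{"lift"}.
#' @return for \code{"region"}: VariantSet of \code{ref_vars} inside
#'   anchored regions; for \code{"lift"}: the [intersect_variant_sets()]
#'   partition against the lifted contig calls.
#' @export
indirect_intersection <- function(ref_vars, contig_vars, anchor_map,
                                  mode = c("region", "lift")) {
  mode <- match.arg(mode)
  bed <- anchored_regions(anchor_map)
  if (mode == "region") {
    if (nrow(bed) == 0L || nrow(ref_vars) == 0L)
      return(ref_vars[integer(0), , drop = FALSE])
    gr_v <- GenomicRanges::GRanges(
      ref_vars$contig, IRanges::IRanges(start = ref_vars$pos + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(gr_v, bed_to_granges(bed))
    out <- ref_vars[sort(unique(S4Vectors::queryHits(ov))), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("VariantSet", "data.frame")
    return(out)
  }
  lifted <- lift_variants(contig_vars, anchor_map)
  intersect_variant_sets(ref_vars, lifted)
}

#' Transition/transversion substitution spectrum
#'
#' A<->G and C<->T are transitions; the other four undirected allele
#' pairs are transversions. Records with non-ACGT alleles are skipped
#' and counted.
#'
#' @param vars a biallelic VariantSet.
#' @return a \code{SubstitutionSpectrum}: per-class counts, \code{ts},
#'   \code{tv}, \code{ratio} and class proportions.
#' @export
tstv <- function(vars) {
  ok <- vars$ref %in% c("A", "C", "G", "T") &
    vars$alt %in% c("A", "C", "G", "T") & vars$ref != vars$alt
  cls <- paste(pmin(vars$ref[ok], vars$alt[ok]),
               pmax(vars$ref[ok], vars$alt[ok]), sep = "-")
  classes <- c("A-G", "C-T", "A-C", "G-T", "A-T", "C-G")
  counts <- vapply(classes, function(k) sum(cls == k), integer(1))
  ts <- sum(counts[c("A-G", "C-T")])
  tv <- sum(counts[c("A-C", "G-T", "A-T", "C-G")])
  sp <- list(counts = counts, ts = ts, tv = tv,
             ratio = if (tv > 0) ts / tv else NA_real_,
             proportions = if (ts + tv > 0) counts / (ts + tv) else counts,
             n_skipped = sum(!ok))
  class(sp) <- "SubstitutionSpectrum"
  sp
}

#' @export
print.SubstitutionSpectrum <- function(x, ...) {
  cat(sprintf("Ts/Tv spectrum: ts=%d tv=%d ratio=%.2f (skipped %d)\n",
              x$ts, x$tv, x$ratio, x$n_skipped))
  invisible(x)
}

#' Mean inter-SNP spacing
#'
#' @param n_snps number of SNPs.
#' @param span genome span in bp.
#' @return \code{round(span / n_snps)} -- "one SNP every N bases".
#' @export
snp_density <- function(n_snps, span) {
  if (n_snps <= 0) stop_domain("n_snps must be > 0")
  round(span / n_snps)
}
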