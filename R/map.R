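#' Seed-and-extend read mapping
#'
#' A deliberately simple gapless mapper standing in for a production
#' aligner on synthetic data: exact seeds at a few offsets per read are
#' looked up in a reference seed table, candidate placements are scored by
#' full-length mismatch count, and the single best placement per read is
#' reported (like a primary alignment). MAPQ is 0 when the best score is
#' tied between placements -- the behaviour that, on a repeat-bearing or
#' collapsed reference, produces the pileup-inflation pathology the
#' anchor-region read subsetting then repairs. Real alignments can be
#' imported with [read_sam()] instead.
#'
#' @param reads a [read_set()].
#' @param ref named character vector of reference sequences.
#' @param seed_len exact seed length (default 21).
#' @param max_mismatch maximum mismatches for a reported placement.
#' @param seed_step spacing between seed offsets along the read.
#' @return alignment data.frame (0-based \code{start}, \code{mapq},
#'   \code{nm}, CIGAR always full-length M, \code{seq}/\code{qual} oriented
#'   to the reference strand). Attribute \code{unmapped}: ids of unplaced
#'   reads.
#' @export
seed_map <- function(reads, ref, seed_len = 21L, max_mismatch = 10L,
                     seed_step = 35L) {
  seed_len <- as.integer(seed_len)
  idx <- ref_seed_index(ref, seed_len)
  rl <- nchar(reads$seq)
  cand <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") reads$seq else revcomp(reads$seq)
    usable <- which(rl >= seed_len)
    offs <- lapply(rl[usable], function(L)
      unique(c(seq.int(1L, L - seed_len + 1L, by = seed_step),
               L - seed_len + 1L)))
    no <- lengths(offs)
    dt <- data.table::data.table(
      read_row = rep(usable, no),
      offset = unlist(offs))
    dt[, seed := substring(qseq[read_row], offset, offset + seed_len - 1L)]
    hits <- idx[dt, on = "seed", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0L) next
    hits[, start0 := hit_pos - (offset - 1L)]
    hits <- unique(hits[, .(read_row, contig, start0)])
    hits[, strand := strand]
    hits[, seq := qseq[read_row]]
    cand[[strand]] <- hits
  }
  cand <- data.table::rbindlist(cand)
  empty <- data.frame(id = character(), mate = integer(),
                      sample_id = character(), contig = character(),
                      start = integer(), strand = character(),
                      mapq = integer(), cigar = character(),
                      nm = integer(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) {
    attr(empty, "unmapped") <- unique(reads$id)
    return(empty)
  }
  cand[, nm := NA_integer_]
  for (cg in unique(cand$contig)) {
    i <- which(cand$contig == cg)
    cand$nm[i] <- hamming_at_cpp(ref[[cg]], cand$start0[i], cand$seq[i])
  }
  cand <- cand[!is.na(nm) & nm <= max_mismatch]
  if (nrow(cand) == 0L) {
    attr(empty, "unmapped") <- unique(reads$id)
    return(empty)
  }
  data.table::setorder(cand, read_row, nm, contig, start0, strand)
  stats <- cand[, .(d1 = nm[1L], n_best = sum(nm == nm[1L]),
                    d2 = if (.N > 1L && any(nm > nm[1L]))
                      min(nm[nm > nm[1L]]) else NA_integer_),
                by = read_row]
  best <- cand[, .SD[1L], by = read_row]
  best <- stats[best, on = "read_row"]
  best[, mapq := data.table::fifelse(
    n_best > 1L, 0L,
    data.table::fifelse(is.na(d2), 60L, pmin(60L, 6L * (d2 - d1))))]
  i <- best$read_row
  qual <- reads$qual[i]
  rc <- best$strand == "-"
  qual[rc] <- stringi::stri_reverse(qual[rc])
  out <- data.frame(id = reads$id[i], mate = reads$mate[i],
                    sample_id = reads$sample_id[i],
                    contig = best$contig, start = best$start0,
                    strand = best$strand, mapq = best$mapq,
                    cigar = paste0(nchar(best$seq), "M"),
                    nm = best$d1, seq = best$seq, qual = qual,
                    stringsAsFactors = FALSE)
  attr(out, "unmapped") <-
    setdiff(unique(reads$id), unique(out$id))
  out
}

ref_seed_index <- function(ref, seed_len) {
  parts <- lapply(names(ref), function(nm) {
    L <- nchar(ref[[nm]])
    if (L < seed_len) return(NULL)
    pos <- seq_len(L - seed_len + 1L)
    data.table::data.table(
      seed = substring(ref[[nm]], pos, pos + seed_len - 1L),
      contig = nm, hit_pos = pos - 1L)
  })
  idx <- data.table::rbindlist(parts)
  idx <- idx[!grepl("[^ACGT]", seed)]
  data.table::setkey(idx, seed)
  idx
}

#' Per-position depth profile of an alignment set
#'
#' @param aln alignment data.frame (full-length M alignments).
#' @param ref named reference sequences (for contig lengths).
#' @return a \code{DepthProfile}: list of per-contig integer depth vectors
#'   plus the overall mean depth \code{d}.
#' @export
depth_profile <- function(aln, ref) {
  profiles <- lapply(names(ref), function(cg) {
    L <- nchar(ref[[cg]])
    inc <- integer(L + 1L)
    a <- aln[aln$contig == cg, , drop = FALSE]
    if (nrow(a)) {
      w <- nchar(a$seq)
      s <- a$start + 1L
      e <- pmin(a$start + w, L) + 1L
      inc <- tabulate(s, L + 1L) - tabulate(e, L + 1L)
    }
    cumsum(inc[seq_len(L)])
  })
  names(profiles) <- names(ref)
  dp <- list(profiles = profiles,
             d = mean(unlist(profiles)))
  class(dp) <- "DepthProfile"
  dp
}

#' Mask of positions exceeding the maximum-depth threshold
#'
#' Flags positions whose depth exceeds \code{d + 4*sqrt(d)} with \code{d}
#' the profile mean -- the classical maximum-depth alternative to
#' anchor-region read subsetting (off by default in the pipeline).
#'
#' @param profile a [depth_profile()].
#' @return BED-style data.frame of masked intervals (0-based half-open).
#' @export
max_depth_mask <- function(profile) {
  if (length(profile$profiles) == 0L ||
      sum(lengths(profile$profiles)) == 0L)
    stop_domain("empty depth profile")
  thr <- profile$d + 4 * sqrt(profile$d)
  out <- list()
  for (cg in names(profile$profiles)) {
    v <- profile$profiles[[cg]] > thr
    if (!any(v)) next
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    out[[cg]] <- data.frame(contig = cg, start = s[r$values],
                            end = e[r$values])
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subset reads whose alignments overlap anchor regions
#'
#' Given alignments of haploid reads to the sister reference and the BED of
#' regions where draft contigs anchor, returns the reads overlapping those
#' regions by at least one base -- the read-subsetting workaround that
#' repairs depth inflation when re-mapping to the small draft assembly.
#'
#' @param aln alignments of the reads to the sister reference.
#' @param anchor_bed BED data.frame (contig/start/end, 0-based half-open).
#' @param reads the original ReadSet to subset.
#' @return list: \code{ids} (template ids) and \code{reads} (ReadSet
#'   subset; both mates of an overlapping template are returned).
#' @export
subset_reads_by_anchor_regions <- function(aln, anchor_bed, reads) {
  missing_ctg <- setdiff(anchor_bed$contig, unique(aln$contig))
  if (length(missing_ctg))
    warning("anchor contigs absent from alignments: ",
            paste(missing_ctg, collapse = ", "))
  bed <- anchor_bed[!anchor_bed$contig %in% missing_ctg, , drop = FALSE]
  gr_aln <- GenomicRanges::GRanges(
    aln$contig, IRanges::IRanges(start = aln$start + 1L,
                                 end = aln$start + nchar(aln$seq)))
  ov <- GenomicRanges::findOverlaps(gr_aln, bed_to_granges(bed),
                                    minoverlap = 1L)
  ids <- unique(aln$id[S4Vectors::queryHits(ov)])
  sub <- reads[reads$id %in% ids, , drop = FALSE]
  rownames(sub) <- NULL
  class(sub) <- c("ReadSet", "data.frame")
  list(ids = ids, reads = sub)
}

#' Fraction of covered positions above a depth multiple
#' @param profile a [depth_profile()].
#' @param expected expected depth.
#' @param mult multiple of the expected depth (default 2).
#' @return fraction of positions with depth greater than
#'   \code{mult * expected}.
#' @export
frac_above_depth <- function(profile, expected, mult = 2) {
  v <- unlist(profile$profiles)
  mean(v > mult * expected)
}
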