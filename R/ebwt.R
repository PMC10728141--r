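#' Build the extended Burrows-Wheeler Transform of a read collection
#'
#' Reads (optionally together with their reverse complements, needed for
#' strand-agnostic positional clustering) are concatenated with one
#' distinct terminator per string; terminators sort before the bases and
#' among themselves by string index, giving a stable generalized suffix
#' array. The eBWT character at row i is the character preceding suffix
#' SA[i]. Reads containing N are split into N-free fragments.
#'
#' @param reads a [read_set()] (or plain character vector of sequences).
#' @param include_rc index reverse complements alongside (default TRUE).
#' @return an \code{EBWTIndex}: suffix array and LCP array (0-based SA),
#'   eBWT symbols, per-position string of origin, string offsets and
#'   provenance of each indexed string.
#' @export
build_ebwt <- function(reads, include_rc = TRUE) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  if (length(seqs) == 0L) stop_domain("empty read set")
  src <- seq_along(seqs)
  if (any(grepl("N", seqs, fixed = TRUE))) {
    parts <- strsplit(seqs, "N+")
    src <- rep(src, lengths(parts))
    seqs <- unlist(parts)
    keep <- nchar(seqs) > 0L
    seqs <- seqs[keep]; src <- src[keep]
  }
  is_rc <- rep(FALSE, length(seqs))
  if (include_rc) {
    seqs <- c(seqs, revcomp(seqs))
    src <- c(src, src)
    is_rc <- c(is_rc, rep(TRUE, length(is_rc)))
  }
  m <- length(seqs)
  lens <- nchar(seqs)
  offsets <- cumsum(c(0L, lens + 1L))[seq_len(m)]  # 0-based string starts
  code <- c(A = m + 1L, C = m + 2L, G = m + 3L, T = m + 4L)
  chars <- strsplit(seqs, "", fixed = TRUE)
  tvec <- integer(sum(lens) + m)
  str_id <- integer(length(tvec))
  p <- 1L
  for (j in seq_len(m)) {
    l <- lens[j]
    if (l > 0L) {
      tvec[p:(p + l - 1L)] <- code[chars[[j]]]
      str_id[p:(p + l - 1L)] <- j
    }
    tvec[p + l] <- j            # terminator of string j
    str_id[p + l] <- j
    p <- p + l + 1L
  }
  n <- length(tvec)
  sa <- suffix_array_cpp(tvec)
  lcp <- lcp_kasai_cpp(tvec, sa)
  bwt_int <- tvec[ifelse(sa == 0L, n, sa)]  # sa is 0-based
  text_str <- paste(ifelse(tvec > m, names(code)[pmax(tvec - m, 1L)], "$"),
                    collapse = "")
  idx <- list(tvec = tvec, sa = sa, lcp = lcp, bwt_int = bwt_int,
              str_id = str_id, offsets = offsets, lens = lens, m = m,
              src = src, is_rc = is_rc, text_str = text_str)
  class(idx) <- "EBWTIndex"
  idx
}

#' @export
print.EBWTIndex <- function(x, ...) {
  cat(sprintf("EBWTIndex: %d strings, text length %d\n", x$m,
              length(x$tvec)))
  invisible(x)
}

#' eBWT symbols as characters ("$" for any terminator)
#' @param index an [build_ebwt()] index.
#' @return character vector of eBWT symbols in SA order.
#' @export
ebwt_chars <- function(index) {
  ifelse(index$bwt_int > index$m,
         c("A", "C", "G", "T")[pmax(index$bwt_int - index$m, 1L)], "$")
}

#' Invert the eBWT back to the indexed strings
#'
#' Uses only the eBWT symbol sequence and LF-mapping: row j of the sorted
#' matrix starts with terminator j, and stepping LF from it spells string
#' j backwards until the preceding terminator. Serves as the round-trip
#' correctness check of the construction.
#'
#' @param index an [build_ebwt()] index.
#' @return character vector of the indexed strings, in input order.
#' @export
invert_ebwt <- function(index) {
  bwt <- index$bwt_int
  m <- index$m
  tab <- tabulate(bwt, nbins = m + 4L)
  C <- c(0L, cumsum(tab))  # C[v+1] = #symbols < v... C[v] offset below
  rk <- stats::ave(seq_along(bwt), bwt, FUN = seq_along)
  LF <- C[bwt] + rk
  base <- c("A", "C", "G", "T")
  out <- character(m)
  for (j in seq_len(m)) {
    r <- j
    chars <- character(0)
    repeat {
      v <- bwt[r]
      if (v <= m) break
      chars <- c(chars, base[v - m])
      r <- LF[r]
    }
    out[j] <- paste(rev(chars), collapse = "")
  }
  out
}

#' Detect positional clusters in an eBWT index
#'
#' Maximal SA intervals whose interior LCP values all reach
#' \code{min_context} (the suffixes share a right context of at least that
#' length) and whose size reaches \code{min_size}. Such clusters gather
#' the characters preceding the same genomic locus across reads.
#'
#' @param index an [build_ebwt()] index.
#' @param min_context minimum shared right-context length (default 20).
#' @param min_size minimum cluster size (default 4).
#' @return data.frame of clusters: 1-based SA rows \code{lo}/\code{hi}
#'   (inclusive) and shared context length \code{ctx}.
#' @export
detect_clusters <- function(index, min_context = 20L, min_size = 4L) {
  lcp <- index$lcp
  n <- length(lcp)
  adj <- lcp >= min_context
  adj[1L] <- FALSE
  r <- rle(adj)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  lo <- starts[runs] - 1L
  hi <- ends[runs]
  sz <- hi - lo + 1L
  keep <- sz >= min_size
  lo <- lo[keep]; hi <- hi[keep]
  ctx <- vapply(seq_along(lo), function(i)
    min(lcp[(lo[i] + 1L):hi[i]]), integer(1))
  data.frame(lo = lo, hi = hi, ctx = ctx)
}

#' Call SNP candidates from positional clusters
#'
#' A cluster yields a candidate iff its preceding-character multiset
#' contains exactly two bases, each supported by at least
#' \code{min_allele_support} entries (terminator entries are ignored;
#' clusters with three or more bases are dropped and counted). The
#' candidate carries the shared right context and a left context of up to
#' 30 bp per allele taken from a representative read. Duplicate
#' candidates (same context and allele pair) are merged.
#'
#' @param index an [build_ebwt()] index.
#' @param clusters a [detect_clusters()] table.
#' @param min_allele_support minimum reads per allele (default 5,
#'   one-quarter of the pooled 20x coverage).
#' @param max_ctx cap on the reported right-context length.
#' @return data.frame of candidates: alleles (alphabetical), supports,
#'   right and per-allele left contexts. Attribute \code{n_multiallelic}
#'   counts dropped many-base clusters.
#' @export
call_snps_from_clusters <- function(index, clusters, min_allele_support = 5L,
                                    max_ctx = 40L) {
  empty <- data.frame(allele_a = character(), allele_b = character(),
                      support_a = integer(), support_b = integer(),
                      right_ctx = character(), left_a = character(),
                      left_b = character(), stringsAsFactors = FALSE)
  if (nrow(clusters) == 0L) return(empty)
  sz <- clusters$hi - clusters$lo + 1L
  rows <- unlist(lapply(seq_len(nrow(clusters)),
                        function(i) clusters$lo[i]:clusters$hi[i]))
  cid <- rep(seq_len(nrow(clusters)), sz)
  ch <- ebwt_chars(index)[rows]
  dt <- data.table::data.table(cid = cid, row = rows, char = ch)
  dt <- dt[char != "$"]
  cnt <- dt[, .(n = .N), by = .(cid, char)]
  nall <- cnt[, .(k = .N), by = cid]
  multi <- nall$cid[nall$k > 2L]
  bi <- cnt[!cid %in% multi]
  ok <- bi[, .(ok = .N == 2L && all(n >= min_allele_support)), by = cid]
  good <- ok$cid[ok$ok]
  if (length(good) == 0L) {
    attr(empty, "n_multiallelic") <- length(multi)
    return(empty)
  }
  bi <- bi[cid %in% good]
  data.table::setorder(bi, cid, char)
  reps <- dt[cid %in% good, .SD[match(sort(unique(char)), char)],
             by = cid]
  cand <- bi[, .(allele_a = char[1L], allele_b = char[2L],
                 support_a = n[1L], support_b = n[2L]), by = cid]
  ctx_len <- pmin(clusters$ctx[cand$cid], as.integer(max_ctx))
  sa_lo <- index$sa[clusters$lo[cand$cid]]  # 0-based text pos of context
  cand[, right_ctx := substr(rep(index$text_str, .N), sa_lo + 1L,
                             sa_lo + ctx_len)]
  left_of <- function(row) {
    p <- index$sa[row]            # 0-based suffix start; allele at p-1
    if (p <= 0L) return("")
    s <- index$str_id[p]          # string of the preceding character
    lo0 <- max(index$offsets[s], p - 1L - 30L)
    if (p - 1L <= lo0) return("")
    substr(index$text_str, lo0 + 1L, p - 1L)
  }
  reps_a <- reps[, .SD[1L], by = cid]
  reps_b <- reps[, .SD[2L], by = cid]
  cand[, left_a := vapply(reps_a$row[match(cid, reps_a$cid)], left_of,
                          character(1))]
  cand[, left_b := vapply(reps_b$row[match(cid, reps_b$cid)], left_of,
                          character(1))]
  out <- as.data.frame(cand[, .(allele_a, allele_b, support_a, support_b,
                                right_ctx, left_a, left_b)])
  out <- out[!duplicated(paste(out$right_ctx, out$allele_a, out$allele_b)),
             , drop = FALSE]
  out <- out[order(out$right_ctx, out$allele_a), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_multiallelic") <- length(multi)
  out
}

#' Anchor reference-free SNP candidates to a reference
#'
#' The shared right context of each candidate is located in the reference
#' (exact match, both strands). A unique hit places the SNP at the base
#' immediately left of the match; the allele matching the reference
#' becomes REF and the other ALT (complemented for reverse-strand hits).
#' Candidates with zero or multiple genomic hits are dropped and counted.
#'
#' @param candidates a [call_snps_from_clusters()] table.
#' @param ref named reference sequences.
#' @param min_ctx minimum usable context length (default 20).
#' @return a [variant_set()] tagged \code{method = "ebwt"}; attribute
#'   \code{anchor_stats} reports dropped candidates by reason.
#' @export
anchor_to_reference <- function(candidates, ref, min_ctx = 20L) {
  stats <- c(anchored = 0L, no_hit = 0L, multi_hit = 0L,
             short_ctx = 0L, ref_mismatch = 0L)
  subj <- Biostrings::DNAStringSet(ref)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  rec <- list()
  for (i in seq_len(nrow(candidates))) {
    ctx <- candidates$right_ctx[i]
    if (nchar(ctx) < min_ctx) { stats["short_ctx"] <- stats["short_ctx"] + 1L; next }
    hf <- Biostrings::vmatchPattern(ctx, subj)
    hr <- Biostrings::vmatchPattern(revcomp(ctx), subj)
    nf <- sum(S4Vectors::elementNROWS(hf))
    nr <- sum(S4Vectors::elementNROWS(hr))
    tot <- nf + nr
    if (tot == 0L) { stats["no_hit"] <- stats["no_hit"] + 1L; next }
    if (tot > 1L) { stats["multi_hit"] <- stats["multi_hit"] + 1L; next }
    al <- c(candidates$allele_a[i], candidates$allele_b[i])
    sup <- c(candidates$support_a[i], candidates$support_b[i])
    if (nf == 1L) {
      cg <- which(S4Vectors::elementNROWS(hf) == 1L)
      s1 <- BiocGenerics::start(hf[[cg]])  # 1-based context start
      pos0 <- s1 - 2L
      if (pos0 < 0L) { stats["no_hit"] <- stats["no_hit"] + 1L; next }
      rb <- substr(ref[[cg]], s1 - 1L, s1 - 1L)
    } else {
      cg <- which(S4Vectors::elementNROWS(hr) == 1L)
      e1 <- BiocGenerics::end(hr[[cg]])    # 1-based context end on ref
      pos0 <- e1                            # base right of rc-context
      if (pos0 >= nchar(ref[[cg]])) { stats["no_hit"] <- stats["no_hit"] + 1L; next }
      rb <- substr(ref[[cg]], e1 + 1L, e1 + 1L)
      al <- comp(al)
    }
    hit <- which(al == rb)
    if (length(hit) != 1L) { stats["ref_mismatch"] <- stats["ref_mismatch"] + 1L; next }
    stats["anchored"] <- stats["anchored"] + 1L
    rec[[length(rec) + 1L]] <- data.frame(
      contig = names(ref)[cg], pos = pos0, ref = rb, alt = al[-hit],
      af = sup[-hit] / sum(sup), stringsAsFactors = FALSE)
  }
  if (length(rec) == 0L) {
    out <- variant_set(character(), integer(), character(), character(),
                       method = "ebwt")
  } else {
    d <- do.call(rbind, rec)
    d <- d[!duplicated(paste(d$contig, d$pos)), , drop = FALSE]
    out <- variant_set(d$contig, d$pos, d$ref, d$alt, af = d$af,
                       method = "ebwt")
  }
  attr(out, "anchor_stats") <- stats
  out
}

#' Write eBWT SNP candidates as paired context sequences
#'
#' Two FASTA records per event (allele embedded between left and right
#' context), mirroring the paired-sequence output convention of
#' reference-free callers.
#'
#' @param candidates a [call_snps_from_clusters()] table.
#' @param path output FASTA.
#' @return \code{path}, invisibly.
#' @export
write_candidates_fasta <- function(candidates, path) {
  n <- nrow(candidates)
  seqs <- character(2L * n)
  nms <- character(2L * n)
  for (i in seq_len(n)) {
    seqs[2L * i - 1L] <- paste0(candidates$left_a[i], candidates$allele_a[i],
                                candidates$right_ctx[i])
    seqs[2L * i] <- paste0(candidates$left_b[i], candidates$allele_b[i],
                           candidates$right_ctx[i])
    nms[2L * i - 1L] <- sprintf("event%05d_allele1_cov%d", i,
                                candidates$support_a[i])
    nms[2L * i] <- sprintf("event%05d_allele2_cov%d", i,
                           candidates$support_b[i])
  }
  write_fasta(stats::setNames(seqs, nms), path)
}
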