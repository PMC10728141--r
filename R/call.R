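#' Pileup-based haploid variant calling
#'
#' For every covered site and haploid sample the consensus base is called
#' with its depth and a phred-like genotype quality
#' \code{GQ = min(60, 4 * (best - second best base support))} -- a simple
#' stand-in for a full genotype-likelihood model, documented as such. A
#' site is emitted when at least one sample's call differs from the
#' reference or the samples disagree. Site MQ is the RMS MAPQ of the
#' contributing reads; per-sample minor-base support is recorded so the
#' within-individual heterozygosity rule can act downstream.
#'
#' @param aln alignment data.frame covering two or more haploid samples
#'   (column \code{sample_id}); only full-length M alignments contribute.
#' @param ref named reference sequences.
#' @param min_base_q minimum base quality for a read base to count.
#' @return a raw [variant_set()] with per-sample \code{calls},
#'   \code{depths}, \code{gqs} and \code{minor} matrices.
#' @export
pileup_call <- function(aln, ref, min_base_q = 13) {
  samples <- sort(unique(aln$sample_id))
  if (length(samples) < 2L)
    stop_domain("pileup_call needs >= 2 haploid samples")
  ok <- grepl("^[0-9]+M$", aln$cigar)
  if (!all(ok)) {
    warning(sum(!ok), " non-gapless alignments skipped in pileup")
    aln <- aln[ok, , drop = FALSE]
  }
  w <- nchar(aln$seq)
  long <- data.table::data.table(
    contig = rep(aln$contig, w),
    pos = unlist(lapply(seq_len(nrow(aln)),
                        function(i) aln$start[i] + seq_len(w[i]) - 1L)),
    sample_id = rep(aln$sample_id, w),
    base = unlist(strsplit(aln$seq, "", fixed = TRUE)),
    qual_i = unlist(phred_decode(aln$qual)),
    mapq = rep(aln$mapq, w))
  long <- long[qual_i >= min_base_q & base %in% c("A", "C", "G", "T")]
  if (nrow(long) == 0L)
    return(variant_set(character(), integer(), character(), character()))
  sitemq <- long[, .(mq = sqrt(mean(mapq^2))), by = .(contig, pos)]
  bc <- long[, .(cnt = .N), by = .(contig, pos, sample_id, base)]
  data.table::setorder(bc, contig, pos, sample_id, -cnt, base)
  calls <- bc[, .(call = base[1L], best = cnt[1L],
                  second = if (.N > 1L) cnt[2L] else 0L,
                  depth = sum(cnt)),
              by = .(contig, pos, sample_id)]
  refch <- lapply(ref, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  calls[, ref := refch[[contig[1L]]][pos + 1L], by = contig]
  cand <- calls[, .(poly = any(call != ref) || length(unique(call)) > 1L),
                by = .(contig, pos)][poly == TRUE, .(contig, pos)]
  if (nrow(cand) == 0L)
    return(variant_set(character(), integer(), character(), character()))
  cc <- calls[cand, on = c("contig", "pos")]
  key <- paste(cand$contig, cand$pos)
  rowi <- match(paste(cc$contig, cc$pos), key)
  coli <- match(cc$sample_id, samples)
  n <- nrow(cand)
  S <- length(samples)
  m_call <- matrix(NA_character_, n, S, dimnames = list(NULL, samples))
  m_dp <- matrix(0L, n, S, dimnames = list(NULL, samples))
  m_gq <- matrix(NA_real_, n, S, dimnames = list(NULL, samples))
  m_minor <- matrix(0L, n, S, dimnames = list(NULL, samples))
  m_call[cbind(rowi, coli)] <- cc$call
  m_dp[cbind(rowi, coli)] <- cc$depth
  m_gq[cbind(rowi, coli)] <- pmin(60, 4 * (cc$best - cc$second))
  m_minor[cbind(rowi, coli)] <- cc$depth - cc$best
  ref_base <- vapply(seq_len(n), function(i)
    refch[[cand$contig[i]]][cand$pos[i] + 1L], character(1))
  alt <- vapply(seq_len(n), function(i) {
    a <- m_call[i, ]
    a <- a[!is.na(a) & a != ref_base[i]]
    if (length(a) == 0L) return(NA_character_)
    tab <- sort(table(a), decreasing = TRUE)
    paste(names(tab), collapse = ",")
  }, character(1))
  called <- rowSums(!is.na(m_call))
  af <- rowSums(!is.na(m_call) & m_call != ref_base) / called
  mqv <- sitemq[cand, on = c("contig", "pos")]$mq
  keep <- !is.na(alt)  # sites where samples merely disagree w/o alt vs ref
  variant_set(cand$contig[keep], cand$pos[keep], ref_base[keep], alt[keep],
              af = af[keep], mq = mqv[keep], method = "pileup",
              calls = m_call[keep, , drop = FALSE],
              depths = m_dp[keep, , drop = FALSE],
              gqs = m_gq[keep, , drop = FALSE],
              minor = m_minor[keep, , drop = FALSE])
}

#' The strict haploid SNP filter cascade
#'
#' Applies, in this fixed order: biallelic; per-sample depth; per-sample
#' genotype quality; site mapping quality; no within-individual
#' heterozygosity (a haploid sample whose minor base reaches
#' \code{het_frac} of its reads with at least \code{het_min_reads} reads
#' marks a collapsed paralog or contamination); minimum alternative allele
#' frequency; and polymorphism among the sequenced haploids (sites where
#' every called haploid carries the alternative allele are reference
#' divergence, not within-species SNPs). Each record is tagged with the
#' first failing rule; removal counts per rule are recorded in the
#' \code{attrition} attribute.
#'
#' @param raw a raw [variant_set()] (from [pileup_call()] or VCF import).
#' @param cfg a [pipeline_config()].
#' @param het_frac minor-base fraction that flags heterozygosity (0.2).
#' @param het_min_reads minimum minor-base reads to flag (2).
#' @param drop_monomorphic_alt apply the polymorphism rule (default TRUE).
#' @param annotate return all records with a \code{filter} column instead
#'   of only the retained ones.
#' @return filtered VariantSet with attribute \code{attrition}.
#' @export
filter_variants <- function(raw, cfg = pipeline_config(), het_frac = 0.2,
                            het_min_reads = 2L, drop_monomorphic_alt = TRUE,
                            annotate = FALSE) {
  n <- nrow(raw)
  filt <- rep(NA_character_, n)
  fail <- function(cur, rule, bad) ifelse(is.na(cur) & bad, rule, cur)
  biallelic_bad <- !(raw$ref %in% c("A", "C", "G", "T")) |
    grepl(",", raw$alt) | !(sub(",.*", "", raw$alt) %in% c("A", "C", "G", "T"))
  filt <- fail(filt, "biallelic", biallelic_bad)
  has_gt <- !is.null(raw$calls)
  if (has_gt) {
    uncalled_or_shallow <- rowSums(is.na(raw$calls) |
                                     raw$depths < cfg$min_depth) > 0L
    filt <- fail(filt, "depth", uncalled_or_shallow)
    gq_bad <- rowSums(!is.na(raw$gqs) & raw$gqs < cfg$min_gq, na.rm = TRUE) > 0L
    filt <- fail(filt, "gq", gq_bad)
  }
  mq_bad <- !is.na(raw$mq) & raw$mq < cfg$min_mq
  filt <- fail(filt, "mq", mq_bad)
  if (has_gt && !is.null(raw$minor)) {
    het_bad <- rowSums(raw$minor >= het_min_reads &
                         raw$minor / pmax(raw$depths, 1L) >= het_frac) > 0L
    filt <- fail(filt, "het", het_bad)
  }
  filt <- fail(filt, "af", !is.na(raw$af) & raw$af < cfg$min_af)
  if (drop_monomorphic_alt)
    filt <- fail(filt, "polymorphic", !is.na(raw$af) & raw$af >= 1)
  filt[is.na(filt)] <- "PASS"
  rules <- c("biallelic", "depth", "gq", "mq", "het", "af", "polymorphic")
  attrition <- vapply(rules, function(r) sum(filt == r), integer(1))
  attrition <- c(attrition, retained = sum(filt == "PASS"))
  if (annotate) {
    out <- raw
    out$filter <- filt
  } else {
    out <- raw[filt == "PASS", , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("VariantSet", "data.frame")
  }
  attr(out, "attrition") <- attrition
  out
}

#' Greedy minimum-spacing filter
#'
#' Left-to-right scan keeping a record iff it lies at least
#' \code{min_spacing} bp from the last kept record on the same contig.
#'
#' @param vars a VariantSet sorted by (contig, pos).
#' @param min_spacing minimum spacing in bp (default 50).
#' @return the spaced VariantSet.
#' @export
spacing_filter <- function(vars, min_spacing = 50L) {
  if (nrow(vars) == 0L) return(vars)
  o <- order(vars$contig, vars$pos)
  if (!identical(o, seq_len(nrow(vars))))
    stop_domain("spacing_filter input must be sorted by (contig, pos)")
  keep <- logical(nrow(vars))
  last_contig <- ""
  last_pos <- -Inf
  for (i in seq_len(nrow(vars))) {
    if (vars$contig[i] != last_contig ||
        vars$pos[i] - last_pos >= min_spacing) {
      keep[i] <- TRUE
      last_contig <- vars$contig[i]
      last_pos <- vars$pos[i]
    }
  }
  out <- vars[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("VariantSet", "data.frame")
  out
}
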