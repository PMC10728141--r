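#' Construct a VariantSet
#'
#' A VariantSet is a data.frame of biallelic-or-raw SNP records with one row
#' per site. Internal coordinates are 0-based; conversion to 1-based happens
#' only at the VCF boundary. Per-sample information (called base, depth,
#' genotype quality, minor-allele read support) is carried in matrix columns
#' whose colnames are the sample ids.
#'
#' @param contig contig/scaffold name.
#' @param pos 0-based position.
#' @param ref reference allele (A/C/G/T).
#' @param alt alternative allele(s), comma-separated when more than one.
#' @param af alternative allele frequency among called haploids.
#' @param mq site mapping quality (RMS of contributing read MAPQ).
#' @param method provenance tag, one of \code{"mas"}, \code{"silver"},
#'   \code{"ebwt"} (or another importer-supplied tag).
#' @param calls,depths,gqs,minor optional per-sample matrices.
#' @return a \code{VariantSet} (classed data.frame), sorted by contig/pos.
#' @export
variant_set <- function(contig, pos, ref, alt, af = NA_real_, mq = NA_real_,
                        method = "import", calls = NULL, depths = NULL,
                        gqs = NULL, minor = NULL) {
  n <- length(contig)
  vs <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   af = rep_len(as.numeric(af), n),
                   mq = rep_len(as.numeric(mq), n),
                   method = rep_len(as.character(method), n),
                   stringsAsFactors = FALSE)
  for (nm in c("calls", "depths", "gqs", "minor")) {
    m <- get(nm)
    if (!is.null(m)) {
      stopifnot(nrow(m) == nrow(vs))
      vs[[nm]] <- m
    }
  }
  o <- order(vs$contig, vs$pos)
  vs <- vs[o, , drop = FALSE]
  rownames(vs) <- NULL
  class(vs) <- c("VariantSet", "data.frame")
  vs
}

#' @export
print.VariantSet <- function(x, ...) {
  cat(sprintf("VariantSet: %d records on %d contigs (method: %s)\n",
              nrow(x), length(unique(x$contig)),
              paste(unique(x$method), collapse = ",")))
  invisible(x)
}

vs_samples <- function(vs) {
  if (!is.null(vs$calls)) colnames(vs$calls) else character()
}

#' Write a VariantSet as VCFv4.2
#'
#' Positions are converted to 1-based. Per-sample calls are written as
#' haploid GT:DP:GQ. An optional \code{filter} column is emitted in FILTER.
#'
#' @param vs a VariantSet.
#' @param path output file.
#' @param ref_lengths optional named contig lengths for the header.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(vs, path, ref_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gametoSNP",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele frequency among called haploids\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=METHOD,Number=1,Type=String,Description=\"Calling method\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  if (!is.null(ref_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(ref_lengths), as.integer(ref_lengths)))
  samples <- vs_samples(vs)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples)) cols <- c(cols, "FORMAT", samples)
  hdr <- c(hdr, paste(cols, collapse = "\t"))
  filt <- if (!is.null(vs$filter)) vs$filter else rep("PASS", nrow(vs))
  info <- sprintf("AF=%s;MQ=%s;METHOD=%s",
                  ifelse(is.na(vs$af), ".", format(vs$af, digits = 4)),
                  ifelse(is.na(vs$mq), ".", format(round(vs$mq, 1))),
                  vs$method)
  body <- character(nrow(vs))
  if (nrow(vs)) {
    fixed <- paste(vs$contig, vs$pos + 1L, ".", vs$ref, vs$alt, ".",
                   filt, info, sep = "\t")
    if (length(samples)) {
      alt1 <- sub(",.*$", "", vs$alt)
      gt_txt <- matrix(".", nrow(vs), length(samples))
      for (j in seq_along(samples)) {
        b <- vs$calls[, j]
        gt <- ifelse(is.na(b), ".", ifelse(b == vs$ref, "0",
                     ifelse(b == alt1, "1", "2")))
        dp <- ifelse(is.na(vs$depths[, j]), ".", vs$depths[, j])
        gq <- if (!is.null(vs$gqs)) ifelse(is.na(vs$gqs[, j]), ".",
                                           round(vs$gqs[, j])) else "."
        gt_txt[, j] <- paste(gt, dp, gq, sep = ":")
      }
      body <- paste(fixed, "GT:DP:GQ",
                    apply(gt_txt, 1, paste, collapse = "\t"), sep = "\t")
    } else {
      body <- fixed
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a VariantSet
#'
#' Uses \pkg{vcfR}; positions are converted to the package's 0-based
#' convention; AF/MQ/METHOD are recovered from INFO when present.
#'
#' @param path VCF file.
#' @param method provenance tag to use when INFO carries none.
#' @return a VariantSet.
#' @export
read_vcf <- function(path, method = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(variant_set(character(), integer(), character(), character()))
  info_get <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0(key, "=[^;]+"), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0(key, "="), fix$INFO)
    out[hit] <- sub(paste0(key, "="), "", m)
    out
  }
  af <- suppressWarnings(as.numeric(info_get("AF")))
  mq <- suppressWarnings(as.numeric(info_get("MQ")))
  meth <- info_get("METHOD")
  if (!is.null(method)) meth <- rep(method, nrow(fix))
  meth[is.na(meth)] <- "import"
  calls <- depths <- gqs <- NULL
  if (ncol(v@gt) > 1) {
    gt <- vcfR::extract.gt(v, element = "GT")
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
    alt1 <- sub(",.*$", "", fix$ALT)
    calls <- matrix(NA_character_, nrow(fix), ncol(gt),
                    dimnames = list(NULL, colnames(gt)))
    for (j in seq_len(ncol(gt))) {
      calls[, j] <- ifelse(is.na(gt[, j]) | gt[, j] == ".", NA,
                           ifelse(gt[, j] == "0", fix$REF, alt1))
    }
    depths <- matrix(as.integer(dp), nrow(fix), ncol(gt),
                     dimnames = list(NULL, colnames(gt)))
    gqs <- matrix(as.numeric(gq), nrow(fix), ncol(gt),
                  dimnames = list(NULL, colnames(gt)))
  }
  variant_set(fix$CHROM, as.integer(fix$POS) - 1L, fix$REF, fix$ALT,
              af = af, mq = mq, method = meth,
              calls = calls, depths = depths, gqs = gqs)
}

#' Read a BED3 file (0-based half-open)
#' @param path BED file.
#' @return data.frame with contig/start/end.
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(b) <- c("contig", "start", "end")
  b$start <- as.integer(b$start); b$end <- as.integer(b$end)
  b
}

#' Write intervals as BED3 (0-based half-open)
#' @param bed data.frame with contig/start/end.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed[, c("contig", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

bed_to_granges <- function(bed) {
  GenomicRanges::GRanges(bed$contig,
                         IRanges::IRanges(start = bed$start + 1L,
                                          end = bed$end))
}
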