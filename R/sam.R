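#' Write alignments as SAM
#'
#' Emits the minimal ("SAM-lite") field set used downstream: id, flag
#' (strand/unmapped), contig, 1-based position, MAPQ, CIGAR, SEQ, QUAL and
#' the NM edit-distance tag.
#'
#' @param aln an alignment data.frame from [seed_map()].
#' @param path output file.
#' @param ref_lengths named contig lengths for \code{@SQ} header lines.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(aln, path, ref_lengths = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(ref_lengths))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                          as.integer(ref_lengths)))
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  body <- paste(paste0(aln$id, "/", aln$mate), flag, aln$contig,
                aln$start + 1L, aln$mapq, aln$cigar, "*", 0L, 0L,
                aln$seq, aln$qual, paste0("NM:i:", aln$nm), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into the package's alignment table
#'
#' Full SAM is accepted; only the fields the pipeline uses are kept
#' (read id, flag, contig, position, MAPQ, CIGAR restricted to M/I/D/S,
#' SEQ/QUAL, NM when present). Unmapped records are dropped.
#'
#' @param path SAM file.
#' @param sample_id sample label attached to the alignments.
#' @return alignment data.frame (0-based \code{start}).
#' @export
read_sam <- function(path, sample_id = "S1") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(id = character(), mate = integer(), sample_id = character(),
                      contig = character(), start = integer(), strand = character(),
                      mapq = integer(), cigar = character(), nm = integer(),
                      seq = character(), qual = character()))
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:11)
  flag <- as.integer(f[[2]])
  nm <- rep(NA_integer_, length(lines))
  nm_m <- regmatches(lines, regexpr("NM:i:[0-9]+", lines))
  has_nm <- grepl("NM:i:", lines)
  nm[has_nm] <- as.integer(sub("NM:i:", "", nm_m))
  ids <- f[[1]]
  mate <- rep(1L, length(ids))
  hm <- grepl("/[12]$", ids)
  mate[hm] <- as.integer(sub("^.*/", "", ids[hm]))
  ids[hm] <- sub("/[12]$", "", ids[hm])
  bad_cig <- grepl("[^0-9MIDS*]", f[[6]])
  if (any(bad_cig))
    warning(sum(bad_cig), " records with CIGAR ops outside M/I/D/S dropped")
  keep <- !bitwAnd(flag, 4L) & !bad_cig
  out <- data.frame(id = ids, mate = mate, sample_id = sample_id,
                    contig = f[[3]], start = as.integer(f[[4]]) - 1L,
                    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    mapq = as.integer(f[[5]]), cigar = f[[6]], nm = nm,
                    seq = f[[10]], qual = f[[11]],
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
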