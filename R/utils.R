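#' Reverse complement of DNA strings
#'
#' Vectorised over character strings in \code{{A,C,G,T,N}}.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

# phred+33 string -> integer vector (list when length > 1)
phred_decode <- function(q) {
  lapply(q, function(s) utf8ToInt(s) - 33L)
}

phred_encode <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

#' @noRd
stop_domain <- function(...) stop(..., call. = FALSE)

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# random DNA of length n (uniform base composition)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# apply substitutions at given 1-based positions, drawing a base different
# from the current one
mutate_bases <- function(seq, pos1) {
  if (length(pos1) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos1) {
    ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# N50 of a vector of contig lengths
n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  lens[which(cumsum(lens) >= half)[1]]
}

# simple stage logger
log_msg <- function(...) {
  if (isTRUE(getOption("gametoSNP.verbose", FALSE)))
    message(sprintf("[gametoSNP] %s", sprintf(...)))
  invisible(NULL)
}
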