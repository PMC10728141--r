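#' Pipeline configuration
#'
#' Bundles the thresholds used across the pipeline. Defaults follow the
#' study conditions: haploid samples at ~5x, a merged ~20x k-mer pool with
#' a coverage band of half to twice the pooled coverage, and the strict
#' variant filter cascade (depth 5, GQ 15, MQ 30, AF 0.25, spacing 50 bp).
#'
#' @param k k-mer length for counting/filtering (odd, 15-99; default 25).
#' @param cov_band integer pair, k-mer coverage band \code{c(low, high)}.
#' @param min_kmer_frac fraction of a read's k-mers required in the band.
#' @param min_depth minimum per-sample depth at a retained site.
#' @param min_gq minimum per-sample genotype quality (phred).
#' @param min_mq minimum site mapping quality (phred).
#' @param min_af minimum alternative allele frequency among haploids.
#' @param min_spacing minimum bp between retained SNPs.
#' @param trim_q 3' quality trimming threshold.
#' @param genome_size genome size in bp (used for coverage arithmetic).
#' @param seed integer RNG seed.
#' @return a \code{PipelineConfig} list.
#' @export
pipeline_config <- function(k = 25L, cov_band = c(10L, 40L),
                            min_kmer_frac = 0.9, min_depth = 5L,
                            min_gq = 15, min_mq = 30, min_af = 0.25,
                            min_spacing = 50L, trim_q = 10,
                            genome_size = 2e5, seed = 1L) {
  cfg <- list(k = as.integer(k), cov_band = as.integer(cov_band),
              min_kmer_frac = min_kmer_frac, min_depth = as.integer(min_depth),
              min_gq = min_gq, min_mq = min_mq, min_af = min_af,
              min_spacing = as.integer(min_spacing), trim_q = trim_q,
              genome_size = genome_size, seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "PipelineConfig"
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$cov_band) != 2L || cfg$cov_band[1] >= cfg$cov_band[2])
    stop_domain("cov_band must be c(low, high) with low < high")
  if (cfg$min_af <= 0 || cfg$min_af > 1)
    stop_domain("min_af must be in (0, 1]")
  thr <- c(cfg$min_kmer_frac, cfg$min_depth, cfg$min_gq, cfg$min_mq,
           cfg$min_spacing, cfg$trim_q, cfg$genome_size)
  if (any(thr < 0)) stop_domain("thresholds must be >= 0")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are passed through (the simulation stage reads its own
#' block); known keys override [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return a \code{PipelineConfig}.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  cfg <- do.call(pipeline_config, y[intersect(names(y), known)])
  extra <- y[setdiff(names(y), known)]
  if (length(extra)) attr(cfg, "extra") <- extra
  cfg
}
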