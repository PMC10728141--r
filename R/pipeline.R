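#' Default toy-study simulation settings
#'
#' The bundled study conditions: a 200 kb genome with 75% high-copy
#' repeats, four ~5x haploid megagametophyte samples from two gene pools,
#' a 2% diverged sister reference, a fragmented draft assembly of the
#' low-copy regions, and a clonal orchard population of 140 genets / 342
#' ramets genotyped at ~200 amplicon loci.
#'
#' @return named list of simulation parameters.
#' @export
toy_sim_config <- function() {
  list(genome_size = 2e5, repeat_fraction = 0.75, n_repeat_families = 3,
       divergence = 0.02, frag_n50 = 600, n_haploids = 4,
       haploid_coverage = 5, read_len = 150, err = 0.002,
       snp_density = 1 / 200, n_trio = 88, n_duo = 26, n_single = 26,
       n_mislabels = 5, n_unrelated_mislabels = 1, n_amplicon_loci = 200,
       amplicon_depth = 21)
}

#' Run the SNP discovery and validation pipeline
#'
#' Executes the stage DAG \code{simulate -> kmerfilter -> map -> call ->
#' ebwt -> intersect -> genotype -> clones} (three calling branches:
#' draft-assembly-based "mas", sister-reference-based "silver", and the
#' reference-free "ebwt" branch feeding the intersection). Outputs are
#' written under \code{outdir}; a run manifest with the configuration
#' hash, seeds and per-stage record counts is written as YAML.
#'
#' @param cfg a [pipeline_config()].
#' @param stages stages to run (prefix-closed subset of the DAG, or
#'   \code{"all"}).
#' @param outdir output directory.
#' @param sim simulation settings, see [toy_sim_config()].
#' @return the run manifest (list), invisibly written to
#'   \code{outdir/manifest.yaml}.
#' @export
run_pipeline <- function(cfg = pipeline_config(), stages = "all",
                         outdir = tempfile("gametoSNP_run_"),
                         sim = toy_sim_config()) {
  all_stages <- c("simulate", "kmerfilter", "map", "call", "ebwt",
                  "intersect", "genotype", "clones")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(stage, file) {
    if (!file.exists(file.path(outdir, file)))
      stop_domain("stage '", stage, "' requires output of stage '",
                  stage_of_file(file), "'; run it first")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  state_file <- function(f) file.path(outdir, f)
  manifest <- list(package = "gametoSNP",
                   version = as.character(utils::packageVersion("gametoSNP")),
                   seed = cfg$seed, stages = list())
  counts <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    log_msg("stage %s done", stage)
  }

  if ("simulate" %in% stages) {
    g <- generate_genome(size = sim$genome_size,
                         repeat_fraction = sim$repeat_fraction,
                         n_repeat_families = sim$n_repeat_families,
                         divergence = sim$divergence,
                         frag_n50 = sim$frag_n50, seed = cfg$seed)
    hap <- sample_haploids(g, n = sim$n_haploids,
                           snp_density = sim$snp_density,
                           seed = cfg$seed + 1L)
    reads <- list()
    for (i in seq_along(hap$haploids)) {
      reads[[i]] <- simulate_reads(hap$haploids[i], sim$haploid_coverage,
                                   read_len = sim$read_len, err = sim$err,
                                   seed = cfg$seed + 10L + i,
                                   sample_id = names(hap$haploids)[i])
      write_fastq(reads[[i]], state_file(sprintf("reads_%s.fastq",
                                                 names(hap$haploids)[i])))
    }
    write_fasta(g$silver_ref, state_file("silver.fasta"))
    write_fasta(g$draft_contigs, state_file("draft.fasta"))
    write_fasta(g$truth, state_file("truth.fasta"))
    write_bed(g$lowcopy_intervals, state_file("lowcopy.bed"))
    dir.create(state_file("truth"), showWarnings = FALSE)
    utils::write.table(hap$truth_snps, state_file("truth/snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pop <- build_clone_population(sim$n_trio, sim$n_duo, sim$n_single,
                                  sim$n_mislabels,
                                  sim$n_unrelated_mislabels,
                                  n_loci = sim$n_amplicon_loci,
                                  seed = cfg$seed + 2L)
    amp <- simulate_amplicons(pop, mean_depth = sim$amplicon_depth,
                              seed = cfg$seed + 3L)
    write_population_tsv(pop, state_file("population.tsv"))
    utils::write.table(amp$ref, state_file("amplicon_ref.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(amp$alt, state_file("amplicon_alt.tsv"),
                       sep = "\t", quote = FALSE)
    counts("simulate", genome_bp = nchar(g$truth),
           n_contigs = length(g$draft_contigs),
           n_truth_snps = nrow(hap$truth_snps),
           n_reads = sum(vapply(reads, nrow, integer(1))),
           n_individuals = nrow(pop$individuals))
  }

  if ("kmerfilter" %in% stages) {
    need("kmerfilter", "reads_H1.fastq")
    fq <- Sys.glob(state_file("reads_H*.fastq"))
    pool <- do.call(rbind, lapply(fq, function(f)
      read_fastq(f, sample_id = sub("reads_(.*)\\.fastq", "\\1", basename(f)))))
    class(pool) <- c("ReadSet", "data.frame")
    pool <- trim_reads(pool, trim_q = cfg$trim_q)
    kt <- count_kmers(pool, k = cfg$k)
    write_kmer_histogram(kmer_histogram(kt), state_file("kmer_histogram.tsv"))
    fl <- filter_low_copy_reads(pool, kt, band = cfg$cov_band,
                                min_frac = cfg$min_kmer_frac)
    rp <- repair_pairs(fl$kept)
    write_fastq(rp$paired, state_file("lowcopy_paired.fastq"))
    if (nrow(rp$singletons))
      write_fastq(rp$singletons, state_file("lowcopy_singletons.fastq"))
    counts("kmerfilter", n_input = nrow(pool), n_kept = nrow(fl$kept),
           n_rejected = nrow(fl$rejected), n_paired = nrow(rp$paired),
           n_singletons = nrow(rp$singletons),
           distinct_kmers = nrow(kt$counts))
  }

  if ("map" %in% stages) {
    need("map", "silver.fasta")
    silver <- read_fasta(state_file("silver.fasta"))
    draft <- read_fasta(state_file("draft.fasta"))
    fq <- Sys.glob(state_file("reads_H*.fastq"))
    aln_silver <- list()
    subs <- list()
    am <- anchor_contigs(draft, silver)
    bed <- anchored_regions(am)
    write_bed(bed, state_file("anchored_regions.bed"))
    utils::write.table(as.data.frame(am), state_file("anchors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (f in fq) {
      sid <- sub("reads_(.*)\\.fastq", "\\1", basename(f))
      rs <- trim_reads(read_fastq(f, sample_id = sid), trim_q = cfg$trim_q)
      a <- seed_map(rs, silver)
      aln_silver[[sid]] <- a
      write_sam(a, state_file(sprintf("silver_%s.sam", sid)),
                ref_lengths = nchar(silver))
      sub <- subset_reads_by_anchor_regions(a, bed, rs)
      b <- seed_map(sub$reads, draft)
      subs[[sid]] <- b
      write_sam(b, state_file(sprintf("mas_%s.sam", sid)),
                ref_lengths = nchar(draft))
    }
    counts("map", n_anchors = nrow(am),
           silver_mapped = sum(vapply(aln_silver, nrow, integer(1))),
           mas_mapped = sum(vapply(subs, nrow, integer(1))))
  }

  if ("call" %in% stages) {
    need("call", "silver_H1.sam")
    silver <- read_fasta(state_file("silver.fasta"))
    draft <- read_fasta(state_file("draft.fasta"))
    for (branch in c("silver", "mas")) {
      ref <- if (branch == "silver") silver else draft
      sams <- Sys.glob(state_file(sprintf("%s_H*.sam", branch)))
      aln <- do.call(rbind, lapply(sams, function(f)
        read_sam(f, sample_id = sub(sprintf("%s_(.*)\\.sam", branch), "\\1",
                                    basename(f)))))
      raw <- pileup_call(aln, ref)
      raw$method <- branch
      filt <- filter_variants(raw, cfg)
      spaced <- spacing_filter(filt, cfg$min_spacing)
      write_vcf(filt, state_file(sprintf("%s_filtered.vcf", branch)),
                ref_lengths = nchar(ref))
      write_vcf(spaced, state_file(sprintf("%s_spaced.vcf", branch)),
                ref_lengths = nchar(ref))
      att <- attr(filt, "attrition")
      utils::write.table(data.frame(rule = names(att), n = att),
                         state_file(sprintf("%s_attrition.tsv", branch)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages[[paste0("call_", branch)]] <-
        list(raw = nrow(raw), filtered = nrow(filt), spaced = nrow(spaced))
    }
    counts("call", done = TRUE)
  }

  if ("ebwt" %in% stages) {
    need("ebwt", "lowcopy_paired.fastq")
    rs <- read_fastq(state_file("lowcopy_paired.fastq"))
    silver <- read_fasta(state_file("silver.fasta"))
    idx <- build_ebwt(rs)
    cl <- detect_clusters(idx)
    cand <- call_snps_from_clusters(idx, cl)
    write_candidates_fasta(cand, state_file("ebwt_candidates.fasta"))
    vs <- anchor_to_reference(cand, silver)
    write_vcf(vs, state_file("ebwt_silver.vcf"), ref_lengths = nchar(silver))
    counts("ebwt", n_clusters = nrow(cl), n_candidates = nrow(cand),
           n_anchored = nrow(vs))
  }

  if ("intersect" %in% stages) {
    need("intersect", "silver_filtered.vcf")
    need("intersect", "ebwt_silver.vcf")
    silver_v <- read_vcf(state_file("silver_filtered.vcf"), method = "silver")
    mas_v <- read_vcf(state_file("mas_filtered.vcf"), method = "mas")
    ebwt_v <- read_vcf(state_file("ebwt_silver.vcf"), method = "ebwt")
    am <- utils::read.table(state_file("anchors.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    class(am) <- c("AnchorMap", "data.frame")
    shared_rb <- indirect_intersection(silver_v, mas_v, am, mode = "region")
    se <- intersect_variant_sets(silver_v, ebwt_v)
    write_vcf(shared_rb, state_file("shared_refbased.vcf"))
    sp <- tstv(shared_rb)
    utils::write.table(
      data.frame(class = names(sp$counts), count = sp$counts,
                 proportion = round(sp$proportions, 4)),
      state_file("tstv_spectrum.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    venn <- c(silver = nrow(silver_v), mas = nrow(mas_v),
              ebwt = nrow(ebwt_v), silver_mas_region = nrow(shared_rb),
              silver_ebwt = nrow(se$shared))
    writeLines(paste(names(venn), venn, sep = "\t"),
               state_file("venn_summary.tsv"))
    counts("intersect", venn = as.list(venn), tstv = sp$ratio)
  }

  if ("genotype" %in% stages) {
    need("genotype", "amplicon_ref.tsv")
    ref_c <- as.matrix(utils::read.table(state_file("amplicon_ref.tsv"),
                                         sep = "\t", check.names = FALSE))
    alt_c <- as.matrix(utils::read.table(state_file("amplicon_alt.tsv"),
                                         sep = "\t", check.names = FALSE))
    popi <- utils::read.table(state_file("population.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
    vl <- variable_loci(ref_c, alt_c)
    gm <- call_amplicon_genotypes(ref_c[, vl, drop = FALSE],
                                  alt_c[, vl, drop = FALSE],
                                  clone_labels = popi$labelled_genet)
    fp <- filter_panel(gm)
    utils::write.table(fp$geno, state_file("genotypes.tsv"), sep = "\t",
                       quote = FALSE)
    manifest$stages[["genotype_attrition"]] <-
      as.list(attr(fp, "attrition"))
    counts("genotype", n_tested = ncol(ref_c), n_variable = sum(vl),
           n_loci_final = ncol(fp$geno), n_indiv_final = nrow(fp$geno))
  }

  if ("clones" %in% stages) {
    need("clones", "genotypes.tsv")
    geno <- as.matrix(utils::read.table(state_file("genotypes.tsv"),
                                        sep = "\t", check.names = FALSE))
    popi <- utils::read.table(state_file("population.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
    gm <- genotype_matrix(geno,
                          popi$labelled_genet[match(rownames(geno),
                                                    popi$ind_id)])
    hc <- het_ci_filter(gm)
    gm_sel <- genotype_matrix(gm$geno[, hc$kept, drop = FALSE],
                              gm$indiv$clone)
    ident <- identity_analysis(gm_sel)
    # mismatch profile after reassigning mislabelled ramets to their clone
    gm_corr <- genotype_matrix(gm_sel$geno, ident$assignments$inferred)
    prof <- mismatch_profile(gm_corr, seed = cfg$seed)
    G <- grm(gm_sel)
    utils::write.table(round(G$G, 5), state_file("grm.tsv"), sep = "\t",
                       quote = FALSE)
    utils::write.table(ident$mislabels, state_file("mislabels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(prof$profile, state_file("mismatch_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts("clones", n_loci_grm = length(hc$kept),
           n_het_excluded = length(hc$excluded),
           gap_pairs = unname(prof$gap["pairs"]),
           gap_trios = unname(prof$gap["trios"]),
           n_mislabels = nrow(ident$mislabels))
  }

  manifest$config <- unclass(cfg)
  cfg_file <- state_file("config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  yaml::write_yaml(manifest, state_file("manifest.yaml"))
  invisible(manifest)
}

stage_of_file <- function(file) {
  map <- c(reads_H1.fastq = "simulate", silver.fasta = "simulate",
           amplicon_ref.tsv = "simulate", lowcopy_paired.fastq = "kmerfilter",
           silver_H1.sam = "map", silver_filtered.vcf = "call",
           ebwt_silver.vcf = "ebwt", genotypes.tsv = "genotype")
  unname(map[basename(file)])
}

# population table as plain TSV (individuals + mislabel truth columns)
write_population_tsv <- function(pop, path) {
  utils::write.table(pop$individuals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
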