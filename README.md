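# gametoSNP

SNP discovery and clone identification from low-coverage sequencing of
haploid conifer megagametophytes.

## The problem

Most conifers have no reference genome, 18–20 Gb of DNA, and up to 75%
repeats — yet breeding programs need thousands of trees genotyped with
reliable biallelic markers. `gametoSNP` implements a complete,
desk-scale-testable pipeline for that setting:

* **haploid sequencing**: megagametophyte (maternal seed tissue) carries
  one allele per locus, so any within-sample polymorphism signals error or
  collapsed paralogs rather than heterozygosity;
* **k-mer low-copy filtering**: canonical k-mer counts from the merged
  ~20x read pool keep only reads whose k-mers sit in a coverage band of
  half to twice the expected coverage (≥ 90% in-band), isolating the 1–2x
  fraction of the genome;
* **dual-reference calling**: haploid pileup calling against both a
  related species' genome and a draft assembly of the species' own
  low-copy regions, with the strict cascade *biallelic → depth ≥ 5 →
  GQ ≥ 15 → MQ ≥ 30 → no within-haploid heterozygosity → AF ≥ 0.25 →
  polymorphic among samples* (with four haploids every retained site has
  AF ∈ {0.25, 0.5, 0.75});
* **reference-free calling**: positional clustering on the extended
  Burrows–Wheeler Transform — suffixes of the read collection sharing a
  ≥ 20 bp right context cluster together, and the eBWT characters
  preceding them expose the two alleles; candidates are anchored back to
  a reference by exact context match;
* **cross-reference intersection**: draft contigs are anchored to the
  related genome (seed voting + alignment, gapless anchor blocks), call
  sets are restricted to anchored regions or lifted through the anchors,
  and Venn counts / the Ts/Tv spectrum summarize agreement;
* **clone validation**: amplicon read counts → posterior genotype calls →
  missingness/MAF/het-CI panel filters → ramet-vs-unrelated mismatch
  profiles, fuzzy identity at threshold 0.10 (single linkage inside the
  empirical gap), and the VanRaden genomic relationship matrix
  `G = ZZ' / (2 Σ pᵢ(1−pᵢ))`.

A fully truth-labelled synthetic generator (genome, repeat families,
2-copy duplicated segments, diverged sister reference, fragmented draft
assembly, two gene pools, four ~5x haploids, a 342-ramet / 140-genet
clonal orchard with planted mislabels) stands in for the study data, so
every stage is testable offline.

## Worked example

```r
library(gametoSNP)

# simulate the study system at desk scale
g   <- generate_genome(size = 2e5, repeat_fraction = 0.75,
                       divergence = 0.02, seed = 1)
hap <- sample_haploids(g, n = 4, snp_density = 1/200, seed = 2)
reads <- do.call(rbind, lapply(1:4, function(i)
  simulate_reads(hap$haploids[i], coverage = 5, err = 0.002,
                 seed = 10 + i, sample_id = names(hap$haploids)[i])))
class(reads) <- c("ReadSet", "data.frame")

# k-mer low-copy filter on the merged ~20x pool
kt <- count_kmers(reads, k = 25)
fl <- filter_low_copy_reads(reads, kt, band = c(10, 40), min_frac = 0.9)
c(kept = nrow(fl$kept), rejected = nrow(fl$rejected))
#>     kept rejected
#>     3831    22833

# sister-reference branch: map, pileup, filter cascade
aln  <- seed_map(reads, g$silver_ref)
raw  <- pileup_call(aln, g$silver_ref)
filt <- filter_variants(raw, pipeline_config())
attr(filt, "attrition")
#>   biallelic       depth          gq          mq         het          af
#>          46        3710          95         151           1           0
#> polymorphic    retained
#>          89          12
table(filt$af)
#> 0.25  0.5 0.75
#>    6    3    3
```

The attrition log is the cascade at work: most raw sites are removed by
the all-four-haploids depth rule (5x data), fixed differences against the
diverged reference fall to the `polymorphic` rule, and every retained
site shows the forced four-haploid AF spectrum {0.25, 0.5, 0.75}.

```r
# clone validation: genotype 342 ramets at ~200 loci, find mislabels
pop <- build_clone_population(88, 26, 26, n_mislabels = 5,
                              n_unrelated_mislabels = 1, seed = 3)
amp <- simulate_amplicons(pop, mean_depth = 21, err = 0.01, seed = 4)
gm  <- call_amplicon_genotypes(amp$ref, amp$alt,
                               clone_labels = pop$individuals$labelled_genet)
id  <- identity_analysis(filter_panel(gm))
id$mislabels
#>   ind_id labelled        inferred      class
#> 1  I0022     G008            G057 reassigned
#> 2  I0036     G012            G035 reassigned
#> 3  I0091     G031 singleton:I0091  unrelated
#> 4  I0137     G046            G056 reassigned
#> 5  I0242     G081            G009 reassigned
```

All five planted mislabels are recovered: four ramets reassigned to their
true clone, one individual unrelated to every genet.

See `vignettes/methods.Rmd` for the models, parameter rationale, and what
the synthetic generator does and does not emulate.

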