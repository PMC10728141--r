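---
title: "SNP discovery from haploid megagametophytes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP discovery from haploid megagametophytes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Conifers combine enormous genomes (roughly 18--20 Gb) with very high repeat
content — up to three quarters of the genome — and for most species no
reference genome exists. `gametoSNP` implements a pipeline for discovering
reliable SNP markers in such a species from *low-coverage* (about 5x)
whole-genome sequencing of **haploid megagametophyte tissue**, and for
validating the resulting marker panel by clone identification in a grafted
seed-orchard population. Megagametophytes carry a single maternal allele
per locus, which removes heterozygote phasing from the problem entirely:
any within-sample polymorphism in a pileup is a signal of error or of
collapsed paralogs, not of genotype.

The package couples three discovery routes that are intersected for
reliability:

1. **sister-reference calling** — mapping the haploid reads to the genome
   of a closely related species;
2. **draft-assembly calling** — mapping to a fragmented draft assembly of
   the species' own low-copy regions (obtained from k-mer-filtered reads);
3. **reference-free calling** — positional clustering on the extended
   Burrows-Wheeler Transform (eBWT) of the reads themselves.

A synthetic-data generator reproduces the study system end to end with
full truth labels, so every stage of the pipeline is testable without any
external download.

# The models, stage by stage

## Read preprocessing

`trim_reads()` removes, at the 3' end only: exact adapter prefixes,
terminal poly-G runs of at least 10 bp (the two-channel chemistry artifact
in which a dark cycle reads as G), and trailing bases below quality 10.
The three rules are applied to a fixpoint, which makes trimming idempotent
by construction. Templates in which either mate falls below 30 bp are
dropped as pairs.

## K-mer low-copy filter

`count_kmers()` counts canonical k-mers (the lexicographic minimum of a
k-mer and its reverse complement) exactly — no probabilistic sketches, a
deliberate choice at desk scale because it makes the filter's behaviour
fully checkable against naive recounts. The four samples are merged into
one pool at roughly 20x before counting. `filter_low_copy_reads()` keeps a
read iff at least 90% of its k-mers have pooled counts inside a band of
half to twice the expected pooled coverage (default `[10, 40]`). Single-
copy sequence sits near pooled coverage, 2-copy sequence near twice it,
and high-copy repeats far above the band, so the filter enriches strongly
for "1--2x" sequence.

The k-mer length for filtering defaults to **k = 25**. The assembly-graph
k of 99 used by de novo assemblers is a graph-construction parameter, not
a coverage-estimation one; 25 keeps per-read k-mer counts high (126 per
150 bp read) so the in-band fraction is estimated with small variance,
while remaining long enough that almost all low-copy 25-mers are unique.

## Mapping and the depth-inflation pathology

`seed_map()` is a deliberately simple gapless seed-and-extend mapper used
on synthetic data (real alignments can be imported as SAM). It reports a
single best placement per read, like a primary alignment, with MAPQ 0 on
ties and otherwise a score-gap phred `min(60, 6 * (d2 - d1))` in mismatch
units. Reporting a single best hit *reproduces on purpose* the
pathology of mapping a whole-genome read set against a small collapsed
assembly: reads from a duplicated region pile onto the single contig that
represents both copies, inflating depth. The pipeline's remedy is
`subset_reads_by_anchor_regions()`: anchor the draft contigs on the
sister reference, export the anchored-region BED, keep only the reads
whose sister-reference alignments overlap those regions, and re-map that
subset to the draft. The classical alternative — masking positions with
depth above `d + 4*sqrt(d)` — is provided (`max_depth_mask()`) but off by
default, because collapsed paralogs can pass a depth cut while still
producing false calls.

## Haploid pileup calling and the filter cascade

`pileup_call()` calls, per site and haploid sample, the consensus base
with its depth and a phred-like genotype quality
`GQ = min(60, 4 * (best - second best base support))`. This GQ is a
documented stand-in for a full genotype-likelihood model: for clean
haploid data the support gap is the sufficient statistic, and the factor 4
maps a gap of 4 reads to the conventional GQ 15 threshold. Site MQ is the
root-mean-square MAPQ of contributing reads.

`filter_variants()` applies the cascade in a fixed order, tagging each
record with the first failing rule:

| rule | default | meaning |
|------|---------|---------|
| biallelic | — | exactly one ALT, alleles in ACGT |
| depth | 5x | every haploid covered at least this deep |
| gq | 15 | every called haploid's GQ |
| mq | 30 | site RMS mapping quality |
| het | 20% and 2 reads | no within-haploid minor-allele signal |
| af | 0.25 | minimum alternative allele frequency |
| polymorphic | on | not all haploids carrying ALT |

Two interpretation choices deserve note. *Depth* is enforced for all four
haploids (a site where any sample is missing or shallow is removed); with
four haploids this forces every retained AF into {0.25, 0.5, 0.75}. The
AF denominator itself remains "samples with a call", so the statistic
stays meaningful for imported call sets with missing data. *Heterozygosity*
in a haploid pileup is not directly observable, so the het rule flags a
sample whose minor base reaches 20% of its reads with at least 2 reads —
low enough to catch collapsed paralogs at 10--40x, high enough to ignore
isolated sequencing errors. The final *polymorphic* rule removes sites at
which every called haploid carries the alternative allele: against a
diverged sister reference those are fixed interspecies differences, not
within-species SNPs.

`spacing_filter()` is the greedy left-to-right scan that keeps a record
iff it lies at least 50 bp from the last kept record — the assay-design
constraint for primer placement.

## Reference-free calling on the eBWT

`build_ebwt()` concatenates the reads (by default together with their
reverse complements, which strand-agnostic clustering requires) with one
distinct terminator per string; terminators sort before the bases and
among themselves by string index, which makes the suffix order — and
hence the eBWT — stable and independent of tie-breaking. Construction is
prefix-doubling over the integer-coded text with Kasai's LCP, both in
C++; at the package's desk scale (tens of Mb of text at most) an
`O(n log^2 n)` build is entirely adequate and much easier to verify
against a brute-force suffix sort than a compressed construction.

`detect_clusters()` finds maximal suffix-array intervals whose interior
LCP stays at or above `min_context` (default 20 bp) with at least
`min_size` (default 4) members: suffixes sharing a 20 bp right context
almost surely arise from the same genomic locus, so the eBWT characters
preceding them expose the alleles at the position immediately left of
that context. `call_snps_from_clusters()` accepts a cluster as a SNP
candidate iff its preceding-character multiset contains exactly two bases
with support at least `min_allele_support` each; clusters with three or
more bases are dropped and counted (at the package's error rates they are
overwhelmingly repeat artifacts), and indel-like events are out of scope.
The support default is **one quarter of the expected coverage of each
allele's read set** (5 at the pooled 20x of the study design); when two
sets of reads are compared directly, the per-set coverage is the relevant
scale. `anchor_to_reference()` then locates each candidate's right
context in a reference on either strand; unique hits place the SNP at the
base immediately left of the match, multi-hits and misses are dropped
with counts. The two flank clusters of one SNP anchor to the same
coordinate and are merged there.

## Cross-reference intersection

Direct intersection of call sets on two different references is
impossible, so `indirect_intersection()` reproduces the indirect route:
anchor the draft contigs to the sister reference
(`anchor_contigs()`, seed voting plus Needleman-Wunsch on the winning
window, anchors being the gapless blocks of that alignment), restrict the
sister-reference call set to the anchored regions (`mode = "region"`, the
default bookkeeping), or additionally lift the contig-based calls through
the anchors and require position-and-allele agreement
(`mode = "lift"`, the stricter variant). Ambiguously placed contigs —
second placement nearly as well supported as the best — are dropped
rather than guessed, consistent with the repeat-safety stance of the
whole pipeline. Because anchors are gapless blocks, `lift_position()` is
an exact offset within a block, and positions split by an indel simply
fall into different blocks.

`tstv()` counts A<->G and C<->T as transitions and the other four
undirected pairs as transversions; the Ts/Tv ratio is the standard scalar
quality indicator for a SNP set.

## Amplicon genotyping and clone validation

`call_amplicon_genotypes()` scores dosages 0/1/2 with binomial
likelihoods at alt-read probabilities `err`, 0.5, `1 - err`, a
Hardy-Weinberg prior at the locus's pooled first-pass frequency, and a
0.95 posterior cutoff; cells with fewer than 3 reads stay missing, since
below that depth the prior alone can push an uninformative cell past the
cutoff. `polymorphism_test()` is a 1-df likelihood-ratio test of the
free-dosage model against the best monomorphic-with-error model — loci
that do not reject at 0.001 are flagged non-variable.

Panel filtering is boundary-faithful: loci with **at least** 15% missing
data are dropped, loci with MAF **at or below** 0.05 are dropped, then
individuals missing more than 20% of loci. `het_ci_filter()` excludes a
locus iff the lower bound of the Wilson score interval (two-sided,
alpha = 0.05, `prop.test` without continuity correction) for its
heterozygote fraction exceeds 0.5 — the Hardy-Weinberg ceiling for the
population mean heterozygosity at a biallelic locus; loci significantly
above it indicate collapsed paralogs amplifying two loci at once.

Clone validation uses the mismatch statistic: for a pair, the fraction of
jointly non-missing loci with different genotypes; for a trio, the
fraction where the three genotypes are not all identical. The trio
definition is chosen so that a trio's mismatch is at least its worst
pair's, matching the observation that trio ranges sit above pair ranges.
`mismatch_profile()` contrasts all within-clone groups against seeded
random unrelated groups (no two members sharing a genet), and reports the
gap `min(unrelated) - max(ramet)` — the quantity that makes fuzzy
identity safe. `identity_analysis()` is single-linkage clustering
(`hclust`/`cutree`) of pairwise mismatch at threshold **0.10**, chosen
inside the empirical gap between the ramet regime (below about 9%) and
the unrelated regime (above about 30%); it reports individuals whose
inferred genet contradicts their label as "reassigned" or "unrelated",
and refuses to merge two well-attested genets silently. Profiles are
computed after reassignment, as in the validation design. `grm()` is the
VanRaden genomic relationship matrix `G = Z Z' / (2 * sum p_i (1 - p_i))`
with dosages centred by `2 p_i` and missing cells mean-imputed; allele
frequencies are taken over all individuals, ramets included — a
documented bias (clonal replication distorts p) accepted for fidelity to
the validation design, with the frequency vector exposed for callers who
prefer one genotype per genet.

# What the generator emulates — and what it does not

`generate_genome()` builds: high-copy repeat families (a few units of
0.5--2 kb, tandem and dispersed copies at 1% inter-copy divergence,
75% of the genome by default), single-copy regions, and a small class of
**duplicated 2-copy segments**. The 2-copy class is essential: the
depth-inflation pathology and the paralog-collapse heterozygosity signal
both need sequence that a low-copy draft assembly collapses, which purely
random unrelated repeats cannot provide. The sister reference is the
genome mutated at 2% substitutions/site plus rare 1--3 bp indels; the
draft assembly is the low-copy intervals fragmented to N50 about 600 bp
with 0.2% base noise, collapsing each duplicated pair to one contig.
`sample_haploids()` plants SNPs at density 1/200 with Balding-Nichols
differentiated frequencies between two gene pools (Fst 0.1 — a
placeholder, since no differentiation estimate exists for the system);
each haploid draws one allele per site. `simulate_reads()` does uniform
fragment sampling, 2 x 150 bp, Gaussian inserts (300 +/- 30),
substitution-only errors. `build_clone_population()` reproduces the
orchard structure (88 trios, 26 duos, 26 singletons = 342 ramets of 140
genets) with planted mislabels, and `simulate_amplicons()` gives
negative-binomially dispersed depths around 21x with binomial allele
counts and dropout.

Passing tests on this generator demonstrate the *logic* of every stage —
filters, coordinates, statistics, truth recovery — under realistic
coverage arithmetic. They do not demonstrate robustness to what the
generator omits: real transposon families with nested and truncated
copies, indel sequencing errors, PCR chimeras, base-quality miscalibration,
GC bias, or contamination. The k-mer histogram of the synthetic pool shows
a clear unique-coverage peak; the anomalous peak-free histogram seen in
real data of this kind is noted but deliberately not reproduced.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package and
  converted only at the VCF boundary (1-based) — BED stays 0-based.
* Suffix-array terminators are distinct and ordered by string index, so
  eBWT output is invariant to read input order up to that labelling; the
  candidate set is checked to be order-invariant.
* `pileup_call()` breaks base ties alphabetically (relevant only at
  error rates far above the defaults); sites covered in no sample are
  simply absent.
* `filter_variants()` is idempotent and its per-rule attrition counts
  partition the input exactly.
* Empty inputs error early with the offending stage named:
  empty read sets for the eBWT, empty depth profiles for the mask,
  all-monomorphic panels for the GRM, filters that empty a panel.
* Seeds: every stochastic generator takes an explicit seed and restores
  the caller's RNG state; the pipeline derives per-stage seeds from the
  config seed by fixed small offsets, so one integer reproduces a run
  byte for byte.

# Problem sizes used by the test suite

The bundled study conditions are a 200 kb genome (75% repeat, 2%
reference divergence), four haploid samples at 5x (pooled 20x), about
1,000 planted SNPs, and the full 342-ramet orchard at 200 amplicon loci —
sizes at which the whole suite, including an error-free end-to-end recall
check and brute-force oracles for the suffix array, the k-mer filter and
the spacing scan, runs in a few minutes on one CPU. The error-free recall
check uses a substitution-only sister reference, because the bundled
mapper is gapless by design and reads spanning reference indels would
lose coverage for reasons unrelated to the caller being tested; the
default generator keeps a small indel rate for all other purposes.

# Known limitations

* The mapper is gapless and single-best-hit; it is a test harness for the
  pipeline's logic, not an aligner. Import real BAM/SAM alignments for
  real data.
* GQ and the polymorphism test are simple proxies for full likelihood
  models; their thresholds (15; 0.001) are calibrated to the cascade's
  role as a coarse reliability sieve, not to genotype-quality semantics
  of any particular caller.
* eBWT construction is in-memory and suited to read sets up to tens of
  megabases of text; genome-scale reference-free calling needs external
  compressed-BWT machinery.
* Allele frequencies for the GRM include clonal replicates (by design of
  the validation); estimates of relatedness between genets inherit that
  bias.
* Absolute genome-scale call counts are not reproducible at desk scale
  and are not targets of the test suite; the printed worked-example
  arithmetic and the property suites are.
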