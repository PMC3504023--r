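---
title: "De novo marker discovery from RAD-seq and shotgun data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo marker discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

radmarkr implements a dual-platform workflow for discovering SNP and
microsatellite markers in a species with no reference genome and very low
genetic diversity. Two sequencing designs are modelled: restriction-site
associated DNA (RAD) paired-end sequencing, which subsamples the genome at
the cut sites of a 6-cutter (EagI, `C*GGCCG`), and long-read whole-genome
shotgun sequencing. Both converge on the same goal: a validated panel of
genotypable markers plus estimates of genotyping error from replicate PCRs.
This vignette explains the models behind each stage, the parameters that
matter, and what the synthetic data used to test the package does and does
not capture.

## The RAD path

### Digest prediction

Under an i.i.d. base model with GC fraction $g$, a window of the genome
matches a recognition sequence with probability
$\prod_i p(b_i)$, where $p(G) = p(C) = g/2$ and $p(A) = p(T) = (1-g)/2$, so
the expected number of sites in a sequence of length $L$ with recognition
length $m$ is $(L - m + 1)\prod_i p(b_i)$ (`expected_site_count()`).
Real genomes depart from this expectation — mammalian genomes are CpG
depleted, which matters for a site that is entirely G/C — so the package
also exposes the exact scan (`find_sites()`, overlapping occurrences
counted, reverse strand scanned for non-palindromic sites) and takes no
position on which a given analysis should quote. Each interior site yields
two sequenceable tags, one per direction from the cut.

### Library geometry

The modelled library is asymmetric paired-end: a 40 bp forward read anchored
at the cut (preceded in-line by the sample barcode, which is what the
demultiplexer keys on) and an 80 bp reverse read at the randomly sheared end
of an insert drawn uniformly from the configured range. The real library's
gel selection window (300–800 bp) is the `sim_config()` default. Because a
fragment's two reads cannot overlap (`insert_range[1] >= 120`), the
reverse-read cloud can never connect to the forward-read unitag in k-mer
space; the locus contig is therefore the assembly of the reverse-read cloud,
and the unitag's role is to define the cluster. The planted locus span is
the reverse-read-covered interval, `[insert_min - 80, insert_max)` bases
from the cut.

### Clustering and local assembly

Unitag clustering is exact-match: identical forward reads define a cluster,
and clusters with depth outside 5x–500x are dropped (sequencing errors
produce low-depth singleton clusters, collapsed repeats produce excessive
depth). The assembler (`debruijn_assemble()`) is a deliberately minimal
single-k de Bruijn walk, k = 31 by default (odd, at most the reverse-read
length, long enough that a random 100 kb genome almost never repeats a
k-mer). Rather than stopping at every ambiguity, the walk takes the
strictly-majority successor, so a heterozygous site inside a locus shows up
as the majority base in the contig — variation is recovered later by
mapping reads back, not during assembly — and exact count ties stop the
walk. Bubble arms left behind by the majority walk are shorter than the 150
bp contig floor and are discarded. The 150 bp floor matches the shortest
contigs this design produces; contigs are reported with their mean k-mer
depth, and per-sample depth outliers (outside 0.25x–4x the sample median)
are removed as repeat collapses or unreliable assemblies.

The sample with the most retained contigs (ties: most assembled bases, then
smallest id) becomes the mini-reference against which every sample's
reverse reads are mapped.

### Mapping and the threshold caller

RAD mapping is ungapped: exact 20-mer seeds propose placements on either
strand, the whole read is compared, at most 4 substitutions are tolerated,
and only a unique best placement is kept — a read fitting two contigs
equally is evidence of paralogy and is deliberately dropped. Genotypes come
from a count threshold, not a likelihood model: with alternate-allele
fraction $f$ at depth $\ge 5$, calls are hom-ref for $f < t$, hom-alt for
$f > 1-t$ and het otherwise, with $t = 0.075$ (7.5% alternate allele
frequency). The boundary convention is that $f = t$ calls het: alternate
evidence *at* the threshold rate counts. Site quality is a binomial-tail
surrogate, $Q = \min(60, -10\log_{10} P(X \ge a))$ for
$X \sim \mathrm{Bin}(d, 0.01)$ — the chance that error alone produced the
alternate support.

### Assay design, paralogs, private alleles

A SNP is assayable when no other polymorphism (including indels and
tri-allelic residues) lies within 60 bp either side, at least 30 bp of
contig flanks it on both sides, it is bi-allelic, and it is the single best
SNP of its contig (highest quality, ties leftmost). The proprietary
designability score of commercial assay-design tools is replaced by these
transparent pass/fail rules, with `design_score` = fraction of rules passed
kept for report compatibility. Survivors are packed into multiplexes of at
most 40.

A locus at which every genotyped individual is heterozygous is flagged as
two co-amplifying monomorphic paralogs (`flag_fixed_heterozygotes()`; at
least 2 genotyped individuals before the flag is trusted — the minimum that
makes "all individuals" informative, configurable). The simulator creates
this signature mechanistically: a duplicated locus with exactly one fixed
difference collapses into one unitag cluster at double depth, and every
individual's pileup shows both alleles at the divergent site. Flagged loci
can be split into co-amplified pairs (`split_duplicated_loci()`), which is
how 161 validated loci with 33 fixed heterozygotes become 194. Private
alleles — the minor allele observed in exactly one heterozygous individual
against an otherwise uniform homozygous background — are counted per
individual as a by-product of the genotype matrix.

## The shotgun path

Shotgun reads (truncated-normal lengths, mean 348 bp, sd 60, bounds 100–800
— the mean is the modelled instrument's; the sd and bounds reproduce the
long right tail such instruments show) are pooled across samples into one
combined de Bruijn assembly. Reads are unstranded, so the graph assembles
each region twice, once per orientation; contigs that mostly re-assemble
kept sequence on the opposite strand are dropped afterwards (canonical
k-mer bookkeeping, `dedupe_revcomp`). Mapping back is seed-and-extend with
a banded semi-global alignment (band 10) so small indels are representable;
an exact-occurrence fast path skips alignment for the error-free majority
of reads. Substitution calls pass at quality $\ge 20$, indel calls at
$\ge 50$ — indels in long-read homopolymer-rich data warrant the stiffer
gate. Indel events are recorded against the base to their left, VCF-style.

Note the depth implication of the indel gate: a heterozygous indel carried
by one haplotype of one of two pooled individuals is supported by a quarter
of spanning reads, so per-haplotype coverage below roughly 10x cannot
reliably clear $Q \ge 50$. The packaged shotgun test sizes its read count
accordingly.

### Microsatellites

`find_ssrs()` detects maximal perfect tandem runs of 1–4 bp motifs, one
class minimum per motif length (defaults: 6 for mononucleotide runs — below
that, homopolymers are mostly noise — and 3 for di/tri/tetra, the
workflow's screening floor). A single interruption ends a run; near-adjacent
runs (gap of at most 10 bp, configurable) are marked compound instead.
Motifs are canonicalised to the lexicographic minimum over rotations and
reverse-complement rotations (`TG`, `GT`, `CA` → `AC`), runs whose motif is
itself periodic are reported at the smallest period only, and overlapping
runs of different periods resolve to the longer (ties: smaller start). A
locus is a *potentially amplifiable locus* (PAL) when at least 30
unambiguous bases flank it on each side and it has at least 3 repeats;
primer candidates additionally need 4 repeats (only a subset of PAL is worth
primer design, since length-polymorphism scoring needs longer runs). The
flank rule is this package's operationalisation of "high-quality priming
sites"; it is deliberately simple and documented rather than thermodynamic.
PAL percentages are reported among di+tri+tetra loci to one decimal,
truncated (so 1,706/9,038 reports as 18.8).

## Replicate genotyping QC

Replicate PCRs of the same sample x locus are reconciled by a support rule:
an allele enters the consensus when seen in at least two replicates; two
accepted alleles give a het consensus, one a hom consensus, none (all
observations conflicting singletons) no consensus. Against the consensus,

- the **allelic dropout** rate is the fraction of positive amplifications of
  het-consensus entries that show only one consensus allele, and
- the **false allele** rate is the fraction of positive amplifications
  showing an allele absent from the consensus,

reported overall, per sample, and per plex. The ≥2-support rule conditions
the ADO denominator on entries whose consensus resolved het, which excludes
the most dropout-laden entries and biases the estimator slightly downward
(about −0.006 at rate 0.2 with 4 replicates); this is a property of
consensus-based estimation generally, not of this implementation, and it is
why replicate counts below 3 are not useful.

Diversity summaries are intentionally elementary: observed heterozygosity
per individual (het loci / genotyped loci), mean number of alleles per
locus, polymorphic fraction, transition/transversion classification of
unordered substitution pairs (ratio to two decimals), and SNP density
(SNPs per contig base, two significant figures; the convention for the
denominator — total bases of the contigs screened — is documented because
printed densities in marker studies are rarely reconstructible otherwise).

## What the simulator emulates, and what it does not

`simulate_reference()` plants every feature the pipeline must detect, with
ground truth retained: verbatim enzyme sites at spaced positions (accidental
background occurrences are scrubbed so digest recall is exact), perfect SSRs
with maximality enforced at their boundaries, duplicated loci with exactly
one fixed difference inside the sequenced span, SNPs at a configured
density with HWE genotypes whose per-individual heterozygosity targets
`target_het` (allele frequency $p$ solving $2p(1-p) = h$), private
variants, and optionally small indels outside the RAD spans. Haplotype
pairs are materialised per individual; reads are substrings of haplotypes
with optional uniform substitution errors (Phred 30 bases, Phred 10 at
injected errors). Replicate genotypes get dropout, false-allele and failure
events by the generative model the estimators are later asked to invert.

Deliberately not modelled: PCR duplicates, indel sequencing errors on the
RAD path, base-quality miscalibration, coverage biases (GC, fragment-size),
barcode cross-talk, and any population structure beyond per-site HWE.
Passing the truth-linked tests therefore demonstrates that the algorithms
are correct on data satisfying their stated assumptions — not that the
pipeline is robust to every artefact of real instruments.

## Evaluation scenario and numerical choices

The packaged end-to-end evaluation (`study_config()`) uses 8 individuals,
120 planted sites (240 single-direction non-paralogous loci), 3 duplicated
loci, 30 error-free read pairs per locus per individual, SNP density 0.001
with target heterozygosity 0.057, and inserts of 120–300 bp. The insert
range is narrower than the library default (300–800) by design: a locus
span of ~260 bp is what 30 random shear points can tile without k-mer gaps,
and it matches the 250–290 bp mean contig lengths this design is built
around. "Sequence-exact recovery" of a planted locus means the cluster's
locus contig is an exact substring of the planted span on at least one
haplotype of the assembled individual — extremities of the span are
shear-coverage-limited, so demanding exact end-to-end span equality would
measure the shear lottery, not the assembler. Genotype concordance is
counted allele-aware over planted variant x individual pairs at recovered
loci (the mini-reference may carry the alternate allele, in which case
calls are re-oriented before comparison); a site never reported is
concordant exactly for individuals that truly match the mini-reference
allele. Problem sizes throughout the tests (100–200 kb genomes, tens of
loci for unit tests, the 240-locus scenario for the end-to-end evaluation,
2 kb sequences against the brute-force SSR oracle) were chosen so the whole
suite exercises every path at depths where the statistics are meaningful.

Other numerical conventions worth stating: all internal coordinates are
0-based half-open and become 1-based only in VCF output; tri-allelic sites
keep their two most frequent alleles and carry a flag (a third allele needs
pooled frequency at least 7.5% to flag, so isolated sequencing errors do
not); site qualities cap at Phred 60; ties in the reference-sample choice,
the assembler walk, SSR overlap resolution and per-contig SNP selection all
have documented deterministic tie-breaks, which is what makes runs
byte-reproducible at a fixed seed.

## Interfaces

Every user-facing function takes a data frame first and returns a tibble,
so stages chain with the pipe; `run_rad_pipeline()` and
`run_shotgun_pipeline()` orchestrate the full paths and their results have
`tidy()`, `glance()` and `autoplot()` methods. Standard formats go through
standard tools: FASTA/FASTQ via Biostrings wrappers, VCF 4.2 written with
contig headers and per-sample GT/DP and read back via vcfR. The package's
functions, scripts and vignettes are its interface; no shell entry point is
shipped.

## Known limitations

The assembler is single-k with no error correction or bubble popping beyond
majority resolution; at per-haplotype coverage under ~8x it fragments. The
RAD mapper requires full containment of a read in a contig, so depth decays
at contig edges — the simulator plants variants away from span edges for
this reason, and real edge variants would be under-called. The shotgun
path's ambiguity handling drops reads that fit two contigs equally, which
under-covers recently duplicated regions (the same trade-off the fixed-het
flag exists to catch on the RAD side). Consensus-based ADO estimation is
slightly conservative, as quantified above. None of these limitations is
hidden by the tests: each is either exercised directly or stated here.
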