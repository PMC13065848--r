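---
title: "Methods: long-read telomere-fusion amplicon analysis with telofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read telomere-fusion amplicon analysis with telofuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telofuse)
```

## The problem

When telomeres shorten critically or sub-telomeric DNA breaks, chromosome
ends can fuse. Single-molecule fusion PCR amplifies the joined molecules
from targeted sub-telomeres, and nanopore sequencing reads each amplicon
end to end. A fusion read therefore consists of a sub-telomeric *flank* at
each end and, in complex events, one or more *insertions* between them:
segments copied from elsewhere in the genome (or from transfected plasmid
or contaminating bacterial DNA). The analytical task is to decompose each
noisy long read into its constituent segments, type the junctions between
them, group reads that sequence the same molecule, and summarise the
rearrangement structure.

`telofuse` implements this as five cooperating stages -- read QC, primer
labelling, spanning-alignment selection, event annotation, and graph-based
clustering -- together with a synthetic fusion simulator and a
precision/recall benchmarking layer, so the whole pipeline can be
validated without any external data.

## Read filtering

Nanopore artefact reads are dominated by long low-complexity tracts.
The built-in masker slides 36-bp windows (stride 12) and flags a window
when, for some tandem period up to 24 bp, fewer than 20% of positions
differ from the position one period ahead; flagged windows merge into
maximal blocks. Lowercase-masked input from an external masker is accepted
as a drop-in (`use_lowercase = TRUE`), since lowercase tracts are the de
facto output contract of such tools.

A read is discarded when it contains a block longer than 150 bp whose
repetitiveness score exceeds 0.3 -- *unless* more than 30% of the block's
overlapping 6-mers are rotations of `TTAGGG`/`CCCTAA`, which protects
genuine telomere repeat arrays, the very signal this assay targets. The
repetitiveness score is defined here as `1 - distinct k-mers / total
k-mers` with `k = 8`: deterministic, bounded in `[0, 1]`, near 0 for
random sequence and approaching 1 for pure repeats, and monotone as a
repeated unit is duplicated. It is a documented stand-in with the same
range and threshold semantics as the published artefact-scoring algorithm,
whose exact definition is not restated in the telomere-fusion literature.

Concatemers (two amplicons read as one molecule) betray themselves by a
primer match away from the read ends: the read interior (everything except
150 bp at each end) is screened against every primer target in both
orientations, and any local alignment reaching the primer score threshold
discards the read. A fast shared-13-mer prescreen makes the scan cheap for
the overwhelming majority of clean reads without changing the decision
rule, which remains the alignment score.

## Primer identification

Raw primers (18-26 nt) are too short to align reliably against noisy read
ends, so each primer is extended with its expected downstream reference
flank into a 68-bp *alignment target*. Each read end is searched within a
150-bp window (leading end forward, trailing end reverse-complemented,
since amplicons are sequenced from either strand); a local alignment
scoring at least `0.4 x maximum score` labels the end with the primer name
and trims the read to the alignment boundary. Unlabelled ends keep an
absent marker (`NA` in tables, `"False"` in text outputs). Scoring uses
match +2, mismatch -3, gap open 5, gap extend 2 -- the same scheme the
recommended external mapper uses, chosen because the primer-scoring scheme
is otherwise unspecified and one consistent scheme is the least arbitrary
option. The 150-bp window covers the 68-bp target plus typical nanopore
end noise; window sizes are configurable.

## Mapping and spanning-set selection

Mapping itself is delegated: any SAM/BAM produced by a mapper in
report-all-candidates mode can be supplied, and `mapper_command()` prints
the recommended invocation (`bwa mem -c 1000 -A2 -B3 -O5 -E2 -T0 -L0 -D
0.25 -r 1.25 -d 200 -k 11 -a`). Query coordinates are reconstructed on the
original read from CIGAR clips, with reverse-strand records mirrored onto
a single query axis -- junction typing requires all of one read's segments
to share that axis. For hermetic testing and the built-in end-to-end path
the package ships its own seed-and-chain mapper: exact 11-mer seeds
(repeat-filtered at 24 occurrences), same-diagonal micro-chains,
indel-tolerant chain merging through a diagonal-bucket index, and x-drop
ungapped extension of boundaries. Two numerical choices matter:

* whether a short segment is reported depends only on seed-supported
  coverage, never on chance extension, so detection is identical for a
  read and its reverse complement -- otherwise reads of the same molecule
  sequenced from opposite strands could disagree on marginal segments and
  refuse to cluster;
* a chain merge across a diagonal shift larger than 3 bp requires at
  least 3 supporting seeds. Chance 11-mer words shared between the two
  loci flanking a junction mimic microhomology and would otherwise drag a
  segment boundary tens of bases across the junction; genuine indel
  bridges almost always carry more seeds.

From all candidates of a read, `choose_spanning_set()` selects the subset
maximising `sum(scores) - 2 x (query bases shared by consecutive chosen
segments)`, with segments strictly ordered on the query, consecutive
overlap capped at half the shorter segment, and coverage gaps free. The
rationale: overlap at junctions *is* the microhomology signal (observed
junction overlaps have median 2-3 bp) and must be allowed, but only when
the alignment evidence pays for it at the per-base match rate; gaps become
insertion/gap junctions downstream and should not be penalised. The
optimum is found by dynamic programming over candidates sorted by query
start, with deterministic tie-breaks (lower query start, higher score,
then chromosome, reference start, strand). The exhaustive-search
equivalence of this DP is part of the test suite.

## Event annotation

The first and last of a read's chosen segments are its sub-telomeric
flanks; interior segments are insertions. Events are classed by insertion
count: none, simple (1-2) or complex (3 or more). The junction between
consecutive segments is typed purely from their query intervals: overlap
`k > 0` is microhomology of size `k`, contiguity is blunt, and a gap is an
`insertion_gap` of the gap size. Unmappable junction sequence and genuine
untemplated insertions are pooled in that last class -- read error makes
them inseparable at this level.

Insertion hotspots within one molecule are found by single-linkage
grouping per chromosome with a 10-kb linkage distance; only groups of two
or more insertions are reported, and a hotspot is flagged *overlapping*
when any two members share reference bases (the signature of repeated
replication of one locus). Whether a 10-kb "hotspot window" should bound
the pairwise gap or the total span is ambiguous; this implementation
bounds the pairwise gap, so a chain of nearby insertions can span more
than 10 kb. Foldbacks -- segment pairs of one molecule mapping to the same
locus in opposite orientations -- use reciprocal overlap of at least 0.8,
the same overlap constant the clustering stage uses, to keep one overlap
semantics across the package.

## Clustering

PCR amplifies each fusion molecule many times, so unique events must be
recovered by grouping reads. Only complex reads (three or more alignments)
are clustered, and only on their insertion sets: the flanks are the
PCR-targeted sub-telomeres and carry almost no identity information.
Candidate pairs must share at least one insertion with 80% *reciprocal*
overlap (one-sided overlap would make tiny insertions promiscuous);
pairs differing by more than 25% in insertion count or 4% in query length
are skipped; surviving pairs are scored with a Jaccard index in which two
insertions are equivalent under the same reciprocal-overlap rule and the
intersection is a greedy highest-overlap one-to-one pairing (element
identity across noisy reads has no natural definition, so equivalence
plus greedy matching stands in). The edge threshold depends on the
smaller insertion-set size -- 1, 1, 0.66, 0.66, 0.66, 0.5 for sizes 1-6
and 0.5 beyond -- demanding exact agreement for small sets and tolerating
noise in large ones.

The graph is kept sparse: each read contributes its 10 highest-Jaccard
edges, and the kept set is the union over reads. The union form matters:
admitting an edge only while *both* endpoints are below the cap provably
disconnects any clique larger than 11 (the first 11 reads saturate one
another, and later copies of the same molecule can never attach), whereas
the union keeps such cliques connected through shared partners while
every kept edge still ranks in the top 10 of at least one endpoint.
Clusters are connected components; reads without edges are singletons
with their own cluster ids. Each cluster's representative is the member
with the highest alignment score per aligned base, ties resolved to the
lexicographically smallest read id so reruns are identical.

## The simulator

`simulate_reference()` builds a miniature study system: 8 random 100-kb
pseudo-chromosomes, sub-telomere contigs of 2 kb whose unique sequence
ends in 25 `TTAGGG` units, tagged decoys (two plasmids, an *E. coli*
contig, a mitochondrial contig), and one primer per sub-telomere with its
68-bp alignment target. At this scale a full simulated run maps and
clusters in minutes on one CPU, while chance k-mer collisions -- the main
small-reference artefact -- are already rare enough not to dominate
benchmarks.

`simulate_fusion_events()` generates the study conditions: 3000 events by
default; insertion counts Poisson with mean 5 (zero allowed -- such events
exercise the non-clusterable path); insertion lengths gamma with mean
900 bp and standard deviation 1600 bp; amplification gamma with mean 15
and standard deviation 35 reads. Gamma distributions are parameterised by
moment matching (`shape = (mean/sd)^2`, `scale = sd^2/mean`), and lengths
and read counts are rounded to the nearest integer with a floor of 1.
With amplification shape ~0.18 a large probability mass lies below one
read, so the floor inflates the realised mean by up to +0.5 reads; the
insertion-length floor bias is negligible. Each insertion takes a uniform
random position and strand; the event sequence is the left sub-telomere,
the oriented insertions, then the reverse-complemented right sub-telomere,
so the two telomere arrays face head-to-head as in real fusion molecules.

`simulate_reads()` emits one read per amplification unit, reverse
complemented for a random half, and corrupts it with a uniform per-base
error model: 5% total error split 40/30/30 between substitutions,
insertions and deletions, a nanopore-like profile. Every read id encodes
the complete ground truth
(`event{k}|n={count}|{chrom}:{start}-{end}:{strand};...|read{j}`), so any
external read simulator that preserves this id convention can replace the
built-in error model. The simulator emulates segment structure,
amplification skew and uniform read error; it does not emulate
pore-specific error context, homopolymer compression, chimeric library
artefacts or basecaller quality strings, so passing benchmarks demonstrate
the pipeline's logic, not robustness to every real-data failure mode.

## Benchmarking

Insertion-level scoring decodes the truth from each read id and matches
called to true insertions one-to-one (greedy, smallest positional
discrepancy first): a match requires the same chromosome and start and end
each within 50 bp. Matched calls are TP, unmatched calls FP, unmatched
truths FN; precision, recall and F1 follow the standard formulas, with
`NA` (not 0) for undefined ratios. Counts are pooled across reads for the
headline (micro-average); per-read macro-averages are reported alongside.
Strand agreement is not required for a match but can be switched on.

Headline metrics apply a 50-bp minimum event size to truth insertions and
to unmatched calls, with calls matched to a sub-threshold truth excused
entirely. The floor equals the positional tolerance -- an event smaller
than the coordinate tolerance cannot be meaningfully localised -- and
reflects a physical detection limit: with 11-mer seeds (the recommended
mapper setting and the built-in default), no aligner can place an
insertion shorter than a seed, and the gamma length distribution (shape
~0.32) puts roughly a fifth of simulated insertions below that seed
length. Sub-seed insertions surface instead as insertion/gap junctions.
Unfiltered metrics over all insertions are always reported next to the
filtered ones.

Cluster-level scoring restricts truth clusters (reads sharing an event) to
reads the pipeline clustered, pairs each truth cluster with the called
cluster of maximal intersection (greedy, each called cluster used once),
and counts the intersection as TP, missing truth members as FN and foreign
called members as FP, pooled into the same metrics.

## Problem sizes and validation

The shipped validation uses, deliberately at desk scale: the full
3000-event default simulation for moment recovery (each sample moment
within three Monte-Carlo standard errors, amplification allowing the +0.5
floor bias); 500 random instances of up to 12 candidates for
exhaustive-search equivalence of the spanning-set DP; and 200-event
end-to-end runs -- at error rate 0 the insertion benchmark reaches
precision and recall above 0.99 with clustering exactly perfect, and at
the default 5% error F1 stays above 0.9 under the 50-bp tolerance. These
sizes keep the whole suite within minutes on a single CPU while leaving
every statistical check adequately powered.

## Known limitations

* The repetitiveness score and the built-in masker are documented
  stand-ins for external tools whose outputs can be substituted.
* The built-in mapper is a testing surrogate: real data should go through
  the recommended external mapper, with the package consuming its SAM.
* Junction typing is purely query-interval arithmetic; reference-side
  homology confirmation is out of scope.
* Hotspot linkage can chain beyond 10 kb (see above); the window is
  configurable.
* The benchmark's size floor means sub-50-bp insertions are scored only
  in the unfiltered metrics.
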