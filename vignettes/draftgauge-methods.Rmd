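---
title: "draftgauge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{draftgauge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Draft genome assemblies are fragmented: scaffolds are stitched from contigs
across runs of `N`s, and many contigs are short. Ab initio gene predictors
operate per contig, so a gene whose exons land on several contigs is
predicted several times ("cleaved"), and predictors typically report each
fragment as a complete gene, inventing the missing start or stop codon. A
second artifact works at the assembly level: a heterozygous locus assembled
twice produces two near-identical apparent paralogs ("split alleles"),
while two true paralogs assembled once produce a single locus ("collapsed
paralogs"). Cleavage and splitting inflate gene counts; collapse deflates
them. Paired-end mRNA sequencing can undo cleavage — a cDNA fragment has an
insert on the scale of introns, so its two mates can land on different
contigs and tie the two predicted fragments back into one locus — but it
carries no information about split alleles, whose two copies are each
full-length.

`draftgauge` models this causal chain end to end on synthetic genomes with
complete ground truth, so that every step (fragmentation, prediction-error
emulation, family clustering, cleaved/split classification, RNA-seq
correction) can be validated against provenance rather than against
irreproducible numbers from real assemblies.

## The pipeline and its parameters

**Genome simulation** (`make_genome`). Genes are valid ORFs (ATG, sense
codons, one stop; spliced CDS length divisible by 3) split into exons with
introns and intergenic spacers drawn from lognormal laws. Defaults emulate
a compact invertebrate genome: exons ~200 bp, introns ~400 bp, intergenic
~1.5 kb, exons per gene 1 + Poisson(4), GC 0.42. Every gene carries an
expression weight (default 1.0 for all genes — expression skew is not part
of the phenomenon being modeled; zero-expression genes exist to exercise
uncorrectable cases).

**Template lengths** (`make_template_lengths`). Fragmentation is matched to
a template contig-length distribution, standing in for a real highly
fragmented assembly (thousands of contigs, heavy right tail, roughly a
quarter of scaffold bases as gaps in the motivating case). The default is a
lognormal with `meanlog = 8.4`, `sdlog = 1.2`, floored at 500 bp (~9.5 kb
mean with a long tail). These are stated fixtures, not estimates.

**Gap splitting** (`split_on_gaps`). Scaffolds split at N-runs of length
≥ 50 by default: 50 bp is the empirical limit above which an ab initio
predictor no longer calls a single gene across the gap, which makes the
contig the operative unit for prediction. Whether the cutoff is "longer
than 50" or "50 or greater" is a genuine open choice; we fix the latter (a
run of exactly 50 splits) and expose `min_gap`.

**Fragmentation** (`plan_fragmentation`). The longest `x` template lengths
are rescaled by largest-remainder rounding to sum exactly to the genome
length, shuffled, and laid end to end along the concatenated genome; cuts
straddling scaffold boundaries are snapped (the boundary becomes a cut and
the nearest template cut is dropped, merging the smaller leftover into its
neighbor). This realizes the template multiset exactly except for at most a
couple of pieces per internal scaffold boundary, yields exactly `x`
contigs, and conserves every base — the entire genome sequence is always
included, with the distribution shape preserved.
An earlier scheme that dealt lengths to scaffolds proportionally and
absorbed rounding in a last piece was abandoned: with heavy-tailed
templates the per-scaffold sums miss by far more than one piece can
absorb. Sweeps use `refine_plan`, which only adds cuts, so
fragmentation-level curves are exactly monotone (nested plans), at the cost
of template fidelity beyond the base level.

**Prediction emulation** (`project_annotation`,
`emulate_boundary_invention`). Rather than running an external predictor,
the truth annotation is projected onto contigs: one model per contig
carrying ≥ 1 exonic base of a gene (intron-only overlap yields nothing —
prediction on fragments is effectively exon prediction), exons clipped at
contig edges, completeness evaluated in transcription order. `p_invent` is
the probability that a predictor invents a missing start/stop on a
fragment; the default 1.0 is the aggressive-predictor limit that reproduces
rising complete-gene counts under fragmentation, 0 is the conservative
limit. No published estimate of this rate exists; it is a free parameter.

**Family clustering** (`all_vs_all_similarity`, `mcl_cluster`). Similarity
is either a local alignment (match 2 / mismatch −3, gap 5/2; identity and
coverages from the best local alignment) or canonical k-mer Jaccard
(k = 11) for speed; scores are just edge weights, so clustering is agnostic
to the engine. Markov clustering runs with inflation 2.0, self-loops equal
to each node's maximum incident weight, tolerance 1e-6, 100-iteration cap
(the original analysis used "default parameters" of an unknowable MCL
build). One property often misstated: raising inflation makes MCL *finer*,
not closer to connected components; what is true, and what the tests
assert, is that families always refine the connected components and match
them exactly on disconnected clique graphs. Family ids are
content-addressed as `fam.<smallest member id>` (readable, deterministic,
comparable across reruns — a hash would add a dependency for no
information). Family-size deltas are binned at integers with tails
|delta| ≥ 3 collapsed but reported.

**Cleaved/split classification** (`classify_family`). Split: two draft
members align to each other with identity > 95% over ≥ 80% of their length
(both coverages) and each covers most of its span against the full-length
reference. Cleaved: two draft members occupy near-disjoint footprints on
the reference — overlap tolerance 10% of the shorter footprint, since
exact-zero overlap is brittle under alignment fuzz — and jointly cover
≥ 80% of it (symmetric with the split fraction). Everything else is
`unclassified`, keeping the undecidable bucket explicit rather than
folding it into either class.
Families with delta ≥ +2 are classified from the full member set; the
one-extra-gene case is the designed-for regime.

**RNA-seq linking** (`build_connection_graph`, `merge_models`). A pair
connects two models iff each mate overlaps (≥ 1 bp) an exon of its model
and the models sit on *different* contigs; same-contig merging is opt-in
(`same_contig`), for predictor-cleaved rather than assembly-cleaved models.
Filtering defaults are conservative: MAPQ ≥ 30 on both mates and
uniqueness required; both MAPQ-based and best-hit-flag notions of
uniqueness are representable in the SAM dialect, and the defaults are
documented and configurable since published analyses rarely pin them down. Merging is union-find (connected components) above a
support threshold `k`; `revised + reduction == original` holds by
construction and is asserted everywhere. Cumulative-dataset order is the
caller's order, logged for replay.

## What the generator emulates — and what it does not

The read simulator places alignments directly (no sequencing errors beyond
an optional engineered multi-mapper fraction, no quality strings, no
isoforms, no mapper): mates are the first and last `read_len` bases of a
fragment drawn uniformly from the spliced transcript, projected through the
fragmentation plan. A mate crossing an exon junction or contig boundary is
represented by its longest gap-free single-contig segment (ties to the
smallest contig id). `exhaustive = TRUE` emits one pair per valid fragment
start — deterministic saturation, used to make the end-to-end recovery
criterion exact instead of asymptotic. Consequently a green end-to-end test
establishes that the *logic* of correction is right (graph construction,
set merging, provenance accounting), not that real mappers, error profiles
or expression skew would behave as well; fragmentation here is positional
only (no mis-joins, no chimeras, no coverage model).

## Numerical choices and degenerate inputs

Coordinates are 1-based inclusive throughout — the native R/Bioconductor
convention, and GFF3 needs no conversion at the boundary (a 0-based
half-open internal scheme was considered and rejected as foreign to the
host ecosystem). Largest-remainder rounding backs every "integers with a
fixed sum" need, with a floor of 1 so no empty piece can arise. MCL prunes
entries below 1e-12 and reads the limit support at 1e-9; non-convergence
returns the current partition with a warning rather than failing. Empty
inputs return typed empty objects (`assembly_stats` of nothing is zeros;
an all-N scaffold yields no contigs; an empty SAM reads to an empty pair
table). All generators are deterministic per seed and restore the caller's
RNG state.

## Known limitations

- The prediction emulator reproduces fragmentation-induced error modes
  only; it cannot emulate predictor-specific differences beyond the
  `p_invent` limit cases.
- All-vs-all local alignment is quadratic and meant for desk-scale inputs;
  use the k-mer engine for larger model sets.
- Collapsed paralogs are diagnosed only as negative family-size deltas;
  no depth-based detection is attempted, and missing genes are not
  recovered.
- The CLI config is JSON, not YAML: no YAML parser is available in the
  supported dependency set, and JSON carries the same structure.
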