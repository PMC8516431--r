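---
title: "Methods: comparative piRNA-cluster analysis with piclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative piRNA-cluster analysis with piclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`piclust` analyses the evolution of germline piRNA clusters across
related species. This vignette describes the statistical models and
procedures the package implements, the parameters that matter, the
synthetic data generator used to validate every stage, and the numerical
and design choices made where the underlying procedures leave room.

All genomic intervals in the package are 0-based half-open (BED
convention); GFF3 input/output converts at the boundary, and deletion
coordinates are ingested in the 1-based inclusive convention genome
browsers print.

# Cluster identification

Clusters are called from **uniquely mapping** 23–29 nt reads
(`map_reads(mode = "unique")`, exact substring matching on both strands
— a no-mismatch alignment policy makes the mapper an exact string search,
so a position-dictionary lookup replaces an external aligner; real
alignments produced elsewhere can be ingested as extended BED instead).
Contigs under 50 kb are dropped before mapping, reflecting the
assembly-quality filter applied to long-read genomes.

`call_clusters()` slides windows of `window_bp` (default 1000, step 500)
along each contig and counts weighted read 5′ ends per window. Under the
null of uniform placement the count is Poisson with
λ = N·w/G, where N is the total mapped read weight, w the window size
and G the summed contig length. Windows with P(X ≥ k) < `density_p`
(default 0.05) are chained; each candidate is trimmed to the extent of
its reads, discarded if shorter than `min_size_bp` (5 kb) or if its
strand-agnostic composition max(frac 1U, frac 10A) falls below
`min_1U_or_10A` (0.30, inclusive — a candidate at exactly 30% passes);
survivors are merged by `merge_clusters()`: two loci merge when their
gap is smaller than their combined length, iterated to a fixed point
with overlapping inputs treated as gap 0. The Poisson window model is a
documented stand-in for the density heuristic of dedicated cluster
prediction tools, whose exact internal model is not restated in the
literature; its parameters are exposed in `cluster_call_params()`.

Strandedness (`classify_strand()`) is uni-strand when strictly more than
95% of unique reads come from one strand; exactly 95% is dual. The
composition floor is evaluated on the read set used for calling (unique
mappers); this is configurable by mapping in `all_best` mode, where
multi-mapper contributions are down-weighted by 1/n genomic hits to
prevent repeat inflation.

The ping-pong z-score (`pingpong_z()`) counts weighted opposite-strand
read pairs by 5′–5′ overlap o ∈ 1..20 nt and contrasts the 10 nt bin
against the others: z = (c₁₀ − mean(c₍o≠10₎)) / sd(c₍o≠10₎), with
population sd over the 19 background bins. Degenerate inputs are kept
distinct from real signal: a single-strand region, no opposite-strand
pairing, or a nonzero 10-nt excess over a zero-variance background all
yield `NA`; a perfectly flat signature (all bins equal, including the
10 nt bin) yields 0, the limiting value of the statistic.

Cluster expression uses two denominators, both configurable: **rpm** is
reads per million miRNA-matching reads of the library (`normalize_rpm`;
the ledger is accumulated while filtering reads against annotation sets
with up to 2 mismatches, miRNA matches counted first), following the
assumption that miRNA pools are constant between compared samples;
**rpkm** is reads per cluster kilobase per million genome-mapped 23–29 nt
reads. The synteny activity thresholds below consume both.

# Repeat landscape

`kimura2p()` implements the two-parameter divergence
K = −½·ln((1−2P−Q)·√(1−2Q)) from transition (P) and transversion (Q)
proportions against the family consensus, returned as a proportion and
raising an explicit error in the saturated domain (1−2P−Q ≤ 0 or
1−2Q ≤ 0) rather than returning NaN. In practice divergence values are
ingested from RepeatMasker-style annotations; the formula is provided
for synthetic data and recomputation. The CpG-adjusted variant is
deliberately omitted. The suite validates the formula against an
independent site-counting simulation: sequences evolved under the
two-parameter substitution process at known expected distance (0.1–0.3,
transition/transversion ratio 2, 40 kb sites) are recovered within 5%.

Border profiles tile each cluster border with 500 bp windows — 10 kb of
flank, 5 kb of interior for content (TE and CDS bp fractions), and
either the same absolute layout or border-centred halves rescaled to
±50% of each cluster's length for divergence. Window divergence is the
overlap-length-weighted mean of insertion divergences; windows with no
TE base pairs are skipped (not zeroed) when averaging across clusters,
and cluster-level means are taken before the cross-cluster mean. Borders
whose flank would leave the contig are dropped; internal windows
reaching past the opposite border of a short cluster are dropped for
that cluster only.

`call_heterochromatin()` replaces a manually validated designation with
a deterministic rule: TE bp density in 50 kb windows, maximal runs of
windows at ≥ 2× the genomic average density that include a contig end
are heterochromatin, everything else euchromatin; the partition tiles
each contig exactly once. Insertions are assigned to
cluster/heterochromatin/euchromatin classes by midpoint, avoiding double
counting at boundaries (`divergence_class_summary()`, 1% histogram
bins).

# Synteny tracing

Because cluster bodies are repeat-rich, homology is anchored on the
gene-rich flanks: `extract_flanks()` takes genes lying wholly within
200 kb on each side of the cluster, ordered from the border outwards,
with ortholog-group tags carried from the annotation. Homology search
itself (sequence alignment of flank genes) is outside the package:
synthetic data carries exact ortholog identities, and real data supplies
ortholog tables; the package's logic starts after gene placement.

`locate_homolog()` proposes the interval between the innermost matched
anchor genes and ranks alternatives by, in order: both flanks on the
same subject contig; innermost anchors closest to the query cluster;
longest contiguous run of collinear orthologs. Ortholog groups
duplicated in the subject are excluded (the correspondence must be
one-to-one). `classify_locus()` then labels the locus *active* when a
cluster called in the subject overlaps it and passes all five activity
thresholds (≥ 100 rpm, ≥ 10 rpkm, ≥ 5 kb, ≥ 25% TE bp, ≤ 25% gene bp);
otherwise *synteny* when the junction between the two flank arrays is
intact in the subject — the innermost left and right flank genes remain
adjacent with signed difference +1 in the query frame, which correctly
treats a wholly inverted locus as unbroken — and *inversion break* when
that junction is disrupted; *unresolved* when no placement is found.
Rpm/rpkm denominators for these thresholds are per-million
miRNA-matching and per-million genome-mapped reads respectively, as
above, and configurable.

Pairwise calls over all ordered species pairs (S species → S(S−1)
comparisons) are linked into homology groups by transitive closure of
locus overlap (> 0 bp; no reciprocal-overlap fraction is imposed, as
none is specified by the procedure this follows), using graph connected
components. Group age is the divergence time of the most recent common
ancestor of the species where the locus is active; single-species groups
are species-specific (age 0). Replacing case-by-case manual review with
these deterministic rules is a deliberate deviation; the pairwise table
retains machine-readable diagnostics instead.

# Rearrangement statistics

`build_signed_permutation()` writes the subject's shared genes in the
query's numbering (1..n by query position) with a sign recording strand
agreement. `find_breakpoints()` pads with 0 and n+1 — the classic
convention, so terminal inversions are counted — and reports adjacencies
with pᵢ₊₁ − pᵢ ≠ 1, flagging sign reversals (padding counts positive) as
inversion breakpoints. The test suite proves equivalence with a
brute-force single-reversal oracle: for every segment reversal of every
identity permutation up to n = 8, exactly the two flanking adjacencies
are created and flagged.

Breakpoint genomic positions are the midpoints of the intergenic span
between the anchoring genes (the true break lies somewhere in that
span); terminal adjacencies use the outer gene edge.
`profile_breakpoints()` bins events by distance to locus borders in
15 kb windows; events inside the between-flank-gene window
(`interflank_loci()`: the cluster extended to its nearest flanking
genes) form the x₀ bin. Enrichment is
Z₀ = (x₀ − μ)/σ with μ, σ the mean and **population** standard deviation
of the flank-window frequencies (no degrees-of-freedom correction is
specified by the source formula; this is configurable by supplying the
frequencies directly), and p = 1 − Φ(Z₀) one-sided. Flank sides
truncated by a contig end are excluded from the averaging; matched
random locus sets (`sample_background()`, default 10 sets, lengths
matched to the observed loci) provide an empirical background. The
profile extent defaults to ±150 kb (10 windows per side). By default
only inversion-flagged breakpoints are profiled, matching the
inversion-breakpoint framing; `inversion_only = FALSE` includes all.

# Attribution and in-silico deletions

Reads are attributed to a TE family when their placement overlaps an
annotated insertion of the family by at least half the read length
(genomic overlap rather than consensus alignment; the alternative is a
documented configuration point). `family_source_matrix()` apportions
each family's piRNAs among named clusters, remaining clusters and
outside-cluster copies (rows sum to 100%); `families_over_threshold()`
applies the strict > 50% principal-source and > 75% loss criteria. The
three telomere-associated families (Het-A, TAHRE, TART) are excluded by
default because of their strain-to-strain variability.

Mutant/control comparisons use miRNA-normalized counts with a
pseudo-count of 1 rpm in log₂ fold changes (no pseudo-count is
prescribed by the source analyses; 1 rpm bounds total losses without
masking real change, and it is configurable). Total TE-piRNA loss is
100·(1 − mutant/control), floored at 0. Genomic copy number inverts the
paired-end coverage identity: copies = reads × 300 / consensus length /
coverage, 300 being the base pairs sequenced per 2 × 150 nt read pair.

`apply_deletion()` removes an interval from the genome sequence and all
annotation layers: features wholly inside are dropped, straddling
features truncated, downstream features shifted left by the deletion
length, and alignment records overlapping the interval dropped (their
template no longer exists). Printed deletion coordinates are 1-based
inclusive, so the stored half-open length is end − start + 1; the ±1 bp
convention ambiguity is absorbed by kb-scale rounding in reports.

# The synthetic world generator

`world_config()`/`generate_ancestor()`/`evolve_species()` build a clade
of fly-like genomes with known truth. The ancestor has random 4-letter
contig sequences (no Ns, so exact-match mapping is unambiguous), ordered
non-overlapping genes whose ortholog group is their ancestral rank,
planted TE-dense piRNA clusters, a TE-dense terminal block per contig
emulating pericentromeric/telomeric heterochromatin, and dispersed
background insertions. Insertion divergences are layered by compartment
— clusters ~3%, terminal blocks ~8%, euchromatic background ~15% — so
the "young repeats in clusters" signature is plantable and testable.
Planted clusters are kept ≥ 25 kb apart because two loci closer than
their combined length would (correctly) be merged by the caller; when
subsequent evolution moves two planted clusters back within merging
range, truth-recovery comparisons treat their merged span as the ground
truth, since that is the locus the merge rule defines.

Evolution applies a Poisson number of inversions per branch (default
mean 1.5). Breakpoints are sampled from feature-free intergenic gaps, so
genes, insertions and clusters are never split — the gene-anchored
synteny logic assumes intact ortholog arrays. A configurable
`hotspot_bias` fraction of inversions draws **both** breakpoints from
≤ 1 kb windows immediately outside planted cluster borders, emulating
recurrent rearrangement at cluster loci; the suite audits this by
replaying each species' recorded event list from the ancestor.
Inversions reverse-complement the sequence and remap all contained
features, flipping strands.

`simulate_small_rna()` draws 23–29 nt reads from each cluster up to its
read budget. A fraction `u1_bias` (default 0.75) of reads start at
genomic positions yielding 5′ U, so reads still match the genome
exactly; in dual-strand clusters a `pingpong_fraction` (default 0.3) of
the budget is emitted as opposite-strand pairs whose 5′ ends overlap by
exactly 10 nt, drawn at positions that give the initiator its 1U/10A and
the responder its 1U. Uni-strand clusters emit 98% of reads from their
major strand by default, matching the > 95% classification margin with
room for noise. Uniform genomic noise adds
`noise_fraction` (default 5%) more reads; total output is exactly the
cluster budgets plus the noise budget. `simulate_te_dnaseq()` draws
per-family read counts Poisson-distributed around family bp × coverage
/ 300, the quantity the copy-number estimator inverts.

What the generator does **not** emulate: sequence-level substitution
(ortholog identity is carried as a tag, not inferable from sequence),
duplications and translocations (inversions only), non-uniform read
length or expression profiles within clusters, sequencing errors, and
genuinely multi-mapping repeat-derived reads (cluster sequences are
random, so nearly all reads are unique mappers). Passing tests therefore
demonstrate the correctness of the statistics and bookkeeping, not
robustness to alignment ambiguity or annotation error in real data.

# Validation scale and determinism

The bundled validation runs on one CPU in minutes and uses these
problem sizes, chosen as the smallest scales at which each property is
informative: cluster recovery on 3-species worlds with two contigs
(400/300 kb), 60 genes and three planted clusters (6–10 kb, 2000–4000
reads); breakpoint-enrichment recovery on 4-species worlds with eight
400 kb contigs, 320 genes and 20 planted clusters (the flank background
needs ≥ 20 loci for a stable σ, and with perfect hotspot placement a
smaller world can produce an all-zero flank background whose Z₀ is
undefined); Kimura recovery on 40 kb site simulations; the mapper is
cross-checked against a literal substring scan on ≤ 50 kb genomes; the
breakpoint detector against exhaustive single reversals at n ≤ 8. All
generator output is deterministic in the configured seed, and a pipeline
rerun with the same config writes byte-identical outputs.

# Known limitations

* The Poisson window model approximates, but is not identical to, the
  density heuristics of dedicated cluster-prediction tools; on real
  data, called boundaries may differ near cluster edges.
* The exact-match mapper is intended for synthetic data and small
  genomes; real libraries should be aligned externally and ingested.
* Highly structured loci (hairpin-rich regions) are not detected
  internally; a user-supplied exclusion BED is honoured instead.
* Synteny classification is only as good as the ortholog tables; tandem
  paralogs are excluded rather than disambiguated.
* Homology-group linking uses any-overlap transitive closure, which can
  chain loosely overlapping loci into one group on fragmented
  assemblies.
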