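---
title: "Models and methods behind teSpread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind teSpread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`teSpread` asks whether repressive chromatin (DNA methylation and H3K9me2)
spreads from the copies of a transposable-element family into the flanking
low-copy DNA, and what that spreading does to nearby genes. This vignette
documents the statistical model, every tunable that matters, the synthetic
world the test suite runs on, and the design decisions that were genuinely
open.

## 1. Flank profiles

Single-copy probes (short array oligos, one genomic match) are assigned to
their *closest* annotated repeat; distance runs from the probe midpoint to
the nearest repeat edge and counts the bases strictly between them, so a
probe abutting the edge has distance 0. Probes farther than
`max_distance_bp` (default 5,000) from every repeat are discarded; probes
whose midpoint falls inside a repeat are kept as `internal` but excluded
from flank statistics. Profiles pool both flanks into half-open 200 bp
bins (`bin k = [200(k-1), 200k)`) out to `profile_window_bp` (default
4,000); the two windows differ deliberately — retention is wider than
profiling — and both are configurable. A family enters the profile matrix
only with at least `min_probes` flanking probes (default 1,000, the filter
appropriate to a ~2M-probe array; desk-scale simulations lower it in
proportion to their genome size).

Replicates are averaged per probe *before* binning, so a bin mean is the
arithmetic mean of replicate-averaged probe values. Whether to average
before or after binning is not dictated by anything upstream; averaging
first makes the bin statistic a plain mean over probes, which is also
exactly the statistic the permutation null resamples, and that coherence
is why it is the default.

Assumptions worth stating: probe signals are treated as exchangeable given
distance (no spatial autocorrelation model), the closest-repeat rule is
applied literally even when a second repeat sits just beyond the probe,
and probe midpoints stand in for footprints (probes are 50–70-mers against
200 bp bins, so the approximation is well below bin resolution).

## 2. The permutation null and the spreading classes

The null asks: how enriched would bins look around insertions placed at
random in probe-bearing sequence? `generate_null_sites()` drops `n_sites`
(default 10,000) zero-length pseudo-insertions uniformly into the union of
chromosome spans that carry probes, and bins the probes around each point
exactly as real flanks are binned (both sides collapsed; the left flank's
distance is measured to the base preceding the insertion point so the two
sides are symmetric).

For family *f* with *m* copies, mark *w*, bin *k*:

* observed statistic: the pooled probe mean of bin *k*;
* null distribution: `B` resampled values (default 10,000), each the
  probe-count-weighted mean of bin *k* over *m* pseudo-insertions drawn
  with replacement — i.e. the same pooled-probe mean, computed on a
  size-matched random family;
* empirical p-value, add-one form: `p = (1 + #{null ≥ obs}) / (B + 1)`.
  p = 0 is impossible, and p < 0.001 is attainable only when B ≥ 1,000.

Classification (alpha = 0.001, strict inequality; `required_bins = 4`,
i.e. 800 bp of 200 bp bins): **spreading_both** if all four bins pass for
both 5mC and H3K9me2; **spreading_H3K9** if H3K9me2 passes and 5mC does
not; **non_spreading** otherwise; **unclassifiable** if any required
p-value is missing (a family must never silently fall into
non_spreading). H3K27me3 p-values are computed and reported but never
consulted — facultative heterochromatin is the negative control.

Two designs here were open and are resolved as follows. First, the per-bin
test could have compared distributions (probe-level rank-sum against
pooled null probes) rather than means; the mean-based form matches the
profile display, controls for copy number through the size-matched
resample, and is the default. Second, the pseudo-insertions could have
been redrawn per family; a single common pool of 10,000 with per-family
resampling is used, which lets one expensive binning pass serve every
family. Per-(family, mark, bin) resampling seeds are derived positionally
from the base seed, so dropping or reordering marks never changes another
mark's p-values, and the full classification is byte-identical across
runs.

Calibration and power are properties the acceptance suite measures, not
claims: under a generator with amplitude 0, per-bin empirical p-values
pass Kolmogorov–Smirnov uniformity and spreading calls stay at or below
1%; with amplitude 0.8 log2 units and decay scale 600 bp at ≥ 50 copies,
the three-way partition is recovered at ≥ 90% accuracy.

## 3. Bisulfite contexts and percent methylation

Contexts follow the standard plant trichotomy — CG, CHG, CHH (H = A, C or
T) — called from the genome: on the forward strand from the two bases
after the cytosine, on the minus strand from the reverse complement
(read-through runs leftward). Positions whose context window runs off the
chromosome are skipped with a warning. The caller is checked against an
independent regex oracle on random sequence.

"Percent methylation" of a region set is the weighted definition:
`100 · Σ meth_count / Σ total_count` over all covered cytosines of a
context, both strands. The alternative — call each site methylated when
`meth/total ≥ 0.5` at coverage ≥ 3 and report the site fraction — is
available as `per_site = TRUE`. Count weighting is the default because it
is stable at the ~7x coverages typical of whole-genome bisulfite data,
where per-site binarization is noisy. The weighted form is exactly
additive: splitting a region and re-aggregating counts reproduces the
summary bit for bit, and a test asserts that. A context with no covered
cytosines yields a missing percentage, never 0.

Low-copy flanks are the `flank_bp` (default 1,000) intervals adjacent to
each repeat edge, kept only if they overlap *no* annotated repeat at all
(strict reading of "low-copy") and lie fully inside the chromosome.
Group comparisons between spreading classes use the two-sided Wilcoxon
rank-sum on family-level values at alpha = 0.001, with non-spreading
families as the reference.

## 4. Empty sites

A TE insertion present in the reference haplotype but absent from a query
haplotype leaves a diagnostic read signature at the "empty site": query
reads align through the low-copy flank up to the annotated repeat edge and
then stop, with the rest of the read overhanging unaligned, while no read
aligns across the flank/repeat junction.

A *supporting read* at a boundary must satisfy every clause: more than
50 bp aligned outside the repeat; identity ≥ 94% (from the SAM NM tag:
`100·(aligned−NM)/aligned`, indels counted as mismatches); a junction-side
unaligned overhang of more than 20 bp whose anchor lies within ± 3 bp of
the annotated edge; and an opposite-side tail of at most 20 bp. The
"≤ 20 bp tails" and "> 20 bp overhang" requirements coexist by reading the
junction-side clip as the overhang and the far-side clip as the tail —
the only assignment under which both are satisfiable. The overhang
sequence is *not* required to match the distal flank. A *junction read*
has more than 3 bp aligned on both sides of the boundary (penetration
within the anchor tolerance is not junction evidence).

A site is called **empty** when supporting reads across its two boundaries
total at least `min_support` (default 3) and no junction read exists at
either boundary; **occupied** when junction reads exist and support is
absent; **ambiguous** otherwise — conflicting evidence is never resolved
to empty. Support is pooled across boundaries because the event being
certified is the absence of the *site*: a read spanning the empty junction
genuinely witnesses both edges at once (as a split alignment, one local
segment per flank), and demanding three reads at a single edge would
double the evidence requirement arbitrarily. The stricter per-boundary
variant is available as `require_both_flanks = TRUE`. Each clause sits on
a published threshold, and the acceptance suite flips every clause across
its threshold (50/51 bp, 93.9/94.0%, 20/21 bp overhang and tail, 3/4 bp
anchor) and demands the verdict flip exactly there.

Differential methylation between the genotype carrying the insertion and
the one lacking it is Welch's unequal-variance t on replicate log-ratios
at the single nearest probe (ties by probe id; sites with no probe within
5 kb are dropped and logged), two-sided at alpha = 0.01, no multiplicity
correction. The per-probe linear modeling appropriate to raw two-color
arrays is upstream of this package; Welch's t on normalized replicate
log-ratios is the faithful desk-scale counterpart.

## 5. Expression near TEs

RPKM is `10⁹ · count / (exon_length · library_size)` on merged exon
models; a gene is "expressed" iff RPKM > 0. "Upstream" is gene-strand
relative: the TSS is the interval start for + genes and the interval end
for − genes, and the scan runs 5′ of the TSS for the closest repeat edge.
A TSS inside a repeat gets distance 0 and joins the smallest stratum (the
case is undefined upstream; 0 is the only distance consistent with the
monotone stratum rule, and such genes are identifiable in the output).
Strata are nested cutoffs at 500/1,000/2,500/5,000 bp — a gene at 400 bp
appears in every cutoff's analysis — with a disjoint-band mode
(`disjoint = TRUE`) for band-wise questions. Within each stratum,
spreading-class gene RPKMs are compared against the non-spreading class
and against genes with no TE within the cutoff (two-sided rank-sum;
midranks with tie correction when the exact distribution is infeasible).

## 6. The synthetic world

The generator emits a complete, mutually consistent bundle from one seed;
identical config + seed gives a byte-identical bundle.

* **Genome**: uniform random A/C/G/T, default two 5 Mb chromosomes. No
  attempt at realistic base composition, repeat nesting, or gene islands.
* **Repeats**: non-overlapping copies placed uniformly (iterative redraw;
  placement fails loudly if the genome cannot host the requested copies).
  Default 20 families, 20–100 copies, 3 kb elements.
* **Signals**: probe at distance d from its closest TE of family f gets
  mean `baseline + A_{f,m}·exp(−d/λ_{f,m})` plus N(0, sd) per replicate;
  sd defaults to 0.5 log2 units (a realistic replicate spread for
  normalized two-color arrays) with 3 replicates. Spreading families use
  A = 0.8 and λ = 600 bp, inside the observed 600–1,600 bp spreading
  range. H3K9-only families share the H3K9me2 decay but get a short 5mC
  decay scale (150 bp) so methylation enrichment dies out before 800 bp —
  producing true spreading_H3K9 structure rather than a zeroed channel.
  In the query genotype the decay term is dropped at copies absent from
  haplotype 2, which is what makes insertion-conditioned methylation
  differences recoverable.
* **Bisulfite**: per-cytosine coverage ~ Poisson(7); methylated counts
  binomial with context baselines CG 0.75, CHG 0.55, CHH 0.05 (config, not
  claims), TE interiors at family-specific levels (defaults 0.9/0.8/0.05),
  and flank probabilities raised through a logistic link by the same
  exponential decay as the array signal.
* **Reads**: fixed-length (400 bp), error-free by default (the identity
  clause is stressed via the configurable error rate), drawn uniformly
  from the haplotype-2 sequence with polymorphic copies excised, then
  mapped back analytically. A read crossing an empty junction is emitted
  as a split alignment — both local segments ≥ 40 bp, each clipped on the
  junction side and anchored exactly at the annotated edge — because that
  is what a local aligner reports; reads across retained insertions align
  contiguously and cover the junction.
* **Genes**: placed outside repeats with TSS-to-TE distances drawn
  uniformly up to 5 kb (a "far" fraction is kept > 5 kb from any repeat);
  expression log-normal (sdlog 0.5) with the mean multiplied by
  `suppression_factor` (default 0.2) when the TSS lies within 500 bp
  upstream of a spreading-family TE. Suppression truth is recorded from
  the realized geometry, so the manifest and the emitted files cannot
  disagree.

What a green test does *not* establish: performance on real maize-scale
data (2.1M probes, 63M reads), robustness to annotation error or nested
repeats, aligner-specific clip semantics (the TSV alignment fallback
exists precisely because those semantics vary), or bisulfite conversion
inefficiency — conversion correction is out of scope.

## 7. Numerical conventions and degenerate inputs

* Coordinates 0-based half-open everywhere; GFF3 converted on read;
  distance counts intervening bases (abutting = 0).
* Nearest-feature ties broken by (chrom, start, copy_id) for repeats and
  lexicographic probe id for probes; every tie-break is deterministic and
  logged.
* Empirical p-values live in (0, 1]; alpha comparisons are strict.
* Empty bins, contexts without coverage, classes without members: missing
  values, never zeros.
* Derived child seeds stay below 2^31 (R integer range).
* Resample draws whose pseudo-sites happen to carry no probes in a bin are
  dropped from that null vector; a bin with no probes across the whole
  pool is an error.
* Desk-scale tests use B = n_null = 2,000 (alpha = 0.001 attainable at
  B ≥ 1,000, granularity 1/2001) and min_probes scaled to the simulated
  genome; the package defaults remain at the published full-scale values
  (B = 10,000, n_null = 10,000, min_probes = 1,000).

## 8. Known limitations

Classification applies no multiple-testing correction across families (as
published); probe signals are modeled as exchangeable, so spatially
correlated array artifacts would inflate enrichment for all families
equally but are not modeled; empty-site detection assumes the reference
repeat annotation is correct at ± 3 bp; per-element (single-copy)
classification, LTR-divergence dating, small-RNA size classes and
raw-array normalization are out of scope. The pipeline ingests normalized
replicate log-ratios and per-cytosine reports; producing those from raw
data is upstream.
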