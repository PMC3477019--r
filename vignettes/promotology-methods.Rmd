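---
title: "Methods: from ortholog promoters to co-regulated gene candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ortholog promoters to co-regulated gene candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coregscan)
```

# The problem

Genes that are regulated together tend to carry the same arrangement of
transcription-factor binding sites (TFBS) in their promoters. `coregscan`
implements a "promotology" workflow that starts from a set of orthologous
promoter sequences of a gene of interest and ends with a list of candidate
co-regulated genes validated against expression data:

1. **Promoter derivation and quality control** (`extract_promoter()`,
   `qc_filter_sequences()`): promoter windows around annotated transcription
   start sites (TSSs) are extracted and sequences that are gapped or too
   ambiguous are discarded.
2. **Ortholog vetting by phylogeny** (`compute_distance_matrix()`,
   `build_nj_tree()`, `build_upgma_tree()`, `bootstrap_support()`): a
   distance-based phylogeny over the ortholog set flags annotation errors
   and rogue sequences before motif analysis.
3. **Motif scanning** (`scan_pwm()`, `scan_iupac()`, `scan_sequences()`):
   position weight matrices (PWMs) and degenerate IUPAC strings are located
   on both strands with information-weighted similarity scores.
4. **Framework discovery** (`discover_frameworks()`): ordered motif
   combinations with consistent inter-element spacing that recur across a
   quorum of the ortholog promoters.
5. **Model construction and screening** (`framework_to_model()`,
   `scan_model()`, `screen_promoter_set()`, `conserved_across_species()`):
   frameworks become screenable *regulatory models* — ordered elements with
   explicit per-gap distance ranges and stringencies — which are then
   searched in promoter databases and across species.
6. **Gene assignment** (`map_hit_to_chromosome()`, `assign_genes()`): model
   hits found in clones/contigs are placed on the chromosome with
   orientation-aware rules and nearby downstream genes are selected as
   co-regulation candidates.
7. **Expression validation** (`quantile_normalize()`, `compare_tissues()`):
   candidates are checked for tissue-specific over-expression in microarray
   style intensity matrices.

Every stage is driven by plain tabular data (tibbles) or the field's
canonical containers (`DNAStringSet`, `phylo`, `dist`), so stages can be
re-ordered, audited, or replaced in a pipe.

# Promoter windows and sequence QC

Promoters are modelled as the window from 1500 nt upstream of the TSS to
500 nt downstream (the start of the transcript, including the beginning of
exon 1). Both extents are parameters; the defaults reflect the window in
which proximal regulatory modules are usually sought. Internally all
coordinates are 0-based and half-open on the forward chromosome strand —
one convention for all arithmetic; GFF3's 1-based inclusive coordinates are
converted on read. The TSS of a gene record is its 5' end; isoform-level
TSS selection is out of scope.

QC discards a sequence when it contains alignment gaps or when its fraction
of undetermined bases (`N`) *strictly exceeds* `max_unknown_frac`
(default 0.10) — a sequence at exactly the threshold is kept, reading "more
than 10%" literally. The `region` argument restricts the fraction to a
sub-window (e.g. only the promoter part of a longer import), since the rule
is most meaningful where the motif search will happen; both readings
(whole sequence vs promoter region) are therefore available.

# Distance phylogenies for ortholog vetting

The phylogeny stage is a sanity check, not an inference goal: orthologs
that cluster absurdly or sit on extreme branches usually indicate
mis-annotation. Distances are computed after **complete deletion** (every
alignment column with a gap or `N` in any taxon is removed globally) under
p-distance, JC69 or K2P. These standard substitution-model distances are
used instead of composite-likelihood estimators found in desktop phylogeny
suites; at promoter-level divergences all of them vet orthologs equally
well, and they are exactly reproducible from the formulas. Tree building
relies on the `ape` implementations of neighbor joining (and
average-linkage clustering for UPGMA): NJ is exact on additive matrices —
the test suite checks path-length recovery to 1e-9 — and negative NJ branch
lengths are clamped to zero with a warning. Bootstrap supports are computed
by resampling alignment columns with replacement, rebuilding a tree per
replicate, and attaching to each internal edge of the point-estimate tree
the percentage of replicates containing the same bipartition (100
replicates by default); a majority-rule consensus is deliberately not
built, so supports always annotate the tree being reported. A replicate
whose resampled columns all die in complete deletion is redrawn. An
optional divergence screen (`divergence_from_reference()`) flags taxa whose
distance to a named reference (e.g. the human sequence) exceeds a
threshold; it is off by default because no universal cutoff exists.

# PWM scoring: information-weighted core and matrix similarity

A PWM stores per-position base frequencies `f(i, b)` and an information
value per position,

$$C_i = \frac{100}{\ln 4}\left(\sum_b f(i,b)\,\ln f(i,b) + \ln 4\right),$$

which is 0 for an uninformative (uniform) position and 100 for an
absolutely conserved one. The similarity of a window \(b_1 \ldots b_L\) to
the matrix is the information-weighted ratio

$$\mathrm{sim} = \frac{\sum_i C_i\, f(i, b_i)}{\sum_i C_i\, \max_b f(i, b)},$$

so the consensus scores exactly 1 and mismatches at uninformative positions
cost nothing. The **core** of a matrix is the run of (by default four)
consecutive positions with the largest summed information, scored
separately: a hit must pass both the core similarity threshold (default
0.75) and the whole-matrix threshold (default 0.80). These defaults are
mid-stringency starting points — per-matrix optimized thresholds from
commercial libraries are not reproducible here — and both are arguments
everywhere. An `N` in the sequence contributes zero to the numerator; a
window against a matrix whose assessed positions carry no information
scores 1 by convention (nothing to violate). Degenerate IUPAC strings are
matched with an explicit per-position mismatch budget, with one deliberate
rule: an `N` in the *sequence* never satisfies a non-`N` pattern symbol,
because an undetermined base is not evidence of a binding site.

Mismatch stringency applies to IUPAC strings only; PWMs are controlled by
their two similarity thresholds. This resolves an ambiguity in how
"maximum number of mismatches" interacts with matrices: a PWM already
grades partial matches continuously.

# Framework discovery

A *framework* is an ordered chain of 2-6 motifs with an observed gap range
(3' end of one element to 5' start of the next) per adjacent pair, carried
by at least `quorum` of the input promoters. Discovery is Apriori-style:
ordered pairs first, then rightward extension one element at a time, which
keeps the search polynomial where exhaustive subset enumeration would not
be. Gap measurement uses gap length rather than start-to-start distance so
that the ranges are invariant to element widths.

The spacing-consistency rule is a **width cap**: the gaps of the instances
supporting a framework must fit in a window of width `2 * gap_tolerance`
(default 10 nt, i.e. ±10 around a center). When a sequence contains several
instances, the implementation slides a window of that width over all
observed gaps and keeps the placement covering the most sequences
(smallest gap on ties); the reported `[dmin, dmax]` is the observed range
inside that window. This explicit single-parameter rule stands in for the
undocumented internal heuristics of commercial framework tools; it is a
design choice of this package, stated here so results can be interpreted
accordingly. Chains must sit on one strand (`same_strand = TRUE`); the
alternative treats all hits as forward. Only maximal frameworks are
reported — a chain that is a contiguous sub-chain of a longer framework
with equal support adds no information. Output order is deterministic
(size, then element names), and identical inputs give byte-identical
output.

`framework_to_model()` converts a framework into a screenable model: the
allowed range for each gap is `[0, distance_factor * g_ref]`, where
`g_ref` is the gap observed in a named reference promoter (e.g. the human
ortholog) and the factor defaults to 2 — "twice the reference distance" —
a permissive band that tolerates spacing drift without losing the
architecture.

# Model screening

A regulatory model is matched by left-to-right chaining of element hits
under the inclusive per-gap ranges, on one whole-model orientation at a
time (mixed-strand elements within one model are not supported); the minus
orientation is scanned on the reverse complement and reported in forward
coordinates. By default **all** elements must match in order. The
`quorum_k` parameter relaxes this to "at least k elements, in order" for
low-stringency screening; the gap constraint across skipped elements is
the sum of the intervening ranges plus the skipped elements' (fixed)
lengths, which is the unique choice consistent with the fully matched
chain. All maximal chains are reported without greedy suppression —
overlapping hits are real alternatives and downstream consumers can
deduplicate by span. On small inputs the chaining output is verified
against brute-force enumeration of all hit combinations.

`screen_promoter_set()` maps the scan over a promoter database and reports
the per-sequence hits plus a sequences-with-hits summary;
`conserved_across_species()` screens one ortholog promoter set per species
and passes when at least `min_species` species contain a hit — screening
reports all positions, and TSS proximity is enforced only at the gene
assignment stage.

# Clone-to-chromosome mapping and gene assignment

Genome screening returns model hits in clone (contig) coordinates. With
`x`/`y` the chromosomal start/end of the clone, `a` the model offset in the
clone and `W` the search-window width (default 2000 nt), the four
orientation configurations give:

| case | model in clone | clone on chromosome | gene strand | a' | z |
|------|----------------|---------------------|-------------|-----|------|
| A | + | + | + | x + a | a' + W |
| B | − | + | − | x + a | a' − W |
| C | − | − | + | y − a | a' + W |
| D | + | − | − | y − a | a' − W |

`a'` is the chromosomal coordinate of the model's 5' end in reading
direction and `z` the far bound of the TSS search window. The sign of
`z − a'` always equals the resulting gene strand, and the mapping is
invertible (`map_hit_to_clone()`); a property test exercises the round trip
over randomized placements, which pins down the model-in-clone orientation
of the B/C configurations by consistency.

Within `[a', z]`, a gene becomes a retained candidate when (1) it lies on
the hit's chromosomal strand, reading away from the model ("directly
downstream"); (2) its TSS is at most `max_tss_distance` nt (default 500,
**inclusive**) from the model's 3' end, or the model overlaps the gene's 5'
end by at most `max_overlap` nt (default 200). The 2000 nt window is the
candidate *search* region (measured from the model's 5' end); the 500 nt
rule is the retention filter applied inside it (measured from the 3' end)
— the two limits answer different questions and coexist without
contradiction. Negative TSS distances denote overlap and route to the
overlap filter. Genes failing a filter are returned with the failed filter
named rather than silently dropped, and hits in regions without genes
simply contribute no rows: rejections stay auditable.

# Expression validation

Candidate gene sets are checked against probes × samples intensity
matrices. Samples are quantile-normalized (each sample's r-th order
statistic replaced by the mean r-th order statistic, ties averaged — via
`limma::normalizeQuantiles`), intensities are averaged per tissue, and each
probe gets a two-sided Wilcoxon rank-sum p-value between the two tissue
sample groups: exact by full enumeration of the rank-sum null (with
midranks) when the pooled size is at most 12 and tie-free, a tie-corrected
normal approximation otherwise. The over-expression flag is
`fold_change >= 1.5` — inclusive, "at least 1.5-fold" — and follows the
fold change only; raw and Benjamini–Hochberg-adjusted p-values are reported
alongside but do not gate the flag, keeping the flag's definition simple
and the statistical evidence visible. Probes measuring the same gene can
be aggregated via a probe→gene map: the gene-level fold change is the
average of the probe ratios, and the gene-level p-value is recomputed on
per-sample expression averaged over the gene's probes. Log ratios use
log2. A zero reference mean leaves the ratio undefined (flagged, not an
error). The sidedness of the test is a choice: two-sided, because
candidate validation should not presuppose the direction.

# Synthetic fixtures and what they show

The `make_*` generators produce ground-truthed inputs for every stage:

- `make_promoter_set()` — i.i.d. background (default GC 0.5, order-0; an
  order-1 Markov background would not change what the planted-recovery
  tests measure) with a model instance planted in a chosen fraction of
  records, gaps jittered uniformly within ±`gap_jitter` of each range's
  midpoint.
- `make_genome_fixture()` — one chromosome per orientation case A–D, a
  clone with known placement, a model instance at a known offset, a target
  gene at a retained TSS distance (default 300 nt) and decoys that each
  violate exactly one filter: wrong strand, TSS distance 501 nt (one past
  the inclusive limit), or overlap past 200 nt. The model span is 300 nt so
  that an overlap violation is geometrically constructible.
- `make_expression_fixture()` — log-normal baselines, planted fold changes
  in the target tissue, Gaussian noise on the log scale.

A single integer seed drives each generator; the same seed yields
byte-identical files, which the determinism tests assert. The fixtures
emulate the *structure* of real data, not its texture: no repeats,
homopolymer bias, motif turnover, probe cross-hybridization or batch
effects. Passing the planted-recovery tests therefore shows the algorithms
are correct and calibrated on clean signal, not that real-genome screens
will be free of false positives — on real data the stringency parameters
(similarity thresholds, quorum, gap tolerance) do that work.

# Numerical and design notes

- Coordinates: 0-based half-open everywhere internally; GFF3 converted at
  the boundary; minus-strand features reported in forward coordinates.
- Tie-breaks: leftmost core window on ties; smallest gap window on ties in
  discovery; `ape`'s deterministic internal tie-break in NJ (adopted with
  the NJ implementation rather than re-implementing the algorithm for a
  different tie rule — determinism, the property that matters for
  reproducibility, is preserved and tested).
- Degenerate inputs: empty QC input returns empty partitions; a
  single-sample matrix quantile-normalizes to itself with a warning;
  all-tied Wilcoxon inputs give p = 1; JC69 is refused (with the pair
  named) when the raw mismatch fraction reaches 3/4, where the distance is
  undefined.
- Exact Wilcoxon enumeration is quadratic-ish in `choose(n, k)` and is
  capped at pooled n = 12 in `auto` mode; beyond that the tie-corrected
  normal approximation is standard practice.
- Problem sizes in the test suite (hundreds of probes, promoter sets of
  6–10 × 600–2000 nt, 100 bootstrap replicates, 1000 mapping round trips)
  were chosen so the full suite runs in minutes on a laptop while still
  exercising every code path; all of them scale up by argument.

# Known limitations

- No statistical over-representation scoring of frameworks or model hits;
  discovery is combinatorial, and significance must come from conservation
  and expression evidence.
- PWM scores are not p-value calibrated and use a uniform background.
- Alignment construction, remote retrieval, isoform-aware TSS catalogues
  and probe-set summarization are out of scope; aligned FASTA, annotations
  and intensity matrices are consumed as inputs.
- The discovery spacing rule is a declared, explicit stand-in for
  proprietary tools' undocumented criteria (see above); results should be
  compared across tools with that in mind.
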