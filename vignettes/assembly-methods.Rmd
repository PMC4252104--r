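---
title: "Paired-end guided greedy assembly: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-end guided greedy assembly: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assembly model

`pegasm` assembles short paired-end reads (50–150 bp) by greedy,
base-by-base contig extension, guided at every step by a strict evidence
hierarchy: paired-end reads first, then single-end reads with the longest
available overlaps, then a trained classifier, then an explicit
look-ahead.  The package implements the whole method — k-mer index,
extension engine, SVM branch navigator, look-ahead repeat resolution,
scaffolding with gap estimation and filling — together with a paired-end
read simulator and an evaluation harness, so that every stage is testable
on synthetic data with a known truth sequence.

## The k-mer index as an overlap oracle

Two reads that overlap error-free over $w$ bases share exactly
$w - k + 1$ consecutive k-mers.  The index therefore stores, for every
sampled k-mer (keyed by the lexicographic minimum of the k-mer and its
reverse complement, so both strands hit one entry), an ascending
occurrence list (read, mate, position, strand).  Read-to-contig alignment
never needs a seed-and-extend aligner: a hash lookup of the contig's
terminal k-mer proposes read placements, and direct sequence comparison
verifies them.

To bound memory, only a fraction of each read's k-mers is indexed
(`sample_fraction`, default 0.1), taken half from each read end — the
positions closest to the termini.  End-anchoring is what matters: a read
is recruited when the growing contig end passes over one of its
end-anchored k-mers, after which full-sequence comparison takes over.
Sampled interior k-mers are never consulted during extension.  k-mers
spanning an N are never indexed, so ambiguous bases cannot create fake
overlap evidence.

## Contig extension

A contig is seeded from the 5'-terminal k-mer of an unused read whose
index frequency exceeds `low_freq_threshold` (default 2) — start k-mers
containing sequencing errors are rare in the index and are excluded from
seeding.  Extension proceeds at the 3' end one base at a time; when it
stops, the contig and all its alignment records are reverse-complemented
and the same 3' machinery extends the other end.

At each step the engine maintains two pools: partially aligned reads
hanging over the 3' end (pool 1, each contributing a candidate next base)
and fully aligned reads (pool 2).  A read joins a pool only if at least
`min_align_frac` (90%) of its bases over the contig match, its overall
similarity reaches `min_similarity` (95%), and no mismatch run exceeds
`O_min` bases (the bubble tolerance).  Reads failing these tests stay
available for other genome regions.  Reads with erroneous tails drop out
of the pools as their mismatch fraction grows — the dead ends such errors
would otherwise cause are shorter than a read length and never
materialise in the contig.

The candidate-base tally is computed in strict priority order:

1. **Paired-end pool.**  Once the insert-size model is established
   (`min_insert_n` pairs observed, contig long enough to place mates), a
   pool-1 read votes with paired weight when it is reverse-strand at the
   3' end and its mate is fully aligned forward upstream at a span within
   `insert_sd_mult` (2.0) standard deviations of the insert mean.  This
   window is the same one used by the tandem-repeat tests, and it is what
   lets pairs resolve repeats up to the insert size.
2. **Single-end sweep.**  If fewer than `min_pairs_paired` (2) pairs
   support the best base, single-end tallies are computed at overlap
   thresholds swept from `O_max` (70) down to `O_min` (= k, 25): a read
   may vote only if its aligned span reaches the current threshold.  The
   sweep descends only while the tally at the current threshold is
   empty — long overlaps are more trustworthy, so once any read of the
   current size exists, that tally decides and shorter overlaps are never
   consulted.
3. **Gap.**  No read at any threshold stops the contig.

The insert-size model itself is inferred on the fly: every pair whose two
mates become fully aligned in inward orientation contributes its
outer-5'-ends span, and mean/standard deviation are the running sample
statistics.  On a 370 ± 56 bp library the model converges within a few
hundred extensions.

## Branches and the navigator

An extension point is a *branch* when the second-best base has at least
`min_branch_support` (2) supporting reads.  With 1% substitution errors
and 50x coverage, a single dissenting vote appears at roughly a fifth of
all columns; requiring two keeps branch counts at the scale of genuine
ambiguity and a lone dissenting read is simply outvoted.  A tie at or
below that support level stops the contig — there is no majority base to
append.

Each branch is summarised by four features: `maxOcc` and `secOcc` (read
counts behind the top two bases), `covRatio` (mean aligned-read density
within two read lengths of the end over the contig-wide mean — values
well above 1 flag a repeat pile-up) and `gapLen` (distance from the last
fully aligned read to the contig end).  The end-window density counts
partially aligned reads too; counting only full alignments would make
the ratio droop by one read length at every extending end and hide
exactly the pile-ups the feature exists to detect.

The navigator is a soft-margin SVM with the polynomial kernel
$K(x,y) = \langle x,y\rangle\,(1+\langle x,y\rangle)^2$ — a
positive-coefficient series in the dot product, hence positive
semi-definite.  Features are z-standardised before the kernel (raw counts
would dominate the dot product); the scaler is stored in the model.  The
quadratic program is solved by `kernlab::ksvm`; classification at
assembly time is the package's own dual expansion
$\sum_i \alpha_i y_i K(s_i, z) + \rho$ over the stored support vectors,
cross-checked against kernlab's decision values in the tests.  Decision
values inside `[-svm_margin, +svm_margin]` (default 0.5, boundary
inclusive) are low-confidence and go to the look-ahead.  A verdict of
CONTINUE is additionally vetoed when `maxOcc == secOcc`: whatever the
classifier thinks, a dead tie offers no base to extend with.

Two models are shipped (`navigator_default()`), one trained on
paired-mode branch features and one on single-mode features, both
produced by `tools/train_default_model.R` from this package's own
simulations: 150 kb genomes carrying short tandem arrays, mid-size
duplications (resolvable by pairs, not by single reads) and 700–1000 bp
duplications (beyond the insert, where stopping is correct), assembled
with pure-majority decisions and labelled against the truth sequence.
The single-mode training run disables the insert model so that every
branch is decided — and therefore labelled — from single-end tallies.
Soft-margin penalty C = 1 and the 0.5 margin are package defaults, not
values inherited from elsewhere.  Without a trained model a
zero-dependency heuristic stands in: continue when
`secOcc/maxOcc < 0.7`, `gapLen` is small (≤ 100 bp) and
`covRatio ≤ 1.5`; anything else is low confidence.

### Truth labelling

For training and evaluation, every branch decision is recorded with the
contig's terminal `trace_context` bases (default 500, about one insert
span).  A context with a unique continuation in the truth sequence makes
an extension correct iff it appended that base, and any stop incorrect.
A context occurring at two or more truth loci with divergent
continuations is ambiguous at the evidence scale even pairs can reach:
stopping there is correct and extending is a gamble, counted incorrect.
Contexts that cannot be located (they contain assembly errors) are
skipped with a warning.  The context length matters: judged on, say,
100 bp contexts, an assembler would be penalised for correctly using
paired evidence across repeats longer than 100 bp.

## The look-ahead

Low-confidence branches are resolved by extracting one candidate forward
path per supported base.  A path grows greedily: its supporting reads
vote base by base, new reads are recruited at the path terminus through
the index, paired-compatible votes take priority (as in the main engine),
and residual ties fork the path (up to 8 states).  Paths end at read
exhaustion or at the horizon — insert mean plus two standard deviations,
beyond which pairs anchored on the contig carry no signal.

The resolver then applies, in order:

1. **Dead-end elimination.**  Paths that die before one read length are
   dead ends caused by erroneous read tails; removing them often leaves a
   single live path, which is followed.
2. **Sequencing-error consensus.**  Per column, over all path-supporting
   reads (deduplicated), the majority-nucleotide ratio is computed on the
   region where at least two paths are defined; shorter path tails are
   ignored so honest length differences are not penalised.  Fewer than
   `max_bad_positions` (3) columns below `path_majority` (0.9) means the
   disagreement is scattered error: extension continues with the majority
   base.
3. **Branch-column decisiveness.**  If the branch column itself has a
   majority ratio of at least 0.9, that base is taken regardless of
   disagreement further ahead — downstream divergence belongs to a later
   decision point, which will be taken with more assembled context.
4. **Tandem merge.**  If one path's suffix matches another's prefix over
   strictly more than `min_path_overlap` (10) bases — with the trailing
   path starting strictly inside the leading one; a shift of zero is a
   convergent bubble, not two copies — the paths trace consecutive copies
   of a nearby tandem repeat.  They are merged and extension continues
   along the leading path.  Its phase-shifted reads are released from the
   active pool and re-recruit automatically at the correct downstream
   copy as the contig reaches it, which is how the trailing path's reads
   are "adjusted" without explicit offset surgery.
5. **Spurious-path removal.**  Remaining paths with more than 2
   mismatches against the local contig sequence *and* bridging-pair spans
   deviating from the insert mean by more than two standard deviations
   come from distant repeat copies; they are removed and their reads
   released.  If exactly one path survives, it is followed; otherwise the
   contig stops.

## Scaffolding

Phase 2 re-aligns all reads to the contigs and keeps only full-length,
uniquely placed alignments inside the linking regions (terminal
`linking_region` bp, default 2000).  Every pair with its mates on two
different contigs determines one of four placements of the ordered
contig pair — both reads point toward the junction, so contig A's
orientation equals its read's strand and contig B's is the flip of its
read's strand.  Each edge of the resulting graph carries the placement
quaternion (one weight per configuration).

Linking is greedy: the longest contig at least as long as the linking
region seeds a scaffold (longest-first rather than an arbitrary random
choice, for determinism), which is extended to the right and then — after
reversing the chain — to the left with the same code path.  A neighbour
is accepted when its best placement weight is at least 3 pairs and at
least twice any competing candidate's weight; undifferentiated
alternatives terminate the extension, and leftover contigs become
singleton scaffolds.

The gap at each junction is estimated as
$\hat g = \frac{1}{n}\sum_i (\mu - d_{a,i} - d_{b,i})$, where $\mu$ is
the insert mean and $d_a, d_b$ are the distances from each read's 5' end
to its contig's gap margin.  Estimates above one insert standard
deviation stay gapped; smaller or negative estimates trigger a pairwise
end alignment, and an overlap longer than `min_contig_merge_overlap` (3)
that agrees with the estimate (within `max(5, sd)` bp) merges the two
contigs, taking the overlap once — which also corrects erroneous contig
ends rather than trimming them.  Remaining gaps go to local assembly:
pairs with one end uniquely anchored on a flanking contig contribute
their mates, and the phase-1 engine, restricted to that read subset,
grows into the gap from the left (then, if needed, the right) flank.  A
gap closes when the local extension reaches the opposite flank with an
overlap of at least `O_min`; residual gaps keep an N-run of the
estimated size (at least one N).

Note one property of the gap estimator on real read sets: only fragments
long enough to bridge a junction contribute, so the bridging sample is
length-biased ($E[F \mid \text{bridge}] > \mu$) and $\hat g$
underestimates by a few tens of bp at typical library geometry.  The
formula is used as stated; the agreement tolerance and gap filling
absorb the bias, and the op-level tests sample $(d_a, d_b)$ from the
estimator's own model, where it is unbiased.

## The simulator

`generate_genome()` produces a uniform-random background with planted
tandem-repeat arrays; `repeat_spec()` describes an array (unit length,
copies, spacer, per-copy divergence) and may be nested — one inner copy
per outer unit, with surplus inner copies appended to the array, so
constructs like "A three times containing B four times containing C five
times" are expressed directly and every copy interval is reported in the
truth annotation.

`simulate_pairs()` emulates a standard short-insert Illumina library:
normal fragment lengths (clamped to at least one read length), uniform
fragment starts, strands sampled with equal probability, the second mate
reverse-complemented so pairs point inward, i.i.d. substitution errors.
Defaults are 100 bp reads with 370 ± 56 bp inserts at 50x — ordinary
bacterial-assembly conditions.  One fragment is anchored at each terminus
(`tile_ends`) because a linear template otherwise has a terminal coverage
ramp, and reconstruction experiments should measure the assembler, not
the sampling ramp.  What the simulator deliberately does *not* model:
indels (the error-handling machinery addresses substitutions; quality
profiles are out of scope), PCR duplicates, GC bias, quality strings
carrying information, and circular genomes.  Passing tests on this
simulator therefore say nothing about indel-rich or coverage-biased real
data.

## Evaluation

`n50()` is the usual halfway length.  `call_misassemblies()` anchors each
record on the reference by shared 31-mers on both strands, clusters hits
by diagonal, verifies the best anchor with a banded global alignment of
the whole record (band 50 — adequate for substitution-dominated
assemblies, not for indel-rich ones), and calls a record mis-assembled
when its whole-length similarity falls below 95%.  Coverage counts a
reference position as covered when any anchored interval of any record
spans it, so a collapsed repeat record credits all its genomic loci.
`tally_branches()` cross-tabulates labelled branch decisions into the
four outcome classes with a look-ahead sub-ledger split into
sequencing-error and short-repeat checks.

# A worked example

```{r, eval = FALSE}
library(pegasm)

g <- generate_genome(50000, list(repeat_spec(60, 3, 30)), seed = 11)
sim <- simulate_pairs(g, coverage = 50, err_rate = 0.01, seed = 11)
cfg <- assembly_config(navigation = "svm", seed = 11)

asm <- assemble_contigs(sim, cfg, model = "default")
ev <- evaluate_assembly(asm, g, trace = asm$trace)
ev$n50; ev$coverage; ev$ledger

sc <- scaffold_contigs(asm, cfg = cfg)
emit_scaffolds(sc, "scaffolds.fa")
```

# Problem sizes and determinism

The test suite and the acceptance script work at desk scale: 20 kb
genomes for reconstruction and tandem-repeat experiments, 200 kb for the
branch-accuracy runs, 50x coverage throughout — sizes at which the full
pipeline completes in seconds while every stage still sees realistic
branch structure.  All randomness flows through explicit integer seeds;
identical seeds give byte-identical reads and identical assemblies.

Degenerate inputs are handled conservatively: empty read sets and
single-class training data are errors; an empty tally is a gap-stop; a
branch tie below the support threshold stops; contigs shorter than
`min_contig_len` (100 bp, about one read length) are discarded, with
their consumed reads retained so seeding cannot loop.

# Known limitations

* **Phase ambiguity inside identical tandem arrays.**  When copies are
  identical, the unit exceeds the read length, and the array period is
  inside the ±2 sd insert window, wrong-phase pairs pass the
  compatibility test and no evidence the data contain can settle the
  phase.  The look-ahead usually keeps such regions in one contig, but a
  copy may be collapsed; with divergent copies (a few percent) the
  similarity rules separate the copies cleanly.
* **Gap-size estimates are length-biased** on bridging pairs, as
  described above.
* **Substitution-only error handling.**  Indels in reads break the
  column-aligned comparison model and are out of scope end to end
  (simulator, engine, evaluator).
* **Leftover-read mini-contigs.**  Reads whose end k-mers all carry
  errors are recruited late or never; at high error rates their leftovers
  can seed short (~100–250 bp) redundant contigs near the reporting
  floor.  They are honest output — real short-read assemblers produce
  them too — and scaffolding ignores them through the uniqueness rule.
* **Single-threaded, in-memory.**  The index and engine target
  desk-scale experiments (up to a few Mbp), not production genomes.
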