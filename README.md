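# pegasm — paired-end guided greedy de novo assembly

`pegasm` is an R package for assembling short paired-end sequencing reads
(50–150 bp) into contigs and scaffolds, aimed at people studying assembly
algorithms on bacterial-scale or synthetic data: it bundles the assembler
itself with a read simulator and an evaluation harness, so every stage of
the method can be exercised against a known truth sequence.

## The method

Contigs grow base by base from a sampled k-mer index of the read set.
Two reads overlapping error-free over *w* bases share *w* − *k* + 1
consecutive k-mers, so a hash lookup of the contig's terminal k-mer is
all the alignment machinery extension needs.  Evidence is consulted in
strict priority order:

1. **Paired-end reads first.**  A partially aligned read votes with
   paired weight when its mate is fully aligned on the contig at an
   insert span within μ ± 2σ of the inferred insert model — pairs resolve
   repeats up to the insert size.
2. **Single-end reads by decreasing overlap.**  When pairs are
   undecidable, tallies are swept over overlap thresholds from
   *O*<sub>max</sub> down to *O*<sub>min</sub> (= *k*); the first
   threshold with any support decides, so long, confident overlaps are
   never diluted by short ones.
3. **SVM branch navigation.**  Ambiguous extension points (branches) are
   classified CONTINUE/STOP by a soft-margin SVM with the polynomial
   kernel *K*(x, y) = ⟨x, y⟩(1 + ⟨x, y⟩)² over four branch features:
   maxOcc, secOcc (support behind the top two bases), covRatio (local
   versus global aligned-read density) and gapLen (distance from the
   last fully aligned read to the contig end).
4. **Look-ahead at low confidence.**  All candidate forward paths are
   extracted and compared: scattered per-column disagreement is
   sequencing error (continue with the majority); paths whose
   suffix/prefix overlap exceeds 10 bp are consecutive copies of a short
   tandem repeat (merge and continue along the leading path); paths with
   high mismatch and incompatible insert spans are removed; anything
   still ambiguous stops the contig.

A second phase orders and orients contigs into scaffolds from a
placement-weighted linking graph built on uniquely mapped pairs,
estimates each junction gap as ĝ = (1/n) Σ (μ − d<sub>a</sub> −
d<sub>b</sub>), merges overlapping neighbours and closes gaps by local
assembly with the phase-1 engine.  See the methods vignette
(`vignettes/assembly-methods.Rmd`) for the full model, parameter
rationale and known limitations.

## A worked example

Simulate a 50 kb genome carrying one short tandem-repeat array, sequence
it to 50x with 1% substitution errors, assemble, and compare with the
truth:

```r
library(pegasm)

g   <- generate_genome(50000, list(repeat_spec(60, 3, 30)), seed = 11)
sim <- simulate_pairs(g, coverage = 50, err_rate = 0.01, seed = 11)
cfg <- assembly_config(navigation = "svm", seed = 11)

asm <- assemble_contigs(sim, cfg, model = "default")
print(asm)
#> assembly: 193 contigs, total 70791 bp, N50 49996 bp
#>   insert model: 370.6 +/- 55.6 bp (n = 11193 ); 152 branch decisions

ev <- evaluate_assembly(asm, g, trace = asm$trace)
#> N50: 49996  coverage: 0.99992  misassembled: 15
print(ev$ledger)
#> branch ledger (152 branches, 0 skipped):
#>   correct_extension       152 (100.00%)
#>   incorrect_extension       0 ( 0.00%)
#>   correct_stop              0 ( 0.00%)
#>   incorrect_stop            0 ( 0.00%)
```

Reading the output: the genome comes back as one 49,996 bp contig — the
four missing bases are unsequenced genome termini — plus ~190 short
(~100–250 bp) leftover contigs assembled from reads whose end k-mers all
carry errors; they sit at the reporting floor, a handful fall below the
95% similarity rule (the `misassembled` count), and the N50 and coverage
are carried entirely by the main contig.  The insert model was inferred
from the data (370.6 ± 55.6 bp against a simulated 370 ± 56), and all
152 branch decisions match the truth sequence.  `scaffold_contigs(asm)`
would link multi-contig assemblies into scaffolds; here the main contig
already spans the genome.

The same pipeline is available from a shell via the bundled CLI:

```sh
pegasm=$(Rscript -e 'cat(system.file("scripts", "pegasm", package = "pegasm"))')
Rscript $pegasm simulate --genome-length 50000 --coverage 50 --err 0.01 \
        --seed 11 --out-prefix sim
Rscript $pegasm assemble --fq1 sim_1.fq --fq2 sim_2.fq --out contigs.fa
Rscript $pegasm evaluate --assembly contigs.fa --truth sim_genome.fa
```

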