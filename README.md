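# regufoot

Comparative-genomics reconstruction of bacterial transcription-factor (TF)
regulons from phylogenetic footprints.

Bacterial regulons — the sets of operons controlled by one TF — can be
inferred without any binding assay by exploiting evolutionary conservation:
a real operator site recurs upstream of the orthologous operons of related
species, while spurious matches do not. `regufoot` implements that workflow
end to end for people studying carbohydrate-utilization (or any other)
regulatory networks across a genus of sequenced bacteria:

1. **Training sets** — upstream/intergenic regions (up to −300 bp from the
   translation start, longer than 50 bp) of candidate co-regulated genes and
   their orthologs across genomes.
2. **De novo motif discovery** — expectation-maximization under a ZOOPS
   sequence model (zero or one site per region, both strands), with the
   symmetry typical of bacterial operators imposed exactly in the M-step:
   palindromes of 20–24 bp, tandem repeats of two identical 7–11 bp boxes at
   21 or 32 bp start-to-start periodicity (two or three DNA helical turns),
   or spaced inverted repeats such as `GGGAC-(27)-GTCCC`.  Geometries
   compete on mean per-column information content; ties go to the smaller
   span.
3. **PWM scanning** — positional weight matrices with log₂-odds weights
   `w(b,i) = log2((n(b,i) + α·q(b)) / ((N + α)·q(b)))` and a score threshold
   equal to the *lowest score observed in the training set*, so training
   recall is 100 % by construction.
4. **Consistency filtering** — a candidate target operon is kept only when
   hits recur upstream of its orthologs in at least
   `max(2, ⌈0.5 · n_eligible⌉)` genomes that carry both the TF and the
   operon.
5. **Mechanism inference** — 5′ transcription start sites (TSS) and σ^A
   promoter elements (`TTGACA`/`TATAAT`, 15–19 bp spacer, −10 element 4–9 bp
   from the TSS) anchor a positional rule: sites inside the 5′ UTR or
   overlapping a promoter hexamer ⇒ repressor; sites entirely upstream of
   the −35 element ⇒ activator.
6. **Expression overlay** — cross-tabulation of genes up-regulated more than
   2 log₂ units between substrate conditions (with a 1.5–2 "moderate" band)
   against reconstructed regulon membership, plus per-regulon concordance
   with the expected inducing substrate.

A ground-truthed synthetic generator (`gen_toy_genomes()`,
`gen_training_set()`, `gen_expression()`) emulates the study design — k
pseudo-species with conserved planted operator sites in diverged upstream
regions, TSS geometries realizing repressor/activator layouts, and
regulon-structured expression over five substrates — so every pipeline stage
can be benchmarked against planted truth.

## Worked example

Simulate a 4-genome benchmark with 6 target operons and 40 decoy genes per
genome, train on 3 operons of known genomic context, and reconstruct the
regulon:

```r
library(regufoot)

run <- run_pipeline(list(
  seed = 7,
  simulate = list(n_species = 4, n_target_operons = 6, n_decoy_genes = 40,
                  n_training_operons = 3)))
run
#> <regufoot_run>
#>   motif: palindrome_w20  consensus CTAAAGTCATATGACTTTAG  (1.63 bits/col, threshold 23.28)
#>   regulon: 6 member operon(s) from 22 scan hits; mode ambiguous
#>   vs truth: precision 1.000, recall 1.000, site recovery 1.000
#>   expression concordance: 0.833
```

The discovery stage selected a 20 bp palindrome (the planted geometry) with
1.63 bits of information per column; scanning all four genomes at the
minimum-training-score threshold (23.28 bits) and applying the consistency
filter recovered all 6 planted target operons and none of the 40 decoys
(precision and recall 1.0 against the generator's truth).  Member-level
detail comes from the broom-style tidiers:

```r
tidy(run$regulon)
#> # A tibble: 6 × 5
#>   group_id n_species_hit best_score n_eligible quorum
#>   <chr>            <int>      <dbl>      <int>  <dbl>
#> 1 tg01                 4       35.5          4      2
#> 2 tg02                 4       35.5          4      2
#> ...
```

`n_species_hit` is the cross-genome conservation count behind each retained
operon and `quorum` the threshold it had to meet.  `utr_stats(run$tss)`
summarises the simulated TSS map (median 5′ UTR 54 bp here, all within
180 bp), and `autoplot(run$discovery)` draws the motif logo.

Lower-level entry points (`extract_upstream()`, `training_regions()`,
`discover_motif()`, `build_pwm()`, `score_region()`, `scan_genomes()`,
`consistency_filter()`, `find_promoter()`, `classify_mode()`,
`de_crosstab()`, `regulon_concordance()`) take and return tibbles and chain
with the pipe; `write_meme()` / `read_meme()` round-trip motifs in MEME
minimal format, and `write_hits_gff()` exports sites as genomic GFF3
intervals.

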