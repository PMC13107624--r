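# adatscan

Integrative screening for genes whose translation depends on
ADAT2-mediated A-to-I tRNA modification, from tRNA-seq, RNA-seq and
Ribo-seq.

## The problem

The ADAT2/ADAT3 deaminase converts adenosine to inosine at the wobble
position (position 34) of eight human tRNA anticodon families —
Leu(AAG), Arg(ACG), Ser(AGA), Pro(AGG), Ala(AGC), Val(AAC), Ile(AAT),
Thr(AGT). Inosine-34 pairs with codons ending in C, U or A, but each
family's **C-ending codon** (TCC, CTC, CGC, CCC, GCC, GTC, ATC, ACC) has
no other cognate tRNA: it is decoded only through the I34:C wobble pair.
Transcripts enriched in these *A-to-I-dependent* codons are therefore
translationally coupled to ADAT2 activity — a mechanism implicated in
codon-biased oncogenic translation.

`adatscan` implements the full desk side of that screen for
anyone analyzing matched perturbation data (ADAT2 overexpression and
knockout, each with controls):

- **Wobble model** — `adat_codon_model()`: the 8 families, their strictly
  dependent codons, and a synonymous recode map that removes inosine
  dependence (NNC→NNG; ATC→ATA).
- **Inosine quantification** — `estimate_inosine()` reads the wobble
  inosine fraction as the A→G mismatch fraction at position 34
  (`i_fraction = G/(A+G)`, `I-to-A ratio = G/A`);
  `inosine_fold_change()` compares conditions per family.
- **Translation metrics** — `translation_efficiency()`: per-condition
  `TE = (mean ribo CPM + c)/(mean rna CPM + c)`, log2 fold changes, and
  the concordance call (TE and Ribo-seq up under overexpression, down
  under knockout).
- **Codon bias** — `codon_bias()`: per-gene dependent-codon usage vs. an
  all-genes background; the screen keeps genes > 1.5-fold enriched in
  {TCC, CTC, CGC}.
- **Candidate funnel** — `run_funnel()`: concordance → codon bias →
  tumor-vs-normal overexpression (rank-sum + BH), with per-gene evidence,
  deterministic ranking, `tidy()`/`glance()`/`autoplot()` methods.
- **Synonymous recoder** — `recode_cds()` for building
  A-to-I-independent reporter sequences.
- **Synthetic data** — `simulate_bundle()` generates ground-truthed
  inputs for every stage (known inosine fractions, planted codon-biased
  TE responders, tumor overexpression), so the whole pipeline is testable
  without external data.

## Worked example

Simulate a full study (500 genes, 5 planted responders whose planted
dependent-codon fraction is 0.30 vs. a 0.12 background), then run every
stage:

```r
library(adatscan)

bundle <- simulate_bundle(seed = 42)

# inosine supply: overexpression vs control, per tRNA family
est_case <- estimate_inosine(bundle$pileup_case)
est_ctrl <- estimate_inosine(bundle$pileup_ctrl)
head(inosine_fold_change(est_case, est_ctrl), 3)
#> # A tibble: 3 × 5
#>   family_id ratio_case ratio_control fold_change log2_fold_change
#>   <chr>          <dbl>         <dbl>       <dbl>            <dbl>
#> 1 Thr-AGT         9.40         0.955        9.75             3.29
#> 2 Ala-AGC         9.96         1.05         9.42             3.24
#> 3 Arg-ACG         9.18         0.995        9.14             3.19

te   <- translation_efficiency(bundle$rna, bundle$ribo, bundle$design)
bias <- codon_bias(bundle$cds, codon_subset = c("TCC", "CTC", "CGC"))
screen <- run_funnel(te, bias, tumor = bundle$tumor)
screen
#> ADAT2 candidate funnel
#>   stage 1 (TE/Ribo concordance):   23 genes
#>   stage 2 (codon bias > 1.5): 5 genes
#>   stage 3 (tumor overexpression):  5 genes
#>   top candidates: g0049, g0485, g0321, g0074, g0153

names(bundle$truth$responders)
#> [1] "g0049" "g0074" "g0153" "g0321" "g0485"
```

The I-to-A ratio jumps ~9-fold in every family (simulated overexpression
raises the wobble inosine fraction from 0.5 to 0.9: ratios 0.9/0.1 = 9
vs. 0.5/0.5 = 1). The funnel's 23 stage-1 genes are the 5 planted
responders plus the sign-flip false positives expected from a pure
direction filter (null rate 9/64 — see the vignette); the codon-bias and
tumor stages then recover exactly the planted set. `tidy(screen)` gives
the per-gene evidence table, `glance(screen)` the stage counts, and
`autoplot(screen)`, `plot_te_concordance(te)`, `plot_bias_scores(bias)`,
`plot_inosine_fold_change(...)` the standard figures. `run_all()` +
`pipeline_config()` run the same flow from files on disk and write all
intermediate tables plus a manifest.

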