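# lbqc — quality control and in silico decontamination for low-biomass 16S data

16S rRNA gene profiles sequenced from low microbial biomass specimens
(nasopharyngeal swabs, induced sputum, dilute mock communities) are easily
dominated by artefacts: reagent/laboratory DNA amplified preferentially at low
template concentration, well-to-well spill-over, extraction bias against
hard-to-lyse gram-positive bacteria, and spurious rare OTUs. `lbqc` is an R
package for researchers analysing such data. It implements a three-step
cleanup —

1. **denoise**: remove "spurious OTUs" (grand total < 5 reads across all
   libraries, no-template controls included);
2. **gate**: exclude biological specimens with ≤ 500 16S copies/µl (qPCR);
3. **decontaminate**: flag "potential contaminants" and subtract, per flagged
   OTU, its maximum NTC proportion from every specimen (clipped at zero,
   optionally re-closed)

— plus the QC and evaluation machinery around it: replicate reproducibility
(R²), biomass correlations, Bray–Curtis / PCoA / PERMANOVA / complete-linkage
beta diversity, compositional statistics (zero replacement, ilr pivot
coordinate, one-way ANOVA with Tukey HSD intervals), mock-community
evaluation, and a truth-labelled synthetic cohort generator.

Contaminants are identified either by the presence-based **NTConly** rule
(detected in ≥ 1 NTC and ≥ 1 specimen) or by a statistical classifier
combining two lines of evidence per OTU:

- **frequency**: on samples where the OTU is present, fit
  `ln f = β₀` (contaminant-free) against `ln f = −ln c + β₀′` (contaminant:
  frequency inversely proportional to biomass `c`) and take
  `p = Pr(F₍ₙ₋₁,ₙ₋₁₎ ≥ SSR₀/SSR₁)`;
- **prevalence**: one-sided Fisher exact test for presence enriched in NTCs
  versus specimens;
- **combined**: Fisher's method, `X = −2(ln p_freq + ln p_prev)` against χ²₄.

An OTU is called a contaminant when its p-value is strictly below the
threshold (default 0.1).

## Worked example

```r
library(lbqc)

run <- run_pipeline(list(
  simulate  = list(seed = 1),                  # synthetic cohort, defaults
  decontam  = list(methods = c("ntconly", "combined"), threshold = 0.1),
  diversity = list(n_permutations = 999),
  mock      = list(reference = "zymobiomics"),
  seed      = 1))
run
#> <lbqc_run> 652 OTUs x 374 samples; 584 spurious OTUs removed; 125 samples gated out
#>   ntconly    35 potential contaminants
#>   combined   20 potential contaminants
```

The simulated cohort (150 specimens with technical repeats, 10 NTCs, 24 mock
libraries) yields 652 OTUs over 374 libraries; 584 rare OTUs fall to the
5-read rule, 125 low-biomass libraries to the 500 copies/µl gate. The
presence-based rule flags 35 OTUs, the combined classifier 20 — every one of
which is also an NTConly call (`run$summary$decontam$overlap_combined_in_ntconly`
is 1).

```r
qc <- qc_table(run$cohort$counts, run$cohort$metadata)
qc_correlations(qc[qc$role == "specimen", ])
#> # A tibble: 3 × 4
#>   term              estimate     n undefined
#> 1 r_age_biomass        0.736   340 FALSE
#> 2 r_biomass_reads      0.514   340 FALSE
#> 3 r_biomass_shannon   -0.827   340 FALSE
```

Specimen biomass rises with age at collection and correlates negatively with
Shannon diversity — low-biomass libraries are background-dominated and
therefore artificially diverse. Beta diversity over the controls separates
biomass levels (`run$summary$diversity` reports pseudo-F = 31.1, p = 0.001
with 999 permutations), and the per-genus shift report
(`tidy(run$shifts)`) shows the NTConly subtraction removing genuine
colonizer genera (e.g. *Staphylococcus*) from more specimens than the
combined classifier, which spares them.

`autoplot()` methods draw ordinations (`pcoa()` results), before/after shift
panels (`shift_report`), and `plot_biomass_qc()` the biomass-vs-QC scatter.

## Command line

A thin CLI over the same functions ships in `inst/scripts/lbqc.R`:

```sh
Rscript inst/scripts/lbqc.R simulate --seed 1 --out sim/
Rscript inst/scripts/lbqc.R qc --counts sim/counts.tsv --metadata sim/metadata.tsv --out qc/
Rscript inst/scripts/lbqc.R decontam --counts ... --metadata ... --method combined --out dc/
Rscript inst/scripts/lbqc.R run --config run.yaml --out out/
```

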