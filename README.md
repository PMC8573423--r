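# paraplank

Parasites are a large but routinely overlooked fraction of freshwater
plankton communities: many are microscopic, cryptic, or known only from
environmental sequences, so they rarely appear in survey checklists even
though they shape food webs and nutrient fluxes. `paraplank` implements a
reproducible workflow for finding them in 18S rRNA metabarcoding
time-series and quantifying their seasonal dynamics:

1. **Rule-based parasite classification.** Each amplicon sequence variant
   (ASV) from a preselected set of parasite-containing higher taxa is
   linked to a host through two offline evidence routes: a *literature
   registry* (species binomial → host, trophic status, citation) and the
   *metadata of its sequence-similarity hits* (an extended BLAST-tabular
   "hit store" carrying the `host`, `isolation_source` and `title` fields
   of each subject record). Hits are admitted at ≥ 90 % identity, ranked
   by bit score, and scanned top-10-first-hit-wins. Provenance of every
   call (`literature`, `ncbi`, `both`) is recorded.
2. **Community statistics, from first principles.** Relative read
   abundance and richness per sample; sequential (Type I) two-way ANOVA
   (season → year → interaction) with Tukey–Kramer HSD and compact letter
   displays; Baselga's partition of Sorensen dissimilarity into turnover
   and nestedness, β<sub>SOR</sub> = β<sub>SIM</sub> + β<sub>NES</sub>,
   both pairwise and multi-site, with per-year 30-sample × 100-repetition
   resampling; PERMANOVA (pseudo-F on the Gower-centred distance matrix,
   free permutations, exact enumeration for small n) with Bonferroni
   pairwise comparisons; NMDS by iterative majorization with isotonic
   regression (Kruskal stress-1); and SIMPER decomposition of
   between-group Bray–Curtis dissimilarity.
3. **A synthetic-data generator with exported ground truth** (weekly
   multi-year calendar, negative-binomial counts with seasonal uplifts,
   planted host metadata at configurable completeness and hit rank,
   negative controls), so the whole pipeline is testable without any
   network access.

The central container is `AsvExperiment` (a `SummarizedExperiment`:
ASVs × samples counts, PR2-style taxonomy in `rowData`, sampling dates
and derived season/year factors in `colData`).

## Worked example

```r
library(paraplank)

sim   <- simulateParasiteDataset(simulationConfig(seed = 42))
sim$experiment
#> AsvExperiment: 300 ASVs x 107 samples (3 controls)
#>   dates 2015-01-05 .. 2016-12-26; years 2015, 2016
#>   total reads: 1,021,022

calls <- classifyParasites(sim$experiment, registry = sim$registry,
                           hits = sim$hits)
calls
#> ParasiteCalls over 300 ASVs
#>   parasitic: 50 (16.7%) [literature 17 | ncbi 28 | both 5]
#>   non-parasitic: 100; excluded by preselection: 150

x   <- relativeAbundance(dropSingletons(sim$experiment))
sm  <- sampleSummaries(x, calls)
fit <- twoWayAnova(sm$rel_abundance, sm$season, sm$year)
fit
#> Two-way ANOVA (sequential SS: season, year, season:year)
#>         term df     sumsq    meansq statistic   p.value signif
#>       season  3 0.0197884 0.0065961   14.1088 1.083e-07    ***
#>         year  1 0.0020588 0.0020588    4.4036 3.849e-02      *
#>  season:year  3 0.0008903 0.0002968    0.6348 5.944e-01
#>    Residuals 96 0.0448817 0.0004675        NA        NA

tukeyHsd(fit$data$y, fit$data$season,
         df_resid = fit$df_resid, ms_resid = fit$ms_resid)$letters
#> spring summer autumn winter
#>   "bc"    "a"   "ac"    "b"
```

The classifier recovers all 50 planted parasites with their evidence
routes; parasite share of reads varies significantly with season
(summer-peaking, per the planted 5× uplift of the summer-peaking
groups), and the letter display separates summer from spring and winter
while autumn is intermediate in this replicate. `runPipeline()` chains
every stage and writes the full TSV bundle (annotations, tallies,
summaries, ANOVA/Tukey, resampled β partition, PERMANOVA + pairwise,
NMDS, SIMPER) plus a JSON manifest.

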