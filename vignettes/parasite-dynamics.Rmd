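---
title: "Identifying planktonic parasites and their seasonal dynamics with paraplank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying planktonic parasites and their seasonal dynamics with paraplank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Metabarcoding of the 18S rRNA V4 region profiles entire eukaryotic
plankton communities, but tells you nothing about trophic roles: an
amplicon sequence variant (ASV) assigned to a chytrid genus may be a
parasite of diatoms or a saprotroph. Classifying ASVs as parasitic from
taxonomy alone (e.g. "all Chytridiomycota are parasites") is known to
over-call. `paraplank` instead requires *host evidence* for every single
ASV, drawn from two offline sources, and then quantifies how the
resulting parasite community changes across seasons and years in a
multi-year weekly time-series.

# The classification protocol

Classification is a deterministic rule engine over three inputs: a
ranked taxonomy (PR2-style, kingdom → species), a *literature registry*,
and a *hit store*.

**Preselection.** Only ASVs whose taxonomy at a configurable rank
(default: division) falls in a list of higher taxa with known parasitic
members are examined at all; everything else is
`excluded_by_preselection` and never reaches the hit store. The default
list ships 18 parasite-containing phyla/clades (chytrids, oomycetes,
dinoflagellates, Perkinsozoa, Microsporidia, and other canonical
parasite-rich lineages). This list is a package convention — the
published protocols this mirrors never enumerate their lists fully — and
is fully user-configurable via `preselectionList()`.

**Species route.** An ASV assigned to species level is looked up in the
registry by its binomial (case-insensitive). A registry entry with
`is_parasite = TRUE` is literature evidence; the ASV's own hits are
*also* scanned (below), and provenance is recorded as `literature`,
`ncbi`, or `both`. The registry is a plain TSV (species, hosts,
host_group, is_parasite, citation) standing in for manual literature
searches, which cannot be automated reproducibly; a starter registry is
packaged under `inst/extdata/` and is meant to be extended.

**Metadata route.** For genus-or-higher ASVs (and as the second arm of
the species route), the ASV's hits are filtered to percent identity
≥ 90, ranked by bit score (ties: ascending E-value, then accession —
a total order, so hit-store row order can never matter), truncated to
the top 10, and scanned in order; the first hit whose metadata yields
host information decides, and later hits are never read. If none of the
top 10 qualifies, the ASV is non-parasitic — absence of evidence is
deliberately treated as absence, making the classifier conservative.

**What counts as host information** is explicit configuration, not
judgement: a non-empty `host` qualifier always qualifies
(semicolon-split into names); otherwise `isolation_source` is matched
against capture-group regular expressions ("gut content of X",
"isolated from X", ...), then `title`/`note` against a second pattern
set ("parasite of X", "infecting X", ...). A phylogenetic-placement
title yields nothing. The defaults live in
`inst/extdata/host_rules.yaml`; real record metadata is messy free
text, and any fixed lexicon will miss paraphrases — this is a stated
limitation, and the reason the completeness of metadata is a first-class
parameter of the synthetic generator.

Recorded host names are bucketed into host taxon groups (phytoplankton,
zooplankton, amphibians, fish, ...) by an ordered first-match-wins
pattern table; the literal `"Various"` survives from registry entries
for taxa with broad host ranges. Unmatched names fall to `"other"`.

Two tuning parameters matter: `max_rank` (default 10 hits) and
`min_identity` (default 90 %). The identity filter is applied *before*
ranking and truncation, reading the threshold as an admission criterion
for candidate matches; whether it also gates the species route is not
fixed by the protocols this mirrors, and here it does (one uniform hit
filter). Both choices make the classifier monotone: narrowing the window
or raising the threshold can only turn parasitic calls non-parasitic,
never the reverse — properties the test suite checks.

# Abundance metrics

ASVs present in fewer than two samples are removed *before*
classification (this ordering fixes the denominator of the "percent
parasitic" figure; all-zero columns are removed by the same rule, since
degenerate columns break distance computations downstream). Counts are
converted to proportions of each sample's total over *all* ASVs,
parasites and non-parasites alike; the per-sample parasite relative read
abundance is the sum of parasite proportions, and parasite richness the
number of parasite ASVs with at least one read. The denominator is the
post-filter table — whether reads of dropped singletons should count is
not decidable from the protocols this mirrors, and the post-filter
choice keeps every metric a function of one table. Negative controls
are reported (reads, ASVs, per-group breakdown, and any control ASV
classified parasitic), never subtracted: no decontamination model is
implied.

# Season, year, ANOVA, Tukey

Seasons are meteorological: spring = March–May, summer = June–August,
autumn = September–November, winter = December–February. December
belongs to the winter of its *own calendar year*, and `year` is always
the calendar year — the simplest reading when season and year enter a
crossed model, at the cost of splitting one meteorological winter across
two year levels.

The two-way ANOVA uses sequential (Type I) sums of squares in the fixed
order season → year → season×year, computed by nested least-squares
projections. Weekly series are unbalanced across years, so the SS type
matters and is pinned down; Type I in this order is the convention of
the standard ANOVA implementation in R. Metrics enter untransformed.
Empty cells drop the interaction with a warning; a constant response is
an error. Post-hoc comparisons use Tukey–Kramer standard errors
(unequal group sizes), the studentized-range distribution with the
residual df of the supplied model, and the insert-and-absorb compact
letter display at α = 0.05: two levels share a letter exactly when
their adjusted p ≥ α. Weekly samples are treated as independent
replicates; no temporal autocorrelation correction is attempted
(a known limitation, shared with the design this reproduces).

# β diversity

Presence for incidence-based β is count ≥ 1 on reads (not relative
abundance). The pairwise Baselga partition uses the incidence components
a, b, c:

β_sim = min(b,c) / (a + min(b,c)),  β_sor = (b+c) / (2a+b+c),
β_nes = β_sor − β_sim.

The multi-site generalization sums min(b_ij, b_ji) and max(b_ij, b_ji)
over site pairs with K = ΣS_i − S_T. When one of two sets is empty the
turnover component is defined as 0 (all dissimilarity is nestedness).
Because unequal yearly sample numbers bias multi-site indices, the
per-year partition is computed on 30 samples drawn without replacement
and resampled 100 times (both configurable), fully reproducible from the
seed. Note one subtlety the test suite documents: even under *pure*
replacement (disjoint per-season blocks), unequal block sizes leave a
small multi-site nestedness residue (~0.02); "turnover dominates" is the
correct reading, not "β_nes exactly 0".

PERMANOVA partitions the Gower-centred inner-product matrix
G = −½ J D² J by the same sequential term order; SS of a term is
tr((H_k − H_{k−1})G), pseudo-F is the ratio of term to residual mean
squares, and p = (1 + #{F* ≥ F}) / (1 + n_perm) under free permutation
of sample labels (999 by default — the count is a convention, as the
protocols this mirrors leave it unstated). For n ≤ 8, `exact = TRUE`
enumerates all n! permutations and the p-value is exact. Pairwise
comparisons run one PERMANOVA per level pair with Bonferroni adjustment
(the default of the common pairwise helper). Bray–Curtis is computed on
relative abundances, matching the conversion step that precedes all
community analyses.

NMDS minimizes Kruskal stress-1 by alternating isotonic regression of
configuration distances on the dissimilarity order (primary tie
treatment: ties may reorder to reduce stress) with Guttman-transform
updates. Each fit takes the best of one metric-scaling start
(`cmdscale`) plus 10 random starts; within a run the stress sequence is
non-increasing by construction (the iteration stops rather than accept a
worse configuration), and the final configuration is centred and rotated
to principal axes. Convergence tolerance is 1e-7 on the stress
improvement, 300 iterations maximum; non-convergence returns the best
configuration found, flagged.

SIMPER decomposes the average between-group Bray–Curtis dissimilarity:
the contribution of ASV i to pair (j,k) is |x_ij − x_ik| / Σ_m(x_mj +
x_mk), which sums over i to exactly the pair's Bray–Curtis value; pair
contributions are averaged over all between-group pairs and reported as
percentages in descending order. Degenerate pairs with zero total are
skipped with a warning.

# The synthetic generator

`simulateParasiteDataset()` emulates the study design the package
targets: weekly Monday sampling over `n_years` (optionally biweekly in
the first January–February), 50 parasite + 250 non-parasite ASVs by
default (about one tenth of the real study's scale; a
`paperScaleConfig()` preset gives 441 + 2622 ASVs, 5 years, 232
samples), negative-binomial read counts (size = 2 — overdispersed, as
amplicon counts are, but not so noisy that two years of weekly samples
cannot resolve a five-fold seasonal signal), per-ASV base means drawn
log-normally (median 20 reads), and three negative-control samples
carrying trace reads of non-parasite ASVs only.

Seasonal structure: summer-peaking groups (Dinoflagellata, Perkinsozoa
by default) get a 5× mean multiplier in summer and 2× in the adjacent
seasons. The shoulder makes the seasonal cycle smooth, so the opposite
season (winter) is the most dissimilar from summer — the qualitative
pattern of temperate lakes. Per-group parasite richness follows the
configured weights deterministically (largest-remainder rounding), so
every replicate has the same community profile and replicate variance
reflects counting noise only.

Ground truth exports, per ASV: parasite status, evidence route, host,
taxon group, seasonal multiplier, and base mean. The hit store is built
so the classifier can be scored against truth: decoy hits carry
phylogeny-style titles with no host; each metadata-route parasite gets
host text planted in exactly one hit, at a rank drawn from `rank_law`
(defaults concentrated at rank 1), with probability `completeness`; all
planting decisions are drawn up front so that, at a fixed seed, the
planted set at lower completeness is a subset of the set at higher
completeness — recall is then monotone in completeness by construction,
not just in expectation. Some non-parasite queries get a *trap* hit
below the 90 % identity threshold that does carry a host, exercising the
admission filter. Two alternative scenarios reshape the parasite block
for β-diversity testing: `"turnover"` (disjoint per-season blocks,
presence guaranteed by a +1 offset) and `"nestedness"` (season
communities nested by tier, which forces the multi-site turnover
component to exactly zero).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequence-level artefacts (chimeras, primer
bias), taxonomic mis-assignment, free-text metadata paraphrases outside
the configured lexicon, host names absent from the grouping patterns,
temporal autocorrelation of abundances, and the year-to-year trend
structure of a real lake. Classifier recall of 1.0 at completeness 1 is
a statement about the engine's correctness, not about NCBI metadata
coverage.

# Numerical and design choices

* Counts are validated as non-negative integers; zero-read samples get
  all-zero relative-abundance rows plus a warning.
* Hit ranking is a total order (bit score, E-value, accession), so all
  results are invariant to input row order.
* The β identity β_nes = β_sor − β_sim holds to 1e-12 by construction
  and is asserted, with bounds, across random incidence data.
* PERMANOVA permutes the centred matrix by index (G[p, p]), which is
  equivalent to relabelling samples; degenerate zero-SS inputs are
  reported as such rather than producing NaN statistics.
* All pipeline randomness derives from one master seed via per-stage
  sub-seeds (below 2^31), recorded in the run manifest; the same inputs
  and seed give byte-identical output files.
* Test problem sizes: the unit suite runs the default 2-year generator
  config (104 samples, 300 ASVs) and smaller toys; calibration checks
  use 1000 null replicates for ANOVA, 1000 datasets × 99 permutations
  for PERMANOVA, and 100 generator replicates for seasonal power —
  sizes at which Monte-Carlo error is well below the asserted bands.

# Known limitations

The host-keyword lexicon is a convention, and recall on real records is
bounded by metadata completeness; the literature registry must be
curated by the user for new systems; ANOVA assumes independent Gaussian
errors on proportions (no transformation, no GLM); weekly samples are
treated as exchangeable within season × year; PERMANOVA is sensitive to
dispersion differences between groups (no PERMDISP is provided); NMDS is
restricted to 2-D by default and, like all NMDS, finds local optima —
restarts mitigate but do not eliminate this.
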