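---
title: "Modelling the durability of Bt + RNAi pyramided cotton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the durability of Bt + RNAi pyramided cotton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btrnai)
library(dplyr)
```

## The problem

Transgenic cotton expressing a *Bacillus thuringiensis* (Bt) toxin controls
*Helicoverpa armigera* effectively, but field-evolved resistance erodes that
control within years. One countermeasure is to "pyramid" a second,
mechanistically independent protective trait in the same plant — here, a
hairpin dsRNA that silences a gene in juvenile-hormone signalling (JH acid
methyltransferase or JH-binding protein) after ingestion. `btrnai` provides
the quantitative toolkit for evaluating such pyramids:

* a deterministic two-locus population-genetic simulator that projects how
  many years each deployment strategy (Bt alone, RNAi alone, a sequence of
  the two, or the pyramid) withstands resistance evolution under different
  refuge sizes;
* the leaf-bioassay statistics that parameterize the simulator: survival and
  mortality, transgene efficacy, the index of multiplicative survival (IMS)
  with its one-sample test, one-way ANOVA with Tukey HSD letters, strain
  t-tests, two-way ANOVA and qPCR relative quantification;
* an exact-match k-mer screen that checks a dsRNA trigger fragment for shared
  21-nt stretches with non-target transcripts;
* a synthetic-data generator that emulates the full bioassay design so every
  stage is testable end to end without external data.

## The selection model

Resistance to each cotton trait is governed by one autosomal locus with a
resistance allele *r* and a susceptibility allele *s*; the two loci are
unlinked (supported empirically by the absence of cross-resistance between Bt
and RNAi cotton). The population is censused as frequencies of the four
gamete types (r1r2, r1s2, s1r2, s1s2). Each generation:

1. random union of gametes forms the nine newborn genotypes;
2. each genotype's realized fitness is the habitat-weighted average
   $w = \phi \, w_\text{refuge} + (1-\phi)\, w_\text{transgenic}$,
   where $\phi$ is the refuge fraction — larvae encounter habitats in
   proportion to area, and refuges of non-transgenic hosts harbour
   susceptible survivors;
3. selection reweighs the genotype frequencies, and the surviving adults
   emit the next gamete pool with recombination fraction 0.5 between the
   unlinked loci.

There is no mutation, migration, drift or density dependence: trajectories
are deterministic and bit-for-bit reproducible. Heterozygote fitness on a
trait plant is the dominance interpolation
$w_{rs} = w_{ss} + h\,(w_{rr} - w_{ss})$, with $h = 0$ fully recessive and
$h = 1$ fully dominant resistance. On the pyramid the default nine-genotype
fitness surface is the per-genotype *product* of the two single-trait
fitnesses — independent action, which the bioassay IMS result supports. A
single-coefficient alternative (`hp`) is available for sensitivity analyses
in which pyramid resistance has its own dominance.

Fitness costs of resistance act on refuge plants only: in additive mode a
genotype carrying $k$ resistance alleles has refuge fitness
$\max(0, 1 - k c)$, so with $c = 0.05$ the doubly resistant homozygote sits
at 0.80.

**Time to resistance.** After each generation the population's fitness on
the deployed transgenic cotton is computed on that generation's newborns
(the genotype-frequency-weighted mean of the nine transgenic-cotton fitness
values); resistance is declared when it reaches 0.50. The newborn census
makes a population that starts fully resistant register resistance in year
one, the only self-consistent reading. With three cotton generations per
year — the *H. armigera* phenology in northern China — years are reported
fractionally as generation/3; strategy contrasts of a single generation then
appear as ±0.33 years, matching how durability differences at small refuges
behave. A sequential release is scored as the sum of the Bt-alone and
RNAi-alone times, each from its own initial allele frequency.

## Parameters and presets

| Parameter | Default | Meaning |
|---|---|---|
| `bt_init_r_freq` | 0.05 | initial Bt-resistance allele frequency (reflects years of Bt exposure) |
| `rnai_init_r_freq` | 0.001 | standard estimate for an unexposed control method (0.01 pessimistic) |
| `h` | 0.5 (0.2 RNAi optimistic) | dominance of resistance |
| `bt_w_ss` | 0.206 | susceptible fitness on Bt cotton, = 1 − 0.794 efficacy |
| `rnai_w_ss` | 0.34 | susceptible fitness on RNAi cotton, = 1 − 0.66 efficacy |
| `cost_per_r_allele` | 0 (0.05 optimistic) | refuge fitness decrement per r allele |
| `generations_per_year` | 3 | cotton-feeding generations per year |
| `resistance_threshold` | 0.50 | population fitness on the transgenic cotton |

The three presets bundle these: *realistic* ($h=0.5$ both loci, no cost),
*optimistic* ($h=0.2$ for RNAi, additive cost 0.05), *pessimistic*
(realistic with RNAi initial frequency 0.01). Trait-plant fitnesses default
to values derived from the printed bioassay efficacies and live in an
editable YAML file (`inst/extdata/default_params.yaml`), so fitness tables
transcribed from other sources can be dropped in verbatim. Because the
defaults are efficacy-derived rather than a full genotype-fitness table, the
absolute years the presets produce are indicative; the *orderings* — pyramid
≥ sequence ≥ Bt alone at large refuges, vanishing pyramid advantage at small
refuges, strong sensitivity to RNAi dominance and initial frequency — are
robust across the three presets and are what the test suite pins down.

```{r presets}
sw <- refuge_sweep(scenario_presets(), refuges = c(0.05, 0.10, 0.25, 0.50))
sweep_deltas(sw) |> filter(refuge == 0.50)
```

## Bioassay statistics

Survival is the proportion of larvae that became normal pupae (malformed
pupae count as dead because they never eclose); mortality is its complement
in percent. Efficacy of a transgenic cotton against a strain is
$100\,(1 - S_T/S_C)$ with $S_C$ the survival on the untransformed control —
negative values are reported, not clipped.

The **IMS** asks whether two traits in a pyramid act independently: the
observed pyramid survival is divided by the product of the single-trait
survivals. Survivals are first adjusted by the control survival of the same
strain, year and replicate, so the index isolates transgene effects; the
replicate is the pairing unit. Replicate IMS values from both pyramids are
pooled into one one-sample t-test against 1 (df = 5 with two pyramids of
three replicates). Replicates whose expected survival is zero have no
defined IMS and are excluded with a warning. Note a small-sample caveat the
package makes no attempt to hide: replicate IMS is a ratio of small binomial
counts and is right-skewed, so the t-test runs slightly hot (attained
type-I level around 0.06–0.07 at nominal 0.05 with three replicates of 50
larvae) — adequate for its screening purpose, but not an exact test.

Group comparisons use `stats::aov` with Tukey HSD; the compact letter
display is assigned greedily from the largest mean downwards, each group
joining every letter class whose members it does not differ from at the
chosen level (ties keep input order). With two groups the Tukey p-value
collapses to the pooled-variance t-test, which the suite verifies. Strain
contrasts default to Welch's t-test — robust with n = 3 replicates — with
the pooled-variance variant available. Effects whose sum of squares is
numerically zero are reported as F = 0, p = 1 rather than 0/0.

qPCR relative expression implements $2^{-\Delta C_T}$ against a reference
gene and $2^{-\Delta\Delta C_T}$ against a calibrator sample.

## The k-mer specificity screen

Silencing through perfectly matched siRNAs requires a shared exact stretch
of (canonically) 21 nt, so the screen reports every *maximal* shared exact
substring of length ≥ k between the trigger fragment and each transcript,
on both strands — dsRNA is double-stranded, so both orientations are active.
Maximal runs keep reports compact without losing information: a run of
length $L$ contains exactly $L - k + 1$ matching k-windows, an identity the
tests enforce. Windows containing N never match (conservative for a
specificity claim). Coordinates are 0-based half-open; minus-strand subject
positions are on the subject's reverse complement. The matcher hashes
subject k-mers and merges diagonal runs; a naive character-by-character
oracle checks it exhaustively on small sequences in the test suite. A panel
is "clean" only when no transcript shares any window — the criterion a
trigger fragment must meet against non-target species.

## The synthetic generator

The generator emulates the study design — susceptible (SCD) and
Bt-resistant (SCD-r1) strains on seven cotton types (W0, GFP, Bt, JHA, JHB,
Bt+JHA, Bt+JHB), two years, three replicates of 50 larvae. Survivor counts
are binomial per replicate; the default survival map reproduces the
qualitative bioassay structure (controls ≈ 0.8 survival; Bt suppressing only
the susceptible strain; RNAi suppressing both strains equally; pyramid cells
the product of the single-trait effects, i.e. independence true by
construction). Development times are truncated-normal within the 14–30 day
recording window — the published data report only means, SEs and the window,
so the shape is a modelling choice; its truncation bounds are exact by
inverse-CDF sampling. qPCR tables place the target Ct at
$-\log_2(\text{fold})$ cycles from the reference with independent noise on
each Ct, so configured folds are recovered exactly at zero noise. Transcript
panels plant copied blocks of the fragment with guard bases at both
junctions, making the manifest the exact ground truth for the screen; at
these sequence lengths a chance 21-mer collision has probability ~10⁻⁷.

One integer seed drives everything via fixed per-stream sub-seeds, so any
module can be exercised independently but reproducibly, and identical seeds
give byte-identical output files.

What passing on synthetic data does *not* show: binomial survivor counts
have no overdispersion between replicates (real leaf bioassays do, from
leaf-to-leaf variation), development-time distributions are symmetric within
the window, and the independence-true pyramid cells build in exactly the
hypothesis the IMS test probes. Conclusions about real cotton lines still
require real bioassays; the synthetic path validates the *machinery*.

## Numerical choices and edge cases

* Gamete frequencies are renormalized each generation; conservation is
  enforced to 1e−12 in tests.
* Zero mean fitness raises an explicit extinction error instead of
  propagating NaN.
* With exactly multiplicative two-locus fitness (refuge fraction 0) the
  recursion preserves linkage equilibrium to machine precision and its
  marginals equal the single-locus recursion; with habitat mixing the
  habitat average breaks multiplicativity and small linkage disequilibrium
  legitimately develops.
* The resistance threshold comparison is `>=`, so a population exactly at
  0.50 counts as resistant.
* Problem sizes in the test suite are chosen to keep the whole run at a few
  minutes: 12 property draws of 5 generations against the 81-pair
  enumeration oracle, 200 synthetic datasets for parameter-recovery
  coverage, 1000 for the IMS type-I check, and k-mer oracle comparisons on
  ≤ 200-nt sequences.

## Known limitations

* Deterministic, panmictic, infinite population: no drift, no spatial
  structure, no larval movement between plants, no non-cotton generations.
* The bundled trait-plant fitnesses are derived from printed efficacies, not
  from a full genotype-fitness table; absolute durability projections
  depend on that table and should be re-run with measured values
  (`scenario_presets(params = ...)`).
* The sequence strategy is scored as the simple sum of its phases; any
  RNAi-locus evolution during the Bt phase (e.g. through refuge fitness
  costs) is deliberately not carried over.
* The k-mer screen is exact-match only — by design it does not model
  mismatch-tolerant seed-region silencing.
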