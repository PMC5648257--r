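---
title: "Modelling resistance evolution against a homing gene drive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling resistance evolution against a homing gene drive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdresist)
```

## The system

A CRISPR-Cas9 homing gene drive inserted into a haplosufficient female-
fertility gene biases its own inheritance: in germ cells of heterozygotes
the nuclease cleaves the homologous wild-type target and homology-directed
repair copies the drive across, so heterozygous parents transmit the
construct to far more than the Mendelian half of their offspring. Because
the disrupted gene is required for female fertility, the drive imposes a
reproductive load as it spreads — and thereby selects for target-site
mutations that the nuclease can no longer cleave. End-joining repair of
cleaved targets creates exactly such mutations: small indels at the cut
site, some of which shift the reading frame (non-functional) and some of
which preserve it and restore gene function.

`gdresist` implements the computational core needed to study this dynamic:

* a deterministic four-allele population-genetic recursion (`drive_model`),
* estimators linking single-generation cross data and cage trajectories to
  the model's rates (`inference`),
* an amplicon-sequencing pipeline that turns pooled reads over the target
  site into allele, SNV, haplotype and mutation-profile tables,
* a microhomology-mediated end-joining (MMEJ) deletion predictor, and
* a fully seeded synthetic-data generator that emulates the pooled
  amplicon assay with known truth, so the whole pipeline is testable
  without any external data.

## The population model

Four alleles segregate at the target locus: wild type `W` (cleavable), the
drive `H`, and cleavage-resistant alleles `R1` (in-frame, functional) and
`R2` (frameshift, non-functional). The ten unordered diploid genotypes are
tracked as sex-specific frequency vectors over discrete, non-overlapping
generations.

**Germline homing.** Gametes of `W/H` individuals (either sex) are
distorted:
$$P(H) = \tfrac{1+e}{2},\qquad P(W) = \tfrac{1-e-\gamma_m}{2},\qquad
  P(R1) = \tfrac{\xi_m\gamma_m}{2},\qquad P(R2) = \tfrac{(1-\xi_m)\gamma_m}{2},$$
where $e$ is the homing rate and $\gamma_m$ the meiotic end-joining rate.
All other genotypes segregate Mendelian — `R1` and `R2` are not cleaved,
so no further distortion arises.

**Embryonic end-joining.** Eggs of drive-carrying mothers contain
maternally deposited nuclease regardless of the egg's own genotype. Each
`W` allele of the zygote is therefore independently converted to `R1` with
probability $\xi_e\gamma_e$, to `R2` with $(1-\xi_e)\gamma_e$, to a copy
of the homologous allele with $\beta$ (embryonic homology-directed repair,
"embryonic homing"), and is left intact otherwise. This happens at
fertilisation, before the individual's own germline acts, which is why a
maternally transmitted drive shows much weaker apparent homing: the
cleavable targets in its carriers were already destroyed as embryos.

**Selection.** The target gene is needed in the female soma. Females with
no functional copy — `H/H`, `H/R2`, `R2/R2` — are sterile; these
sterilities are structural features of the genotype-to-phenotype map, not
tunable parameters. `W/H` females additionally suffer leaky somatic
nuclease expression and retain only $1-d$ of wild-type fecundity, $d$
being the dominance of the fertility cost. `H/R1` and `R1/R1` females are
fully fertile: `R1` restores function. Males are unaffected.

One generation multiplies female frequencies by fecundity, draws maternal
and paternal gametes, applies the embryonic step to offspring of
drive-carrying mothers, and assigns the same offspring distribution to
both sexes. If every remaining female genotype is sterile the recursion
signals an explicit `gd_extinction` condition instead of renormalising a
zero vector.

```{r}
params <- model_params()
params
traj <- simulate_drive(params, n_generations = 25)
head(summarize_trajectory(traj), 4)
```

### Parameters, defaults, and why

| symbol | argument | default | meaning |
|---|---|---|---|
| $e$ | `e` | 0.984 | meiotic homing rate in `W/H` germlines |
| $\gamma_m$ | `gamma_m` | 0.01 | meiotic end-joining rate |
| $\gamma_e$ | `gamma_e` | 0.796 | embryonic end-joining rate (maternal nuclease) |
| $\beta$ | `beta` | 0 | embryonic HDR rate |
| $\xi_m,\xi_e$ | `xi_m`, `xi_e` | 1/3 | fraction of end-joining products that are in-frame functional (`R1`) |
| $d$ | `d` | 0.907 | dominance of the `W/H` female fertility cost |

The rate defaults are the experimental estimates from the caged-population
study of this drive (single-generation crosses for $e$, $\gamma_m$,
$\gamma_e$, $d$). Two defaults were genuinely open design choices:

* **$\xi_m = \xi_e = 1/3$.** The split of end-joining products between
  in-frame and frameshift alleles is not identifiable from the headline
  rates. If indel lengths fall uniformly across residue classes modulo 3,
  one third of products preserve frame, and we adopt that as the single
  shared default. The late-generation composition of non-drive alleles is
  quite sensitive to this choice (the wild-type share at generation 12
  moves by roughly 3 percentage points as $\xi$ moves from 1/4 to 0.4),
  so analyses that depend on it should set $\xi$ from their own data; both
  parameters are exposed independently.
* **$\beta = 0$.** Embryonic HDR has little effect when meiotic homing is
  already near-complete; it is retained as a parameter for sensitivity
  analysis of resistant-allele homozygosis.

The default initial state is the cage release: 50% `W/H` heterozygotes and
50% wild type in both sexes (`initial_release_state()`).

### Numerical behaviour and limits

Frequency vectors are renormalised every generation and conserve mass to
1e-12. With $e=\gamma_m=\gamma_e=\beta=0$ and $d=0$ the recursion reduces
to random mating; because the `H/H`, `H/R2` and `R2/R2` female sterilities
are structural, the Hardy–Weinberg/Mendelian limit (constant allele
frequencies, equilibrium genotype frequencies after one round) applies on
the fully fertile drive-free subspace spanned by `W` and `R1`, and that is
how the package's tests state it. With equal initial male and female
vectors the two sexes remain identical forever — fertility selection
re-weights mothers but offspring are assigned to sexes symmetrically — so
the recursion is effectively one-vector; the two-sex interface is kept
because sex-specific initial conditions are legitimate inputs.

The test suite validates one deterministic generation against an
independent individual-based Monte-Carlo simulation of $10^6$ mosquitoes
(five parameter sets, every genotype class within three binomial standard
errors), which exercises the gamete, embryo and selection steps through a
completely separate code path.

## Estimators

`estimate_homing()` inverts the transmission map $t = (1+e)/2$.
`estimate_embryonic_ej()` compares apparent homing under maternal versus
paternal drive origin:
$$\hat\gamma_e \;=\; 1 - \frac{2t_{maternal}-1}{2t_{paternal}-1},$$
i.e. the fraction of cleavable alleles already lost to embryonic
end-joining before the carrier's germline could home. This odds-of-homing
form is scale-free in the homing signal and reproduces the published rate
from the published transmission proportions to within input rounding; when
per-lineage counts are available, `estimate_rates()` pools them (totals,
not lineage means) before estimating.

`fit_dominance()` profiles the sum of squared differences between observed
and predicted drive-carrier fractions over a grid of $d$ (default step
0.005 on [0, 1]), all other parameters fixed. A grid search is the honest
tool here: the objective is one-dimensional, cheap, and reported to two
decimals; ties break toward smaller $d$ and boundary minima are flagged as
poorly identified. Multiple cages are fitted jointly against the single
deterministic trajectory. Unweighted least squares is used; no binomial
weighting is applied.

```{r}
run_recipe("embryonic-ej", list(transmission_maternal = 0.596,
                                transmission_paternal = 0.975))$results$gamma_e_hat
```

## The amplicon pipeline

The assay amplifies a ~320-bp window around the cut site from pooled DNA
under non-saturating PCR, so read counts are proportional to allele
abundance; the drive cassette is far too long to amplify, so every
frequency is within the class of non-drive alleles. The pipeline stages
and their conventions:

1. **Merging** (`merge_read_pairs`): mate 2 is reverse-complemented and
   the best ungapped overlap (score = matches − 4·mismatches, minimum
   length 20, mismatch fraction ≤ 0.1) reconstructs the fragment;
   disagreements go to the higher base quality, ties to mate 1. Failures
   are counted, not silently dropped.
2. **Collapsing** (`collapse_reads`): exact-match collapse; only unique
   sequences with ≥ 100 reads (inclusive) enter the analysis set. At a
   depth of 50,000 reads and a 0.1% per-base substitution error this
   filter implies a detection floor of roughly 0.3% allele frequency
   (erroneous copies of an allele scatter into unique sequences and are
   discarded); validation datasets are therefore built so that allele
   masses of interest sit above the floor.
3. **Alignment** (`align_to_reference`): Needleman–Wunsch global alignment
   with match +2, mismatch −4 and affine gap cost 10 + L. The scheme
   deliberately concentrates edits into one contiguous indel, matching the
   single-junction structure of end-joining products. Sequences whose
   length is outside 0.5–1.5× the reference are set aside as off-target.
4. **Indel calling** (`call_indels`): indels are left-normalised within
   repeat runs before labelling, fixing the placement ambiguity inherent
   to repeats (e.g. a 6-bp deletion inside a `GAGGAG` run); labels use the
   field notation `start-DELETEDBASES` / `position+INSERTEDBASES`. Only
   indels whose footprint lies within ±30 bp of the cut are reported
   (distal artifacts are ignored); a read with several window indels is
   `complex`, and with more than two is excluded from allele tables but
   logged. Substitutions never create indel labels.
5. **Frame classification**: in-frame iff the net length change is a
   multiple of 3.
6. **Frequency tables** (`allele_frequency_table`): counts normalised
   within sample; alleles below the 1% threshold in *every* sample are
   grouped into one `<1%` row (per-sample grouping is available by flag).
7. **SNVs and haplotypes**: per-position alternative-base frequencies with
   an inclusive 2.5% threshold; reads carrying a focal allele are reduced
   to their base string at the SNP positions, giving the haplotype
   multiplicity of the allele and a novelty flag against a known colony
   pool — novel hybrid strings are the signature of embryonic homing.
8. **MMEJ prediction** (`enumerate_mmej`): all identical ≥2-bp arm pairs
   flanking the cut, deduplicated by resulting left-normalised deletion
   allele (longest arm kept), with deletion size capped at 50 bp by
   default.

## The synthetic generator

`generate_cage_dataset()` emulates the study design end to end: a random
320-bp reference with a planted protospacer/PAM and a planted 3-bp
microhomology pair (so MMEJ prediction is never vacuous), a colony pool of
12 SNP haplotypes with Dirichlet frequencies, a resistance spectrum
mixing MMEJ deletions (weighted toward longer microhomologies, capped at
the ±30 bp reporting window) with random geometric-length indels, class
frequencies taken from the deterministic trajectory (`W`/`R1`/`R2` shares
of non-drive alleles), multinomial read sampling over (allele, haplotype)
classes — the non-saturating-PCR proportionality assumption — and paired
2×250 reads with i.i.d. substitution errors at 0.001 per base.

What it deliberately does **not** emulate: indel sequencing errors (so
indel calls reflect planted biology only), quality-score structure (all
bases Q40), PCR chimeras and index hopping, stochastic genetic drift in
the cage itself (the trajectory is deterministic; read sampling is the
only stochastic layer). Consequently, passing round-trip tests demonstrate
that the pipeline recovers what the assay model contains — they do not
certify behaviour under structured errors or drift, and real-data use
should treat the 100-read filter and the ±1-point recovery claims as
conditional on comparable depth and error rates.

The generator is deterministic under its mandatory seed (R's integer-state
Mersenne-Twister; sub-steps use fixed seed offsets), and each sample's
truth tables trace every read to its (allele, haplotype) class.

```{r}
cfg <- generator_config(seed = 1, reads_per_sample = 2000, error_rate = 0,
                        generations = 6)
ds <- generate_cage_dataset(cfg)
head(ds$samples[[1]]$truth_alleles[order(-ds$samples[[1]]$truth_alleles$frequency), ], 5)
```

## Problem sizes used in validation

The shipped tests use: 50,000 read pairs per sampled generation at error
rate 0.001 for pipeline recovery (sampling generations whose allele masses
span ~0.4%–60%, above the filter's detection floor); $10^6$ individuals
per parameter set for the Monte-Carlo oracle; 100 random ≤60-nt sequences
for the exhaustive MMEJ cross-check; and 20 noisy replicates at the cage
census size (600 individuals/generation) for dominance recovery. These
sizes make the binomial standard errors small relative to every asserted
tolerance while keeping the full suite fast.

## Known limitations

* The recursion is deterministic and unstructured: no drift, density
  dependence, age structure or spatial structure. Stochasticity enters
  only through the synthetic assay layer and the test oracle.
* $\xi_m$ and $\xi_e$ default to the mod-3 argument, not to a measured
  split; late-generation allele compositions inherit that uncertainty.
* The aligner's single-indel preference can fold two nearby small indels
  into one complex call on adversarial inputs; such reads are labelled
  `complex` rather than force-fitted.
* Haplotype assignment requires SNPs outside the indel window; alleles
  whose deletions reach a SNP would shorten the haplotype string.
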