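---
title: "Quantifying adaptive substitutions lost to Hill-Robertson interference"
author: "hriquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adaptive substitutions lost to Hill-Robertson interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hriquant)
```

## The problem

Hill-Robertson interference (HRi) is the mutual reduction in the efficacy of
selection among linked selected sites: an advantageous mutation arising in a
region of low recombination may be trapped in linkage with deleterious
variants, or compete with another sweep it cannot recombine onto, and so be
lost where a freely recombining genome would have fixed it. `hriquant`
implements a pipeline for putting a number on that loss in a
*Drosophila*-like coding genome: the fraction

$$f_{HRi} = \frac{\text{adaptive substitutions lost to interference}}
                 {\text{adaptive substitutions expected under free recombination}}$$

estimated from the relationship between the adaptive nonsynonymous
substitution rate $K_{a+}$ and the local crossover rate.

The chain of reasoning is:

1. Classify coding sites *physically* into 0-fold degenerate (every change
   is an amino-acid change; the selected class) and 4-fold degenerate sites
   in exon core codons (every change is synonymous; the neutral reference),
   with positions 8-30 of short introns (<= 65 bp) as an alternative
   neutral class.
2. For each gene, compute the folded site frequency spectrum (SFS) of each
   class after downsampling every site to a common number of chromosomes,
   and divergence out to an outgroup sampled on a single chromosome,
   corrected for multiple hits (Jukes-Cantor at 0-fold sites; Tamura at
   4-fold sites, which allows unequal GC and a ts/tv bias).
3. Pool genes into equal-size bins of similar recombination rate and, per
   bin, estimate the fraction $\alpha$ of nonsynonymous substitutions that
   were adaptive with a McDonald-Kreitman derivative that corrects for
   segregating slightly deleterious mutations: a two-epoch demography is
   fitted to the neutral folded SFS, a gamma distribution of fitness
   effects (DFE) to the selected folded SFS, and the expected nonadaptive
   divergence is subtracted from the observed. Then
   $K_{a+} = \alpha K_a$.
4. Fit a LOESS curve to $K_{a+}$ against recombination rate; take the mean
   $K_{a+}$ of bins above a recombination threshold (2 cM/Mb by default) as
   the no-HRi rate $K_{a+,\mathrm{no\ HRi}}$; account the shortfall of the
   smoothed curve below the threshold, weighted by the 0-fold sites in each
   bin, as the loss.
5. Attach uncertainty by bootstrapping genes, and compare gene categories
   (gene-density halves crossed with mutation-rate halves) with paired
   bootstrap differences and permutation tests.

## The adaptation estimate

With $S = 4N_e s$ the scaled selection coefficient, a new semidominant
mutation fixes with probability $r(S) = S/(1 - e^{-S})$ relative to a
neutral one (`fixation_relative()`). If deleterious effects at 0-fold sites
follow a gamma DFE $f$ with mean $\gamma = -N_e s$ and shape $\beta$, the
expected nonadaptive nonsynonymous divergence is
$d_{exp} = K_4\, E_f[r(S)]$, and

$$\alpha = \frac{K_a - d_{exp}}{K_a}, \qquad
  K_{a+} = \alpha K_a, \qquad \omega_A = K_{a+}/K_4 .$$

$E_f[r(S)]$ is integrated over a fixed quadrature grid of 64 log-spaced
$|S|$ mass points in $[10^{-4}, 10^4]$ plus a point at 0 that absorbs the
effectively neutral mass; the grid is configurable
(`selection_grid()`). Because the correction factor multiplies $K_4$, the
estimate needs no assumption about absolute mutation rates, only that the
0-fold and 4-fold mutation rates are equal.

### Expected folded SFS

Likelihoods need the expected folded sample SFS under selection and a
two-epoch demography. `expected_folded_sfs()` iterates a discretised
Wright-Fisher mutation-inflow recursion on a fixed grid of $G$ alleles
(default 200): the first epoch is solved to equilibrium exactly,
$(I - A)^{-1}e_1$; the second epoch of relative size $r = N_2/N_1$ is
emulated on the same grid by diffusion rescaling - selection multiplied by
$r$, inflow by $r^2$, and $t_2 G/2$ grid generations for a change $t_2$
(in units of $N_2$ generations) ago. The grid spectrum is then sampled
binomially to the $n$ observed chromosomes and folded. Per-generation grid
selection is capped at $-0.98$; mutations more deleterious than the cap
are effectively absent from the spectrum either way, and their fixation
probability is essentially zero, so the cap does not move the estimates.
Transition matrices, equilibria and sampling matrices are memoised, which
is what makes per-bin refitting over 45 bins and bootstrap replicates
affordable.

Maximisation is by Nelder-Mead on log-parameters with five fixed starting
points and a $10^{-8}$ relative tolerance; the best of the restarts is
kept, so fits are deterministic given the data. Demography parameters can
trade off along a likelihood ridge on folded data - the identified object
is the expected spectrum, which is what the tests assert.

### Splitting $K_4$ by hypergeometric sampling

$K_{a+}$ is estimated *from* $K_4$, so correlating the two, or binning by
one and reading out the other, shares sampling error and biases
correlations negative. `split_k4()` divides each gene's 4-fold divergent
sites into 2 or 3 statistically independent parts by (multivariate)
hypergeometric draws over the $L_4$ sites - one part ranks genes into
bins, another estimates the rate, a third (when present) reads out the
mutation rate. The parts sum to $D_4$ exactly, for every gene and seed;
draw sizes use `round(0.33 L4)` (the rounding convention behind the
nearest-integer draw is immaterial because rates divide by the exact
share $L_4/3$).

## The loss accounting

With $L_{a}(i)$ the 0-fold sites of bin $i$ and $K_{a+}(i)'$ the LOESS
prediction at the bin's mean recombination rate:

$$\mathrm{Total}_{\mathrm{no\ HRi}} = \sum_{\text{all } i} L_a(i)\,
    K_{a+,\mathrm{no\ HRi}}, \qquad
  \mathrm{Total}_{\mathrm{lost}} = \sum_{i:\ rr_i < 2} L_a(i)\,
    (K_{a+,\mathrm{no\ HRi}} - K_{a+}(i)'),$$

and $f_{HRi}$ is their ratio. The first sum runs over all bins, the second
only over bins below the threshold. LOESS predictions can be negative in
the lowest bins; results are reported both raw and with negative
predictions clamped to zero (`estimate_fhri(clamp = )`), which bounds
$f_{HRi}$ into $[0, 1]$. The asymptote is the unweighted mean of eligible
bin estimates; site weighting enters through the $L_a(i)$ totals, as in
the equations above. For gene categories that show no asymptote by
2 cM/Mb, a 5 cM/Mb threshold gives a lower bound on the loss.

LOESS uses local quadratics with tricube weights and span 1 - every local
fit sees all bins, down-weighted by distance - which trades a little
smoothing bias for stability across bootstrap replicates
(`loess_predict()` evaluates the exact direct surface, and the test suite
pins it against an independently coded weighted least-squares fit).

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `n_chromosomes` | 128 | chromosomes every site is downsampled to |
| `core_margin_codons` | 8 | codons excluded at each exon boundary ("exon core") |
| short intron filter | <= 65 bp, pos 8-30 | alternative neutral class; >= 2 introns, < 10% gaps |
| `rr_threshold` | 2 cM/Mb | asymptote/loss threshold (5 for non-asymptoting categories) |
| `span` | 1.0 | LOESS span |
| `n_bins` | 45 | recombination bins (136 genes each at 6,141 genes) |
| `G` | 200 | Wright-Fisher grid alleles (>= `n_chromosomes`) |
| `selection_grid()` | 64 pts, $10^{-4}$-$10^4$ | DFE quadrature over $|4N_e s|$ |
| `B` | study-dependent | bootstrap/permutation replicates |

The exon-core margin is a convention rather than a published constant; 8
codons per boundary is the shipped default and it is configurable
everywhere it matters. Columns where the outgroup is gapped or uncalled
are excluded from every class, since divergence is undefined there.
Degeneracy is assessed on the ingroup majority codon; the requirement that
ingroup and outgroup encode the same amino acid applies only to the 4-fold
(synonymous-rate) class, so codons segregating for amino-acid changes keep
their 0-fold sites - the deliberately asymmetric filter avoids discarding
exactly the sites where adaptive change is visible.

## The synthetic genome generator

`simulate_genes()` produces gene-level data with the statistical structure
the analysis assumes, and a known truth for every recovery test. Counts
are simulated at the SFS level (Poisson random field): folded SFS entries
are Poisson around $L\,\theta$ times the model's expected spectrum - the
same Wright-Fisher machinery the fitter uses - integrated over the gamma
DFE for 0-fold sites; divergent-site counts are binomial with the
forward-mapped (multiple-hit) probability of the true per-site rate. The
true adaptive rate follows $K_{a+}(rr) = a + b e^{-c\,rr}$, multiplied by
the gene's mutation multiplier (adaptation is mutation-limited) and by a
configurable factor for flagged immune/testes genes. `true_fhri()` applies
the same loss accounting to the generating curve itself, giving the
estimand.

Default conditions emulate the study system: 6,120 autosomal genes sampled
at 128 chromosomes; 4-fold diversity $\theta_4 = 0.015$ per site with
log-normal per-gene mutation heterogeneity (sd 0.3 on the log scale); a
leptokurtic gamma DFE ($\beta = 0.35$, mean $-N_e s = 2000$); a two-fold
recent expansion ($t_2 = 0.1$); 4-fold divergence 0.18 per site; a
recombination mixture with a quarter of genes piled near 0 cM/Mb and the
rest spread over 0-10; and curve coefficients $(0.0126, -0.012, 2.1237)$ -
the genome-wide fitted asymptote and decay, with $b$ shrunk just enough to
keep the curve nonnegative at zero recombination, a constraint the
generating (as opposed to fitted) curve must satisfy. Divergence is drawn
with a uniform substitution pattern (transition share 1/3, GC 0.5), under
which the Tamura and Jukes-Cantor corrections coincide exactly, so the
generator does not have to commit to a substitution process richer than
the analysis assumes.

What the generator does *not* emulate: linkage itself. HRi enters only
through the imposed $K_{a+}(rr)$ law - there is no forward simulation of
interference, sweeps, or background selection, and no sequence-level
realism beyond what the counts require. Passing recovery tests therefore
demonstrates that the *estimator* recovers a curvilinear adaptive-rate
law and its implied loss fraction from SFS-plus-divergence data; it does
not validate the population-genetic interpretation of that law. Real data
additionally carry alignment error, annotation error, selection on
synonymous sites and spatial autocorrelation of recombination, none of
which are generated here.

`emit_fixtures()` writes a small gene set down to FASTA/GFF3/map files
built from glycine-codon exons with polymorphic and divergent columns
placed on dedicated codons, so the alignment-and-counting path can be
round-tripped exactly against the recorded counts.

## Numerical and design choices

* **Problem sizes.** Per-bin DFE fits take a fraction of a second at
  $G = 200$ thanks to memoisation; the survey-scale recovery study runs
  10 replicates of 6,120 genes x 45 bins at $G = 150$ (the generator and
  fitter share the grid; 150 exceeds the 128 sampled chromosomes). The
  bootstrap and permutation calibration studies run 100-200 outer
  simulations at $B = 100$-$200$ replicates on 600-1,350 genes.
* **Plug-in mode for resampling loops.** Refitting demography and DFE in
  every bootstrap replicate is the dominant cost. `plugin_ka_plus()` and
  `fhri_plugin_stat()` reuse the correction factor $E_f[r(S)]$ fitted once
  on the full data; replicates then only recompute corrected divergence
  rates, binning, LOESS and the loss ratio. Point estimates always come
  from full fits. This treats the DFE correction as common across
  replicates - its sampling error, small when fitted on thousands of
  pooled genes, is not propagated into the intervals.
* **Coverage study design.** Percentile bootstrap intervals attain nominal
  coverage only where the point estimator is approximately unbiased. The
  span-1 LOESS chain has a deterministic smoothing bias under the steepest
  decay regime (about +0.014 on $f_{HRi}$ at $c = 2.12$, measured by
  running the chain on noiseless bin-level truth). The CI calibration
  study therefore uses $c = 1.3$ - within the range fitted across data
  subsets - where the same noiseless diagnostic shows bias +0.003, an
  order of magnitude below the sampling noise, so the study isolates the
  resampling machinery. The steep regime is still covered by the
  end-to-end recovery test, whose tolerance (+-0.05) absorbs the
  smoothing bias; that bias is the known cost of the span-1 choice, which
  buys replicate-to-replicate stability.
* **Ties and determinism.** Gene ranking breaks ties lexicographically by
  id; leftover genes (the $N \bmod n_{bins}$ highest-ranked) are
  discarded and logged; every stochastic operation takes an explicit seed
  and per-replicate seeds derive from the master seed, so reruns are
  bit-identical.
* **Degenerate inputs.** Saturated divergence (Jukes-Cantor $p \ge 0.75$,
  non-positive Tamura log arguments) raises an error naming the term;
  monomorphic SFS input makes the demography likelihood flat and is
  refused; a curvilinear fit to data with $b \approx 0$ flags the decay
  rate as unidentifiable rather than reporting a meaningless $c$; ties at
  zero in paired bootstrap comparisons count towards the null.
* **Permutation convention.** The observed statistic is not added to the
  permutation null (p-values divide by exactly $B$); `add_observed = TRUE`
  switches to the $+1$ convention.

## Known limitations

* The DFE stage assumes equal 0-fold and 4-fold mutation rates and a
  gamma-shaped deleterious DFE; divergence-informed or multi-class DFEs
  are out of scope, as is the unfolded SFS.
* Bin-level estimation replaces each gene's recombination rate by its
  bin mean; with a convex $K_{a+}(rr)$ law this contributes a small
  upward bias to the loss estimate, bounded by the recovery tests.
* No modelling of gene conversion, spatial autocorrelation of
  recombination, or selection on synonymous sites; the recombination map
  is taken as given, unsmoothed, at 100-kb resolution.
* Bit-compatibility with any external DFE-fitting binary is not a goal;
  the contract is the published model (gamma DFE, two-epoch demography,
  folded multinomial likelihood) with simulation recovery as the
  acceptance surface.
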