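---
title: "Methods: stabilizing selection and polygenic score portability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stabilizing selection and polygenic score portability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyport)
```

## The model

`polyport` studies a strictly additive quantitative trait under Gaussian
stabilizing selection in diploid Wright–Fisher populations. An individual's
additive genetic value is $G_i = \sum_l a_l g_{il}$, the effect-weighted sum
of derived-allele copy counts over the loci segregating in its population,
and fitness is

$$ W(z) = \exp\!\left(-\frac{(z - \mathrm{opt})^2}{2 w^2}\right), $$

where $w$ sets the width of the fitness peak ($w^2$ plays the role of
$V_S$). Loci are physically unlinked (free recombination), mutation
introduces $\mathrm{Poisson}(NU)$ new trait alleles per generation with
effects from a symmetric mean-zero distribution, and loci that fix are
folded into a *substitution offset* so that the tracked state is always the
set of segregating sites.

Two consequences of this model drive everything downstream:

* **Phenotypic constraint.** Selection holds the population mean at the
  optimum and keeps $V_P \ll w^2$, so two populations sharing an optimum
  barely diverge in mean phenotype.
* **Locus-level underdominance.** With the mean at the optimum, the
  marginal fitnesses of the three genotypes at a locus of effect $a$ work
  out to an effective selection *against heterozygotes*, giving the
  deterministic per-generation change
  $$\Delta p = s\,p(1-p)(2p-1), \qquad s = \frac{a^2}{2\,(w^2 + V_P)}.$$
  The common allele is driven toward fixation, so stabilizing selection
  *accelerates* the loss of trait polymorphisms even though it *freezes*
  the mean. The per-generation heterozygosity loss is $s(2p-1)^2$, whose
  classical $p$-averaged approximation ($\approx s/2$) yields the
  closed-form retention
  $(1 - \tfrac{1}{2N})^t\,(1 - \tfrac{a^2}{4(w^2+V_P)})^t
  \approx \exp\{-F_{ST}(1 + S/4)\}$ with $S = 2Na^2/w^2$ and
  $F_{ST} \approx t/2N$.

Because shared trait variance between two diverged populations can only come
from ancestral polymorphisms that survived in *both*, this accelerated
turnover erodes polygenic-score portability faster than neutral $F_{ST}$
would suggest, while leaving mean phenotypes almost identical.

## The three theory tiers and their domains

1. **Closed forms** (`closed_form_retention()`): cheap, good intuition,
   accurate to a couple of percent for $S \lesssim 8$. They assume a
   frequency-independent per-generation loss, which fails once the standing
   frequency distribution concentrates near the boundaries: at $S = 20$ and
   $t/2N = 0.1$ the closed form over-predicts retention by roughly 20%
   relative to the exact tiers. This is a property of the approximation, not
   a numerical artifact, and the test suite records it.
2. **Wright–Fisher transition matrix** (`wf_matrix_retention()`): the
   brute-force oracle. Builds the full $(2N{+}1)^2$ binomial transition
   matrix with the deterministic $\Delta p$ applied before sampling and
   iterates it exactly. Usable to $N \le 500$.
3. **Underdominant diffusion** (`diffusion_retention()`,
   `shared_variance_ratio()`): the figure-grade tier. The backward
   Kolmogorov equation
   $\partial_\tau h = \tfrac{S}{2}x(1-x)(2x-1)\,h' + \tfrac{x(1-x)}{2}h''$
   (time in units of $2N$ generations) is solved by implicit Euler on a
   uniform interior grid (1200 points, $\Delta\tau = 5\times10^{-4}$ by
   default), with absorbing boundaries. Implicit Euler is first-order but
   monotone, which matters because ascertainment payoffs are indicator
   functions. Matrix and diffusion tiers agree to better than 0.5% over
   $S \le 20$, $t/2N \le 0.1$.

Standing variation is described by Wright's stationary sojourn density for
influx at frequency $0$:
$\psi(x) \propto e^{-Sx(1-x)} \int_x^1 e^{Sy(1-y)}dy \,/\, x(1-x)$, which
reduces to the neutral $1/x$ spectrum at $S=0$. Integrating expected
heterozygosity over a sojourn and over the mutation-effect density gives the
equilibrium variance density `equilibrium_variance_density()`, normalized so
its integral is the total genic variance ($2NU\,\mathbb{E}[a^2]$ in the
neutral limit). Retention integrals start from $\psi$; quadrature is
trapezoidal with a mass-conservation guard that rejects grids too coarse to
integrate stably.

Portability predictions (`shared_variance_ratio()`) treat the two descendant
lineages as independent diffusions given the ancestral frequency: the
expected score variance in the unrepresented population is
$\int \psi(x)\, h(x,\tau)\, u(x,\tau)\,dx$ per effect class, where $h$ is
the expected-heterozygosity payoff and $u$ is the probability that the
representing lineage satisfies the ascertainment rule at present (survival
for the `all` scheme, an indicator payoff for MAF and top-variance schemes).
The top-variance cutoff is the upper 5% quantile of per-locus variance under
the standing $(a, x)$ measure truncated to $[1/2N, 1-1/2N]$.

## Simulator design

The generation cycle (compiled C++) computes genetic values, adds optional
environmental noise, samples parent pairs with probability proportional to
fitness, transmits every locus independently, introduces mutations, and
folds or drops boundary loci. Mendelian coin flips come from a 32-bit cache
refilled by one `unif_rand()` call, so the whole run is reproducible from a
single R seed; the two post-split branches use derived child seeds drawn
from the master stream. During divergence runs fixed ancestral columns are
*kept* (not folded) so that locus tables, scores and the ascertained /
non-ascertained partition stay exactly reconstructible across populations;
the test suite verifies that folding and keeping are numerically identical
where they overlap.

Neutral markers for $F_{ST}$ are zero-effect loci attached to the ancestor
at the split with frequencies drawn from the neutral $1/x$ spectrum and
Hardy–Weinberg genotypes, then transmitted through the same machinery. They
drift but never feel selection, which is all the Hudson ratio-of-averages
estimator needs over divergence times of interest.

## Study conditions and desk scaling

Reference conditions are $N = 10\,000$, $w \in \{4, 5\}$, Gaussian mutation
effects with sd 0.1 (or sd 0.05, or a heavy-tailed mixture), and divergence
measured by $F_{ST} \approx t/2N$. Locus dynamics depend on $(a, N, w)$ only
through $S = 2Na^2/w^2$, so the package's default desk scale divides $N$ by
10–20 and multiplies effect sds by $\sqrt{10}$–$\sqrt{20}$, preserving $S$
and $t/2N$. Test and acceptance ensembles run at $N = 500$ with 10N burn-ins
(stationarity asserted by a trend test on the recorded $V_a$ series);
replicate equilibria are harvested from independent chains thinned every
$2N$ generations. The default mutation rate ($U = 0.1$ at $N = 1000$;
$U = 0.04$ at $N = 500$) keeps the segregating trait basis near the
"thousands of unlinked loci" regime at full scale while staying inside a
laptop-minute budget at desk scale; $U$ affects locus counts and total
variance but not retention shapes, which are set by $S$.

The heavy-tailed default (`heavy_tail_effects()`: 95% of mutations at sd
0.01, 5% at sd 0.2, quoted at the $N=10^4$ scale) encodes an architecture
in which most mutations are effectively neutral while a strongly selected
minority carries much of the standing variance — producing the
early-steep-then-neutral decay of ancestral variance and the markedly worse
top-5% portability that distinguish heavy-tailed from Gaussian
architectures.

**What desk scale does not preserve.** $S$-preserving rescaling inflates
each locus's *share* of the trait variance by the same factor as $a^2$.
Two finite-size effects follow, both documented by direct measurement:

* With few loci, the compensatory response of the polygenic background to
  one locus's frequency fluctuation partially restores that same locus
  (its variance share is no longer negligible), slowing divergence relative
  to the independent-locus diffusion. At $N = 500$, $U = 0.1$, $w = 5$ the
  simulated ancestral-variance retention sits within ~1% of the
  $V_P$-corrected diffusion at $t/2N \le 0.05$ and ~3% above it at
  $t/2N = 0.1$.
* $V_P$ is not infinitesimal relative to $w^2$, so theory comparisons pass
  the measured $V_P$ into the effective peak width ($S_{\mathrm{eff}} =
  2Na^2/(w^2+V_P)$); all theory functions accept a `V_P` argument.

Consequently the quantitative sim-vs-theory tests use the $V_P$-corrected
tier and modest tolerances, while ordering claims (selection faster than
drift, heavy tail faster than Gaussian, $w=4$ worse than $w=5$) are asserted
strictly. Passing tests at desk scale demonstrate the mechanisms, not
full-scale effect sizes; where a full-scale number is quoted it comes from
the diffusion tier, which has no particle-number dependence.

## Differentiation statistics

`qx()` implements
$Q_X = (Z_A - Z_B)^2 / (4 V_a F_{ST})$ for a pair of populations, with the
$\chi^2_1$ upper tail as p-value. Conventions, each chosen once:

* $Z = 2\sum_l p_l a_l$ over ascertained loci; loci fixed in one
  population stay in the score at $p \in \{0, 1\}$ — a genotyping panel
  does not drop markers that are monomorphic somewhere.
* $V_a$ in the denominator uses frequencies averaged across the two
  populations ($2\bar p(1-\bar p)a^2$), which is symmetric and reduces to
  the usual genic variance when the populations coincide; population-A
  frequencies are available as a sensitivity switch.
* $F_{ST}$ defaults to the Hudson ratio-of-averages estimator on the
  simulated neutral markers; the expected $t/2N$ is available by option.
* The standardized difference $|Z_A - Z_B|/\sqrt{V_a}$ satisfies
  $\mathrm{std}^2 = 4\,Q_X F_{ST}$ exactly, and the ascertained plus
  non-ascertained mean-difference parts sum exactly to the full
  additive-genetic-value difference; both identities are asserted on every
  simulated record.

$Q_{ST}$ is the proportion of additive-genetic-value variance among
populations, $V_B/(V_B + V_W)$ with $V_B = (\bar G_A - \bar G_B)^2/2$ (the
one-degree-of-freedom among-group component). Its exact neutral expectation
at divergence $F$ is $2F/(1+2F)$ — "twice $F_{ST}$" in the small-$F$ limit.
Because $V_B$ is $\chi^2_1$-shaped for a single pair, per-replicate $Q_{ST}$
is noisy and Jensen-biased low; ensemble summaries therefore pool the
variance components across replicates (the same ratio-of-averages convention
as the $F_{ST}$ estimator) before taking the ratio. At $t/2N = 0.05$ the
pooled neutral ratio computes to ≈1.9, exactly where the finite-$F$
expectation puts it.

## Experiments

`run_decay()`, `run_portability()` and `run_qx()` orchestrate replicate
ensembles (independent burn-ins, optionally several splits per ancestor —
replicates sharing an ancestor are conditionally independent given its
standing variation, which is enough for null calibration and is noted where
binomial confidence intervals are used). `run_qx(optimum_shift = 2)`
implements the shared-optimum-shift scenario: at the split, the optimum
moves by two phenotypic standard deviations of the ancestral equilibrium in
*both* descendants. Both populations adapt in parallel and their mean
genetic values track each other closely; but a top-5% score ascertained in
population A captures more of A's response than of B's, manufacturing a
spurious mean-score difference. The false-positive rate of the $Q_X$ test
at $\alpha = 0.05$ is inflated severalfold across the divergence grid while
staying bounded well below one-half, reproducing the qualitative signature
of false polygenic-adaptation signals under parallel adaptation.

## Numerical choices and degenerate inputs

* Implicit Euler rather than Crank–Nicolson: unconditional monotonicity
  with discontinuous payoffs; step $5\times10^{-4}$ (in $2N$-generation
  units) makes time-discretization error negligible against the 2%
  comparison bands.
* Transition-matrix states at the boundaries are absorbing by construction;
  starting distributions put mass only on segregating states.
* Ties in top-variance ranking break by ascending locus id, making
  ascertainment a pure function of the locus table.
* Zero mutation rate, monomorphic populations, empty ascertained sets,
  all-monomorphic marker panels and zero $F_{ST}$ all return defined
  results (`NA` with a warning where the statistic is undefined) rather
  than errors; exhausted variance is a valid absorbing state.

## Known limitations

* Physically linked loci, selection-generated LD dynamics (the Bulmer
  effect appears only transiently through $V_A$ vs $V_a$ bookkeeping),
  migration, GxE, pleiotropy and time-varying optima in the theory layer
  are out of scope.
* Effects are estimated perfectly; there is no GWAS sampling noise,
  winner's curse, or tagging — portability losses here are purely from
  allele-frequency turnover, a lower bound on real-world losses.
* Desk-scale ensembles inherit the finite-polygenicity caveats above.
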