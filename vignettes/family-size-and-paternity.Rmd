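---
title: "Planning and validating inter-pollination hybrid breeding: family sizes, SSR paternity and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning and validating inter-pollination hybrid breeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhcross)
```

## The breeding scheme this package serves

Classical F1 hybrid breeding is throttled by combining-ability testing: to
evaluate every non-reciprocal pairwise cross among $n$ inbred lines a breeder
needs $n(n-1)/2$ crosses (`cross_count()`), which is 4,950 crosses for 100
lines — far beyond what is practical in most vegetable programmes. An
alternative is to skip controlled crossing altogether: produce fully
homozygous lines (ideally doubled haploids, DH), genotype each line once with
a small panel of codominant markers, let the whole group inter-pollinate at
random (insect cages or open field), grow the F1 progeny in *maternal-parent
rows* so that maternity is known by position, select superior individual
plants by phenotype, and only then genotype the few selected elites to
recover their paternal line by paternity testing. The genotyping effort
scales with the number of lines plus the number of selected elites, not with
the number of crosses.

Two quantitative questions decide whether this works, and they are the two
computational pillars of this package:

1. **Design**: how many F1 plants per maternal row are needed so that, with
   high probability, enough different paternal lines are represented?
2. **Identification**: with what confidence can a marker panel point to the
   true paternal line among the candidates?

## 1. Exact family-size mathematics

### Model

Let $L = \{v_1, \dots, v_n\}$ be the lines, and consider one maternal row.
Each of its $k$ offspring receives pollen from one line chosen uniformly and
independently — including the mother's own pollen, exactly as in the model's
derivation (a `self_incompatible` switch exists in the simulator, but the
closed form below always includes self). A row is then a uniform random
string in $L^k$. The number of strings in which *exactly* $j$ lines other
than $v_i$ appear is

$$|M_{j,k,n}| = \binom{n-1}{j}\, j!\, S(k+1,\, j+1),$$

where $S(k,j)$ is the Stirling number of the second kind (partitions of a
$k$-set into $j$ non-empty blocks): choosing the $j$ foreign lines, the
strings over those $j$ lines plus $v_i$ that use all $j$ of them decompose
into surjections with and without $v_i$, and the two surjection counts
telescope into a single Stirling number one row down. The probability that a
fixed maternal line is fathered by at least $m$ distinct other lines is
therefore

$$Q(n,k,m) \;=\; \frac{1}{n^k} \sum_{j=m}^{n-1} \binom{n-1}{j}\, j!\,
S(k+1,\, j+1).$$

`q_probability()` evaluates this expression; `min_offspring()` inverts it in
$k$ (exponential bracket plus bisection, valid because $Q$ is non-decreasing
in $k$); `probability_table()` renders the published-style grids;
`brute_force_q()` enumerates $L^k$ directly and is kept as an independent
oracle — the test suite checks exact rational equality of the two routes for
all $n \le 4$, $k \le 7$.

### Numerical choices

* **Exact arithmetic throughout.** $S(721, 61)$ has more than a thousand
  decimal digits, and the sum is a ratio of such numbers. All integers are
  exact big integers (base-$10^9$ limb vectors with C++ kernels in `src/`,
  since no arbitrary-precision package is assumed available); $Q$ is held as
  an exact rational and floating point appears only in the final rendering.
  Binomial-times-factorial terms are computed as falling factorials
  $(n-1)_j$, so no division ever occurs.
* **Rounding** is half-up at the requested number of decimals (default 3,
  matching the published tables), implemented by binary search on the exact
  rational; the acceptance tolerance against printed tables is
  $\pm 0.0005$ in case a different rounding engine produced them.
* **Exact comparison in `min_offspring()`**: the target $p$ (a double) is
  read as the rational $\mathrm{round}(p \cdot 10^{12})/10^{12}$ and compared
  by cross-multiplication, so the bisection never consults floating point.
* **Degenerate inputs**: $Q = 0$ whenever $k < m$ (you cannot see $m$
  distinct fathers in fewer draws) and $Q = 1$ for $m = 0$; both fall out of
  the formula and are asserted in tests.
* `stirling_cache()` rolls a single row of the Stirling triangle forward, so
  a whole ascending-$k$ table costs one pass; the full 61-line table takes
  well under a second.

One published inconsistency had to be adjudicated: the discussion of diallel
workloads elsewhere quotes 2,450 crosses for 50 lines (the
reciprocal-inclusive count), while the introduction of the scheme defines the
non-reciprocal $n(n-1)/2$. `cross_count()` implements the definition, so
`cross_count(50)` is 1,225.

## 2. SSR genotypes and marker informativeness

`marker_panel` stores unordered diploid genotypes (integer fragment lengths,
pairs sorted, a locus either fully typed or missing) for parent lines and
offspring, with CSV input/output (`read_genotypes()`/`write_genotypes()`;
missing code 0, the usual parentage-software convention). DH parents are
homozygous at every locus. `find_identical_lines()` partitions lines by
multilocus genotype: lines sharing every allele cannot be separated by the
panel — in the cabbage experiment exactly one such pair of lines occurred,
and every assignment to either must be reported as the pair.

`allele_frequencies()` counts allele copies; the base population defaults to
the candidate parents (the DH database), with offspring includable by flag.
`diversity_stats()` reports, per locus, observed heterozygosity $H_o$, Nei
gene diversity $H_e = 1 - \sum_i p_i^2$ (no small-sample correction; the
convention closest to the common parentage software at these panel sizes),
Botstein's polymorphic information content
$PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, and the average
**non-exclusion probability** `NE_1P` for a candidate parent when the other
parent's genotype is known. For `NE_1P` we derived the closed form in power
sums $a_r = \sum_i p_i^r$ by exact symbolic enumeration over
mother–father–offspring–candidate genotypes at Hardy–Weinberg proportions:

$$NE = 2a_2 - a_3 - 2a_4 + 3a_5 + 2a_2^2 - 3a_2 a_3.$$

Coefficient sets circulating in the literature for this quantity differ; we
therefore kept a brute-force enumerator in the test suite and require the
closed form to match it to $10^{-12}$ on assorted frequency vectors. A
monomorphic locus correctly gives $H_o = H_e = PIC = 0$ and $NE = 1$.

## 3. Likelihood-ratio paternity assignment

For each offspring (mother known from its row) and candidate father, the LOD
is the natural log of the overall likelihood ratio summed over loci typed in
all three individuals:

$$\mathrm{LOD} = \sum_{\ell} \ln
\frac{P(\text{off}_\ell \mid \text{mo}_\ell, \text{fa}_\ell)}
     {P(\text{off}_\ell \mid \text{mo}_\ell)},$$

with the numerator from Mendelian segregation and the denominator
integrating the paternal allele over population frequencies. The reference
method's exact error likelihood is not printed in the source material, so
each probability is blended with the genotyping error model as the mixture

$$P_{\text{obs}} = (1 - e)\,P_{\text{core}} + e\,P_{\text{HWE}}(\text{off}),$$

i.e. a mistyped locus looks like a random population genotype. This keeps
LODs finite for $e > 0$, reduces to hard exclusion ($-\infty$) at $e = 0$,
and behaves like the standard implementations in the regimes we test. Novel
offspring alleles absent from the frequency table get the floor frequency
$1/(2N+1)$. An offspring is evaluable only if at least `min_typed_loci` loci
are typed — by default *all* panel loci, the "8 of 8" rule used in the
cabbage experiment.

**Confidence calibration** (`simulate_confidence_thresholds()`) follows the
usual Monte-Carlo recipe: simulate progenies from parents drawn at
Hardy–Weinberg proportions (10,000 progenies, all parents sampled, typed
rate 0.998, mistype rate 0.002 are the experiment's settings), score the
best candidate per progeny, and return the smallest threshold at which the
proportion of correct assignments above it reaches 95% (strict) and 80%
(relaxed). Whether the published thresholds were calibrated on the best
LOD or on $\Delta$ (best minus runner-up) is not stated; both statistics are
computed, the default gate is the best candidate's LOD (the published
numbers are LOD thresholds), and the statistic is selectable. On a default
36-candidate synthetic panel the simulated strict threshold lands near
LOD $\approx 5.4$, closely matching the magnitude reported for the real
36-line cage experiment (5.35) — a consistency check, not a reproduction,
since the real genotypes are not packaged.

`assign_paternity()` assigns the top-ranked candidate only if its statistic
clears the threshold *and* it has zero mismatching loci. Ties among
genotypically identical candidates are assigned as the identity group
(label `"A/B"`, `ambiguous = TRUE`) — never as a confident unique father.
Offspring incompatible with their recorded mother are flagged
(`maternal_ok = FALSE`) and left unassigned rather than reassigned, since
maternity is recorded at sowing and was fully confirmed in the experiment.
`detect_reciprocals()` summarises selected hybrids by unordered parent pair:
distinct combinations, pairs selected in both orientations (reciprocals) and
per-pair multiplicity — the repeatability signatures of single-plant
selection.

## 4. The simulator's stated world

`simulation_config()` defaults describe the cage-pollination experiment as
closely as its public description allows: 36 DH lines, 8 SSR loci carrying
2–5 alleles each (29 in total, mean 3.625/locus, the counts reported for the
real panel), uniform allele frequencies within a locus, 139 offspring per
maternal row (~5,000 plants), typed rate 0.998, mistype rate 0.002, 2.5%
single-plant selection. Where the source states no value we chose once:
uniform within-locus frequencies (no frequency spectrum is published for
the parents), and a phenotype model
$y = g_i + g_j + s_{ij} + \varepsilon$ with additive line effects
$g \sim N(0, 1)$, symmetric pair deviations $s_{ij} \sim N(0, 0.5^2)$ and
noise $\varepsilon \sim N(0, 1)$ — the simplest GCA/SCA-style model that
produces repeated and reciprocal selections of good pairs. The phenotype
model is explicitly synthetic plumbing: it makes no claim about cabbage
trait architecture.

`recovery_experiment()` runs the whole pipeline and closes the loop with the
mathematics: the empirical fraction of replicate maternal rows with at least
$m$ distinct fathers must fall in the exact binomial 99% confidence interval
around $Q(n,k,m)$ (always with self-pollination allowed, since the closed
form includes self), and with error-free typing and distinct genotypes the
assignment accuracy must be exactly 1.

What a green simulation test does **not** establish: real pollination is not
uniform (flowering time, pollinator behaviour and plant vigour all bias
paternal contributions — the real experiment saw only 23 of 36 and 18 of 33
paternal lines among its elites), real allele frequencies are skewed,
lines may be unequally represented in the crossing block, and selection
acts on traits no additive model fully captures. The simulator validates
the *statistical machinery* under the model's assumptions, not the field
behaviour of any crop.

## Limitations

* No asymptotic approximations to $Q$ are offered; exact only.
* Unequal pollination probabilities are not modelled (the uniformity
  assumption is structural); self-incompatibility is a simple on/off flag.
* The published per-trio LOD tables of the cabbage experiment require the
  study's private genotypes and are out of scope; so are fragment calling,
  Hardy–Weinberg testing and null-allele handling.
* Heterozygosity values of the real 282-genotype dataset are likewise not
  reproducible here and are not targets.

## Session

```{r}
q_probability(design_params(61, 420, 60))
min_offspring(61, 60, 0.95)
```
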