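---
title: "Neutral coalescent simulation and the frequency spectrum by tip extension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral coalescent simulation and the frequency spectrum by tip extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalgrow)
```

## The model

coalgrow simulates sample genealogies under the standard neutral model: a
constant-size, panmictic, neutrally evolving diploid Wright–Fisher
population of size $N$, in the coalescent limit. Looking backward in time
from a sample of $n$ alleles, the epoch during which $i$ ancestral lineages
are extant lasts an exponential time $t_i$ with mean $4N/(i(i-1))$
generations, after which a uniformly chosen pair of the $i$ lineages merges.
We measure all times in **coalescent units of $4N$ generations**, so
$E(t_i) = 1/(i(i-1))$, the time to the most recent common ancestor has
expectation $E(t_{\mathrm{MRCA}}) = \sum_{i=2}^n E(t_i) = (n-1)/n$, and $N$
never appears on its own anywhere in the package.

Mutation follows the infinite-sites model: along a branch of length $L$
(coalescent units) the number of mutations is Poisson with mean
$\theta L$, where $\theta = 4Nu$ is the scaled mutation rate and $u$ the
per-locus neutral mutation rate per generation. Every mutation hits a fresh
site — represented here by a continuous uniform position on $[0,1)$, which
makes collisions probability-zero events that need no handling — so
mutations and polymorphic sites are in one-to-one correspondence. A
mutation's *size* is the number of sampled alleles that carry it, i.e. the
number of tips below its branch. The **site frequency spectrum (SFS)**
$\{s_i^{(n)}\}_{i=1}^{n-1}$ counts the polymorphic sites of each size, and
under this model

$$E\!\left(s_i^{(n)}\right) = \frac{\theta}{i}, \qquad
  E\!\left(S^{(n)}\right) = \theta \sum_{i=1}^{n-1} \frac{1}{i}.$$

```{r theory}
theory_table(n = 6, theta = 5)
```

## The tip-extension construction

The distinctive operation of the package is `grow_tree()`: an
$(n+1)$-sample mutated genealogy is generated from an $n$-sample one
*without* re-simulating. One tip of the $n$-tree — the **\*-tip**, chosen
uniformly — is split into two zero-length children, and then **all** $n+1$
tips are extended downward by a shared increment $e$, exponential with mean
$1/(n(n+1))$ coalescent units (the distribution of $t_{n+1}$). The $n+1$
extension segments then mutate at rate $\theta$ per unit length, so each
step adds on average $(n+1)\,\theta\,/(n(n+1)) = \theta/n$ new mutations,
every one of size 1.

This is deliberately *not* the same thing as sampling one more allele from
the population and coalescing it into the existing tree; the two operations
sound similar but have different bookkeeping, and the package implements
only the former.

The bookkeeping is exact. Call the mutations on the path from the \*-tip to
the root the **\*-mutations**, and let $s_{i,*}^{(n)}$ count those of size
$i$. A \*-mutation of size $i$ has the \*-tip among its descendants, so it
gains exactly one carrier and becomes size $i+1$; every other mutation is
untouched. Hence, defining $s_n^{(n)} = s_{n,*}^{(n)} = 0$,

$$s_i^{(n+1)} = s_i^{(n)} - s_{i,*}^{(n)} + s_{i-1,*}^{(n)},
  \quad i = 2, \dots, n,$$

and for singletons, with $M$ the realized number of extension mutations,
$s_1^{(n+1)} = s_1^{(n)} - s_{1,*}^{(n)} + M$. `check_recurrence()` asserts
both identities with zero tolerance on every growth step; a violation is a
bug, never sampling noise, and the growth experiment treats it as a hard
error.

Because a uniformly chosen tip descends from a given size-$i$ mutation with
probability $i/n$, and there are $\theta/i$ size-$i$ mutations on average,

$$E\!\left(s_{i,*}^{(n)}\right) = \frac{\theta}{i}\cdot\frac{i}{n}
  = \frac{\theta}{n},$$

independent of $i$ — the cancellation that makes the expected spectrum
reproduce itself under growth. `sfs_by_induction()` re-executes this
induction numerically from the two-sample base case
$E(s_1^{(2)}) = E(S^{(2)}) = \theta$ up to any target $n$, recovering the
singleton class at each step by subtracting the classes of size $\ge 2$
from $E(S^{(n+1)})$; it reproduces $\theta/i$ to machine precision (the
test suite checks $n$ up to 100).

```{r grow}
set.seed(1)
ms <- place_mutations(simulate_tree(5), theta = 3)
sfs_from_mutations(ms)
gr <- grow_tree(ms)
gr$record
check_recurrence(ms, gr$ms, gr$record)
```

### Mechanics and design choices

Several aspects of the growth step were genuinely open and were fixed as
follows.

* **Split in place, then re-normalize.** The \*-tip's node becomes an
  internal node; its two children are created at its height; all tips are
  then extended by the shared $e$ and every height is shifted so tips sit
  at exactly 0 again. This keeps the ultrametric invariant, so growth
  composes: a grown tree is a valid input to the next step. Growing a tree
  whose tips are not at height 0 raises an invalid-state error rather than
  silently producing a non-exchangeable genealogy.
* **Relabelling.** The \*-tip's label is retired; the surviving $n-1$ tips
  are relabelled $1..n-1$ in order of their old labels and the two children
  take labels $n$ and $n+1$. The old-to-new mapping is recorded in the
  `star_record`, so no label is ever silently reused across steps.
* **Auditability.** Every mutation carries an `origin` tag (initial
  simulation vs. the growth step that created it), so the star bookkeeping
  can be verified from the records alone, without geometric inference.
* **Draw order.** Within one step the random draws occur in a fixed,
  documented order — star tip, extension length, then the per-tip extension
  mutation counts and coordinates in new-label order — so any run is
  reproducible from `set.seed()`. This is the R-native equivalent of
  passing an explicit random stream into every operation.

## The Monte-Carlo harness

The three `run_*_experiment()` functions are the verification layer. Each
simulates replicates, reports sample means with standard errors
($\mathrm{SD}/\sqrt{R}$), and scores each mean against its closed form as
$z = (\bar{x} - \text{theory})/\mathrm{SE}$:

* `run_direct_experiment()` checks $E(s_i) = \theta/i$, $E(S)$, every
  $E(t_i)$ and $E(t_{\mathrm{MRCA}})$ from independent simulations;
* `run_growth_experiment()` grows chains (e.g. $2 \to 10$), asserts the
  exact recurrence at every step, and checks $E(s_{i,*}) = \theta/n$ (and
  its flatness in $i$), the star-path fraction $i/n$, and the extension
  mutation mean $\theta/n$;
* `run_equivalence_experiment()` compares direct simulation at $n$ with
  one-step growth from $n-1$ by per-bin two-sample z-scores, plus a pooled
  chi-square on the size-class counts as a stricter distributional
  diagnostic.

The default threshold is $|z| < 4$. With at most a few dozen simultaneous
checks per report this gives a family-wise false-alarm probability below
0.2% under the null, without distributional assumptions beyond the CLT at
$R \ge 10^4$; a report therefore counts exceedances instead of failing on a
single borderline value. The star-path fraction is a ratio of sums across
replicates, so its standard error uses the delta-method ratio-estimator
form, which is robust to the fact that the star indicators of mutations in
the same tree share one tip draw and are therefore correlated.

The problem sizes used by the shipped verification runs — $10^5$ replicates
for direct and equivalence checks at $n \le 10$, $10^4$ replicates for
growth chains $2 \to 10$ — were chosen so that standard errors are a few
percent of the means, tight enough that a systematic error of a few percent
in any closed form would be detected, while a full verification completes
in minutes on one core.

```{r verify}
run_direct_experiment(n = 6, theta = 5, reps = 2000, seed = 42)
```

## What the simulations do and do not show

The simulator *is* the model: constant population size, no recombination,
no migration, no selection, a single non-recombining locus with
continuous-position infinite sites. Agreement between the Monte-Carlo means
and the closed forms verifies the implementation and the internal
consistency of the theory; it says nothing about how real data deviate from
the standard neutral model (real spectra are distorted by demography,
linkage, selection and finite-sites effects, none of which are modelled
here). The coalescent limit itself is treated as exact: no finite-$N$
Wright–Fisher comparison is attempted, since the model offers no error
bound for it.

## Numerical notes and limitations

* Exact identities (the growth recurrence, SFS conservation
  $\sum_i s_i = |$mutations$|$, the telescoping
  $t_{\mathrm{MRCA}} = \sum t_i$) are integer or construction-level
  identities and are asserted with zero tolerance; purely floating-point
  identities (harmonic-sum consistency, the $\theta/n$ cancellation) are
  asserted to machine precision.
* Harmonic sums are computed by direct ascending summation — adequate at
  the sample sizes this package targets (hundreds, not billions).
* Newick output carries branch lengths to 6 decimal places; the reader
  (built on the ape package) accepts trees whose tips deviate from ultrametricity
  by up to $n \times 10^{-6}$, the worst case for rounding accumulated
  along a root path at that precision. Multifurcating or non-ultrametric
  input is rejected with the offending node reported.
* Times are reported in coalescent units throughout; `to_generations()`
  multiplies by a user-supplied $4N$ when generations are wanted.
* Sample size $n = 2$ is the smallest supported; $\theta = 0$ is allowed
  and yields mutation-free trees, useful for topology-only checks.
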