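---
title: "Models and methods behind tfbsdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tfbsdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbsdyn)
```

`tfbsdyn` asks a quantitative question about regulatory evolution: how fast
can a population gain or lose a transcription factor binding site (TFBS),
and which biophysical and population-genetic parameters control that speed?
The package couples three layers — a thermodynamic model of TF occupancy, an
origin–fixation Markov chain over binding genotypes, and a forward
Wright–Fisher simulator — and keeps them mutually testable: every analytic
object has a simulation counterpart and vice versa.

## The biophysical layer

A TF binds an $n$-bp window with additive energy
$E(\sigma) = \sum_j \xi_{\sigma_j, j}$ (in units of $k_BT$; the consensus
base contributes 0 per column). Under the *mismatch assumption* all
non-consensus entries share one value, the specificity $\epsilon$, so a
window is summarized by its mismatch class $k$ and $E = \epsilon k$.
Occupancy is the equilibrium binding probability

$$\pi(k) = \frac{1}{1 + e^{\beta(\epsilon k - \mu)}},$$

a sigmoid whose midpoint sits at $k = \mu/\epsilon$; the chemical potential
$\mu$ tracks the log free TF concentration. We call classes with
$\pi > 2/3$ *strong* ($k \le k_S$), classes with $\pi < 1/3$ *weak*
($k \ge k_W$), and the class one mutation above the strong boundary
($k_S + 1$) the *presite*. Both thresholds are strict; with the baseline
$\epsilon = 2$, $\mu = 4$, $n = 7$ used throughout, $k_S = 1$, the presite
is $k = 2$ and $k_W = 3$. Fitness is proportional to expression, which we
take proportional to occupancy: $f(k) = s\,\pi(k)$ for an isolated site, and
for an $L$-bp promoter the sum of all $L - n + 1$ window occupancies
(options: the strongest window only, or the product of the two strongest —
a toy for synergistic activation). Scanning is single-stranded: the model
has no strand notion, and windows are indexed 1-based.

Two deliberate conventions are worth flagging:

* **Cooperativity sign.** Two TFs bound within `window` (default 3) bp of
  each other gain an interaction energy $E_c$; the joint-occupancy weight is
  $e^{-\beta(\epsilon k + \epsilon k_c + E_c - 2\mu)}$, so *negative* $E_c$
  is favorable, reduces exactly to independence at $E_c = 0$, and acts as a
  local shift of the chemical potential at the focal site. Within a
  promoter each window pairs with its lowest-energy non-overlapping
  neighbor within the gap window (ties to the leftmost).
* **Default consensus.** The mismatch model needs a concrete consensus
  string for sequence-level work; the default cycles `ACGT`, which has
  minimal self-overlap. A homopolymer consensus would make windows that
  overlap a planted site by $n-1$ bp sit one mismatch away and triple the
  apparent strong-site count.

## The mutation layer

Point mutations occur at rate $u$ per bp per generation; indels at rate
$\theta u$ per bp, insertions and deletions equally likely, lengths 1 and
2 bp with relative frequencies $0.45 : 0.18$ (renormalized — these are the
reported frequencies of 1- and 2-bp events among all indel lengths). The
sequence is anchored at its final position, as appropriate for a promoter
measured from a transcription start site: an insertion pushes distal
sequence out of frame (the editor trims the index-1 end), a deletion pulls
random bases in. At the level of mismatch classes, a point mutation moves
$k \to k+1$ with probability $1 - k/n$ and $k \to k-1$ with $k/3n$. An
indel at position $i$ (uniform) preserves the mismatches on the anchored
side, $X \sim \mathrm{Binomial}(i-1, k/n)$, and randomizes the rest,
$Y \sim \mathrm{Binomial}(n-i+1, 3/4)$; the class kernel is the
position-averaged convolution and is independent of indel length.

The binomial form of $X$ is itself an approximation: in an explicit
sequence the preserved segment carries a hypergeometric number of the $k$
original mismatches. The two agree exactly at $k = 0$ and $k = n$ and
differ by a few percent per cell at intermediate $k$ for short sites
($n = 7$). Our Monte-Carlo tests therefore check the endpoint classes at
sampling precision and the intermediate classes in total variation; an
explicit-event ensemble large enough to resolve a few times $10^{-3}$ per
cell will reliably *detect* the binomial approximation, which is a property
of the analytic kernel, not of the simulator.

## The population layer: origin–fixation chain

With $2Nu \ll 1$ the population is monomorphic almost always and evolution
is a jump process over genotypes: a mutation to a neighbor with fitness
difference $\Delta f$ enters at the population mutation rate and fixes with
Kimura's probability

$$P_\mathrm{fix}(N, \Delta f) = \frac{1 - e^{-2\Delta f}}{1 - e^{-4N\Delta f}},$$

giving class-level substitution rates
$R_{k'k} = 2N\,U_{k'k}\,P_\mathrm{fix}(N, f(k') - f(k))$. All rates are
expressed in units of $u$ and all times in $1/u$; at neutrality
$2N P_\mathrm{fix} = 1$ and $R$ reduces to the mutation generator exactly.
A second-order series replaces the $0/0$ at $|4N\Delta f| < 10^{-8}$.

From $R$ the package computes:

* **Stationary distributions.** For $\theta = 0$ the chain is birth–death
  and the stationary distribution follows from the product of detailed-
  balance ratios, which is numerically exact even when entries span
  hundreds of log-units; general chains use the null eigenvector with a
  linear-solve fallback, with entries clipped at $-10^{-12}$ and
  renormalized. The closed form
  $\hat\psi_k \propto e^{4Nf(k)}\phi_k(n, 3/4)$ — selection ($F = 4Nf$)
  balancing mutational entropy ($H = \log$ binomial redundancy) — is the
  weak-selection limit: the exact per-step ratio is
  $e^{(4N-2)\Delta f}$, so the closed form is recovered to any desired
  accuracy by realizing a given $Ns$ with large $N$, and the equivalence
  test runs at $N = 10^{12}$ where agreement reaches $10^{-8}$ in absolute
  probability. (Relative comparisons are meaningless for entries of order
  $e^{-400}$ in double precision.)
* **Relaxation.** $\psi(t) = e^{Rt}\psi(0)$ via scaling-and-squaring
  (`Matrix::expm`; the chains have at most a few tens of states), and the
  spectral convergence rate $|\lambda_2|$, the nonzero eigenvalue closest
  to zero. Below the strong-selection threshold the stationary shape is
  bimodal — one attractor at the fit classes, one at the redundancy core
  $k \approx 3n/4$ — and relaxation across the fitness gap is slow; the
  threshold scales as $Ns \sim n\log(2)/2$, and the package also finds the
  empirical threshold (5% stationary mass outside the strong classes) by
  bisection.
* **Gain and loss times.** Mean first-passage times to a target class set
  solve the transposed linear system on the transient block. For
  tridiagonal chains the cumulative-stationary closed form is implemented
  as an independent cross-check (computed with upper-tail sums directly —
  forming $1 - \Psi$ by subtraction cancels catastrophically under strong
  selection). The shortest-path approximation sums inverse one-step rates
  along the monotone path, using downward rates for gain and upward rates
  for loss; it converges to the exact times as selection strengthens.
  Presite gain rates come out at about $Ns\,u$ at baseline parameters. A
  naive one-step estimate for loss from the consensus under strong
  negative selection suggests roughly $2n|Ns|u$; the exact chain at
  $\epsilon = 2$, $\mu = 4$ gives about $0.12$ of that (the occupancy drop
  is spread over three steps of $\Delta\pi \approx 0.10, 0.38, 0.38$, and
  the slowest step caps the rate), approaching the naive estimate only for
  sharper landscapes — the acceptance suite computes and reports this
  ratio rather than asserting the folklore value.

## The simulation layer

Two engines share one haplotype bookkeeping (distinct sequences with
counts; mutation as a Poisson number of events per generation; selection
weights $e^f$ — differences from $1 + f$ are $O(f^2)$ and negligible at
the $s \le 0.1$ used here):

* **Wright–Fisher** (`simulate_single_site`, and
  `simulate_promoter(method = "wright_fisher")`): $2N$ haplotypes
  resampled multinomially each generation — diploid bookkeeping with genic
  selection, equivalent to a haploid population of $2N$. Used to validate
  the fixed-state chain (at $Nu = 0.01$) and to probe where it fails
  ($Nu = 0.1$, where clonal interference makes the chain an upper bound on
  the gain rate).
* **Origin–fixation on sequences**
  (`simulate_promoter(method = "fixed_state")`, the default): proposals
  arrive at rate $2NLu(1+\theta)$ per generation and fix instantly with
  probability $P_\mathrm{fix}$. This is the same approximation the
  analytic theory makes, so it shares the theory's clock, and it is fast
  enough for ensembles of hundreds of replicates in seconds.

The clocks differ in one known, deterministic way: the chain counts a
substitution at the *origination* of the successful mutant, while a
forward simulation records the population event when the allele crosses
majority frequency. Conditioned on fixation a beneficial allele grows
quasi-logistically, so the crossing lags by about
$\log(2N P_\mathrm{fix})/\Delta f$ generations (`sweep_sojourn()`; 131
generations, i.e. 13% of the expected gain time, at the baseline
validation parameters $Nu = 0.01$, $Ns = 100$, $k_0 = 2$). Comparisons
between Wright–Fisher ensembles and chain predictions add this sojourn to
the prediction. Relatedly, the gain event is defined on the combined
frequency of the target *class*: distinct genotypes within a class are
selectively equivalent, and demanding a single genotype above 50% adds an
$O(N)$-generation neutral tie-break whenever two equivalent sweeps
overlap.

## Promoter-scale theory

With constant per-site gain and loss rates the expected strong-site count
obeys $\dot z = \lambda_\mathrm{gain}(z_\mathrm{max} - z) -
\lambda_\mathrm{loss} z$, solved in closed form by `z_of_t()`; under
strong positive selection loss is negligible and the newly evolved count
is $(1 - e^{-\lambda t})\, z_\mathrm{max} \sum_{k > k_S}\psi_k$ for
background class distribution $\psi$. Two limiting rate/capacity pairings
are reported side by side rather than blended through an invented
crossover time: the early epoch uses the presite-only rate with the
overlap-allowed capacity $L - n + 1$ (presites are the only single-step
sources, so early growth is linear with this slope), and the late epoch
uses the all-class rate with the packed capacity $\lfloor L/n \rfloor$.
Each is accurate in its own epoch and neither is a uniform bound: the
exponential form overestimates early multi-step contributions, and the
packed capacity binds only once sites actually crowd each other, so
mid-trajectory ensembles can legitimately exceed the late-epoch curve
while the count is still far below capacity. `count_strong_sites()`
reports the raw overlap-allowed count as primary (the additive fitness is
overlap-blind) along with a greedy non-overlapping count.

The ancient-site scenario biases the background toward presites: one
window carries a formerly strong site that has decayed neutrally for
$t'$, giving the mixture
$\Psi = \psi(t')/(L - n + 1) + \phi\,(L - n)/(L - n + 1)$ with $\psi(t')$
propagated under the neutral chain. The resulting boost in newly evolved
sites *peaks when the decayed site sits at the presite class*: an ancient
site at $k_\mathrm{ancient} \le k_S$ still counts as strong at $t = 0$ and
only its decayed fraction is convertible, so the prediction rises from
$k_\mathrm{ancient} = 0$ to the presite and decays steeply beyond it.
Cooperativity accelerates accumulation by promoting near-threshold
windows next to strong sites into the strong class, which both raises the
counted $z$ and steepens the selection gradient in otherwise flat
regions.

## Synthetic inputs

The generators in this package define the study conditions rather than
adapt to them: random uniform ACGT backgrounds; planted sites with an
exact mismatch count at chosen positions; Gaussian energy matrices with
mean $\epsilon = 2\,k_BT$ and sd $0.5\,k_BT$, truncated at zero so the
consensus stays the energy minimum, with the consensus base uniform per
column. Defaults mirror the baseline study conditions: $n = 7$,
$\epsilon = 2$, $\mu = 4$, $\alpha = 3/4$, $\theta \in \{0, 0.15\}$,
$Ns \in [-300, 1000]$ realized with $N = 1000$ diploids, $Nu = 0.01$
(and $0.1$ for the polymorphic regime), $L = 30$ bp, ensembles of 200
replicates. These sizes keep every check below a few minutes on one CPU;
they were chosen as the smallest ensembles whose standard errors still
resolve the effects under test (separations of several SEM).

What the synthetic data deliberately leave out — and what passing tests
therefore do not establish about real regulatory DNA: GC-content and
repeat structure in backgrounds, unequal indel polarity and fat-tailed
indel lengths, alignment-aware indel accounting in cross-species
comparisons, multiple TF species with distinct matrices, recombination,
and any feedback of genome-wide binding on the chemical potential.

## Known limitations

* The fixed-state chain overestimates gain rates once $Nu$ approaches
  0.1; the Wright–Fisher engine is the arbiter there.
* The mismatch-class chain ignores within-class sequence structure; with
  energy matrices the class description is only approximate, and the
  sequence-level engines are the reference.
* The indel class kernel's binomial preserved-segment model deviates by a
  few percent per cell at intermediate $k$ for short sites (see above).
* Hitting times assume the target is reachable; under vanishing selection
  against an absorbing-complement target the linear system approaches
  singularity and times of order $10^{15}/u$ are reported as such.
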