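---
title: "Simulating multiple-merger genealogies in species trees and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multiple-merger genealogies in species trees and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(lambdanet)
```

## The model

Gene genealogies of samples taken from several species are shaped by two
processes: the ancestral relationships of the species themselves (a rooted
species tree, or a network when hybridization occurred), and the coalescent
process running inside each ancestral population. For low-fecundity organisms
the Kingman coalescent — only pairwise mergers, pairs coalescing at rate
$\binom{b}{2}$ when $b$ lineages are active — is the standard choice. For
high-fecundity organisms with sweepstakes-like reproduction (oysters, sea
stars, cod and many other broadcast spawners), single reproduction events can
replace a substantial fraction of the population, and ancestral lineages may
merge more than two at a time. `lambdanet` simulates genealogies under two
families of such $\Lambda$-coalescents, inside arbitrary rooted species trees
and hybridization networks:

* the **point-mass ($\psi$) coalescent**, where a fraction $\psi \in [0,1]$
  of the population descends from one parent in a sweepstakes event; $k$ of
  $b$ lineages merge at rate
  $\lambda_{b,k} = \binom{b}{k}\psi^{k-2}(1-\psi)^{b-k}$;
* the **Beta$(2-\alpha,\alpha)$-coalescent**, $\alpha \in (1,2)$, with
  $\lambda_{b,k} = \binom{b}{k}\,B(k-\alpha,\,b-k+\alpha)/B(2-\alpha,\alpha)$,
  which approaches the Kingman coalescent as $\alpha \to 2$.

Both families are normalised so that two lineages coalesce at rate 1
($\lambda_{2,2}=1$), which defines the coalescent time unit. A coalescent
parameter value dispatches the family: $(0,1]$ is read as $\psi$, $(1,2)$ as
$\alpha$, and $0$, $2$ or unset as Kingman ($\psi = 0$ collapses to Kingman
exactly, so the boundary is consistent). Each branch of the species network
can carry its own parameter and its own effective population size.

Within a branch the simulation draws exponential waiting times with the total
rate $\sum_{k=2}^{b}\lambda_{b,k}$, picks the merger size $k$ proportionally
to $\lambda_{b,k}$, and merges a uniformly chosen $k$-subset; exactly one
merger happens per event ($\Lambda$-coalescents have no simultaneous
mergers). Lineages that have not coalesced when they reach the top of a
branch are handed to the parent branch unchanged (censored coalescent). At a
hybrid node each lineage independently derives from the left parental
population with the inheritance probability $\gamma$ attached to that node's
left parent edge. Above the root, the root population's parameter and size
apply until the grand most recent common ancestor.

## Input format and conventions

Species trees use plain Newick; networks use the extended `#`-tag dialect in
which the two occurrences of a hybrid label denote one node with two parent
edges. Two dialects for $\gamma$ are accepted, because both occur in
practice: a symbolic tag (`h1#H1` with `gamma = c(H1 = 0.6)` supplied
separately) and an inline numeric tag (`h_2#.5`). "Left" parent means the
parent edge encountered first in a left-to-right scan of the string; this is
a convention, documented and stable, since the format itself does not order
parents. When both occurrences carry inline values they must sum to 1
(checked to $10^{-9}$).

```{r}
net <- parse_network("((((B,C)s1)h1#H1,A)s2,(h1#H1,D)s3)r;", gamma = c(H1 = 0.6))
net
```

Branch lengths default to coalescent units. Lengths in generations are
converted by dividing by each branch's effective population size $N$
(`convert_units()`). On a Beta-coalescent branch the timescale of the process
is proportional to $N^{\alpha-1}$, and `alpha_timescale = TRUE` uses that
divisor instead; the default is plain division by $N$ on every branch, which
keeps the conversion independent of the coalescent parameter. The network
remembers which convention was used, so the generation-scaled output of the
simulator inverts the conversion exactly. Simulation assumes an ultrametric
network (all root-to-tip paths equal); `check_ultrametric()` compares every
path against the deepest one with a relative tolerance (default $10^{-6}$ of
the height) and deviations are reported as warnings, not errors — the
simulation proceeds, with all sampled tips at the present.

Defaults in the programmatic interface are relative units: $N = 1$ and the
Kingman coalescent everywhere. The command-line interface (`hybrid_lambda()`
and the installed `hybrid-lambda` script) instead defaults to $N = 10{,}000$,
so that a split written as `(A:10000,B:10000);` in generations corresponds to
populations separated by one coalescent unit, and to a mutation rate of
$10^{-5}$ per generation — conventional values for the mitochondrial data
sets this class of models is typically fitted to.

## Mutations and haplotypes

Mutations follow the infinitely-many-sites model: each branch receives a
Poisson number of mutations with mean $\mu$ times the branch length in
generations, independently across branches, and every mutation hits a new
site. Each mutation becomes one 0/1 column (1 = carriers of the derived
state, i.e. the tips below the mutated branch). No mutations are placed above
the grand most recent common ancestor, so the ancestral state is 0 by
construction and every column is segregating. Columns are ordered oldest
first, ties broken by node index, which makes output deterministic under a
fixed seed. The `seg` file written by the command-line interface contains one
block per replicate: a `//replicate <i> segsites <S>` header followed by one
row per sample (`label 0 1 0 ...`). The mutation-labelled Newick output
(`-sim_num_mut`) writes each branch's simulated mutation count in the
branch-length position, e.g. `(a_1:3,b_1:1);`.

## F_ST: estimator and analytic approximation

For two populations with $n$ samples each, the package computes
$$\hat F_{ST} = 1 - \frac{n}{n-1}\,\frac{H_w}{H_b},$$
where $H_b$ is the average number of pairwise differences over all
$n_1 n_2$ between-population pairs and $H_w = (H_{w,1}+H_{w,2})/2$ with
$H_{w,i}$ the average over all $n_i^2$ *ordered* within-population pairs,
self-pairs (zero differences) included. This symmetric convention is
deliberate: the $n/(n-1)$ factor then exactly cancels the $(n-1)/n$
deflation introduced by the self-pairs, so the estimator is centred on
$1 - E[T_w]/E[T_b]$ for every sample size, not only asymptotically. (Had
$H_w$ been averaged over distinct pairs only, the corrected estimator would
be strongly biased downward at small $n$ — at $n=2$ it would estimate
$1 - 2\,E[T_w]/E[T_b]$.) With one sample per population the correction is
undefined; the uncorrected ratio $1 - H_w/H_b$ (which is then always 1) is
available via `correction = FALSE`, and the command-line interface falls back
to it with a note. Replicates with $H_b = 0$ are flagged undefined, excluded
from summary means, and counted. For multi-locus data, pairwise differences
are summed across loci per pair before averaging (ratio of averages), the
standard low-variance pooling.

The analytic module covers a split model: populations $A$ and $B$ isolated
since time $\tau$ (coalescent units), pairwise rate $\lambda_A$ within each
daughter population and $\lambda_{AB}$ in the ancestral one. It implements
the classical low-mutation approximation
$$E[T_w] = (1-e^{-\lambda_A\tau})\lambda_A^{-1}
          + e^{-\lambda_A\tau}(\tau + \lambda_{AB}^{-1}),\qquad
  E[T_b] = \tau + \lambda_{AB}^{-1},$$
$$F_{ST}^{(0)} = 1 - \frac{E[T_w]}{E[T_b]}
  = (1-e^{-\lambda_A\tau})\Bigl(1-\frac{1}{(\tau+\lambda_{AB}^{-1})\lambda_A}\Bigr),$$
with limits 0 as $\tau \to 0$ and 1 as $\tau \to \infty$. For the
Beta$(2-\alpha,\alpha)$-coalescent $\lambda_A = 1$ on its own timescale; for
the point-mass family the pairwise rate is left as a free input.

One caveat users should know: the $E[T_w]$ expression above evaluates the
conditional coalescence time of pairs that merge before $\tau$ as
$\lambda_A^{-1}$, whereas the exact truncated mean is smaller; the exact
within expectation is $(1-e^{-\lambda_A\tau})/\lambda_A +
e^{-\lambda_A\tau}/\lambda_{AB}$ (with equal rates the within pair is
memoryless and $E[T_w] = 1/\lambda_A$ for every $\tau$). The approximation is
therefore accurate when $\lambda_A\tau$ is large — a few coalescent units or
more, the regime of clearly diverged populations — and that is where its
monotonicity in $\tau$ holds as well (it can be non-monotone, even negative,
when $\lambda_A < \lambda_{AB}$ at small $\tau$). The simulator itself is
exact; the test suite verifies its pair marginals against closed forms
(pair-coalescence probability $1-e^{-\tau}$, single-population mean TMRCA
$2(1-1/n)$, three-taxon concordance $1-\tfrac23 e^{-t}$) and checks that
pooled simulated $\hat F_{ST}$ over an $\alpha$ grid tracks the analytic
curve within Monte-Carlo bands where the approximation is sharp.

```{r}
expected_fst(c(0.1, 1, 10))
```

## A worked simulation

```{r}
net <- parse_network("(A:1,B:1);")                  # one coalescent unit apart
net <- set_branch_attributes(net, 1.5, "coalescent_param")
net <- set_branch_attributes(net, 1e4, "pop_size")  # for the mutation clock
trees <- simulate_gene_trees(net, samples = c(A = 4, B = 4), n = 500)
table(vapply(trees, classify_monophyly, ""))
head(topology_table(trees), 3)
haps <- lapply(trees, function(tr) haplotypes(tr, place_mutations(tr, 1e-4)))
estimate_fst(haps)   # pooled over the 500 replicate loci
```

## Numerical and design choices

* Beta rates are computed in log space (`lchoose` + `lbeta`) to stay finite
  at large $b$; validity ranges ($\psi \in [0,1]$, $\alpha \in (1,2)$ open)
  are enforced at the boundary of each kernel.
* Merger-size sampling uses the exact discrete distribution
  $\lambda_{b,k}/\sum_k \lambda_{b,k}$; participant subsets are uniform,
  which the suite checks by a $\chi^2$ exchangeability test.
* One seeded generator (R's global RNG) drives every stochastic step, so a
  seed fully determines all output files, byte for byte.
* Event heights are measured from the present (tips at height 0). Generation
  heights are accumulated branch by branch during the traversal, so a gene
  lineage crossing several populations with different $N$ gets the correct
  piecewise scaling automatically.
* Hybrid routing happens at the hybrid-node instant, before any coalescence
  in the parent branches.
* Newick output uses 6 significant digits by default (configurable).
* Test problem sizes: closed-form comparisons use $10^4$ replicates at 3
  standard errors; the $\alpha$-grid F_ST comparison uses $10^3$ replicate
  loci per cell with bootstrap bands, widened by a Poisson band on the
  observed within-population mutation count because at small $\alpha$ the
  within diversity is a handful of discrete mutations at most.

## What the simulations do and do not show

Simulated data here are idealised: a single non-recombining locus per
replicate, free of sequencing error, missing data, and selection, with known
ancestral states and a strict molecular clock. Passing the included checks
demonstrates the internal consistency of the coalescent machinery and its
agreement with closed-form expectations — not that any particular organism
follows a $\psi$- or Beta-coalescent. Migration after divergence,
recombination, heterochronous sampling, and time-varying coalescent
parameters are out of scope.
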