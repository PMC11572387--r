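# paleotip

Phylogenetic analysis of discrete morphological matrices with fossil taxa,
in one tested R package: maximum parsimony under equal and implied weights,
Mkv likelihood, Bayesian tip-dating under the fossilized birth-death (FBD)
tree prior with relaxed clocks, rogue-taxon pruning, stratigraphic
congruence, and ancestral-state reconstruction. A forward simulator
generates FBD time trees and Mk-evolved matrices so every stage can be
validated end to end without external data.

The package is aimed at paleontologists analysing dental or osteological
character matrices of extinct clades — the motivating case is a matrix of
44 cricetine (hamster) taxa scored for 116 dental characters, with fossil
tip ages spanning the Neogene — but nothing in it is specific to rodents.

## What it computes

**Parsimony.** Unordered (Fitch-type) tree lengths via a unit-cost Sankoff
dynamic program in C++, exact on multifurcating trees and with missing data
and polymorphisms treated as uncertainty sets. Heuristic search uses random
addition sequences, SPR/TBR branch swapping and an optional reweighting
ratchet; under implied weighting the objective is the Goloboff fit
`sum_i k/(k + h_i)` with concavity `k` (default 12). Ensemble indices are

    CI = sum(m_i) / sum(s_i)        RI = (sum(g_i) - sum(s_i)) /
                                         (sum(g_i) - sum(m_i))

with `m_i`, `s_i`, `g_i` the minimum, observed and maximum steps per
character. Bootstrap proportions come from character resampling.

**Likelihood and tip-dating.** The Mk model with per-character state counts,
discrete-gamma rate heterogeneity and the Mkv variable-only ascertainment
correction; Felsenstein pruning in C++. The Bayesian sampler estimates
topology, node ages, fossil tip ages (uniform priors on stratigraphic
intervals), the clock rate (lognormal prior derived from a non-clock run:
rate = median tree length / root-prior median), FBD rates (lambda, mu, psi;
exponential hyperpriors), and clock-variance parameters under strict, IGR
(independent gamma) or TK02 (autocorrelated lognormal) clocks, with
`fossiltip` (fossils terminal) or `random` (sampled ancestors allowed) FBD
sampling strategies. Stepping-stone sampling gives marginal likelihoods and
`2 ln BF` model comparisons.

**Downstream.** Majority-rule consensus, greedy rogue-taxon detection by
consensus-information maximization, tree-set pruning, maximum clade
credibility trees with HPD node ages, stratigraphic congruence indices
(RCI, GER, MSM*) with permutation tests, parsimony mapping of character
changes with synapomorphy extraction, and stochastic character mapping with
per-character ER/SYM/ARD selection by AIC.

## Worked example

```r
library(paleotip)

## simulate a fossil dataset: FBD tree, Mk characters, age intervals
p <- fbd_params(lambda = 0.3, mu = 0.1, psi = 0.2, rho = 1,
                strategy = "fossiltip")
d <- simulate_dataset(p, origin = 15,
                      clock = list(type = "igr", c = 0.1, v = 0.02),
                      n_char = 40, seed = 11, min_tips = 8)

## parsimony
mp <- parsimony_search(d$matrix, "ew", n_starts = 5, seed = 1)
mp
#> mp_search (EW): 19 optimal tree(s), 138 steps, CI 0.333, RI 0.560

## tip-dated Bayesian inference
rp <- offset_exp_prior(max(d$ages$max_ma) + 0.01, max(d$ages$max_ma) + 8)
post <- run_tip_dating(d$matrix, d$ages, clock = "igr",
                       strategy = "fossiltip", rho = 1,
                       root_prior = rp, generations = 20000,
                       sample_every = 50, seed = 2)
post
#> tip_dating: 280 samples, 19 taxa
#>   posterior median root age: 14.68 Ma
#>   WARNING: ESS < 200 for: loglik, tree_length, root_age, clock_rate, ...

summary <- mcc_tree(post$trees)
head(summary$clades[, c("prob", "age_median", "age_lo", "age_hi")])

## stratigraphic fit of the parsimony tree
strat_indices(mp$best, d$ages, permutations = 1000, seed = 3)
#> strat_fit: MIG 49.422 My, SRL 14.629 My (analytic bounds)
#>   RCI -237.84 (p 0.002), GER 0.700 (p 0.002), MSM* 0.221 (p 0.002)
```

(The printed numbers above are what these seeds produce: a 19-taxon
simulated dataset whose equal-weights optimum has 138 steps with ensemble
CI 0.333 and RI 0.560; the tip-dated posterior root-age median is 14.68 Ma
— the short demonstration chain honestly flags its low effective sample
sizes — and the stratigraphic fit has GER 0.700 with permutation p = 0.002.
A negative RCI means implied ghost ranges exceed observed ranges, which is
common when occurrences are near-points.)

The full workflow — both parsimony criteria, the non-clock stage, the
clock-prior derivation, the clock runs, rogue pruning, consensus/MCC
summaries, stratigraphic congruence and ancestral states — is one call:

```r
cfg <- run_config(outgroup = "f9", generations = 10000, seed = 1)
res <- run_full(cfg, matrix = d$matrix, ages = d$ages, out_dir = "out/")
res$summary$mp_ew$steps
res$summary$rogues
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/paleotip.R` (subcommands `mp`, `bayes`, `consensus`, `rogues`,
`prune`, `stratfit`, `simulate`).

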