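# focalnet

Activity budgets, grooming cliques, and proximity-based social networks
from focal-animal sampling data.

`focalnet` implements the comparative behavioral-ecology workflow used to
contrast a captive primate group with a wild one: per-individual activity
budgets from instantaneous samples, three-digit grooming-clique coding with
mutual-grooming ratios, dyadic proximity indices assembled into a weighted
social network that is thresholded at the third quartile and scored by
eigenvector centrality, and the statistical battery that goes with it
(Mann–Whitney U, Kruskal–Wallis with Holm-corrected Dunn comparisons,
Welch's t, and a sex-label randomization test). Because raw observational
records of this kind are rarely deposited, the package ships a synthetic
focal-sampling generator whose presets emulate the two study designs, so
every stage of the pipeline is testable and calibratable end to end.

## The statistics at the core

**Proximity index.** For individuals $A$ and $B$,

$$PI_{AB} = \frac{T_{A(B)} + T_{B(A)}}{T_A + T_B}$$

where $T_A$ is the total proximity-observation time of focal $A$ and
$T_{A(B)}$ the time $B$ was recorded within the protocol radius while $A$
was observed. Times come from counting sampling points (instantaneous
protocol) or scored intervals (one-zero protocol) times the sampling
interval. $PI$ is symmetric and lies in $[0,1]$.

**Q3 network filter.** With a long-observed stable group every dyad has
$PI > 0$ and the raw network is complete; only dyads with
$PI \ge Q_3$ (the third quartile of all $N(N-1)/2$ dyadic values, zeros
included) are kept as edges, weights retained.

**Eigenvector centrality.** Node scores are the principal eigenvector of
the filtered weighted adjacency matrix (power iteration with a Perron
shift; a dense eigendecomposition is available as a cross-check),
normalised to unit Euclidean norm over all nodes; isolates score 0.

**Sex-label randomization test.** The observed Welch t (female − male) on
the centralities is compared against the distribution of t over uniformly
permuted sex labels (group sizes preserved), with `p_lower` the fraction of
resampled t at or below the observed value and `p_two_sided` the fraction
at least as extreme in absolute value.

**Grooming cliques.** A bout's clique is coded by three digits: mutual
flag, focal-grooms flag, and the number of individuals grooming the focal
(codes 111/112/114 are mutual grooming; 001–012 one-directional). The
mutual-grooming ratio is mutual seconds over total grooming seconds, with
individuals below 300 s of recorded grooming (or in excluded age
categories) flagged out of the analysis.

## Worked example

Simulate the wild-like design (16 focals, 8 male / 8 female, one-zero
proximity sampling at 5-min intervals within 10 m) and run the network
stages:

```r
library(focalnet)

colony <- simulate_colony(wild_like_config(seed = 1))
tal <- tally_proximity(colony$proximity, colony$sessions)
m   <- build_pi_matrix(tal, colony$roster)

pis <- sex_combination_pis(m, colony$roster)
dplyr::summarise(dplyr::group_by(pis, sex_combination),
                 n = dplyr::n(), mean_pi = mean(pi))
#>   sex_combination     n mean_pi
#> 1 FF                 28  0.0883
#> 2 MF                 64  0.0853
#> 3 MM                 28  0.171

kruskal_wallis(pis$pi, pis$sex_combination)
#> Kruskal-Wallis test
#> chi-squared = 64.4309, df = 2, p = 1.021e-14
#> Pairwise comparisons (dunn, Holm-adjusted):
#>  group1 group2          z      p_value       p_holm
#>      FF     MF  0.6941574 4.875835e-01 4.875835e-01
#>      FF     MM -6.0486186 1.460930e-09 2.921861e-09
#>      MF     MM -7.8287187 4.928669e-15 1.478601e-14

net <- q3_filter(m)
net
#> Filtered proximity network: 16 nodes, 30 edges at threshold 0.1134 (quartile 0.75)

cen <- eigenvector_centrality(net)
sex_label_permutation_test(cen$centrality, colony$roster$sex, b = 10000, seed = 1)
#> Sex-label randomization test (permutation)
#> observed t (female - male) = -67.6529, B = 10000
#> p_lower = 0, p_two_sided = 1e-04
```

Male–male dyads associate roughly twice as strongly as the other sex
combinations (mean PI 0.171 vs ≈ 0.086), the Kruskal–Wallis test rejects
homogeneity across sex combinations with both Holm-adjusted male contrasts
significant, and after Q3 filtering the males monopolise the network core,
so the randomization test finds male centrality significantly higher than
female (negative t under the female-minus-male convention). The captive
preset (`captive_like_config()`), with equal association probabilities
across sex combinations, shows none of this structure.

`run_pipeline(pipeline_config(colony = wild_like_config(seed = 1), out_dir = "out"))`
runs every stage and writes `budgets.csv`, `grooming_summary.csv`,
`pi_matrix.csv`, `network_edges.csv`, `network.graphml`, `centrality.csv`,
`stats_report.json`, and a parameter log. A thin command-line wrapper with
`simulate | budgets | grooming | network | stats | report` subcommands is
installed at `inst/cli/focalnet.R`.

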