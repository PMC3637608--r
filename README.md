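# paralogasym

Measuring asymmetric sequence divergence between evolutionarily young gene
duplicates, and relating it to the genomic features of the duplicate pair.

## The problem

After a gene duplication, the two copies need not evolve at the same rate:
one copy typically keeps the ancestral role under purifying selection while
the other accumulates substitutions faster under relaxed constraint or
positive selection. For *young* duplicates (synonymous divergence
K<sub>S</sub> ≤ 0.14) this asymmetry is hard to detect — classical
relative-rate tests have very low power when few mutations have accrued —
so the analysis needs both a significance test and a continuous per-site
asymmetry measure, plus the genomic covariates that might drive the
asymmetry: evolutionary age (K<sub>S</sub>), chromosomal location of the
two copies, duplication span, and structural resemblance.

`paralogasym` is a complete, tested R implementation of that analysis for
paralog–paralog–outgroup triplets, aimed at molecular-evolution
researchers who have (or simulate) paralog pairs with an outgroup
ortholog.

## The statistics at its core

* **Unique-site relative-rate test.** For an aligned triplet (A, B,
  outgroup O), m<sub>A</sub> counts columns where A differs from B and O
  while B = O (m<sub>B</sub> symmetric). Under equal rates,
  χ² = (m<sub>A</sub> − m<sub>B</sub>)² / (m<sub>A</sub> + m<sub>B</sub>)
  on 1 df. At a total of 20 unique sites a difference of 9 is needed for
  significance at α = 0.05 (`min_detectable_difference(20)`).
* **Asymmetry/site** = |m<sub>A</sub> − m<sub>B</sub>| / L over the usable
  homologous length L, at the nucleotide and amino-acid level; the
  *signed* variant (m<sub>anc</sub> − m<sub>der</sub>) / L for pairs with
  an ancestral/derived assignment (by synteny or exon-structure match to
  the outgroup).
* **K<sub>S</sub>** by Nei–Gojobori (1986) counting with Jukes–Cantor
  correction, on a codon alignment back-threaded through the protein
  alignment; five age cohorts on [0, 0.14).
* **Duplication span**: homologous tract length between duplication
  termination points, found by sliding-window homology detection (100 bp,
  ≥ 60% identity) with 1 kb outward extension steps over a compiled
  affine-gap global alignment; the lower of the two per-paralog spans is
  reported. Structure classes: complete / partial / chimeric by the
  unique-exon rule.
* **Inference battery**: stepwise mixed-selection regression (partial-F,
  entry 0.15 / stay 0.10, least-squares refit with a Summary of
  fit / ANOVA / Parameter-estimates report), Kendall's τ<sub>b</sub>,
  Wilcoxon rank-sum and signed-rank (T = (W⁺ − W⁻)/2), Kruskal–Wallis,
  and the Williams-corrected G-test.

A synthetic-data module (`simulate_triplet`, `simulate_dataset`,
`simulate_pair_features`) generates triplets and whole datasets with known
ground truth (branch rates, asymmetry factors, spans, structure classes,
relocation), so every stage — and the full regression analysis — is
testable without any external download.

## A worked example

```r
library(paralogasym)
set.seed(1)
d <- simulate_dataset(sim_config(n_pairs = 30))   # 30 triplets + genomic context
report <- run_full_analysis(d)
print(report)
```

```
== Paralog rate-asymmetry analysis report ==
Pairs analysed: 30 of 30

-- Cohort significance profile --
       cohort n   frac_nt   frac_aa
1    [0,0.01) 4 0.0000000 0.0000000
2 [0.01,0.03) 6 0.3333333 0.3333333
3 [0.03,0.05) 3 0.6666667 0.3333333
4 [0.05,0.08) 4 1.0000000 0.2500000
5 [0.08,0.14) 8 1.0000000 0.6250000

-- Stepwise regression (nt asymmetry/site) --
Summary of fit:
  R-square           0.5723
  R-square adjusted  0.5570
  Root mean square error  0.02077
  Mean of response   0.03003
  Observations       30
Analysis of variance:
  Model    df   1  SS 0.0161653  MS 0.0161653  F 37.4624  p 1.324e-06
  Error    df  28  SS 0.0120822  MS 0.000431508
  C. Total df  29  SS 0.0282476
Parameter estimates:
      term  estimate std_error t_ratio     p_value
 Intercept 0.0102623 0.0049819 2.05991 4.88114e-02
        ks 0.2184181 0.0356854 6.12065 1.32360e-06
...
-- Tests --
Pseudogene x structure G-test: G_adj = 3.7813 , p = 0.151
Span by structure (Kruskal-Wallis): H = 0.80717 , p = 0.6679
Ks vs asym tau (nt): tau = 0.6899 , p = 1.101e-07
Ancestral vs derived signed-rank (aa): T = -74.5 , p = 4.578e-05
```

Reading the output: the cohort profile shows the fraction of pairs with a
significant relative-rate test rising with K<sub>S</sub> (the test gains
power as mutations accumulate, and this simulation couples the asymmetry
factor to age); the stepwise regression retained K<sub>S</sub> as a
predictor of per-site asymmetry with a positive coefficient (0.218); at
n = 30 the weaker span and relocation effects are not retained — they are
at n = 130+. The negative signed-rank T says derived copies accumulated
more unique sites than ancestral copies. `write_report(report, dir)`
writes `pair_features.tsv`, `report.json` and `report.txt`.

A thin command-line wrapper is included at `inst/cli/paralogasym.R`
(`validate`, `simulate`, `run`).

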