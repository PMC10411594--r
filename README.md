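# asereg

Cis- and trans-regulatory analysis of allele-specific expression in
reciprocal crosses.

## The problem

When two inbred lines (A and B) are crossed in both directions
(A♀ × B♂ and B♀ × A♂), the F1 hybrids carry one allele from each line,
and RNA-seq reads can be assigned to the parental allele they came from.
This makes regulatory variation directly observable: a *cis*-acting
variant (promoter, enhancer) changes the expression of its linked allele
only, producing allelic imbalance inside the hybrid, while a
*trans*-acting variant (e.g. a transcription-factor difference) acts on
both alleles equally, producing divergence between the parental lines
without hybrid imbalance. Reciprocal directions additionally separate
parent-of-origin effects (imprinting-like) from maternal-genotype effects
(maternal deposits, mitochondria). `asereg` implements the statistical
machinery for this design — as used for sex- and tissue-resolved studies
of regulatory divergence in *Drosophila* heads and gonads — for anyone
with allele-resolved count tables from parental and reciprocal hybrid
samples.

## The models

**Allelic GLM.** For each gene, within one sex × tissue × cross, the
allele-level counts *E* (two alleles × two reciprocal directions × two
replicates = 8 observations) are modelled as negative-binomial with log
link and log library-size offsets:

    E ~ mu + CR + PO + MG + error

with binary codings CR = 0/1 for allele A/B, PO = 0/1 for a
maternally/paternally inherited copy, and MG = 0/1 for the A×B / B×A
direction. Each effect is tested by a likelihood-ratio test against the
model dropping that term, with the gene's dispersion estimated once on
the full model (Cox–Reid adjusted profile likelihood, shrunk toward a
common dispersion) and held fixed across the nested fits; the *deviance
explained by CR* — deviance(PO+MG model) − deviance(full model) — is the
per-gene measure of cis-effect strength. Significance is called at
Benjamini–Hochberg FDR < 0.05. Sex- (tissue-) dependent cis effects are
modelled as `E ~ mu + CR + sex + CR*sex`, and pure allelic *reversal* by
recoding the allele indicator to be contrary in the two sexes
(`E ~ mu + CRsex`).

**Cis/trans classification.** Three tests — parental differential
expression (P), hybrid allelic imbalance (H), and a trans test (T,
Fisher's exact test comparing the parental ratio P1:P2 with the hybrid
allelic ratio A1:A2 on summed counts) — combine into seven categories:
conserved, cis-only, trans-only, cis+trans, cis×trans (the ratio
log2(P1/P2)/log2(A1/A2) ≷ 1 separating the last two), compensatory, and
ambiguous.

**Inheritance mode.** Comparing hybrid overall expression with the two
parents under a 1.25-fold cutoff (genes with ≥ 1.5-fold parental
divergence and ≥ 20 summed parental reads): additive (between the
parents), dominant (matches exactly one parent), overdominant /
underdominant (beyond both), conserved.

**Comparisons.** Sex bias SB = log2((exp_F + 1)/(exp_M + 1)) binned into
MS/MB/UB/FB/FS at −1, −0.3, 0.3, 1; Mann–Whitney U comparisons of
CR-deviance across bins; two-proportion z and Fisher tests for category
proportions; chi-square tests on shared-CR contingency tables between
samples; tissue-specificity shares and Spearman association.

Every inference stage is driven by a negative-binomial simulator
(`simulate_ase()`) with exact per-gene ground truth (cis, trans, PO, MG,
sex-reversal, inheritance mode, dispersion), so sensitivity, FDR and
classifier behaviour are verifiable without any external data.

## Worked example

```r
library(asereg)

# one reciprocal cross, 800 genes with known regulatory structure
sim <- simulate_ase(sim_config(n_genes = 800, seed = 11))

# per-gene E ~ mu + CR + PO + MG models, one model per sex x tissue
cr <- run_cr_glm(sim$hybrid, sim$hybrid_obs_tpm, analysis_config())
aggregate(fdr_CR ~ sex + tissue, cr,
          function(f) round(100 * mean(f < 0.05, na.rm = TRUE), 1))
#>   sex tissue pct_CR_genes
#> 1   F  gonad         24.0
#> 2   M  gonad         23.4
#> 3   F   head         23.8
#> 4   M   head         23.8
```

About 24% of genes are called cis-regulated in each scope — matching the
23% of simulated genes that carry a cis component (10% cis-only plus the
cis+trans, cis×trans, compensatory and sex-reversed classes), detected
near-perfectly at the simulator's default read depth.

```r
ct <- run_cistrans(sim$parental, sim$hybrid, analysis_config())
ct$proportions[ct$proportions$sex == "F" & ct$proportions$tissue == "head", ]
#>        category proportion n_genes
#>       conserved    0.57875     800
#>        cis_only    0.12625     800
#>      trans_only    0.08875     800
#>  cis_plus_trans    0.03625     800
#>    cis_by_trans    0.01375     800
#>    compensatory    0.04500     800
#>       ambiguous    0.11125     800

inh <- run_inheritance(sim$parental_tpm, sim$hybrid_tpm, sim$parental,
                       analysis_config())
inh$proportions[inh$proportions$sex == "M" & inh$proportions$tissue == "head", ]
#>           mode proportion n_eligible
#>       additive 0.21142857        175
#>       dominant 0.66285714        175
#>   overdominant 0.05142857        175
#>  underdominant 0.07428571        175
```

The category proportions track the simulated class mix (e.g. 12.6%
called cis-only against 10% simulated, the excess coming from other
cis-carrying classes whose trans component went undetected), and the
inheritance proportions are reported over the 175 genes passing the
parental-divergence and read-sum eligibility filters.

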