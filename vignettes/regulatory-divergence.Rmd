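---
title: "Models and design choices in asereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in asereg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asereg)
```

This vignette documents the statistical models implemented in `asereg`,
the assumptions behind them, and the choices made where the underlying
methodology leaves room for interpretation. It is the package's design
record: everything here is either a model statement or a documented
decision, not an empirical claim — the quantitative behaviour of the
pipeline is established by the test suite and `scripts/acceptance.R`,
which compute every number they assert.

## The experimental design and its data model

The unit of analysis is a reciprocal cross between two inbred lines, A
and B. Four sample groups exist per sex × tissue: the two parental lines
(homozygous, one overall count per gene) and the two reciprocal F1
directions A×B and B×A (mother listed first), where every RNA-seq
library yields two observations per gene, one per parental allele. With
2 replicate libraries, a sex × tissue × cross scope holds 8 allelic
observations, the size at which all per-gene models operate. Counts are
accepted as nonnegative reals, because upstream allele-assignment
tools produce estimated (fractional) counts; the negative-binomial
likelihood is evaluated through `lgamma` and does not require integers.
Only where an exact test needs integers (Fisher's trans test) are counts
rounded, half-up.

Genes carry two flags: `is_autosomal` (all analyses use autosomal genes
only, since X-linked genes are hemizygous in males) and `has_min_snvs`
(whether the upstream assignment had enough exonic variants to be
reliable). Both are metadata: the package does not re-derive them.

## The allelic GLM

Within a scope, each gene's allelic counts are modelled as

$$E \sim \mu + \mathrm{CR} + \mathrm{PO} + \mathrm{MG} + \varepsilon$$

a negative-binomial GLM with log link, where CR is 0/1 for allele A/B,
PO is 0/1 for maternally/paternally inherited copies, and MG is 0/1 for
the A×B/B×A direction. The design is orthogonal: each covariate is
balanced with respect to the other two, so the three effects are
separable at 8 observations. The offset is the natural log of the
sample's library size (the sum of counts over analyzed autosomal genes,
shared by the two allele rows of a sample). Normalizing the two allele
columns separately would absorb genome-wide allelic imbalance into the
offsets and silence the CR term, so the per-sample convention is the
only defensible one. An important consequence of offset normalization:
MG effects are estimated *relative to the library total*, so a
hypothetical maternal-genotype effect acting uniformly on every gene is
not identifiable — only gene-specific MG deviations from the genome-wide
behaviour are. The same holds for any count-based differential
expression analysis.

### Dispersion

Eight observations cannot support a free per-gene dispersion, so the
package uses a three-layer policy:

1. a **per-gene estimate** by Cox–Reid adjusted profile likelihood
   (the $\tfrac12 \log\det X^\top W X$ penalty removes most of the
   downward bias of plain ML at 4 residual degrees of freedom);
2. a **common dispersion** for the scope, maximizing the CR-adjusted
   profile likelihood summed over genes (an evenly spaced subsample of
   up to 400 genes caps the cost);
3. **empirical-Bayes shrinkage** of the per-gene value toward the common
   one, weighted as residual df : `prior_df` (default 20 — deliberately
   strong, since the per-gene information is 4 df).

The common value is the maximizer of the summed adjusted profile
likelihood rather than a trimmed mean of per-gene estimates: during
development the trimmed mean proved biased low at this design size
(per-gene estimates are right-skewed), which made the likelihood-ratio
tests anticonservative, while the profile-based common value keeps the
raw null p-values close to uniform. `common_dispersion_only = TRUE`
forces the shared value for every gene.

### Testing and the deviance explained by CR

Each effect is tested by a likelihood-ratio test of the full model
against the model dropping that term, referred to $\chi^2_1$. The
dispersion is estimated once on the full model and **held fixed across
the nested fits**; this guarantees the nested-deviance inequality, so
the *deviance explained by CR* — deviance(PO+MG) − deviance(full) — is
nonnegative by construction and equals the CR test statistic. It is the
package's per-gene measure of cis-effect strength, comparable across
genes within a scope. If a numerical fit ever leaves a negative
difference, the full model is refitted starting from the reduced
solution and the larger likelihood kept. Benjamini–Hochberg FDR is
applied per effect (CR, PO, MG separately) within each scope, matching
the framing of one model per sex × tissue × cross.

Degenerate genes are handled explicitly rather than crashed on: a gene
with all-zero counts in one allele class receives a half-count
continuity adjustment (flagged in the output); all-zero genes, scopes
with a single CR level, fewer than 6 observations, or rank-deficient
designs are skipped with a reason string.

### Interaction and reversal models

Sex-dependent cis effects are tested on the 16 observations spanning
both sexes of a tissue × cross as `E ~ mu + CR + sex + CR*sex` (LRT on
the interaction term): significance captures sex differences of either
magnitude or direction. Directional reversal is tested separately with
`E ~ mu + CRsex`, where CRsex equals CR in females and 1 − CR in males:
a shared-direction effect cancels in this column by symmetry, so
significance specifically indicates opposite allelic usage. The same
machinery applies to tissues. The reversal model intentionally contains
no main effects — that is its defining property — so a strong sex main
effect (sex-biased expression) or the unmodelled CR main effect of a
shared cis signal ends up in the estimated dispersion, making the test
conservative for non-reversed genes. Genes must pass the expression
filter in each factor level separately.

## Cis/trans divergence classification

Three tests per gene, all at BH-FDR < 0.05 within scope:

* **P** — parental differential expression, NB-LRT of the line effect on
  overall parental counts (same engine, library-size offsets);
* **H** — hybrid allelic imbalance, NB-LRT of the allele effect with a
  per-sample covariate pairing the two alleles of each library;
  reciprocal directions pooled as replicates by default (a
  `pool_reciprocals = FALSE` mode analyses them separately);
* **T** — trans test: Fisher's exact test on
  `[[P1, P2], [A1, A2]]`, the parental versus hybrid-allelic summed
  counts. A significant difference between the two ratios indicates a
  trans component.

The P and H tests use the package's own NB-LRT engine rather than an
external differential-expression package; the inferential role is
identical and the engine is shared with the allelic GLM, which keeps the
pipeline self-contained and its calibration uniform.

The seven-way decision table is total over the eight significance
combinations: conserved (none), ambiguous (exactly one), cis-only
(P∧H∧¬T), trans-only (P∧¬H∧T), compensatory (¬P∧H∧T), and for P∧H∧T the
ratio $\log_2(P_1/P_2)/\log_2(A_1/A_2)$ splits cis+trans (≥ 1, same
allele favoured) from cis×trans (< 1). Two boundary conventions are
documented choices: a ratio of exactly 1 goes to cis+trans, and an
undefined 0/0 ratio (both pseudocounted ratios exactly zero — possible
only for tied counts) also goes to cis+trans. Log ratios add a
pseudocount of 0.5 to each summed count; Fisher's test uses the raw
(rounded) counts without pseudocounts.

A caveat inherent to the T test: Fisher's exact test treats the summed
counts as the only source of noise, so replicate-level (biological)
overdispersion inflates its significance. At high depth and appreciable
dispersion it will call trans components that are really replicate
noise, shifting borderline cis-only genes into the joint categories.
This is a property of the method being implemented, kept deliberately;
the simulator makes the behaviour measurable.

## Inheritance mode

Genes are eligible when the parents differ at least 1.5-fold (TPM,
floored at 0.01 to avoid division by zero) and carry at least 20 summed
parental reads. With the 1.25-fold cutoff $c$, lo/hi the smaller/larger
parent, and all comparisons **inclusive**:

* overdominant: $h \ge c \cdot hi$;  underdominant: $h \le lo/c$;
* additive: $c \cdot lo \le h \le hi/c$;
* dominant: within $c$-fold of exactly one parent;
* conserved: within $c$-fold of both.

Boundary points (e.g. $h = c \cdot lo$ exactly) satisfy two definitions
at once; they are resolved in the order above, which makes the rule
total and mutually exclusive — verified exhaustively against a
brute-force oracle on a ~10⁴-point lattice. Parental TPM is averaged
across each line's replicates, hybrid TPM across reciprocals and
replicates, averaging normalized TPM (not raw counts). Inclusive
comparisons are used because the methodology leaves strictness
unstated; the direction of the convention only affects measure-zero
boundary inputs.

## Sex bias and comparison statistics

SB = log₂((exp_F + 1)/(exp_M + 1)) with exp_F/exp_M the mean TPM across
the female/male samples of a tissue × cross. Bins: MS (SB < −1), MB, UB,
FB, FS (SB > 1) with boundaries at −1, −0.3, 0.3, 1; the printed
open-interval definitions leave boundary values unassigned, so
boundaries go to the **less-biased** side (conservative with respect to
claiming strong bias). Deviance-by-SB comparisons use two-sided
Mann–Whitney U tests: exact enumeration when both groups have ≤ 20
observations without ties, normal approximation with tie correction and
no continuity correction otherwise. The two-proportion z test uses the
pooled variance without continuity correction; shared-CR overlap uses a
2×2 χ² without continuity correction (the tests are named without
corrections in the methodology being implemented). Degenerate inputs
return explicit NA/1 values rather than errors: a 0/0 pooled proportion
gives z = 0, p = 1; a zero margin gives an NA χ² with a reason;
all-zero tissue profiles give NA specificity.

## The synthetic-data generator

The simulator is first-class, tested code. It emulates the study design
exactly: one cross, both reciprocal directions, 2 sexes × 2 tissues × 2
replicates, NB counts for hybrid alleles and parental overall
expression, plus TPM tables. The generative model (closed form in
`expected_means()`): line A parental mean $b \cdot s$, line B
$b \cdot s \cdot 2^{c+t}$, hybrid alleles share
$b \cdot s \cdot 2^{t/2} \cdot 2^{mg\,[BxA]}$ with allele B further
multiplied by $2^{c}$ and the paternal copy by $2^{po}$; $s = 2^{\pm
sb/2}$ is the sex multiplier. Placing the hybrid trans environment at
the geometric midpoint of the parental backgrounds makes trans-only
genes parentally divergent but allelically balanced — exactly the
signature the classifier keys on.

Choices a user should know:

* **Exact allocation.** Effect classes and inheritance modes are
  apportioned by largest remainder, not sampled, so recovery rates have
  fixed denominators. Conserved-inheritance slots go preferentially to
  genes whose parental divergence is below 1.2-fold, because a hybrid at
  the midpoint of clearly divergent parents is additive by definition;
  the remaining modes are assigned by a seeded permutation.
* **Dispersion default**: log-normal with median 0.005 (BCV ≈ 7%),
  sdlog 0.5. The reference design pools ~20 individuals of an isogenic
  line per library, so individual-level biological variation (BCV ~0.25)
  is averaged down by the pool and library noise dominates; 0.005 sits
  between pure technical replication (~0.01 BCV reference points) and
  unpooled isogenic individuals (~0.1). Variance = μ + dispersion·μ².
* **Base means**: log-normal, median 200 counts, sdlog 1; `depth = NULL`
  leaves expected totals unscaled so a stated base mean is the realized
  expected count (a `depth` can be set to rescale all means per sample).
* **Effect sizes**: |log₂ fold changes| drawn N(1, 0.25); classes fix
  the sign structure (compensatory genes have trans = −cis exactly;
  sex-reversed genes have cis_F = −cis_M).
* **Hybrid overall expression** is generated from the gene's inheritance
  mode (midpoint / one parent / 1.5× beyond the extreme parent), not as
  the sum of the allelic counts, so the inheritance classifier has its
  own clean ground truth independent of the allelic machinery.
* **TPM** scales each sample to 10⁶ with equal gene lengths.

What the simulator does **not** emulate — and hence what passing
recovery tests do not establish about real data: no gene-length or
GC/mapping bias, no allele-assignment errors from too few variants (the
`has_min_snvs` flag is always true), no correlated noise across genes,
no composition-realistic class mixes (classes are independent of
expression level), and TPM composition effects only insofar as the class
mix creates them — note that when a large fraction of genes carries
strong one-line effects, per-sample TPM denominators diverge between
lines and parent/hybrid TPM comparability degrades, a property real TPM
shares.

## Problem sizes of the verification runs

The acceptance checks use 5,000 all-null genes (base mean 200,
dispersion 0.1) for type-I calibration; 2,000 genes with 10% pure cis at
|log₂fc| = 1 and base mean 500 for recovery through the GLM and the
cis/trans pipeline; 1,000 genes (300 reversed, 300 shared, 400 null) for
reversal specificity; a 2,000-gene default-configuration run for
generative-model agreement; and a ~10⁴-point lattice for the inheritance
rule. These sizes keep every stage's Monte-Carlo error well below the
margins being asserted while the full suite runs in minutes on one CPU.

## Known limitations

* The χ²₁ reference for the LRT at 8 observations is asymptotic; with
  the dispersion policy above the raw null p-values are close to, but
  not perfectly, uniform (slightly anticonservative in the far tail).
* Fisher's trans test ignores replicate-level overdispersion (see
  above).
* TPM-based stages (inheritance, sex bias) inherit TPM's composition
  sensitivity.
* The package classifies regulatory categories; it does not decompose
  variance into cis and trans contributions.
* Missing samples are supported down to 6 observations per gene and
  scope; below that genes are reported as skipped rather than fitted.
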