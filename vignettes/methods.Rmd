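---
title: "Methods: models, conventions and design choices in sexbiasevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in sexbiasevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexbiasevo)
```

# Scope

`sexbiasevo` analyses sex-biased (SB) gene expression across a species
phylogeny from strain-replicated bulk RNA-seq counts: it calls male-biased
(MB), female-biased (FB) and unbiased (UB) genes per species and body part,
traces the conservation and turnover of sex bias on a rooted species tree,
classifies the male/female expression changes underlying lineage-specific
gains and losses as concordant or opposing, tests for directional selection
on expression with the divergence-to-polymorphism statistic Δx, and relates
sex bias to tissue specificity (τ) and chromosomal location. A
negative-binomial simulator with planted truth backs every stage with
end-to-end validation.

The intended design is a multi-species panel of inbred (isofemale) strains,
two sexes and two body parts (head and body), with one RNA-seq library per
strain x sex x body part, quantified against CDS models so that a single
CDS length per gene supports TPM normalisation across species.

# Quantification and filtering

**TPM.** Counts are divided by CDS length (bp) and rescaled per sample to
sum to $10^6$ (`compute_tpm()`). The TPM denominator uses *all* genes in the
supplied matrix — restricting it to a curated ortholog subset would make
TPM values depend on the curation, which is undesirable for a reusable
tool; users who want ortholog-restricted TPM can subset the counts first.

**Expressed-gene rule.** A gene is analysed in a species x body-part
stratum when its mean TPM over strains reaches a threshold (default 0.5) in
at least one sex (`filter_expressed()`). This deterministic rule replaces
the data-adaptive independent filtering used by black-box differential
callers: it is reproducible from the text of a methods section and makes
the analysed set independent of the test statistics. Mean TPM per
species/sex/body part is always the arithmetic mean over strains (one
replicate each).

**Expression divergence** between two sample groups is
$1 - \rho_{\mathrm{Spearman}}$ of per-gene mean TPM, bounded in $[0, 2]$;
constant vectors yield a flagged `NA` rather than an arbitrary value.

# The sex-bias caller

Within one species and body part, counts are modelled per gene as negative
binomial with a log link on sex and median-of-ratios size factors as
offsets, a deliberate re-implementation of the standard NB Wald approach
with every step stated explicitly:

* **Size factors** (`size_factors()`): median across all-positive genes of
  the ratio to the per-gene geometric mean, rescaled to geometric mean 1.
  The rescaling makes factors comparable across strata; it does not change
  any test statistic because factors enter only as offsets.
* **Dispersion**: per-gene method of moments on size-factor-normalised
  counts after removing the male/female mean difference,
  $\hat\alpha = \max\{(s^2 - \bar m)/\bar m^2, 10^{-8}\}$ with $s^2$ on
  $n-2$ degrees of freedom. There is no empirical-Bayes shrinkage, no
  outlier refitting: the package's validation targets are error control
  and recovery on its own generator, not call-by-call identity with any
  external tool, and a floor of $10^{-8}$ keeps the Poisson limit stable.
* **Estimation**: with dispersion fixed, the two-group NB MLE with offsets
  reduces to one 1-D score equation per sex,
  $\sum_j (y_j - s_j m)/(1 + \alpha s_j m) = 0$, solved by damped Newton
  iteration vectorised across genes; the Wald variance of
  $\log(m_M/m_F)$ is $1/I_F + 1/I_M$ with
  $I = \sum_j \mu_j/(1+\alpha\mu_j)$. This is mathematically the same
  model as an NB GLM of counts on sex (the unit tests verify agreement
  with an independent `glm` fit at fixed dispersion) but runs in
  milliseconds for thousands of genes.
* **Reference distribution**: the Wald statistic uses a *t* reference with
  $n - 2$ degrees of freedom by default. With a plug-in moment estimate of
  the dispersion and 10–16 libraries per stratum the statistic behaves
  like a *t*, not a normal; a small-sample power analysis during design
  showed the normal reference inflates the type-I rate (about 0.08 at
  nominal 0.05) while the *t* reference is calibrated (about 0.05). The
  normal reference remains available via `p_reference = "normal"`.
* **Decision rule**: Benjamini–Hochberg q-values within the analysed set
  of the stratum; MB iff $q < 0.05$ and $\log_2\!\mathrm{FC} > 0$, FB for
  the negative sign, UB otherwise, `NA` when unanalysed or all-zero.

**Sign convention.** `log2fc` is male relative to female everywhere:
positive means male-biased. All outputs and the MB/FB labels follow this
single convention.

A gene all-zero in one sex still yields a call: its group mean is floored
at $10^{-8}$, which produces an extreme fold change with a huge standard
error and therefore a conservative (non-significant) test rather than a
crash. Genes all-zero in both sexes are `NA`. Raw (unshrunken) fold
changes are used throughout, including for bias-magnitude analyses.

# Conservation, turnover and polarization

**Sharing spectrum** (`sharing_spectrum()`): restricted to genes
classifiable (non-`NA`) in *every* species of a body part, genes are
switchers (MB in at least one species and FB in at least one),
same-direction SB in $k = 1..n$ species, or UB in all. The same
eligibility rule is reused for turnover polarization, since a gene that
cannot be classified in some species cannot support a claim about the
branch separating that species.

**Polarization** (`polarize_turnover()`): a branch carries an event for a
gene when all tips below it share one category, all tips outside share
another, and the two differ — gain when the outside is UB, loss when the
lineage is UB, switch when both are sex-biased. The two root-incident
branches define a single bipartition that cannot be polarized without an
external outgroup; it is emitted once as `unpolarized_root_change`,
attributed to the smaller root-adjacent clade (ties broken by newick tip
order; only the single-tip-outgroup case arises on the default topology).
The implementation is validated against a brute-force enumeration of the
verbal rule over all $3^6 = 729$ category vectors on the six-species tree.

**Ancestral expression** (`asr_bm()`): joint maximum-likelihood states
under Brownian motion, i.e. each internal node is the precision-weighted
(1/branch-length) average of its neighbours, solved as one sparse linear
system per sex/body part for all genes simultaneously. This equals the GLS
solution under the BM covariance; tests verify agreement with a dense
Laplacian-partition oracle to $10^{-8}$ and with a numerical optimiser.

Reconstruction runs on the **raw mean-TPM scale** by default. BM on a
positive quantity can reconstruct non-positive ancestors; such nodes
propagate `NA` into the change statistic rather than being floored at an
arbitrary epsilon, so no pseudo-ancestor is ever invented. An
`asr_scale = "log2"` option reconstructs on $\log_2(\mathrm{TPM}+1)$ for
users who prefer a scale on which BM is better behaved; it is off by
default to keep the headline statistic exactly
$\log_2(\mathrm{TPM}_{Focal}/\mathrm{TPM}_{Anc})$ on the stated scale.

The ancestor of a terminal branch is the parent node of that branch. Only
terminal-branch (species-specific) gains and losses feed the concordance
analysis; clade-level events are reported in the event table but not
paired with changes, because a multi-species clade has no single focal
TPM.

# Concordance of male and female changes

For each species-specific gain or loss, the pair
$(\Delta_f, \Delta_m) = (\log_2 F/F_{anc}, \log_2 M/M_{anc})$ is placed in
a quadrant: **ii** both positive, **iii** both negative (the concordant
pair), **i** female up / male down, **iv** female down / male up. The
published figure this convention mirrors constrains only which quadrants
are concordant, not their numbering; the convention chosen here is printed
in every output header so downstream consumers never have to guess. Exact
zeros are excluded (`NA`) rather than assigned — they have measure zero
under the generator and any assignment would be arbitrary.

A change is **large** when $\max(|\Delta_f|, |\Delta_m|) \ge$ 1 (head) or
2 (body): the max-of-sexes rule is the symmetric choice when no single
sex is privileged. Summaries report quadrant counts, concordant fractions
(overall, gains, losses, large, small), per-species Spearman
$\rho(\Delta_m, \Delta_f)$ for gains and losses, a 2x4 head-vs-body
chi-squared on quadrant counts, a rank test comparing gain vs loss
correlations and a paired (by species) rank test comparing body parts.

# The Δx selection statistic

Per gene, sex and body part, with per-strain log2 expression $X_F$ in the
focal species ($m$ strains) and $X_R$ in the reference species:

$$d = \frac{\overline{X_F} - \overline{X_R}}{\overline{X_F}}, \quad
  r = \frac{\max X_F - \min X_F}{\overline{X_F}}, \quad
  f = \frac{mN - 1}{mN - m}, \quad \Delta x = \frac{d\,f}{r}$$

with $N$ the study's reference strain count (default 5, the most common
strain number in the emulated design). $|\Delta x| > 1$ flags putative
directional selection — divergence from the outgroup exceeding
within-species polymorphism — with $\Delta x < -1$ indicating
down-regulation in the focal species. Note $\overline{X_F}$ cancels
between $d$ and $r$, so $\Delta x$ is driven purely by the
divergence-to-range ratio; it is invariant to strain order and to global
scaling of the log values (both asserted as metamorphic tests), and $f \to
1$ as $N \to \infty$.

Inputs are $\log_2(\mathrm{TPM} + 1)$ per strain; the pseudocount is
configurable and recorded in the run report, since a zero-handling rule is
needed on the log scale and none is canonical. Genes are eligible when
analysed in the focal species and expressed in at least one reference
strain; a focal mean $\le 0$ (possible on the log scale) or a zero range
yields `NA` with a reason code (`nonpositive_mean`, `zero_range`) rather
than a fabricated value. The outgroup itself receives no Δx.

Enrichment of selected genes across MB/FB/UB uses observed-vs-expected
chi-squared with expectations proportional to category sizes; categories
with an expected selected *or* non-selected count below 5 are excluded
with a logged note. Between-sex comparisons use a Welch t-test on
$|\Delta x|$ and Spearman correlation of signed values over complete
gene pairs.

# Tissue specificity and chromosomal location

$\tau = \sum_i (1 - \hat x_i)/(n - 1)$ with $\hat x_i = x_i/\max x$: 0 for
uniform positive expression, 1 for single-tissue expression. The default
transform is $\log_2(x+1)$ before $\tau$ — expression atlases are heavily
right-skewed and the log transform keeps $\tau$ from saturating — while
`transform = "none"` preserves the raw-index arithmetic (e.g.
$\tau([1, 0.5]) = 0.5$). All-zero profiles give `NA`; the top tissue
breaks ties alphabetically. $\tau$ is computed once per gene from a single
reference tissue matrix and joined to all species.

X-vs-autosome tests exclude dot-chromosome genes (an ancestral X, Muller
element F) and unknowns from both classes, then compare observed category
counts on the X and on the autosomes against expectations from the overall
category proportions, separately per class.

# The synthetic-data generator

`simulate_study()` emulates the targeted study design: 6 species on the
tree `(((((mel:2,sim:2):8,suz:10):5,ana:15):15,sub:30):20,imm:50)` (units:
My), strains 8/6/6/5/5/5 (so the most common strain count is 5, matching
the Δx default $N$), two sexes x two body parts, one library per
strain/sex/body part, and NB counts with dispersion 0.05
(variance $= \mu + \alpha\mu^2$).

Per gene and body part a log2 baseline evolves by Brownian motion along
the tree. The BM rate defaults to $\sigma^2 = 8\times10^{-4}$ per My,
fixed during a single design-time calibration so that (i) simulated
between-species divergence ($1-\rho \approx 1.6\%$ for the most distant
pair) sits at the conservative low end of the divergence range such
studies report (roughly 1–12% across comparisons), and (ii)
within-species polymorphism dominates neutral drift for most genes —
the regime in which the $|\Delta x| > 1$ flag is meaningfully specific
(false-positive rate $\approx 0.09$ on unshifted genes at defaults).
Larger rates are available for stress-testing but make neutral drift
itself trip the selection flag, which is a property of the statistic, not
a bug.

Planted structure:

* **Sex bias**: fractions of genes get an ancestral MB/FB category; the
  sexes then split the planted effect ($\pm$`sex_effect_log2fc`/2,
  default 2 log2 units total).
* **Turnover**: `turnover_spec()` plants per-sex magnitudes on a branch;
  true categories are derived from the realized male-minus-female
  difference (threshold: half the sex effect) and the event list is
  validated against them, so truth tables and the polarization rule are
  consistent by construction. One event per gene per body part, which
  rules out nested-event ambiguity. `plant_terminal_events()` spreads
  events over the polarizable tips with a chosen concordant fraction;
  concordant events add a shared downward shift (both sexes move the same
  way, magnitudes $\ge 1$ log2 unit), opposing events split the effect
  antisymmetrically — mirroring the empirical observation that gains are
  often concordant and down-regulated.
* **Selection**: `selection_spec()` shifts one species/sex by a log2
  amount; the default `default_selection_shift()` is 3x the expected
  within-species range ($3 \times 2.326\sqrt{\alpha}/\ln 2 \approx 2.25$
  at dispersion 0.05), making $|\Delta x| > 1$ attainable by construction.
* **Tissue profiles** are Dirichlet draws whose concentration decreases
  with planted bias magnitude, coupling $\tau$ to sex bias; **chromosome
  labels** are drawn with a configurable X fraction, a small dot fraction,
  and an odds multiplier for body-FB genes on the X.

Library sizes are log-uniform over 0.5–2x of $10^6$ to exercise size-factor
normalisation. Identical seeds give bit-identical studies.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: no batch or lane effects, no strain-level
random effects beyond NB noise (strains are exchangeable replicates), no
gene–gene correlation, no read-level artefacts (multi-mapping, isoform
ambiguity), no expression-level dependence of the BM rate, and tissue
profiles that are independent across genes. Recovery rates on this
generator are best-case figures for the inferential machinery, not
field performance estimates.

# Problem sizes and runtime choices

Validation simulations use 2,000 genes — large enough that fractions
(type-I rate, FDP, recovery) have Monte-Carlo error well inside the
asserted bands, small enough that the full suite and the acceptance script
each run in well under a minute of compute per scenario. Event-recovery
scenarios plant 300+ events so concordant fractions are estimated to a few
percentage points. The full pipeline on a 2,000-gene, 140-library study
runs in a few seconds on one core; the NB caller is the dominant cost and
is vectorised across genes.

# Known limitations

* The NB stage is intentionally simpler than shrinkage-based callers; at
  very low counts or two strains per sex its moment dispersion is noisy,
  and power comparisons with empirical-Bayes machinery are out of scope.
* BM reconstruction on the raw TPM scale can produce non-positive
  ancestors for strongly right-skewed genes; these propagate `NA` (the
  fraction is reported via the `valid` flag) instead of being imputed.
* Polarization requires binary rooted trees; polytomies must be resolved
  upstream.
* Δx has no per-gene significance machinery; $|\Delta x| > 1$ is a
  descriptive flag whose specificity depends on the divergence-to-
  polymorphism regime, as the generator's rate parameter makes explicit.
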