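---
title: "Methods: comparative lipoprotein proteomics and an MR proteome screen"
author: "lipoproteomr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative lipoprotein proteomics and an MR proteome screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipoproteomr)
```

## Scope and scientific setting

Lipoprotein(a) — Lp(a) — is an LDL-like particle carrying one apolipoprotein B
molecule plus apolipoprotein(a) bound through a disulphide bridge. Two
questions drive this package:

1. **Which proteins ride on Lp(a) rather than LDL?** Answered with label-free
   quantitative proteomics of particle fractions isolated *from the same
   subjects* (a paired design), plus targeted parallel-reaction-monitoring
   (PRM) quantification of selected proteins (apoB, PCSK9) against
   heavy-isotope-labelled peptide standards.
2. **Does lifelong exposure to elevated Lp(a) or LDL cholesterol reshape the
   plasma proteome?** Answered with a two-sample Mendelian-randomization (MR)
   screen over per-protein GWAS summary statistics.

Raw mass-spectrometry and cohort genotype data for studies of this design are
typically not redistributable, so the package pairs every analysis stage with
a seeded generator that draws synthetic inputs with the statistical structure
the stage assumes. Everything upstream of protein-level intensities (spectral
search, FDR control of identifications, chromatographic peak picking) and
everything requiring external services (pathway enrichment, protein-network
databases) is out of scope.

## Label-free differential enrichment (`lfq_diff`)

### Model and procedure

For protein $g$ in sample $s$ the observed intensity is modelled as
log-normal: $\log_2 x_{gs} = \mu_{gc(s)} + \varepsilon_{gs}$,
$\varepsilon \sim N(0, \sigma^2)$, where $c(s)$ is the fraction (Lp(a) or
LDL) and $\mu_{g,\mathrm{LPA}} - \mu_{g,\mathrm{LDL}}$ is the log2
enrichment. The pipeline applies, in order:

1. **Quantifiability filter** on the *pre-imputation* mask: a protein must be
   observed in at least a fraction 2/3 of the replicates of one condition
   (4 of 6 pairs; 6 of 9 in a replication phase) and be supported by at least
   2 distinct peptides. The conventional "67%" is the printed rounding of
   2/3; a literal `ceiling(0.67 * 6) = 5` would contradict the 4-of-6 intent,
   so the implementation uses `ceiling(frac * n)` with a `1e-9` tolerance and
   `frac = 2/3` by default.
2. **Median normalization**: each sample is scaled multiplicatively so its
   observed median matches the grand median of per-sample medians. The
   reference is arbitrary for inference — any fixed reference yields the same
   paired statistics on the log scale — and only affects reported
   intensities.
3. **First-percentile imputation**: missing cells become the 1st percentile
   of that sample's observed intensities, the standard proxy for
   below-detection signal when missingness concentrates at low abundance.
   Percentile definition: linear interpolation between order statistics
   (R's type-7 quantile), declared here because protocols rarely state it.
   The imputed mask is carried on the object so that a second normalization
   pass ignores imputed cells — this makes normalize-then-impute idempotent.
4. **Paired testing**: the reported effect is the natural-scale ratio
   $\bar x_{\mathrm{LPA}} / \bar x_{\mathrm{LDL}}$; the test is a paired
   two-sided $t$ on per-subject **log2** differences. Protocol descriptions
   of "a test on the ratio" are ambiguous between raw and log scales; log2
   is the defensible default (multiplicative noise, symmetric nulls) and
   `log_transform = FALSE` preserves the literal raw-scale reading.
5. **Empirical-Bayes moderation**: per-protein variances are shrunk toward a
   scaled-inverse-chi-square prior $s_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$.
   The hyperparameters are estimated by matching the mean and variance of
   $\log s_g^2$ to the theoretical log-F moments via digamma/trigamma
   equations; the trigamma inverse is solved by Newton iteration (75-step
   cap, relative tolerance $10^{-10}$). When the spread of log variances
   does not exceed sampling noise, $d_0 = \infty$ (complete shrinkage) — a
   valid fit, not an error. The moderated statistic is
   $t_g = \bar d_g \big/ \sqrt{s^2_{g,\mathrm{post}} / n}$ with
   $s^2_{g,\mathrm{post}} = (d_0 s_0^2 + \nu s_g^2)/(d_0 + \nu)$ on
   $d_0 + \nu$ degrees of freedom.
6. **FDR control**: Benjamini–Hochberg step-up, implemented directly
   ($q_{(i)} = \min_{j \ge i} m\, p_{(j)}/j$, capped at 1; ties share the
   rank value) and cross-checked in the tests against a brute-force oracle
   and `p.adjust`.
7. **Replication logic**: a protein replicates iff it meets the discovery
   criterion (default: moderated $q < 10^{-4}$, the stringent threshold
   conventional for discovery-phase calls; configurable), the replication
   $P < 0.05$, and the enrichment direction (ratio vs 1) agrees.

### Degenerate inputs

Constant paired differences have zero variance: the $P$ value is 1 when the
common difference is 0 and the smallest representable positive double
otherwise, with a `zero_variance` flag either way. The same rule applies to
a degenerate moderated posterior (possible only when $d_0 = 0$). A sample
with no observed values is an error naming the sample.

### What the generator emulates — and what a green test establishes

`simulate_lfq()` draws a paired matrix under the model above with logistic
intensity-dependent missingness,
$\Pr(\text{missing}) = \mathrm{logis}(a + b\,\mu)$, defaults $a = 23$,
$b = -1$ against base intensities $\mu \sim N(25, 2)$ on the log2 scale
(MaxQuant-like magnitudes). This yields roughly 20% missing cells
concentrated at low abundance — the regime that justifies first-percentile
imputation. Within-condition coefficient of variation defaults to 0.20
(typical label-free replicate spread); peptide support is $1 +
\mathrm{Pois}(4)$. No spectrum-level structure (m/z, retention time, peak
shape), no correlated proteins, no batch effects, and no
missingness-at-random component are simulated; green tests therefore
establish correctness of the *computation*, not robustness to those realities.

Two calibration caveats are deliberate:

* **Type-I-error calibration is a complete-data property.** Imputation
  injects pseudo-values that violate the paired-$t$ assumptions by design,
  so the null-calibration tests disable missingness. On imputed data the
  null is in fact conservative (imputed-imputed pairs contribute near-zero
  differences).
* **Power and ratio accuracy degrade under censoring.** A truly enriched
  protein whose LDL-side values are left-censored mixes imputed and complete
  pairs; the paired-difference variance inflates several-fold and BH at
  $q < 0.05$ misses it. This is why the full-pipeline smoke check recovers
  ~70–90% of spiked proteins rather than ~100% (the complete-data figure),
  and why spike-ratio accuracy is asserted on complete data only. We kept
  the stated missingness world rather than tuning it to make the smoke
  check pass.

## PRM absolute quantification (`prm_quant`)

Duplicate injections are averaged arithmetically (more than two per key is
an error). Light and heavy areas are then scaled by each record's
internal-standard response relative to the peptide's reference IS area (the
median IS area across that peptide's calibration and sample records jointly
— the per-peptide reading of "median across records", identical for
single-peptide batches); the light/heavy ratio within a record is invariant.

The dilution series (e.g. five heavy-spike levels, 10–1000 fmol/µL for an
apoB peptide in an Lp(a) background) is fitted by ordinary least squares,
optionally 1/x-weighted as is common for dilution series. The fitted curve
serves as a **linearity/QC gate** (default $r^2 \ge 0.98$), not for
calibration: quantification is single-point against the known heavy spike in
each sample,
$$\mathrm{conc} = \frac{\text{light area}}{\text{heavy area}} \cdot
\frac{\text{heavy spike (fmol)}}{\text{loaded mass (µg)}}\,,$$
in fmol per µg of loaded fraction protein. This reading reconciles protocols
that describe both curve construction and per-sample heavy spikes; the
alternative (curve calibration) is a one-line change and was consciously not
taken. A zero light area is a true zero (`detected = FALSE`); a zero heavy
area invalidates the reference and propagates as *missing*, never as zero,
so molar ratios (e.g. PCSK9 per apoB, meaningful because each particle
carries exactly one apoB) are only reported where both terms are detected.
Fraction comparisons use Welch's unequal-variance $t$ with Satterthwaite
degrees of freedom.

## Two-sample MR screen (`mr_screen`)

Instruments are genome-wide-significant variants (strict $P <
5\times10^{-8}$) thinned by greedy LD clumping: repeatedly keep the
most significant remaining variant and discard everything with $r^2 \ge 0.1$
against it. Outcome tables are harmonized to the exposure's allele
orientation: swapped alleles negate the outcome effect; strand-complement
reports are accepted (configurable); palindromic A/T / C/G variants are
aligned by effect-allele frequency when unambiguous frequencies are present
in both tables (ambiguity window 0.5 ± 0.08) and dropped otherwise, with a
logged reason. Drops are data, not errors.

Per variant the Wald ratio is $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
with first-order standard error $\sigma_{Yj}/|\hat\beta_{Xj}|$ — the
strong-instrument approximation that ignores exposure-side uncertainty,
appropriate when instruments are genome-wide significant; a second-order
delta option exists. The fixed-effect inverse-variance-weighted estimate
$$\hat\theta = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j}, \qquad
w_j = \hat\sigma_j^{-2}, \qquad \mathrm{se} = \Big(\sum_j w_j\Big)^{-1/2}$$
is algebraically the zero-intercept weighted least-squares slope of
$\hat\beta_Y$ on $\hat\beta_X$ with weights $\sigma_Y^{-2}$; the tests
verify the identity to $10^{-10}$ relative tolerance. A multiplicative
random-effects correction (`se * max(1, sqrt(Q/(k-1)))`) is available behind
a flag; fixed-effect is the canonical reading of "a meta-analysis of the
Wald ratios". Screening applies a strict Bonferroni rule $P < \alpha/m$.
The Bonferroni denominator is explicit configuration: published aptamer-panel
screens use $m = 3283$ (even though the measured panel is sometimes quoted
as 2994 proteins — the printed divisor wins), and cytokine panels $m = 41$.

`simulate_mr_panel()` draws the two-sample design: the analyst sees
$\hat\beta_X = \beta_X + N(0, \sigma_X^2)$ while outcomes are generated from
the *true* $\beta_X$, $\hat\beta_{Yj} \sim N(\theta \beta_{Xj} + \alpha_j,
\sigma_Y^2)$ with pleiotropic effects $\alpha_j \sim N(0, \tau^2)$
(default $\tau = 0$). Defaults mirror strong published instruments:
$\beta_X \sim U(0.03, 0.3)$ per SD with random sign, $\sigma_X = 0.003$
(large lipid-consortium scale, every instrument genome-wide significant by
construction), $\sigma_Y = 0.025$ (a ~3300-person aptamer pQTL cohort), 26
instruments for an Lp(a)-like exposure and 54 for an LDL-cholesterol-like
one. Twenty percent of outcome rows have alleles flipped to exercise
harmonization; generated allele pairs are non-palindromic so the default
drop rule never fires on clean simulations. Weak-instrument bias, LD
structure, sample overlap and directional pleiotropy are *not* emulated.

## Reporting, PCA and I/O

All tables are TSV with numbers serialized at 17 significant digits, so
write-then-read round-trips are exact; missing cells parse from either empty
strings or `NA`. PCA for the fraction-separation diagnostic runs on log2
imputed intensities, column-centered per protein, *not* variance-scaled
(proteomics convention: abundant proteins keep their weight); component
signs are fixed by making each component's largest-magnitude loading
positive, so scores are reproducible. Volcano emitters order rows by
ascending $P$ then identifier, making outputs byte-stable under a fixed
seed. Configuration files use the flat `key: value` subset of YAML, parsed
internally (no YAML dependency is available in the supported environment);
nesting is intentionally unsupported.

## Known limitations

* First-percentile imputation biases enrichment ratios upward for
  left-censored proteins and costs power at small $n$; see the smoke-check
  discussion above. Alternatives (censored-likelihood models, per-protein
  detection limits) are out of scope.
* The moderation fit assumes a common residual degree of freedom per protein
  when given a scalar `df`; unequal per-protein df are supported but the
  estimator's small-sample behaviour is then less studied.
* The MR screen implements only fixed-effect IVW (plus the multiplicative
  RE variant); MR-Egger, weighted-median and Steiger filtering are
  deliberately excluded.
* Published-table replays validate thresholding and replication logic
  against printed values; printed $P$ values are rounded, so replays count
  threshold passes rather than recomputing $P$ from rounded $\beta$/SE.
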