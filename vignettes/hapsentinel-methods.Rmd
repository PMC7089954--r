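---
title: "Dissecting a risk locus: replicated association, haplotype reconstruction, and sentinel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a risk locus: replicated association, haplotype reconstruction, and sentinel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapsentinel)
```

## The problem

A densely genotyped disease locus in a case-control study of familial
disease typically shows hundreds of correlated associated variants. Three
questions follow. Which associations replicate across independent study
populations? How are the replicating minor alleles organized into ancestral
haplotypes carrying risk or protection? And which individual variants best
detect the *independent* risk signals, so that a compact multivariable risk
model can be built and honestly evaluated?

hapsentinel implements this analysis chain end to end: per-study
single-variant scans, two-study concordance replication, combined analysis
with genome-wide flags, sliding-window haplotype association over phased
genotypes with assembly of ancestral haplotype models, the RISSc recursive
LD-binning algorithm for sentinel selection, bootstrap optimism-corrected
AUC, and genotype modifier tests of age at diagnosis and clinical severity.

## Statistical model

All association tests are unconditional logistic regressions that are
additive on the logit scale (multiplicative odds per minor allele):

$$\operatorname{logit} P(\text{case}) = \alpha + \beta \cdot g + \gamma^\top z,$$

where $g \in \{0,1,2\}$ is the minor-allele dosage (or a haplotype copy
count) and $z$ optional covariates such as ancestry principal components or
a study indicator. Significance is assessed by two-sided Wald tests; 95%
confidence intervals are $\exp(\beta \pm 1.96\,\mathrm{SE})$.

When genotype perfectly predicts status (complete or quasi-complete
separation) the Wald statistic degenerates. Such fits are flagged —
non-convergence, rank deficiency, $|\beta| > 10$, or $\mathrm{SE} > 15$ —
and routed to a penalized-likelihood ratio chi-squared test: both the
dosage model and the slope-constrained null are fitted under the Jeffreys
(Firth) penalty, with the null penalty evaluated on the full-model
information so the two penalized likelihoods are comparable. This yields a
finite P and a finite penalized effect estimate for separated data.

Fits of a single dosage term with at most a categorical covariate are
computed on the aggregated dosage-level binomial likelihood. The MLE and
Wald covariance are identical to the subject-level fit; this is purely a
computational device that makes the window scans tractable.

## Replication and combined analysis

A variant is considered replicated when it is nominally significant
($P \le 0.05$, inclusive) in *both* studies separately with a consistent
direction of effect. Under the global null this retains a fraction of about
$\alpha^2/2$ of variants — the direction-agreement requirement halves
$\alpha^2$ — which the acceptance suite verifies by simulation.

Combined analysis pools subjects across studies. By default a fixed study
main effect is included, guarding against allele-frequency drift between
studies; pooling without the indicator is available
(`combined_scan(..., study_covariate = FALSE)`) since either reading of
"combined data" is defensible. Genome-wide significance uses the
conventional $P \le 5 \times 10^{-8}$, inclusive. Bonferroni thresholds are
reported at one significant figure (e.g. $0.05/765 = 7\times10^{-5}$,
$0.05/242 = 2\times10^{-4}$); false discovery rates use Benjamini-Hochberg.

## Sliding-window haplotype analysis

Windows of width 2–20 adjacent variants move along the (sub)map in
single-variant increments. Within a window, every observed phased allele
string with at least `min_copies` total copies (default 5, below which the
additive model is dominated by separation) is tested one-vs-rest by the
additive model on copy counts, per study; subjects whose phase confidence
falls below 0.9 are excluded from that window. Window haplotypes
concordantly significant in both studies with consistent direction are
retained and re-tested on the pooled data with a study covariate.

Retained window haplotypes are assembled into ancestral haplotype models by
a graph merge. Two retained haplotypes are linked when

1. their windows overlap and their alleles agree on every shared variant;
2. the overlap segment identifies exactly one retained haplotype in each of
   the two windows (the uniqueness condition behind "uniquely aligning");
3. their total copy counts are similar (the smaller at least half the
   larger) — carrier continuity. The same ancestral haplotype is detected
   with nearly the same frequency in overlapping windows, whereas a rare
   compound haplotype sharing an allele run with a common one is not the
   same object and must not be chained into it;
4. the union of the two partial models assigns a single allele to every
   variant. Links are processed longest-overlap first in a canonical order,
   so assembly is deterministic and independent of input row order;
   conflicting links are recorded as ambiguous and skipped.

Each connected component becomes a model: an ordered set of (variant,
required allele) pairs, its member windows, and the windows of peak effect
size ($\arg\max |\log \mathrm{OR}|$) and peak significance ($\arg\min P$),
with ties broken by wider window then lower start index — favoring maximal
spans.

A variant's minor allele *marks* a model when at least $\theta = 0.8$
(configurable) of the chromosomes carrying that allele also carry the
model's full signature, no other single model reaches $\theta$, and the
variant's effect direction matches the model's. When no single model
reaches $\theta$ but the top two jointly do (each carrying more than 10% of
the allele's chromosomes), the allele is labeled shared between them. The
constrained secondary scan re-runs the window analysis on the submap of one
model's marking variants, which concentrates the signal of rare haplotypes
otherwise diluted by interleaved variants.

## RISSc sentinel selection

RISSc (recursively identified sentinel scoring) selects variants that are
mutually significant under joint adjustment and mutually in low LD. LD is
the squared Pearson correlation of dosages (composite LD, so unphased data
work), computed by default over all subjects of the analysis set — the
choice of reference subjects is exposed as an option since cases-only is
equally defensible.

Step 1 bins perfectly correlated candidates ($r^2 = 1$) and keeps one
representative per bin (smallest simple P, then lowest position). Steps
2–40 descend the threshold schedule $0.975, 0.95, \ldots, 0.025$. At each
step, bins are formed greedily: the unassigned variant with the smallest
simple-logistic P seeds a bin (ties: larger $|\beta|$, then lower
position) and absorbs all unassigned variants with $r^2 \ge$ threshold to
the seed; singletons are allowed. Within each bin, the best-in-bin variant
(greatest simple association), any member with $P \le 0.01$ in the
within-bin joint model, and any member marked at the previous step are
selected; the rest are deleted permanently. A global joint model over all
survivors then marks those with $P \le 0.01$ — previously marked variants
that no longer meet the threshold become unmarked — or, if it fails to
converge (IRLS non-convergence, rank deficiency, or coefficient/SE
overflow), survivors keep only their previous-step marks. Sentinels are the
variants still marked after step 40, reported with mutually adjusted
estimates. When consecutive steps leave the survivor set unchanged the
global refit is skipped, as it would reproduce the previous fit exactly.

The marking level (`mark_alpha`) is a single knob used for both within-bin
selection and global marking; relaxing it from 0.01 to 0.05 admits more
sentinels.

An important statistical caveat, which the validation suite measures
directly: when a non-causal proxy's $r^2$ with a causal variant approaches
1, their observed association strengths differ by a margin comparable to
sampling noise, and *no* selection rule based on observed significance can
reliably prefer the causal one. On simulated panels whose proxies reach
$r^2 = 0.99$, RISSc returns a set detecting the planted signals essentially
always, but the set coincides with the planted variants themselves only in
a minority of runs — the remainder substitute a near-perfect proxy. This is
an identifiability limit of the data, not of the algorithm.

## Optimism-corrected AUC

The sentinel risk model is the multivariable logistic fit of status on the
sentinel dosages; its linear predictor is scored by the rank-based AUC
(all case-control pair concordance, ties 0.5). Apparent AUC overstates
performance because the same data selected the sentinels. Per bootstrap
replicate: subjects are resampled with replacement stratified by
case-control status (preserving the retrospective design's margins — the
natural choice, though unstratified resampling would also be defensible);
RISSc is re-run on the replicate over the fixed original candidate list;
the replicate model's AUC (AUCboot) and the AUC of the original data scored
with the replicate's coefficients (AUCreal) give the replicate optimism
AUCboot − AUCreal. The bagged optimism is the mean over usable replicates
(replicates with no sentinels or failed fits are counted and excluded), and
the shrunken AUC is apparent minus bagged optimism — an exact identity on
every report. An empty sentinel set degrades to the intercept-only model
with AUC exactly 0.5. Re-deriving the candidate list per replicate is
available as a switch; the default keeps the candidate set fixed, reading
the bootstrapped procedure as sentinel selection itself.

## Modifier tests

Cases are classified into three severity categories, evaluated aggressive
rule first: aggressive (stage T3 or higher, N1 or M1, or Gleason sum ≥ 8,
or PSA ≥ 20 ng/ml at diagnosis, or death from disease), insignificant
(stage T1, or single-lobe T2a with prostatectomy, with no extra-prostatic
disease, Gleason ≤ 6, PSA ≤ 4, and no death from disease), and moderate
(everything else). Boundaries are inclusive exactly as written. TNM strings
are normalized (`pT3a` → T3 level; N1/M1 anywhere trigger the aggressive
clause); an unparseable stage makes the case unclassifiable rather than
guessing. "Lethal disease" is taken as death attributed to the disease,
with no follow-up window, since none is defined.

Age at diagnosis is compared between carriers (dosage ≥ 1) and
non-carriers by a two-sided Wilcoxon rank-sum test — carrier coding because
the quantity of interest is the carrier mean-age contrast; a trend-style
coding is available. The exact distribution is used for combined group
sizes up to 50 (ties force the normal approximation), the
continuity-corrected normal approximation above. Severity pairs
(aggressive vs insignificant, moderate vs insignificant, aggressive vs
moderate) are compared by the additive logistic model, unadjusted by
default with optional covariate adjustment.

## The synthetic-data generator

The generator stands in for controlled-access study data and defines the
package's reference conditions: two independent case-control studies of
1500 cases and 1500 controls each over a 120-variant map. Background LD is
mosaic-founder: per-site ancestral allele frequencies are drawn once
(uniform 0.05–0.5), eight founder haplotypes are drawn from them, and each
background chromosome copies founder segments with a switch probability of
0.02 per adjacent interval plus a per-site mutation flip of 0.002 —
enough blockwise LD to exercise LD-driven algorithms without a coalescent
simulator, which the analyses do not require (they depend only on $r^2$
structure and planted carriage).

Planted ancestral haplotypes are drawn mutually exclusively per chromosome
at their population frequencies. The defaults plant one infrequent
higher-risk haplotype (frequency 0.02, one causal allele, OR 4, carriers
diagnosed 2 years younger) and one common moderate-risk haplotype
(frequency 0.10, OR 1.8) with disjoint 19-site signatures; signature sites
get a low background ancestral frequency (0.003) so their minor alleles
predominantly mark the planted haplotype, mirroring how marking alleles
arise on real ancestral segments. Case status follows
$\operatorname{logit} \pi = \beta_0 + \sum_c \beta_c x_c$ over planted
causal dosages, and rejection sampling fills the case/control quotas
exactly — retrospective sampling preserves odds ratios. Ages are normal
(mean 59, SD 8, truncated to 35–90 years, case carriers shifted younger);
severity is drawn from baseline probabilities (0.20 insignificant, 0.55
moderate, 0.25 aggressive — about a fifth of cases with extra-prostatic
disease) shifted on the cumulative log-odds scale for carriers, and
clinical fields (stage, Gleason sum, PSA, prostatectomy, death) are
emitted consistently with the drawn category so that the severity
classifier round-trips. Minor-allele orientation is fixed once over the
combined studies; the truth record therefore also reports each planted
haplotype's signature in minor-allele coding, which is what the analysis
sees.

What the generator does not emulate: realistic human demography and
recombination hotspots, imputation dosage uncertainty (phase confidence is
emitted as 1; the 0.9 phase threshold is exercised through fixtures),
relatedness, and X-chromosome inheritance. Passing tests therefore show
that the chain recovers planted structure under idealized LD, not that it
is robust to imputation artifacts.

## Numerical choices and degenerate inputs

- Dosages are integers; the data model rejects fractional dosages.
- Monomorphic variants are excluded at load with a reason; their LD is 0
  by convention if ever requested.
- Missing genotypes: pairwise-complete for LD, complete-case per model fit.
- P values are floored at 1e-300 and never reported as 0; results tables
  serialize floats at 17 significant digits and round-trip losslessly.
- All tie-breaks (bin seeding, best-in-bin, step-1 representatives, peak
  windows) are documented and deterministic, so identical inputs give
  identical outputs; the simulator is reproducible bit-for-bit under a
  fixed seed.
- Windows are closed intervals of consecutive indices on the sorted map;
  positions are 1-based as in VCF.

## Problem sizes used in the validation suite

The test suite runs the full chain at the reference scale above (25
replicate seeds for haplotype recovery), RISSc recovery panels of 2000
cases / 2000 controls with 42 candidates over 25 seeds, exhaustive
small-instance sentinel oracles on panels of 8 candidates, a 5000-variant
null calibration of the concordance filter, and 10 pure-noise optimism
panels of 600/600 subjects with 40 candidates and 100 bootstrap
replicates. These sizes were chosen so each property is measured with
enough replication to be stable while the whole suite stays desk-scale.

## Known limitations

- Statistical phasing is out of scope; phased input is required for the
  haplotype stages (the simulator emits phased data).
- The combined-study model pools subjects; inverse-variance meta-analysis
  of per-study estimates is deliberately not implemented.
- Sentinel identifiability against near-perfect proxies is bounded by the
  data, as discussed above.
- The exact formalization of "uniquely aligning" windows is this package's
  own (uniqueness + carrier continuity + conflict veto); other defensible
  readings exist and would fragment or join borderline models differently.
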