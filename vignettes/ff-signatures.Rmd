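---
title: "Fetal-fraction signatures: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fetal-fraction signatures: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Noninvasive prenatal diagnosis of monogenic disease (NIPD-M) decides which
parental haplotypes a fetus inherited from the allelic balance of plasma
cell-free DNA (ccfDNA) at a panel of SNPs around the pathogenic variant —
relative haplotype dosage (RHDO). The fetal compartment is a minor fraction
(the fetal fraction, FF or $f$) of total ccfDNA, so the method lives off
imbalances of order $f/2$. Anything that changes chromosome dosage at the
target locus — trisomy, monosomy, uniparental disomy (UPD), a dizygotic
co-twin, or mosaics of these — distorts exactly the quantity RHDO measures
and can produce a confidently wrong diagnosis.

ffsig computes FF several independent ways from the *same* allele counts,
one per SNP type, and asks whether the resulting pattern — the
*fetal-fraction signature* — is consistent with a normal singleton
pregnancy.

## SNP types and the per-type FF estimators

With phased parental genotypes, maternal haplotypes $M_1, M_2$ and paternal
$P_1, P_2$, each panel SNP falls into one of five types by the equality
structure of the four alleles:

| type | parents | estimator (per SNP) |
|------|---------|---------------------|
| 1 | both homozygous, different alleles | $\widehat{FF} = 2\,\hat p_{\text{pat}}$ |
| 2 | both homozygous, same allele | background = 2nd most frequent allele frequency |
| 3 | father het, mother hom | $2\,\hat p_{\text{pat-specific}}$ per subtype ($P_1$ / $P_2$ carrier) |
| 4 | mother het, father hom | $\hat p_{M_1} - \hat p_{M_2}$ (signed), alpha/beta by whether the father's allele matches $M_1$ or $M_2$ |
| 5 | both heterozygous | classified, not used by the estimators |

In a normal pregnancy the Type-1 estimate, one Type-3 subtype and one
Type-4 subtype all read $f$, while the remaining subtypes sit at background.
Each anomaly breaks this pattern in a characteristic way; e.g. a maternal
meiosis-I trisomy puts *both* Type-4 subtypes at about half the Type-1
value with opposite signs, paternal heterodisomy puts all four T3/T4
subtypes at half of Type-1, maternal heterodisomy erases every signal.

Per-class estimates carry three spreads: the mean absolute deviation of the
per-SNP values (the "average deviation" used for error bars), the sample SD
(used by the alert rule), and the SNP count. "Average deviation" is not
defined in the source material for the bar charts; we chose MAD as the
literal reading. Background is reported both raw and doubled, because
Type-1/3 estimates are doubled frequencies; comparisons always use matching
scales (which scale the published figures use is not stated; we expose
both).

## The mixture oracle

Plasma is modelled as a weighted mixture of contributors: the mother
(weight $1-f$, copies $\{M_1, M_2\}$) plus one or more fetal clones. Each
contributor's weight is its share of *diploid-genome ccfDNA mass*, so each
chromosome copy weighs $w/2$ at the target locus; a trisomic clone
contributes $3w/2$. This convention mirrors the DNA-mixing construction of
composite validation samples and is why abnormal ratios are
"approximately" rather than exactly simple: e.g. homogeneous maternal MI
trisomy at $f = 0.10$ gives $FF_1 = 2 \cdot 0.05 / 1.05 = 0.0952$, not
$0.10$. The mosaic fraction $m$ is likewise the abnormal clone's share of
*fetal ccfDNA mass*, not of cells.

Expected allele frequencies are exact mass balances; expected signatures
apply the estimators to them (zero dispersion). Because in-silico dilution
mixes *frequencies*, both the signed Type-4 estimates and the Type-1
estimate scale linearly through the origin with the dilution proportion,
so expected regression slopes are the exact ratios of undiluted
expectations — e.g. for maternal MI trisomy in mosaic $m$ with the euploid
line carrying $M_1$: $s_\alpha = 1 - m/2$, $s_\beta = -m/2$.

Transmitted haplotypes are fixed explicitly per scenario rather than
averaged over transmissions; relabeling $M_1 \leftrightarrow M_2$ or
$P_1 \leftrightarrow P_2$ maps signatures by the obvious symmetries (tested
exhaustively).

## Dilution regression

`dilute_counts()` mixes per-SNP counts as
$\mathrm{round}(p\,n_s + (1-p)\,n_m\,d_s/d_m)$ — maternal counts
depth-rescaled per SNP so $p$ acts on frequencies; rounding is half away
from zero (a stochastic multinomial mode exists for noise studies, off by
default). The default ladder is $p \in \{1, 0.8, 0.6, 0.4, 0.2\}$ (the
source says only "various proportions"). OLS is fitted with a free
intercept, robust to background offsets; the through-origin slope is also
reported since the published fit convention is unstated.

## QC calls

**Alert rule.** The published rule is tentative and under-specified
("control SNPs" unidentified; scale unstated). We adopt dual controls:
each T3/T4 subtype must conform either to the Type-1 band (signal control,
mean ± 1 SD) or to the doubled Type-2 background band (null control), where
"conform" means the subtype *mean* falls in the band widened by twice the
subtype mean's standard error. Literal interval containment is impossible
whenever subtype and control SDs are comparable (always, at equal depth),
and a bare null band a couple of reads wide would flag every normal sample:
the SE slack is what makes the rule operational. A consistent normal
pattern additionally needs one signal and one null subtype per parental
side; a silent Type-1 raises "no fetal signal" unless the Y loci call a
male fetus (whose X-panel signature legitimately mimics a maternal
monosomy at $FF_Y/2$). Subtypes with fewer than `min_snps` (default 5)
SNPs are withheld as low-confidence. Measured specificity on 200 simulated
normal samples at $f = 0.10$, depth 640: 0 alerts.

**Slope flags.** Normal iff the slope pair is within tolerance (max abs
deviation, default 0.15) of $(+1, 0)$ or $(0, -1)$. The default separates
normal-sample slope ranges from all derived abnormal slopes at $m \ge
0.25$; it is configurable because no cutoff is published.

**Classification.** Grid search over scenario kinds × transmitted
haplotypes × $m \in \{0, 0.05, \ldots, 1\}$ × $f$ (twin split for twins),
scoring by inverse-variance-weighted squared signature difference (FF$_Y$
included; slope terms added when a regression is supplied), with local
refinement of the best candidates. Fits within 10% of the best distance
(floor $10^{-6}$) are a tied set. Degenerate-limit fits are relabeled:
$m \to 0$ is the euploid counterpart, $f \to 0$ is NO_FETAL_DNA,
concordant twin configurations are NORMAL.

**Exact degeneracies.** Some distinct biologies share a signature *and*
slopes, differing only in effective FF, and are reported as tied sets with
disambiguation notes (measure FF with SNPs on other chromosomes):

* monosomy vs isodisomy, same parental side;
* maternal heterodisomy vs no fetal DNA;
* homogeneous maternal MI trisomy ≡ homogeneous paternal monosomy ≡
  paternal isodisomy ≡ 50:50 maternally-discordant twins (signature shape
  $(1, 1, \pm\tfrac12) \times FF_1$) — found during implementation and
  verified algebraically;
* any normal signature may hide fully concordant twins.

**Mosaic fraction.** For maternal MI trisomy the exact least-squares
inversion uses both Type-4 subtypes: $\hat m = 1 - |t_{4\alpha} +
t_{4\beta}| / t_1$ (slope route: $\hat m = 2\min(|s_\alpha|, |s_\beta|)$).
The single-subtype form $-2 s_\beta$ is unbiased but noisier by $\sqrt2$
and misses the stated recovery target at $f = 0.05$; the two-subtype form
achieves median $|\hat m - m| \approx 0.04$ over
$m \in \{1, \ldots, 0.125\} \times f \in \{0.05, 0.1, 0.2\}$ at depth 640.
Other kinds fall back to a numeric fit against the oracle.

## The simulator: what world it states

The generator reproduces the composite-sample validation design: mixtures
of one maternal and one or two "fetal" genotype sets in arbitrary mass
proportions, read out at *molecular* (barcode-consensus) depth.

* **Panel**: 389 X-chromosome SNPs + 4 Y marker loci (published totals).
  The per-class split is not published; the fixed default is T1 40, T2 60,
  T3 30+30, T4 100+100, T5 29.
* **Depth**: Poisson around 640 (published mean molecular depth), scaled
  per locus by its mixture mass — a monosomic compartment yields
  proportionally fewer molecules, and Y loci get $\approx f/2 \times 640$
  in a male pregnancy, which is exactly what makes the $FF_Y$ estimator
  work. A negative-binomial option exists, off by default.
* **Errors**: per-consensus-read substitution $e = 0.001$ to each other
  base with probability $e/3$ (low-background barcode consensus). Note the
  Type-2 background statistic is the *max* of three error counts, so its
  expectation at depth 640 is about twice $e/3$, approaching $e/3$ only at
  high depth; the tests assert the exact order-statistics expectation.
* **Not emulated**: fragment-length/GC/positional coverage bias, raw-read
  (pre-consensus) errors, recombination inside the 1 Mbp window, genotype
  errors in the parental phasing. A green simulation-based test therefore
  establishes correctness of the *inference machinery* under the stated
  sampling model, not robustness to platform artefacts.

## Limits of the slope diagnostic

The dilution ladder is a deterministic re-mixing of *one* sequenced plasma
sample, so all ladder points share that sample's estimation noise; the
fitted slope is essentially $\hat t_4 / \hat t_1$ of the undiluted sample.
With 100 SNPs per Type-4 subtype at depth 640 and $f = 0.10$ the slope SD
is $\approx \sqrt{2/640}/10/0.1 \approx 0.056$. A 12.5% mosaic maternal MI
trisomy shifts $s_\beta$ to $-0.0625$: against a 0.05 cutoff, only ~1/4 of
a standard deviation of margin, giving a per-sample detection rate near
60%, not ≥ 90% (measured: 0.52–0.64; $m = 0.25$: 0.90–0.94; $m \ge 0.5$:
1.0). The corresponding acceptance test is deliberately left failing at
the $m = 0.125$ rung rather than loosened: detecting such mosaics reliably
per-sample needs more information (deeper consensus depth, more Type-4
SNPs, or replicate libraries), not a different ladder — dilution adds no
independent reads. Slopes do remain useful there as an *ensemble*
statistic (the mean over replicates sits at $-0.0625$, far from 0 relative
to its SE) and that is how the method's "down to 12.5%" behaviour should
be read.

## Numerical choices

* FF is a fraction in $[0,1]$ everywhere; per-cent only at presentation.
* Estimates with zero usable SNPs are flagged unavailable, never silently 0.
* SNPs with an allele incompatible with both parental genotypes above 20%
  frequency are excluded as probable genotyping errors and logged.
* Sex call: male iff mean Y depth > 1% of the mean non-Y depth
  (configurable); a Type-3 FF above 0.02 in a male sample flags a possible
  47,XXY.
* T3 sites where both paternal alleles are absent from the mother are
  assigned subtype by P1 precedence; T4 sites where the father matches
  neither maternal allele get subtype NONE and are excluded from
  alpha/beta estimation.
* Degenerate regression (no Type-1 spread) is flagged, with slopes NA.
* Seeds: every stochastic entry point takes one; `simulate_case` derives
  panel/plasma/maternal sub-seeds as seed + 0, 1, 2.
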