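---
title: "Models and methods for hypodiploid leukemia genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for hypodiploid leukemia genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypokaryo)
```

# The biological setting

Hypodiploid acute lymphoblastic leukemia (ALL) is defined by clones with
fewer than 46 chromosomes, divided by modal chromosome number into
near-haploid (NH, 25–30), low hypodiploid (HoL, 31–39) and high hypodiploid
(HoH, 40–44) subgroups. Retention of chromosomes is nonrandom: NH clones
keep the sex chromosomes, 14, 18 and 21 as heterodisomies; HoL additionally
retains 1 (nearly always), 5, 6, 8, 10, 11 and 19. Every non-retained
chromosome is a monosomy with complete loss of heterozygosity (LOH).

Two phenomena complicate diagnosis. First, hypodiploid stemlines frequently
double, producing a clone in the hyperdiploid or near-triploid range
("masked hypodiploidy"). The doubled genome looks hyperdiploid by
chromosome count but carries a tell-tale signature: former monosomies
become two *identical* copies — copy-neutral LOH, with a normal log R ratio
(LRR) but no heterozygous B-allele-frequency (BAF) band. Second, some
doubled clones continue to mis-segregate chromosomes, producing cell-to-cell
karyotype heterogeneity (chromosomal instability, CIN) that appears on bulk
arrays as allelic ratios fitting no single integer copy-number state.

This package provides (i) generators for karyotypes, SNP-array profiles,
variant read counts, diagnosis/relapse alteration pairs, and
expression/methylation matrices with exactly this structure, and (ii) the
inference chain that recovers purity, allele-specific states, LOH, masked
hypodiploidy, CIN, variant origin, clonal relationships, and chromosome-level
dosage effects from them.

# The mixture signal model

All array-level inference rests on one mixture identity. A sample is a mix
of leukemic cells (fraction, i.e. purity, $x$) and normal diploid cells
($1-x$). For a chromosome present in $n_a + n_b$ homologue copies in the
clone, a germline-heterozygous probe whose B allele sits on homologue $b$
has expected BAF

$$\mathrm{BAF} = \frac{x\,n_b + (1-x)}{x\,(n_a+n_b) + 2(1-x)},
\qquad
\mathrm{LRR} = \log_2 \frac{x\,(n_a+n_b) + 2(1-x)}{2}.$$

The mutant-allele-fraction (MAF) model for variants on monosomic
chromosomes is the one-locus special case. With the clone monosomic
($n_a + n_b = 1$), the three possible variant origins give

* acquired by the clone: $x/(x + 2(1-x)) = x/(2-x)$,
* constitutional, on the homologue the clone lost: $(1-x)/(2-x)$,
* constitutional, on the retained homologue: $(x + (1-x))/(2-x) = 1/(2-x)$,

and the identity acquired $+$ lost $=$ retained holds for every $x$. The
third formula's published form is not parenthesis-balanced; $1/(2-x)$ is
the only reading consistent with a constitutional heterozygous variant on
the retained homologue, and the one implemented. `classify_origin()` turns
these point predictions into a binomial posterior over the three
hypotheses. A plain binomial (no overdispersion) is the simplest model
consistent with point predictions; note that at $x = 0.5$ the acquired and
constitutional-lost expectations coincide ($1/3$), so calls within
$|x - 0.5| < 0.02$ are flagged degenerate. The model deliberately refuses
chromosomes not called monosomic rather than silently extending the
formulas; other copy states route through `expected_signal()`.

# Synthetic data: what is emulated, what is not

The generator defaults encode the study conditions:

* **Retention weights** (`retention_weights()`): NH gives weight 0.9 to the
  sex pair, 0.8/0.7/0.95 to 14/18/21 and 0.05 to the rest; HoL adds 1.0 for
  chromosome 1 and 0.6 for 5/6/8/10/11/19. These reproduce the qualitative
  frequency statements for the subgroups (disomy 1 in essentially all HoL,
  chromosome 21 retained in nearly all NH). HoH has no published
  retention table; its background weight is lifted to 0.8 so rejection
  sampling lands in 40–44. All weights are user-overridable.
* **Probes**: evenly spaced per chromosome with rounded GRCh37 lengths,
  150 per chromosome by default, 30% germline-heterozygous — a desk-scale
  stand-in for real array manifests, which no inference step depends on.
* **Noise**: truncated Gaussian on BAF (clipped to $[0,1]$), Gaussian on
  LRR, both SD 0.03 — a standard array noise approximation. Real arrays add
  GC waves, probe-specific biases and genotyping error, none of which are
  modelled; passing tests therefore demonstrate correctness of the
  inference logic under the stated noise model, not robustness to real
  array artifacts.
* **CIN** (`apply_cin()`): each cell deviates from the founder
  independently per chromosome with probability `change_rate`; the
  *direction* of deviation is drawn once per chromosome per call. The
  per-chromosome direction reflects clonal selection — cells that gained or
  lost a given chromosome expand as a lineage rather than as a symmetric
  cloud. This choice also makes the heterogeneity visible in bulk data: with
  per-cell random signs the gains and losses cancel in the population
  average (the realized mean-copy shift is of order
  $\sqrt{r/n_\mathrm{cells}} \approx 0.014$ copies at $r = 0.1$,
  $n = 500$), which no bulk assay could detect. The per-cell deviation rate
  default of 0.05 is a free parameter, not an estimate: the cohort data
  establish that heterogeneity exists, not its per-division rate.
* **Sex chromosomes**: the haploid baseline is 22 autosomes + X; Y enters
  only via explicit gains, matching the relative-to-haploid notation. For
  XY samples the normal reference contributes one X and one Y, and sex
  chromosomes carry only homozygous probes.
* **Expression**: negative binomial with mean
  $\mu = \mathrm{baseline} \cdot (\mathrm{CN}/2)^{\gamma}$; $\gamma = 0$ is
  the no-dosage null, $\gamma = 1$ proportional dosage. **Methylation**:
  logistic model on the logit scale with per-gene baselines, a per-group
  shift (subtype clustering) and a per-copy effect; `copy_effect = 0`
  reproduces the observed *absence* of copy-number–methylation association.

Every stochastic operation takes a mandatory seed and uses no hidden global
RNG state, so identical calls are byte-for-byte reproducible.

# Inference choices

**Purity** is estimated by grid search (step 0.01, smallest-x tie-break):
for each candidate purity, each chromosome's median mirrored heterozygous
BAF and median LRR are matched to the nearest integer state
$(n_a, n_b)$, $0 \le n_b \le n_a \le 4$, and squared deviations are summed.
Two numerical details matter. The mirrored-BAF median of a balanced state
carries a half-normal folding bias of $\approx 0.675\sigma$, so the
expectation is folded the same way, with $\sigma$ estimated from the LRR
spread (MAD). Even so, at very low true purity the estimator has an
identifiability floor: for any $x > 0$ the per-chromosome minimum over
states can only undercut the diploid fit, so a truly pure-normal sample
returns $\hat{x} \approx 0.03$ rather than 0. Within the working range
($x \ge 0.6$) recovery is within $\pm 0.05$ in $>95\%$ of simulations.

**Chromosome calls** fit every candidate state by the equal-weighted mean
squared deviation of heterozygous-probe BAF (against the nearer allelic
band) and all-probe LRR; ties break by smallest total copy number, then the
more balanced state (parsimony). LOH is declared empirically — fewer than
5% of germline-AB probes inside $[0.25, 0.75]$ — rather than from the
fitted state, so it remains meaningful when no state fits. Calls need at
least 50 probes; the whole package works at whole-chromosome resolution
only (focal deletions are a different problem, out of scope).

**The CIN flag** is `fit_score > fit_threshold` for the best single state.
The default threshold 0.003 was calibrated on null simulations at the
default noise (0.03) and probe density (150): the null score concentrates
near $2\sigma^2 \approx 0.0018$ with a 99.9th percentile near 0.0025, while
a 10% per-chromosome deviating fraction adds $\approx 0.004$. The published
cohort gives no quantitative criterion for "allelic ratios indicative of
variable copy number"; this threshold is our operationalization and is
labelled as such in output.

**Masked hypodiploidy** requires at least 8 chromosomes in copy-neutral LOH
(total $\ge 2$) and all called totals even, except where the CIN flag
excuses odd totals. The inferred founder modal number halves the totals
(rounding flagged chromosomes); it is reported as a number rather than
forced into an NH/HoL/HoH label because a doubled-then-unstable genome does
not pin the founder's subgroup.

**Clonal relationships** are a pure function of shared/unique alteration
counts: no overlap → unrelated; unique on both sides → ancestral clone;
unique only at relapse → major clone; none → identical. A relapse strictly
contained in the diagnosis has no published category and gets its own label
(`backward_subset`) rather than being forced into one. Subclonal
alterations participate by default (matching how subclonal imbalances were
counted in the cohort) and can be excluded.

**Enrichment** uses the weighted Kolmogorov–Smirnov running sum with
signal-to-noise ranking (SD floored at $0.2\,|\mathrm{mean}|$ and 0.2) on
log2 counts, phenotype-label permutation (exhaustive below 8 samples or
when fewer distinct relabelings than requested exist), NES normalization by
the same-sign permutation mean, and the pooled-NES FDR. The ranking metric
is a design choice — the source analyses name only "GSEA" — and a
t-statistic alternative would slot into the same machinery. Exact ties in
the running sum are resolved to the first position within a $10^{-9}$
tolerance so floating-point noise cannot flip the sign of a tied score.
Chromosome gene sets include X by default; in mixed-sex cohorts the X set
confounds sex with dosage, and `chromosome_gene_sets(drop_sex = TRUE)`
removes it.

**The methylation dosage test** compares mean β between disomic and
monosomic samples per chromosome, with a gene-label permutation null and
Benjamini–Hochberg adjustment. The cohort design matters: with per-sample
independent hypodiploid karyotypes the strata decorrelate across
chromosomes, whereas in a case/control design the permutation null absorbs
the genome-wide dosage effect and the test has no power by construction.
Note the inherent boundary of its null behaviour: under the global null,
Benjamini–Hochberg makes at least one rejection with probability close to
its level (Simes), so "no significant chromosome" holds in roughly 90% of
datasets at FDR 0.1 — that is a property of the procedure, not a defect of
the implementation.

# Problem sizes

The shipped analyses and tests run at desk scale, chosen so the full chain
exercises every code path with tight statistical bounds: 150 probes per
chromosome, 100-seed recovery studies for purity and masked hypodiploidy,
30 instability genomes of 500 cells, 200 null datasets for the enrichment
type-I study (200 permutations each), and 200 methylation cohorts of 12
samples (999 permutations each). Power and calibration at these sizes are
documented by the test suite itself; nothing is asserted that the tests do
not compute.

# Known limitations

* Whole-chromosome resolution only; no segmentation, no focal CNAs.
* No allele-specific phasing; homologue identity of extra copies beyond the
  second is arbitrary.
* The binomial read-count model ignores overdispersion; a beta-binomial
  would be the next refinement.
* The karyotype parser covers the relative-to-haploid dialect only;
  structural ISCN tokens raise a complex-karyotype error by design.
* Real-data effects (array waves, probe manifests, read-level artifacts,
  450K probe chemistry) are outside the generators, so conclusions about
  real-data robustness require real data.

# A worked example

```{r example, eval = FALSE}
stem <- make_hypodiploid_karyotype("NH", "XX", seed = 1)
masked <- double_clone(stem)
profile <- simulate_snp_array(sample_mixture(masked, normal_fraction = 0.05),
                              seed = 2)
g <- call_genome(profile)
g
# <genome_call> purity 0.95 (estimated), 23 chromosomes called
#   masked hypodiploidy: TRUE (inferred founder modal 26)
#   unstable (CIN-flagged) chromosomes: 0%
modal_number(stem)  # 26: the founder is recovered exactly
```
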