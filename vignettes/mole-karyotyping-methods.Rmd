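---
title: "Methods: molecular karyotyping and parent-of-origin calling in androgenetic moles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular karyotyping and parent-of-origin calling in androgenetic moles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molekaryo)
```

## The biological problem

A complete hydatidiform mole (CHM) is a conception whose nuclear genome is
androgenetic: it derives entirely from sperm. Monospermic (homozygous) CHMs
arise from a single sperm whose genome endoduplicates; dispermic
(heterozygous) CHMs carry the genomes of two distinct sperm from the same
father. Dispermic moles occasionally carry an additional chromosome, and
that extra homolog can be of paternal origin (a disomic sperm or unequal
division) or — counter-intuitively for an "androgenetic" conception — of
maternal origin (incomplete extrusion of the maternal pronucleus material).
Some disomic chromosomes inside an otherwise androgenetic genome even turn
out to be biparental: one maternal plus one paternal homolog. Whether any
maternal material is retained is of clinical interest as a candidate
stratifier of gestational trophoblastic neoplasia (GTN) risk.

`molekaryo` implements the duo (mole + maternal blood) analysis that
resolves these constitutions from SNP-array data, together with a
forensic-style STR classifier and a fully seeded simulator, so that every
stage of the pipeline can be exercised and validated without access to
patient data.

## BAF band geometry and copy-number calling

At a biallelic locus covered by $n$ homologs of which $k$ carry the B
allele, the ideal B-allele frequency (BAF) is $k/n$ and the ideal log R
ratio (LRR) is $a\,\log_2(n/2)$, where $a \in (0,1]$ is a platform
attenuation factor. A heterozygous disomic chromosome therefore plots as
three BAF lines $\{0, 0.5, 1\}$, a trisomic chromosome as four lines
$\{0, 1/3, 2/3, 1\}$ (AAA, AAB, ABB, BBB), and a chromosome whose homologs
are all identical as two lines $\{0, 1\}$ regardless of copy number.

`call_copy_number()` turns this geometry into a call in two steps:

1. **Band nomination.** `baf_band_profile()` measures, for each copy
   hypothesis $n \in \{1,\dots,4\}$, the fraction of loci within
   `tolerance` (default ±0.08) of each theoretical level. Presence of the
   intermediate bands nominates hypotheses: 1/3 and 2/3 nominate trisomy,
   1/4, 1/2 and 3/4 nominate tetrasomy, 0.5 alone is compatible with
   balanced disomy or tetrasomy, and a bare $\{0,1\}$ pattern leaves all
   hypotheses open. A band counts as present at ≥ 2% of chromosome loci
   and at least 10 loci — high enough to ignore stray noise, low enough to
   keep rare bands (selected-BAF BB loci occupy only a few percent).
2. **LRR arbitration.** The median LRR picks the nominated hypothesis whose
   expected shift $a \log_2(n/2)$ it is closest to. A gain call
   additionally requires the median LRR to exceed
   `lrr_gain_threshold` = $0.5\,a\log_2(1.5)$ (half the ideal trisomy
   shift), and when the median is further than `lrr_margin` (0.3) from
   every nominated expectation the chromosome is reported ambiguous
   rather than forced — BAF/LRR disagreement is a red flag, not a vote.

The ±0.08 tolerance separates adjacent bands at the default BAF noise
(SD 0.03: adjacent trisomy bands are 1/3 apart, > 4 SD from the window
edge) while absorbing clipping pile-up at 0 and 1. Balanced tetraploidy
versus diploidy is decided purely by LRR, and only when attenuation makes
the shifts distinguishable; otherwise the call is ambiguous — consistent
with the general caution that array data alone cannot strictly exclude
tetraploidy.

Sex constitution (`call_sex()`) uses the Y-locus call rate (a missing Y
renders as no-calls with background LRR around −3) to decide Y presence,
then reads X and Y copy numbers off their median LRR. X in males is
hemizygous (two BAF bands, LRR near −1) and is exempted from the autosomal
disomy baseline.

## The selected-BAF parent-of-origin procedure

Restrict the mole's BAF values to the loci at which the *mother* was
genotyped AA. If every homolog in the mole is paternal, the mole can still
be all-B at such a locus, so a BAF ≈ 1 band persists. If the chromosome
carries even one maternal homolog, that homolog contributes an A allele at
every selected locus, capping the true BAF at $(n-1)/n < 1$: the top band
vanishes deterministically. Loss of the top band among selected loci is
therefore a structural, not statistical, signature of maternal
contribution — on a trisomy it labels the extra homolog maternal, and on a
disomy it exposes a biparental chromosome pair hiding inside an
androgenetic genome.

`top_band_retention()` quantifies this as
$$
R = \frac{\text{fraction of selected loci with BAF} \ge c}
         {\text{expected fraction under the all-paternal hypothesis}},
$$
with $c$ = `top_band_cut` = 0.85 (more than 4 noise SDs above the ABB band
at 2/3). The expectation is analytic: for a locus with population B-allele
frequency $p$, the mother is AA with probability $(1-p)^2$ and $n$
independent paternal homologs are all B with probability $p^n$, giving the
weighted mean $\sum_i (1-p_i)^2 p_i^n / \sum_i (1-p_i)^2$ over the
chromosome's panel loci. Two sperm from one father share homologs
identical-by-descent over roughly half the genome, which raises the true
all-B probability above the independence baseline ($\tfrac{p+p^2}{2} >
p^2$ at $n=2$), so all-paternal chromosomes score $R \approx 1.5$–$1.7$
rather than exactly 1. This bias is harmless by design: the decision rule
only asks whether $R$ collapses towards 0, and `loss_threshold` = 0.25
sits far below any all-paternal value while maternal contribution drives
the numerator to exactly 0 on noise-free data (and within noise of 0
otherwise). An `expected = "empirical"` mode (median observed fraction
over the other autosomes) is available when panel frequencies are
unreliable; the analytic mode is the default because it is deterministic
and needs no reference chromosomes.

Chromosomes with fewer than `min_selected` = 30 selected loci are reported
undetermined rather than called: roughly a third of loci survive maternal-AA
selection, so this floor corresponds to ~90 panel loci, below which the
top-band fraction is too granular to trust. The mirrored procedure on
maternal-BB loci and the BAF ≈ 0 band (`select_loci_maternal_BB()`) is
provided as a consistency diagnostic, never as the decider.

The mother's homozygous genotypes say nothing about the X chromosome
contribution in an androgenetic conceptus analysis here: extra sex
chromosomes are annotated paternal by constitution (a Y is always
paternal; supernumerary X's in an androgenetic genome come from sperm).

Mitochondrial identity (`mito_identity()`) is the companion sample-swap
check: mole tissue carries the maternal mitochondria, so a duo must match
exactly at every informative MT locus (those with ≥ 2 distinct genotypes
across the cohort; uniform loci are excluded as uninformative). MT
identity is reported alongside origin calls but never overrides a
retention-based call.

## STR classification

`classify_conceptus()` applies the standard allele-sharing rules: at least
one locus sharing no allele with the mother ⇒ androgenetic; an
androgenetic profile with a two-allele locus ⇒ dispermic, otherwise
monospermic; a profile sharing at every locus ⇒ biparental diploid; any
locus with ≥ 3 distinct alleles ⇒ triploid suspect. Peak heights are
deliberately not modelled — electropherogram peak ratios scatter too much
to encode reliably in allele-set data — so triploidy detection rests on
third alleles only, and diandric versus digynic triploids are not
subclassified. A minimum of 8 loci typed in both profiles is required for
a call; below that the classifier returns indeterminate with a reason
(the rule set itself states no minimum; 8 is this package's policy).

## What the simulator emulates — and what it does not

`simulate_parents()` draws parental haplotypes from per-locus population
B-allele frequencies; `simulate_gamete()` performs meiosis with
Poisson-distributed crossovers (mean = genetic length in Morgans, uniform
genetic positions, linear physical↔genetic map, no obligate crossover and
no interference); `construct_conceptus()` assembles monospermic,
dispermic, biparental diploid and triploid constitutions, extra maternal
or paternal homologs, biparental disomies, sex constitutions from XX to
XXYY, and copies the maternal MT haplotype; `render_array()` adds
Gaussian BAF/LRR noise, clipping, attenuation and no-calls.

Defaults (all overridable):

| parameter | default | rationale |
|---|---|---|
| panel | 20,000 autosomal + 800 X + 100 Y + 208 MT loci | exome-array scale; dense enough that the smallest autosome keeps ~100+ selected loci |
| population BAF | Uniform(0.05, 0.95) | most loci informative; no licensed frequency tables |
| genetic lengths | 1.0–2.8 M, linear in physical size | desk-scale realism; the claims are insensitive to map detail |
| `baf_sd` | 0.03 | typical array band width |
| `lrr_sd` | 0.15 | typical LRR scatter |
| `lrr_attenuation` | 1.0 | configurable because real platforms compress LRR |
| `missing_rate` | 0.005 | typical no-call rate |
| STR panel | 15 loci, 6–10 alleles, uniform frequencies | forensic-multiplex-like without real tables |

Noise magnitudes are stand-ins chosen once as typical array behaviour;
they are not calibrated to any particular platform. Deliberately out of
scope: mosaicism, segmental (sub-chromosomal) aneuploidy, pseudoautosomal
regions, STR mutation/stutter, intensity-channel simulation, and real
allele-frequency panels. STR loci are simulated as unlinked whole-genome
markers drawn per gamete, so a chromosome-specific extra homolog does not
add a third STR allele — matching the observation that trisomic dispermic
moles still classify as dispermic by allele sets. Consequently, passing
tests demonstrate correctness of the calling logic under the stated noise
model, not robustness to platform artefacts (wavy LRR, allelic imbalance,
contamination) that real data may add.

The shipped 31-case cohort table (`chm31_cohort()`) encodes the reference
constitutions the package is validated against: 22 euploid cases, 8
autosomal-trisomy cases (one double trisomy), one 47,XYY, three biparental
disomies, with post-molar outcomes (7 GTN / 24 SR). Simulating it at the
defaults and running the full caller chain recovers the composition
exactly; the test suite asserts this at two fixed seeds, and a spot check
across ten seeds during development showed no failures. Reported problem
sizes: the full cohort run covers 31 duos × 21,108 loci and completes in a
few seconds; unit tests use three-chromosome panels of a few hundred loci.

## Numerical and degenerate-input choices

* Exact two-sided Fisher testing (`fisher_exact()`) sums hypergeometric
  probabilities in log space under the probability-ordering convention
  (all tables with probability ≤ observed, relative tie tolerance 1e-7),
  matching common statistical software; a zero margin returns p = 1 with
  a warning. The implementation is validated against exhaustive
  enumeration for every 2×2 table with total ≤ 40.
* Seeds: one root seed is split deterministically per case and operation
  (`simulate_cohort()`), so cohorts are byte-reproducible; all derived
  seeds stay below $2^{31}$.
* Degenerate inputs error early and informatively: empty panels,
  single-haplotype recombining chromosomes, constitutions referencing
  chromosomes absent from the panel, biparental disomies outside
  androgenetic modes, duos sharing < 90% of loci, duplicate (sample,
  locus) rows in final reports, > 4 alleles at an STR locus.
* Population frequencies are required to lie strictly inside (0, 1);
  fixed loci carry no information for any stage of the analysis.

## Known limitations

* Origin calling needs enough maternal-AA loci; very small chromosomes on
  sparse panels return undetermined rather than a forced call.
* The LRR arbitration thresholds assume approximately unattenuated LRR;
  under strong attenuation balanced tetraploidy becomes indistinguishable
  from diploidy and is flagged, not resolved.
* The analytic retention expectation assumes panel frequencies describe
  the sampled population; the empirical mode trades that assumption for
  the assumption that most autosomes are all-paternal disomies (true in
  this application).
* Cohort-level statistics are descriptive counts plus exact tests; no
  survival modelling or risk adjustment is attempted.
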