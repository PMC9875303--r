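---
title: "Models and methods behind herdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind herdscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

herdscan characterizes genomic diversity, inbreeding, relatedness and
selection signatures in multi-population resequencing cohorts — the typical
setting is a panel of cattle breeds genotyped against one reference, with a
focal (often small, endangered) breed compared against dozens of others.
This vignette explains the statistical models the package implements, the
parameters that matter, what the bundled simulator does and does not
emulate, and the numerical decisions a careful reader should know about.

## The cohort container

All statistics operate on a `cohort`: a sorted variant table, a sample
table with population labels, an alternate-allele dosage matrix (0/1/2,
`NA` for missing — never imputed), and, when the source VCF is phased, a
0/1 haplotype matrix with two columns per sample. Positions are 1-based
(VCF convention) everywhere a user sees them; window arithmetic internally
uses half-open intervals and reports 1-based inclusive bounds; BED export
and import convert to and from 0-based half-open coordinates in one
central, property-tested place.

## Differentiation: Hudson's F_ST

Per biallelic site with alternate frequencies $p_1, p_2$ and called allele
counts $n_1, n_2$:

$$N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad D = p_1(1-p_2) + p_2(1-p_1).$$

Genome-wide and per-window estimates are the *ratio of averages*
$\sum N / \sum D$, never the average of per-site ratios; the ratio of
averages is the form with well-behaved behaviour under rare variants and
unequal sample sizes. Each population pair is restricted to its own
segregating subset (sites where the pooled pair carries both alleles).
Sites with fewer than two called alleles in either population are excluded.
Two consequences worth knowing: the estimator is exactly invariant to
swapping the reference and alternate labels, and comparing a sample set
with itself gives exactly $-1/(n-1)$, not 0 — near-zero expectations only
hold for independent samples from one population (e.g. split halves).

Windowed scans use 10-kb tiles and keep windows with at least five usable
variants (both defaults are parameters). "Top" windows are selected by a
counting rule: the $\lceil f N \rceil$ highest values at top fraction $f$
(default $10^{-4}$, i.e. the top 0.01 %), with the reported threshold being
the smallest selected value; adjacent selected windows merge into regions.
The same ceiling-and-threshold rule drives RoH island selection (default
top fraction $5 \times 10^{-4}$). Ties are resolved deterministically by
position. Negative window values are not excluded before selection.

## Diversity and inbreeding

Per-site nucleotide diversity is the mean pairwise allele difference
$n_{ref} \, n_{alt} / \binom{n}{2}$; window values are the site sum divided
by the window width in bp and multiplied by 100, so all π output is in
percent per bp. Windows tile each chromosome; windows without SNPs
contribute zeros to chromosome and genome means and medians by default
(`include_empty = FALSE` restricts to covered windows), because the tiling
definition — not the variant density — defines the support.

Observed and expected heterozygosity are reported per individual against a
*fixed external denominator* (by default the cohort-wide variant count),
so that breeds with different numbers of segregating sites remain
comparable; the per-sample expected homozygosity sums
$1 - 2p q \, n/(n-1)$ over the sample's called sites. Allele frequencies
default to the focal population (`freq_scope = "population"`); a
cohort-wide option exists because per-breed versus pooled frequencies is a
genuine modelling choice with visible consequences for admixed breeds. The
excess-of-homozygosity inbreeding coefficient is

$$F_{Hom} = \frac{O_{hom} - E_{hom}}{T - E_{hom}},$$

with $T$ the same fixed denominator. Breed-level values are unweighted
means over individuals. The heterozygosity goodness-of-fit test is a
1-degree-of-freedom chi-squared on breed-summed heterozygous/homozygous
counts — the granularity (breed totals rather than per-site) is a
documented choice.

## Runs of homozygosity

A two-state HMM per sample and chromosome: states HW (Hardy–Weinberg) and
AZ (autozygous). Emissions use hard genotype calls and per-site allele
frequencies ($q$ = reference frequency):

* HW: het $2pq$; hom-ref $q^2 + pq\,\varepsilon'$; hom-alt
  $p^2 + pq\,\varepsilon'$ (with $\varepsilon' = 0$ by default, pure
  Hardy–Weinberg);
* AZ: het $\varepsilon$ (the genotype-error rate, default 0.01); hom-ref
  $(1-\varepsilon)q$; hom-alt $(1-\varepsilon)p$.

Transitions between adjacent sites at distance $d$ bp are
$P(HW \to AZ) = 1 - e^{-\alpha d}$ (default $\alpha = 6.6\times10^{-9}$)
and $P(AZ \to HW) = 1 - e^{-\beta d}$ with $\beta = 10^{-8}$ per bp
(1 cM/Mb), the standard bovine recombination-rate assumption. Initial
probabilities default to the stationary distribution. Decoding is Viterbi;
maximal AZ runs become segments spanning their first to last site, each
annotated with its mean forward–backward posterior as a quality score.

Three numerical choices deserve emphasis:

* **Uninformative sites.** Missing genotypes, sites with no called allele
  in the frequency scope, and sites monomorphic there all emit 1 in both
  states but keep their place in the transition chain. A fixed site
  predicts the same homozygote under either state; dropping it instead
  would distort inter-marker distances, and keeping it with its nominal
  emission would let the $(1-\varepsilon)$ factor act as a spurious
  anti-autozygosity penalty at segment boundaries. Because the HW dwell
  cost ($\alpha d$) is below the AZ dwell cost ($\beta d$), decoded runs
  still begin and end at informative sites.
* **Boundary identifiability.** The true boundary of an autozygous tract
  is only identifiable up to the nearest flanking heterozygous marker: any
  decoder extends through chance runs of homozygous flanking markers, and
  with irregular marker spacing the distance-dependent exit cost
  $\log(\beta d)$ legitimately prefers wide gaps as transition points.
  Recovery tests therefore bound the *undershoot* (planted markers missed
  at segment ends, zero on an evenly spaced grid) and control the outward
  extension through the false-positive base rate.
* **Hard calls.** Genotype likelihoods are out of scope; the intended
  inputs are hard-filtered WGS calls.

$F_{RoH}$ sums segment lengths at or above each minimum-length class
(50 kb, 100 kb, 1 Mb, 2 Mb, 4 Mb) over the SNP-covered genome length
(default the bovine autosome total 2,487,849,970 bp; always set this to
your own assembly's value). RoH islands take per-variant SNP-in-RoH
frequencies (animals covered by a RoH at the variant over animals in the
breed, using all segments by default), select the top fraction by the
ceiling rule, and merge members separated by at most 100 kb (configurable);
internal gaps above a reporting threshold are retained as annotations.

## Phylogeny, kinship, admixture

Manhattan distances between animals sum $|g_i - g_j|$ over
pairwise-complete sites and rescale by (total/complete) so missingness
does not shrink distances (this is `stats::dist`'s convention). UPGMA
clustering merges the closest pair with size-weighted arithmetic-mean
updates; node heights are half the merge distance, and ties are broken by
the lexicographically smallest pair of cluster labels so that the merge
order is reproducible. Outlier curation mirrors manual practice: per breed
the largest all-one-breed clade is kept, other members of the breed are
removed, and surviving clades collapse to one labelled branch. Trees
serialize to Newick through `ape`.

The genomic relationship matrix is VanRaden method 1 on
monomorphic-filtered dosages centred by $2p$ and scaled by
$2\sum p(1-p)$; missing genotypes contribute zero after centring. Because
frequencies are estimated from the same samples, the off-diagonal mean of
an unrelated panel is constrained to about $-1/(n-1)$ rather than 0 — a
known finite-sample property, asserted as such in the tests. The "least
related" subset is greedy: a seeded random start, then repeatedly the
sample with the smallest mean relationship to the current set (ties by
sample id).

The f3 statistic for target $C$ and sources $A, B$ averages
$(p_C-p_A)(p_C-p_B) - p_C(1-p_C)/(n_C-1)$ over usable sites — the
bias-correction applies to the target only. Standard errors come from an
unweighted leave-one-block-out jackknife over consecutive blocks of 10,000
variants (a trailing block shorter than half the nominal size merges into
its neighbour). Significantly negative $Z = f_3/SE$ indicates admixture;
independent drift of the target makes $f_3$ positive.

## XP-EHH

The scan uses site-EHH (allele-agnostic): haplotypes of one population are
partitioned by their allele strings from a core variant outwards, and

$$hh(x) = \frac{\sum_k n_k (n_k - 1)}{n (n - 1)}$$

normalized by its core value gives a curve equal to 1 at the core and
non-increasing outwards. Each side is integrated trapezoidally over
physical distance (no genetic map), truncated at the interpolated crossing
of the cutoff (default 0.05), and the sides sum to iES. The raw score
$\ln(iES_A / iES_B)$ is standardized genome-wide over all scanned cores
(no frequency binning), giving z-scores with mean 0 and sd 1 by
construction; two-sided normal p-values are Bonferroni-corrected over the
number of scanned cores, and positive scores indicate selection in the
first population. Cores are the variants segregating in the pooled pair;
cores with a zero integral on either side are skipped and logged.
Consecutive significant cores of one sign merge into regions (no maximum
gap — "neighbouring" means adjacent in the scan). Chromosome edges simply
truncate the integral; there is no edge penalty, which slightly shrinks
scores near ends of chromosomes in both populations symmetrically.

## The simulator and what passing tests mean

`sim_balding_nichols()` draws, per site, an ancestral frequency uniform on
$[maf_{min}, 1-maf_{min}]$ (default $maf_{min} = 0.05$), then population
frequencies from the Balding–Nichols Beta distribution with per-population
drift $F$, then Bernoulli haplotypes paired into diploids. The expected
pairwise Hudson F_ST between populations with parameters $F_i, F_j$ is
$(F_i + F_j)/2$, which is what the recovery tests assert at the
differentiation scale typical of related cattle breeds (0.03–0.10). Planted truth comes from two operators:
`plant_autozygosity()` copies one haplotype over the other inside known
intervals (with an optional heterozygous-error rate inside the tract), and
`plant_sweep()` replaces a seeded fraction of a population's haplotypes by
one template over a fixed extent around a core.

Sites are **independent** — there is no background linkage disequilibrium,
no recombination map, no mutation model, and no coalescent ancestry.
That is a deliberate choice: independence makes the expectations of every
statistic exact, so recovery tests are sharp. The flip side is what the
tests do *not* show: behaviour under realistic LD decay (EHHS decays much
more slowly in real data), allele-frequency spectra (real spectra are
skewed towards rare variants; the uniform law is not), pedigree structure,
or genotyping-error correlation. Parameter-recovery on these fixtures
validates the estimators' arithmetic and decoding, not their field
calibration on a particular species.

Simulation sizes used by the test suite and acceptance script (chosen to
give sharp expectations at desk scale): F_ST recovery uses 2 × 50 diploids
at 5,000 sites over 10 seeds per truth value; autozygosity recovery plants
2.5 Mb of tracts on a 10-Mb chromosome at 1 SNP/kb; the XP-EHH null runs
20 panmictic splits of 40 diploids at 2,000 cores, and sweep detection 10
seeds of a 40-Mb chromosome at 1 variant per 4 kb with a 0.6-carrier,
±500-kb sweep; f3 uses 50,000 sites with five 10,000-variant jackknife
blocks, and the jackknife SE is compared against the standard deviation of
f3 across 30 independent seeds.

## Other conventions and limitations

* LD pruning is PLINK-style greedy (`window 50 SNPs / step 5 / r² > 0.6`
  defaults): within each window the worst pair above the threshold loses
  its lower-MAF member (ties: later position) until no pair exceeds the
  threshold; non-estimable r² (monomorphic or too-missing pairs) counts as
  0, i.e. never prunes. Pruning is an explicit stage, not a global policy:
  trees and GRMs are typically computed on pruned variants, F_ST and
  diversity on unpruned ones, mirroring common practice.
* The QTL length rule keeps intervals strictly shorter than 10 kb; trait
  classes outside the configured set are dropped with a warning. Gene
  annotation classifies hits as `inside` (overlapping the unflanked
  region) versus `flank` (only within ±250 kb). Flanked regions that
  overlap each other are annotated independently.
* `run_config()` seeds all randomness once from its configuration, so
  reruns are byte-identical; every table is plain TSV/Newick/JSON.
* The demo pipeline and all tests run in minutes on one CPU; the package
  is pure R, and the XP-EHH scanner is the only stage whose cost grows
  quickly with cohort size (cores × haplotypes × extension length).
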