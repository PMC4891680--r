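---
title: "Coincident SNP analysis: models, mechanisms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coincident SNP analysis: models, mechanisms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistic

A *coincident SNP* (coSNP) is an orthologous genomic position that is
polymorphic in each of two compared species; the two species' alleles need
not be identical. Over a set of $n$ examined orthologous sites with $n_A$
sites polymorphic in species A, $n_B$ in species B and $n_{co}$ in both, the
package's central quantity is the observed-to-expected ratio

$$\mathrm{coSNP}_{O/E} \;=\;
  \frac{P_{coSNP}}{P_{SNP,A}\,P_{SNP,B}} \;=\;
  \frac{n_{co}\, n}{n_A\, n_B},$$

where $P$ denotes frequencies over the examined sites. If SNPs arise
independently and uniformly in the two species, every site is equally likely
to be hit, $P_{coSNP} = P_{SNP,A} P_{SNP,B}$, and the ratio is 1; this null
is also testable as independence of the 2×2 table {SNP in A} × {SNP in B}
by Pearson's chi-square (`chisq_independence()`, no continuity correction by
default because the intended tables are large; Yates' correction is a
switch, and the result carries a `low_expected` flag when an expected cell
falls below 5).

Three biological mechanisms push the ratio above 1, and each has a closed
form that the synthetic-data generator plants and the test suite recovers:

* **Mutation-rate heterogeneity.** If site $i$ is hit with probability
  proportional to a shared rate $r_i$ (mean 1, squared coefficient of
  variation $CV^2$) in both species, then at low densities
  $E[\mathrm{coSNP}_{O/E}] = E[r^2]/E[r]^2 = 1 + CV^2$.
* **A tolerant fraction of sites.** If polymorphism is confined to a
  fraction $f$ of sites in both species (purifying selection eliminating
  variants at the remaining $1-f$), uniform within the tolerant subset, the
  ratio converges to $1/f$. This is the selective mechanism by which sites
  under strong constraint show *elevated* coSNP enrichment: the few
  surviving polymorphisms in the two species are squeezed onto the same
  mutation-tolerant positions.
* **Shared ancestral polymorphism.** Variants segregating since before the
  species split are polymorphic in both descendants at the same site with
  the same allele pair; they inflate $n_{co}$ directly and specifically
  enrich the *same-allele* diagonal of the pattern table (below).

## The site universe

Every denominator is computed over the same explicitly constructed site
table (`build_site_table()`): one row per coding base of each orthologous
gene, built from per-species FASTA references and a TSV map of colinear,
equal-length (indel-free) CDS blocks. Coordinates are 0-based half-open
internally and converted at the VCF/BED boundary. Degeneracy is classified
from the species-A codon under the standard genetic code: a position is
zero-fold if all three single-base changes alter the amino acid (changes to
a stop codon count as amino-acid-changing — the standard convention),
four-fold if none does, two-/three-fold otherwise. Genes whose CDS length is
not a multiple of 3 or that contain a stop codon are skipped with a warning.
A genomic position covered by overlapping genes with conflicting classes
becomes `ambiguous` and is excluded from every numerator and denominator, as
are masked sites (BED exclusion intervals in either species, and sites with
multiallelic records, since the pattern machinery assumes dimorphism).

CpG context is hypermutable (deamination of methylated cytosine) and is the
classic confounder of coincidence statistics, so the headline analyses
exclude CpG-flagged sites. The flag is computed from each species' own
reference; the default exclusion policy is *either* species (conservative),
configurable to one species or both, because the choice of reference genome
for this filter is genuinely open. When CpG exclusion is on, flagged sites
leave both the numerator and the denominator, keeping $O$ and $E$ on the
same universe.

Variants are matched to sites per species and complemented onto the coding
strand for minus-strand genes, so allele patterns are compared in a
consistent frame. The six dimorphic patterns (A/C, A/G, A/T, C/G, C/T, G/T)
give a 6×6 observed table over coSNPs; the expectation for cell $(p, q)$ is
the product of the marginal pattern frequencies among all A-SNPs and all
B-SNPs of the stratum. (A product-of-marginals expectation is the natural
independence reference here; it is documented as this package's definition.)
The diagonal — same two alleles in both species — is reported separately as
the shared-ancestry-sensitive subset.

## Stratified analyses

**Windows.** Fixed-width windows are anchored at position 0 of each
chromosome for reproducibility. A window's coSNP class follows the dominance
hierarchy zero > two/three > four (a "zero" window may contain any other
classes; a "four" window contains only four-fold coSNPs). Tajima's D is
computed in-package from haplotype matrices with the standard 1989 constants
($a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$), so synthetic runs are fully
self-contained; windows without a segregating site are flagged undefined and
excluded. Classes are compared by two-sample Kolmogorov–Smirnov on D and by
a chi-square test of equal proportions of windows with $D \ge 2$ (the
conventional balancing-selection/contraction flag). Per-window covariates
are the single-species SNP density (SNPs / examined sites) and the mean
recombination rate of overlapping map intervals; windows with no examined
site or no map coverage are excluded.

**Constraint binning.** Exons/genes are ranked by a conservation score
(PhastCons-like) or by dN/dS and cut into groups of near-equal size by rank;
tied scores share the minimum rank and therefore fall in the lower bin. The
trend of per-group coSNP O/E against constraint rank is tested by Spearman's
rank correlation, one-tailed by default in the direction "more constraint,
higher zero-fold O/E" (the $1/f$ mechanism); groups with an undefined ratio
(zero SNP margin) are dropped with a warning.

**Nearest-neighbour pairing.** Each zero-fold coSNP is paired with the
nearest candidate site (non-coSNP or nonSNP of the same degeneracy class)
within the same gene, by absolute distance in species-A coordinates, ties
broken toward the lower coordinate — a deterministic rule that makes the
matching invariant to input order. Paired scores are compared with a paired
t-test by default; the paired Wilcoxon signed-rank is available because both
appear in common practice for this comparison.

**Impact thresholds.** Damaging calls use the published conventions exactly:
SIFT $\le 0.05$ (boundary damaging), Grantham $> 100$ (boundary not
damaging), PolyPhen-2 "possibly" and "probably" both damaging. Variants
missing a score are excluded from that metric only. Enrichment contrasts
(GWAS sites, disease/essential/housekeeping gene labels) use the sample odds
ratio $(ad)/(bc)$ — undefined on a zero margin, in which case the exact
p-value is still reported — with two-tailed Fisher exact p-values.

## Discovery curves and extrapolation

`discovery_curve()` subsamples $k = 2..K$ individuals without replacement
(5 random draws per $k$, averaged; the single full cohort at $k = K$) and
counts sites segregating within the subsample, plus those also polymorphic
in the fixed partner-species SNP set. When the number of distinct
$k$-subsets is no larger than the requested draws, all subsets are
enumerated exactly. `fit_log_linear()` fits $\log(\mathrm{count}) = a + b
\log k$ by OLS (both axes logged — power-law discovery; a
$\log(\mathrm{count}) \sim k$ variant of the "log-linear" reading would make
counts grow exponentially in cohort size, which discovery counts cannot).
`project_oe()` evaluates the fitted laws at a target cohort (default 1000
individuals) and recomputes O/E with the projected counts over the fixed
orthologous site universe, which does not grow with cohort size. Both the
SNP and the coSNP counts are projected directly.

A power-law projection is only as good as the spectrum it extrapolates. For
a folded neutral spectrum (density $\propto 1/q$) the number of segregating
sites in $k$ individuals grows logarithmically, and a power law fitted at
$k \le 6$ over-projects roughly four-fold by $k = 1000$; a bounded
common-variant spectrum saturates and over-projects similarly. The panel
generator's default spectrum therefore has a rare-variant power-law tail
(density $\propto q^{-1.55}$ above a cutoff well below $1/2k_{max}$) plus a
5% common-variant component; this family makes the *expected* subsampled
discovery curve log-log linear from $k = 2$ through the full panel (the
mixture weight cancels the curvature induced by the folded upper bound at
$q = 0.5$; numerically the expected projection/realized ratio is 0.994).
This mirrors the empirical fact that real exome panels show a strong rare
excess and near-power-law discovery — which is the premise of using a
log-linear projection at all — and it is the stated limitation of the
method: applied to a saturating spectrum, the projection is an upper bound,
and the package makes no attempt to hide that.

## The two-population Wright–Fisher simulator

The compiled simulator (`simulate_pair()`) implements a finite-site,
biallelic Wright–Fisher model: per generation, $\mathrm{Poisson}(2N\mu L)$
new mutations land on random haplotypes at random positions (optionally
weighted by a shared per-site rate field, which changes where mutations land
but not how many arrive); viability selection is multiplicative across sites
with genotype fitnesses $1$, $1+hs$, $1+s$ ($h = 0.5$ by default,
codominance); recombination draws the generation's total crossover count
once from $\mathrm{Poisson}(2N\,rL)$ and scatters it over gametes (an exact
Poisson thinning) with uniform breakpoints. One ancestral population is
burnt in to mutation–selection–drift balance, duplicated, and the two
copies evolve independently for the post-split horizon; SNPs are
ascertained as sites segregating in a sample (whole population by default),
and per-iteration $\mathrm{coSNP}_{O/E}$ uses $n = L$. Iterations in which
a population has no SNP leave the ratio undefined and are flagged. All
randomness flows through R's RNG, so a seed makes runs bit-reproducible.

The full-scale configuration is $N = 10^4$ diploids per population,
$L = 2.5$ Mb, $r = 10^{-8}$, 1000 post-split generations, a grid of
$s \in \{-0.01, -0.05, -0.1, -0.15\}$ by
$\mu \in \{10^{-8}, 5\times10^{-8}, 10^{-7}\}$, 1000 iterations per
scenario. The desk preset rescales on the diffusion scale: $N = 500$,
$L = 20$ kb, $\mu$ and $r$ multiplied by $10^4/N = 20$ (preserving
$\theta = 4N\mu$ per site), post-split generations divided by 20 (preserving
$t/2N = 0.05$), with a $2\cdot 2N$-generation burn-in — long relative to
both the sojourn time of deleterious variants and the post-split horizon, so
the split starts from equilibrium at a fraction of the $10\cdot 2N$ cost
used by the full-scale default. Calibration: under neutrality the mean
number of segregating sites matches Watterson's
$\theta\, a_{n-1}$ within 10%, and a split from a monomorphic ancestor (no
burn-in) gives mean O/E statistically indistinguishable from 1.

### What the selection contrast actually shows in this regime

With a burnt-in ancestor, the dominant contribution to $n_{co}$ at a
divergence of only $t/2N = 0.05$ is shared ancestral polymorphism. A
standing deleterious variant declines deterministically at rate $hs$, so
the probability that it still segregates in *both* descendants after $t$
generations falls roughly like $e^{-2hs\,t}$, while the per-site standing
polymorphism probability falls only like $1/hs$; the shared excess
$\mathrm{coSNP}_{O/E} - 1 \approx \varphi(t)^2 / P_{seg}$ therefore
*decreases* steeply in $|s|$. The simulation shows exactly this: at desk
scale the median per-iteration O/E runs from order $10$–$100$ at
$s = -0.01$ down to order $0$–$1$ at $s = -0.15$, at every mutation rate,
and the two-tailed Wilcoxon contrast between the extreme selection levels
is overwhelmingly significant ($p \ll 10^{-5}$). The direction, however, is
the opposite of the intuition that "stronger selection means more
coincidence": a homogeneous-sites model with shared ancestry cannot produce
rising O/E with rising constraint at short divergence. What does produce
it — and what the degeneracy and constraint-binning analyses measure on
real-data-like input — is *between-site heterogeneity in tolerance*: when
selection confines polymorphism to a tolerant fraction $f$ of sites, O/E
rises as $1/f$ regardless of divergence. The synthetic generator plants
exactly this mechanism (tolerant fraction falling with constraint tier),
and the pipeline recovers the positive constraint–O/E trend at zero-fold
sites with no trend at four-fold sites. The two-way type II ANOVA of O/E on
selection level and mutation rate (balanced grid, so equal to type I/III)
quantifies main effects and their interaction on whichever grid is run.

## The synthetic-data generator

The generator emulates the statistical structure the analysis consumes, not
primate sequence per se: random sense-codon genes (stop-free by
construction) on one chromosome per species, ~1% divergence with stop
avoidance, mixed strands and occasional strand flips, some genes split into
two colinear blocks; per-species SNP densities of 3% and 1% (a large
human-like panel against a small chimp-like one); a shared gamma rate field
($CV^2 = 1$); five constraint tiers with zero-fold tolerant fractions from
1 down to 0.2; 20% identical-allele sharing among coSNPs; folded-neutral
MAFs discretised on 200 chromosomes with a flatter uniform admixture for
coSNPs; transitions at 73% (Ts/Tv = 2.7). Annotation tables carry the
planted directions the functional analyses look for: exon conservation and
gene dN/dS track the constraint tier, per-site conservation is lower at
coSNP sites by a configurable shift, damaging probability is lower for
coSNPs, and GWAS/disease labels follow configurable odds. Setting every
effect to zero (and odds to 1) yields null data on which the corresponding
tests are calibrated (p-values uniform across seeds).

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium outside the simulator
module (SNP placements are independent given the rate field), indels and
alignment error, sequencing and calling artifacts, base-composition and
context effects beyond CpG, and realistic gene structure. Conclusions about
real primate data rest on the statistics being correct and calibrated, not
on the generator being a sequence simulator.

## Numerical and interface choices

* Coordinates 0-based half-open internally; VCF (1-based) and BED converted
  at I/O. Strands handled by complementing variant alleles onto the coding
  strand at ingest.
* `cosnp_oe()` errors on a zero SNP margin by default (`strict = FALSE`
  returns NA for grid use); $n_{co} = 0$ is a valid ratio of 0.
* Quantile binning uses ranks with ties to the lower bin; group sizes differ
  by at most 1 when scores are distinct; all-identical scores collapse to a
  single group with a warning.
* Nearest-neighbour ties break toward the lower coordinate; distances are
  measured in species-A coordinates.
* The simulator purges fixed derived alleles periodically; a fixed site is
  not segregating in that population, so no SNP or coSNP count changes.
* Problem sizes used by the automated checks (chosen as adequate-power desk
  sizes): 100,000 sites × 200 replicates for the independence null;
  200-iteration scenario pairs at the desk preset for the selection
  contrast; ~150k-site tables over 30–40 generator seeds for the
  closed-form checks ($1+CV^2$ within 5%, $1/f$ within 10%); $N = 200$,
  $L = 5$ kb, 100 iterations for Watterson calibration; 30k-site,
  1000-individual panels over 20 seeds for extrapolation recovery (within
  25%); 400-gene, 10-tier tables for trend recovery and 200 annotation
  seeds for null calibration.

## Known limitations

The pattern-table expectation is a product of marginals (no mutational
context beyond CpG). Degeneracy is classified from the species-A codon;
sites whose degeneracy differs between species after divergence are not
specially flagged. The simulator's selection contrast, run faithfully,
demonstrates the shared-ancestry regime described above rather than a
constraint-driven O/E elevation; the latter requires tolerance
heterogeneity, which is modelled in the generator, not the simulator's
homogeneous sites. Extrapolation assumes the discovery process is in its
power-law regime; on saturating spectra the projection overshoots.
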