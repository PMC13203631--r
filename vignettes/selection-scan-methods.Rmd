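---
title: "Methods: two-population selection-signature scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-population selection-signature scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`sweepscan` implements a complete two-population selection-signature
analysis for diploid SNP-chip genotypes, of the kind used to contrast a
local, environmentally adapted chicken breed against a production-oriented
cross: quality control, population-structure inference, a sliding-window
scan combining population differentiation (F~ST~) with the within-population
nucleotide-diversity ratio, candidate-region extraction, gene annotation by
interval overlap, and gene-set enrichment. Because real paired datasets of
this kind are rarely fully public, the package ships a calibrated
two-population genotype simulator whose ground truth (injected divergence
and sweep intervals) drives every recovery test.

All internal genomic coordinates are 0-based half-open; conversion from the
1-based VCF/GFF3 conventions happens only at the I/O boundary. This makes
window tiling, truncation, merging and overlap arithmetic free of ±1
bookkeeping.

# The scan statistics

**Per-site differentiation.** For alternate-allele frequencies $p_A$, $p_B$
computed over non-missing genotypes in each population,

$$F_{ST} = \frac{(p_A - p_B)^2}{p_A(1-p_A) + p_B(1-p_B)}.$$

This squared-difference form is widely used in chip-based scans, but it is
not bounded by 1: $p_A = 0.9, p_B = 0.1$ gives $0.64/0.18 \approx 3.6$.
Values above 1 are clipped to 1 and the clip count is logged, so the
statistic stays on the conventional $[0,1]$ scale while the ranking of
extreme windows is preserved. When both populations are fixed — zero
denominator — the site is undefined for identical fixation and 1 for a
fixed difference (the limit of the expression). `fst_site()` also offers
the Hudson estimator ($1 - H_w/H_b$) and a frequency-only Weir–Cockerham
variance-components estimator behind the `estimator` flag; the
squared-difference form is the default, and window F~ST~ is the unweighted
mean of defined per-site values.

**Within-population diversity.** At one site with $n \ge 2$ non-missing
diploids,

$$\pi = \frac{1}{n(n-1)} \sum_{i<j} d_{ij}, \qquad
  d_{ij} = \frac{|g_i - g_j|}{2} \in \{0, 0.5, 1\},$$

where $g$ is the alternate-allele dosage. $d_{ij}$ is the expected allele
mismatch when one allele is drawn from each genotype. Note the
normalization is $1/(n(n-1))$ — half the conventional mean pairwise
difference $1/\binom{n}{2}$. The package implements this form verbatim:
the factor of two is common to both populations and cancels exactly in the
log2 ratio that drives selection, so only absolute π values are affected.
Window π sums the per-site values and divides by the window span in bp
(truncated trailing windows use their actual span), giving per-bp
diversity. The computation uses genotype-class counts
($\sum_{i<j} d_{ij} = \tfrac12 n_0 n_1 + n_0 n_2 + \tfrac12 n_1 n_2$),
which is algebraically identical to the pair sum and is verified against an
explicit double-loop oracle in the tests.

**The diversity ratio.** Per window, $\log_2(\pi_A/\pi_B)$ contrasts the
two populations: a strongly positive value means population B has lost
diversity locally (a candidate sweep in B), a strongly negative value the
converse.

# Windows, thresholds and candidate regions

Windows are 50 kb wide and slide by 25 kb (defaults), starting at 0 on
every chromosome; a window is emitted whenever its start is inside the
chromosome and its end is truncated at the chromosome length. A window
needs at least `min_snps = 3` defined sites for a window-level F~ST~;
single-SNP windows otherwise dominate the extreme tails of the empirical
distribution.

Thresholds are empirical quantiles computed genome-wide over all defined
windows, with linear interpolation between order statistics (the
$(q(m-1))$-th order statistic, R's type-7 convention) and *strict*
inequality at the threshold, so exact ties are excluded. The defaults take
the top 5% of window F~ST~ and the top/bottom 2.5% of the log2 ratio.
Candidates selected in population B are the intersection of the F~ST~ tail
with the high-ratio tail; candidates in A intersect with the low-ratio
tail.

One boundary case required a decision. A window where the swept population
is *completely* monomorphic has $\pi = 0$ and an undefined (infinite) log2
ratio. Excluding such windows from the ratio ranking is correct for
threshold computation — an infinity cannot enter a quantile — but dropping
them from selection would discard precisely the strongest sweep signal the
statistic can produce: a complete sweep at full intensity. The package
therefore computes quantile thresholds over finite ratios only, and treats
a window with exactly one zero-diversity population as lying beyond the
corresponding tail (selected on that side, subject to the same F~ST~
intersection). Windows where *both* populations have zero diversity carry
no directional information and are never selected.

Selected windows of one direction that overlap or are book-ended are merged
into maximal candidate regions; a gene is annotated to a region if their
half-open intervals share at least one base pair, ignoring strand, and each
gene is reported once per direction.

# Quality control

Three per-site filters run in a fixed order, each removal attributed to
the first failing filter: call missingness > 0.10, folded minor-allele
frequency < 0.05 (computed over non-missing genotypes), and a
Hardy–Weinberg exact-test p-value < 10^-6^. Both boundary comparisons are
strict, so a site exactly at a threshold is retained, and passing the
vacuous thresholds (1, 0, 0) is the identity filter. The HWE exact test
conditions on the observed minor-allele count: the heterozygote count $k$
(sharing the allele count's parity) has conditional probability
proportional to $2^k n! / (n_{AA}!\, k!\, n_{aa}!)$, and the two-sided
p-value sums all outcomes no more likely than the observed one. The
implementation works in log space and is verified against exact factorial
enumeration for every genotype configuration with $n \le 10$.

By default HWE is tested on the merged two-population matrix, matching
common chip-QC practice for a merged dataset; this deliberately conflates
the Wahlund effect (structure-induced heterozygote deficit) with
genotyping error, which is why the filter's α is so small. A
`hwe_mode = "per_population"` flag tests each population separately and
removes a site when its minimum per-population p-value falls below α.

The exact test is discrete and conservative at moderate sample sizes: at
288 diploids its null p-values deviate visibly from uniform (a
Kolmogorov–Smirnov distance near 0.13) purely because of the lattice of
attainable heterozygote counts. The test-suite uniformity check therefore
runs at a large per-site sample (5,000 diploids), where the discrete
support is fine enough that the null distribution approaches uniformity;
this is a property of the statistic, not of the implementation.

# Population structure

**Relationship matrix and PCA.** Each site is standardized as
$z = (g - 2p)/\sqrt{2p(1-p)}$; missing entries contribute zero after
standardization (mean imputation), monomorphic sites are skipped, and
$R = ZZ^\top/m$. PCA is the eigendecomposition of $R$; coordinates are
eigenvectors scaled by $\sqrt{\lambda}$, variance fractions are
$\lambda_i / \sum_j \max(\lambda_j, 0)$, and each eigenvector's
largest-magnitude entry is made positive so plots are reproducible up to
data, not solver, conventions.

**Distances and the NJ tree.** The allele-sharing p-distance
$d(i,j) = \operatorname{mean}_s |g_{is} - g_{js}|/2$ over sites non-missing
in both samples feeds a from-scratch Saitou–Nei neighbor-joining
agglomeration: repeatedly join the pair minimizing
$Q(i,j) = (n-2)d(i,j) - r_i - r_j$, with branch lengths from the
three-point formulas. Negative branch lengths — possible on non-additive
input — are clamped to zero with the deficit transferred to the sister
branch, preserving the path length through the joined pair. Ties in $Q$
break deterministically on the first (row-major) minimal pair. The tree is
serialized as newick with a trifurcating root. On additive matrices the
algorithm recovers the generating tree exactly (verified to 1e-9 on random
4–8-taxon trees against path-length oracles and an independent NJ
implementation).

**Ancestry proportions.** The sNMF-style ancestry model is implemented as
masked alternating least squares: $X \approx QF$ with $X = $ dosage/2
($n \times L$), $Q$ row-stochastic ($n \times K$) and $F \in [0,1]^{K
\times L}$. Updates are ridge-stabilized least squares followed by
projection — rows of $Q$ onto the probability simplex (Euclidean
projection), $F$ clipped to $[0,1]$. Missing entries are excluded from the
loss by refilling them from the current reconstruction each iteration
(an EM-style fill). Because projected ALS is not guaranteed monotone, an
update that would increase the training loss is rejected and the fit stops
there; the logged loss trace is therefore non-increasing by construction.
Convergence is declared at a relative training-loss change below 1e-6 or
500 iterations.

Model selection follows the held-out cross-entropy idea: before fitting, a
random 5% of observed entries is masked, and the binomial cross-entropy of
the reconstruction on those entries (clipped to $[10^{-6}, 1-10^{-6}]$) is
the criterion. `select_K()` fits each candidate K with several restarts
and keeps each K's minimum; crucially, the held-out mask is shared across
K within a restart — the same validation entries score every model, as
cross-validation shares folds across models — which removes mask-sampling
noise from the comparison and makes the selected K stable. In `run_all`
the NMF runs on a deterministic every-k-th-site thinning (default 10,000
sites), the usual practice for ancestry inference on dense chip data;
PCA, distances and the scan always use the full matrix.

# The synthetic-data generator

The generator emulates the study conditions: two populations of 144
diploids genotyped at ~60,000 biallelic SNPs placed uniformly over a
five-chromosome, 300-Mb genome (90/75/60/45/30 Mb) — a desk-scale stand-in
for the macrochromosome-dominated chicken karyotype. Its model is
Balding–Nichols divergence: an ancestral frequency
$p \sim U(0.05, 0.95)$ per site (the floor standing in for chip
ascertainment's depleted rare-variant spectrum), independent
per-population frequencies
$\tilde p \sim \mathrm{Beta}\bigl(p\tfrac{1-F}{F}, (1-p)\tfrac{1-F}{F}\bigr)$
with $F$ the genome-wide divergence, and binomial(2, $\tilde p$)
genotypes. Selective sweeps act deterministically on frequencies: inside a
sweep interval the swept population's frequency moves to
$f + \mathrm{intensity}\cdot(\mathrm{round}(f) - f)$, so intensity 1 fixes
every in-sweep site and erases diversity exactly within the truth
interval. A configured fraction of sites violates HWE via an
inbreeding-like deflation of the heterozygote probability
($P(\mathrm{het}) = 2pq(1 - 0.5)$ by default), and calls are masked i.i.d.
at the missingness rate. Everything is reproducible from one seed.

Defaults, chosen once as a realistic regime for a chip-based two-breed
contrast and fixed throughout: $F = 0.05$ (moderately diverged breeds),
2% missing calls, 2% HWE-violating sites, and one 500-kb intensity-1.0
sweep per population. Because frequencies, not haplotypes, are simulated,
the generator has *no linkage disequilibrium*, no genotyping-error model,
no sex chromosomes and no pedigree structure. The scan statistics depend
only on allele-frequency structure and genotype draws, so this is
sufficient for testing them — but passing recovery tests here says nothing
about LD-driven phenomena (haplotype statistics, LD pruning effects) or
about real chip error modes.

# The pipeline

`run_all()` executes simulate/load → QC → structure → scan → annotate →
enrich, writes every stage's outputs (VCF, TSV, BED, newick, JSON
manifest) under one directory, and halts on the first stage failure with
the stage named. Each stage derives its own RNG substream from the master
seed, so adding or re-running a stage never perturbs another's draws; a
rerun with the same configuration and seed is bit-identical file for file
(checksums are recorded in the manifest; stage timings, which naturally
vary, live alongside them and are not part of the determinism contract).
All randomized stages are single-threaded. `validate_config()` checks
every configuration invariant up front and returns named violations;
boundary QC thresholds that are legal (if vacuous) for direct `apply_qc()`
calls are rejected for pipeline runs.

The numbered scripts under `analysis/` run the same stages as separate
narrative steps over files in `results/`, which doubles as a demonstration
that staged invocation and `run_all()` agree.

# Problem sizes and known limitations

The shipped tests run the full default scale (288 × 60,000) for the
end-to-end determinism and sweep-recovery checks, 10,000-site simulations
for divergence calibration, and 2,000-site simulations for structure
recovery; oracle-equivalence checks use small random instances where
brute force is exact and fast. Known limitations, beyond the generator's
scope above: the squared-difference F~ST~ is an index, not an unbiased
estimator (no sample-size correction; use the `wc` flag when sample sizes
are very unequal); the NMF optimizer is a simplified stand-in for the
published sNMF algorithm and is documented as such (contract preserved:
row-stochastic Q, held-out cross-entropy selection); enrichment takes a
user-supplied gene-set table and makes no attempt to model GO hierarchy or
term redundancy; and multiallelic sites, BCF, PLINK binary and indexed
access are out of scope — VCF with GT fields is the single genotype
interchange format.
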