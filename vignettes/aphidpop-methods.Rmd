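---
title: "Methods: diversity statistics and X-scaffold assignment for clonal aphid lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity statistics and X-scaffold assignment for clonal aphid lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aphidpop)
```

This vignette is the package's account of its models and the choices made
where the design was genuinely open: what each statistic computes and under
which missing-data conventions, how the X-assignment mixture is fitted, what
the synthetic-data generator does and does not emulate, and the numerical
and boundary decisions that define edge-case behaviour.

## The biological setting

Aphid clonal lines are laboratory lineages descended asexually from single
field-collected females; all members of a line share one diploid genotype.
Males are produced asexually in autumn and are identical to their mother
except for the random loss of one X chromosome (females XX, males X0), and
— uniquely to this system — both sexes transmit an X to every sexual
offspring, so X and autosomal effective population sizes are expected to be
essentially equal.

Two male morphs (winged and wingless) from a line heterozygous at an
X-linked wing-determination locus carry *alternate* maternal X haplotypes
but *identical* autosomes.  Genome-wide consensus comparisons between such
brother males therefore reveal X linkage: a scaffold on the X differs
between the brothers at the rate at which two haplotypes drawn from the
population differ (≈ π), an autosomal scaffold at (ideally) zero.

## Consensus calling

Per-line consensus follows a hard-filter rule: only bases with Phred
quality strictly above 20 are considered; if the modal base exceeds 80% of
the retained observations it is the consensus, otherwise the position is
ambiguous (`N`).  Decisions taken where the rule is silent:

* Both inequalities are strict: a Q20 base is discarded, a modal fraction
  of exactly 0.8 yields `N`.  Ties for the modal base can never exceed the
  threshold, so no tie-break is needed.
* Positions whose observations were all filtered out, like uncovered
  positions, are *no data* (`-`), distinct from `N`, and excluded from
  every denominator downstream.  `N` marks ambiguity among observed reads.
* Read-start/end marks and indel insertions in the pileup dialect are
  stripped before counting; only base substitutions enter the rule.
* A line's two male samples are merged (observations concatenated
  position-wise) before calling, so each line yields one sequence set.

One property worth stating because it is easy to assume and false: raising
the quality cutoff does **not** monotonically reduce the number of called
(non-`N`) bases when more than two quality values occur — removing a
dissenting mid-quality read can push the modal fraction over 0.8 and turn
an `N` into a call (e.g. 4×A at Q30 + 2×G at Q21 is `N` at Q20 but `A` at
Q25).  Coverage (positions with any retained data) is monotone, and under
the package's two-tier quality model calls are monotone too; the tests
assert exactly these forms.

## Diversity statistics with missing data

Low-coverage consensus data have a different sample size at every site, so
the estimators are per-site normalized.  With `n_i` valid (non-`N`,
non-missing) alleles at site *i*, sites with `n_i ≥ 2` counting toward the
valid length `L`:

* segregating: site with ≥ 2 distinct valid alleles;
* Watterson: `θw = Σ_i s_i / a1(n_i) / L`, `a1(n) = Σ_{k<n} 1/k`;
* diversity: `π = Σ_i h_i / L`, `h_i = n_i/(n_i−1) (1 − Σ_a p_a²)` —
  algebraically the fraction of differing pairs at the site;
* Tajima's D uses the 1989 variance constants at a single sample size
  `n_eff = round(mean n_i over segregating sites)` with the region's summed
  π and θw.  D is reported `NA` (never 0) when `S = 0`, `n_eff < 4`, or
  the variance term is non-positive.  Whether to use the panel size or a
  coverage-adjusted `n` is genuinely open for data this sparse; `n_eff`
  keeps D stable as coverage varies and is applied uniformly, so contrasts
  between region classes are unaffected.
* Fst (two populations) is Hudson's `1 − Hw/Hb` with within- and
  between-population sums taken over sites before the ratio
  (ratio-of-sums); negative values under panmixia are legal and preserved.
  A Weir–Cockerham variance-components version is available as a
  cross-check (`fst(..., method = "wc")`).

Gene regions come from GFF3: whole gene, gene ± 5 kb, CDS, 5′/3′ UTRs,
introns (gene span minus exons), and 10-kb upstream/downstream intergenic
flanks.  Flanks are strand-aware and clipped at scaffold ends but *not* at
neighbouring genes.  Analysed regions must contain at least 50
polymorphisms (inclusive), scaffolds for X assignment must exceed 100 kb
(exclusive) at full scale; both thresholds scale with the simulated
problem sizes in tests.

Synonymous/nonsynonymous classification substitutes each observed allele of
a variable CDS site into the codon's majority-base background.  At the
study's coverage a line covers all three positions of a codon only ~2% of
the time, so requiring complete per-line codons would discard essentially
all sites; the background-codon form keeps the single-variable-position
restriction (codons variable at more than one site, or with an uncovered
background position, are excluded as ambiguous) without demanding per-line
completeness.  Multi-hit pathway averaging is deliberately out of scope.

## The corrected difference and the t mixture

For each scaffold, `diff_per_bp` counts differing positions among those
called in both brother males, and `cd = diff_per_bp − π` with π from the
full line panel on the same scaffold.  Scaffolds failing the length or
polymorphism filters are excluded from the fit and reported unclassified.

The `cd` distribution is bimodal — a large autosomal component centred
near `−π` and a smaller X component centred near zero — and is modelled as
a two-component location-scale Student's-t mixture, fitted by EM using the
scale-mixture representation (responsibilities plus latent precision
weights).  Numerical choices:

* Initialization encodes the scientific expectation: `μ_X = 0`, `μ_A` at
  the median of the negative half of the data, `w_A = 0.85`, MAD-based
  scales; five additional jittered restarts, best log-likelihood kept;
  restart jitter is seeded, so fits are reproducible.
* Degrees of freedom are estimated per component by an ECME step (direct
  1-D maximization of the observed log-likelihood over `log ν` in
  [0.5, 200]); every step is monotone in the observed log-likelihood, which
  the tests assert on every run.  `ν` can be fixed instead.
* Convergence: improvement `< 1e-8` for three consecutive iterations, cap
  500; non-convergence returns a flagged fit with a warning.
* Components are relabelled so `μ_A < μ_X`; a mixing weight at or below
  `1e-3` flags a degenerate, effectively single-component fit (e.g. data
  containing no X scaffolds).

The posterior `p_x` is evaluated in log space.  `p_x` is monotone in `cd`
between the component modes; in the extreme tails its limit depends on the
`ν` ordering (with equal `ν` both tails decay at the same polynomial rate
and `p_x` tends to the mixing weights), which is immaterial in the data
range.  Scaffolds are labelled X when `p_x > 0.5`, autosomal when
`< 0.5`; exactly 0.5 is left unresolved rather than forced.  A depth-ratio
check (mean male read depth of predicted-A over predicted-X scaffolds,
expected → 2) and a predicted-vs-verified cross-tabulation support the
classification.

## What the generator emulates — and what it does not

Defaults are the study conditions: ~12% of scaffold length X-linked;
21 diploid lines; θ = 0.005/bp placed under the infinite-sites model with
derived counts ∝ 1/i (density θ·a1(2n), which makes E[π] = θ); one
high-coverage line (9 reads/bp per male, ~18 for the pair on autosomes)
providing the brother males; panel lines at 0.2 reads/bp per male so that
after merging and quality filtering ~5–6 of 21 lines are represented per
bp; per-site Poisson depth halved on the male X; error rate 1e-3 with
errors uniform over the three other bases; two quality values straddling
Q20 so the filter acts deterministically; optional single-breakpoint
X/autosome chimeras.  Site positions are drawn without replacement — the
exact limit of rejection-resampling — and the generator refuses densities
above 0.1/bp where the infinite-sites assumption becomes meaningless.
`sfs_alpha > 1` (counts ∝ i^−α) skews the spectrum toward singletons, per
mutation class if desired (with optional per-class thinning to emulate
purifying constraint), which is how the directional selection-signature
checks are built.

At scale the study engine draws per-position counts of quality-passing
bases directly (Poisson thinning of depth, binomial errors, binomial
allele split at heterozygous sites) instead of materializing reads; this
is distributionally identical to the read-level pileup generator and feeds
the same consensus-rule code path, which the tests exercise on both
routes.

Not emulated: linkage (sites are independent, so between-region variance
of D is smaller than under a coalescent with recombination — estimator
*means* are unaffected, which is what the checks use); the real studies'
uneven per-line coverage; indels, structural variation and alignment
artifacts; reference bias.  Passing tests therefore validate the
estimators and the assignment machinery under the stated sampling model,
not robustness to alignment pathologies.

### Sequencing error and the centering of `cd`

A consensus call backed by a single Q>20 read is wrong with probability
equal to the post-filter error rate, which inflates pairwise diversity by
roughly twice that rate (partially offset by heterozygote masking).  At
the default low panel coverage most calls are single-read, so panel π
carries this inflation while the high-coverage brother-male consensus does
not.  Consequently `cd` on X scaffolds centres slightly *below* zero (on
the order of −4×10⁻⁴/bp at error rate 1e-3, against π = 5×10⁻³ — measured
by the acceptance checks), and brother-male differences on autosomes sit
slightly *above* zero (~+4×10⁻⁵/bp, the male miscall rate).  Both offsets
vanish as the error rate does, and both components shift together, so the
X/A separation — and classification accuracy — is unaffected.  The strict
within-Monte-Carlo-error centering check in the acceptance suite fails for
exactly this reason and is left failing as an accurate statement about
error-prone low-coverage consensus data rather than loosened.

## The life-cycle simulator

`simulate_life_cycle()` is a forward infinite-alleles simulation of the
annual cycle: parthenogenetic generations copy a resampled set of mothers
exactly (plus mutation); in the sexual generation each female contributes
one male — a clone missing one maternal X, the same copy at every X locus,
since male production involves no recombination — and offspring are formed
from a maternal gamete and a sperm that always carries the sire's X.
Making males a permutation of mothers (rather than an independent
resample) avoids an extra drift stage that is no part of the
neutral-equivalence prediction, and makes the obligately sexual control
(zero parthenogenetic generations) match Wright–Fisher diversity
θ/(1+θ), θ = 4Nμ, which the tests verify.  The X0 male stage itself still
adds slightly more drift to the X than to autosomes (two sperm of one male
share his single X), depressing the X:A ratio by a few percent at five
parthenogenetic generations per year — visible as ratios of ~0.92–1.02
across seeds and well inside the Monte-Carlo tolerance of the 1:1 check.

## Problem sizes used in validation

The package's own validation runs use desk-scale versions of the study:
replicates of ~100–150 scaffolds of 8–16 kb (with the length filter scaled
to 5 kb) for corrected-difference centering and end-to-end classification;
200 independent 10-kb regions for the neutral Tajima's-D check; 12 male
pileup simulations for the depth ratio; and 150–200 females × 50–120 loci
× 70–80 years for the life-cycle checks.  These sizes were chosen so that
Monte-Carlo standard errors are several times smaller than the effects
being checked; every stochastic assertion is made within 3 SE over
replicate seeds.

## Known limitations

* Statistics assume biallelic-leaning, independently evolving sites;
  no linkage-aware statistics (LD, haplotype tests) are provided.
* Synonymous/nonsynonymous classification ignores multi-hit codons and
  pathway ambiguity.
* The mixture model assumes exactly two components; chimeric scaffolds are
  flagged only through intermediate posteriors, not split.
* Scaffolds below the length filter are never assigned.
* GFF3 handling covers the gene/mRNA/exon/CDS/UTR feature set the pipeline
  produces and consumes; exotic annotation structures (trans-splicing,
  shared exons across genes) are out of scope.
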