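---
title: "Quantitative methods behind the tpbla screen analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative methods behind the tpbla screen analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpbla)
```

# The assay and what the package quantifies

In a tripartite β-lactamase assay (TPBLA) a test protein is fused in-frame
between the two domains of TEM-1 β-lactamase and expressed in the
*E. coli* periplasm. Only when the insert folds without aggregating do the
two enzyme halves reconstitute, so bacterial survival on ampicillin reads
out the insert's innate aggregation propensity. Used as a directed-evolution
screen, an error-prone PCR library of the insert is plated on a selective
ampicillin concentration; survivors are sequenced, and the positions that
are repeatedly substituted ("hotspots") mark aggregation liabilities.

`tpbla` implements the quantitative machinery around that experiment:
survival-curve scoring, replicate statistics, ranking and representative
selection; codon-level single-base reachability analytics; mutational
profiling of survivor libraries with hotspot calling, substitution spectra
and bias-weighted expected substitution frequencies; relative surface
accessibility from structures; and a synthetic generator that emulates the
whole screen so every stage can be exercised and validated without
laboratory data.

# In vivo growth score

The raw readout per variant, replicate and ampicillin concentration
$x_i$ is MCD~GROWTH~, the maximal 10-fold cell dilution still allowing
growth (an integer $y_i \in [0, 8]$ under the standard 8-dilution
spotting). A curve is summarised by the trapezoidal area

$$A_\mathrm{curve} = \sum_{i=1}^{n-1} \frac{y_i + y_{i+1}}{2}\,(x_{i+1} - x_i),$$

in dilution-steps × µg mL⁻¹ ("A.U."). On the standard gradient (0–140
µg mL⁻¹ in 20 µg mL⁻¹ steps) this is a sum of exactly 7 trapezia; the
implementation accepts any strictly ascending grid. Replicates are
aggregated as mean, $n-1$ standard deviation and s.e.m.; a single
replicate reports its s.d. as unavailable (`NA`) rather than zero.

Absolute A.U. magnitudes depend on how the MCD axis is encoded
numerically, which is a convention; the package's values are internally
consistent but no claim is made that they match any particular published
axis scaling. Comparisons that matter — ranks, differences in units of the
replicate s.d., and enhancement percentages
$100\,(v - b)/(r - b)$ relative to a baseline $b$ and reference $r$ —
are invariant to affine rescaling of the axis. Enhancement percentages are
rounded half-away-from-zero to integers, matching how such percentages are
reported.

`selectRepresentatives()` reproduces the screen's walk across a ranked
list: score bins of width one replicate s.d. are laid down from the top
score ($[\mathrm{top}-k\sigma,\ \mathrm{top}-(k-1)\sigma)$, the top score
itself in bin 1), and within each occupied bin the variant with the fewest
substitutions is picked (ties: higher score, then lexicographic id). An
optional baseline stops the walk.

# Genetic-code analytics

Every codon has exactly nine single-base neighbours. The *reachable set*
of a sense codon is the set of amino acids encoded by those neighbours,
stops excluded and the codon's own amino acid included only when a
synonymous neighbour exists. Reachable sets and substitution reports are
rendered in decreasing Kyte–Doolittle hydropathy. The KD scale has one
tied group, {E, Q, D, N} at −3.5; the package uses the fixed total order
E < Q < D < N (exported as `KD_ORDER`). E before Q before N and D before N
are forced by how reachable sets for lysine and asparagine codons are
conventionally printed; D against E/Q is not constrained by any such
report, and the choice here is alphabetical-by-hydropathy-family, fixed
once.

`minBaseChanges()` gives the minimum Hamming distance from a codon to any
codon of a target amino acid; substitutions needing ≥ 2 changes are the
"multi-base" events that per-position reports flag, since a single
error-prone PCR cycle essentially never makes two hits in one codon.

# Library profiling

Variants are compared to the parent codon-by-codon. Only substitutions
are modelled: any length difference is treated as an indel and the variant
excluded with a logged reason, which matches substitution-dominant
mutagenesis kits and the fact that survivors are in-frame by construction.
Variants that gain a stop codon cannot express the full-length fusion, so
they are excluded from all *survivor* profiles. For a *naive* (unselected)
library, built with `excludeStops = FALSE`, stop-carrying variants do
contribute to the per-kb mutation rate and to the nucleotide bias: the
premature stop is itself a product of the mutagenesis process, and
excluding such variants would thin the Poisson mutation load and bias the
rate estimate low by roughly the per-hit stop probability (~4%).

The positional profile counts nonsynonymous events per residue and
normalises to a cumulative frequency of 1. Hotspots are positions with
frequency above mean + 2σ. By default mean and σ are computed over **all**
residue positions of the scored region, zeros included; `mode = "mutated"`
restricts them to mutated positions, since which convention a given report
used is often unstated. A uniform profile (σ = 0) yields no hotspots.

The nucleotide bias matrix is the 4×4 row-normalised tally of from→to
single-nucleotide changes in a naive library, with a default pseudocount
of 0.5 per cell (a Jeffreys-style smoother that keeps rare rows finite at
the depths — tens of sequenced clones — these libraries are characterised
at). Bias is modelled as position-independent on the sequenced strand;
strand symmetry is not assumed.

The expected frequency of observing amino acid $a$ at a position with
parent codon $c$ is

$$P(a \mid c) = \frac{\sum_{c \to c'\,:\ \mathrm{aa}(c') = a} w(c \to c')}
{\sum_{c \to c'\ \mathrm{nonsyn,\ non\text{-}stop}} w(c \to c')},$$

with $w$ the bias probability of the underlying nucleotide change. The
denominator excludes synonymous and stop outcomes because observed
frequencies are tallied over amino-acid substitutions among full-length
survivors; with that convention the expectations sum to 1 over the
reachable nonsynonymous amino acids of every sense codon, which the test
suite verifies for random bias matrices. Whether a published table used
this normalisation, or included stops or a per-position bias, is generally
not recoverable without the underlying naive-library data, so no exact
agreement with printed expected-frequency values is claimed.

# Relative surface accessibility

`sasa()` implements Shrake–Rupley: each heavy atom carries a
deterministic golden-spiral lattice of N points on its probe-expanded
sphere (probe 1.4 Å, N = 960 by default); the accessible fraction times
$4\pi(r+p)^2$ is the atom's area. The embedded van der Waals radii are a
Bondi-style heavy-atom set (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å);
hydrogens are ignored. Isolated atoms match the closed form to < 1% at
N = 960, and total areas change by < 2% between N = 960 and N = 4000 on
the test systems. Coincident atom centres are deduplicated with a warning
(the duplicate scores zero area) so results stay deterministic.

RSA divides a residue's area by the maximum possible area for its type
from the Miller et al. Gly-X-Gly survey (embedded as `MILLER_MAX_ASA`).
Values slightly above 1 occur for extended conformations and are flagged,
not clipped. Published per-residue RSA values computed with other tools
and radii on other structural models will differ by up to ~10–15%; this
package reproduces the normalisation convention, not any specific tool's
output.

# The synthetic screen generator

The generator produces everything the wet lab produces, so the pipeline
can be validated by parameter recovery.

*Error-prone PCR* (`simulateEpcr`): per variant the mutation count is
Poisson(rate × length/1000) — a per-base process, which is how the kits
behave — with distinct positions drawn uniformly without replacement and
the substituted base drawn from the bias row. The default rate, 8.1
mutations per 1000 bp, is a realistic kit setting for an aggressive
library on a ~750-bp antibody-fragment gene.

*Phenotype* (`phenotypeModel`): the latent growth score is additive —
baseline 172 A.U. (an aggregation-prone parent), +300 per nonsynonymous
hit at a planted liability position, a deleterious penalty of −40 with
probability 0.2 for other nonsynonymous changes (purifying background),
and Gaussian noise of s.d. 25. Epistasis is deliberately out of scope: an
additive model is the simplest one sufficient for recovery testing. An
internal stop scores exactly 0 — no functional fusion.

*Curves and selection* (`selectionModel`): the MIC is affine in the
latent score (0.16 µg mL⁻¹ per A.U., clamped to [0, 320]), and
$\mathrm{MCD}(x) = \mathrm{round}(8\,\mathrm{logistic}(0.08\,(\mathrm{MIC}-x)))$
gives the step-like curves plate assays show (the drop spans roughly ±25
µg mL⁻¹). A latent score ≤ 0 maps to the all-zero curve: it denotes a
nonfunctional fusion, not merely a weak one. Plate selection retains
variants with MCD ≥ 1 at 80 µg mL⁻¹. No quantitative aggregation→MIC
mapping is published for such screens; the logistic link is an explicit
modelling choice of this package.

*Benchmark* (`endToEndBenchmark`): 5000 variants of a random 750-bp
stop-free parent, 12 planted liability positions, full pipeline, then
comparison of called versus planted hotspots. Liabilities are planted
only at codons offering at least 6 nonsynonymous non-stop single-base
neighbours (`codonAccessibility`). This constraint is part of what
"plantable strong liability" means: at a codon where most single-base
changes are synonymous (leucine/serine/arginine family codons go as low
as 5 of 9), a liability is largely invisible to single-base mutagenesis
regardless of its effect size, and real reported hotspots sit at
well-accessible codons. With the default configuration the benchmark
recovers all 12 planted positions with no false discoveries at the
default seed, and keeps mean sensitivity ≥ 0.9 across seeds; in the
vanishing-effect limit the survivor set empties and the report states
zero recovery.

What the generator does **not** emulate: PCR jackpot lineages (variants
are independent), epistasis, codon-usage or context-dependent mutability,
colony-count stochasticity, and any mechanistic folding or aggregation
kinetics. Passing recovery tests therefore demonstrates that the
*analysis* is correct and well-calibrated under a faithful stochastic
model of the experiment's sampling structure — not that any particular
real protein would yield these hotspots.

# Numerical and degenerate-input conventions

- Strict ACGT alphabet; ambiguity codes are rejected (library members are
  clonal Sanger reads, not consensus calls).
- Curves require strictly ascending concentrations and ≥ 2 points;
  duplicate concentrations are an error, not averaged.
- Ranking ties break by fewest substitutions, then lexicographic id, so
  output is a deterministic permutation.
- All randomness flows through one seeded generator per run; seeded runs
  are bit-reproducible, and pipeline TSV output fixes floats to 6
  significant digits so re-runs are byte-identical.
- Profile σ = 0 (uniform profile) returns an empty hotspot set rather
  than calling everything.
- `rsa()` errors on unknown residue types instead of guessing a maximum.

# Problem sizes used by the validation suite

The test suite and the acceptance script size their simulations as the
package's own validation choices: rate calibration uses 2000 variants of a
750-bp parent (the per-kb estimate then carries a Poisson standard error
of ~0.07, tight enough to detect a mis-calibrated generator); bias
recovery uses ~10⁴ nucleotide changes (row-wise total-variation distance
< 0.06); the hotspot benchmark uses the full 5000-variant default; SASA
convergence uses a tripeptide built from ideal extended geometry.

# Known limitations

- Absolute growth-score magnitudes are convention-dependent (see above).
- The hotspot rule is the field's 2σ threshold, not a calibrated
  false-discovery-rate procedure; on non-exchangeable nulls (positions of
  unequal codon accessibility) its false-positive behaviour is
  correspondingly approximate.
- Expected substitution frequencies assume position-independent bias.
- The RSA module reads single-model PDB ATOM records; it does not model
  mutations into structures and does not attempt to reproduce values
  computed by other tools on other models.
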