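---
title: "Reconstructing and typing ancestral class-II peroxidases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and typing ancestral class-II peroxidases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peroxasr)
```

`peroxasr` implements the computational route from a protein alignment and a
rooted phylogeny of fungal class-II (ligninolytic) peroxidases to
resurrected-ancestor candidates, together with the kinetic and stability
analyses used to characterise the resurrected enzymes. This vignette is the
package's account of the underlying models, the tunable parameters, the
numerical choices, and what the validation machinery does and does not show.

## The evolutionary model

Sequences evolve site-independently under a reversible continuous-time
Markov chain on the 20 amino acids. The generator is assembled from a
published empirical exchangeability matrix $S$ (WAG, LG, or Dayhoff,
bundled as plain-text PAML-layout files and parsed at load) and equilibrium
frequencies $\pi$:

$$Q = S\,\mathrm{diag}(\pi), \qquad Q_{ii} = -\sum_{j \ne i} Q_{ij},$$

normalised so that $-\sum_i \pi_i Q_{ii} = 1$: branch lengths are expected
substitutions per site. Reversibility ($\pi_i Q_{ij} = \pi_j Q_{ji}$) makes
$\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$ symmetric, so
transition matrices $P(t) = e^{Qt}$ come from a symmetric
eigendecomposition, with tiny negative round-off clipped and rows
renormalised. Residues are indexed in alphabetical one-letter order
(A, C, D, …, Y) in every matrix and vector.

Frequencies are either the model defaults or `+F` frequencies counted from
the alignment's non-gap residues with a pseudocount of 1 per amino acid
(avoiding zero frequencies on small alignments; the choice matters little
beyond that).

Among-site rate variation uses the discrete-gamma approximation: the
$\Gamma(\alpha, \alpha)$ density (mean 1) is cut into $K$ equal-probability
bins and each category's rate is the bin's conditional mean (computed by the
incomplete-gamma identity, then renormalised so the category mean is
exactly 1). Mean-of-bin rather than median-of-bin is used because it
preserves the mean without ad-hoc rescaling; $K = 4$ by default, the
field's customary compromise between fidelity and cost. Whether the
original reconstructions of this family used rate heterogeneity at all is
not documented; the pipeline supports both, defaults to $+\Gamma$ with
$K = 4$, and can estimate $\alpha$ by bounded 1-D maximum likelihood over
$[0.05, 100]$ (log scale). An estimate at the upper bound is flagged as
effectively rate-homogeneous rather than reported as a meaningful shape.

## Likelihood and reconstruction

The alignment likelihood is computed by Felsenstein pruning. Leaves carry
indicator vectors; gaps and the ambiguity letters X/B/Z/J carry all-ones
vectors (missing data, the convention of the standard reconstruction
software for this task). Partial likelihoods are rescaled per site at every
internal node with accumulated log factors, so alignments of hundreds of
columns cannot underflow. Identical columns are collapsed to patterns with
weights purely for speed; the per-site values are bit-identical to
uncompressed evaluation, which the test suite asserts.

Branch lengths, when re-optimised, use coordinate-wise bounded 1-D search
(lengths clamped to $[10^{-8}, 20]$), at least two full sweeps, stopping
when the total log-likelihood improves by less than $10^{-6}$; the reported
log-likelihood sequence is non-decreasing by construction. Model comparison
uses $\mathrm{AIC} = 2k - 2\log L$, counting as free parameters the gamma
shape if estimated and the branch lengths if optimised, with ties broken by
the order the model names were supplied.

Marginal (empirical-Bayes) reconstruction computes, at every internal node
and site, the posterior distribution over the 20 residues given all leaf
data, integrating over all other internal states and rate categories. The
implementation is a single inside/outside pass: the pruning pass provides
the likelihood of the data below each node; a preorder pass propagates the
likelihood of everything above it. For a reversible model this is exactly
equivalent to re-rooting at each queried node but costs $O(n)$ overall. Two
internal consistency checks guard the algebra: summing the unnormalised
posterior over states must reproduce the site likelihood, and posteriors
must match brute-force enumeration over internal-state assignments on small
trees; both are enforced at $10^{-9}$–$10^{-10}$ in the tests.

The most-probable ancestral sequence takes the per-site argmax, with exact
ties broken by the canonical alphabetical order — a documented, determinate
rule rather than platform-dependent floating-point whim. Node confidence is
the arithmetic mean of per-site maximum posteriors over unmasked sites.

Insertions and deletions are not modelled in the CTMC. Instead, ancestral
presence/absence is decided per site by the node's progeny: a site is
called ancestrally absent when fewer than half of the node's descendant
leaves are non-gap there (exactly half counts as present). This automates
the manual, progeny-based indel curation that resurrection studies apply to
C-terminal and other indels; the threshold is exposed because the manual
step it replaces is a judgement call, and the approximation is exactly
that — an approximation.

## Sampling alternative ancestors

Reconstruction uncertainty is explored by Monte-Carlo sampling from the
per-site posteriors under relative-probability thresholds. For threshold
$\theta$, a residue is eligible at a site iff its posterior is at least
$\theta$ times the site's maximum posterior, and one eligible residue is
drawn with probability proportional to its posterior. The package defaults
are the two thresholds 0.2 and 0.5 with 5000 total sequences; how the
original studies split their 5000 between thresholds, and whether
duplicates were counted, is not documented, so the package declares its own
convention: the requested $n$ is split as evenly as possible across
thresholds, duplicates are retained (so frequency statistics stay
unbiased), and the most-probable sequence is appended if not already drawn
— meaning the returned set holds $n$ or $n+1$ sequences and always
contains the most-probable ancestor. An absolute-threshold mode exists but
is off by default. Randomness is consumed site by site in column order,
with each site's per-threshold block of draws taken at once; identical
(posterior, $n$, thresholds, seed) inputs give byte-identical FASTA output.

## Catalytic typing

Two substrate oxidation sites define the family labels: the Mn²⁺-binding
acidic triad (default positions 37/41/183 with required residues E/E/D) and
the exposed catalytic tryptophan (position 172, W). Position labels resolve
through a site map anchored to a declared reference sequence, with residue
numbers 1-based on the ungapped reference; extant-enzyme numbering differs
by one from the ancestor numbering in this family, which is precisely why
the package refuses to hard-code columns and ties everything to a named
reference. One documented discrepancy is worth stating: the family
literature gives the second triad position once as 40 and elsewhere as 41;
the default rules use 37/41/183 and the rules object is fully configurable.

"Exact match" distinguishes glutamate from aspartate, because a D where an
E is required abolished Mn²⁺ oxidation in the resurrected first-LiP while
two-of-three acidic residues (non-basic third) still supported weak
activity. The triad state is: *typical* (3 exact), *blocked* (2 exact,
mismatch R/K — a basic residue occludes the cation site), *atypical*
(2 exact, non-basic mismatch), or *none* (≤ 1 exact). Histidine is not
counted as blocking. The type is then a total, pure function:
typical → VP/MnP, atypical → VP-atypical/MnP-atypical, blocked or
none → LiP/GP, by tryptophan presence/absence. Gapped rule positions count
as mismatches and are flagged. Sampled sets are partitioned into the triad
subsets (typical / atypical / basic-blocked / other) with per-type
fractions, the statistic behind "100 % of sampled sequences carry the
site" style statements.

## The simulator, and what passing tests show

The synthetic-data generator exists so that reconstruction, sampling, and
typing can be validated against a known truth without any data download.
Topologies are Yule (uniformly chosen tip splits); branch lengths are a
fixed value or uniform range; the root is drawn from $\pi$ (or given); each
site gets one rate category; each branch transforms each site by
$P(t r_k)$. Designed catalytic histories are imposed as *overrides*: forced
residues at a named node, inherited by descendants unless re-overridden.
Overrides are applied after evolution — motif gains and losses are treated
as given history, not as a modelled selective process, mirroring how
resurrection studies treat them as observed events. Per-branch change
counts record visible endpoint differences (not the full jump history,
which endpoint simulation does not resolve); gaps are simulated only as an
optional C-terminal truncation, enough to exercise the gap-mask logic.

`make_peroxidase_like_fixture()` encodes a 10-leaf, 300-column family with
the canonical MnP → VP → LiP history: triad E/E/D and no tryptophan at the
root; W gained at a node two edges below the root; triad degraded
(D37, N183) in a nested clade. Each transition sits at a node whose sibling
still witnesses the ancestral state, so every designed state is supported
by at least two independent branches; this is what makes the fixture's
types decisively recoverable at branch length 0.05, where a design with the
gain directly on a root child would leave the root state genuinely
ambiguous (a single change on either root edge explains the data, and the
model's slight preference for conserving tryptophan can flip the argmax).

What the simulator does *not* emulate: real indel processes, site-specific
structural constraints (heme contacts, disulfides, Ca²⁺ ligands evolve like
any other site here), compositional heterogeneity across lineages, and
alignment error. Passing the recovery tests therefore shows the inference
machinery is correct under its own model assumptions — not that
reconstructions of real peroxidase families reach the same accuracy.

Validation problem sizes were chosen to separate signal from noise while
keeping the suite quick: 4-leaf × 10-site instances for exact enumeration
checks, 16 leaves × 300 sites × 20 paired replicates for the
branch-length/accuracy monotonicity experiment (accuracy ≈ 99.8 % at
branch length 0.02 vs ≈ 73 % at 0.5, and → 100 % at $10^{-6}$), $n = 5000$
draws for the sampling-law checks.

## Kinetics and stability

Steady-state curves are fit by nonlinear least squares (Levenberg–
Marquardt). The single-site model is $v = k_{cat}[S]/(K_m+[S])$,
initialised from the largest observed rate and the concentration nearest
half of it; a fitted $K_m$ above the largest assayed concentration raises a
saturation warning. Biphasic ("sigmoid" in double-log coordinates) curves
are fit as the sum of two independent Michaelis–Menten terms — the standard
reading of two independent oxidation sites on one enzyme (high-efficiency
catalytic tryptophan plus low-efficiency heme-channel site), stated here
prominently because published tables report "two sets of constants" without
a formula. The two-site fit uses a small multistart grid around the
single-site solution, orders sites by ascending $K_m$ (site 1 = the low-Km,
high-efficiency site), is AIC-compared against the single-site model, and
warns when the fitted $K_m$ separation is under 5-fold (the design is then
ill-conditioned). Confidence limits are asymptotic (Wald) from the
parameter covariance, matching the mean-and-95 %-limits presentation of
kinetic tables in this literature.

Units are fixed — $K_m$ in µM, $k_{cat}$ in s⁻¹, efficiency in s⁻¹mM⁻¹ —
and the µM→mM factor of 1000 is applied in exactly one function,
`catalytic_efficiency()`. Efficiencies are reported at 2–3 significant
figures, the precision the source tables print. Relative-efficiency
profiles normalise per substrate to max = 100 %, with absent activities
as 0 %.

Stability: residual activities are percentages of a declared reference
condition (conventionally, activity after 1 min at 25 °C in pH 5 buffer);
values above 100 % are legal. T50 is the linear interpolation of the first
downward 50 % crossing of the residual-activity-vs-temperature curve — an
interpolation, not a fit, because 5 °C-step residual-activity series are
too sparse to constrain a four-parameter sigmoid and the midpoint of the
first loss event is the quantity of interest. Tm is the midpoint of a
four-parameter two-state sigmoid (two baselines, midpoint, width) fit to a
CD-vs-temperature melt; the fit works on the raw least-squares objective
via `nls.lm`, because a noiseless (zero-residual) curve leaves a singular
crossproduct Hessian that the higher-level wrapper treats as failure —
in that case parameters are exact and standard errors are reported as
zero/NA rather than aborting. Flat curves and fits whose midpoint lands far
outside the measured range are errors ("no transition"), not numbers. Both
extractions are invariant to uniform rescaling of the signal axis.
Validation melts are generated at 1 °C spacing, the effective density of a
continuously monitored CD melt at typical scan rates.

## Design choices on genuinely open points

* **Marginal, not joint, reconstruction** — the sampled-ancestor workflow
  needs per-site posteriors, which are marginal objects; joint
  reconstruction is out of scope.
* **Unrooted input trees are refused unless a rooting leaf is named** — the
  ancestors of interest are defined by the root, so guessing one silently
  would be worse than an error.
* **The ambiguous-residue policy** (read, flag, treat as missing) keeps
  real-world FASTA files usable without letting ambiguity codes silently
  bias the likelihood.
* **Tabular surfaces are tibble-first** (kinetics, stability, typing
  fractions, variability, identity, reports) with `tidy()`/`glance()`/
  `autoplot()` methods, while alignments, trees, and posterior matrices
  stay in the field's containers (character matrices, `ape::phylo`,
  numeric matrices) — 20-column probability matrices and trees are not
  naturally data-frame-shaped, and forcing them would only obscure the
  algebra.
* **The command-line layer is thin**: every subcommand is a few lines over
  the exported functions, so scripted runs and interactive R sessions
  cannot drift apart.

## Known limitations

Single-partition, single-matrix models only (no mixtures, no partitioning,
no covarion behaviour); no topology search — the tree is an input; no indel
evolution model; typing inspects sequence positions only and cannot verify
the structural exposure of the catalytic tryptophan; kinetic confidence
limits are asymptotic and can understate uncertainty near parameter bounds
(a bootstrap is the obvious extension); and the published kinetic tables
this package's arithmetic mirrors contain one internally inconsistent row
(the extant-LiP phenolic-substrate row), which is documented and excluded
rather than reconciled.
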