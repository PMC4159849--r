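---
title: "Methods: interface analysis of transmembrane helix dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface analysis of transmembrane helix dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmdimer)
```

# Scope and model

`tmdimer` analyses two-helix coarse-grained (CG) systems — the canonical
case being the Glycophorin A (GpA) transmembrane homodimer, residues
Glu72–Arg96, whose G79xxxG83 motif packs the helices into a right-handed
dimer with a crossing angle near −40°.  The package takes trajectories (or
single structures) of such systems and characterizes the *dimer interface*:
which residues touch, how interfaces cluster into discrete architectures,
how long each architecture lives, how architectures interconvert, and how
completely a batch of simulations has sampled the space of architectures.
Running the simulations themselves (force fields, membranes, thermostats)
is out of scope; the package consumes coordinates and produces statistics.

The analysis chain is:

1. **Contact maps.** For each frame, a boolean matrix over the analysed
   residue segment: entry (i, j) is `TRUE` when residue i of helix A and
   residue j of helix B are closer than the contact cutoff.  The
   inter-residue distance is by default the minimum over all bead pairs of
   the two residues.
2. **Stable-dimer detection.** A dimer is stable once at least
   `stable_contact_min` contacts are present in every stored frame of a
   window spanning `stable_span`.
3. **Clustering.** Contact maps (those with at least
   `stable_contact_min` contacts) are flattened to boolean vectors,
   pairwise Dice dissimilarities
   $(c_{TF}+c_{FT})/(2c_{TT}+c_{TF}+c_{FT})$ are computed, and
   average-linkage (UPGMA) clustering is cut at a fixed height to give the
   interface clusters.  Cluster ids are assigned by decreasing size.
4. **Geometry.** Helix axes, the signed crossing angle, tilt angles and
   helix-length distributions per cluster.
5. **Kinetics.** Retention times (contiguous runs of one cluster label)
   and a pruned directed transition network over the major clusters.
6. **Sampling statistics.** Pearson correlation between cluster-frequency
   vectors of subsampled batches as a function of subsample size, fitted
   with a saturating double exponential.
7. **Topology augmentation.** Elastic-network-style backbone bonds that
   restrain helix geometry in CG topologies, and a screen driver scoring
   helix-length distributions against a reference.
8. **NOE validation.** Fulfillment of maximum-distance constraints by
   atomistic ensembles, per cluster.  Backmapping CG → atomistic is an
   input boundary: the package consumes atomistic ensembles produced
   elsewhere.

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `contact_cutoff` | 0.6 | nm | residue–residue contact threshold (strict `<`) |
| `stable_contact_min` | 19 | contacts | stable-dimer and clustering filter |
| `stable_span` | 100 | ns | time the contact minimum must persist |
| `cluster_frame_interval` | 50 | ns | frame spacing used for clustering |
| `cluster_cutoff` | 0.5 | — | flat-cut height on the UPGMA tree |
| elastic equilibrium lengths | 0.49 / 0.61 / 0.82 | nm | i+3 / i+4 / i+5 backbone bonds |
| force-constant grid | None, 500, 1000, 5000, 10000 | kJ mol⁻¹ nm⁻² | screen values |

These defaults are the standard operating point of the GpA CG analysis this
package implements; all are overridable through `analysis_config()` and
`elastic_bond_spec()`.  Internal units are nm and ns throughout; PDB
Ångström coordinates are converted on read.

# Design choices at genuinely open points

**Residue distance mode.** "Residues in contact" does not pin down a bead
set.  The default `min_bead` uses the minimum over BB and side-chain beads
(side chains carry the GxxxG packing signal); `bb_only` is provided for
sensitivity checks, and the 1AFO acceptance check accepts either mode.

**Which NMR model.**  NMR ensembles contain many models and no single one
is canonical; `read_pdb_models()` defaults to model 1 and takes an explicit
`model` argument.

**Flat-cut semantics.**  The UPGMA cut at 0.5 is applied to cophenetic
merge heights *inclusively* (merges at exactly 0.5 join), matching
`stats::cutree()` semantics.  UPGMA merge heights are monotone in exact
arithmetic; floating-point jitter below 10⁻⁸ is clamped before cutting so
valid trees never fail the cut.

**Cluster identity.**  Cluster numbers from any particular simulation
campaign are arbitrary.  This package orders cluster ids by global
frequency (ties by first occurrence); mapping them onto ids from other
campaigns is done by inspecting contact maps, not by number.

**Helix axis.**  The axis is estimated by the local-helix-axis method:
second differences of consecutive BB positions point radially toward the
axis, so cross products of successive second differences lie along it;
sign-aligned averaging gives the axis.  This is exact for regular helices
of any length, whereas the principal-component axis is measurably biased
(≈1.5° for a 25-residue helix) whenever the helix spans a non-integer
number of turns — which a 6.7-turn transmembrane helix always does.  PCA
remains the fallback for degenerate (near-collinear or very short) input.

**Crossing-angle sign.**  With unit axes $\hat a$, $\hat b$ (N→C) and the
closest-approach direction $\hat w$ from helix A to B, the signed angle is
$\mathrm{atan2}\big((\hat a \times \hat b)\cdot\hat w,\; \hat a \cdot \hat
b\big)$.  Under this convention canonical right-handed GxxxG dimers come
out negative, mirror reflection flips the sign (tested as a chirality
property), and the angle is invariant under rigid-body motion.  Parallel
axes return 0 with a `parallel` attribute rather than erroring.

**Indirect transitions.**  Building the transition net, each trajectory's
label sequence is collapsed onto the node set, so a transition passing
through clusters outside the net counts once.  A round trip A→C→A therefore
collapses to a self-visit and is discarded — excursions invisible to the
net are not transitions.  Pruning keeps edges seen at least twice
(singletons are not reproducible) and at most the three most frequent
outgoing edges per node, ties broken toward the smaller target id.
Transition counts are pooled across trajectories before the minimum-count
filter.

**Dwell runs.**  Unassigned frames (below the contact filter) break dwell
runs by default; `bridge_unassigned = TRUE` absorbs an unassigned gap
flanked by the same cluster.  A dwell's duration is `run length × dt`,
while the stable-dimer window uses first-to-last frame span — the former
measures occupancy, the latter persistence.

**Correlation curves.**  Frequency vectors are always formed over the full
global cluster space (zeros included), so vectors from different conditions
are comparable.  In autocorrelation mode the two size-n samples are
disjoint subsets of one pool (sampling without replacement); degenerate
draws with zero variance yield `NA`, never a silent 1.  The
double-exponential target $r(n) = a(1-e^{-bn}) + c(1-e^{-dn})$ is fitted by
constrained least squares (all parameters ≥ 0) from a fixed multistart
grid, weighted by $1/\mathrm{sd}^2$ when permutation standard deviations
are available and positive; the two exponential terms are reported with the
faster rate first ($b \ge d$), resolving the term-swap symmetry.  The
fitted large-n limit is $a + c$.  A constant curve has no identifiable
rates and is returned directly as a saturated constant with that limit.

**Length-distribution score.**  The difference between two helix-length
distributions is by default the L1 distance over shared 0.01 nm bins
(maximum 2), with an explicit `scale` argument for reporting conventions;
only rankings across a screen are meaningful, not absolute values.

**Command-line layer.**  The pipeline is exposed as seeded R functions
(`run_pipeline()` plus the stage functions) rather than a shell tool: the
package's users drive analyses from R scripts, and every stage writes plain
CSV so any figure can be regenerated from intermediates alone.

# The synthetic generator

`simulate_interface_markov()` produces two-helix trajectories whose
interface switches among a small set of planted states.  Each state fixes
the azimuthal rotation of both helices, the signed crossing angle and the
inter-axis separation; the process dwells in a state for an exponential
time (memoryless — the simplest kinetics consistent with observed
retention-time behaviour), jumps by a row-stochastic embedded chain, and
each stored frame adds isotropic Gaussian bead noise (default σ = 0.05 nm,
chosen so contact maps fluctuate without erasing planted interfaces —
within-state Dice stays well below the 0.5 cut while between-state Dice
stays above it).  `sample_condition_assemblies()` emulates batches of short
self-assembly runs under one membrane condition as i.i.d. draws from a
condition-specific state-frequency vector.

What the generator does *not* emulate: physical energetics (no force field,
lipids or membrane), continuous interface deformation between states,
sub-frame excursions (jumps are resolved at frame resolution `dt`), and
state-dependent noise.  Passing tests on synthetic data therefore
demonstrate that the *analysis* is correct under the stated statistical
model — planted parameters are recovered, invariants hold — not that any
particular physical simulation will show these statistics.

Synthetic atomistic structures (`synthetic_gpa_dimer()`) are ideal helices
carrying the GpA 72–96 sequence with backbone atoms placed to reproduce
standard bond lengths, packed at −40° with the GxxxG faces inward
(separation 0.65 nm, a realistic close-packing inter-axis distance for
GxxxG dimers).  They are labelled synthetic everywhere: they exercise the
atomistic→CG→analysis path and are not a stand-in for experimental
coordinates in any scored comparison.

# Problem sizes and verification

The test suite runs entirely on synthetic data at desk scale: planted-state
recovery on 4 µs / 50 ns-frame trajectories (81 maps), dwell statistics on
50–100 µs label paths at 1–2 ns resolution (hundreds of dwells, assertions
at 3 standard errors), clustering verified against a brute-force
hierarchical oracle on 12-map fixtures, correlation curves on 300-draw
pools with 60–1000 permutations, and noiseless double-exponential recovery
to 10⁻⁴.  The acceptance script (`scripts/acceptance.R`) recomputes the
headline quantities with 1000 permutations at n up to 150.  Two
acceptance-level checks score the experimental 1AFO ensemble and require
that file (locally provided or downloaded); they are the only checks not
self-contained.

# Known limitations

- Hydrogen-bond-level detail (e.g. the interface threonine's hydroxyl
  contacts) is not representable at CG resolution; contact maps are the
  finest interface descriptor used.
- The transition net is count-based, not a Markov state model: no rates,
  lag-time analysis or uncertainty on edges.
- Minimum-image distances support orthorhombic boxes only.
- The force-constant screen consumes helix-length distributions from an
  external provider; it never runs dynamics, so its verdicts are only as
  good as the distributions supplied.
- NOE scoring uses plain minimum distances over ambiguous selectors; no
  $r^{-6}$ ensemble averaging.
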