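---
title: "Geometric construction of click-chemistry products: methods and design"
author: "ClickMol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric construction of click-chemistry products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClickMol)
```

## The problem

Click chemistry restricts synthesis to a small set of reliable,
high-yield reactions, the archetype being the azide–alkyne Huisgen
cycloaddition that fuses R–N₃ and R′–C≡C–R″ into a 1,2,3-triazole.
Enumerating click products *in silico* therefore produces virtual
screening libraries whose every member is easy to make. ClickMol takes
explicit-hydrogen 3D models (PDB), finds the reactive groups itself, and
constructs 3D product models purely geometrically — no force field, no
SMILES round trip, no external 3D builder.

## Bond perception

PDB files carry no trustworthy connectivity for small molecules, so
bonds are perceived from geometry: atoms $i,j$ are bonded iff

$$0.4\,\text{Å} \le d_{ij} \le r_i + r_j + t,$$

with Cordero single-bond covalent radii (H 0.31, C 0.76, N 0.71, O 0.66,
S 1.05, Cl 1.02, Br 1.20, I 1.39 Å) and tolerance $t = 0.4$ Å (tunable
per call). CONECT records, when present, are kept as a union. Hydrogens
are capped at one bond (the shortest wins), which makes perception
robust to marginal contacts. No bond orders are stored; multiplicity is
inferred contextually — an alkyne is two mutually bonded sp carbons of
degree 2, where hybridization is classified from connectivity and bond
angles (sp: carbon with 2 neighbours subtending ≥ 155°; sp2: 3
neighbours with angle sum ≥ 350°, or a 2-neighbour carbon with mean
angle in [115°, 128°]; otherwise sp3 up to degree 4). These thresholds
classify all idealized geometries used here with ≥ 25° margin; heavily
distorted experimental conformers could fall outside them, which is a
known limitation.

Ring perception is bounded at ring size 8 — ample for click chemistry,
wrong for macrocycles, and documented as such. The *ring-bond* test used
by fragmentation (may this bond be cut?) is unbounded: it simply asks
whether the bond's endpoints stay connected without it.

## Functional-group patterns

Groups are matched as element/degree/hybridization graph rules with
role-labelled atoms (an azide match, e.g., labels proximal, medial and
distal N plus the attachment carbon). Two exclusion rules are worth
stating because they are design choices, not consequences of the
patterns: a nitrogen adjacent to a carbonyl carbon is an amide, not a
reactive amine; and the hydroxyl of a carboxyl group is not an alcohol.
Alkene detection refuses pairs of sp2 carbons that share a six-ring
whose members are all sp2 carbons — a deliberately crude aromaticity
guard whose only job is to keep benzene rings from being "epoxidized"
in library mode. Across kinds, the more specific pattern claims its
atoms first (azide before alkynes before epoxide before acids/halides
before amines/thiol/alcohol before alkene).

## Product assembly

Every bimolecular builder follows the same six steps, illustrated by the
cycloaddition:

1. **Fragmentation.** The alkyne is cut along its triple bond, the azide
   along the proximal–medial N–N bond. Each fragment keeps a *handle*
   atom (a former alkyne carbon; the proximal nitrogen).
2. **Tether alignment.** An idealized planar triazole core (uniform ring
   bond 1.36 Å, exocyclic direction points 1.45 Å radially outward —
   idealized values, not fit to a crystal structure) provides target
   positions. Each fragment is placed by a two-point least-squares
   superposition: handle → ring position, handle-adjacent atom →
   exocyclic point. The alignment minimizes the *sum of squared* tether
   lengths via the Kabsch/SVD closed form. (A plausible alternative is
   the sum of unsquared lengths; the squared form has a closed-form
   optimum and the identical minimizer in the near-zero-residual
   configurations used here, so it was chosen deliberately.) Degenerate
   tether sets — one tether, collinear targets — leave residual degrees
   of freedom that the SVD's canonical sign convention fixes, so results
   are reproducible.
3. **Steric relief.** Substituents are rotated about the new exocyclic
   single bonds in fixed 10° steps over [0°, 360°), keeping the angle
   that maximizes the minimum cross-fragment interatomic distance; ties
   break toward the smallest rotation, so a clash-free pose is never
   perturbed. The scan is greedy and sequential over the new bonds in
   formation order — cheap, deterministic, and sufficient because the
   objective is clash avoidance, not conformational optimization.
4. **Scaffold deletion and merge.** Core atoms superseded by fragment
   handles are deleted and the fragments merged; the five ring bonds are
   formed between the handles. Because the handles are real reactant
   atoms, cycloaddition conserves every atom: the product formula is the
   exact sum of the reactant formulas, an invariant the test suite
   enforces across hundreds of seeded pairs.
5. **Regiochemistry.** Non-symmetric alkynes give both regioisomers:
   "1,4" places the larger alkyne branch para-like across the ring from
   the azide substituent (ring carbon C4, adjacent to N3), "1,5" places
   it on C5. Symmetry is decided by element-labelled graph isomorphism
   of the two substituent branches (VF2, cross-checked against a
   brute-force permutation oracle in the tests); a terminal alkyne is
   symmetric only if it is ethyne itself.
6. **Sanity.** Products are screened for non-bonded contacts < 0.7 Å,
   bonded distances outside [0.7, max(1.9, $r_i+r_j+0.25$)] Å (the
   element-aware upper bound admits long single bonds such as C–Br at
   1.94 Å), and triazole ring planarity (max deviation from the best-fit
   plane ≤ 0.1 Å). A product whose fragments cannot be separated beyond
   0.7 Å is *flagged*, never dropped, so library counts stay exactly
   predictable.

The other registry reactions reuse the same machinery with reaction-
specific templates: azide formation grows a linear N₃ unit along the
former C–X (or C–N) vector with C–N 1.47 Å, N–N 1.24/1.13 Å, C–N–N 115°,
N–N–N 172°; epoxide opening bonds the nucleophile anti to the broken
C–O bond and transfers one hydrogen from the nucleophile to the ring
oxygen; amide formation condenses with planar amide geometry (C–N
1.35 Å, 120° in the acyl plane, amine carbon anti to the carbonyl
oxygen). One corner case is deliberate: an azide nucleophile has no
hydrogen to donate, so the opened-epoxide oxygen is left unprotonated
(alkoxide) rather than inventing an atom — exact atom conservation is
the invariant the package promises. Stereochemistry is not modelled
anywhere (no inversion bookkeeping at attacked epoxide carbons);
products are single 3D conformers.

## The combinatorial enumerator

`enumerateLibrary()` crosses reactant collections in deterministic
sorted-label order. Dry-run mode computes exact product counts from the
detected groups and the symmetry rules alone — a pair with a
non-symmetric alkyne contributes 2, a symmetric one 1, a symmetric
epoxide's two attack products collapse to 1 — without building any
geometry, and the tests verify the counts agree with full generation.
Unreadable input files are skipped with a logged warning and a manifest
note; a library run never aborts halfway. With only one collection
given, the unimolecular conversions run (mirroring the standard
preprocessing step of turning a bromide collection into azides before a
cycloaddition campaign).

The Lipinski report uses the original counting rules: donors are O–H
and N–H hydrogens, acceptors are all N plus O atoms, and logP is a
deliberately crude per-element contribution estimate (C +0.27, H +0.12,
N −0.60, O −0.41, S +0.25, halogens +0.59/+0.77/+1.10, table pluggable).
It gates drug-likeness screening only and is never reported as a
physicochemical property.

## The synthetic reactant generator

Tests and the acceptance script need reactant collections at the scale
of real campaigns (a thousand azides, a thousand alkynes) without
downloading anything, so `generateReactantSet()` emits structurally
distinct molecules by decorating alkyl scaffolds — chain lengths 1–12,
optional methyl branches on interior carbons, optional terminal phenyl;
4,096 scaffolds in all, enumerated deterministically and shuffled by the
seed. Scaffolds are anchored trees, so distinct (length, branch-mask,
phenyl) triples give non-isomorphic molecules. Geometrically, branch
methyls alternate sides of the chain plane against a fixed reference
normal, and methyl torsions and phenyl ring azimuths are chosen by a
deterministic max–min-distance scan, which keeps the closest
non-bonded H–H contact at 1.10 Å — clash-free for the perception rule
(H–H bonds would require ≤ 1.02 Å) without any stochastic embedding.

What the generator emulates is the *combinatorics* of a real reactant
library: one reactive group per member, all terminal alkynes
non-symmetric, controlled structural diversity. What it does not
emulate is chemical realism — no heteroaromatic scaffolds, no multiple
functional groups, no conformer ensembles, no protonation states.
Passing tests therefore demonstrate the correctness of perception,
assembly and counting, not robustness to the full messiness of vendor
catalogues.

## Problem sizes and numerical choices

The test suite and acceptance script use the scales the method is
specified at: the ligand-optimization example (1 azide × 23
non-symmetric alkynes → 46 triazoles, full 3D construction, a few
seconds) and the library campaign (1,215 azides × 939 alkynes →
2,281,770 products by exact dry-run counting, with full generation
spot-verified on a seeded random subsample of 1,000 pairs). Property
suites run at 500 seeded pairs (stoichiometry, regio rule, alignment
self-recovery), 300 instances (ring/distance oracles) and 50 cases
(relief vs a 1°-grid oracle), sizes chosen to exercise the whole
scaffold catalogue while keeping a full run in minutes on one core.

Remaining numerical conventions, in one place: rotations are
right-handed with angles in radians internally (degrees at the CLI);
internal atom indexing is 1-based with PDB serials renumbered from 1 on
output; coordinates print at 3 decimals, so PDB round-trips are exact
to 0.0005 Å and byte-stable after one write–read cycle; molecules reject
duplicate atoms closer than 0.01 Å; only the first MODEL and blank/'A'
altLocs of a PDB are read; element symbols come from columns 77–78 with
a documented atom-name fallback in which only the unambiguous two-letter
names (CL, BR, SI, SE) are trusted — a bare "CA" reads as carbon unless
the element column says calcium. Hydrogens are required to be explicit
throughout; no hydrogen addition is ever performed.
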