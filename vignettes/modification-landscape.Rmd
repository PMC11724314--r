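---
title: "Reading the modification landscape of a ribosome model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading the modification landscape of a ribosome model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribomod)
library(dplyr)
```

## The problem

Cryo-EM maps of ribosomal subunits now reach resolutions below 2 Å, where
chemical modifications of rRNA and ribosomal proteins, metal ions, polyamines
and ordered waters all become visible as discrete features of the deposited
atomic model. Once such a model exists, a series of questions about it are
purely geometric:

* **Census** — which residues carry which modification, per chain, and how do
  the modified positions cluster around the peptidyl transferase centre (PTC)?
* **Pseudouridine plausibility** — pseudouridine (Ψ) is an isomer of uridine
  with a C–C glycosidic bond, which frees N1 as an extra hydrogen-bond donor.
  Its geometric signature is an acceptor (a water, a neighbouring phosphate
  oxygen, or a ribose 2′-OH) at a heavy-atom distance under 3.2 Å, lying in
  the plane of the aromatic ring. Does each modelled Ψ show that pattern, and
  do any modelled uridines show it at what would be their C5 position?
* **Ion identity** — Mg²⁺ and K⁺ are nearly indistinguishable by density
  alone, but their coordination chemistry separates them: Mg²⁺ forms
  octahedral [Mg(H₂O)ₙX₆₋ₙ] complexes with ligand distances of 1.8–2.4 Å,
  K⁺ pentagonal [K(H₂O)ₙX₅₋ₙ] complexes at 2.8–3.2 Å, and waters sit in the
  ordinary hydrogen-bond window of 2.4–3.5 Å.
* **Polyamines and networks** — putrescine, spermidine and spermine anchor
  their amines to phosphate oxygens and participate in water-mediated
  hydrogen-bond networks, which can be traced as graphs over O/N atoms.

`ribomod` implements these four analyses as a tidyverse-style pipeline over
mmCIF/PDB models, together with a deterministic synthetic-structure generator
so that every rule is testable without downloading any deposited entry.

## Geometric rules and their parameters

All hydrogen bonds are inferred from heavy-atom distances alone: models at
these resolutions do not place hydrogens, so a donor–H–acceptor angle term is
not available and is deliberately not approximated. The defaults live in one
place, `ribomod_thresholds()`:

| parameter | default | meaning |
|---|---|---|
| `hbond_window` | 2.4–3.5 Å | heavy-atom donor–acceptor distance accepted as an H-bond |
| `covalent_cutoff` | 1.8 Å | pairs closer than this are bonded, never H-bonds |
| `mg_window`, `mg_min_ligands`, `oct_tol` | 1.8–2.4 Å, 4, 20° | Mg²⁺ rule |
| `k_window`, `k_min_ligands`, `pent_tol` | 2.55–3.35 Å, 3, 20° | K⁺ rule (strict mode narrows to 2.8–3.2 Å) |
| `psu_cutoff` | 3.2 Å (strict `<`) | Ψ acceptor distance rule |
| `coplanarity_tol` | 1.0 Å | maximum acceptor offset from the base plane |
| `env_radius` | 6 Å | radius within which *any* O/N counts as an ordered environment |

Some of these deserve a note on where they come from:

* The Mg²⁺ and K⁺ distance ranges are the observed coordination-bond lengths
  in near-atomic ribosome structures. The observed ranges describe where true
  sites sit, not a decision boundary, so the default K⁺ window is widened to
  2.55–3.35 Å for tolerance at partially resolved sites; a strict-mode flag
  (`ribomod_thresholds(strict = TRUE)`) reproduces the narrow window exactly.
* The minimum ligand counts (4 for Mg²⁺ of an ideal 6, 3 for K⁺ of an ideal
  5) accept partially resolved shells at the surface of a structure; the
  distance windows do most of the discriminating work.
* **Both metal rules carry a shell-geometry score.** The octahedral score is
  the RMS deviation of all ligand–centre–ligand angles from the nearest ideal
  octahedral angle (90° or 180°); the pentagonal score is the analogous RMS
  deviation from the nearest multiple of 72°. The pentagonal requirement is
  what separates a K⁺ site from a well-hydrated water: a water with three
  tetrahedrally arranged partners (~109.5°) sits ≥ 34° from any multiple of
  72° and can never satisfy the K⁺ rule, while any subset of a pentagonal
  shell scores near zero. Without this term, a water with three partners in
  the K⁺ distance window would be indistinguishable from a partially
  resolved K⁺ site.
* A non-metal centre whose nearest metal lies within the coordination window
  is a *coordination water* — a ligand of that metal, not a site of its own —
  and is labelled water directly, with the metal distance in its rationale.
  Without this guard, the ligand cage around a metal (e.g. four oxygens at
  ~3 Å with 60°/90° angles, seen from one of the metal's own waters) can
  mimic a partially resolved shell.
* If both metal rules fire, the label whose window midpoint is closer to the
  mean ligand distance wins and the conflict is recorded in the site's
  rationale text. Deposited metals other than Mg/K are passed through with
  their deposited label and flagged rather than forced into the binary.
* There is no published numeric tolerance for "lies in the same plane"; the
  1.0 Å default for `coplanarity_tol` is chosen to admit the thermal spread
  of water positions around a planar acceptor geometry while rejecting
  clearly axial contacts (a stacking-distance contact sits ~3.4 Å out of
  plane, an in-plane one near 0). It is exposed in the configuration and
  reported per residue, so strictness is auditable.
* The Ψ screen distinguishes three negative outcomes: `unsupported` (ordered
  atoms exist nearby but none matches the pattern), and
  `unresolved-environment` (no O/N within 6 Å — a flexible region with no
  ordered solvent, where absence of the pattern is not evidence of absence
  of the modification). The 6 Å radius is about two solvation shells.

### The probe-atom convention

For a modelled pseudouridine the probe is N1 (the freed donor). For a
modelled uridine the probe is the C5 atom — the position N1 would occupy if
the base were flipped — so the same acceptor-pattern test doubles as a screen
for unannotated pseudouridines. The probed residue's *own* atoms are never
counted as partners: a pyrimidine's O4 lies ~3.3–3.6 Å from N1 in the ring
plane, so without this exclusion every uridine would trivially "support" the
pattern. The binding pattern is defined by external partners only.

## Numerical choices

* **Plane fits** are total least squares via SVD of the centred ring
  coordinates; the residual RMS is reported, and the normal's sign is fixed
  (first non-zero component positive) for determinism. The fit uses the
  six-membered ring (plus the imidazole for purines and His/Trp side
  chains).
* **Distance comparisons** use closed intervals; sort ties are broken by
  atom serial. `neighbor_search` is a brute-force exact scan — on models of
  this size (≤ a few hundred thousand atoms) a spatial index is unnecessary,
  and the contract is exactness, verified against an all-pairs oracle in the
  tests.
* **Altlocs** are collapsed to a single conformer at load time: highest
  occupancy wins, ties broken by alphabetical altloc id, so downstream
  geometry is deterministic. Zero-occupancy atoms are retained but flagged.
* **Author numbering** is used in every user-facing output (the literature
  cites author positions); a per-chain sequential numbering is stored
  alongside.
* **Network tracing** is breadth-first over O/N atoms: H-bond edges within
  the window, plus metal coordination edges (1.8–3.35 Å) whenever a metal is
  encountered, so water-mediated and metal-mediated paths are both crossed.
  Expansion is truncated at `max_depth` steps from the nearest seed; node
  and edge order is deterministic and independent of seed order. The depth
  and window used are recorded with any export, since rendered network
  figures rarely state them.
* **Stacking** is reported as pure geometry (inter-plane distance, folded
  angle, lateral offset) and never as an energy or a "stabilisation" claim.

## The census tally convention

A 2′-O-methylpseudouridine (Ψm) is one modified position that is both a
pseudouridinylation and a ribose methylation. The census therefore counts it
once toward total positions and once in *each* of the two class tallies:

```{r census}
t <- make_toy_assembly(toy_spec(psu = 3, nm = 4, combined = 1,
                                standard = 5, spd = 2), seed = 1)
m <- read_structure(t$structure) |>
  classify_components() |>
  assign_chain_roles(c(R = "28S", S = "ligands"))
glance(modification_census(m))
```

Three Ψ plus one Ψm give a Ψ tally of 4; four Nm plus the same Ψm give an Nm
tally of 5; the total is 8 positions, not 9. This is the only convention
under which per-class tallies and a printed total can coexist; the `combined`
count is carried in the report so the alternative convention is one
subtraction away. When a reference list is supplied, the comparison returns
four exact set partitions: `confirmed`, `reported_but_absent` (position
modelled, modification not), `unresolved` (position not modelled at all, the
honest category for flexible regions) and `observed_but_unreported`.

## What the synthetic generator emulates — and what it does not

The generator (`make_ion_field()`, `make_psu_cases()`, `make_toy_assembly()`)
produces mmCIF files plus JSON manifests of ground truth, and is part of the
tested surface of the package:

* Ion sites are ideal octahedra/planar pentagons with ligand distances drawn
  uniformly from the observed windows and Gaussian jitter on each ligand
  coordinate; jitter that would push a distance out of its window is redrawn,
  so an out-of-spec site is never emitted. Waters receive 1–3 partners at
  tetrahedral directions in 2.6–3.4 Å. Sites sit on a lattice with ≥ 12 Å
  separation (asserted post-generation) so shells never overlap.
* Ψ cases are idealised hexagonal rings (1.4 Å bonds) with one planted
  acceptor at an exact distance and out-of-plane offset; the single-case
  builder is axis-aligned so planted distances survive the 3-decimal
  coordinate serialisation exactly, which lets the test suite pin the cutoff
  flip to 3.2 Å precisely.
* Toy assemblies use real component ids from the shipped component map, so
  classification runs end-to-end exactly as it would on a deposited file.
* Regeneration from the same seed is byte-identical; the seed is written
  into the manifest.

What passing these tests shows is that the *rules are implemented exactly as
stated*: planted geometry in-window is recovered, planted geometry
out-of-window is rejected, and tallies follow the stated conventions. What it
does **not** show is how the rules perform on real structures, where shells
overlap, occupancies are partial, solvent is mis-modelled, and the boundary
cases the windows were widened for actually occur. The generator makes no
attempt at chemical realism beyond geometry: rings are regular hexagons,
polyamines are arcs, ligand chemistry is reduced to atom names. Conclusions
about real models should rest on running the pipeline on deposited entries
(see the README for the full-scale workflow), with the synthetic suite
guaranteeing only that the geometry engine underneath is exact.

## Problem sizes

The test-suite and the acceptance script run entirely on synthetic fixtures:
a 300-site ion field (plus smaller fields for the jitter sweep at σ = 0.05,
0.15 and 0.3 Å, three replicates each), a 2000-atom cloud for the
neighbour-search oracle, a 250-atom cloud for the network-enumeration oracle
and toy assemblies of a few hundred atoms. These sizes exercise every code
path while keeping a full run around a minute on one CPU; all of them scale
linearly if larger checks are wanted.

## Known limitations

* No map-derived evidence: occupancy estimation, density-level checks and
  anything requiring the experimental map are out of scope by design; the
  pipeline reads coordinates only.
* Heavy-atom H-bond detection cannot distinguish donors from acceptors, and
  the element-based partner filter (O/N) is deliberately permissive; the
  optional atom-name tables refine partner *typing* for reports, not
  detection.
* The component map ships with candidate CCD ids for three rare
  modifications (flagged in the file comments); verify them against the
  wwPDB chemical component dictionary before production use on deposited
  entries, and extend the map for components the defaults do not cover.
* The chain-role heuristic (largest RNA chains → 28S, 5.8S, 5S) is a
  convenience for single-subunit models; explicit role maps are the reliable
  route and always win.
* Na⁺, Zn²⁺ and other metals are passed through, not classified; adding
  rules for them would follow the same window + geometry-score pattern.
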