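---
title: "Helical lattices, honeycombs and cross-threading compatibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical lattices, honeycombs and cross-threading compatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helicomb)
```

## The scientific problem

Death-fold domains — pyrin domains (PYDs) and caspase-recruitment domains
(CARDs), both ~90-residue six-helix bundles — signal by polymerizing into
helical filaments. Inflammasome signaling in particular proceeds by
*templated* polymerization: an upstream receptor's PYD filament nucleates
the PYD filament of the adapter ASC, which is only possible because the two
filaments share one lattice architecture. A PYD whose filament adopts a
*different* architecture cannot template, or be templated by, the
inflammasome lattice; architectural compatibility is therefore a signaling
specificity mechanism. The pyrin domain of the DNA sensor IFI16 is the
motivating case: its filament has an atypical lattice (a five-subunit base
and a tighter rim than the canonical six-subunit inflammasome PYD
filaments), which argues structurally against direct IFI16–ASC templating.

helicomb provides the quantitative toolkit for this kind of argument:

1. **helical parameter estimation** — recover the twist/rise screw operator,
   axial point-group order and strand count from a multi-chain filament
   model;
2. **lattice analysis** — contact graphs, the six-contact "honeycomb"
   neighborhood with Type 1/2/3 interface labels, base-layer subunit counts
   and rim diameters;
3. **cross-threading compatibility** — rigidly place one monomer into
   another filament's lattice and score clashes and contacts per interface,
   with top/bottom half sums;
4. **synthetic fixtures** — coarse-grained six-helix-bundle protomers on
   lattices with known ground truth, so every stage is testable without any
   structure download.

## The helical model and its conventions

A filament is modeled as an ordered set of protomers indexed along the
1-start helix: subunit $k$ is the reference protomer transformed by the
$k$-th power of a screw operator $S = (R_{\theta}, \, t\,\hat{u})$, a
rotation by the twist $\theta$ (degrees per subunit) about the filament
axis $\hat{u}$ composed with a translation by the rise $t$ (Å per subunit)
along it. An axial point group $C_n$ ($n \ge 1$) replicates each level by
rotations of $360/n$ degrees. Conventions:

* the axis direction is chosen so the rise from index $k$ to $k+1$ is
  positive; positive twist is a right-handed screw about that direction;
* twist is reported in $(0, 360]$ degrees, so a left-handed lattice reads
  as a twist above 180° rather than a negative angle;
* the *strand count* ("$n$-start") is a descriptive output, not a free
  parameter: it is reported as $c_n \cdot \mathrm{round}(360 / \min(\theta,
  360 - \theta))$, the number of near-co-level strands the eye traces on
  the surface lattice. For the IFI16 operator (134.6°, 5.6 Å) this gives 3,
  matching the three-start appearance of that filament.

**Estimation** inverts construction: each subunit is superposed onto its
successor (Kabsch over matched C-alpha atoms when present, otherwise all
heavy atoms), each consecutive transform is screw-decomposed in closed
form, and the median twist and rise are returned. The median (not the
mean) makes the estimate insensitive to end effects and to a minority of
distorted subunits. The filament axis is fit beforehand by cylindrical
least squares on the protomer centroids (principal axis refined by
minimizing the variance of centroid radii), with collinear centroids
rejected as degenerate. Assemblies whose consecutive transforms disagree
(median absolute deviation above 3° in twist or 3 Å in rise) are rejected
as non-helical rather than silently averaged.

One genuine ambiguity deserves a note: on a $C_n$ lattice the 1-start
generator is only defined modulo $360/n$ once subunit identity is
forgotten — rotating the generator by a ring step produces the same point
set. The estimator resolves this using the assembly's index order (it
superposes subunit $k$ onto $k + c_n$, pairing matching ring copies of
adjacent levels), which recovers the generating operator exactly for
assemblies ordered by `build_filament()` or `order_protomers()`.

## Lattice analysis choices

**Contacts.** Two protomers are in contact when any heavy-atom pair lies
within 4.5 Å, the standard interface-contact convention; atom pairs are
found with a cell-grid spatial hash and the implementation is checked
against a brute-force $O(N^2)$ oracle in the tests. The cutoff is a
configuration parameter (`filament_config()`), not a constant.

**Interface typing.** Death-fold filaments use three conserved asymmetric
contact classes, each with an `a` and a `b` surface. The package assigns a
shell contact to a surface by which secondary-structure segments of the
*center* subunit carry the contact: Type 1 is the h1+h2 face against the
h3+h4 face, Type 2 the h4/h5 corner against the h5–h6 loop, Type 3 the
short helix 3 against the h1–h2 loop. Per contact, heavy-atom contacts are
attributed to each candidate surface through the segment ranges and the
argmax surface wins; ties between overlapping surfaces are broken toward
the more specific (fewer-segment) surface, so a contact carried purely by
helix 3 reads Type 3a rather than the broader h3+h4 face. A runner-up of a
*different* type within 10% flags the contact as ambiguous — a label,
never an error. An `a`/`b` tie within the winning type resolves to `a` on
the +axis (top) half, a deterministic documented convention. Segment
ranges come from an editable packaged annotation table
(`ss_segment_table()`); the shipped IFI16 entry is an approximate
canonical-PYD annotation and is meant to be replaced by a curated one.

**Base-layer count.** The number of subunits forming the filament's end
polygon (six in canonical inflammasome PYD filaments, five in IFI16) is
measured as the size of the minimal set of protomers that (a) have their
centroids in the terminal axial slab — thickness equal to the median
protomer axial extent — and (b) together span the full 360° of azimuth.
Azimuthal footprints give each heavy atom its van der Waals angular width
($\arcsin(1.7\,\text{Å}/r)$ at radius $r$), so the footprint is what a
caliper sees rather than a set of zero-width points; the minimal cover is
found by exhaustive subset search (the slab holds at most a dozen or so
candidates).

**Rim diameters.** The outer diameter is twice the maximum heavy-atom
radial distance over interior subunits, the inner-cavity diameter twice
the minimum radial distance, both to 1 Å. This is deliberately a plain
caliper reading: no solvent-probe radius is added or subtracted, because
the quantity is used for architecture comparison, not solvent energetics.
Interior subunits (at least one slab thickness from either end) are used
so terminal fraying cannot inflate either number.

## The compatibility score

Cross-threading asks: how well does monomer X fit position 0 of filament
Y's lattice? The monomer is superposed onto the template's center subunit
over mapped C-alpha atoms (global Needleman–Wunsch alignment, BLOSUM62,
gap open 10 / extend 1, when the sequences differ; a residue correspondence
must cover at least 60% of the template center). Threading is strictly
rigid — no backbone remodeling, no side-chain repacking — so the resulting
score is a property of the two architectures, reproducible to the last
digit, and deliberately *not* an energy. Each shell interface is scored

$$ \text{score} = w_{\text{clash}} \cdot \#\{d < 2.6\,\text{Å}\}
   - w_{\text{contact}} \cdot \#\{2.6 \le d < 4.5\,\text{Å}\} $$

with default weights 10 and 1; lower is more favorable. The 2.6 Å clash
threshold sits below any non-bonded heavy-atom distance found in refined
native interfaces, which is what makes "the native center re-scored in its
own shell has zero clashes" a structural identity rather than a tuned
outcome. Top- and bottom-half sums partition the total exactly. Only the
*signs and orderings* of these scores are meaningful — native vs foreign,
compatible vs incompatible; the package makes no claim that the magnitudes
track physical energies, which is the main divergence from repacking-based
interface-energy protocols.

`model_honeycomb()` builds a neighborhood directly from a screw operator
and a chosen interface set, which is how "species A modeled on
architecture B" experiments are composed: the interface set stays fixed
(e.g. the canonical six contacts at index offsets ±2, ±3, ±5) while the
geometry comes from the operator under study.

## The synthetic generator and its calibration

`make_toy_protomer()` emulates a death-fold domain as six short
pseudo-helices (one C-alpha-like pseudo-atom per residue on an ideal
helical trace, ~3.8 Å spacing) joined by two-residue loops, anisotropically
scaled to a target bundle size, tilted by a fixed orientation, placed at a
fixed centroid radius from the axis, and perturbed by a small seeded jitter
(0.25 Å) that breaks the bundle's internal symmetry so superpositions are
uniquely determined. Everything is deterministic in the seed.

The generator's defaults (bundle 33.2 × 25.4 × 20.7 Å, centroid radius
22.8 Å, 9 residues per pseudo-helix) are a *calibration*, chosen once so
that filaments built with the IFI16 operator (134.6°, 5.6 Å, C1) have the
canonical death-fold neighborhood: every interior subunit touches exactly
six neighbors (index offsets ±2, ±3, ±5 for this operator), with all
inter-subunit minimum distances in the contact band (3.0–4.1 Å) and none
below the clash threshold. The tests assert this calibration. Under the
same defaults the fixture's base layer counts five subunits — the pentagon
the real IFI16 lattice shows — because that property follows from the
operator and protomer proportions, not from fitting.

What the toy fixtures do **not** emulate: side-chain packing and shape
complementarity (pseudo-atoms are single spheres per residue), sequence-
dependent interface chemistry, bent or polymorphic filaments, and the
absolute atom counts of real interfaces. Consequently, passing fixture
tests validates the *geometry and bookkeeping* of the pipeline — operator
algebra, neighbor detection, classification plumbing, score identities —
but says nothing about any particular real protein; the claims about real
filaments are exercised separately on deposited models when those
coordinate files are available locally (they cannot be redistributed with
the package).

A related honesty note on the mismatch sweep: for rigid bodies on a
cylinder, clash counts cannot grow monotonically with twist mismatch over
an arbitrary range — beyond roughly 20° the blobs begin to rotate *past*
one another and the count saturates and oscillates. The monotone property
the package asserts (and tests, on a denser 160-atom protomer whose counts
are less grainy) is therefore an *onset* property, over 0–20° of twist
mismatch, where every additional degree presses the approaching neighbors
deeper into the center subunit.

## Problem sizes and determinism

All shipped analyses run on fixtures of 6–30 subunits (64–160 pseudo-atoms
per protomer), sizes at which every estimator behaves identically to
longer filaments (the tests include explicit length-invariance checks for
shell composition and base-layer counts). Parameter recovery is exact to
numerical precision on noise-free fixtures; under 0.3 Å isotropic
coordinate noise the twist is recovered within 0.5° and the rise within
0.2 Å in at least 19 of 20 seeded replicates. Reports are byte-identical
for identical inputs and configuration; the only random number streams are
the protomer jitter and the optional fixture noise, both seeded and both
restored after use so library calls never disturb the caller's RNG state.

## Worked example

```{r example}
fx <- make_filament_fixture(preset = lattice_preset("IFI16"), n = 24)
report <- analyze_filament(fx$filament)
glance(report)
tidy(report$honeycomb)
```

```{r threading}
hc <- report$honeycomb
native <- score_shell(thread_monomer(make_toy_protomer(), hc), hc)
glance(native)
```

## Known limitations

* The Type 1/2/3 assignment depends on the segment annotation; with the
  approximate shipped ranges, borderline contacts can be labeled ambiguous
  or differ from a curated assignment.
* The compatibility score is a transparent clash/contact count, not an
  energy; it reproduces orderings, never magnitudes.
* `order_protomers()` sorts co-level subunits of a $C_n$ lattice by
  azimuth, which fixes an arbitrary but deterministic ring phase; the
  estimated twist of such lattices is exact for assemblies it ordered
  itself but is in general only defined modulo $360/c_n$.
* Bent, polymorphic, or variable-twist filaments violate the single-
  operator model and are rejected by the consistency check rather than
  fitted.
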