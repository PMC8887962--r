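---
title: "Describing, wiring and exchanging extracellular probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Describing, wiring and exchanging extracellular probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroprobe)
```

## The problem

Extracellular electrophysiology records voltages from tens to thousands of
electrode sites on silicon probes, microwire bundles or dense arrays. Every
analysis that exploits geometry — above all spike sorting, which models the
spatial footprint of each neuron across neighbouring sites — needs an exact
map from *recorded trace index* to *contact position on the probe*. That map
is distorted twice before data reach the analyst: the probe has its own
intrinsic channel naming, and the connector/headstage chain between probe and
acquisition system reorders channels again. `neuroprobe` models all three
layers explicitly so the full chain is declared once, validated, and stored
with the data.

## The data model and its assumptions

A **contact** is one recording site: a position (2-d or 3-d, in a declared
length unit, `um` by default), a shape (`circle`, `square` or `rect`), the
shape's size parameters, and an in-plane orientation given by a pair of
orthonormal axis vectors. A **shank** is the subset of contacts sharing a
`shank_id`; a **probe** holds all per-contact arrays plus an optional planar
outline polygon and free-form annotations; a **probe group** is the ordered
set of probes connected to one acquisition device.

The classes are S4 with validity methods enforcing the model invariants:

* all per-contact arrays have identical length;
* every coordinate and axis vector has exactly `ndim` components;
* each shape carries exactly its required, positive parameters
  (`circle` → `radius`; `square` → `width`; `rect` → `width`, `height`);
* plane-axis pairs are orthonormal within `1e-9`;
* non-negative device channel indices are pairwise distinct within a probe
  and across a probe group (the `-1` "unconnected" sentinel is exempt).

Conventions chosen where several were defensible: coordinates put x across
shanks and y along the insertion axis with larger y farther from the tip;
rotation angles are in *degrees* (a human-facing API); contact and shank ids
are stored as text because vendor channel names need not be numeric; default
ids are `"0".."n-1"` in storage order with a single shank `"0"`; default
plane axes are the unit x/y vectors, i.e. un-rotated contacts lying in the
probe plane. Empty probes are legal everywhere except wiring. Probe equality
in round-trip tests means field-wise agreement with `1e-12` absolute
tolerance on reals.

Shank ids are reported in first-appearance order, never sorted — an ordering
the on-disk formats do not constrain, so we preserve what the user wrote.
Per-contact material/coating/impedance have no dedicated fields in the
interchange format; they travel in the optional `contact_annotations`
extension (a map of per-contact vectors), which readers must tolerate along
with any other unknown optional key.

## Generators

`generateMultiColumnsProbe()` lays contacts column-major (column 0
bottom-to-top, then column 1, ...), column `c` at `x = c * xPitch`, row `r`
at `y = r * yPitch + yShift[c]`. `generateMultiShankProbe()` repeats that
grid at multiples of `shankPitch` in x, labelling shank `k` with id `"k"`.
Storage order (column-major within shank, shanks by increasing x) is fixed
and documented because wiring acts on storage order; two calls with the same
spec are bit-identical. Staggered layouts such as the NeuroNexus "Poly3"
column pattern come from per-column counts and y shifts:

```{r}
poly3 <- generateMultiColumnsProbe(numColumns = 3,
                                   contactsPerColumn = c(10, 12, 10),
                                   xPitch = 18, yPitch = 50,
                                   yShiftPerColumn = c(25, 0, 25))
numContacts(poly3)
```

Default pitches (20 µm grid, 150 µm shank pitch, 5 µm circular contacts) are
in the range of commercial high-density silicon probes; the published
descriptions of the layouts we emulate fix counts and shank structure but
not exact pitches, so only counts and structure are treated as normative by
the tests and the stand-in fixtures.

The auto-generated outline is a pentagon per shank — a rectangle with a
configurable margin (default 20 µm) around the contacts plus a triangular
tip extending one further margin below the lowest contact — matching the
silhouette of real single- and multi-shank devices well enough for plots
while remaining trivially testable.

## Wiring semantics

A **stage table** of size `m` maps input channel `i` (0-based) to output
channel `s(i) < m`, with `-1` for unconnected inputs and distinct
non-negative outputs. A **pathway** is a named, ordered list of stages —
probe connector, headstage, possibly further adapters; any number of stages
(≥ 1) of a common size is accepted, since hardware chains vary. Composition
walks each input through the stages in order, propagating `-1` (a contact
legitimately wired to nothing stays unconnected rather than raising an
error). The composite of valid stages is again a valid stage table;
composition is associative, and a fully connected table composed with its
inverse yields the identity — all three properties are exercised by
randomized tests against an independent per-element loop.

The domain of a pathway is *contact storage order*, not lexical contact-id
order: contact `i` receives the composed mapping of input `i`. Pathways live
as JSON data files (`{"name": ..., "stages": [{"name": ..., "mapping":
[...]}]}`) so new hardware can be contributed without code changes; the
package bundles `identity`/`reverse` test pathways and a 64-channel
`synthetic-ASSY-156>RHD2164` stand-in whose permutations are deterministic
inventions with the correct channel count, *not* vendor documentation —
anything depending on true vendor wiring must supply the real table.

## File formats

The JSON probe description has a `specifications_version` and a `probes`
list; each record requires `ndim`, `si_units`, `annotations`,
`contact_positions`, `contact_shapes` and `contact_shape_params`, with
shapes/parameters allowed as a scalar (broadcast to all contacts) or as
per-contact lists. The writer emits a fixed key order, always-decimal reals
at full precision and arrays for all per-contact fields, which makes
serialization deterministic: write → read → write reproduces the file byte
for byte, and read ∘ write is field-wise identity (at `1e-12`) across
everything the generators can produce. The reader rejects each malformed
document with an error naming the offending field, and ignores unknown
optional keys so future extensions do not break old readers.

`.prb` files — the legacy dialect of Klusta-family spike sorters — carry
only `channel_groups` with `channels` and a per-channel 2-d `geometry`.
Reading turns each channel group into one probe (device indices from
`channels`, positions from `geometry`, dialect defaults elsewhere: 5 µm
circles, one shank); `graph` entries are ignored. Because the dialect is
Python source, the reader tokenizes and evaluates *literals only* — a
malicious `.prb` cannot execute code. Writing drops what the dialect cannot
express (shapes, contour, axes, annotations) with a warning and refuses 3-d
probes; positions are printed with 17 significant digits so the
lossy-but-stable round trip preserves positions and device indices exactly.

## Probe library access

`getProbe(manufacturer, probe_name)` fetches
`<base>/<manufacturer>/<probe_name>/<probe_name>.json`, caches it under the
per-user cache directory, and serves the cache when the source is
unreachable; base URL and cache directory are configurable via options or
environment variables, and a local directory may stand in for the base (used
by the tests, which never touch the network). No checksum scheme is imposed:
the cache is trusted once written, and `forceDownload = TRUE` refreshes it.
`getFixtureProbe()` builds deterministic synthetic stand-ins whose contact
counts and shank/column structure match published vendor descriptions
(64 contacts over 4 shanks of 16; 32 contacts in 10/12/10 columns) while the
coordinates are invented — tests against fixtures therefore verify structure,
never vendor geometry.

## Plotting

`probeToPolygons()` is a drawing-free geometry layer: one polygon per contact
(circles discretized with 32 vertices, which keeps the polygon area within
1% of pi r^2; squares/rects as 4 corners oriented by the plane axes), the
contour, and per-contact label anchors carrying the contact id and, once
wired, the device index text (`dev27`). The ggplot2 layer on top adds equal
aspect ratio and unit-labelled axes; 3-d probes are drawn as a projection
onto a configurable coordinate plane (default `xy`). Patch and label counts
are asserted against contact counts in the tests.

## Numerical choices and degenerate inputs

* Validity tolerances: `1e-9` for axis orthonormality (absolute, on unit
  vectors); rigid-motion tests assert pairwise-distance preservation within
  `1e-9` by exhaustive pair enumeration on probes of ≤ 64 contacts.
* Rotation uses the closed-form 2-d matrix or the Rodrigues formula in 3-d;
  the default center is the contact centroid.
* `to3d()` inserts an exact 0 for the unnamed coordinate; `to2d()` is its
  inverse for probes lying in a coordinate plane.
* Empty probes round-trip through the JSON format and plot as contour-only
  figures; an empty probe group serializes to an empty `probes` list.
* Ties/ordering: shank order is first appearance; `.prb` channel groups are
  numbered by probe position on write and taken in file order on read.

## Problem sizes and what the tests show

The test suite runs entirely offline in a few seconds: probes up to 64
contacts, 200 randomized stage-composition cases (sizes 4–64, up to 3
stages, with unconnected holes), randomized rotations, and round trips over
a "zoo" of generator outputs (tetrode, staggered columns, mixed shapes,
wired probes, multi-shank, 3-d-lifted). These sizes exercise every code path
while staying desk-scale; nothing in the implementation depends on contact
count beyond memory. Passing tests demonstrate internal consistency,
format fidelity and wiring arithmetic — they cannot certify vendor geometry
or vendor pathway tables, which exist only in the online library and vendor
documentation.

## Known limitations

* Readers for acquisition-system formats (SpikeGLX, Maxwell, MEArec, NWB,
  BIDS) are out of scope; interchange is via the JSON format and `.prb`.
* Impedance and materials are annotation text, not modelled quantities.
* The bundled vendor-named pathway is a synthetic stand-in; real wiring
  tables must be supplied as pathway JSON files.
* `.prb` writing discards everything but channels and 2-d geometry, by
  design of that dialect.
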