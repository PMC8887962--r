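# neuroprobe

Spike sorting and most downstream analyses of extracellular recordings need
to know, for every recorded trace, *where on the probe* the signal was picked
up. In practice that knowledge lives in vendor catalogs, hand-written `.prb`
files and lab lore about which headstage shuffles which channels — a manual
mapping step that is tedious and a classic source of silent sorting errors.

`neuroprobe` is an R package that makes probe handling explicit and
reproducible. It provides:

* **A layered data model** — a *contact* (one recording site: position,
  shape, size), a *shank* (the contacts on one silicon prong), a *probe*
  (shanks + outline + intrinsic contact ids), and a *probe group* (all probes
  connected to one acquisition device), implemented as S4 classes with strict
  validity checking.
* **Layout generators** for multi-column grids, multi-shank silicon probes
  and tetrodes, plus rigid transformations (`moveProbe()`, `rotateProbe()`,
  `to3d()`).
* **Wiring (channel mapping)**: the assignment of each contact to the index
  of the recorded trace. A *pathway* is a named chain of hardware stages
  (probe connector → headstage → device); each stage is a permutation table
  `s(i) = output channel receiving input i`, with `-1` for unconnected
  channels, and the composed table
  `(s_k ∘ ... ∘ s_1)(i)` gives the `device_channel_index` of contact `i`.
  Manual wiring (`setDeviceChannelIndices()`), named pathways
  (`wireProbe()`) and group-level wiring
  (`setGlobalDeviceChannelIndices()`) are all supported; non-negative device
  indices must be unique across a probe group.
* **File interchange**: a deterministic reader/writer for the community JSON
  probe-description format (required fields `ndim`, `si_units`,
  `annotations`, `contact_positions`, `contact_shapes`,
  `contact_shape_params`; optional plane axes, contour, shank ids, device
  indices), and read/write support for the legacy `.prb` dialect used by
  spike sorters (parsed as Python literals, never executed).
* **Probe library access**: `getProbe(manufacturer, probe_name)` downloads a
  vendor probe definition from the public online probe library and caches it
  locally, so later calls work offline. Deterministic synthetic stand-ins
  (`getFixtureProbe()`) cover fully offline work and testing.
* **Plotting** with a testable geometry layer (`probeToPolygons()`) beneath
  `plotProbe()` / `plotProbeGroup()`.

## A worked example

Build a two-shank probe (two columns of eight contacts per shank), duplicate
it 600 µm away, and aggregate the pair into a probe group:

```r
library(neuroprobe)

probe0 <- generateMultiShankProbe(numShanks = 2, shankPitch = 150,
                                  numColumns = 2, contactsPerColumn = 8,
                                  xPitch = 20, yPitch = 20)
probe0
#> Probe - 32 contacts, 2 shank(s), 2d, unit um
#>   shapes: circle x32

probe1 <- moveProbe(probe0, c(600, 0))
group  <- probeGroup(probe0, probe1)
group
#> ProbeGroup - 2 probe(s), 64 contacts total
#>   Probe - 32 contacts, 2 shank(s), 2d, unit um
#>   shapes: circle x32
#>   Probe - 32 contacts, 2 shank(s), 2d, unit um
#>   shapes: circle x32

plotProbeGroup(group)   # contacts as patches, outline, equal aspect, µm axes
```

The 32 contacts per probe are split 16/16 across the two shanks
(`vapply(getShanks(probe0), numContacts, integer(1))` returns `16 16`).

Wiring a 64-contact, 4-shank probe through a registered
connector→headstage pathway assigns every contact its device channel index:

```r
p <- getFixtureProbe("assy156-standin")   # synthetic: 64 contacts, 4 shanks x 16
wired <- wireProbe(p, "synthetic-ASSY-156>RHD2164")
head(deviceChannelIndices(wired), 8)
#> [1] 32  0 33  1 34  2 35  3
```

i.e. the first contact feeds recorded trace 32, the second trace 0, and so
on; the 64 indices form a permutation of `0..63`. (The bundled
`synthetic-ASSY-156>RHD2164` pathway is a deterministic *stand-in* with the
correct channel count — not the vendor-documented wiring; real pathway
tables can be dropped into a directory named by
`options(neuroprobe.pathwayDirs = ...)` as JSON files.)

Round-trip through the JSON format is lossless and deterministic:

```r
f <- tempfile(fileext = ".json")
writeProbeInterface(group, f)
readProbeInterface(f)          # field-wise identical ProbeGroup
```

A command-line front door (`exec/neuroprobe-tool`) wraps the same functions:
`validate`, `convert` (JSON ↔ `.prb`), `wire`, `get`, `plot`.

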