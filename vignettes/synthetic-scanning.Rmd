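---
title: "Synthetic scanning: simulating scanned SD-OCT acquisition from one plane-wave field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic scanning: simulating scanned SD-OCT acquisition from one plane-wave field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octsynth)
```

## The problem

Simulating image formation in scanned, fiber-based spectral-domain OCT
normally requires one scattered-field computation per A-scan: the focussed
beam is moved to a scan position, the field scattered by the sample is
propagated to the collection optics, coupled into the single-mode fiber,
and the interference spectrum is Fourier transformed into a depth profile.
When the scattered field comes from an expensive wave solver, the cost is
proportional to the number of scan positions.

Synthetic scanning replaces all of those computations with a single one:
the scattered field `g1(x, y, k)` recorded in the back focal plane of the
objective under a **normally incident plane wave**. Every other
illumination of interest — a tilted plane wave, and from there a focussed
scanned beam — is synthesized from that one record by translations and
phase manipulations in the back focal plane.

## The model

All fields are scalar (low NA, negligible depolarization), and all
wavenumbers are wavenumbers in the background medium,
`k = 2*pi*nb/lambda_vac`, so a scatterer at physical depth `zs` below the
focus contributes a round-trip phase `2*k*zs` and the A-scan depth axis is
physical sample depth.

**Normal incidence.** For a point scatterer at `(xs, ys, zs)` the
back-focal-plane field under unit normally incident plane-wave
illumination is, in the paraxial regime,

```
g1(x, y) = amp/(i*lam*f2) * exp(i*2*k*zs)
           * exp(-i*k*zs*(x^2 + y^2)/(2*f2^2))
           * exp(i*k*(xs*x + ys*y)/f2).
```

**Tilt and scan by translation.** If the same scatterer is illuminated by
a plane wave with transverse wavenumber `(kx, ky)` and collected by a lens
displaced to the scan position `(xd, yd)`, the new field `g2` is *exactly*
a translation of `g1` by `(kx, ky)*f2/k` in the back focal plane, times
three phase factors (one involving the scatterer depth `zs`, two involving
the scan position). Crucially, none of the factors involves the *lateral*
scatterer position, so `g2` can be synthesized from a recorded `g1` of an
arbitrary sample without knowing where its scatterers are — only an
**assumed depth** `zs` enters, through a slowly varying phase. This is the
same physics as the tilt optical memory effect: a small change of
illumination angle changes the transmitted field by a predictable phase
ramp even after substantial scattering.

**Focussed beam, coupling, A-scan.** A focussed beam at scan position
`(xd, yd)` is the angular superposition of tilted plane waves weighted by
the fiber mode read at the mapped pupil position (illumination and
collection share one fiber); summing the synthesized `g2` over a
cell-centered angular grid inside the cutoff `k*NA` gives `g3`; the
complex coupling amplitude is the overlap of `g3` with the translated
fiber mode over the hard aperture `x^2 + y^2 < Ra^2`; and the A-scan is
the Fourier transform over `k` of `2*Re(a3 * Conj(amirr))`, with depth bin
`pi/(n_k*dk)`.

**Banded stitching.** The assumed depth is only approximately right for
scatterers away from it, so the final B-scan is stitched from
reconstructions at assumed depths `0, 50, ..., 250 um`, each populating
the half-open band of `+-25 um` around it. Scatterers at most 25 um from
their band center acquire a residual phase
`exp(i*(zs_assumed - zs_true)*(kx*xb + ky*yb)/f2)`, which is the method's
intrinsic error source; it vanishes at band centers.

## Parameters that matter

- `f2 = 36 mm`, `Ra = 3.5 mm` (`NA = 0.097`), `lambda0 = 1.3 um`: the
  reference scan-lens geometry of a commercial 1.3-um SD-OCT system.
- `bandwidth` (default 170 nm sampled span): the source envelope is
  Gaussian in k with FWHM equal to half the sampled span, a standard
  idealization for a broadband 1300-nm source; the instrument's true
  spectrum is not modelled. With 256 or more wavenumbers the depth bin is
  4.9 um and the axial resolution about 12 um.
- `fiber_mode_radius` (default `0.64*Ra`): the Gaussian mode field radius
  in the back focal plane. The reference instrument's value is not
  published; the default fills the aperture without severe truncation
  (focal spot radius about 6.6 um). The residual banding error scales
  roughly with the fourth power of this radius, so it is the single most
  influential unknown when comparing against published error levels.
- `n_angle` (default 63, matching the reference experiment; 31 in the
  scaled runs): cell-centered midpoint quadrature over `[-k*NA, k*NA]^2`
  with a disk mask. Convergence was verified by angular doubling (31 vs
  63 changes the banding error by under 1% of itself).
- `bfp_samples` (default 256 over `+-1.5*Ra`): back-focal-plane sampling.

## Numerical design

**Guard-band windowing instead of hard masking.** The synthesis resamples
the recorded field at translated positions by Fourier-shift (trigonometric)
interpolation on a two-fold zero-padded grid. A hard-masked record is not
band-limited, and interpolating it cannot reach the accuracy the
translation identity deserves; recorded fields are therefore windowed with
a smooth (C-infinity Planck) taper over the guard band `r` in
`[1.02, 1.45]*Ra` — entirely outside the aperture — and the hard aperture
is enforced only where the physics puts it, in the coupling integral's
domain. The direct references apply the identical window analytically at
the translated radius, so window truncation never contaminates
synthesized-vs-direct comparisons. Measured oracle accuracy of the
translation identity (synthesized vs first-principles tilted response at
the true depth): relative L2 of 8e-8 at 256^2 sampling, 1.2e-5 at 128^2.

**Chirp-cancelled interpolation.** The assumed-depth phase factor is
applied through the identity
`zs*(kx*xb + ky*yb)/f2 = c/2*(|xb+D|^2 - |xb|^2 - |D|^2)` with
`c = zs*k/f2^2` and `D = (kx, ky)*f2/k`: the record is premultiplied by
`exp(i*c/2*r^2)`, which cancels the quadratic phase of scatterers near the
assumed depth, so interpolation acts on the least oscillatory
representation available.

**Factorized scanning.** Because the translation lattice `D` and the
angular mode weights are identical for every wavenumber (angles scale with
k), the full coupling over all angles reduces, per wavenumber, scan
position and band, to one FFT and two small complex matrix products that
evaluate the mode-weighted cross-correlation at every lattice node at
once. This path is algebraically identical to the literal per-angle chain
(`synthesize_g2` + `synthesize_g3` + `couple_to_fiber`), which the tests
verify to 1e-10.

**Reference arm.** The reference return is modelled as a mirror at the
reference plane coupled through the same objective/fiber path as the
sample arm, so it carries the sample path's quadrature constant (`1/i`).
With a purely real reference spectrum the in-focus scatterer — which the
reference experiment places at the PSF maximum — would be in quadrature
and vanish under the real-part operation.

**Split-step solver.** For scattering phantoms the forward field is
computed by angular-spectrum split-step propagation with projected phase
screens: raster cells (default 0.5 um) are grouped into propagation slabs
(configurable, e.g. 2 um), the index contrast within a slab is projected
onto one screen, free propagation uses the non-paraxial
`kz = sqrt(k^2 - kx^2 - ky^2)`, and a raised-cosine absorbing margin
covers the outer 10% of the transverse grid (switchable off for ideal
plane-wave checks). The stored field at each slab is the field *arriving*
there, before the slab's own screen: in the first-Born return path each
scatterer re-radiates the arriving field, and sampling is performed with a
standoff above the particle's own raster cells to exclude
self-interaction. The return path itself is the paraxial point-response
of the normal-incidence model with the lens displaced to the scan
position; multiple backscattering is excluded by construction. TiO2-like
particles (n = 2.488 in nb = 1.42) accumulate more than pi of phase in a
single screen — the solver warns about this; it is inherent to
representing Mie-regime particles by thin screens and the solver is used
for *trend* studies, not quantitative scattering cross-sections.

## The phantom generator

`make_axial_point_grid()` reproduces the axial PSF object: nine on-axis
unit scatterers spaced `152 * lambda0/6 = 32.93 um`, first at the focus.
`make_single_scatterer()` places one scatterer at a chosen depth (the
isolated-scatterer experiments use 61.75 um). `make_letter_phantom()`
fills a glyph-shaped volume (built-in letter "B", oriented in the x-z
plane, extruded over the y extent) with uniformly random point scatterers
at a seeded, bit-reproducible density; each particle is an isotropic point
scatterer with one complex amplitude proportional to its polarizability
`(n^2 - nb^2)*volume` — no Mie phase function, no polydispersity. The
default density (0.007 per cubic micrometre) produces fully developed
speckle at these optical parameters; the published scattering coefficient
of the reference object (11.4 per mm) cannot be reproduced without its
unpublished number density and is not claimed. What passing tests on
these phantoms show is that the synthesis chain treats point-scatterer
ensembles correctly under the stated forward models; they do not certify
quantitative accuracy for continuous-index tissue, for strong multiple
backscattering, or for polarization effects.

## Problem sizes used by the shipped studies

The shipped studies are scaled to desk hardware as the package's own
standard configurations. The PSF comparison uses 256 wavenumbers, a 31x31
angular grid, 21 scan positions at 1.95 um pitch and 96^2
back-focal-plane samples (the banding error was verified converged under
angular doubling and finer grids; the oracle-exactness checks use 256^2).
The scattering-sample trend studies use a 100 x 40 x 150 um seeded
phantom on a 0.5-um raster: the internal-field and isolated-scatterer
studies with 48 wavenumbers, a 5x5 angular grid and 2-um slabs; the
B-scan comparison with 96 wavenumbers (so the whole phantom depth is
imaged without aliasing), a 3x3 angular grid, 5-um slabs, and the scan
running along the glyph's spine, where scatterers are present at every
depth — the configuration in which a depth-resolved error metric is
meaningful.

## Known limitations and deliberate exclusions

- The forward models are single-backscatter: the elevated multiple
  scattering that plane-wave illumination adds to synthesized images in
  signal-free regions below a full-wave solver cannot be reproduced here
  and is not claimed.
- Both the analytic point responses and the synthesis are paraxial and
  mutually consistent, so the shipped synthesized-vs-direct comparisons
  isolate the assumed-depth (banding) error alone. A full-wave reference
  would add depth-growing error floors of its own on top of it.
- Published phase-discrepancy dispersions for the reference scattering
  object (0.2677 / 0.4774 rad) depend on that object's exact realization
  and solver and are not reproduced; the package asserts the trends in
  tilt angle and depth instead.
- Vectorial effects, chromatic aberration, dispersion mismatch and
  sensitivity roll-off are out of scope.
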