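---
title: "Methods: estimating the jurisdictional importance of tracked marine populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating the jurisdictional importance of tracked marine populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wide-ranging marine animals — the motivating case is breeding albatrosses
and large petrels carrying GLS, PTT, or GPS devices — spend their year
moving among national jurisdictions (a country's land plus its EEZ and
those of its dependencies), the high seas, and, within the high seas, the
competence areas of regional fisheries management organisations (RFMOs).
Conservation negotiation needs those stakes quantified: how much of the
year does each breeding population spend where, which jurisdictions host
which species, and which origin-country → visited-area links are
strongest. `juristrack` implements that estimation pipeline as reusable,
tested components, together with a synthetic-data generator that provides
ground truth for validating every stage.

## The model

**Standardisation.** Devices report at different rates, so tracks are
reduced to the lowest common interval: one fix per bird per local day, the
fix nearest local noon. "Local" is solar time derived from the fix
longitude (UTC + lon/15 h) because a bird at sea has no meaningful civil
time zone; a UTC mode is provided for comparison. Tracks are truncated to
the 365 days following device attachment, so all results describe a single
breeding year (this matters for biennial breeders, whose second-year
coverage is poor). GLS tracks pass through a configurable filter chain
(equinox-window removal, then a daily displacement-rate gate); the
published analyses applied unpublished contributor-specific filters, so the
defaults here (±15 days, 1000 km/day) are explicit package defaults, not
field-calibrated constants, and each filter can be disabled.

**Representativeness.** Within each breeding population, calendar months
are pooled across years and a month is kept only if it has at least 10
tracking days (bird-days); a conservative variant additionally requires
those days to span at least 5 individuals. We count bird-days rather than
distinct calendar dates, which makes the conservative rule a strict
tightening of the base rule.

**Zone assignment.** Every daily position receives exactly one
country-layer zone: positions south of 60°S are Antarctic regardless of
nominal claims; otherwise the containing country (or disputed) polygon
wins, with ties on shared boundaries broken by lexicographically smallest
zone id; everything else is high seas. High-seas positions additionally
collect every containing RFMO competence area — competences genuinely
overlap and no attribution rule is published, so multi-assignment is
deliberate and per-RFMO totals are flagged as non-additive. Disputed areas
are kept as their own zones named `disputed - A/B`; when a disputed zone
hosts a tracked colony the analysis is run once per claimant with the
colony's origin switched (bilateral disputes only).

**Time spent.** For population $p$ of species $s$, month $m$ and zone $e$:

$$T_{spme} = \frac{\sum_{i=1}^{n_m} D_{ime}/D_{im}}{n_m}\, N_p$$

where $D_{im}$ is the days individual $i$ was tracked in month $m$ and
$D_{ime}$ the subset spent in $e$; the mean individual proportion is
extrapolated by the breeding population size $N_p$ (individuals) to
bird-months. Annual time is

$$T_e = \sum_p \sum_m T_{spme} / 12$$

— divided by 12, never by the number of tracked months, so untracked
months contribute zero. This is a deliberate conservative underestimate:
dividing by tracked months would extrapolate occupancy into unsampled
seasons. It yields the conservation identity used throughout the tests,
$\sum_e T_e = \sum_p N_p\, \text{months}_p/12$ over the country layer.

**Connectivity.** The per-species origin share is
$G_{soe} = \sum_p \sum_m T_{spme} / (12\, N_s)$ with $N_s$ the species'
global breeding population, and the connection strength
$G_{oe} = 100 \sum_s G_{soe}$ sums shares over the species breeding in
origin $o$. Rankings keep the top 5 links per origin on the country layer
and top 3 on the RFMO layer; an origin's own waters are excluded from its
"visited areas" ranking by default (`include_self` reverses this — the
published figures do not state which convention they used, so both are
available).

**Richness.** A zone's breeding species are those with a tracked
population whose origin country owns the zone; presence (≥ 1 retained
daily fix) by populations of any other origin is visiting. The three
reported categories — breeding-only, visiting-only, both — are disjoint.
Because only tracked populations count, breeding richness is an
underestimate; `richness_underestimation()` audits the deficit against
known breeding-country lists.

## The grid

Richness and time surfaces are binned on a global equal-area grid of
hexagon-like cells with the target mean cell-centre spacing of 495 km
(± 30), the resolution that envelops the ~186 km GLS position error. With
no DGGS library available, the grid is a spherical Fibonacci lattice with
nearest-centre binning — exactly the lattice's spherical Voronoi cells.
The realized spacing (mean great-circle distance from each centre to its
six nearest neighbours, which matches the mean Delaunay edge length to
<0.1%) is auto-tuned to the target; the default resolves to ~2,500 cells
at 494 km. A Fibonacci grid's cells are equal-area within 5% except the
few spiral-end cells around each pole (≤ 8% deviation); these are flagged
`irregular`, the analogue of the 12 pentagons of an icosahedral DGGS. The
tests verify the area contract against exact spherical Voronoi areas
computed by an independent implementation. Because binning is a partition
of daily positions, grid time totals conserve the zone-layer totals
exactly, at any resolution.

## Geometry engine

Zones are stored as multipolygons in WGS84 with longitudes normalised to
[-180, 180) and edges straight in (lon, lat), matching how EEZ/RFMO
boundary products are digitised. Rings crossing the antimeridian are split
at read time, making all predicates planar-safe; containment uses the
winding-number test (an independently written even–odd ray-casting oracle
backs it in the tests), and areas use the exact spherical closed form for
lon/lat-linear edges. Country zones are unions kept as polygon
collections (membership = inside any part), so no geometric dissolve is
needed; the RFMO "clip to high seas" is enforced functionally — a day
counts toward an RFMO only when its country-layer assignment is high seas
— with clipped areas estimated by deterministic quasi-Monte-Carlo
sampling. Accuracy caveat: planar predicates distort near the poles, but
the Antarctic rule (everything south of 60°S) makes that region rule-based
rather than geometric.

## The synthetic world

`sim_config()` defaults state the validation world: a 365-day breeding
year of daily positions; country zones as EEZ-scale boxes (thousands of
km) in a northern band partitioning the globe with a high-seas
complement; RFMO boxes confined to a southern high-seas band with a
deliberate overlap; colonies at country centres; a device mix of GLS, PTT
and GPS with isotropic Gaussian GLS error of SD 186 km (the published GLS
error scale; isotropy is our explicit simplification, as no anisotropy is
published). Movement is a stand-in: central-place scatter at the colony
(trip radius 300 km), waypoint migration into the southern high seas, a
wintering dwell, and return, with 60 km/day path noise — parameters chosen
once so that monthly zone mixes are nondegenerate (populations touch
several zones per month). Population sizes default to 18–30 individuals,
every one simulated, so that full-tracking runs can be compared exactly
against ground truth; `n_s` defaults to the summed population sizes so
that complete coverage drives $\sum_e G_{soe}$ to exactly 1.

What a green test does establish: the estimator is exact under complete
noiseless tracking; its error shrinks as the tracked fraction grows; the
partition, conservation, and oracle-equivalence invariants hold; zone-size
dependence of GLS-error sensitivity behaves as expected. What it does not:
realism of seabird behaviour, real EEZ geometry (fjords, enclaves,
archipelagic baselines), device-specific error structure beyond isotropic
Gaussian, or the published headline numbers, which require the restricted
tracking archive.

## Numerical choices

- All intermediate quantities are unrounded; bird-years are rounded
  half-up to integers and percentages to one decimal only on report. The
  published worked example (a monthly mean "printed as 17%" of
  $N_p = 66{,}080$ yielding 11,284 bird-months) is reproducible only with
  unrounded means — the rounded value gives 11,233.6 — and the tests
  assert exactly that.
- Ties between fixes equidistant from local noon go to the earliest
  timestamp; boundary points between zones go to the smallest zone id;
  equal connection strengths are broken by species count, then zone id.
  All are determinism devices with measure-zero effect.
- The country-partition overlap check and all clipped-area estimates use
  deterministic seeded sampling (tolerance: overlap beyond 0.1% of the
  sphere is an error); the caller's RNG state is always preserved.
- The GLS sensitivity resampler perturbs each daily GLS fix independently
  per replicate (the published supplement's exact resampling design is not
  in the main text; per-fix perturbation with configurable replicates is
  our stand-in).
- Filter order matters (equinox before speed); the applied chain is
  recorded in the output's `filters` attribute rather than pretending to
  commutativity.

## Known limitations

- Country zones are membership unions, not dissolved geometries; exporting
  a dissolved boundary per country is out of scope.
- RFMO multi-assignment means per-RFMO times are not additive across
  RFMOs; consumers must not sum them.
- Planar containment near (non-Antarctic) poles is approximate; irrelevant
  for the stated world, documented for real-data use.
- Only bilateral disputes are supported for sovereignty variants, matching
  the published cases.
- The movement model is not a behavioural simulator; it exists to give the
  estimator a known truth, not to mimic foraging ecology.
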