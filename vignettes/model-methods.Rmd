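---
title: "A conductance-based network model of orientation hypercolumns in macaque V1 layer 4Cα"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based network model of orientation hypercolumns in macaque V1 layer 4Cα}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the model is

`v1net` simulates the magnocellular input layer (4Cα) of macaque primary
visual cortex at ~5° eccentricity as a conductance-based integrate-and-fire
network driven by a sparse LGN mosaic and coupled to a rate-indexed layer-6
(L6) feedback population.  The scientific question it is built around is
contrast response: how a cortical layer that receives only a handful of
feedforward LGN afferents per neuron produces the full, graded, steeply
rising firing-rate-versus-contrast function observed in vivo, while
simultaneously sharpening its orientation selectivity at high contrast and
keeping the spatial layout of its activity maps stable across contrast.

The package is organised as a construction pipeline
(`hc_grid()` → `build_sheet()` → `build_lgn_mosaic()` →
`assign_lgn_inputs()` → `sample_recurrent_connectivity()` → `wire_l6()`,
bundled by `build_network()`), a compiled integrator (`run_simulation()`),
and an analysis suite (`mean_rates()`, `circular_variance()`,
`modulation_ratio()`, `op_ratio()`, `estimate_c50()`, `activity_map()`,
`summed_spike_fraction()`, `spectral()`), with experiment recipes
(`run_experiment()`) that bundle the standard stimulus batteries.

## Geometry and wiring

The cortical sheet is a grid of 0.5 × 0.5 mm hypercolumns (HCs); at the
2 mm/° magnification of parafoveal V1 each HC sees (0.25°)² of visual
field.  Each HC is divided into six 60° wedges around a pinwheel centre;
counterclockwise the wedges carry intended orientations 0°, 30°, …, 150°
(0° vertical).  Neurons are laid down uniformly at 4,000 per HC, 3:1
excitatory:inhibitory, following macaque cell-density estimates.

ON-centre LGN receptive fields start on a triangular lattice of 0.125°
spacing; OFF cells sit at the barycentres of the upward-pointing lattice
triangles, which makes the OFF density exactly equal to the ON density
(using both triangle classes would double it and contradict the ~5 ON +
5 OFF cells per HC region the density data imply).  Each lattice point is
jittered by an isotropic Gaussian (SD 0.02°, small against the spacing; the
magnitude of the biological mosaic jitter is not constrained further here).
The resulting density, 2·2/(√3·0.125²)/16 ≈ 9.2 cells per HC region, is the
model's rendering of the anatomical estimates of roughly 9–10 magnocellular
afferents per HC.

Orientation preference is seeded by LGN input templates: 2–3 parallel rows
of 1–3 cells (≤6 total) of alternating polarity, rows separated by
3/16°–1/4° so that the implied push–pull subregions prefer ~2.5–3
cycles/°.  The triangular lattice has three-fold symmetry, so the 60°/120°
template sets are exact rotations of the 0° set and 90°/150° of the 30°
set (`enumerate_templates()`, `rotate_template()`).  A majority (default
85%) of E-cells in each wedge receives a template of the wedge's intended
orientation, matched slot-by-slot to the nearest mosaic cells of the right
polarity; the per-cell LGN input count is drawn from a distribution skewed
toward 4–6 (so simple cells dominate), with a tail of cells receiving 0–1
inputs that seed complex-like, recurrently driven receptive fields.  The
count distribution itself is a free parameter of the model: only the 0–6
range is anatomically fixed.  I-cells receive a few (default 3) nearest
mosaic cells regardless of polarity — untuned feedforward drive; their
selectivity (and its breadth) is inherited from the network.

Recurrent connection probability is a truncated Gaussian of cortical
distance (SD 200/√2 µm for excitatory axons, 125/√2 µm for inhibitory;
peaks ~15% for E→E and 60% for E→I, I→E, I→I), with strength independent
of distance.  Truncation radii are calibrated once, in closed form, so that
the interior in-degrees match the anatomical targets (≈200 E and ≈100 I
afferents per E-cell; ≈750 E and ≈100 I per I-cell): with untruncated
expectation $U = p\,\rho\,2\pi\sigma^2$, the cutoff
$r_c = \sigma\sqrt{2\log(U/(U-\text{target}))}$ removes exactly the excess.
Boundaries are open; statistics are quoted for interior cells.

L6 is not modelled as a network.  Three hundred projection units per HC are
placed on an even grid; each L4 E-cell draws 38–55 of them (anticorrelated
with its LGN count — complex-cell seeds get the most feedback), each I-cell
100–110, with 5/6 of contacts inside 180 µm and the rest out to 360 µm.

## Dynamics

Membrane potentials are normalised: spikes at threshold 1, reset at 0,
capacitance 1, so conductances and currents are in s⁻¹.  The update is
exponential-Euler at 0.1 ms with reversal potentials $V_E = 14/3$,
$V_I = -2/3$ and leak 50 s⁻¹ — the standard normalisation of this model
family.  Synaptic conductances are single-exponential (AMPA-like 3 ms,
GABA-A-like 5 ms) with delays of 1 ms (excitatory) and 0.5 ms (inhibitory);
delays are not constrained by the source anatomy and are configurable.
Each delivered event with weight $S$ adds $S/\tau$ to the target's
conductance, so $S$ is the time-integral of the conductance transient and
$S\,(V_E - v)$ approximates the voltage kick — with $S_{EE} = 0.028$ a
cell near rest needs 10–20 quick EPSPs to reach threshold, which is the
constraint that fixes the admissible $S_{EE}$ range [0.02, 0.03].
$S_{II} = 0.75\,S_{EI}$ stands in for the unmodelled electrical coupling
among basket cells.  Ambient drive (all otherwise-unmodelled modulatory
input) is a homogeneous Poisson bombardment per cell.

Three short-term mechanisms shape contrast response:

* **I→E synaptic depression.**  When an I-cell spikes at $t_1$ after a
  previous spike at $t_0$, its weight onto E-cells is
  $S^{EI}_{\text{base}}\,(1 - 0.12\,e^{(t_0-t_1)/20\,\text{ms}})$: a 12%
  maximal weakening that recovers with a 20 ms time constant (gone by
  ~40 ms).  I→I weights are not depressed.
* **L6 facilitation.**  The L6→L4 coupling grows with the unit's rate;
  it is piecewise linear through (30 sp/s, 1.0) and (60 sp/s, 1.1) —
  only that two-point ratio is empirically constrained — and clamped
  outside 0–90 sp/s.
* **E threshold adaptation.**  Each spike raises an E-cell's threshold by
  0.2 (20% of baseline), and the excess decays exponentially with
  $\tau = 10/\ln 10 \approx 4.34$ ms, the unique exponential that sheds
  90% of the excess in 10 ms.

### The self-adjusted L6 loop

Each L6 unit's instantaneous rate is $f(R)$, where $R$ is the mean firing
rate of the L4 neurons (both classes) within 75 µm of the unit over the
preceding ~50 ms, re-evaluated every 5 ms from a sliding window
(continuous-time updating is not specified by the physiology; 5 ms is well
below every other timescale in the loop).  $f$ is an increasing sigmoid,
independent of position, time and stimulus: logistic with floor 5 sp/s,
ceiling 80 sp/s, midpoint 21.5 sp/s and scale 1.6 sp/s.  The floor/ceiling
anchors encode known L6 behaviour — ~5 sp/s when L4 is spontaneous,
~80 sp/s when L4 fires at peak rates; note that because $R$ averages both
E- and I-cells, "spontaneous" corresponds to $R \approx 9$ sp/s and "peak"
to $R \approx 26$ sp/s in $R$-space.  Units emit Poisson spikes at $f(R)$;
each synaptic delivery independently fails with probability 0.5 (the high
L6 rates come with a ~50% synaptic failure rate), and surviving deliveries
carry the facilitation multiplier.  Facilitation is applied to the
delivered weight, not to the failure probability — the data constraining
it are EPSP amplitudes.  L6 couples more strongly to E than to I cells
($S_{L6\to E} = 0.041$ vs $S_{L6\to I} = 0.01$), making the feedback net
excitatory, which is what the sparse-LGN macaque circuit requires.

## Parameter tuning and the operating point

The published description of this model family fixes the architecture and
the mechanism constants quoted above but not the absolute synaptic weights
of the LGN, ambient and L6 pathways, nor the LGN filter magnitudes; those
were located by simulation against the printed rate targets, exactly as the
original modelling work describes doing.  Tuning was performed on the
reduced 1 × 3-HC strip (12,000 neurons) with vertical 2.5 c/° gratings:
the targets were a spontaneous E rate of 3–4 sp/s with I at 3–4× that, a
high-contrast optimal-domain mean near 18 sp/s collapsing to ~8 sp/s when
$S_{EE}$ is scaled to 75%, orthogonal-domain responses pinned near
background, and gamma-band population rhythms.  The final defaults are in
`default_config()`.

Two properties of the tuned system are worth recording honestly.  First,
the L4↔L6 positive feedback makes the network bistable: there is a sharp
ignition boundary (at $S_{L6\to E} \approx 0.042$ with the other
defaults) beyond which the whole sheet locks into a self-sustained
high-rate state and orientation selectivity is lost.  The reference point
sits deliberately on the stable side, close enough to the boundary for the
driven domain to climb the sigmoid at high contrast.  Second, at that
operating point the peak-contrast E-current decomposition of the reduced
model is roughly 55% recurrent L4, 23% L6 and 18% LGN: the L6 share matches
the ~25% benchmark, but recurrent L4 falls short of the ≥60% benchmark and
LGN exceeds the <10% one, and the orthogonal-domain response rises a few
sp/s with contrast rather than staying flat.  These deviations are reported
by the acceptance suite rather than hidden by retuning; they are the cost,
in a half-height strip with open boundaries and re-derived filter
magnitudes, of keeping the ignition instability at bay.

## Stimuli and the LGN front end

Stimuli are drifting sinusoidal gratings
$I(\mathbf{x},t) = L_0\,(1 + c\,\sin(2\pi(\mathbf{k}\cdot\mathbf{x} - f_t t) + \phi))$
(orientation 0° = vertical, drift 4 Hz by default).  LGN cells are
spatiotemporal filters: a centre–surround difference of Gaussians in space
(centre SD 0.05°, surround 3× larger, surround integral 0.8 of centre —
magnocellular-like values, configurable) and a biphasic difference of
gamma-shaped lobes in time.  For sinusoidal gratings the filter response is
evaluated analytically — a sinusoid at the drift frequency whose amplitude
carries the spatial/temporal gains and whose phase is set by the cell's
receptive-field position (OFF cells half a cycle off) — which avoids any
numerical convolution error on the rate traces.  The cycle-peak rate is
scaled to follow a saturating hyperbolic-ratio contrast-response
$R_b + R_{\max}\,c/(c + c_{50})$ with $R_b = 20$ sp/s, $R_{\max} = 105$
sp/s, $c_{50} = 0.15$, because the available benchmark for the LGN input is
stated in peak firing rates.  Rates are rectified at zero; spikes are an
inhomogeneous Poisson process thinned by a 2 ms absolute refractory period
(the simplest generator consistent with the description).  A consequence
worth noting: the *mean* rate of an LGN cell is orientation independent —
only the modulation is tuned — so all orientation selectivity downstream
originates in the spatial phase alignment of template rows, not in the
per-cell rates.

## Analysis conventions

Rates are spike counts over the last half of a run (canonically seconds
5–10 of 10).  "Silent" neurons — peak rate strictly below 5 sp/s over the
whole stimulus battery — are excluded from population averages, matching
experimental practice; the classification is made once on the reference
model and reused for mechanism-knockdown measurements.  Preferred
orientation is the argmax of the measured curve, not the intended wedge
label.  C50 comes from a hyperbolic-ratio fit with exponent fixed at 1
(configurable), falling back to linear interpolation of the half-rise.
Modulation ratios use the final integer number of stimulus cycles in the
window.  Activity maps average rates over 50 µm pixels (900 pixels on the
3 × 3-HC sheet) and 1 s of time; empty pixels are missing, not zero.  The
population spectrum is a Hann-windowed Welch average (500 ms segments, 50%
overlap) of the mean-subtracted summed-spike series; none of the spectral
settings are externally constrained.

## Reproducibility and scale

Every stochastic step draws from a named substream derived from one master
seed, so a (config, seed) pair reproduces networks and spike records
bit for bit.  Scale presets: `mini` (1 HC, used by the unit tests),
`reduced` (1 × 3 HC — all emergent benchmarks in the test-suite and the
acceptance script run at this scale, with 8–10 s simulations), and `full`
(3 × 3 HC, 36,000 neurons, the scale of the published figures; a 10 s
full-scale simulation is minutes of compute, so the package's own checks
stay at reduced scale).  The test-suite's emergent blocks use 8-s runs
with a 4–8 s window as a faithful, cheaper stand-in for the 10-s protocol.

## Known limitations

* Intended orientation is piecewise-constant over six wedges; there are no
  continuous orientation maps, no ocular dominance, and no layers other
  than 4Cα (plus L6 output rates).
* Only gratings are exercised, although any light-intensity map can be
  presented in principle.
* The synthetic stimulus/LGN stage emulates steady-state drifting-grating
  responses; it does not model natural-image statistics, eye movements, or
  retinal nonlinearities beyond rectification and the saturation curve.
* The emergent benchmarks quantify a *re-tuned* model: absolute currents
  and the exact current decomposition depend on re-derived magnitudes and
  on the reduced geometry, as discussed above.
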