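# acoustosort

A desk-scale digital twin of an image-activated acoustofluidic cell
sorter, for microfluidics and cytometry researchers who want to reason
quantitatively about such a device — its throughput ceiling, its
coincidence statistics, its gating arithmetic, and its image pipeline —
without hardware.

The device being modelled couples real-time deformability cytometry
(RT-DC) to a focused travelling surface-acoustic-wave (TSAW) actuator:
cells flow single-file through a narrow channel, each frame is reduced to
morphometric features, and cells whose features fall inside a gate are
pushed into a target outlet by a millisecond acoustic pulse. The package
implements:

- **Synthetic data**: parametric cell/bead populations with ground-truth
  labels, Poisson arrival streams, and rendered grayscale frame stacks
  (filled ellipses over noise, with analytic area/perimeter ground truth).
- **Feature extraction**: temporal-median background, sub-pixel
  (marching-squares) contour detection with half-contrast edge refinement,
  convex hull, and the four gating features — area *A*, deformation
  *D* = 1 − 2√(πA)/ℓ, hull/raw area ratio, mean brightness.
- **Acoustofluidic physics**: IDT resonance *f* = *v*/λ; regime factor
  κ = 2π*d*ₚ*f*/*C*_f (radiation force above κ ≈ 1.28, streaming drag
  below); acoustic contrast factor
  φ = (5ρₚ − 2ρ_f)/(2ρₚ + ρ_f) − βₚ/β_f; standing-wave force
  −(πP₀²Vₚβ_f/2λ)·φ·sin(2kx); travelling-wave force Y_T·π*d*ₚ²⟨E⟩/4;
  Stokes drag 3πη*d*v; quasi-steady pulse displacement Δy = Fτ/(3πη*d*).
- **Sorting simulation**: residence and coincidence in the sorting
  region, gate-triggered pulses after a detection delay, co-sort vs
  abort coincidence policies, and reports of initial/target purity,
  enrichment, recovery and throughput.
- **Gating metrics**: half-open interval and polygon gates, purity with an
  area-ratio quality pre-filter, enrichment = TP/IP, recovery, CV, and
  Gaussian KDE curves.

Everything is tidyverse-native: event tables in, tibbles out, `tidy()` /
`glance()` on run reports, `plot_events()` / `autoplot()` for figures, and
a YAML configuration layer in which every physical quantity carries an
explicit unit (`"0.08 ul/s"`, `"135 MHz"`).

## Worked example

Sort the smaller of two closely sized bead populations (modal diameters
1.7 µm apart, 3.2% CV) with a 115–135 µm² size gate, at an in-channel
concentration of 10⁶ cells ml⁻¹ in the standard 0.08 µl s⁻¹ flow:

```r
library(acoustosort)

geom  <- channel_geometry(volume_nl = 0.2)          # 50 x 130 um sorting region
flow  <- flow_config(sample_ul_s = 0.01, sheath_ul_s = 0.07)
field <- acoustic_field("TSAW", frequency = 135e6,
                        energy_density = 100, pulse_duration = 1e-3)
beads <- bead_mixture_spec()
g     <- gate("bead_small", area_range = c(115, 135), area_ratio_max = 1.05)

set.seed(1)
stream <- generate_arrival_stream(1e6, flow$total_ul_s, 360,
                                  c(bead_small = 0.5, bead_large = 0.5))
events <- sample_events_for_stream(stream, beads)
run <- simulate_sort(stream, events, g, field, geom = geom, flow = flow,
                     coincidence = "abort")
run$report
#> Sorting run report (gate 'bead_small', abort policy)
#>   events: 28693 total | 11367 gated | 9318 pulses | 2049 aborted | 9318 collected
#>   IP 39.62% -> TP 100.00%  (2.52-fold enrichment)
#>   recovery 82.0% | throughput 79.7 events/s
```

Reading the numbers: 39.6% of arriving beads fall inside the gate (the
initial purity). Every gated bead requests a pulse, but at this
concentration the sorting region (0.2 nl, residence 2.5 ms) already holds
a second bead 18% of the time, and the abort policy suppresses those
pulses rather than risk co-sorting a bystander — hence 2049 aborts and a
recovery of 82%, while the sorted sample stays 100% pure. Switching to
`coincidence = "co-sort"` trades that purity for yield.

The throughput ceiling of the device follows from single occupancy of the
sorting region:

```r
max_in_channel_concentration(geom)                    # 5e+06  cells/ml
max_sorting_rate(5e6, flow$total_ul_s)                # 400    cells/s
residence_time(geom, flow) * 1e3                      # 2.5    ms
max_sample_concentration(5e6, flow$sheath_to_sample)  # 4e+07  cells/ml
kappa_factor(2.25e-6, 135e6, 1487)                    # 1.28   (ARF/ASF boundary)
```

A thin CLI over the same functions ships in
`inst/scripts/acoustosort.R` (subcommands `physics`, `simulate-images`,
`extract`, `gate`, `simulate-sort`, `sweep-concentration`, `report`).

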