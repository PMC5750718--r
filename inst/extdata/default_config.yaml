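# Default anatomical constants and stimulus for the macaque early visual pathway.
# Any subset of these keys may be overridden by a user config file; unknown keys
# are rejected. Units: eccentricity deg, areas deg^2, depths mm, densities
# cells/deg^2 (retina, LGN) or neurons/mm^3 (V1).
stimulus:
  area: 1.0            # deg^2
  eccentricity: 3.0    # deg, stimulus center
  width: ~             # deg; optional, only used in integrated mode
  height: ~            # deg; optional, width*height must equal area
  mode: point          # point | integrated
v1:
  magnification:       # areal magnification M(E) = scale*(offset + E)^-exponent, mm^2/deg^2
    scale: 103.0
    offset: 0.82
    exponent: 2.28
  laminar_depth: 0.75        # mm, layers 2/3/4B
  excitatory_fraction: 0.8   # pyramidal (excitatory) share of V1 neurons
  density: 120000.0          # neurons/mm^3
  tuned_fraction: 0.75       # share with orientation bandwidth < 30 deg
  responsive_fraction: 0.55  # share responsive to at least one stimulus (non-silent)
lgn:
  parvo:               # N_P(E) = scale*(offset + E)^-exponent, cells/deg^2
    scale: 1011688.0
    offset: 2.9144
    exponent: 2.6798
  magno:               # N_M(E) = scale*(floor + (E - center)^2)^-exponent, cells/deg^2
    scale: 2620.2
    floor: 5.5638
    center: 1.8322
    exponent: 0.8012
rgc:
  anchors:             # piecewise-linear density anchors (binocular, 90% of RGCs projecting to LGN)
    - eccentricity: 2.0
      density: 8500.0
    - eccentricity: 5.0
      density: 3000.0
  extrapolate: false   # refuse eccentricities outside the anchor range by default
rounding:              # half-up reporting grains matching the printed "approximately" figures
  surface: 1.0         # mm^2
  volume: 1.0          # mm^3
  v1: 10000.0          # neurons
  lgn: 1000.0          # neurons
  rgc: 500.0           # cells
  ratio: 1.0
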