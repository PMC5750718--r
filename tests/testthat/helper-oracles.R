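# Independent oracles, kept separate from the implementation paths they check.

# log-domain re-evaluation of the power law a*(b+E)^-c
power_law_log_oracle <- function(a, b, c, E) exp(log(a) - c * log(b + E))

# log-domain re-evaluation of the shifted parabola a*(b+(E-d)^2)^-c
parabola_log_oracle <- function(a, b, d, c, E) exp(log(a) - c * log(b + (E - d)^2))

# midpoint Riemann sum of the magnification over an eccentricity band
riemann_surface <- function(model, ecc, width, height, n = 1e4) {
  edges <- seq(ecc - height / 2, ecc + height / 2, length.out = n + 1)
  mid <- (edges[-1] + edges[-(n + 1)]) / 2
  width * sum(predict(model, mid)) * height / n
}

# half-up rounding via integer arithmetic (distinct route from floor(x/g + .5))
round_half_up_oracle <- function(value, grain) {
  q <- value %/% grain
  (q + as.numeric(value - q * grain >= grain / 2)) * grain
}

# frozen high-precision closed-form values, computed independently before the build
ORACLE <- list(
  M3 = 4.849899701631094,      # 103 * 3.82^-2.28
  M0 = 161.93534141952006,     # 103 * 0.82^-2.28
  NP3 = 8639.335169061726,     # 1,011,688 * 5.9144^-2.6798
  NP0 = 57563.575847819186,
  NM3 = 555.7272180908284,     # 2,620.2 * 6.9276…^-0.8012
  NM_peak = 662.434264594758,  # at E = 1.8322
  RGC3 = 6666.6666666666667,   # linear interpolation between the anchors
  V1_RAW = 349192.7785174388,  # M(3) * 0.6 * 120,000
  LGN_RAW = 9195.062387152553  # NP(3) + NM(3)
)
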