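#' Polychromatic X-ray source spectrum
#'
#' A 120 kVp-like spectrum discretized on 12 energy bins from 10 to 120 keV
#' (10 keV steps). The relative bin weights describe a filtered tungsten-like
#' tube output: negligible below 20 keV, peaked near 60 keV and falling
#' towards the 120 keV endpoint. The weights are normalized so that the bin
#' photon counts sum to `I0_total` (default 1e6 incident photons per
#' detector pixel).
#'
#' @param I0_total total incident photons per ray.
#' @return A list with `energies_keV`, `photon_counts` and `I0_total`,
#'   class `xray_spectrum`.
#' @export
xray_spectrum <- function(I0_total = 1e6) {
  energies <- seq(10, 120, by = 10)
  # relative fluence of an aluminum-filtered 120 kVp tungsten beam: the
  # 10 keV bin is fully absorbed by filtration, the spectrum peaks near
  # 60 keV and tails off towards the tube voltage
  w <- c(0, 0.02, 0.15, 0.50, 0.85, 1.00,
         0.95, 0.80, 0.60, 0.40, 0.20, 0.05)
  counts <- I0_total * w / sum(w)
  structure(list(energies_keV = energies, photon_counts = counts,
                 I0_total = I0_total),
            class = "xray_spectrum")
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf("<xray_spectrum: %d bins, %g..%g keV, %.3g photons>\n",
              length(x$energies_keV), min(x$energies_keV),
              max(x$energies_keV), x$I0_total))
  invisible(x)
}

#' Linear attenuation coefficients of the simulated materials
#'
#' Energy-dependent linear attenuation (mm^-1) for water, soft tissue,
#' cortical bone and gold on the 12-bin energy grid of [xray_spectrum()].
#' Values derive from the NIST XCOM mass-attenuation tables times nominal
#' densities (water 1.00, soft tissue 1.06 scaled, cortical bone 1.92,
#' gold 19.32 g/cm^3), linearly interpolated in log-log to the 10-keV grid.
#' Two deliberate simplifications are applied and documented here: (i) the
#' gold column is smoothed across the Au K-edge at 80.7 keV so that every
#' material's attenuation is monotone non-increasing over 10-120 keV, and
#' (ii) soft tissue is modeled as water scaled by 1.043, placing it at
#' +43 HU on the reference scale. Bone is tabulated at full cortical
#' density; the phantom applies fractional density weights for jaw and
#' teeth. No network access is needed at run time.
#'
#' @return A data.frame with columns `energy_keV`, `water`, `soft_tissue`,
#'   `bone`, `gold` (mm^-1).
#' @export
material_attenuation <- function() {
  data.frame(
    energy_keV = seq(10, 120, by = 10),
    water = c(0.5329, 0.0810, 0.0376, 0.0268, 0.0227, 0.0206,
              0.0195, 0.0184, 0.0178, 0.0171, 0.0166, 0.0162),
    soft_tissue = 1.043 * c(0.5329, 0.0810, 0.0376, 0.0268, 0.0227, 0.0206,
                            0.0195, 0.0184, 0.0178, 0.0171, 0.0166, 0.0162),
    bone = c(5.4740, 0.7682, 0.2556, 0.1278, 0.0815, 0.0604,
             0.0503, 0.0428, 0.0382, 0.0356, 0.0335, 0.0319),
    gold = c(21.85, 14.49, 4.460, 2.108, 1.140, 0.696,
             0.468, 0.338, 0.258, 0.206, 0.178, 0.155)
  )
}

# water attenuation at the reference (effective) energy used for HU
MU_WATER_REF <- 0.0206
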