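#' Lumped electrode-tissue measurement model
#'
#' The voltage reaching the amplifier is the tissue potential attenuated by a
#' frequency-dependent divider between the electrode-tissue interface impedance
#' `Ze(f, A)` and the amplifier input impedance `Zin(f)`:
#'
#'   H(f) = Zin(f) / (Zin(f) + Ze(f, A))
#'
#' with `Ze = Rs(A) + (Rct/A || 1/(j 2 pi f Cdl A))`, where `Rs` is the disc
#' spreading resistance `rho_t / (4 sqrt(A/pi))`, `Cdl` the double-layer
#' capacitance (per unit area) and `Rct` the charge-transfer resistance
#' (area-normalized). All interface elements scale with the contact area `A`,
#' which is how electrode size enters the measurement. Thermal (Johnson) noise
#' of the interface, one-sided PSD `4 kB T Re(Ze)`, can be added at the
#' amplifier input.
#'
#' @param area Contact surface area A in mm^2 (1.08 = high-density grid contact).
#' @param c_dl Double-layer capacitance per unit area, F/mm^2. Default 0.2 uF/mm^2,
#'   a typical platinum value.
#' @param r_ct Charge-transfer resistance times area, Ohm*mm^2. Default is large
#'   so the interface is capacitive in the HFO band.
#' @param tissue_resistivity Tissue resistivity in Ohm*m for the spreading
#'   resistance (about 3 Ohm*m for grey matter).
#' @param z_in Amplifier input impedance: `list(r =, c =)` (Ohm, F),
#'   interpreted as a parallel RC.
#' @param temperature Temperature in K for thermal noise.
#' @param material Electrode material label.
#' @return An object of class `electrode_model`.
#' @examples
#' em <- electrode_model(area = 1.08)
#' Mod(electrode_transfer_gain(c(100, 250, 400), em))
#' @export
electrode_model <- function(area = 1.08,
                            c_dl = 0.2e-6,
                            r_ct = 1e6,
                            tissue_resistivity = 3,
                            z_in = list(r = 1e8, c = 10e-12),
                            temperature = 310,
                            material = "platinum") {
  stopifnot(
    is.finite(area), area > 0,
    is.finite(c_dl), c_dl > 0,
    is.finite(r_ct), r_ct > 0,
    is.finite(tissue_resistivity), tissue_resistivity > 0,
    is.finite(z_in$r), z_in$r > 0, is.finite(z_in$c), z_in$c > 0,
    temperature > 0
  )
  structure(
    list(
      area = area, c_dl = c_dl, r_ct = r_ct,
      tissue_resistivity = tissue_resistivity,
      z_in = z_in, temperature = temperature, material = material
    ),
    class = "electrode_model"
  )
}

#' @export
print.electrode_model <- function(x, ...) {
  cat(sprintf(
    "<electrode_model> %s, A = %.3g mm^2, Cdl = %.3g F/mm^2, Rct = %.3g Ohm mm^2\n",
    x$material, x$area, x$c_dl, x$r_ct
  ))
  invisible(x)
}

zpar <- function(z1, z2) z1 * z2 / (z1 + z2)

#' Electrode-tissue interface impedance
#'
#' @param f Frequency vector, Hz.
#' @param em An [electrode_model()].
#' @return Complex impedance in Ohm (same length as `f`).
#' @export
electrode_impedance <- function(f, em) {
  stopifnot(inherits(em, "electrode_model"))
  a_m2 <- em$area * 1e-6                      # mm^2 -> m^2
  rs <- em$tissue_resistivity / (4 * sqrt(a_m2 / pi))
  rct <- em$r_ct / em$area
  cdl <- em$c_dl * em$area
  jw <- 2i * pi * f
  # Rct || Cdl, written to stay finite at f = 0 (-> Rct)
  z_if <- rct / (1 + jw * cdl * rct)
  rs + z_if
}

#' Amplifier input impedance
#'
#' @inheritParams electrode_impedance
#' @return Complex impedance in Ohm.
#' @export
amplifier_impedance <- function(f, em) {
  jw <- 2i * pi * f
  em$z_in$r / (1 + jw * em$z_in$c * em$z_in$r)
}

#' Measurement transfer function H(f)
#'
#' @inheritParams electrode_impedance
#' @return Complex gain, `Mod(H)` in (0, 1].
#' @export
electrode_transfer_gain <- function(f, em) {
  zin <- amplifier_impedance(f, em)
  ze <- electrode_impedance(f, em)
  zin / (zin + ze)
}

#' Measure a tissue potential through the electrode model
#'
#' Applies `H(f)` in the frequency domain and optionally adds interface
#' thermal noise (one-sided PSD `4 kB T Re(Ze)`, referred to the amplifier
#' input after the divider).
#'
#' @param potential Tissue potential waveform, uV.
#' @param em An [electrode_model()].
#' @param fs Sampling rate, Hz.
#' @param add_noise Add Johnson noise of the interface?
#' @return Measured waveform in uV, same length as `potential`.
#' @export
electrode_transfer <- function(potential, em, fs, add_noise = TRUE) {
  stopifnot(inherits(em, "electrode_model"), fs > 0)
  n <- length(potential)
  if (n == 0L) return(potential)
  fbin <- fft_bin_freqs(n, fs)
  h <- electrode_transfer_gain(abs(fbin), em)
  h[fbin < 0] <- Conj(h[fbin < 0])
  y <- Re(stats::fft(stats::fft(potential) * h, inverse = TRUE)) / n
  if (add_noise) {
    y <- y + thermal_noise(n, fs, em)
  }
  y
}

# two-sided FFT bin frequencies in natural fft() order
fft_bin_freqs <- function(n, fs) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n == 1L) k <- 0
  k * fs / n
}

# interface Johnson noise in uV, shaped in the frequency domain so that the
# one-sided PSD equals 4 kB T Re(Ze(f))
thermal_noise <- function(n, fs, em) {
  kb <- 1.380649e-23
  fbin <- fft_bin_freqs(n, fs)
  s1 <- 4 * kb * em$temperature * Re(electrode_impedance(abs(fbin), em)) # V^2/Hz
  g <- sqrt(s1 * fs / 2)
  w <- stats::rnorm(n)
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
  x * 1e6
}
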