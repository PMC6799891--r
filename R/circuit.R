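#' Equivalent-circuit parameters of the electrode-electrolyte interface
#'
#' The sensing channel is modelled as a double-layer capacitance `C_dl` at
#' each of the two polarizable electrodes, in series with the solution
#' resistance `R_s`, which is in parallel with the direct coupling
#' capacitance `C_cell` between the electrodes.
#'
#' @param c_dl Double-layer capacitance per electrode, in farad.
#' @param r_s Solution (ionic) resistance of the channel, in ohm.
#' @param c_cell Electrode-to-electrode coupling capacitance, in farad.
#' @return An object of class `circuit_params`.
#' @examples
#' circuit_params()
#' @export
circuit_params <- function(c_dl = 1e-9, r_s = 1e5, c_cell = 1e-13) {
  for (nm in c("c_dl", "r_s", "c_cell")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single finite positive number", nm),
           call. = FALSE)
    }
  }
  structure(list(c_dl = c_dl, r_s = r_s, c_cell = c_cell),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Electrode-electrolyte equivalent circuit\n")
  cat(sprintf("  C_dl   : %.4g F (per electrode)\n", x$c_dl))
  cat(sprintf("  R_s    : %.4g Ohm\n", x$r_s))
  cat(sprintf("  C_cell : %.4g F\n", x$c_cell))
  invisible(x)
}

#' Complex impedance of the sensing channel
#'
#' Evaluates `Z(omega) = 2/(j omega C_dl) + R_s || 1/(j omega C_cell)` with
#' `omega = 2 pi f`: two double-layer capacitors in series with the parallel
#' combination of the solution resistance and the coupling capacitance.
#' The network is purely resistive-capacitive, so `Im(Z) < 0` at every
#' frequency and `|Z| -> 0` as `f -> Inf`.
#'
#' @param params A [circuit_params()] object.
#' @param frequency Excitation frequency (or vector of frequencies), Hz.
#' @return Complex impedance in ohm, same length as `frequency`.
#' @examples
#' circuit_impedance(circuit_params(), 5e5)
#' @export
circuit_impedance <- function(params, frequency) {
  stopifnot(inherits(params, "circuit_params"))
  if (!is.numeric(frequency) || any(!is.finite(frequency)) ||
      any(frequency <= 0)) {
    stop("`frequency` must be finite and strictly positive (Hz)",
         call. = FALSE)
  }
  omega <- 2 * pi * frequency
  z_dl <- 2 / (1i * omega * params$c_dl)
  z_cc <- 1 / (1i * omega * params$c_cell)
  z_par <- params$r_s * z_cc / (params$r_s + z_cc)
  z_dl + z_par
}

#' Default excitation frequency set
#'
#' Four simultaneous lock-in excitation frequencies; 500 kHz is always
#' included as the low-frequency (size-sensitive) channel, and 20-30 MHz
#' probe the cell interior.
#'
#' @param frequencies Strictly increasing numeric vector of 1 to 8
#'   frequencies, Hz.
#' @return Validated numeric vector of frequencies (Hz) with class
#'   `frequency_set`.
#' @export
frequency_set <- function(frequencies = c(5e5, 2e7, 2.5e7, 3e7)) {
  if (!is.numeric(frequencies) || length(frequencies) < 1L ||
      length(frequencies) > 8L) {
    stop("between 1 and 8 excitation frequencies are supported",
         call. = FALSE)
  }
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("frequencies must be finite and positive (Hz)", call. = FALSE)
  }
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  structure(as.numeric(frequencies), class = "frequency_set")
}

#' Human-readable labels for a frequency set ("500kHz", "20MHz", ...)
#' @param freqs A [frequency_set()] or numeric vector of Hz.
#' @return Character vector of labels.
#' @export
frequency_labels <- function(freqs) {
  vapply(as.numeric(freqs), function(f) {
    if (f >= 1e6) sprintf("%gMHz", f / 1e6) else sprintf("%gkHz", f / 1e3)
  }, character(1))
}
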