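# Base-graphics diagnostic plots for the main result objects.

#' @export
print.impedance_profile <- function(x, ...) {
  cat(sprintf("<impedance_profile> %d frequencies, f_R = %.2f Hz (%s)\n",
              length(x$frequencies_Hz), x$f_R_Hz,
              classify_resonant(x$f_R_Hz)))
  invisible(x)
}

#' @export
plot.impedance_profile <- function(x, ...) {
  graphics::plot(x$frequencies_Hz, x$impedance_MOhm, type = "l",
                 xlab = "Frequency (Hz)", ylab = "Impedance (MOhm)", ...)
  graphics::abline(v = x$f_R_Hz, lty = 2)
  invisible(x)
}

#' @export
print.current_components <- function(x, ...) {
  cat("<current_components>\n")
  cat(sprintf("  I_K_total peak %.0f pA | KA_fast %.0f | K_slow %.0f | ",
              x$peaks_pA["total"], x$peaks_pA["KA_fast"],
              x$peaks_pA["K_slow"]))
  cat(sprintf("sustained %.0f pA\n", x$sustained_pA))
  cat(sprintf("  fractions: fast %.2f, slow %.2f, sustained %.2f\n",
              x$fractions["fast"], x$fractions["slow"],
              x$fractions["sustained"]))
  invisible(x)
}

#' @export
plot.current_components <- function(x, ...) {
  rng <- range(x$I_K_total, x$I_KA_fast, x$I_K_slow, x$I_K_sustained)
  graphics::plot(x$time_ms, x$I_K_total, type = "l", ylim = rng,
                 xlab = "Time from step onset (ms)", ylab = "Current (pA)",
                 ...)
  graphics::lines(x$time_ms, x$I_KA_fast, col = 2)
  graphics::lines(x$time_ms, x$I_K_slow, col = 4)
  graphics::lines(x$time_ms, x$I_K_sustained, col = 3)
  graphics::legend("topright", lty = 1, col = c(1, 2, 4, 3), bty = "n",
                   legend = c("total", "KA fast", "K slow", "sustained"))
  invisible(x)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s (%s): V_1/2 = %.1f mV, k = %.2f mV, ",
              x$component, x$on, x$V_half_mV, x$k_mV))
  cat(sprintf("max %.2f %s\n", x$G_max_nS,
              if (x$on == "conductance") "nS" else "pA"))
  invisible(x)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$data$V_mV, x$data$G / x$G_max_nS,
                 xlab = "Command (mV)",
                 ylab = if (x$on == "conductance") "G / G_max"
                        else "I / I_max", ...)
  vv <- seq(min(x$data$V_mV), max(x$data$V_mV), length.out = 200)
  graphics::lines(vv, 1 / (1 + exp(-(vv - x$V_half_mV) / x$k_mV)))
  invisible(x)
}

#' @export
print.spike_features <- function(x, ...) {
  cat(sprintf(
    "<spike_features> threshold %.1f mV, max dV/dt %.0f mV/ms, amplitude %.0f mV\n",
    x$threshold_mV, x$max_dVdt_mV_per_ms, x$ap_amplitude_mV))
  invisible(x)
}

#' @export
plot.threshold_curve <- function(x, ...) {
  graphics::plot(x$duration_ms, x$threshold_mV, log = "x", type = "b",
                 xlab = "Pulse duration (ms)", ylab = "Threshold (mV)", ...)
  invisible(x)
}

#' @export
print.ih_measurement <- function(x, ...) {
  cat(sprintf("<ih_measurement> I_h_max %.1f pA", x$I_h_max_pA))
  if (is.finite(x$tau_fast_ms))
    cat(sprintf(", tau %.0f/%.0f ms (fraction fast %.2f)",
                x$tau_fast_ms, x$tau_slow_ms, x$fraction_fast))
  cat("\n")
  invisible(x)
}
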