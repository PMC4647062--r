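# Nonlinear fit helpers: single/double exponentials and the Boltzmann, via
# Levenberg-Marquardt least squares with multi-start over log-spaced time
# constants; tau ordering enforced, ties broken by residual.

.rms <- function(x) sqrt(mean(x^2))

# long traces carry no extra information for smooth exponential fits;
# thin them so the optimizer cost stays bounded
.thin_xy <- function(t, y, n_max = 500L) {
  if (length(t) <= n_max) return(list(t = t, y = y))
  idx <- unique(round(seq(1L, length(t), length.out = n_max)))
  list(t = t[idx], y = y[idx])
}

.fit_exp1 <- function(t_ms, y, tau_starts = NULL) {
  th <- .thin_xy(t_ms, y); t_ms <- th$t; y <- th$y
  rng <- diff(range(t_ms))
  if (is.null(tau_starts)) tau_starts <- rng / c(20, 4, 1)
  C0 <- y[length(y)]
  best <- NULL
  for (tau0 in tau_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-t_ms / tau) + C,
                        start = list(A = y[1] - C0, tau = tau0, C = C0),
                        lower = c(-Inf, 1e-6, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    r <- .rms(stats::resid(fit))
    if (is.null(best) || r < best$residual_rms) {
      cf <- stats::coef(fit)
      best <- list(amplitudes = unname(cf["A"]), taus_ms = unname(cf["tau"]),
                   offset = unname(cf["C"]), residual_rms = r)
    }
  }
  if (is.null(best))
    stop("single-exponential fit failed to converge", call. = FALSE)
  best
}

.fit_exp2 <- function(t_ms, y, tau_starts = NULL, tau_max = Inf) {
  th <- .thin_xy(t_ms, y); t_ms <- th$t; y <- th$y
  rng <- diff(range(t_ms))
  if (is.null(tau_starts)) {
    e1 <- tryCatch(.fit_exp1(t_ms, y), error = function(e) NULL)
    tau_starts <- if (!is.null(e1) && is.finite(e1$taus_ms))
      c(e1$taus_ms / 3, e1$taus_ms) else rng / c(50, 10, 2)
  }
  C0 <- y[length(y)]
  A0 <- y[1] - C0
  best <- NULL
  for (tf0 in tau_starts) {
    for (mult in c(5, 20)) {
      ts0 <- tf0 * mult
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ Af * exp(-t_ms / tf) + As * exp(-t_ms / ts) + C,
          start = list(Af = A0 / 2, tf = min(tf0, tau_max / 3),
                       As = A0 / 2, ts = min(ts0, tau_max), C = C0),
          lower = c(-Inf, 1e-6, -Inf, 1e-6, -Inf),
          upper = c(Inf, tau_max, Inf, tau_max, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (is.null(fit)) next
      r <- .rms(stats::resid(fit))
      if (is.null(best) || r < best$residual_rms) {
        cf <- stats::coef(fit)
        taus <- c(cf["tf"], cf["ts"])
        amps <- c(cf["Af"], cf["As"])
        ord <- order(taus)
        best <- list(amplitudes = unname(amps[ord]),
                     taus_ms = unname(taus[ord]),
                     offset = unname(cf["C"]), residual_rms = r)
      }
    }
  }
  if (is.null(best))
    stop("double-exponential fit failed to converge", call. = FALSE)
  best
}

# Boltzmann fit of conductance (or current) vs command voltage:
#   G(V) = G_max / (1 + exp(-(V - V_half)/k)), k > 0 for activation
.fit_boltzmann <- function(V, G) {
  Gmax0 <- max(G)
  half <- Gmax0 / 2
  Vh0 <- V[which.min(abs(G - half))]
  best <- NULL
  for (k0 in c(4, 8, 16)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(G ~ Gmax / (1 + exp(-(V - Vh) / k)),
                        start = list(Gmax = Gmax0, Vh = Vh0, k = k0),
                        lower = c(1e-12, -150, 0.1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    r <- .rms(stats::resid(fit))
    if (is.null(best) || r < best$residual_rms) {
      cf <- stats::coef(fit)
      best <- list(V_half_mV = unname(cf["Vh"]), k_mV = unname(cf["k"]),
                   G_max = unname(cf["Gmax"]), residual_rms = r)
    }
  }
  if (is.null(best)) stop("Boltzmann fit failed to converge", call. = FALSE)
  best
}
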