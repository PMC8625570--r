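#' Bimolecular rate constants
#'
#' Container for the association rate `kon` (per µM per s), dissociation
#' rate `koff` (per s) and the derived equilibrium dissociation constant
#' `kd = koff/kon` (µM).
#'
#' @param kon Association rate constant, µM^-1 s^-1, > 0.
#' @param koff Dissociation rate constant, s^-1, >= 0.
#' @return An object of class `RateConstants`.
#' @examples
#' rate_constants(kon = 8, koff = 0.216)  # Kd = 27 nM
#' @export
rate_constants <- function(kon, koff) {
  stopifnot(is.numeric(kon), kon > 0, is.numeric(koff), koff >= 0)
  structure(list(kon = kon, koff = koff, kd = koff / kon),
            class = "RateConstants")
}

#' @export
print.RateConstants <- function(x, ...) {
  cat(sprintf("<RateConstants> kon = %g 1/(uM*s), koff = %g 1/s, Kd = %s\n",
              x$kon, x$koff, format_kd(x$kd)))
  invisible(x)
}

#' Stopped-flow mixing configuration
#'
#' Concentrations are the values in the observation cell, i.e. after the
#' 1:1 stopped-flow mixing (syringe contents halved). Defaults follow the
#' standard protocol: 0.2 µM fluorescently labelled GTPase mixed with
#' 2 µM effector; competition premixes add a 10-fold molar excess of
#' competitor over effector (20 µM); displacement uses 10 µM unlabelled
#' GTPase. The instrument dead time (2 ms) is truncated from every trace.
#'
#' @param R0 Labelled GTPase concentration after mixing (µM).
#' @param E0 Effector concentration (µM).
#' @param C0 Competitor concentration (µM).
#' @param U0 Unlabelled displacer concentration (µM).
#' @param dead_time Instrument dead time (s); traces start here.
#' @param duration Trace duration (s); `NULL` chooses ~6 relaxation times
#'   of the simulated scheme.
#' @param n_points Number of samples per trace (>= 10).
#' @return A `MixConfig` list.
#' @export
mix_config <- function(R0 = 0.2, E0 = 2, C0 = 20, U0 = 10,
                       dead_time = 0.002, duration = NULL,
                       n_points = 200L) {
  stopifnot(R0 >= 0, E0 >= 0, C0 >= 0, U0 >= 0, dead_time >= 0,
            n_points >= 10L)
  if (!is.null(duration) && duration <= dead_time) {
    stop("duration must exceed the dead time", call. = FALSE)
  }
  list(R0 = R0, E0 = E0, C0 = C0, U0 = U0, dead_time = dead_time,
       duration = duration, n_points = as.integer(n_points))
}

# Baseline and span of the fluorescence readout (arbitrary units).
SIGNAL_BASELINE <- 0.1
SIGNAL_SPAN <- 1.0

new_trace <- function(times, signal, sigma = 0, seed = NULL) {
  stopifnot(length(times) == length(signal), !is.unsorted(times,
                                                          strictly = TRUE))
  structure(data.frame(time = times, signal = signal),
            sigma = sigma, seed = seed, class = c("Trace", "data.frame"))
}

add_noise <- function(trace, sigma, seed) {
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    trace$signal <- trace$signal + rnorm(nrow(trace), 0,
                                         sigma * SIGNAL_SPAN)
  }
  attr(trace, "sigma") <- sigma
  attr(trace, "seed") <- seed
  trace
}

#' Write/read traces as two-column TSV (time_s, signal)
#' @param trace A trace (data.frame with `time`, `signal`).
#' @param path File path.
#' @return `path` (write) or a trace (read).
#' @export
write_trace <- function(trace, path) {
  write.table(data.frame(time_s = trace$time, signal = trace$signal),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  new_trace(tab[[1L]], tab[[2L]])
}

# Shared stiff integrator settings: rate constants can span several orders
# of magnitude, so use lsoda with tight tolerances.
integrate_scheme <- function(y0, times, derivs, parms) {
  out <- deSolve::lsoda(y = y0, times = times, func = derivs,
                        parms = parms, rtol = 1e-8, atol = 1e-12)
  as.data.frame(out)
}

trace_times <- function(mix, tau) {
  duration <- mix$duration
  if (is.null(duration)) {
    duration <- max(mix$dead_time * 2, 6 * tau)
  }
  seq(mix$dead_time, duration, length.out = mix$n_points)
}

#' Closed-form association curve
#'
#' Bound-complex concentration for the reversible bimolecular scheme
#' R + E <-> RE starting from free species. With `exact = TRUE` the exact
#' analytic solution of the mass-action rate equation is returned; with
#' `exact = FALSE` the pseudo-first-order approximation
#' `RE(t) = A (1 - exp(-kobs t))` with `kobs = kon E0 + koff`, valid for
#' effector excess.
#'
#' @param rates [rate_constants()] of the effector.
#' @param mix [mix_config()] providing `R0`, `E0`.
#' @param times Time points (s).
#' @param exact Use the exact bimolecular solution (default) or the
#'   pseudo-first-order approximation.
#' @return Numeric vector of `[RE]` (µM) at `times`.
#' @export
association_closed_form <- function(rates, mix, times, exact = TRUE) {
  R0 <- mix$R0; E0 <- mix$E0
  kon <- rates$kon; koff <- rates$koff; kd <- rates$kd
  if (E0 == 0 || R0 == 0) return(rep(0, length(times)))
  if (exact) {
    # roots of kon*x^2 - kon*(R0+E0+Kd)*x + kon*R0*E0
    s <- R0 + E0 + kd
    disc <- sqrt(max(s^2 - 4 * R0 * E0, 0))
    x1 <- (s - disc) / 2
    x2 <- (s + disc) / 2
    if (disc < 1e-12) {
      # coincident roots (irreversible binding of equimolar partners)
      out <- x1 * kon * x1 * times / (1 + kon * x1 * times)
      out[is.infinite(times)] <- x1
      out
    } else {
      e <- exp(-kon * (x2 - x1) * times)
      x1 * x2 * (1 - e) / (x2 - x1 * e)
    }
  } else {
    kobs <- kon * E0 + koff
    amp <- R0 * E0 / (E0 + kd)
    amp * (1 - exp(-kobs * times))
  }
}

# [RE] -> fluorescence signal
complex_to_signal <- function(re, R0) {
  if (R0 == 0) return(rep(SIGNAL_BASELINE, length(re)))
  SIGNAL_BASELINE + SIGNAL_SPAN * re / R0
}

#' Simulate a stopped-flow association trace
#'
#' Integrates the mass-action scheme R + E <-> RE from free species and
#' returns the fluorescence trace (baseline plus a span proportional to
#' the bound fraction `[RE]/R0`), with optional seeded Gaussian noise
#' expressed as a fraction of the total signal span. A warning is emitted
#' when the effector excess is below 5-fold, where the observed kinetics
#' visibly depart from the single-exponential pseudo-first-order form.
#'
#' @param rates [rate_constants()] of the effector.
#' @param mix [mix_config()]; uses `R0` and `E0`.
#' @param sigma Noise standard deviation as a fraction of the span.
#' @param seed Integer seed for the noise.
#' @return A trace (`data.frame` with `time`, `signal`).
#' @export
simulate_association <- function(rates, mix = mix_config(), sigma = 0,
                                 seed = NULL) {
  if (mix$R0 < 0 || mix$E0 < 0) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  if (mix$E0 > 0 && mix$E0 < 5 * mix$R0) {
    warning("effector excess E0 < 5*R0: pseudo-first-order assumption ",
            "violated; fitted kobs will be biased", call. = FALSE)
  }
  sim <- simulate_competition_scheme(rates, rates, mix, C0 = 0)
  add_noise(sim, sigma, seed)
}

# Two-ligand mutually exclusive scheme R+E<->RE (signal), R+C<->RC (dark).
# Association is the C0 = 0 special case.
simulate_competition_scheme <- function(ratesE, ratesC, mix, C0 = mix$C0) {
  R0 <- mix$R0; E0 <- mix$E0
  tau <- 1 / max(ratesE$kon * E0 + ratesE$koff, 1e-6)
  times <- trace_times(mix, tau)
  if (E0 == 0 && C0 == 0) {
    return(new_trace(times, rep(SIGNAL_BASELINE, length(times))))
  }
  derivs <- function(t, y, p) {
    R <- y[1L]; E <- y[2L]; C <- y[3L]; RE <- y[4L]; RC <- y[5L]
    vE <- p$konE * R * E - p$koffE * RE
    vC <- p$konC * R * C - p$koffC * RC
    list(c(-vE - vC, -vE, -vC, vE, vC))
  }
  out <- integrate_scheme(
    y0 = c(R = R0, E = E0, C = C0, RE = 0, RC = 0),
    times = c(0, times), derivs = derivs,
    parms = list(konE = ratesE$kon, koffE = ratesE$koff,
                 konC = ratesC$kon, koffC = ratesC$koff)
  )
  re <- out$RE[-1L]
  trace <- new_trace(times, complex_to_signal(re, R0))
  attr(trace, "species") <- out[-1L, ]
  trace
}

#' Simulate a competition association trace
#'
#' Effector (signal-generating) and competitor (dark) are premixed and
#' bind the labelled GTPase mutually exclusively: R + E <-> RE,
#' R + C <-> RC. The readout follows `[RE]` only. With `C0 = 0` this
#' reduces exactly to [simulate_association()].
#'
#' @param ratesE,ratesC [rate_constants()] of effector and competitor.
#' @param mix [mix_config()]; uses `R0`, `E0`, `C0`.
#' @inheritParams simulate_association
#' @return A trace.
#' @export
simulate_competition <- function(ratesE, ratesC, mix = mix_config(),
                                 sigma = 0, seed = NULL) {
  if (mix$R0 < 0 || mix$E0 < 0 || mix$C0 < 0) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  sim <- simulate_competition_scheme(ratesE, ratesC, mix)
  add_noise(sim, sigma, seed)
}

#' Simulate a displacement (dissociation) trace
#'
#' The labelled complex, pre-equilibrated at `R0`/`E0`, is mixed with an
#' excess of unlabelled GTPase `U0` that recaptures the effector as it
#' dissociates (RE -> R + E at `koff`; E + U -> UE at `kon [U]`), so the
#' falling signal decays at the dissociation rate in the limit of large
#' `U0`.
#'
#' @param rates [rate_constants()] of the effector.
#' @param mix [mix_config()]; uses `R0`, `E0`, `U0`.
#' @inheritParams simulate_association
#' @return A trace.
#' @export
simulate_displacement <- function(rates, mix = mix_config(), sigma = 0,
                                  seed = NULL) {
  R0 <- mix$R0; E0 <- mix$E0; U0 <- mix$U0
  if (R0 < 0 || E0 < 0 || U0 < 0) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  if (U0 < 10 * R0) {
    warning("displacer excess U0 < 10*R0: decay rate will overestimate ",
            "koff", call. = FALSE)
  }
  re0 <- association_closed_form(rates, mix, times = Inf, exact = TRUE)
  tau <- 1 / max(rates$koff, 1e-3)
  times <- trace_times(mix, tau)
  if (rates$koff == 0 || re0 == 0) {
    sim <- new_trace(times, complex_to_signal(rep(re0, length(times)), R0))
    return(add_noise(sim, sigma, seed))
  }
  derivs <- function(t, y, p) {
    R <- y[1L]; E <- y[2L]; RE <- y[3L]; U <- y[4L]; UE <- y[5L]
    vR <- p$kon * R * E - p$koff * RE
    vU <- p$kon * U * E - p$koff * UE
    list(c(-vR, -vR - vU, vR, -vU, vU))
  }
  out <- integrate_scheme(
    y0 = c(R = R0 - re0, E = E0 - re0, RE = re0, U = U0, UE = 0),
    times = c(0, times), derivs = derivs,
    parms = list(kon = rates$kon, koff = rates$koff)
  )
  sim <- new_trace(times, complex_to_signal(out$RE[-1L], R0))
  attr(sim, "species") <- out[-1L, ]
  add_noise(sim, sigma, seed)
}

#' Simulate a GAP-stimulated hydrolysis trace with effector protection
#'
#' Free labelled GTPase loses its signal through GAP-stimulated GTP
#' hydrolysis (pseudo-first-order rate `k_gap`), while GTPase bound to
#' the effector (R + E <-> RE) is protected. Under rapid binding
#' equilibrium the observed hydrolysis rate approaches
#' `k_gap * Kd / (Kd + E0)`, i.e. protection grows with effector
#' concentration.
#'
#' @param rates_effector [rate_constants()] of the protecting effector.
#' @param k_gap Pseudo-first-order hydrolysis rate of the free GTPase
#'   (s^-1, > 0).
#' @param mix [mix_config()]; uses `R0` and `E0`.
#' @inheritParams simulate_association
#' @return A trace whose signal is the unhydrolysed fraction.
#' @export
simulate_gap_reaction <- function(rates_effector, k_gap,
                                  mix = mix_config(), sigma = 0,
                                  seed = NULL) {
  stopifnot(k_gap > 0)
  R0 <- mix$R0; E0 <- mix$E0
  if (R0 < 0 || E0 < 0) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  expected <- k_gap * rates_effector$kd / (rates_effector$kd + E0)
  tau <- 1 / max(expected, k_gap * 1e-3)
  times <- trace_times(mix, tau)
  derivs <- function(t, y, p) {
    R <- y[1L]; E <- y[2L]; RE <- y[3L]
    v <- p$kon * R * E - p$koff * RE
    list(c(-v - p$kgap * R, -v, v))
  }
  out <- integrate_scheme(
    y0 = c(R = R0, E = E0, RE = 0), times = c(0, times),
    derivs = derivs,
    parms = list(kon = rates_effector$kon, koff = rates_effector$koff,
                 kgap = k_gap)
  )
  intact <- out$R[-1L] + out$RE[-1L]
  sim <- new_trace(times, complex_to_signal(intact, R0))
  add_noise(sim, sigma, seed)
}

#' Simulate a GEF-catalysed nucleotide exchange trace
#'
#' The labelled GDP-bound GTPase exchanges its fluorescent nucleotide at
#' the catalysed rate `k_gef` (excess unlabelled GDP), producing a
#' falling signal. An effector that binds only the triphosphate-loaded
#' form does not see the GDP-bound substrate and leaves the rate
#' unchanged; a hypothetical GDP-form binder (`effector_binds_gdp =
#' TRUE`) sequesters substrate and slows the observed exchange.
#'
#' @param k_gef Catalysed exchange rate (s^-1, > 0).
#' @param effector Optional [rate_constants()] of an effector present in
#'   the reaction.
#' @param effector_binds_gdp Does the effector bind the GDP-bound form?
#'   Default `FALSE` (GTP-form-specific effector).
#' @param mix [mix_config()]; uses `R0` and `E0`.
#' @inheritParams simulate_association
#' @return A trace.
#' @export
simulate_gef_reaction <- function(k_gef, effector = NULL,
                                  effector_binds_gdp = FALSE,
                                  mix = mix_config(), sigma = 0,
                                  seed = NULL) {
  stopifnot(k_gef > 0)
  R0 <- mix$R0; E0 <- if (is.null(effector)) 0 else mix$E0
  tau <- 1 / k_gef
  times <- trace_times(mix, tau)
  if (is.null(effector) || !effector_binds_gdp || E0 == 0) {
    # GDP-form-blind effector: plain single-exponential release
    signal <- complex_to_signal(R0 * exp(-k_gef * times), R0)
    return(add_noise(new_trace(times, signal), sigma, seed))
  }
  derivs <- function(t, y, p) {
    R <- y[1L]; E <- y[2L]; RE <- y[3L]
    v <- p$kon * R * E - p$koff * RE
    list(c(-v - p$kgef * R, -v, v))
  }
  out <- integrate_scheme(
    y0 = c(R = R0, E = E0, RE = 0), times = c(0, times),
    derivs = derivs,
    parms = list(kon = effector$kon, koff = effector$koff, kgef = k_gef)
  )
  intact <- out$R[-1L] + out$RE[-1L]
  sim <- new_trace(times, complex_to_signal(intact, R0))
  add_noise(sim, sigma, seed)
}
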