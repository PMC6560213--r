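#' @useDynLib qti, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Tissue parameter set
#'
#' Bundles the biophysical parameters of a voxel: longitudinal and
#' transverse relaxation times, through-plane velocity and a (possibly
#' complex) proton-density scale.
#'
#' @param T1 Longitudinal relaxation time, ms (> 0).
#' @param T2 Transverse relaxation time, ms (> 0).
#' @param v Through-plane velocity, mm/s (>= 0). Default 0 (stationary).
#' @param rho Proton-density scale, complex or positive real. Default 1.
#' @return An object of class `qti_tissue`.
#' @export
tissue_params <- function(T1, T2, v = 0, rho = 1 + 0i) {
  stopifnot(is.numeric(T1), length(T1) == 1L, T1 > 0)
  stopifnot(is.numeric(T2), length(T2) == 1L, T2 > 0)
  stopifnot(is.numeric(v), length(v) == 1L, v >= 0)
  stopifnot(length(rho) == 1L)
  structure(list(T1 = T1, T2 = T2, v = v, rho = as.complex(rho)),
            class = "qti_tissue")
}

#' Acquisition design
#'
#' The design variables of a transient-state acquisition: the flip-angle
#' and RF-phase trains, the repetition/echo times, slice thickness and
#' whether the train is preceded by an adiabatic inversion.
#'
#' @param flip_deg Numeric vector of N flip angles, degrees, each in
#'   \[0, 180\].
#' @param TR Repetition time, ms.
#' @param TE Echo time, ms; `0 < TE < TR`.
#' @param d Slice thickness, mm (> 0).
#' @param invert Apply an ideal 180 degree inversion before repetition 1?
#' @param phase_deg RF phases, degrees; scalar is recycled. Default 0 (no
#'   RF spoiling; the sequence relies on unbalanced gradients).
#' @param inversion_ms Duration booked for the inversion event when
#'   reporting scan time, ms. It does not enter the signal recursion.
#' @return An object of class `qti_design` with element `N = length(flip_deg)`.
#' @export
acquisition_design <- function(flip_deg, TR, TE, d = 2, invert = TRUE,
                               phase_deg = 0, inversion_ms = 20) {
  N <- length(flip_deg)
  if (N < 1L) stop("design needs at least one repetition")
  if (any(flip_deg < 0 | flip_deg > 180)) stop("flip angles must lie in [0, 180] degrees")
  if (!(TE > 0 && TE < TR)) stop("need 0 < TE < TR")
  if (d <= 0) stop("slice thickness must be positive")
  phase_deg <- rep_len(phase_deg, N)
  structure(list(flip_deg = as.numeric(flip_deg), phase_deg = phase_deg,
                 TR = TR, TE = TE, d = d, invert = isTRUE(invert),
                 inversion_ms = inversion_ms, N = N),
            class = "qti_design")
}

#' @method print qti_design
#' @export
print.qti_design <- function(x, ...) {
  cat(sprintf("qti acquisition design: N = %d, TR/TE = %g/%g ms, d = %g mm, %s\n",
              x$N, x$TR, x$TE, x$d,
              if (x$invert) "inversion-prepared" else "no inversion"))
  cat(sprintf("  flip angles %.3g..%.3g deg, duration %.4g s\n",
              x$flip_deg[1], x$flip_deg[x$N], design_duration(x)))
  invisible(x)
}

#' Total acquisition duration of a design
#'
#' @param design A [acquisition_design()].
#' @return Duration in seconds: inversion event (if any) plus `N * TR`.
#' @export
design_duration <- function(design) {
  ((if (design$invert) design$inversion_ms else 0) + design$N * design$TR) / 1000
}

#' Equilibrium EPG configuration state
#'
#' The configuration state matrix holds complex populations over dephasing
#' orders k = 0..K-1: `F` (dephasing transverse), `Fstar` (rephasing
#' transverse) and `Z` (longitudinal). At thermal equilibrium `Z[1] = 1`
#' (order k = 0) and everything else vanishes.
#'
#' @param K Maximum retained dephasing order (>= 2).
#' @return An object of class `qti_epg` with complex vectors `F`, `Fstar`,
#'   `Z` of length `K`.
#' @export
epg_state <- function(K) {
  stopifnot(K >= 2)
  s <- list(F = complex(K), Fstar = complex(K), Z = complex(K), K = as.integer(K))
  s$Z[1] <- 1 + 0i
  structure(s, class = "qti_epg")
}

#' RF pulse operator
#'
#' Mixes `F`, `Fstar` and `Z` within each order k by the standard 3x3 EPG
#' rotation; there is no mixing across orders, so a lossless rotation
#' conserves the magnetization energy of every order.
#'
#' @param state A [epg_state()].
#' @param flip Flip angle, degrees, in \[0, 180\].
#' @param phase RF phase, degrees.
#' @return The rotated state.
#' @export
epg_rf <- function(state, flip, phase = 0) {
  if (!is.finite(flip) || flip < 0 || flip > 180) stop("flip must lie in [0, 180] degrees")
  if (!is.finite(phase)) stop("phase must be finite")
  a <- flip * pi / 180; p <- phase * pi / 180
  c2 <- cos(a / 2)^2; s2 <- sin(a / 2)^2; sa <- sin(a); ca <- cos(a)
  eip <- exp(1i * p); ei2p <- exp(2i * p)
  F <- state$F; Fs <- state$Fstar; Z <- state$Z
  state$F     <- c2 * F + ei2p * s2 * Fs - 1i * eip * sa * Z
  state$Fstar <- Conj(ei2p) * s2 * F + c2 * Fs + 1i * Conj(eip) * sa * Z
  state$Z     <- -0.5i * Conj(eip) * sa * F + 0.5i * eip * sa * Fs + ca * Z
  state
}

#' Relaxation operator
#'
#' Scales transverse states by `exp(-dt/T2)` and longitudinal states by
#' `exp(-dt/T1)`, with `Z` at order 0 recovering toward equilibrium.
#'
#' @param state A [epg_state()].
#' @param T1,T2 Relaxation times, ms.
#' @param dt Interval, ms (>= 0).
#' @return The relaxed state.
#' @export
epg_relax <- function(state, T1, T2, dt) {
  if (!is.finite(dt) || dt < 0) stop("dt must be >= 0")
  e2 <- exp(-dt / T2); e1 <- exp(-dt / T1)
  state$F <- state$F * e2
  state$Fstar <- state$Fstar * e2
  state$Z <- state$Z * e1
  state$Z[1] <- state$Z[1] + (1 - e1)
  state
}

#' Gradient dephasing (shift) operator
#'
#' One unit of unbalanced gradient area per repetition advances every
#' transverse population by one order: dephasing states move up
#' (`F_k -> F_{k+1}`), rephasing states move down toward and across k = 0,
#' with conjugation at the crossing. Longitudinal states are untouched.
#' Population reaching the retained cap K is truncated; a warning is
#' emitted if its magnitude exceeds `tol`.
#'
#' @param state A [epg_state()].
#' @param tol Truncation-population warning threshold.
#' @return The shifted state.
#' @export
epg_shift <- function(state, tol = 1e-8) {
  K <- state$K
  if (Mod(state$F[K]) > tol)
    warning(sprintf("EPG order cap K = %d truncates population %.3g; increase K",
                    K, Mod(state$F[K])))
  state$F <- c(Conj(state$Fstar[2]), state$F[-K])
  state$Fstar <- c(state$Fstar[-1], 0 + 0i)
  state
}

#' Plug-flow washout fraction
#'
#' Fraction of slice spins retained after an interval `dt` under plug flow
#' perpendicular to the slice: spins leave a slice of thickness `d` at
#' velocity `v` at a linear rate, so the retained fraction is
#' `max(0, 1 - dt*v/d)`.
#'
#' @param dt Interval, ms.
#' @param v Through-plane speed, mm/s.
#' @param d Slice thickness, mm (> 0).
#' @return Retained fraction in \[0, 1\]; 1 iff `v = 0` or `dt = 0`.
#' @export
washout_fraction <- function(dt, v, d) {
  if (d <= 0) stop("slice thickness must be positive")
  if (dt < 0 || v < 0) stop("dt and v must be >= 0")
  max(0, 1 - dt * v / d / 1000)  # dt ms * v mm/s -> mm when /1000
}

#' Flow washout operator
#'
#' Replaces a fraction `1 - h` of the slice magnetization by fresh,
#' fully-polarized spins: every configuration state is scaled by `h` and
#' `1 - h` of equilibrium longitudinal magnetization is added to `Z_0`.
#'
#' @param state A [epg_state()].
#' @param h Retained fraction in \[0, 1\] (see [washout_fraction()]).
#' @return The updated state.
#' @export
epg_flow <- function(state, h) {
  if (!is.finite(h) || h < 0 || h > 1) stop("h must lie in [0, 1]")
  state$F <- state$F * h
  state$Fstar <- state$Fstar * h
  state$Z <- state$Z * h
  state$Z[1] <- state$Z[1] + (1 - h)
  state
}

#' Simulate a transient-state signal evolution
#'
#' Runs the EPG recursion over all repetitions of a design and records the
#' complex signal `rho * F_0` at each echo. Per repetition the events are:
#' RF pulse, relaxation to the echo (TE), signal readout, relaxation over
#' the remainder of TR, one unit of gradient dephasing, and flow washout
#' with the constant per-repetition retained fraction
#' `washout_fraction(TR, v, d)`. An inversion-prepared design starts from
#' an ideal 180 degree pulse.
#'
#' @param design A [acquisition_design()].
#' @param params A [tissue_params()].
#' @param K Retained order cap; default `N + 1` is lossless for one shift
#'   per repetition.
#' @param engine `"cpp"` (fast compiled recursion, default) or
#'   `"reference"` (composition of the exported R operators).
#' @return A list of class `qti_signal` with complex vector `s` (length N)
#'   and echo timestamps `t_echo` (ms, counted from the first excitation;
#'   the inversion event adds `inversion_ms`).
#' @export
simulate_signal <- function(design, params, K = design$N + 1L,
                            engine = c("cpp", "reference")) {
  engine <- match.arg(engine)
  N <- design$N
  flip <- design$flip_deg * pi / 180
  phase <- design$phase_deg * pi / 180
  if (engine == "cpp") {
    s <- epg_signal_cpp(flip, phase, design$TR, design$TE, params$T1,
                        params$T2, params$v, design$d, design$invert,
                        as.integer(K))
  } else {
    h <- washout_fraction(design$TR, params$v, design$d)
    st <- epg_state(K)
    if (design$invert) st <- epg_rf(st, 180, 0)
    s <- complex(N)
    for (t in seq_len(N)) {
      st <- epg_rf(st, design$flip_deg[t], design$phase_deg[t])
      st <- epg_relax(st, params$T1, params$T2, design$TE)
      s[t] <- st$F[1]
      st <- epg_relax(st, params$T1, params$T2, design$TR - design$TE)
      st <- epg_shift(st)
      st <- epg_flow(st, h)
    }
  }
  t0 <- if (design$invert) design$inversion_ms else 0
  structure(list(s = params$rho * s,
                 t_echo = t0 + (seq_len(N) - 1) * design$TR + design$TE),
            class = "qti_signal")
}

# Batch signals for rows of cbind(T1, T2, v); returns complex N x n matrix
# of rho = 1 signals. Internal fast path shared by design, dictionary and
# subspace code.
signal_batch <- function(design, params_mat, K = design$N + 1L) {
  stopifnot(ncol(params_mat) == 3)
  epg_signal_batch_cpp(design$flip_deg * pi / 180, design$phase_deg * pi / 180,
                       design$TR, design$TE, params_mat, design$d,
                       design$invert, as.integer(K))
}
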