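# Shunting-inhibition model of binocular pupillary summation.
#
# The steady-state binocular constriction amplitude B (mm) is a sub-additive
# combination of the monocular amplitude M (mm),
#
#     B = 2 M / (1 + k M),
#
# where k (mm^-1) is the strength of the forward interocular shunting
# inhibition. Under first-order dynamics the time constant shortens by the
# same divisor, tau_b = tau_m / (1 + k M). A third-order variant (first-order
# low-pass cascaded with a damped second-order oscillator, damping D,
# resonant frequency f) relates tau_b to tau_m through the real root of a
# cubic characteristic polynomial in Laplace space.
#
# Internal units: seconds, Hz, mm. Millisecond inputs are accepted by the
# *_ms wrappers at the interface.

#' Binocular constriction amplitude predicted from monocular amplitude
#'
#' Steady-state shunting summation: \code{B = 2*M/(1 + k*M)}.
#'
#' @param M monocular steady-state constriction amplitude (mm), positive
#' @param k shunting strength (1/mm), non-negative
#' @return predicted binocular amplitude B (mm)
#' @examples
#' binocular_from_monocular(3.6, 0.22)
#' @export
binocular_from_monocular <- function(M, k) {
  stopifnot(is.numeric(M), is.numeric(k), M > 0)
  if (any(k < 0)) stop("shunting strength k must be >= 0")
  if (any(1 + k * M <= 0)) stop("1 + k*M must be positive")
  2 * M / (1 + k * M)
}

#' Shunting strength from steady-state amplitudes
#'
#' Inverts \code{B = 2*M/(1 + k*M)}: \code{k = (2*M - B)/(B*M)}.
#'
#' @param M monocular constriction amplitude (mm)
#' @param B binocular constriction amplitude (mm), must satisfy 0 < B <= 2M
#' @return k (1/mm)
#' @examples
#' k_from_amplitudes(3.6, 4.0)  # ~0.22
#' @export
k_from_amplitudes <- function(M, B) {
  stopifnot(is.numeric(M), is.numeric(B), M > 0, B > 0)
  if (any(B > 2 * M)) {
    stop("B > 2M: super-additive summation violates the shunting model")
  }
  (2 * M - B) / (B * M)
}

#' First-order shunting strength from time constants
#'
#' Under first-order dynamics tau_b = tau_m/(1 + k*M), so
#' \code{k = (tau_m/tau_b - 1)/M}. Units of the two time constants cancel;
#' they only need to agree.
#'
#' @param tau_m monocular time constant
#' @param tau_b binocular time constant (same units as \code{tau_m})
#' @param M monocular constriction amplitude (mm)
#' @return k (1/mm); negative with a warning if tau_b > tau_m
#' @examples
#' k_from_time_constants(756, 588, 3.6)  # dilation, ~0.079
#' @export
k_from_time_constants <- function(tau_m, tau_b, M) {
  stopifnot(tau_m > 0, tau_b > 0, M > 0)
  k <- (tau_m / tau_b - 1) / M
  if (any(k < 0)) {
    warning("tau_b > tau_m: binocular response slower than monocular, ",
            "negative k violates the shunting model")
  }
  k
}

#' Coefficients of the third-order characteristic cubic
#'
#' Returns the coefficients (a3, a2, a1, a0) of
#' \code{a3 s^3 + a2 s^2 + a1 s + a0 = 0}, the denominator of the monocular
#' transfer function obtained by running the binocular third-order model
#' backwards through the shunting stage:
#' a3 = 2 tau_b / w^2; a2 = 4 D tau_b / w + 2 / w^2;
#' a1 = 2 tau_b + 4 D / w; a0 = 2 - k B, with w = 2 pi f.
#'
#' @param tau_b binocular primary time constant (s)
#' @param D damping coefficient of the oscillator stage (unitless)
#' @param f resonant frequency (Hz), positive
#' @param k shunting strength (1/mm)
#' @param B binocular constriction amplitude (mm)
#' @return named numeric vector c(a3, a2, a1, a0)
#' @export
third_order_coeffs <- function(tau_b, D, f, k, B) {
  stopifnot(tau_b > 0)
  if (f <= 0) stop("resonant frequency f must be positive")
  w <- 2 * pi * f
  c(a3 = 2 * tau_b / w^2,
    a2 = 4 * D * tau_b / w + 2 / w^2,
    a1 = 2 * tau_b + 4 * D / w,
    a0 = 2 - k * B)
}

#' Monocular time constant from the third-order model
#'
#' Finds the negative real root s* of the characteristic cubic and returns
#' \code{tau_m = -1/s*} (seconds). With k = 0 this reproduces tau_b.
#'
#' @inheritParams third_order_coeffs
#' @return tau_m (s)
#' @export
tau_m_from_cubic <- function(tau_b, D, f, k, B) {
  a <- third_order_coeffs(tau_b, D, f, k, B)
  # polyroot takes coefficients in increasing order
  r <- polyroot(c(a[["a0"]], a[["a1"]], a[["a2"]], a[["a3"]]))
  real <- r[abs(Im(r)) < 1e-8 * pmax(1, abs(Re(r)))]
  real <- Re(real)
  neg <- real[real < 0]
  if (length(neg) != 1L) {
    stop("expected exactly one negative real root, found ", length(neg),
         " (roots: ", paste(signif(real, 6), collapse = ", "), ")")
  }
  -1 / neg
}

#' Solve for the third-order shunting strength
#'
#' Finds k in \code{[0, k_max]} such that the third-order model maps the
#' binocular time constant tau_b to a given monocular target tau_m, by
#' root-finding on \code{tau_m_from_cubic}.
#'
#' @param tau_b binocular primary time constant (s)
#' @param tau_m_target monocular time constant to match (s), >= tau_b
#' @param D damping coefficient
#' @param f resonant frequency (Hz)
#' @param B binocular constriction amplitude (mm)
#' @param k_max upper end of the search bracket (default 1)
#' @return k (1/mm)
#' @examples
#' solve_k_third_order(0.156, 0.176, 0.7, 1.3, 4.0)  # ~0.029
#' @export
solve_k_third_order <- function(tau_b, tau_m_target, D, f, B, k_max = 1) {
  stopifnot(tau_b > 0, tau_m_target > 0)
  if (tau_m_target < tau_b) {
    stop("tau_m_target < tau_b: shunting can only lengthen the monocular ",
         "time constant relative to binocular")
  }
  # beyond k = 2/B the constant coefficient changes sign and the system is
  # unstable (positive real root); keep the bracket strictly below it
  k_max <- min(k_max, 2 / B * (1 - 1e-9))
  g <- function(k) tau_m_from_cubic(tau_b, D, f, k, B) - tau_m_target
  lo <- g(0); hi <- g(k_max)
  if (sign(lo) == sign(hi)) {
    stop("no sign change in k bracket [0, ", k_max, "]")
  }
  uniroot(g, c(0, k_max), tol = 1e-12)$root
}

#' Constriction amplitude from dark and steady-state diameters
#'
#' @param dark_diameter fully dilated (dark) pupil diameter (mm)
#' @param steady_diameter steady-state diameter in the light (mm)
#' @return amplitude dark - steady (mm)
#' @export
constriction_amplitude <- function(dark_diameter, steady_diameter) {
  stopifnot(dark_diameter > 0, steady_diameter > 0)
  if (any(steady_diameter >= dark_diameter)) {
    stop("steady-state diameter must be smaller than the dark diameter")
  }
  dark_diameter - steady_diameter
}

#' One-shot shunting-model report
#'
#' Convenience wrapper computing the steady-state k from amplitudes, the
#' first-order k from time constants, and the third-order k from
#' root-finding, in one list. Time constants are in milliseconds here (the
#' scale on which they are usually tabulated).
#'
#' @param M,B monocular and binocular constriction amplitudes (mm)
#' @param tau_m_ms,tau_b_ms monocular and binocular time constants (ms);
#'   optional
#' @param D,f third-order damping and resonant frequency; optional
#' @return list with components \code{k_steady_state}, \code{k_first_order},
#'   \code{k_third_order} (NA where inputs are missing)
#' @export
shunting_report <- function(M, B, tau_m_ms = NA, tau_b_ms = NA,
                            D = 0.7, f = 1.3) {
  out <- list(k_steady_state = k_from_amplitudes(M, B),
              k_first_order = NA_real_, k_third_order = NA_real_)
  if (is.finite(tau_m_ms) && is.finite(tau_b_ms)) {
    out$k_first_order <- k_from_time_constants(tau_m_ms, tau_b_ms, M)
    out$k_third_order <- solve_k_third_order(tau_b_ms / 1000,
                                             tau_m_ms / 1000, D, f, B)
  }
  out
}
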