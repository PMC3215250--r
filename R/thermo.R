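## physical constants (SI)
.R_GAS <- 8.314462618   # J/(mol K)
.K_B <- 1.380649e-23    # J/K
.H_PLANCK <- 6.62607015e-34  # J s

#' Free energy difference between exchanging states
#'
#' \eqn{\Delta G = -RT \ln K} with \eqn{K = p_b/p_a} (minor over major),
#' so the minor state lies uphill (\eqn{\Delta G > 0}) whenever
#' \eqn{p_b < 0.5}.
#'
#' @param pb population of the minor state, strictly between 0 and 1.
#' @param temperature_k temperature, K.
#' @return Delta-G in J/mol.
#' @export
delta_g <- function(pb, temperature_k) {
  if (any(pb <= 0 | pb >= 1)) stop("pb must lie strictly in (0, 1)")
  -.R_GAS * temperature_k * log(pb / (1 - pb))
}

#' Minor population from a free energy difference
#'
#' Inverse of \code{\link{delta_g}}: \eqn{p_b = 1/(1 + e^{\Delta G/RT})}.
#'
#' @param dg free energy difference, J/mol.
#' @inheritParams delta_g
#' @return the minor-state population.
#' @export
pb_from_delta_g <- function(dg, temperature_k)
  1 / (1 + exp(dg / (.R_GAS * temperature_k)))

#' Population from a known chemical shift difference
#'
#' In the fast limit only \eqn{\Phi = p_a p_b \delta\omega^2} is
#' observable.  When \eqn{\delta\omega} is known independently (e.g. from
#' a titration end point), the populations follow from the smaller root
#' of \eqn{p(1-p) = \Phi/\delta\omega^2}; no physical solution exists
#' when that quotient exceeds 1/4.
#'
#' @param phi fast-exchange amplitude, (rad/s)^2.
#' @param dw_known chemical shift difference, rad/s.
#' @return the minor population p_b.
#' @export
pb_from_dw <- function(phi, dw_known) {
  stopifnot(phi > 0, dw_known > 0)
  q <- phi / dw_known^2
  if (q > 0.25)
    stop("phi/dw^2 = ", signif(q, 4),
         " > 1/4: no physical population solves p(1-p) = phi/dw^2")
  (1 - sqrt(1 - 4 * q)) / 2
}

#' Forward and backward rates from kex and populations
#'
#' Detailed balance splits the total exchange rate:
#' \eqn{k_{ab} = p_b k_{ex}}, \eqn{k_{ba} = p_a k_{ex}}, so that
#' \eqn{k_{ab} + k_{ba} = k_{ex}} and \eqn{k_{ab}/k_{ba} = p_b/p_a}.
#'
#' @param kex total exchange rate, 1/s.
#' @param pb minor population.
#' @return named list with \code{k_ab} (A to B, forward) and \code{k_ba}.
#' @export
rates_from_kex <- function(kex, pb) {
  stopifnot(kex > 0, pb > 0, pb < 1)
  list(k_ab = pb * kex, k_ba = (1 - pb) * kex)
}

#' Activation free energy from the Eyring equation
#'
#' \eqn{\Delta G^\ddagger = -RT \ln(k h / k_B T)} with transmission
#' coefficient 1.
#'
#' @param rate rate constant, 1/s.
#' @inheritParams delta_g
#' @return activation free energy, J/mol.
#' @export
eyring_dg_activation <- function(rate, temperature_k) {
  stopifnot(all(rate > 0))
  -.R_GAS * temperature_k *
    log(rate * .H_PLANCK / (.K_B * temperature_k))
}

#' Two-state energy landscape
#'
#' Tabulates the ground-state free energy difference and the forward /
#' backward activation barriers; by construction
#' \eqn{\Delta G^\ddagger_{fwd} - \Delta G^\ddagger_{bwd} = \Delta G}.
#'
#' @inheritParams rates_from_kex
#' @inheritParams delta_g
#' @return data.frame with \code{dG}, \code{dG_act_fwd},
#'   \code{dG_act_bwd} (J/mol).
#' @export
energy_landscape <- function(kex, pb, temperature_k) {
  k <- rates_from_kex(kex, pb)
  data.frame(
    dG = delta_g(pb, temperature_k),
    dG_act_fwd = eyring_dg_activation(k$k_ab, temperature_k),
    dG_act_bwd = eyring_dg_activation(k$k_ba, temperature_k)
  )
}

#' Van't Hoff analysis of a temperature series
#'
#' Extracts enthalpy and entropy changes from the temperature dependence
#' of the equilibrium constant \eqn{K = p_b/p_a}.
#'
#' Linear mode regresses \eqn{\ln K} on \eqn{1/T}: slope
#' \eqn{= -\Delta H/R}, intercept \eqn{= \Delta S/R}.  Non-linear mode
#' fits the heat-capacity extension
#' \deqn{\Delta H(T) = \Delta H_0 + \Delta C_p (T - T_0), \quad
#'   \Delta S(T) = \Delta S_0 + \Delta C_p \ln(T/T_0)}
#' with \eqn{\ln K(T) = -\Delta H(T)/RT + \Delta S(T)/R}, by
#' Levenberg-Marquardt least squares on \eqn{\ln K}.
#'
#' @param temperature_k temperatures, K (distinct; >= 2 for linear, >= 4
#'   for non-linear).
#' @param pb minor populations at each temperature; alternatively supply
#'   \code{K} directly.
#' @param K equilibrium constants \eqn{p_b/p_a}; overrides \code{pb}.
#' @param mode \code{"linear"} or \code{"nonlinear"}.
#' @param t0 reference temperature for the non-linear mode, K.
#' @param eval_t temperature at which \code{dG} is reported, K.
#' @return an object of class \code{"vant_hoff"}: list with \code{dH}
#'   (J/mol), \code{dS} (J/(mol K)), \code{dCp} (J/(mol K), non-linear
#'   only, else \code{NA}), \code{dG} at \code{eval_t}, the mode and the
#'   data.
#' @export
vant_hoff <- function(temperature_k, pb = NULL, K = NULL,
                      mode = c("linear", "nonlinear"),
                      t0 = 298.15, eval_t = t0) {
  mode <- match.arg(mode)
  if (is.null(K)) {
    stopifnot(!is.null(pb), all(pb > 0 & pb < 1))
    K <- pb / (1 - pb)
  }
  stopifnot(length(temperature_k) == length(K),
            all(temperature_k > 0), all(K > 0))
  if (anyDuplicated(temperature_k))
    stop("temperatures must be distinct")
  need <- if (mode == "linear") 2 else 4
  if (length(temperature_k) < need)
    stop(mode, " van't Hoff needs at least ", need, " temperatures")
  lnK <- log(K)
  if (mode == "linear") {
    fit <- stats::lm(lnK ~ I(1 / temperature_k))
    dH <- -unname(stats::coef(fit)[2]) * .R_GAS
    dS <- unname(stats::coef(fit)[1]) * .R_GAS
    dCp <- NA_real_
  } else {
    resid_fn <- function(th) {
      dH0 <- th[1]; dS0 <- th[2]; dCp <- th[3]
      dH_t <- dH0 + dCp * (temperature_k - t0)
      dS_t <- dS0 + dCp * log(temperature_k / t0)
      (-dH_t / (.R_GAS * temperature_k) + dS_t / .R_GAS) - lnK
    }
    lin <- stats::lm(lnK ~ I(1 / temperature_k))
    start <- c(-unname(stats::coef(lin)[2]) * .R_GAS,
               unname(stats::coef(lin)[1]) * .R_GAS, 0)
    fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                              control = .lm_control())
    dH <- fit$par[1]; dS <- fit$par[2]; dCp <- fit$par[3]
  }
  dH_eval <- if (mode == "linear") dH else dH + dCp * (eval_t - t0)
  dS_eval <- if (mode == "linear") dS else dS + dCp * log(eval_t / t0)
  structure(
    list(dH = dH, dS = dS, dCp = dCp, t0 = t0,
         dG = dH_eval - eval_t * dS_eval, eval_t = eval_t, mode = mode,
         data = data.frame(temperature_k = temperature_k, K = K)),
    class = "vant_hoff"
  )
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat("Van't Hoff analysis (", x$mode, " model, ",
      nrow(x$data), " temperatures)\n", sep = "")
  cat(sprintf("  dH  = %.4g kJ/mol\n", x$dH / 1000))
  cat(sprintf("  dS  = %.4g J/(mol K)\n", x$dS))
  if (!is.na(x$dCp))
    cat(sprintf("  dCp = %.4g J/(mol K) (reference T0 = %g K)\n",
                x$dCp, x$t0))
  cat(sprintf("  dG(%g K) = %.4g kJ/mol\n", x$eval_t, x$dG / 1000))
  invisible(x)
}
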