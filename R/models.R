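#' Closed-form dispersion model equations
#'
#' Effective transverse relaxation rate R2eff as a function of the CPMG
#' refocusing frequency for the three supported two-site exchange models:
#'
#' \describe{
#'   \item{model 1}{no exchange, \eqn{R_2^{eff} = R_2^0}.}
#'   \item{model 2}{fast-limit exchange (\eqn{k_{ex} \gg \delta\omega}),
#'     \eqn{R_2^{eff} = R_2^0 + \Phi/k_{ex}\,[1 - (4\nu/k_{ex})
#'     \tanh(k_{ex}/4\nu)]} with \eqn{\Phi = p_a p_b \delta\omega^2}.}
#'   \item{model 3}{slow-limit exchange, the Carver-Richards equation
#'     (see \code{\link{r2eff_model3}}).}
#' }
#'
#' All rates are in 1/s, frequencies in Hz and chemical shift differences
#' in rad/s.
#'
#' @param nu_cpmg CPMG pulse frequency in Hz (vectorised).
#' @param r20 exchange-free transverse relaxation rate, 1/s.
#' @return R2eff in 1/s, same length as \code{nu_cpmg}.
#' @seealso \code{\link{r2eff_model2}}, \code{\link{r2eff_model3}},
#'   \code{\link{rex_contribution}}
#' @export
r2eff_model1 <- function(nu_cpmg, r20) {
  stopifnot(is.numeric(r20), length(r20) == 1L, r20 > 0)
  rep_len(r20, length(nu_cpmg))
}

#' Fast-limit (Luz-Meiboom type) exchange model
#'
#' @inheritParams r2eff_model1
#' @param kex total exchange rate constant \eqn{k_{ex} = k_{ab} + k_{ba}}, 1/s.
#' @param phi composite amplitude \eqn{\Phi = p_a p_b \delta\omega^2},
#'   (rad/s)^2.  Only \eqn{\Phi}, not \eqn{p_b} and \eqn{\delta\omega}
#'   individually, is observable in the fast limit.
#' @return R2eff in 1/s.
#' @export
r2eff_model2 <- function(nu_cpmg, r20, kex, phi) {
  stopifnot(kex > 0, phi >= 0)
  if (any(nu_cpmg <= 0)) stop("nu_cpmg must be > 0 for model 2")
  r20 + phi / kex * (1 - 4 * nu_cpmg / kex * tanh(kex / (4 * nu_cpmg)))
}

#' Slow-limit exchange: the Carver-Richards equation
#'
#' \deqn{R_2^{eff} = R_2^0 + k_{ex}/2 - \nu\,\mathrm{cosh}^{-1}[D_+
#'   \cosh\eta_+ - D_- \cos\eta_-]}
#' with
#' \deqn{D_\pm = \tfrac12[\pm 1 + (\Psi + 2\delta\omega^2)/
#'   \sqrt{\Psi^2+\xi^2}]}
#' \deqn{\eta_\pm = \frac{1}{2\sqrt{2}\,\nu}\,[\pm\Psi +
#'   \sqrt{\Psi^2+\xi^2}]^{1/2}}
#' \deqn{\Psi = k_{ex}^2 - \delta\omega^2, \qquad
#'   \xi = -2\delta\omega\,(p_a k_{ex} - p_b k_{ex})}
#'
#' The argument of the inverse hyperbolic cosine is clamped at 1 to absorb
#' floating-point undershoot near the no-exchange limit (\eqn{\delta\omega
#' \to 0} or \eqn{p_b \to 0}), where the expression collapses analytically
#' to \eqn{R_2^0}.
#'
#' @inheritParams r2eff_model2
#' @param pb population of the minor state, 0 < pb < 0.5.
#' @param dw chemical shift difference between the exchanging states,
#'   rad/s (at the field the profile was recorded at).
#' @return R2eff in 1/s.
#' @export
r2eff_model3 <- function(nu_cpmg, r20, kex, pb, dw) {
  stopifnot(kex > 0, pb >= 0, pb < 1, dw >= 0)
  if (any(nu_cpmg <= 0)) stop("nu_cpmg must be > 0 for model 3")
  pa <- 1 - pb
  psi <- kex^2 - dw^2
  xi <- -2 * dw * (pa * kex - pb * kex)
  root <- sqrt(psi^2 + xi^2)
  d_plus <- 0.5 * (1 + (psi + 2 * dw^2) / root)
  d_minus <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  eta_plus <- sqrt(pmax(psi + root, 0)) / (2 * sqrt(2) * nu_cpmg)
  eta_minus <- sqrt(pmax(-psi + root, 0)) / (2 * sqrt(2) * nu_cpmg)
  arg <- d_plus * cosh(eta_plus) - d_minus * cos(eta_minus)
  clamped <- arg < 1
  if (any(clamped)) arg[clamped] <- 1
  r20 + kex / 2 - nu_cpmg * acosh(arg)
}

#' Evaluate a dispersion model from a named parameter list
#'
#' Dispatcher used by the fitting and simulation layers.  \code{pars} holds
#' \code{r20} and, depending on the model, \code{kex} plus \code{phi}
#' (model 2) or \code{pb} and \code{dw} (model 3).
#'
#' @param nu_cpmg CPMG frequencies, Hz.
#' @param model integer model id in \code{1:3}.
#' @param pars named list of parameters.
#' @return R2eff values in 1/s.
#' @export
r2eff_curve <- function(nu_cpmg, model, pars) {
  switch(as.character(model),
    "1" = r2eff_model1(nu_cpmg, pars$r20),
    "2" = r2eff_model2(nu_cpmg, pars$r20, pars$kex, pars$phi),
    "3" = r2eff_model3(nu_cpmg, pars$r20, pars$kex, pars$pb, pars$dw),
    stop("unknown model id: ", model)
  )
}

#' Exchange contribution to transverse relaxation
#'
#' For fast exchange \eqn{R_{ex} = \Phi/k_{ex}}; for slow exchange
#' \eqn{R_{ex} = p_a p_b k_{ex} / (1 + (k_{ex}/\delta\omega)^2)}.
#' Model 1 carries no exchange, \eqn{R_{ex} = 0}.
#'
#' @inheritParams r2eff_curve
#' @return \eqn{R_{ex}} in 1/s.
#' @export
rex_contribution <- function(model, pars) {
  switch(as.character(model),
    "1" = 0,
    "2" = pars$phi / pars$kex,
    "3" = {
      pa <- 1 - pars$pb
      pa * pars$pb * pars$kex / (1 + (pars$kex / pars$dw)^2)
    },
    stop("unknown model id: ", model)
  )
}

#' Static-field context
#'
#' Records the spectrometer 1H frequency a data set was acquired at, the
#' reference frequency chemical shift differences are quoted at, and the
#' sample temperature.  \eqn{\delta\omega} scales linearly with field:
#' \eqn{\delta\omega_{field} = (f / f_{ref})\,\delta\omega_{ref}}.
#'
#' @param frequency_mhz spectrometer 1H frequency, MHz.
#' @param ref_frequency_mhz reference frequency for delta-omega values,
#'   MHz; defaults to \code{frequency_mhz}.
#' @param temperature_k sample temperature, K.
#' @return an object of class \code{"field_context"}.
#' @export
field_context <- function(frequency_mhz, ref_frequency_mhz = frequency_mhz,
                          temperature_k = 298) {
  stopifnot(frequency_mhz > 0, ref_frequency_mhz > 0, temperature_k > 0)
  structure(
    list(frequency_mhz = frequency_mhz,
         ref_frequency_mhz = ref_frequency_mhz,
         temperature_k = temperature_k),
    class = "field_context"
  )
}

#' Scale a chemical shift difference to another static field
#'
#' @param dw_ref delta-omega in rad/s at the reference field.
#' @param field a \code{\link{field_context}}.
#' @return delta-omega in rad/s at \code{field$frequency_mhz}.
#' @export
scale_dw <- function(dw_ref, field) {
  dw_ref * field$frequency_mhz / field$ref_frequency_mhz
}
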