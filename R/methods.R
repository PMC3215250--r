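#' @export
print.cpmg_fit <- function(x, ...) {
  lab <- c("no exchange", "fast-limit exchange",
           "slow-limit exchange (Carver-Richards)")[x$model]
  cat("CPMG dispersion fit: model ", x$model, " (", lab, ")\n", sep = "")
  cat("  residue ", x$profile$residue, ", ", x$n, " points",
      if (length(x$pars$r20) > 1)
        paste0(" at ", length(x$pars$r20), " fields"), "\n", sep = "")
  print(coef(x))
  cat(sprintf("  chi2 = %.6g, AICc = %.6g, converged: %s\n",
              x$chi2, x$aicc, x$converged))
  invisible(x)
}

#' @export
coef.cpmg_fit <- function(object, ...) {
  p <- object$pars
  if (is.null(p)) return(numeric(0))
  out <- stats::setNames(as.numeric(p$r20),
                         paste0("r20_", names(p$r20)))
  if (object$model == 2) out <- c(out, kex = p$kex, phi = p$phi)
  if (object$model == 3)
    out <- c(out, kex = p$kex, pb = p$pb, dw = p$dw)
  out
}

#' Predicted dispersion curve
#'
#' @param object a \code{\link{cpmg_fit}}.
#' @param nu_cpmg CPMG frequencies to evaluate at; defaults to the
#'   fitted points.
#' @param field_mhz field to evaluate at (one of the fitted fields);
#'   defaults to the first.
#' @param ... unused.
#' @return predicted R2eff values, 1/s.
#' @export
predict.cpmg_fit <- function(object, nu_cpmg = NULL, field_mhz = NULL,
                             ...) {
  keys <- names(object$profile$fields)
  key <- if (is.null(field_mhz)) keys[1] else as.character(field_mhz)
  stopifnot(key %in% keys)
  if (is.null(nu_cpmg)) {
    d <- object$profile$data
    nu_cpmg <- d$nu_cpmg[d$field_mhz == as.numeric(key)]
  }
  p <- .field_pars(object$pars, object$model,
                   object$profile$fields[[key]])
  r2eff_curve(nu_cpmg, object$model, p)
}

#' @export
residuals.cpmg_fit <- function(object, type = c("response", "pearson"),
                               ...) {
  type <- match.arg(type)
  d <- object$profile$data
  res <- numeric(nrow(d))
  for (f in names(object$profile$fields)) {
    idx <- d$field_mhz == as.numeric(f)
    calc <- predict(object, d$nu_cpmg[idx], as.numeric(f))
    res[idx] <- d$r2eff[idx] - calc
    if (type == "pearson")
      res[idx] <- res[idx] / object$profile$sigma[[f]]
  }
  res
}

#' Simulate noisy replicates from a fitted dispersion model
#'
#' Draws parametric replicates of the fitted profile: the best-fit curve
#' plus Gaussian noise with the profile's pooled sigma per field — the
#' same scheme the Monte Carlo error estimate uses.
#'
#' @param object a \code{\link{cpmg_fit}}.
#' @param nsim number of replicate profiles.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of \code{\link{dispersion_profile}} objects.
#' @export
simulate.cpmg_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fp <- .pars_by_field(object$pars, object$model,
                       object$profile$fields)
  lapply(seq_len(nsim), function(i)
    .perturbed_profile(object$profile, object$model, object$pars, fp))
}

#' @export
summary.cpmg_fit <- function(object, ...) {
  est <- coef(object)
  err <- if (is.null(object$errors)) rep(NA_real_, length(est))
         else {
           e <- object$errors
           out <- as.numeric(e$r20)
           if (object$model == 2) out <- c(out, e$kex, e$phi)
           if (object$model == 3) out <- c(out, e$kex, e$pb, e$dw)
           out
         }
  structure(
    list(model = object$model,
         coefficients = cbind(Estimate = est, `MC error` = err),
         chi2 = object$chi2, n = object$n, k = object$k,
         aic = object$aic, aicc = object$aicc, rex = object$rex,
         converged = object$converged, mc = object$mc),
    class = "summary.cpmg_fit"
  )
}

#' @export
print.summary.cpmg_fit <- function(x, ...) {
  cat("CPMG dispersion fit, model", x$model, "\n\nCoefficients:\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("\nchi2 = %.6g on %d points (%d parameters)\n",
              x$chi2, x$n, x$k))
  cat(sprintf("AIC = %.6g, AICc = %.6g, Rex = %.4g 1/s\n",
              x$aic, x$aicc, x$rex))
  if (!is.null(x$mc))
    cat(sprintf("Monte Carlo: %d simulations, %d failed%s\n",
                x$mc$n_sims, x$mc$n_failed,
                if (isTRUE(x$mc$unreliable)) " (errors unreliable)"
                else ""))
  invisible(x)
}

#' Plot a dispersion profile and fitted curve
#'
#' @param x a \code{\link{cpmg_fit}}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.cpmg_fit <- function(x, ...) {
  d <- x$profile$data
  keys <- names(x$profile$fields)
  cols <- grDevices::hcl.colors(max(length(keys), 2), "Dark 2")
  graphics::plot(d$nu_cpmg, d$r2eff, type = "n",
                 xlab = expression(nu[CPMG] ~ "(Hz)"),
                 ylab = expression(R[2]^{eff} ~ (s^{-1})),
                 main = paste("Residue", x$profile$residue,
                              "- model", x$model), ...)
  for (i in seq_along(keys)) {
    idx <- d$field_mhz == as.numeric(keys[i])
    graphics::points(d$nu_cpmg[idx], d$r2eff[idx], col = cols[i],
                     pch = 19)
    graphics::arrows(d$nu_cpmg[idx],
                     d$r2eff[idx] - x$profile$sigma[[keys[i]]],
                     d$nu_cpmg[idx],
                     d$r2eff[idx] + x$profile$sigma[[keys[i]]],
                     angle = 90, code = 3, length = 0.02,
                     col = cols[i])
    grid_nu <- exp(seq(log(min(d$nu_cpmg)), log(max(d$nu_cpmg)),
                       length.out = 200))
    graphics::lines(grid_nu, predict(x, grid_nu, as.numeric(keys[i])),
                    col = cols[i])
  }
  if (length(keys) > 1)
    graphics::legend("topright", legend = paste(keys, "MHz"),
                     col = cols[seq_along(keys)], lty = 1, pch = 19,
                     bty = "n")
  invisible(x)
}

#' @export
print.cpmg_cluster_fit <- function(x, ...) {
  cat("CPMG cluster fit: model ", x$model, ", ",
      length(x$fits), " residues\n", sep = "")
  cat("  shared: kex = ", signif(x$shared$kex, 6),
      if (!is.null(x$shared$pb))
        paste0(" 1/s, pb = ", signif(x$shared$pb, 4)), "\n", sep = "")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  residue %s: r20 = %.4g, %s = %.6g, partial chi2 = %.4g\n",
                nm, f$pars$r20[[1]],
                if (x$model == 3) "dw" else "phi",
                if (x$model == 3) f$pars$dw else f$pars$phi,
                f$chi2_partial))
  }
  cat(sprintf("  joint chi2 = %.6g on %d points (%d parameters), AICc = %.6g\n",
              x$chi2, x$n, x$k, x$aicc))
  invisible(x)
}
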