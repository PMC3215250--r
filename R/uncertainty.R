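#' Monte Carlo parameter uncertainties
#'
#' Parametric Monte Carlo around the best-fit curve: each simulation adds
#' Gaussian noise with the profile's pooled sigma(R2eff) to the best-fit
#' curve at every measured point and refits, starting from the best-fit
#' parameters (set \code{full_grid = TRUE} to rerun the whole multi-start
#' grid per simulation).  Parameter errors are the standard deviations of
#' each parameter over the converged simulations.  Global and cluster
#' fits perturb all fields / residues jointly, so shared parameters get a
#' single error.
#'
#' @param fit a \code{\link{cpmg_fit}} or \code{\link{cpmg_fit_cluster}}
#'   result (converged).
#' @param n_sims number of simulations (default 500).
#' @param seed integer seed; recorded on the returned object.
#' @param full_grid rerun the full multi-start grid in every simulation.
#' @return the fit with \code{errors} filled (same shape as \code{pars};
#'   for cluster fits each per-residue result gets its errors and the
#'   shared-parameter errors are stored once), plus \code{mc} metadata:
#'   \code{n_sims}, \code{seed}, \code{n_failed}, \code{unreliable} (set
#'   when more than half the simulations failed to converge).
#' @export
monte_carlo_errors <- function(fit, n_sims = 500, seed = NULL,
                               full_grid = FALSE) {
  UseMethod("monte_carlo_errors")
}

.perturbed_profile <- function(profile, model, pars, fields_pars) {
  d <- profile$data
  for (f in names(profile$fields)) {
    idx <- d$field_mhz == as.numeric(f)
    calc <- r2eff_curve(d$nu_cpmg[idx], model, fields_pars[[f]])
    d$r2eff[idx] <- calc + stats::rnorm(sum(idx), 0, profile$sigma[[f]])
  }
  p <- profile
  p$data <- d
  p
}

.pars_by_field <- function(pars, model, fields)
  lapply(fields, function(ctx) .field_pars(pars, model, ctx))

#' @export
monte_carlo_errors.cpmg_fit <- function(fit, n_sims = 500, seed = NULL,
                                        full_grid = FALSE) {
  stopifnot(n_sims >= 2)
  if (!isTRUE(fit$converged) || is.null(fit$pars))
    stop("Monte Carlo errors require a converged fit")
  if (!is.null(seed)) set.seed(seed)
  profile <- fit$profile
  keys <- names(profile$fields)
  fp <- .pars_by_field(fit$pars, fit$model, profile$fields)
  theta_hat <- unlist(fit$pars, use.names = FALSE)
  draws <- matrix(NA_real_, n_sims, length(theta_hat))
  n_failed <- 0L
  for (s in seq_len(n_sims)) {
    sim_prof <- .perturbed_profile(profile, fit$model, fit$pars, fp)
    refit <- cpmg_fit(sim_prof, fit$model,
                      starts = if (full_grid) NULL else list(theta_hat))
    if (isTRUE(refit$converged)) {
      draws[s, ] <- unlist(refit$pars, use.names = FALSE)
    } else n_failed <- n_failed + 1L
  }
  sds <- apply(draws, 2, stats::sd, na.rm = TRUE)
  if (all(profile$sigma == 0)) sds[] <- 0
  errors <- .unpack(sds, fit$model, keys)
  unreliable <- n_failed > n_sims / 2
  if (unreliable)
    warning("more than half of the Monte Carlo simulations failed to ",
            "converge; errors flagged unreliable")
  fit$errors <- errors
  fit$mc <- list(n_sims = n_sims, seed = seed, n_failed = n_failed,
                 unreliable = unreliable)
  fit
}

#' @export
monte_carlo_errors.cpmg_cluster_fit <- function(fit, n_sims = 500,
                                                seed = NULL,
                                                full_grid = FALSE) {
  stopifnot(n_sims >= 2)
  if (!isTRUE(fit$converged))
    stop("Monte Carlo errors require a converged fit")
  if (!is.null(seed)) set.seed(seed)
  model <- fit$model
  profiles <- lapply(fit$fits, `[[`, "profile")
  fps <- lapply(fit$fits, function(f)
    .pars_by_field(f$pars, model, f$profile$fields))
  nres <- length(profiles)
  theta_hat <- c(unlist(fit$shared, use.names = FALSE),
                 unlist(lapply(fit$fits, function(f) {
                   p <- f$pars
                   c(p$r20, if (model == 3) p$dw else p$phi)
                 }), use.names = FALSE))
  shared_draws <- matrix(NA_real_, n_sims, length(fit$shared))
  res_draws <- lapply(fit$fits, function(f)
    matrix(NA_real_, n_sims, length(unlist(f$pars))))
  n_failed <- 0L
  for (s in seq_len(n_sims)) {
    sim_profiles <- lapply(seq_len(nres), function(i)
      .perturbed_profile(profiles[[i]], model, fit$fits[[i]]$pars,
                         fps[[i]]))
    refit <- cpmg_fit_cluster(sim_profiles, model,
                              starts = if (full_grid) NULL
                                       else list(theta_hat))
    if (isTRUE(refit$converged)) {
      shared_draws[s, ] <- unlist(refit$shared)
      for (i in seq_len(nres))
        res_draws[[i]][s, ] <- unlist(refit$fits[[i]]$pars,
                                      use.names = FALSE)
    } else n_failed <- n_failed + 1L
  }
  shared_err <- stats::setNames(
    apply(shared_draws, 2, stats::sd, na.rm = TRUE), names(fit$shared))
  for (i in seq_len(nres)) {
    keys <- names(profiles[[i]]$fields)
    sds <- apply(res_draws[[i]], 2, stats::sd, na.rm = TRUE)
    err <- list(r20 = stats::setNames(sds[seq_along(keys)], keys))
    extra <- sds[-seq_along(keys)]
    if (model == 2) { err$kex <- extra[1]; err$phi <- extra[2] }
    else { err$kex <- extra[1]; err$pb <- extra[2]; err$dw <- extra[3] }
    # shared parameters carry the shared error
    err$kex <- shared_err[["kex"]]
    if (model == 3) err$pb <- shared_err[["pb"]]
    fit$fits[[i]]$errors <- err
  }
  unreliable <- n_failed > n_sims / 2
  if (unreliable)
    warning("more than half of the Monte Carlo simulations failed to ",
            "converge; errors flagged unreliable")
  fit$shared_errors <- as.list(shared_err)
  fit$mc <- list(n_sims = n_sims, seed = seed, n_failed = n_failed,
                 unreliable = unreliable)
  fit
}
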