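## Parameter packing -------------------------------------------------------
##
## A fit works on a flat parameter vector theta.  Layout by model and mode
## (single residue; fields ordered as in the profile):
##   model 1: [r20_f1 .. r20_fm]
##   model 2: [r20_f1 .. r20_fm, kex, phi_ref]
##   model 3: [r20_f1 .. r20_fm, kex, pb, dw_ref]
## phi_ref / dw_ref are at the declared reference field; per-field values
## scale linearly with field for dw and quadratically for phi.

.par_bounds <- list(r20 = c(1e-3, 200), kex = c(1e-3, 1e6),
                    pb = c(1e-4, 0.5 - 1e-6), dw = c(1e-6, 1e5),
                    phi = c(1e-6, 1e9))

.k_params <- function(model, n_fields) {
  n_fields + switch(as.character(model), "1" = 0L, "2" = 2L, "3" = 3L)
}

.pack_names <- function(model, field_keys) {
  c(paste0("r20_", field_keys),
    switch(as.character(model), "1" = character(),
           "2" = c("kex", "phi"), "3" = c("kex", "pb", "dw")))
}

.unpack <- function(theta, model, field_keys) {
  m <- length(field_keys)
  pars <- list(r20 = stats::setNames(theta[seq_len(m)], field_keys))
  if (model == 2) { pars$kex <- theta[m + 1]; pars$phi <- theta[m + 2] }
  if (model == 3) {
    pars$kex <- theta[m + 1]; pars$pb <- theta[m + 2]; pars$dw <- theta[m + 3]
  }
  pars
}

## sigma-weighted residual vector over all points of a (multi-field) profile
.profile_residuals <- function(theta, profile, model, field_keys) {
  pars <- .unpack(theta, model, field_keys)
  res <- numeric(0)
  for (f in field_keys) {
    d <- profile$data[profile$data$field_mhz == as.numeric(f), ]
    ctx <- profile$fields[[f]]
    p_f <- list(r20 = pars$r20[[f]], kex = pars$kex)
    if (model == 2)
      p_f$phi <- pars$phi * (ctx$frequency_mhz / ctx$ref_frequency_mhz)^2
    if (model == 3) {
      p_f$pb <- pars$pb
      p_f$dw <- scale_dw(pars$dw, ctx)
    }
    calc <- r2eff_curve(d$nu_cpmg, model, p_f)
    res <- c(res, (calc - d$r2eff) / profile$sigma[[f]])
  }
  res
}

#' Chi-square target function for a dispersion profile
#'
#' \deqn{\chi^2 = \sum_n \frac{(R_{2,calc}^{n,eff} -
#'   R_2^{n,eff})^2}{\sigma_{R_2^{eff}}^2}}
#'
#' summed over all points (all fields) of the profile, with the pooled
#' per-field sigma.
#'
#' @param profile a \code{\link{dispersion_profile}}.
#' @param model integer model id in \code{1:3}.
#' @param pars named parameter list: \code{r20} (named per field, or a
#'   scalar for single-field profiles), and \code{kex} plus \code{phi}
#'   (model 2) or \code{pb}, \code{dw} (model 3); \code{phi}/\code{dw} at
#'   the reference field.
#' @return the chi-square value (dimensionless).
#' @export
chi2_profile <- function(profile, model, pars) {
  keys <- names(profile$fields)
  if (length(pars$r20) == 1 && is.null(names(pars$r20)))
    pars$r20 <- stats::setNames(rep(pars$r20, length(keys)), keys)
  theta <- c(pars$r20[keys],
             switch(as.character(model), "1" = NULL,
                    "2" = c(pars$kex, pars$phi),
                    "3" = c(pars$kex, pars$pb, pars$dw)))
  sum(.profile_residuals(theta, profile, model, keys)^2)
}

## deterministic multi-start grid (ordered; ties broken by grid order)
.start_grid <- function(profile, model, field_keys) {
  d <- profile$data
  r20_0 <- vapply(field_keys, function(f) {
    df <- d[d$field_mhz == as.numeric(f), ]
    df$r2eff[which.max(df$nu_cpmg)]
  }, 0)
  r20_0 <- pmin(pmax(r20_0, .par_bounds$r20[1] * 2), .par_bounds$r20[2] / 2)
  if (model == 1)
    return(list(stats::setNames(r20_0, NULL)))
  # dispersion amplitude guess from the low/high-nu R2eff difference
  f1 <- field_keys[1]
  df <- d[d$field_mhz == as.numeric(f1), ]
  rex_hat <- max(df$r2eff[which.min(df$nu_cpmg)] -
                   df$r2eff[which.max(df$nu_cpmg)], 0.1)
  kex_grid <- c(100, 500, 1000, 3000, 8000)
  starts <- list()
  if (model == 2) {
    for (kex in kex_grid)
      starts[[length(starts) + 1]] <- c(r20_0, kex, rex_hat * kex)
  } else {
    pb_grid <- c(0.01, 0.05, 0.1, 0.3)
    for (kex in kex_grid)
      for (pb in pb_grid) {
        dw0 <- sqrt(rex_hat * kex / (pb * (1 - pb)))
        starts[[length(starts) + 1]] <- c(r20_0, kex, pb, dw0)
      }
  }
  starts
}

.fit_bounds <- function(model, n_fields) {
  lo <- rep(.par_bounds$r20[1], n_fields)
  hi <- rep(.par_bounds$r20[2], n_fields)
  extra <- switch(as.character(model), "1" = NULL,
                  "2" = c("kex", "phi"), "3" = c("kex", "pb", "dw"))
  for (p in extra) {
    lo <- c(lo, .par_bounds[[p]][1]); hi <- c(hi, .par_bounds[[p]][2])
  }
  list(lower = lo, upper = hi)
}

.lm_control <- function(maxfev = 2000)
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, gtol = 0,
                             maxfev = maxfev, maxiter = 500)

## run bounded LM from one start; returns theta, chi2, converged
.lm_once <- function(theta0, resid_fn, lower, upper, maxfev = 2000) {
  theta0 <- pmin(pmax(theta0, lower), upper)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                       fn = resid_fn, control = .lm_control(maxfev)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(theta = theta0, chi2 = Inf, converged = FALSE))
  list(theta = fit$par, chi2 = sum(fit$fvec^2),
       converged = fit$info %in% 1:4)
}

#' Fit a two-site exchange model to a dispersion profile
#'
#' The central fitting routine: minimizes the chi-square target
#' (\code{\link{chi2_profile}}) by bounded Levenberg-Marquardt over a
#' deterministic multi-start grid, for one residue at one or several
#' static fields.  With a multi-field profile the exchange parameters
#' (\code{kex} and \code{phi}, or \code{kex}, \code{pb} and \code{dw}) are
#' shared across fields while \code{r20} is fitted per field;
#' \code{dw} scales linearly and \code{phi} quadratically with the field
#' ratio.
#'
#' @param profile a \code{\link{dispersion_profile}} (one or more fields).
#' @param model integer model id: 1 (no exchange), 2 (fast limit),
#'   3 (slow limit, Carver-Richards).
#' @param starts optional list of start vectors overriding the built-in
#'   grid (layout: per-field r20 values, then the exchange parameters).
#' @param maxfev maximum function evaluations per start.
#' @return an object of class \code{"cpmg_fit"} with components
#'   \code{model}, \code{pars} (named list; \code{r20} named per field),
#'   \code{errors} (filled by \code{\link{monte_carlo_errors}}),
#'   \code{chi2}, \code{n}, \code{k}, \code{aic}, \code{aicc},
#'   \code{converged}, \code{n_starts}, \code{rex} (at the first field)
#'   and the \code{profile} itself.
#' @examples
#' prof <- simulate_profile(model = 2,
#'   pars = list(r20 = 15.23, kex = 3750.3, phi = 47457.4))
#' fit <- cpmg_fit(prof, model = 2)
#' coef(fit)
#' @export
cpmg_fit <- function(profile, model, starts = NULL, maxfev = 2000) {
  stopifnot(inherits(profile, "dispersion_profile"), model %in% 1:3)
  keys <- names(profile$fields)
  k <- .k_params(model, length(keys))
  n <- nrow(profile$data)
  if (n < k + 2)
    stop("need at least k + 2 = ", k + 2, " points to fit model ", model,
         " (have ", n, ")")
  if (is.null(starts)) starts <- .start_grid(profile, model, keys)
  b <- .fit_bounds(model, length(keys))
  resid_fn <- function(th) .profile_residuals(th, profile, model, keys)

  best <- list(theta = NULL, chi2 = Inf, converged = FALSE)
  for (i in seq_along(starts)) {
    cand <- .lm_once(starts[[i]], resid_fn, b$lower, b$upper, maxfev)
    if (cand$chi2 < best$chi2 - 1e-12) best <- cand
  }
  pars <- if (is.null(best$theta)) NULL else .unpack(best$theta, model, keys)
  chi2 <- best$chi2
  structure(
    list(model = model, pars = pars, errors = NULL, chi2 = chi2,
         n = n, k = k,
         aic = aic_score(chi2, k),
         aicc = if (n > k + 1) aicc_score(chi2, k, n) else NA_real_,
         converged = best$converged, n_starts = length(starts),
         rex = if (is.null(pars) || model == 1) 0 else
           rex_contribution(model, .field_pars(pars, model,
                                               profile$fields[[1]])),
         profile = profile),
    class = "cpmg_fit"
  )
}

## parameters evaluated at one field context
.field_pars <- function(pars, model, ctx) {
  p <- list(r20 = pars$r20[[1]], kex = pars$kex)
  key <- as.character(ctx$frequency_mhz)
  if (key %in% names(pars$r20)) p$r20 <- pars$r20[[key]]
  if (model == 2)
    p$phi <- pars$phi * (ctx$frequency_mhz / ctx$ref_frequency_mhz)^2
  if (model == 3) { p$pb <- pars$pb; p$dw <- scale_dw(pars$dw, ctx) }
  p
}

#' Cluster fit: shared exchange across residues
#'
#' Simultaneously fits several residues that experience the same exchange
#' process: a single \code{kex} (and \code{pb} for model 3) is optimized
#' jointly, while \code{r20} and \code{dw} (or \code{phi}) are fitted per
#' residue.  The joint chi-square is the sum of each residue's own
#' sigma-normalized chi-square.
#'
#' @param profiles list of \code{\link{dispersion_profile}} objects
#'   sharing the same schedule per field.
#' @param model 2 or 3.
#' @param starts optional list of start vectors overriding the built-in
#'   grid (layout: shared kex (and pb), then per residue its per-field
#'   r20 values and dw or phi).
#' @param maxfev maximum function evaluations per start.
#' @return an object of class \code{"cpmg_cluster_fit"}: a list with the
#'   shared parameters (\code{kex}, \code{pb}), per-residue
#'   \code{\link{cpmg_fit}}-like results (each carrying the shared values
#'   plus its own \code{r20}, \code{dw}/\code{phi} and partial chi2), the
#'   joint \code{chi2}, \code{n}, \code{k} and convergence flag.
#' @export
cpmg_fit_cluster <- function(profiles, model, starts = NULL,
                             maxfev = 4000) {
  stopifnot(model %in% 2:3, length(profiles) >= 1)
  usable <- vapply(profiles, function(p)
    nrow(p$data) >= .k_params(model, length(p$fields)) + 2, TRUE)
  if (!all(usable)) {
    warning(sum(!usable), " residue(s) with insufficient points dropped ",
            "from cluster")
    profiles <- profiles[usable]
  }
  if (length(profiles) == 1) {
    fit <- cpmg_fit(profiles[[1]], model, maxfev = maxfev)
    return(structure(list(shared = fit$pars[intersect(names(fit$pars),
                                                      c("kex", "pb"))],
                          fits = stats::setNames(list(fit),
                                                 profiles[[1]]$residue),
                          chi2 = fit$chi2, n = fit$n, k = fit$k,
                          converged = fit$converged, model = model),
                     class = "cpmg_cluster_fit"))
  }
  nres <- length(profiles)
  keys_list <- lapply(profiles, function(p) names(p$fields))
  nf <- vapply(keys_list, length, 0L)
  n_shared <- if (model == 3) 2L else 1L  # kex (+ pb)
  per_res <- nf + 1L                      # r20 per field + dw or phi
  # theta: [shared..., res1: r20_f..., dw; res2: ...]
  offsets <- c(0L, cumsum(per_res)) + n_shared

  split_theta <- function(theta, i) {
    keys <- keys_list[[i]]
    block <- theta[(offsets[i] + 1):(offsets[i] + per_res[i])]
    pars <- list(r20 = stats::setNames(block[seq_along(keys)], keys),
                 kex = theta[1])
    if (model == 3) {
      pars$pb <- theta[2]; pars$dw <- block[length(block)]
    } else pars$phi <- block[length(block)]
    pars
  }
  resid_fn <- function(theta) {
    unlist(lapply(seq_len(nres), function(i) {
      pars <- split_theta(theta, i)
      th <- c(pars$r20,
              if (model == 2) c(pars$kex, pars$phi)
              else c(pars$kex, pars$pb, pars$dw))
      .profile_residuals(th, profiles[[i]], model, keys_list[[i]])
    }))
  }
  # bounds
  lo <- c(.par_bounds$kex[1], if (model == 3) .par_bounds$pb[1])
  hi <- c(.par_bounds$kex[2], if (model == 3) .par_bounds$pb[2])
  for (i in seq_len(nres)) {
    lo <- c(lo, rep(.par_bounds$r20[1], nf[i]),
            if (model == 3) .par_bounds$dw[1] else .par_bounds$phi[1])
    hi <- c(hi, rep(.par_bounds$r20[2], nf[i]),
            if (model == 3) .par_bounds$dw[2] else .par_bounds$phi[2])
  }
  # starts: share the per-residue single-fit heuristics over the kex/pb grid
  if (is.null(starts)) {
  res_starts <- lapply(seq_len(nres), function(i)
    .start_grid(profiles[[i]], model, keys_list[[i]]))
  kex_grid <- c(100, 500, 1000, 3000, 8000)
  pb_grid <- if (model == 3) c(0.01, 0.05, 0.1, 0.3) else NA
  starts <- list()
  for (kex in kex_grid) for (pb in pb_grid) {
    th <- c(kex, if (model == 3) pb)
    for (i in seq_len(nres)) {
      s1 <- res_starts[[i]][[1]]  # r20 part is start-independent
      keys <- keys_list[[i]]
      r20s <- s1[seq_along(keys)]
      d <- profiles[[i]]$data
      df <- d[d$field_mhz == as.numeric(keys[1]), ]
      rex_hat <- max(df$r2eff[which.min(df$nu_cpmg)] -
                       df$r2eff[which.max(df$nu_cpmg)], 0.1)
      tail_par <- if (model == 3) sqrt(rex_hat * kex / (pb * (1 - pb)))
                  else rex_hat * kex
      th <- c(th, r20s, tail_par)
    }
    starts[[length(starts) + 1]] <- th
  }
  }

  best <- list(theta = NULL, chi2 = Inf, converged = FALSE)
  for (s in starts) {
    cand <- .lm_once(s, resid_fn, lo, hi, maxfev)
    if (cand$chi2 < best$chi2 - 1e-12) best <- cand
  }
  n_tot <- sum(vapply(profiles, function(p) nrow(p$data), 0L))
  k_tot <- n_shared + sum(per_res)
  fits <- stats::setNames(vector("list", nres),
                          vapply(profiles, function(p)
                            as.character(p$residue), ""))
  for (i in seq_len(nres)) {
    pars <- split_theta(best$theta, i)
    part_chi2 <- chi2_profile(profiles[[i]], model, pars)
    fits[[i]] <- structure(
      list(model = model, pars = pars, errors = NULL,
           chi2 = best$chi2, chi2_partial = part_chi2,
           n = nrow(profiles[[i]]$data), k = k_tot,
           aic = aic_score(best$chi2, k_tot),
           aicc = if (n_tot > k_tot + 1)
             aicc_score(best$chi2, k_tot, n_tot) else NA_real_,
           converged = best$converged, n_starts = length(starts),
           rex = rex_contribution(model, .field_pars(
             pars, model, profiles[[i]]$fields[[1]])),
           profile = profiles[[i]]),
      class = "cpmg_fit")
  }
  structure(
    list(shared = if (model == 3) list(kex = best$theta[1],
                                       pb = best$theta[2])
                  else list(kex = best$theta[1]),
         fits = fits, chi2 = best$chi2, n = n_tot, k = k_tot,
         aic = aic_score(best$chi2, k_tot),
         aicc = if (n_tot > k_tot + 1) aicc_score(best$chi2, k_tot, n_tot)
                else NA_real_,
         converged = best$converged, model = model),
    class = "cpmg_cluster_fit"
  )
}
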