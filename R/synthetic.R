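#' Default CPMG frequency grid
#'
#' A typical constant-time CPMG acquisition list (Hz), 14 points between
#' 25 and 2000 Hz, no replicates.
#'
#' @export
default_nu_grid <- c(25, 50, 75, 100, 150, 200, 300, 500, 600, 700,
                     900, 1000, 1500, 2000)

.apply_noise <- function(r2, noise_percent) {
  if (noise_percent == 0) return(r2)
  sd <- noise_percent / 100
  eps <- stats::rnorm(length(r2), 0, sd)
  eps <- pmin(pmax(eps, -3 * sd), 3 * sd)  # truncate at 3 SD
  r2 * (1 + eps)
}

.synth_sigma <- function(r2, noise_percent)
  max(noise_percent / 100 * mean(r2), 1e-6)

#' Simulate a dispersion profile
#'
#' Generates R2eff from the exact model equation on a CPMG frequency
#' grid, then applies multiplicative Gaussian noise: each point is
#' multiplied by \eqn{1 + \epsilon} with \eqn{\epsilon \sim
#' N(0, (p/100)^2)} truncated at three standard deviations, where p is
#' \code{noise_percent}.  The attached sigma(R2eff) equals the nominal
#' noise level times the mean R2eff (floored at 1e-6 for noiseless data
#' so the chi-square target stays defined).  The generating parameters
#' are recorded as attribute \code{"truth"}.
#'
#' @param model integer model id in \code{1:3}.
#' @param pars generating parameters: \code{r20}, and \code{kex} plus
#'   \code{phi} (model 2) or \code{pb}, \code{dw} (model 3), quoted at
#'   the reference field of \code{field}.
#' @param nu_grid CPMG frequencies, Hz.
#' @param field a \code{\link{field_context}}; \code{dw}/\code{phi} are
#'   scaled to it from the reference frequency.
#' @param noise_percent relative noise level in percent (0, 2, 5, 8, 10,
#'   ...).
#' @param residue residue label for the profile.
#' @param seed optional integer seed.
#' @return a \code{\link{dispersion_profile}} with attribute
#'   \code{"truth"} (the generating model and parameters).
#' @examples
#' prof <- simulate_profile(3,
#'   list(r20 = 15.23, kex = 306.2, pb = 0.072, dw = 1875.5),
#'   noise_percent = 5, seed = 1)
#' @export
simulate_profile <- function(model, pars, nu_grid = default_nu_grid,
                             field = field_context(800),
                             noise_percent = 0, residue = 1L,
                             seed = NULL) {
  stopifnot(model %in% 1:3, noise_percent >= 0, length(nu_grid) >= 6)
  if (!is.null(seed)) set.seed(seed)
  p_f <- .field_pars(.normalize_pars(pars, model), model, field)
  r2 <- r2eff_curve(nu_grid, model, p_f)
  r2_noisy <- .apply_noise(r2, noise_percent)
  prof <- dispersion_profile(
    residue = residue,
    data = data.frame(field_mhz = field$frequency_mhz, nu_cpmg = nu_grid,
                      r2eff = r2_noisy),
    sigma = stats::setNames(.synth_sigma(r2, noise_percent),
                            as.character(field$frequency_mhz)),
    fields = stats::setNames(list(field),
                             as.character(field$frequency_mhz))
  )
  attr(prof, "truth") <- list(model = model, pars = pars,
                              noise_percent = noise_percent)
  prof
}

## pars as stored in fits carry a named per-field r20; accept plain lists
.normalize_pars <- function(pars, model) {
  if (is.null(names(pars$r20))) pars$r20 <- pars$r20[[1]]
  pars
}

#' Simulate one residue at several static fields
#'
#' Generates per-field dispersion curves with the chemical shift
#' difference scaled linearly (\code{dw}) and the fast-exchange amplitude
#' quadratically (\code{phi}) with the field ratio, then merges them into
#' one multi-field profile.  Noise is drawn independently per field.
#'
#' @inheritParams simulate_profile
#' @param fields list of \code{\link{field_context}} objects; their
#'   \code{ref_frequency_mhz} designates the field \code{pars} are quoted
#'   at.
#' @return a multi-field \code{\link{dispersion_profile}} with attribute
#'   \code{"truth"}.
#' @export
simulate_multifield <- function(model, pars, fields,
                                nu_grid = default_nu_grid,
                                noise_percent = 0, residue = 1L,
                                seed = NULL) {
  stopifnot(length(fields) >= 1)
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(fields, function(ctx)
    simulate_profile(model, pars, nu_grid, ctx, noise_percent, residue))
  prof <- if (length(parts) == 1) parts[[1]] else merge_fields(parts)
  attr(prof, "truth") <- list(model = model, pars = pars,
                              noise_percent = noise_percent)
  prof
}

#' Simulate a residue cluster sharing one exchange process
#'
#' All residues share \code{kex} (and \code{pb}); \code{r20} and
#' \code{dw} (or \code{phi}) differ per residue.  Noise is independent
#' per residue.
#'
#' @inheritParams simulate_profile
#' @param shared named list with \code{kex} and, for model 3, \code{pb}.
#' @param r20 numeric vector, one baseline rate per residue.
#' @param dw numeric vector of shift differences (model 3), rad/s.
#' @param phi numeric vector of amplitudes (model 2), (rad/s)^2.
#' @return list of \code{\link{dispersion_profile}} objects, each with a
#'   \code{"truth"} attribute.
#' @export
simulate_cluster <- function(model, shared, r20, dw = NULL, phi = NULL,
                             nu_grid = default_nu_grid,
                             field = field_context(800),
                             noise_percent = 0, seed = NULL) {
  stopifnot(model %in% 2:3)
  n <- length(r20)
  per_res <- if (model == 3) dw else phi
  stopifnot(length(per_res) == n)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    pars <- c(list(r20 = r20[i]), shared,
              if (model == 3) list(dw = dw[i]) else list(phi = phi[i]))
    simulate_profile(model, pars, nu_grid, field, noise_percent,
                     residue = i)
  })
}

#' Write a synthetic profile back out as peak intensities
#'
#' Inverts the R2eff extraction: for a chosen reference intensity I(0)
#' and constant CPMG period, each point becomes
#' \eqn{I(\nu) = I(0)\exp(-R_2^{eff} T_{CPMG})}.  Returns the peak table
#' and schedule that \code{\link{build_profiles}} consumes, so the
#' intensity pipeline can be exercised end to end.
#'
#' @param profiles list of single-field \code{\link{dispersion_profile}}
#'   objects on a common grid and field.
#' @param i0 reference intensity (arbitrary units).
#' @param t_cpmg constant CPMG period, seconds.
#' @return list with \code{peaks} (data.frame) and \code{schedule}
#'   (\code{\link{cpmg_schedule}}).
#' @export
profiles_to_intensities <- function(profiles, i0 = 1e6, t_cpmg = 0.08) {
  if (inherits(profiles, "dispersion_profile")) profiles <- list(profiles)
  nu <- profiles[[1]]$data$nu_cpmg
  field <- profiles[[1]]$fields[[1]]
  ids <- c("ref", paste0("s", seq_along(nu)))
  schedule <- cpmg_schedule(ids, c(NA, nu), t_cpmg, field)
  rows <- lapply(profiles, function(p) {
    stopifnot(isTRUE(all.equal(p$data$nu_cpmg, nu)))
    c(i0, i0 * exp(-p$data$r2eff * t_cpmg))
  })
  peaks <- as.data.frame(do.call(rbind, rows))
  names(peaks) <- ids
  peaks <- cbind(residue = sapply(profiles, `[[`, "residue"), peaks)
  list(peaks = peaks, schedule = schedule)
}
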