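#' CPMG experiment schedule
#'
#' Maps spectrum identifiers to CPMG pulse frequencies.  Reference spectra
#' (recorded without the CPMG period) are marked with \code{NA}; replicate
#' frequencies are allowed and are what the pooled-variance error estimate
#' feeds on.
#'
#' @param spectrum_id character vector of spectrum identifiers (must match
#'   peak-table column names).
#' @param nu_cpmg numeric vector of CPMG frequencies in Hz; \code{NA}
#'   marks a reference spectrum.
#' @param t_cpmg constant CPMG relaxation period, seconds.
#' @param field a \code{\link{field_context}}.
#' @return an object of class \code{"cpmg_schedule"}.
#' @export
cpmg_schedule <- function(spectrum_id, nu_cpmg, t_cpmg,
                          field = field_context(600)) {
  stopifnot(length(spectrum_id) == length(nu_cpmg), t_cpmg > 0)
  if (!any(is.na(nu_cpmg)))
    stop("schedule needs at least one reference spectrum (nu_cpmg = NA)")
  if (any(nu_cpmg <= 0, na.rm = TRUE))
    stop("all nu_cpmg must be > 0")
  structure(
    list(points = data.frame(spectrum_id = as.character(spectrum_id),
                             nu_cpmg = as.numeric(nu_cpmg),
                             stringsAsFactors = FALSE),
         t_cpmg = t_cpmg, field = field),
    class = "cpmg_schedule"
  )
}

#' Effective transverse relaxation rate from peak intensities
#'
#' \deqn{R_2^{eff} = \frac{1}{T_{CPMG}} \ln\frac{I(0)}{I(\nu_{CPMG})}}
#'
#' Non-positive intensities make the logarithm undefined: those points are
#' returned as \code{NA} with a warning so that downstream profile
#' construction can drop them.  Negative rates (\eqn{I(\nu) > I(0)}) are
#' valid data and are kept.
#'
#' @param i0 reference-spectrum intensity.
#' @param i_nu intensity at the CPMG frequency (vectorised).
#' @param t_cpmg constant CPMG period, seconds.
#' @return R2eff in 1/s; \code{NA} where an intensity was unusable.
#' @export
compute_r2eff <- function(i0, i_nu, t_cpmg) {
  stopifnot(t_cpmg > 0)
  n <- max(length(i0), length(i_nu))
  i0 <- rep_len(i0, n)
  i_nu <- rep_len(i_nu, n)
  bad <- !is.finite(i0) | !is.finite(i_nu) | i0 <= 0 | i_nu <= 0
  out <- rep(NA_real_, n)
  if (any(bad))
    warning(sum(bad), " point(s) with non-positive or missing intensity ",
            "marked missing")
  out[!bad] <- log(i0[!bad] / i_nu[!bad]) / t_cpmg
  out
}

#' Pooled standard deviation of R2eff over replicate groups
#'
#' \deqn{\sigma^2 = \frac{\sum_j s_j^2 (n_j - 1)}{\sum_j (n_j - 1)}}
#'
#' summed over the replicate groups \eqn{j} (each group is one replicated
#' CPMG frequency with \eqn{n_j} measurements of standard deviation
#' \eqn{s_j}).  A degenerate zero pooled variance is floored at
#' \code{floor_sigma} so that the chi-square target stays finite.
#'
#' @param n integer vector of group sizes (each >= 2).
#' @param s numeric vector of group standard deviations, 1/s.
#' @param floor_sigma lower bound applied to the result, 1/s.
#' @return pooled standard deviation, 1/s.
#' @export
pooled_sigma <- function(n, s, floor_sigma = 1e-6) {
  stopifnot(length(n) == length(s), length(n) >= 1, all(n >= 2))
  dof <- n - 1
  sig <- sqrt(sum(s^2 * dof) / sum(dof))
  if (sig < floor_sigma) {
    warning("pooled sigma below floor; using ", floor_sigma, " 1/s")
    sig <- floor_sigma
  }
  sig
}

#' Dispersion profile container
#'
#' One residue's R2eff versus CPMG frequency, possibly at several static
#' fields, with one pooled error per field.
#'
#' @param residue residue identifier (number, optionally with amino-acid
#'   code attached elsewhere).
#' @param data data.frame with columns \code{field_mhz}, \code{nu_cpmg},
#'   \code{r2eff}.
#' @param sigma named numeric vector, pooled sigma(R2eff) per field; names
#'   are the field frequencies in MHz.
#' @param fields named list of \code{\link{field_context}} objects, keyed
#'   like \code{sigma}.
#' @return an object of class \code{"dispersion_profile"}.
#' @export
dispersion_profile <- function(residue, data, sigma, fields = NULL) {
  stopifnot(all(c("field_mhz", "nu_cpmg", "r2eff") %in% names(data)))
  data <- data[order(data$field_mhz, data$nu_cpmg), , drop = FALSE]
  rownames(data) <- NULL
  keys <- as.character(unique(data$field_mhz))
  if (is.null(fields))
    fields <- stats::setNames(
      lapply(unique(data$field_mhz), field_context), keys)
  if (is.null(names(sigma))) names(sigma) <- keys
  stopifnot(all(keys %in% names(sigma)), all(sigma[keys] > 0))
  structure(
    list(residue = residue, data = data, sigma = sigma[keys],
         fields = fields[keys]),
    class = "dispersion_profile"
  )
}

#' @export
print.dispersion_profile <- function(x, ...) {
  cat("CPMG dispersion profile, residue", x$residue, "\n")
  for (f in names(x$fields)) {
    d <- x$data[x$data$field_mhz == as.numeric(f), ]
    cat(sprintf("  %s MHz: %d points, nu %g-%g Hz, sigma(R2eff) = %.4g 1/s\n",
                f, nrow(d), min(d$nu_cpmg), max(d$nu_cpmg), x$sigma[[f]]))
  }
  invisible(x)
}

#' Build dispersion profiles from a peak table and schedule
#'
#' Converts raw peak intensities into per-residue R2eff dispersion
#' profiles.  Multiple reference spectra are averaged into I(0); replicate
#' CPMG frequencies yield separate points and drive the pooled-variance
#' error estimate.  Residues whose pooled sigma cannot be computed (no
#' replicates anywhere) get \code{default_rel_error} times their median
#' R2eff, with a warning.
#'
#' @param peaks data.frame; first column \code{residue}, remaining columns
#'   one per spectrum (named by spectrum id), cells are intensities
#'   (\code{NA} for missing peaks).
#' @param schedule a \code{\link{cpmg_schedule}}.
#' @param default_rel_error relative error used when no replicates exist.
#' @param drop_negative if \code{TRUE}, negative R2eff values are dropped
#'   instead of kept-and-flagged.
#' @param replicate_tol frequencies closer than this (Hz) form one
#'   replicate group.
#' @return named list of \code{\link{dispersion_profile}} objects.
#' @export
build_profiles <- function(peaks, schedule, default_rel_error = 0.02,
                           drop_negative = FALSE, replicate_tol = 0.5) {
  stopifnot(inherits(schedule, "cpmg_schedule"),
            "residue" %in% names(peaks))
  pts <- schedule$points
  missing_cols <- setdiff(pts$spectrum_id, names(peaks))
  if (length(missing_cols))
    stop("peak table lacks spectra named in the schedule: ",
         paste(missing_cols, collapse = ", "))
  ref_ids <- pts$spectrum_id[is.na(pts$nu_cpmg)]
  cpmg <- pts[!is.na(pts$nu_cpmg), ]
  fkey <- as.character(schedule$field$frequency_mhz)

  out <- list()
  for (i in seq_len(nrow(peaks))) {
    res <- peaks$residue[i]
    i0_vals <- as.numeric(peaks[i, ref_ids, drop = TRUE])
    i0_vals <- i0_vals[is.finite(i0_vals) & i0_vals > 0]
    if (!length(i0_vals)) {
      warning("residue ", res, ": no usable reference intensity; excluded")
      next
    }
    i0 <- mean(i0_vals)
    inten <- as.numeric(peaks[i, cpmg$spectrum_id, drop = TRUE])
    usable <- is.finite(inten) & inten > 0
    if (sum(usable) < 2) {
      warning("residue ", res, ": fewer than 2 usable points; excluded")
      next
    }
    nu <- cpmg$nu_cpmg[usable]
    r2 <- log(i0 / inten[usable]) / schedule$t_cpmg
    if (any(r2 < 0)) {
      if (drop_negative) {
        keep <- r2 >= 0
        nu <- nu[keep]; r2 <- r2[keep]
      } else {
        warning("residue ", res, ": ", sum(r2 < 0),
                " negative R2eff value(s) retained (I(nu) > I(0))")
      }
    }
    # replicate groups by frequency proximity
    ord <- order(nu)
    grp <- integer(length(nu))
    g <- 1L
    grp[ord[1]] <- g
    for (j in seq_along(ord)[-1]) {
      if (nu[ord[j]] - nu[ord[j - 1]] >= replicate_tol) g <- g + 1L
      grp[ord[j]] <- g
    }
    tab <- table(grp)
    rep_groups <- as.integer(names(tab)[tab >= 2])
    if (length(rep_groups)) {
      nrep <- as.integer(tab[as.character(rep_groups)])
      srep <- vapply(rep_groups, function(g) stats::sd(r2[grp == g]), 0)
      sig <- pooled_sigma(nrep, srep)
    } else {
      sig <- default_rel_error * stats::median(r2)
      if (!is.finite(sig) || sig <= 0) sig <- 1e-6
      warning("residue ", res, ": no replicated nu_cpmg; sigma(R2eff) set ",
              "to ", signif(default_rel_error * 100, 3),
              "% of the median R2eff")
    }
    out[[as.character(res)]] <- dispersion_profile(
      residue = res,
      data = data.frame(field_mhz = schedule$field$frequency_mhz,
                        nu_cpmg = nu, r2eff = r2),
      sigma = stats::setNames(sig, fkey),
      fields = stats::setNames(list(schedule$field), fkey)
    )
  }
  out
}

#' Merge per-field profiles of the same residue
#'
#' Combines single-field profiles (e.g. from \code{\link{build_profiles}}
#' run per field) into one multi-field profile for global fitting.
#'
#' @param ... \code{\link{dispersion_profile}} objects for one residue,
#'   each at a distinct field.
#' @return a multi-field \code{\link{dispersion_profile}}.
#' @export
merge_fields <- function(...) {
  ps <- list(...)
  if (length(ps) == 1 && is.list(ps[[1]]) &&
      !inherits(ps[[1]], "dispersion_profile")) ps <- ps[[1]]
  stopifnot(length(ps) >= 1,
            all(vapply(ps, inherits, TRUE, "dispersion_profile")))
  dispersion_profile(
    residue = ps[[1]]$residue,
    data = do.call(rbind, lapply(ps, `[[`, "data")),
    sigma = do.call(c, lapply(ps, `[[`, "sigma")),
    fields = do.call(c, lapply(ps, `[[`, "fields"))
  )
}
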