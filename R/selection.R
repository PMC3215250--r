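#' Chi-square based Akaike information criterion
#'
#' Score = chi2 + 2k.  Lower is better; the penalty guards against
#' over-fitting when richer exchange models are compared against the flat
#' no-exchange baseline.
#'
#' @param chi2 chi-square of the fit.
#' @param k number of optimized parameters (>= 1).
#' @return the AIC score.
#' @export
aic_score <- function(chi2, k) {
  stopifnot(k >= 1)
  chi2 + 2 * k
}

#' AICc: AIC with second-order small-sample correction
#'
#' Score = chi2 + 2k + 2k(k+1)/(n - k - 1).  Dispersion profiles rarely
#' exceed 15-20 points, so the correction matters; it vanishes as n grows.
#'
#' @inheritParams aic_score
#' @param n number of data points; must exceed k + 1.
#' @return the AICc score.
#' @export
aicc_score <- function(chi2, k, n) {
  stopifnot(k >= 1)
  if (n <= k + 1)
    stop("AICc undefined for n <= k + 1; use aic_score() instead")
  chi2 + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' F-test between a simpler and a more complex nested fit
#'
#' \deqn{F = \frac{(\chi^2_s - \chi^2_c)/(k_c - k_s)}{\chi^2_c/(n - k_c)}}
#'
#' The complex model is accepted when the p-value falls below
#' \code{alpha}.  A degenerate perfect complex fit (chi2 = 0) is accepted
#' with p = 0 and a warning.
#'
#' @param simple,complex \code{\link{cpmg_fit}} objects with
#'   \code{complex$k > simple$k} and the same number of points.
#' @param alpha significance level.
#' @return list with \code{choose_complex}, \code{f}, \code{p}.
#' @export
f_test <- function(simple, complex, alpha = 0.05) {
  stopifnot(complex$k > simple$k, complex$n == simple$n)
  if (complex$chi2 <= 0) {
    warning("degenerate perfect fit of the complex model; F-test p = 0")
    return(list(choose_complex = alpha > 0, f = Inf, p = 0))
  }
  df1 <- complex$k - simple$k
  df2 <- complex$n - complex$k
  f <- max((simple$chi2 - complex$chi2) / df1, 0) / (complex$chi2 / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(choose_complex = p < alpha, f = f, p = p)
}

#' Select the best exchange model for a residue
#'
#' Ranks competing fits of one residue by AICc (default), AIC, or an
#' F-test chain (model 1 vs 2, then the winner vs 3).  Score ties within
#' \code{1e-9} favor the simpler model.  The exchange contribution
#' \eqn{R_{ex}} of the winning model is reported alongside.
#'
#' @param fits list of \code{\link{cpmg_fit}} objects for the same
#'   residue, one per candidate model (>= 2).
#' @param criterion \code{"AICc"}, \code{"AIC"} or \code{"F-test"}.
#' @param alpha F-test significance level.
#' @return an object of class \code{"cpmg_selection"}: residue, criterion,
#'   a per-model table (model, chi2, score), \code{selected} model id (or
#'   \code{NA} if nothing converged), \code{rex} and \code{kex} of the
#'   winner, and the winning fit itself.
#' @export
select_model <- function(fits, criterion = c("AICc", "AIC", "F-test"),
                         alpha = 0.05) {
  criterion <- match.arg(criterion)
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, TRUE, "cpmg_fit")))
  models <- vapply(fits, `[[`, 0, "model")
  ord <- order(models)
  fits <- fits[ord]; models <- models[ord]
  conv <- vapply(fits, function(f) is.finite(f$chi2), TRUE)
  tab <- data.frame(
    model = models,
    chi2 = vapply(fits, `[[`, 0, "chi2"),
    score = vapply(fits, function(f)
      switch(criterion, AICc = f$aicc, AIC = f$aic, `F-test` = f$chi2), 0)
  )
  residue <- fits[[1]]$profile$residue
  if (!any(conv)) {
    return(structure(list(residue = residue, criterion = criterion,
                          table = tab, selected = NA_integer_,
                          rex = NA_real_, kex = NA_real_, fit = NULL),
                     class = "cpmg_selection"))
  }
  if (criterion %in% c("AICc", "AIC")) {
    sc <- tab$score
    sc[!conv] <- Inf
    # ties within 1e-9 go to the simpler model (fits sorted by model id)
    best <- which(sc <= min(sc) + 1e-9)[1]
  } else {
    idx <- which(conv)
    best <- idx[1]
    for (j in idx[-1]) {
      if (fits[[j]]$k > fits[[best]]$k &&
          f_test(fits[[best]], fits[[j]], alpha)$choose_complex)
        best <- j
    }
  }
  win <- fits[[best]]
  structure(
    list(residue = residue, criterion = criterion, table = tab,
         selected = win$model, rex = win$rex,
         kex = if (win$model > 1) win$pars$kex else NA_real_,
         fit = win),
    class = "cpmg_selection"
  )
}

#' Fit all candidate models to a profile and select the best
#'
#' Convenience wrapper: runs \code{\link{cpmg_fit}} for each model id and
#' hands the results to \code{\link{select_model}}.
#'
#' @param profile a \code{\link{dispersion_profile}}.
#' @param models integer vector of model ids to fit.
#' @inheritParams select_model
#' @return a \code{"cpmg_selection"} object; the per-model fits are
#'   attached as attribute \code{"fits"}.
#' @export
fit_models <- function(profile, models = 1:3,
                       criterion = c("AICc", "AIC", "F-test"),
                       alpha = 0.05) {
  fits <- lapply(models, function(m) cpmg_fit(profile, m))
  sel <- select_model(fits, criterion, alpha)
  attr(sel, "fits") <- fits
  sel
}

#' @export
print.cpmg_selection <- function(x, ...) {
  cat("Model selection (", x$criterion, "), residue ", x$residue, "\n",
      sep = "")
  tab <- x$table
  tab$chi2 <- signif(tab$chi2, 6)
  tab$score <- signif(tab$score, 6)
  print(tab, row.names = FALSE)
  if (is.na(x$selected)) {
    cat("No converged fit; no model selected.\n")
  } else {
    cat(sprintf("Selected: model %d  (Rex = %.4g 1/s%s)\n", x$selected,
                x$rex,
                if (!is.na(x$kex)) sprintf(", kex = %.4g 1/s", x$kex)
                else ""))
  }
  invisible(x)
}
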