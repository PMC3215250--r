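# Independent term-by-term transcription of the Carver-Richards
# expression, kept deliberately separate from the package implementation
# so it can serve as an oracle.
oracle_carver_richards <- function(nu, r20, kex, pb, dw) {
  pa <- 1 - pb
  Psi <- kex * kex - dw * dw
  xi <- -2 * dw * (pa * kex - pb * kex)
  root <- sqrt(Psi * Psi + xi * xi)
  D_plus <- (1 / 2) * (+1 + (Psi + 2 * dw * dw) / root)
  D_minus <- (1 / 2) * (-1 + (Psi + 2 * dw * dw) / root)
  eta_plus <- sqrt((+Psi + root)) / (2 * sqrt(2) * nu)
  eta_minus <- sqrt((-Psi + root)) / (2 * sqrt(2) * nu)
  inner <- D_plus * cosh(eta_plus) - D_minus * cos(eta_minus)
  r20 + kex / 2 - nu * acosh(inner)
}

# Table-style generating parameter sets used across tests
pars_fast <- list(r20 = 15.23, kex = 3750.3, phi = 47457.4)
pars_slow <- list(r20 = 15.23, kex = 306.2, pb = 0.072, dw = 1875.5)

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_true(all(abs(object - expected) <= rel_tol * abs(expected)),
              label = sprintf("%s vs %s (rel tol %g)",
                              paste(signif(object, 8), collapse = ","),
                              paste(signif(expected, 8), collapse = ","),
                              rel_tol))
}
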