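# Independent numerical oracles used across the test suite.  These are
# deliberately implemented with different representations and optimizers than
# the package internals (tangent-angle elasticas via stats::optim, closed-form
# polymer formulas) so they can referee the rigid base-pair machinery.

# Minimum bending energy coefficient of the planar teardrop elastica (a loop
# with coincident ends and free end orientations), computed by direct
# minimization of the continuum bending energy over tangent angles with a
# ramped closure penalty.  Returns E * L / Lp; the classical value is 14.055.
teardrop_elastica_coef <- function(n = 400) {
  h <- 1 / n
  efun <- function(phi, mu) {
    d <- diff(phi)
    sum(d^2) / (2 * h) + mu * ((sum(cos(phi)) * h)^2 + (sum(sin(phi)) * h)^2)
  }
  gfun <- function(phi, mu) {
    d <- diff(phi)
    g <- numeric(length(phi))
    g[-1] <- g[-1] + d / h
    g[-length(phi)] <- g[-length(phi)] - d / h
    x <- sum(cos(phi)) * h
    y <- sum(sin(phi)) * h
    g + mu * (-2 * x * sin(phi) * h + 2 * y * cos(phi) * h)
  }
  phi <- 0.9 * 2 * pi * (seq_len(n) - 0.5) / n
  for (mu in c(1e2, 1e4, 1e6, 1e8)) {
    phi <- stats::optim(phi, efun, gfun, mu = mu, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))$par
  }
  sum(diff(phi)^2) / (2 * h)
}

# Mean cosine of the bend angle between successive segments of a discrete
# wormlike chain with joint measure p(cos t) ~ exp(k cos t): the Langevin
# function relation <cos> = coth(k) - 1/k.
wlc_mean_cos <- function(kappa) 1 / tanh(kappa) - 1 / kappa

# Mean squared end-to-end distance of a freely rotating / discrete wormlike
# chain of n segments of length l with per-joint mean cosine c.
wlc_r2 <- function(n, l, c) {
  l^2 * (n * (1 + c) / (1 - c) - 2 * c * (1 - c^n) / (1 - c)^2)
}

# Gaussian-chain estimate of the capture J factor in mol/L: probability of
# the ends lying within a ball of radius a, for end-to-end variance <R^2>.
gaussian_j_capture <- function(r2, a_nm) {
  avogadro <- 6.02214076e23
  p <- (3 / (2 * pi * r2))^1.5 * 4 / 3 * pi * a_nm^3
  vol_L <- 4 / 3 * pi * a_nm^3 * 1e-24
  p / (vol_L * avogadro)
}

# default parameter set used by many geometry tests
test_params <- function(n_bp = 105, ...) dna_params(n_bp, ...)
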