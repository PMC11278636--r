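# Independent oracles used across the suite. These deliberately avoid the
# package's own estimator/transform code paths.

# O(N^2) time-and-ensemble averaged MSD (x: vector or time-by-particle matrix)
brute_msd <- function(x, lags) {
  M <- if (is.null(dim(x))) matrix(x, ncol = 1) else x
  n <- nrow(M)
  vapply(lags, function(l) {
    if (l == 0) return(0)
    acc <- 0
    cnt <- 0
    for (p in seq_len(ncol(M))) {
      for (t0 in seq_len(n - l)) {
        acc <- acc + (M[t0 + l, p] - M[t0, p])^2
        cnt <- cnt + 1
      }
    }
    acc / cnt
  }, 0)
}

brute_acf <- function(x, lags) {
  M <- if (is.null(dim(x))) matrix(x, ncol = 1) else x
  n <- nrow(M)
  m2 <- mean(M^2)
  vapply(lags, function(l) {
    acc <- 0
    cnt <- 0
    for (p in seq_len(ncol(M))) {
      for (t0 in seq_len(n - l)) {
        acc <- acc + M[t0, p] * M[t0 + l, p]
        cnt <- cnt + 1
      }
    }
    acc / cnt / m2
  }, 0)
}

# central finite-difference gradient of the trap potential
halo_potential <- function(pos, geometry) {
  rho <- sqrt(pos[1]^2 + pos[2]^2)
  0.5 * geometry$kappa_r * (rho - geometry$major_R)^2 +
    0.5 * geometry$kappa_z * pos[3]^2
}

num_force <- function(pos, geometry, h = 1e-6) {
  -vapply(1:3, function(i) {
    hp <- hm <- pos
    hi <- h * max(1, abs(pos[i]))
    hp[i] <- pos[i] + hi
    hm[i] <- pos[i] - hi
    (halo_potential(hp, geometry) - halo_potential(hm, geometry)) / (2 * hi)
  }, 0)
}

# unilateral Fourier transform by adaptive quadrature (decaying integrands);
# a finite upper limit well past the decay gives better oscillatory accuracy
# than the semi-infinite transform
ft_quadrature <- function(f, omega, upper = Inf) {
  vapply(omega, function(w) {
    re <- stats::integrate(function(t) f(t) * cos(w * t), 0, upper,
                           rel.tol = 1e-12, subdivisions = 20000L)$value
    im <- stats::integrate(function(t) -f(t) * sin(w * t), 0, upper,
                           rel.tol = 1e-12, subdivisions = 20000L)$value
    complex(real = re, imaginary = im)
  }, complex(1))
}

# time-domain NPAF of one confined coordinate (stiffness k_hat, in radial
# units) of the Jeffreys embedding: the (u, Q) pair is linear with drift
# matrix M and stationary covariance diag(1/k, 1/q); the lagged
# autocorrelation is [exp(M tau)]_{11}, evaluated by eigendecomposition.
jeffreys_npaf_time <- function(k_hat, q, De, tau) {
  M <- matrix(c(-k_hat, -k_hat, -q, -q * (De + 1) / De), nrow = 2)
  ev <- eigen(M)
  Vi <- solve(ev$vectors)
  sapply(tau, function(s) {
    Re(sum(ev$vectors[1, ] * exp(ev$values * s) * Vi[, 1]))
  })
}

# shared SI reference context (water, micron bead, kappa_r = 1e-6 N/m)
ref_si <- list(kappa_r = 1e-6, a = 1e-6, temperature = 298, eta1 = 1e-3)
ref_particle <- function() probe_particle(ref_si$a, ref_si$temperature)
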