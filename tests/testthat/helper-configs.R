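# Shared helpers: small hand-built configurations and cached simulation runs.

# Two particles at separation r along +x in a large box, with orientations
# that point one patch of each at the other ("aligned") or away
# ("anti-aligned").
two_particle_config <- function(s1 = "P", s2 = "P", r = 1.2,
                                aligned = TRUE, L = 10) {
  tet1 <- c(1, 1, 1) / sqrt(3)
  zhat <- c(0, 0, 1)
  xhat <- c(1, 0, 0)
  face <- function(species, dir) {
    ref <- if (species == "P") tet1 else zhat
    quat_from_vectors(ref, dir)
  }
  q1 <- face(s1, if (aligned) xhat else -xhat)
  q2 <- face(s2, if (aligned) -xhat else xhat)
  configuration(tibble::tibble(
    species = c(s1, s2),
    x = c(2, 2 + r), y = c(2, 2), z = c(2, 2),
    qw = c(q1[1], q2[1]), qx = c(q1[2], q2[2]),
    qy = c(q1[3], q2[3]), qz = c(q1[4], q2[4])
  ), box_edge = L)
}

# Synthetic sample stream with prescribed per-box densities (gaussian noise
# on particle-count-at-fixed-volume), for labeling/binodal tests that must
# not depend on a simulation.
fake_samples <- function(n = 100, nP_I = 20, nP_II = 150, nR_I = 0, nR_II = 0,
                         vol = 320, noise = 2, seed = 1) {
  set.seed(seed)
  jitter <- function(mu) pmax(0, round(mu + noise * rnorm(n)))
  s <- tibble::tibble(
    cycle = seq_len(n),
    n_P_I = jitter(nP_I), n_R_I = jitter(nR_I), volume_I = vol,
    energy_I = 0, n_PP_I = 0, n_PR_I = 0, n_RR_I = 0,
    n_P_II = jitter(nP_II), n_R_II = jitter(nR_II), volume_II = vol,
    energy_II = 0, n_PP_II = 0, n_PR_II = 0, n_RR_II = 0
  )
  dplyr::mutate(s,
    rho_P_I = n_P_I / volume_I, rho_R_I = n_R_I / volume_I,
    rho_P_II = n_P_II / volume_II, rho_R_II = n_R_II / volume_II)
}

# Crude integrated-autocorrelation correction for the s.e. of a mean of an
# autocorrelated sample stream.
effective_n <- function(x, max_lag = 50) {
  n <- length(x)
  x <- x - mean(x)
  v <- sum(x^2) / n
  if (v == 0) return(n)
  rho_sum <- 0
  for (lag in seq_len(min(max_lag, n - 1))) {
    r <- sum(x[1:(n - lag)] * x[(1 + lag):n]) / n / v
    if (r < 0.05) break
    rho_sum <- rho_sum + r
  }
  max(4, n / (1 + 2 * rho_sum))
}

# Cache of the desk-scale Gibbs runs shared across acceptance criteria so
# each state point is simulated once per test session.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}
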