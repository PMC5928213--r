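# Deterministic fixtures and deliberately naive brute-force oracles. The
# oracles re-implement the pair law from its definition (explicit double loop
# over all patch pairs, quaternion rotation by the sandwich formula) and
# share no code with the production path, so a shared bug cannot hide.

# Independent quaternion rotation: v' = v + 2 w (u x v) + 2 u x (u x v),
# with q = (w, u).
oracle_rotate <- function(q, v) {
  w <- q[1]; u <- q[2:4]
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  uv <- cross(u, v)
  v + 2 * w * uv + 2 * cross(u, uv)
}

oracle_patches <- function(species, q, params) {
  m <- if (species == "P") params$m_P else params$m_R
  ref <- ref_dirs_m(m)
  t(apply(ref, 1, function(v) oracle_rotate(q, v)))
}

# Full pair evaluation: returns "overlap", "bond" or "none".
oracle_pair <- function(ri, rj, si, sj, qi, qj, L, params) {
  d <- rj - ri
  if (L > 0) d <- d - L * round(d / L)
  r <- sqrt(sum(d^2))
  if (r <= params$sigma) return("overlap")
  if (r > params$sigma + params$lam) return("none")
  rhat <- d / r
  ni <- oracle_patches(si, qi, params)
  nj <- oracle_patches(sj, qj, params)
  ci <- if (si == "P") params$cos_theta_P else params$cos_theta_R
  cj <- if (sj == "P") params$cos_theta_P else params$cos_theta_R
  for (a in seq_len(nrow(ni))) {
    for (b in seq_len(nrow(nj))) {
      if (sum(rhat * ni[a, ]) > ci && sum(-rhat * nj[b, ]) > cj) {
        return("bond")
      }
    }
  }
  "none"
}

#' Brute-force total energy (testing oracle)
#'
#' Direct O(N^2) double loop over all particle pairs and all patch pairs
#' under the minimum image; no caching, no factorization of the bond
#' condition. Returns the `+Inf` overlap sentinel if any pair overlaps.
#'
#' @param config A [configuration()].
#' @param params A [model_params()].
#' @return Total energy.
#' @export
brute_force_energy <- function(config, params = model_params()) {
  p <- config$particles
  n <- nrow(p)
  if (n < 2) return(0)
  L <- config$box_edge
  # tally bonded pairs by species pair, then multiply: the total is an exact
  # integer combination of the well depths, so equality with the production
  # path is exact, not approximate
  npair <- c(PP = 0, PR = 0, RR = 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      res <- oracle_pair(
        c(p$x[i], p$y[i], p$z[i]), c(p$x[j], p$y[j], p$z[j]),
        p$species[i], p$species[j],
        c(p$qw[i], p$qx[i], p$qy[i], p$qz[i]),
        c(p$qw[j], p$qx[j], p$qy[j], p$qz[j]), L, params)
      if (res == "overlap") return(Inf)
      if (res == "bond") {
        k <- paste0(sort(c(p$species[i], p$species[j])), collapse = "")
        npair[k] <- npair[k] + 1
      }
    }
  }
  -(npair[["PP"]] * params$eps_PP + npair[["PR"]] * params$eps_PR +
      npair[["RR"]] * params$eps_RR)
}

#' Brute-force per-particle bond counts (testing oracle)
#'
#' @inheritParams brute_force_energy
#' @param energetic_only Count only species pairs with positive well depth.
#' @return Tibble `id`, `species`, `n_P_partners`, `n_R_partners`, `n_bonds`.
#' @export
brute_force_bond_counts <- function(config, params = model_params(),
                                    energetic_only = TRUE) {
  p <- config$particles
  n <- nrow(p)
  L <- config$box_edge
  nP <- integer(n); nR <- integer(n)
  eps <- function(si, sj) {
    k <- paste0(sort(c(si, sj)), collapse = "")
    switch(k, PP = params$eps_PP, PR = params$eps_PR, RR = params$eps_RR)
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        res <- oracle_pair(
          c(p$x[i], p$y[i], p$z[i]), c(p$x[j], p$y[j], p$z[j]),
          p$species[i], p$species[j],
          c(p$qw[i], p$qx[i], p$qy[i], p$qz[i]),
          c(p$qw[j], p$qx[j], p$qy[j], p$qz[j]), L, params)
        if (res == "bond") {
          if (energetic_only && eps(p$species[i], p$species[j]) <= 0) next
          if (p$species[j] == "P") nP[i] <- nP[i] + 1L else nR[i] <- nR[i] + 1L
          if (p$species[i] == "P") nP[j] <- nP[j] + 1L else nR[j] <- nR[j] + 1L
        }
      }
    }
  }
  tibble::tibble(id = seq_len(n), species = p$species,
                 n_P_partners = nP, n_R_partners = nR, n_bonds = nP + nR)
}

particle_row <- function(species, pos, q) {
  tibble::tibble(species = species, x = pos[1], y = pos[2], z = pos[3],
                 qw = q[1], qx = q[2], qy = q[3], qz = q[4])
}

# FCC fragment of 16 sites (2 x 2 x 1 conventional cells), nearest-neighbour
# distance `nn`.
fcc_fragment_16 <- function(nn = 1.2) {
  a <- nn * sqrt(2)
  base <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  cells <- expand.grid(i = 0:1, j = 0:1, k = 0)
  pos <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    sweep(base, 2, as.numeric(cells[r, ]), "+")
  }))
  pos * a
}

#' Hand-built deterministic fixtures
#'
#' Small named configurations with known observables, used as documentation
#' examples and as anchors for the oracle tests. The `expected` map is
#' regenerated from the brute-force oracle at construction, so it is exact
#' by definition.
#'
#' Available fixtures:
#' \describe{
#'   \item{dimer_PP}{Two P particles at distance 1.2 with mutually facing
#'     patches: energy -1, one bond each.}
#'   \item{trimer_PPR}{A central P bonded to one P (along x) and one R
#'     (along y) with `eps_PR = 0.5`: energy -1.5.}
#'   \item{square_well_limit}{Full patch coverage (`chi = 1`, two polar
#'     patches per species): the interaction reduces to a plain isotropic
#'     square well.}
#'   \item{dense_lattice_16}{16 P on an FCC fragment with all nearest
#'     neighbours in-well and patch-aligned (identity orientations: the
#'     tetrahedral patch directions face the 12 FCC neighbour directions
#'     within the patch half-angle at chi = 0.7).}
#'   \item{ideal_gas_box}{Random particles with all well depths zero:
#'     energy 0, no bonds.}
#' }
#'
#' @param name Fixture name.
#' @return List with elements `name`, `config`, `params`, `expected` (named
#'   list of observable values).
#' @export
make_fixture <- function(name = c("dimer_PP", "trimer_PPR",
                                  "square_well_limit", "dense_lattice_16",
                                  "ideal_gas_box")) {
  name <- match.arg(name)
  xhat <- c(1, 0, 0); yhat <- c(0, 1, 0); zhat <- c(0, 0, 1)
  tet1 <- c(1, 1, 1) / sqrt(3)
  tet2 <- c(1, -1, -1) / sqrt(3)

  fx <- switch(name,
    dimer_PP = {
      params <- model_params()
      q1 <- quat_from_vectors(tet1, xhat)
      q2 <- quat_from_vectors(tet1, -xhat)
      cfg <- configuration(rbind(
        particle_row("P", c(2, 2, 2), q1),
        particle_row("P", c(3.2, 2, 2), q2)
      ), box_edge = 10)
      list(config = cfg, params = params)
    },
    trimer_PPR = {
      params <- model_params(eps_PR = 0.5)
      # central P: patches 1 and 2 rotated into the xy-plane, symmetric
      # about the x=y diagonal, so one faces +x and the other +y within
      # the patch half-angle
      half <- acos(-1 / 3) / 2
      u1 <- c(cos(pi / 4 - half), sin(pi / 4 - half), 0)
      u2 <- c(cos(pi / 4 + half), sin(pi / 4 + half), 0)
      q0 <- quat_from_pair_alignment(tet1, tet2, u1, u2)
      qx_ <- quat_from_vectors(tet1, -xhat)
      qy_ <- quat_from_vectors(zhat, -yhat)
      cfg <- configuration(rbind(
        particle_row("P", c(3, 3, 3), q0),
        particle_row("P", c(4.2, 3, 3), qx_),
        particle_row("R", c(3, 4.2, 3), qy_)
      ), box_edge = 10)
      list(config = cfg, params = params)
    },
    square_well_limit = {
      params <- model_params(chi = 1, m_P = 2, m_R = 2)
      set.seed(421)
      q <- random_quaternion(2)
      cfg <- configuration(rbind(
        particle_row("P", c(2, 2, 2), q[1, ]),
        particle_row("P", c(2, 2, 3.3), q[2, ])
      ), box_edge = 8)
      list(config = cfg, params = params)
    },
    dense_lattice_16 = {
      params <- model_params()
      pos <- fcc_fragment_16(1.2) + 2
      rows <- lapply(seq_len(nrow(pos)), function(i) {
        particle_row("P", pos[i, ], c(1, 0, 0, 0))
      })
      cfg <- configuration(do.call(rbind, rows), box_edge = 12)
      list(config = cfg, params = params)
    },
    ideal_gas_box = {
      params <- model_params(eps_PP = 0, eps_PR = 0, eps_RR = 0)
      set.seed(422)
      cfg <- random_configuration(10, 5, 6, params)
      list(config = cfg, params = params)
    }
  )

  counts <- brute_force_bond_counts(fx$config, fx$params)
  fx$expected <- list(
    energy = brute_force_energy(fx$config, fx$params),
    total_bonds = sum(counts$n_bonds) / 2,
    bonds_per_particle = counts$n_bonds
  )
  fx$name <- name
  fx
}

#' Generate a synthetic binodal from the rectilinear-diameter law
#'
#' Inverts the diameter and width laws into coexistence-density pairs on a
#' temperature grid, optionally with multiplicative Gaussian noise. Used to
#' test critical-point fitting round trips.
#'
#' @param T_c,rho_c,A,B Generating parameters: critical temperature and
#'   density, diameter slope, width amplitude.
#' @param T_grid Temperatures, all strictly below `T_c`.
#' @param noise Multiplicative Gaussian noise level (0 = exact).
#' @param seed Optional seed for the noise.
#' @return Binodal tibble compatible with [fit_critical_point()].
#' @export
synthetic_binodal <- function(T_c, rho_c, A, B, T_grid, noise = 0,
                              seed = NULL) {
  stopifnot(noise >= 0, B >= 0)
  if (any(T_grid >= T_c)) {
    stop("all grid temperatures must lie strictly below T_c")
  }
  if (!is.null(seed)) set.seed(seed)
  mid <- rho_c + A * (T_grid - T_c)
  width <- B * (T_c - T_grid)^CRITICAL_EXPONENT
  rI <- mid - width / 2
  rII <- mid + width / 2
  if (noise > 0) {
    rI <- rI * (1 + noise * rnorm(length(rI)))
    rII <- rII * (1 + noise * rnorm(length(rII)))
  }
  tibble::tibble(
    temperature = T_grid,
    rho_P_I = rI, rho_P_I_se = noise * abs(rI),
    rho_P_II = rII, rho_P_II_se = noise * abs(rII),
    rho_R_I = 0, rho_R_I_se = 0, rho_R_II = 0, rho_R_II_se = 0,
    rho_I = rI, rho_II = rII,
    coexistence = TRUE, n_samples = NA_integer_
  )
}
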