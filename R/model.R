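# Two-species Kern-Frenkel patchy-particle model: a four-patch "protein" (P)
# with tetrahedrally arranged patches and a two-patch "regulator" (R) with
# polar patches. All lengths are in units of the hard-core diameter sigma and
# energies in units of the P-P well depth.

#' Cosine of the spanning half-angle of a patch
#'
#' For a species with `m` patches jointly covering a fraction `chi` of the
#' particle surface, each patch is a spherical cap of polar half-angle
#' `theta` with `cos(theta) = 1 - 2 * chi / m`.
#'
#' @param m Number of patches (>= 1).
#' @param chi Total surface coverage fraction, in (0, 1].
#' @return `cos(theta)`, in (-1, 1].
#' @examples
#' patch_cos_half_angle(4, 0.7)  # 0.65
#' patch_cos_half_angle(2, 0.7)  # 0.30
#' @export
patch_cos_half_angle <- function(m, chi) {
  stopifnot(length(m) == 1, length(chi) == 1, m >= 1, m == as.integer(m))
  if (chi <= 0 || chi > 1) stop("chi must lie in (0, 1]")
  ct <- 1 - 2 * chi / m
  if (ct <= -1) {
    stop("patch spanning angle exceeds a hemisphere: 1 - 2*chi/m = ", ct)
  }
  ct
}

# Reference patch frames by valence: 1 = +z, 2 = poles, 3 = equatorial
# triangle, 4 = tetrahedron.
ref_dirs_m <- function(m) {
  s3 <- 1 / sqrt(3)
  switch(as.character(m),
    "1" = matrix(c(0, 0, 1), ncol = 3),
    "2" = rbind(c(0, 0, 1), c(0, 0, -1)),
    "3" = rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0)),
    "4" = rbind(c(s3, s3, s3), c(s3, -s3, -s3), c(-s3, s3, -s3), c(-s3, -s3, s3)),
    stop("unsupported patch count m = ", m, " (allowed: 1-4)")
  )
}

#' Reference patch directions of a species
#'
#' Unit vectors from the particle centre to the patch centres, in the
#' species' body frame. P carries four tetrahedral patches (pairwise dot
#' product -1/3); R carries two polar patches at (0,0,+1) and (0,0,-1).
#'
#' @param species `"P"` or `"R"`.
#' @param params A [model_params()] object (patch counts may be customized).
#' @return m x 3 matrix of unit row vectors.
#' @export
reference_patch_directions <- function(species = c("P", "R"),
                                       params = model_params()) {
  species <- match.arg(species)
  ref_dirs_m(if (species == "P") params$m_P else params$m_R)
}

#' Interaction and geometry parameters of the patchy-particle mixture
#'
#' Houses the hard-core diameter, patch coverage, square-well width and the
#' three well depths of the two-species model. Validates that the derived
#' patch half-angles are representable and that patches on one particle do
#' not overlap (the coverage fraction is only meaningful for disjoint caps).
#'
#' @param chi Total patch surface coverage fraction, in (0, 1]. Default 0.7.
#' @param lam Square-well width in units of sigma. Default 0.5.
#' @param eps_PR P-R well depth (units of eps_PP). Default 0.
#' @param eps_RR R-R well depth. Default 0: regulators experience only steric
#'   repulsion between each other.
#' @param eps_PP P-P well depth. Default 1 (the energy unit).
#' @param sigma Hard-core diameter. Default 1 (the length unit). `sigma = 0`
#'   disables the hard core (ideal-gas checks).
#' @param m_P,m_R Patch counts of the two species (1-4). Defaults 4 and 2.
#' @return An object of class `patch_model`: a named list with the fields
#'   above plus derived `cos_theta_P`, `cos_theta_R`.
#' @examples
#' p <- model_params(eps_PR = 0.5)
#' p$cos_theta_P  # 0.65
#' @export
model_params <- function(chi = 0.7, lam = 0.5, eps_PR = 0, eps_RR = 0,
                         eps_PP = 1, sigma = 1, m_P = 4L, m_R = 2L) {
  stopifnot(sigma >= 0, lam > 0, eps_PP >= 0, eps_PR >= 0, eps_RR >= 0)
  m_P <- as.integer(m_P); m_R <- as.integer(m_R)
  ct_P <- patch_cos_half_angle(m_P, chi)
  ct_R <- patch_cos_half_angle(m_R, chi)
  p <- structure(list(
    sigma = sigma, chi = chi, lam = lam,
    m_P = m_P, m_R = m_R,
    eps_PP = eps_PP, eps_PR = eps_PR, eps_RR = eps_RR,
    cos_theta_P = ct_P, cos_theta_R = ct_R
  ), class = "patch_model")
  check_patch_overlap(p)
  p
}

# Reject parameter sets whose patches overlap on a single particle: for every
# pair of patch centres the angular separation must be at least twice the
# spanning half-angle (equality allowed; caps may touch).
check_patch_overlap <- function(p, tol = 1e-9) {
  for (sp in c("P", "R")) {
    m <- if (sp == "P") p$m_P else p$m_R
    if (m < 2) next
    ct <- if (sp == "P") p$cos_theta_P else p$cos_theta_R
    theta <- acos(ct)
    d <- ref_dirs_m(m)
    dots <- tcrossprod(d)
    sep <- acos(pmin(1, pmax(-1, dots[upper.tri(dots)])))
    if (any(sep < 2 * theta - tol)) {
      stop("patches on species ", sp, " overlap: half-angle ",
           signif(theta, 4), " rad exceeds half the minimal separation ",
           signif(min(sep) / 2, 4), " rad")
    }
  }
  invisible(p)
}

#' @export
print.patch_model <- function(x, ...) {
  cat("<patch_model>\n")
  cat(sprintf("  species P: %d patches, cos(theta) = %.4f\n", x$m_P, x$cos_theta_P))
  cat(sprintf("  species R: %d patches, cos(theta) = %.4f\n", x$m_R, x$cos_theta_R))
  cat(sprintf("  chi = %g, lambda = %g sigma, sigma = %g\n", x$chi, x$lam, x$sigma))
  cat(sprintf("  eps_PP = %g, eps_PR = %g, eps_RR = %g\n",
              x$eps_PP, x$eps_PR, x$eps_RR))
  invisible(x)
}

# Marshal params into the flat list the C++ layer expects.
params_cpp <- function(p) {
  list(sigma = p$sigma, lam = p$lam, eps_PP = p$eps_PP, eps_PR = p$eps_PR,
       eps_RR = p$eps_RR, cos_theta_P = p$cos_theta_P,
       cos_theta_R = p$cos_theta_R, m_P = p$m_P, m_R = p$m_R)
}

#' Build a simulation-cell configuration
#'
#' A configuration is a cubic periodic box of patchy particles. Particles are
#' held as a tibble with one row per particle: `species` ("P"/"R"),
#' positions `x, y, z` (wrapped into `[0, box_edge)`) and orientation
#' quaternion `qw, qx, qy, qz` (unit norm within 1e-9).
#'
#' @param particles Data frame with columns `species`, `x`, `y`, `z`,
#'   `qw`, `qx`, `qy`, `qz`.
#' @param box_edge Cubic box edge length.
#' @return An object of class `patch_config` with elements `particles`
#'   (tibble) and `box_edge`.
#' @export
configuration <- function(particles, box_edge) {
  stopifnot(is.data.frame(particles), box_edge > 0)
  need <- c("species", "x", "y", "z", "qw", "qx", "qy", "qz")
  missing <- setdiff(need, names(particles))
  if (length(missing)) stop("particles lacks columns: ", paste(missing, collapse = ", "))
  particles <- tibble::as_tibble(particles)[need]
  if (!all(particles$species %in% c("P", "R"))) {
    stop("species must be \"P\" or \"R\"")
  }
  qn <- sqrt(particles$qw^2 + particles$qx^2 + particles$qy^2 + particles$qz^2)
  if (any(abs(qn - 1) > 1e-9)) {
    stop("orientation quaternions must have unit norm (tolerance 1e-9)")
  }
  for (cc in c("x", "y", "z")) {
    v <- particles[[cc]] %% box_edge
    v[v == box_edge] <- 0
    particles[[cc]] <- v
  }
  structure(list(particles = particles, box_edge = box_edge),
            class = "patch_config")
}

#' @export
print.patch_config <- function(x, ...) {
  n <- nrow(x$particles)
  nP <- sum(x$particles$species == "P")
  cat(sprintf("<patch_config> %d particles (%d P, %d R), box edge %.4g\n",
              n, nP, n - nP, x$box_edge))
  invisible(x)
}

# Internal: configuration -> (int species, pos matrix, quat matrix)
config_matrices <- function(config) {
  p <- config$particles
  list(sp = as.integer(p$species == "R"),
       pos = cbind(p$x, p$y, p$z),
       quat = cbind(p$qw, p$qx, p$qy, p$qz))
}

#' Is a particle pair bonded?
#'
#' Geometric Kern-Frenkel bond criterion under the minimum image: the pair
#' distance lies in the square well and some patch on each particle faces the
#' other (`rhat . n_i > cos(theta_i)` and `-rhat . n_j > cos(theta_j)`). A
#' pair is bonded or not as a whole: multiple aligned patch pairs still count
#' as one bond.
#'
#' @param config A [configuration()].
#' @param i,j Particle indices (1-based).
#' @param params A [model_params()].
#' @return Logical. `FALSE` for overlapping or out-of-range pairs.
#' @export
is_bonded <- function(config, i, j, params = model_params()) {
  m <- config_matrices(config)
  res <- cpp_pair_energy(params_cpp(params), m$sp[i], m$sp[j],
                         m$pos[i, ], m$pos[j, ], m$quat[i, ], m$quat[j, ],
                         config$box_edge)
  isTRUE(res$bonded)
}

#' Pair interaction energy
#'
#' Directional square well: `+Inf` (overlap sentinel) for `r <= sigma`,
#' `-eps_ij` when the pair is in the well and bonded, else 0. The well depth
#' is selected by the species pair (PP / PR / RR).
#'
#' @inheritParams is_bonded
#' @return Energy value in `{Inf, -eps_ij, 0}`.
#' @export
pair_energy <- function(config, i, j, params = model_params()) {
  m <- config_matrices(config)
  res <- cpp_pair_energy(params_cpp(params), m$sp[i], m$sp[j],
                         m$pos[i, ], m$pos[j, ], m$quat[i, ], m$quat[j, ],
                         config$box_edge)
  res$energy
}

#' Total potential energy of a configuration
#'
#' Sum of the directional square-well pair energies over all unordered pairs
#' under the minimum-image convention; an exact integer combination of the
#' well depths. Returns the `+Inf` overlap sentinel if any pair overlaps.
#'
#' @param config A [configuration()].
#' @param params A [model_params()].
#' @return Total energy (scalar).
#' @export
total_energy <- function(config, params = model_params()) {
  m <- config_matrices(config)
  res <- cpp_box_tallies(params_cpp(params), m$sp, m$pos, m$quat,
                         config$box_edge)
  res$energy
}

#' Random non-overlapping configuration by sequential insertion
#'
#' Places particles one at a time at uniform positions with uniform random
#' orientations, retrying on hard-core overlap. Fails fast when the density
#' is too high for naive insertion.
#'
#' @param n_P,n_R Particle counts of each species.
#' @param box_edge Cubic box edge.
#' @param params A [model_params()].
#' @param max_tries Insertion retry budget per particle.
#' @return A [configuration()]. Draws from R's RNG stream; seed with
#'   [set.seed()] for reproducibility.
#' @export
random_configuration <- function(n_P, n_R, box_edge, params = model_params(),
                                 max_tries = 1e4) {
  n <- n_P + n_R
  species <- c(rep("P", n_P), rep("R", n_R))
  pos <- matrix(NA_real_, n, 3)
  s2 <- params$sigma^2
  L <- box_edge
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- runif(3) * L
      if (i > 1 && s2 > 0) {
        d <- sweep(pos[seq_len(i - 1), , drop = FALSE], 2, cand)
        d <- d - L * round(d / L)
        if (min(rowSums(d^2)) <= s2) next
      }
      pos[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("sequential insertion failed at particle ", i, " of ", n,
           ": density too high for naive insertion; grow from dilute instead")
    }
  }
  q <- random_quaternion(n)
  configuration(tibble::tibble(
    species = species, x = pos[, 1], y = pos[, 2], z = pos[, 3],
    qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4]
  ), box_edge = L)
}
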