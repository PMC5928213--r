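# Droplet-phase bond-network statistics. A "bond" is the geometric
# patch-contact condition; in reports only species pairs with a positive well
# depth count (with eps_RR = 0 an R particle can only have P partners, so
# R-R patch contacts do not stabilize the network and are excluded).

#' Bonded particle pairs of a configuration
#'
#' @param config A [configuration()].
#' @param params A [model_params()].
#' @param energetic_only Drop pairs whose species combination has zero well
#'   depth (default; the reported bonding convention). Set `FALSE` for the
#'   raw geometric contacts.
#' @return Tibble with columns `i`, `j` (1-based indices, `i < j`),
#'   `species_i`, `species_j`.
#' @export
bond_pairs <- function(config, params = model_params(), energetic_only = TRUE) {
  m <- config_matrices(config)
  pr <- cpp_bond_pairs(params_cpp(params), m$sp, m$pos, m$quat,
                       config$box_edge, isTRUE(energetic_only))
  sp <- config$particles$species
  tibble::tibble(
    i = if (nrow(pr)) pr[, 1] else integer(),
    j = if (nrow(pr)) pr[, 2] else integer(),
    species_i = sp[pr[, 1]],
    species_j = sp[pr[, 2]]
  )
}

#' Per-particle bond counts split by partner species
#'
#' For every particle, the number of distinct bonded partner particles of
#' each species (a pair contributes at most one bond however many patch
#' pairs align).
#'
#' @inheritParams bond_pairs
#' @return Tibble with one row per particle: `id`, `species`,
#'   `n_P_partners`, `n_R_partners`, `n_bonds`.
#' @export
count_bonds <- function(config, params = model_params(), energetic_only = TRUE) {
  n <- nrow(config$particles)
  pr <- bond_pairs(config, params, energetic_only)
  nP <- integer(n); nR <- integer(n)
  if (nrow(pr)) {
    pP <- c(pr$i[pr$species_j == "P"], pr$j[pr$species_i == "P"])
    pR <- c(pr$i[pr$species_j == "R"], pr$j[pr$species_i == "R"])
    tp <- tabulate(pP, nbins = n)
    tr <- tabulate(pR, nbins = n)
    nP <- tp; nR <- tr
  }
  tibble::tibble(
    id = seq_len(n),
    species = config$particles$species,
    n_P_partners = nP,
    n_R_partners = nR,
    n_bonds = nP + nR
  )
}

#' Connected components of the bond graph
#'
#' Clusters of particles connected through bonded pairs; isolated particles
#' form singleton clusters. Cluster labels are ordered by decreasing size.
#'
#' @inheritParams bond_pairs
#' @return Tibble with one row per particle: `id`, `species`, `cluster`.
#'   The attribute `"summary"` holds a per-cluster tibble
#'   (`cluster`, `size`, `n_P`, `n_R`).
#' @export
extract_clusters <- function(config, params = model_params(),
                             energetic_only = TRUE) {
  n <- nrow(config$particles)
  pr <- bond_pairs(config, params, energetic_only)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(pr)) {
    g <- igraph::add_edges(g, rbind(pr$i, pr$j))
  }
  comp <- igraph::components(g)
  # relabel by decreasing size, ties by first member
  ord <- order(-comp$csize, match(seq_along(comp$csize), comp$membership))
  relabel <- match(comp$membership, ord)
  out <- tibble::tibble(
    id = seq_len(n),
    species = config$particles$species,
    cluster = relabel
  )
  summary <- out |>
    dplyr::count(.data$cluster, .data$species) |>
    tidyr::pivot_wider(names_from = "species", values_from = "n",
                       values_fill = 0L)
  for (sp in c("P", "R")) {
    if (!sp %in% names(summary)) summary[[sp]] <- 0L
  }
  summary <- summary |>
    dplyr::transmute(.data$cluster, size = .data$P + .data$R,
                     n_P = .data$P, n_R = .data$R) |>
    dplyr::arrange(.data$cluster)
  attr(out, "summary") <- summary
  out
}

#' Export bonding clusters as JSON adjacency lists
#'
#' Raw cluster data for external rendering: per cluster, the member particle
#' ids with species, and the bonded-pair adjacency list.
#'
#' @inheritParams bond_pairs
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(config, params = model_params(), path,
                                energetic_only = TRUE) {
  cl <- extract_clusters(config, params, energetic_only)
  pr <- bond_pairs(config, params, energetic_only)
  clusters <- lapply(split(cl, cl$cluster), function(d) {
    edges <- pr[pr$i %in% d$id, c("i", "j")]
    list(members = d$id, species = d$species,
         bonds = unname(as.matrix(edges)))
  })
  jsonlite::write_json(clusters, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Per-sample bond observables of one labeled phase, from engine tallies.
# Columns in `d` must be n_P, n_R, n_PP, n_PR, n_RR (that phase's counts)
# plus rho_P, rho_R. eps filtering implements the reporting convention.
sample_bond_stats <- function(d, params) {
  wPP <- as.numeric(params$eps_PP > 0)
  wPR <- as.numeric(params$eps_PR > 0)
  wRR <- as.numeric(params$eps_RR > 0)
  bPP <- wPP * d$n_PP
  bPR <- wPR * d$n_PR
  bRR <- wRR * d$n_RR
  n <- d$n_P + d$n_R
  tibble::tibble(
    n_b = ifelse(n > 0, 2 * (bPP + bPR + bRR) / n, NA_real_),
    n_bP = ifelse(d$n_P > 0, (2 * bPP + bPR) / d$n_P, NA_real_),
    n_bPP = ifelse(d$n_P > 0, 2 * bPP / d$n_P, NA_real_),
    n_bPR = ifelse(d$n_P > 0, bPR / d$n_P, NA_real_),
    n_bR = ifelse(d$n_R > 0, (bPR + 2 * bRR) / d$n_R, NA_real_),
    rho_P = d$rho_P,
    rho_R = d$rho_R,
    r_fraction = ifelse(d$rho_P + d$rho_R > 0,
                        d$rho_R / (d$rho_P + d$rho_R), NA_real_)
  )
}

block_se <- function(x, n_blocks = 10) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < n_blocks) return(NA_real_)
  blk <- split(x, cut(seq_len(n), n_blocks, labels = FALSE))
  means <- vapply(blk, mean, numeric(1))
  sd(means) / sqrt(length(means))
}

#' Time-averaged bond report for one phase of a sample stream
#'
#' Computes the mean bonds per particle `n_b`, its decomposition by species
#' (`n_bP`, `n_bR`) and by partner type (`n_bPP`, `n_bPR`), the phase's
#' species densities and the regulator molar fraction, with standard errors
#' by block averaging over consecutive sample blocks. Per sample, `n_b` is
#' the density-weighted average of `n_bP` and `n_bR` and
#' `n_bP = n_bPP + n_bPR`; both identities hold exactly by construction.
#'
#' @param samples Samples tibble from [run_gibbs()] (or any data frame with
#'   the same per-box columns).
#' @param params The [model_params()] of the run (selects which species
#'   pairs count as bonds: only pairs with positive well depth).
#' @param phase `"dense"` (default; the droplet phase, higher total density
#'   per sample) or `"dilute"`.
#' @param n_blocks Number of blocks for the standard errors.
#' @return One-row tibble: `n_b`, `n_bP`, `n_bPP`, `n_bPR`, `n_bR`,
#'   `rho_P`, `rho_R`, `r_fraction`, each with a `*_se` companion, plus
#'   `n_samples`. Species-specific fields are `NA` when the phase holds no
#'   particle of that species.
#' @export
bond_report <- function(samples, params, phase = c("dense", "dilute"),
                        n_blocks = 10) {
  phase <- match.arg(phase)
  if (nrow(samples) < 30) {
    warning("fewer than 30 samples; bond report will be noisy")
  }
  lab <- split_phases(samples)
  d <- if (phase == "dense") lab$dense else lab$dilute
  per <- sample_bond_stats(d, params)
  vars <- c("n_b", "n_bP", "n_bPP", "n_bPR", "n_bR", "rho_P", "rho_R",
            "r_fraction")
  out <- list()
  for (v in vars) {
    out[[v]] <- mean(per[[v]], na.rm = TRUE)
    out[[paste0(v, "_se")]] <- block_se(per[[v]], n_blocks)
  }
  out$n_samples <- nrow(per)
  if (all(is.na(per$n_bR))) {
    out$n_bR <- NA_real_
    out$n_bR_se <- NA_real_
  }
  tibble::as_tibble(out)
}
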