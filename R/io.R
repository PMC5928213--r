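# Serialization: configurations as an extended-XYZ dialect (species tag,
# position, orientation quaternion; box edge on the comment line), sample
# streams as TSV, run manifests as JSON, run configs as YAML.

fnv1a <- function(s) {
  # tiny content hash for manifests; not cryptographic. 32-bit state kept in
  # doubles, split into 16-bit halves (bitwXor/`*` overflow above 2^31/2^53).
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    lo <- h %% 65536; hi <- h %/% 65536
    h <- hi * 65536 + bitwXor(lo, b)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * p + (hi * p %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

params_hash <- function(params) {
  fnv1a(paste(unlist(params[c("sigma", "chi", "lam", "m_P", "m_R",
                              "eps_PP", "eps_PR", "eps_RR")]),
              collapse = ","))
}

#' Write a configuration as extended XYZ
#'
#' One atom line per particle: species tag (P/R), position and orientation
#' quaternion, at 17 significant digits so the round trip through
#' [read_xyz()] is bit-exact. The comment line carries the box edge and a
#' parameter content hash.
#'
#' @param config A [configuration()].
#' @param path Output path.
#' @param params Optional [model_params()] whose hash is recorded.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(config, path, params = NULL) {
  p <- config$particles
  header <- sprintf("box_edge=%.17g%s", config$box_edge,
                    if (is.null(params)) ""
                    else paste0(" params_hash=", params_hash(params)))
  lines <- c(
    as.character(nrow(p)),
    header,
    sprintf("%s %.17g %.17g %.17g %.17g %.17g %.17g %.17g",
            p$species, p$x, p$y, p$z, p$qw, p$qx, p$qy, p$qz)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an extended-XYZ configuration
#'
#' @param path File written by [write_xyz()].
#' @return A [configuration()]. The parameter hash, when present, is
#'   attached as attribute `"params_hash"`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  header <- lines[2]
  be <- regmatches(header, regexec("box_edge=([^ ]+)", header))[[1]][2]
  if (is.na(be)) stop("missing box_edge in XYZ comment line")
  hash <- regmatches(header, regexec("params_hash=([0-9a-f]+)", header))[[1]][2]
  fields <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  m <- do.call(rbind, lapply(fields, function(f) as.numeric(f[-1])))
  cfg <- configuration(tibble::tibble(
    species = vapply(fields, `[[`, character(1), 1),
    x = m[, 1], y = m[, 2], z = m[, 3],
    qw = m[, 4], qx = m[, 5], qy = m[, 6], qz = m[, 7]
  ), box_edge = as.numeric(be))
  if (!is.na(hash)) attr(cfg, "params_hash") <- hash
  cfg
}

#' Write a sample stream as TSV
#'
#' @param run A `gibbs_run` (or its samples tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples_tsv <- function(run, path) {
  s <- if (inherits(run, "gibbs_run")) run$samples else run
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV sample stream
#'
#' @param path File written by [write_samples_tsv()].
#' @return Samples tibble.
#' @export
read_samples_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE))
}

#' Write a JSON run manifest
#'
#' Full echo of the run inputs (model, system, schedule, cycles, seed),
#' acceptance summary and a content hash, for provenance tracking of sweep
#' outputs.
#'
#' @param run A `gibbs_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(run, path) {
  inp <- run$inputs
  manifest <- list(
    model = unclass(inp$params),
    system = list(n_P = inp$n_P, n_R = inp$n_R, rho0 = inp$rho0,
                  temperature = inp$temperature,
                  X = if (inp$n_P > 0) inp$n_R / inp$n_P else NA),
    schedule = unclass(inp$schedule),
    run = list(n_equil = inp$n_equil, n_collect = inp$n_collect,
               sample_stride = inp$sample_stride, seed = inp$seed),
    acceptance = as.list(setNames(run$acceptance$rate, run$acceptance$move)),
    n_samples = nrow(run$samples)
  )
  manifest$content_hash <- fnv1a(jsonlite::toJSON(manifest, digits = NA))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Expects the sections `model` (chi, lam, eps_PP, eps_PR, eps_RR, sigma),
#' `system` (n_total, X, rho0, temperature), `schedule` (attempt counts and
#' step sizes) and `run` (n_equil, n_collect, sample_stride, seed). All
#' physics keys are required; there are no silent defaults.
#'
#' @param path YAML file path.
#' @return List with `params` ([model_params()]), `system`, `schedule`
#'   ([move_schedule()]) and `run` components ready for [run_gibbs()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- function(section, keys) {
    if (is.null(cfg[[section]])) stop("missing config section [", section, "]")
    miss <- setdiff(keys, names(cfg[[section]]))
    if (length(miss)) {
      stop("config section [", section, "] lacks keys: ",
           paste(miss, collapse = ", "))
    }
    cfg[[section]]
  }
  mod <- need("model", c("chi", "lam", "eps_PP", "eps_PR", "eps_RR", "sigma"))
  sys <- need("system", c("n_total", "X", "rho0", "temperature"))
  sch <- need("schedule", c("n_displacement", "n_exchange", "n_volume",
                            "max_translation", "max_rotation",
                            "max_ln_volume_change"))
  run <- need("run", c("n_equil", "n_collect", "sample_stride", "seed"))

  n_R <- round(sys$n_total * sys$X / (1 + sys$X))
  list(
    params = model_params(chi = mod$chi, lam = mod$lam, eps_PP = mod$eps_PP,
                          eps_PR = mod$eps_PR, eps_RR = mod$eps_RR,
                          sigma = mod$sigma),
    system = list(n_P = sys$n_total - n_R, n_R = n_R, rho0 = sys$rho0,
                  temperature = sys$temperature),
    schedule = move_schedule(
      n_displacement = sch$n_displacement, n_exchange = sch$n_exchange,
      n_volume = sch$n_volume, max_translation = sch$max_translation,
      max_rotation = sch$max_rotation,
      max_ln_volume_change = sch$max_ln_volume_change),
    run = run
  )
}
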