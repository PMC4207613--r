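#' Configuration for synthetic-gonad simulation
#'
#' Collects every knob of the generative model in one validated object. The
#' count-level model is: per nucleus, each of `n_chromosome_pairs` receives
#' one crossover-designated focus independently with probability
#' `p_designate` (at most one per pair, encoding chromosome-wide
#' interference); each designated focus matures into a chiasma independently
#' with probability `p_success`; the diakinesis DAPI-body count is
#' `2 * n_chromosome_pairs - matured`, optionally degraded by a touching
#' artifact in which disjoint pairs of bodies are miscounted as one with
#' probability `p_merge` each.
#'
#' @param n_gonads gonads per simulated genotype (default 6, a typical
#'   scoring effort per genotype).
#' @param nuclei_per_gonad nuclei per gonad (default 250, giving zone totals
#'   of a few hundred nuclei across six gonads).
#' @param n_chromosome_pairs default 6, the *C. elegans* karyotype.
#' @param p_designate per-pair probability of crossover designation.
#' @param p_success per-focus maturation probability.
#' @param p_merge probability that a disjoint pair of diakinesis bodies is
#'   counted as one (default 0).
#' @param pairing_curve per-zone probability that a homolog pair is paired;
#'   its length sets the number of zones (default a 5-zone curve rising to
#'   complete pairing, the wild-type autosomal pattern).
#' @param pairing_threshold_um centre-to-centre distance at or below which
#'   two locus signals are scored as paired (default 0.75 um).
#' @param focus_rate_per_zone per-zone Poisson mean of recombination-focus
#'   counts per nucleus (default a 7-zone profile peaking at ~5 in
#'   mid-pachytene).
#' @param nucleus_radius_um nuclear radius for geometry and rendering.
#' @param focus_intensity,nucleus_intensity expected photon counts: peak of
#'   a rendered focus and interior of a rendered nucleus.
#' @param psf_sigma_xy_nm,psf_sigma_z_nm Gaussian point-spread sigmas.
#' @param noise_rate background photon rate per voxel (Poisson).
#' @param voxel_size_nm named numeric `(z, y, x)` voxel size in nm; the
#'   default 125 nm z-spacing matches structured-illumination acquisition.
#' @param seed optional integer seed; when set, every simulation function
#'   seeds R's RNG with it so outputs are reproducible bit-for-bit.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_gonads = 6L, nuclei_per_gonad = 250L,
                       n_chromosome_pairs = 6L,
                       p_designate = 1, p_success = 1, p_merge = 0,
                       pairing_curve = c(0.1, 0.3, 0.6, 0.9, 1.0),
                       pairing_threshold_um = 0.75,
                       focus_rate_per_zone = c(0, 0, 2, 5, 5, 3, 1),
                       nucleus_radius_um = 1.0,
                       focus_intensity = 50, nucleus_intensity = 15,
                       psf_sigma_xy_nm = 130, psf_sigma_z_nm = 300,
                       noise_rate = 1,
                       voxel_size_nm = c(z = 125, y = 100, x = 100),
                       seed = NULL) {
  cfg <- list(n_gonads = as.integer(n_gonads),
              nuclei_per_gonad = as.integer(nuclei_per_gonad),
              n_chromosome_pairs = as.integer(n_chromosome_pairs),
              p_designate = p_designate, p_success = p_success,
              p_merge = p_merge, pairing_curve = pairing_curve,
              pairing_threshold_um = pairing_threshold_um,
              focus_rate_per_zone = focus_rate_per_zone,
              nucleus_radius_um = nucleus_radius_um,
              focus_intensity = focus_intensity,
              nucleus_intensity = nucleus_intensity,
              psf_sigma_xy_nm = psf_sigma_xy_nm,
              psf_sigma_z_nm = psf_sigma_z_nm,
              noise_rate = noise_rate,
              voxel_size_nm = voxel_size_nm,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(p_designate = cfg$p_designate, p_success = cfg$p_success,
             p_merge = cfg$p_merge, cfg$pairing_curve)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  counts <- c(cfg$n_gonads, cfg$nuclei_per_gonad, cfg$n_chromosome_pairs)
  if (any(is.na(counts)) || any(counts < 1))
    stop("counts (gonads, nuclei, chromosome pairs) must be >= 1",
         call. = FALSE)
  if (length(cfg$voxel_size_nm) != 3L || any(cfg$voxel_size_nm <= 0))
    stop("voxel_size_nm must be three positive values (z, y, x)",
         call. = FALSE)
  pos <- c(cfg$pairing_threshold_um, cfg$nucleus_radius_um,
           cfg$focus_intensity, cfg$nucleus_intensity,
           cfg$psf_sigma_xy_nm, cfg$psf_sigma_z_nm)
  if (any(pos <= 0)) stop("geometric and intensity parameters must be > 0",
                          call. = FALSE)
  if (cfg$noise_rate < 0) stop("noise_rate must be >= 0", call. = FALSE)
  if (any(cfg$focus_rate_per_zone < 0))
    stop("focus_rate_per_zone must be >= 0", call. = FALSE)
  invisible(cfg)
}

maybe_seed <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  invisible(NULL)
}

#' Simulate designated-focus and chiasma count distributions
#'
#' Draws, for every nucleus of every gonad, the number of crossover-
#' designated foci `k ~ Binomial(n_pairs, p_designate)` (one per pair at
#' most), the number that mature `~ Binomial(k, p_success)`, and the
#' observed DAPI-body count `2 * n_pairs - matured` with the optional
#' touching artifact applied. Ground truth is kept per nucleus.
#'
#' @param config a [sim_config()].
#' @return a list with components `cosa` (a [count_dist] of designated-focus
#'   counts), `chiasma` (a [count_dist] of chiasma counts inferred from the
#'   observed DAPI bodies), and `nuclei`, a data frame with one row per
#'   nucleus: `gonad_id`, `nucleus_id`, `k_true`, `matured_true`,
#'   `dapi_true`, `dapi_count` (after merging), `chiasma_inferred`.
#' @examples
#' sim <- simulate_cosa_and_dapi(sim_config(p_success = 0.85, seed = 1))
#' mean_count(sim$chiasma) / mean_count(sim$cosa)  # ~ 0.85
#' @export
simulate_cosa_and_dapi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  maybe_seed(config)
  np <- config$n_chromosome_pairs
  n <- config$n_gonads * config$nuclei_per_gonad
  k <- rbinom(n, size = np, prob = config$p_designate)
  matured <- rbinom(n, size = k, prob = config$p_success)
  dapi_true <- 2L * np - matured
  n_merge <- rbinom(n, size = dapi_true %/% 2L, prob = config$p_merge)
  dapi_obs <- dapi_true - n_merge
  nuclei <- data.frame(
    gonad_id = rep(seq_len(config$n_gonads), each = config$nuclei_per_gonad),
    nucleus_id = rep(seq_len(config$nuclei_per_gonad), config$n_gonads),
    k_true = k, matured_true = matured,
    dapi_true = dapi_true, dapi_count = dapi_obs,
    chiasma_inferred = chiasmata_from_dapi(dapi_obs,
                                           n_chromosomes = 2L * np)
  )
  list(cosa = count_dist(k, k_max = np),
       chiasma = count_dist(nuclei$chiasma_inferred, k_max = np),
       nuclei = nuclei)
}

new_synthetic_gonad <- function(nuclei, foci = NULL, config,
                                stage_boundaries = NULL) {
  structure(list(nuclei = nuclei, foci = foci, config = config,
                 stage_boundaries = stage_boundaries),
            class = "synthetic_gonad")
}

#' @export
print.synthetic_gonad <- function(x, ...) {
  cat("Synthetic gonad:", nrow(x$nuclei), "nuclei")
  if (!is.null(x$foci)) cat(",", nrow(x$foci), "foci")
  cat("\n")
  invisible(x)
}

# uniform direction on the unit sphere
runit3 <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Simulate a gonad with zone-dependent homolog pairing
#'
#' Places nuclei uniformly along a normalised gonad axis (0 = distal tip,
#' 1 = start of cellularization), assigns each to one of the equal-length
#' zones implied by `pairing_curve`, and draws its paired state from the
#' zone's probability. Paired loci are placed within the pairing distance
#' threshold, unpaired loci beyond it; the two 3D locus coordinates (um) and
#' the ground-truth state are recorded per nucleus.
#'
#' @param config a [sim_config()]; `pairing_curve` sets one probability per
#'   zone and `pairing_threshold_um` the paired/unpaired distance boundary.
#' @param gonad_id identifier stored in the output (default 1).
#' @return a `synthetic_gonad` whose `nuclei` data frame has columns
#'   `gonad_id`, `nucleus_id`, `axial_pos`, `zone`, `paired_true`, and locus
#'   coordinates `l1_x .. l2_z` in um.
#' @export
simulate_pairing_gonad <- function(config, gonad_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  curve <- config$pairing_curve
  if (length(curve) < 1L)
    stop("pairing_curve must contain at least one zone probability",
         call. = FALSE)
  maybe_seed(config)
  n <- config$nuclei_per_gonad
  pos <- sort(runif(n))
  zone <- assign_zones(pos, length(curve))
  paired <- runif(n) < curve[zone]
  thr <- config$pairing_threshold_um
  # first locus at the nucleus centre; the second at a distance drawn
  # within the threshold (paired) or well beyond it (unpaired)
  centre <- cbind(x = pos * 50, y = runif(n, 0, 10), z = runif(n, 0, 4))
  d <- ifelse(paired, runif(n, 0, 0.9 * thr), runif(n, 1.5 * thr, 4 * thr))
  dir <- runit3(n)
  nuclei <- data.frame(
    gonad_id = gonad_id, nucleus_id = seq_len(n),
    axial_pos = pos, zone = zone, paired_true = paired,
    l1_x = centre[, "x"], l1_y = centre[, "y"], l1_z = centre[, "z"],
    l2_x = centre[, "x"] + d * dir[, 1],
    l2_y = centre[, "y"] + d * dir[, 2],
    l2_z = centre[, "z"] + d * dir[, 3]
  )
  new_synthetic_gonad(nuclei, config = config)
}

#' Simulate per-nucleus records for a whole pairing study
#'
#' Convenience wrapper running [simulate_pairing_gonad()] once per gonad in
#' the configuration and stacking the per-nucleus records. The configured
#' seed (if any) is applied once, before the first gonad.
#'
#' @param config a [sim_config()].
#' @return a data frame of per-nucleus records across all gonads.
#' @export
simulate_pairing_records <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  maybe_seed(config)
  cfg1 <- config
  cfg1$seed <- NULL  # seed applied once for the whole study
  do.call(rbind, lapply(seq_len(config$n_gonads), function(g)
    simulate_pairing_gonad(cfg1, gonad_id = g)$nuclei))
}

#' Simulate a gonad of nuclei with recombination foci for image rendering
#'
#' Lays nuclei on a jittered grid inside a single optical layer (so they are
#' spatially well separated), maps the grid's long axis to the normalised
#' gonad axis, and draws each nucleus's focus count from the zone-dependent
#' Poisson profile `focus_rate_per_zone`. Focus positions are uniform within
#' the inner 75% of the nuclear radius — so every true focus lies strictly
#' inside its nucleus — and are rejection-sampled to pairwise separations of
#' at least `min_sep_um`, since focus counting is defined on optically
#' resolvable signals. Separation is measured in PSF units: axial (z)
#' distances count for less by the ratio of the axial to lateral PSF
#' sigmas, reflecting the poorer axial resolution.
#'
#' @param config a [sim_config()].
#' @param n_nuclei number of nuclei to place (default 50).
#' @param min_sep_um minimum distance between foci of one nucleus (default
#'   0.45 um, about the lateral diffraction limit).
#' @return a `synthetic_gonad` with `nuclei` (id, axial position, zone,
#'   centre `cz, cy, cx` in um, radius, focus count) and `foci`
#'   (`nucleus_id`, `z, y, x` in um) data frames.
#' @export
simulate_focus_gonad <- function(config, n_nuclei = 50L,
                                 min_sep_um = 0.45) {
  stopifnot(inherits(config, "sim_config"))
  maybe_seed(config)
  rates <- config$focus_rate_per_zone
  n_zones <- length(rates)
  r <- config$nucleus_radius_um
  pitch <- 3.2 * r
  ncol_grid <- ceiling(sqrt(n_nuclei * 2))   # wide grid: long x axis
  nrow_grid <- ceiling(n_nuclei / ncol_grid)
  idx <- seq_len(n_nuclei) - 1L
  gx <- idx %% ncol_grid
  gy <- idx %/% ncol_grid
  jit <- 0.25 * r
  cx <- (gx + 0.5) * pitch + runif(n_nuclei, -jit, jit)
  cy <- (gy + 0.5) * pitch + runif(n_nuclei, -jit, jit)
  cz <- r + 0.6 + runif(n_nuclei, -0.1, 0.1)
  axial <- (gx + 0.5) / ncol_grid
  zone <- assign_zones(axial, n_zones)
  nfoci <- rpois(n_nuclei, rates[zone])
  nuclei <- data.frame(nucleus_id = seq_len(n_nuclei), axial_pos = axial,
                       zone = zone, cz = cz, cy = cy, cx = cx,
                       radius_um = r, n_foci = nfoci)
  tot <- sum(nfoci)
  if (tot > 0) {
    zscale <- config$psf_sigma_xy_nm / config$psf_sigma_z_nm
    place_in_nucleus <- function(i) {
      pts <- matrix(numeric(0), ncol = 3)
      tries <- 0L
      while (nrow(pts) < nfoci[i] && tries < 500L) {
        tries <- tries + 1L
        u <- stats::runif(1)^(1 / 3) * 0.75 * r
        cand <- c(cz[i], cy[i], cx[i]) + u * runit3(1)[1, ]
        if (nrow(pts) > 0) {
          dd <- (pts - rep(cand, each = nrow(pts)))
          dd[, 1] <- dd[, 1] * zscale  # axial distances resolve less
          if (min(sqrt(rowSums(dd^2))) < min_sep_um) next
        }
        pts <- rbind(pts, cand)
      }
      pts
    }
    placed <- lapply(seq_len(n_nuclei), place_in_nucleus)
    nfoci <- vapply(placed, nrow, integer(1))
    nuclei$n_foci <- nfoci
    coords <- do.call(rbind, placed)
    foci <- data.frame(nucleus_id = rep(seq_len(n_nuclei), nfoci),
                       z = coords[, 1], y = coords[, 2], x = coords[, 3])
  } else {
    foci <- data.frame(nucleus_id = integer(), z = numeric(),
                       y = numeric(), x = numeric())
  }
  new_synthetic_gonad(nuclei, foci = foci, config = config)
}
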