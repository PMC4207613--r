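#' Render a synthetic gonad as multi-channel 3D image stacks
#'
#' Produces two photon-count stacks on the configured voxel grid: a
#' DNA-stain-like channel in which each nucleus is a filled sphere of
#' expected intensity `nucleus_intensity`, and a focus channel in which each
#' true focus is an anisotropic 3D Gaussian of peak `focus_intensity` and
#' sigma `psf_sigma_xy_nm` / `psf_sigma_z_nm`. A uniform background of
#' `noise_rate` expected photons per voxel is added to both channels and
#' every voxel is drawn from a Poisson law, the standard shot-noise model
#' for fluorescence counts. Arrays are `(z, y, x)`; physical coordinate =
#' (index - 0.5) * voxel size, i.e. voxel centres.
#'
#' @param gonad a `synthetic_gonad` from [simulate_focus_gonad()].
#' @param config a [sim_config()] (defaults to the gonad's own).
#' @param seed optional integer seed for the noise draw (defaults to the
#'   config seed plus one so noise is decoupled from geometry).
#' @return a list with `dapi` and `signal` 3D arrays, `voxel_size_nm`, and
#'   `truth` (the input gonad's nucleus and focus tables).
#' @export
render_image_stack <- function(gonad, config = gonad$config, seed = NULL) {
  stopifnot(inherits(gonad, "synthetic_gonad"))
  validate_sim_config(config)
  if (is.null(seed) && !is.null(config$seed)) seed <- config$seed + 1L
  if (!is.null(seed)) set.seed(seed)

  nuc <- gonad$nuclei
  if (is.null(nuc$cz))
    stop("gonad carries no 3D nucleus centres; use simulate_focus_gonad()",
         call. = FALSE)
  vs <- config$voxel_size_nm / 1000  # um per voxel, (z, y, x)
  margin <- 2 * config$nucleus_radius_um
  ext <- c(z = max(nuc$cz) + margin, y = max(nuc$cy) + margin,
           x = max(nuc$cx) + margin)
  dims <- pmax(ceiling(ext / vs), 4)
  if (prod(dims) == 0 || any(!is.finite(dims)))
    stop("voxel size yields an empty stack", call. = FALSE)

  dapi_lam <- array(config$noise_rate, dims)
  sig_lam <- array(config$noise_rate, dims)

  # voxel-centre coordinates along each axis, in um
  ax <- lapply(1:3, function(i) (seq_len(dims[i]) - 0.5) * vs[i])

  for (i in seq_len(nrow(nuc))) {
    ctr <- c(nuc$cz[i], nuc$cy[i], nuc$cx[i])
    r <- nuc$radius_um[i]
    rng <- lapply(1:3, function(a) {
      which(abs(ax[[a]] - ctr[a]) <= r + vs[a])
    })
    if (any(lengths(rng) == 0)) next
    dz2 <- (ax[[1]][rng[[1]]] - ctr[1])^2
    dy2 <- (ax[[2]][rng[[2]]] - ctr[2])^2
    dx2 <- (ax[[3]][rng[[3]]] - ctr[3])^2
    inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r^2
    dapi_lam[rng[[1]], rng[[2]], rng[[3]]] <-
      dapi_lam[rng[[1]], rng[[2]], rng[[3]]] +
      config$nucleus_intensity * inside
  }

  foci <- gonad$foci
  sig_z <- config$psf_sigma_z_nm / 1000
  sig_xy <- config$psf_sigma_xy_nm / 1000
  if (!is.null(foci) && nrow(foci) > 0) {
    for (i in seq_len(nrow(foci))) {
      ctr <- c(foci$z[i], foci$y[i], foci$x[i])
      hw <- 4 * c(sig_z, sig_xy, sig_xy)
      rng <- lapply(1:3, function(a) which(abs(ax[[a]] - ctr[a]) <= hw[a]))
      if (any(lengths(rng) == 0)) next
      gz <- exp(-0.5 * ((ax[[1]][rng[[1]]] - ctr[1]) / sig_z)^2)
      gy <- exp(-0.5 * ((ax[[2]][rng[[2]]] - ctr[2]) / sig_xy)^2)
      gx <- exp(-0.5 * ((ax[[3]][rng[[3]]] - ctr[3]) / sig_xy)^2)
      sig_lam[rng[[1]], rng[[2]], rng[[3]]] <-
        sig_lam[rng[[1]], rng[[2]], rng[[3]]] +
        config$focus_intensity * outer(outer(gz, gy), gx)
    }
  }

  dapi <- array(rpois(length(dapi_lam), dapi_lam), dims)
  signal <- array(rpois(length(sig_lam), sig_lam), dims)
  list(dapi = dapi, signal = signal,
       voxel_size_nm = config$voxel_size_nm,
       truth = list(nuclei = nuc, foci = foci))
}
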