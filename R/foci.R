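#' Segment nuclei in a 3D DNA-stain stack
#'
#' Gaussian-smooths the stack, thresholds it (Otsu's method by default, on
#' the smoothed intensities), labels 3D-connected components
#' (6-connectivity), and filters components by physical volume. Components
#' outside the volume bounds are dropped and reported in `flagged` for
#' manual review, mirroring semi-automated practice in which mis-identified
#' nuclei are corrected by hand.
#'
#' @param dapi_stack 3D array `(z, y, x)` of intensities.
#' @param voxel_size_nm named numeric `(z, y, x)` voxel size in nm.
#' @param params list of optional parameters: `smooth_sigma_nm` (default
#'   200), `threshold` (absolute, on the smoothed stack; default Otsu),
#'   `min_volume_um3` (default 1), `max_volume_um3` (default 50).
#' @return an object of class `nucleus_segmentation`: `labels` (integer
#'   array), `nuclei` (data frame: `nucleus_id`, centroid `cz, cy, cx` in
#'   um, `n_voxels`, `volume_um3`, `axial_pos` = centroid x over stack x
#'   extent), `flagged` (dropped components with reasons), `voxel_size_nm`,
#'   `params_used`.
#' @export
segment_nuclei <- function(dapi_stack, voxel_size_nm, params = list()) {
  stopifnot(length(dim(dapi_stack)) == 3L)
  p <- modify_defaults(list(smooth_sigma_nm = 200, threshold = NULL,
                            min_volume_um3 = 1, max_volume_um3 = 50), params)
  vs <- voxel_size_nm / 1000
  sm <- cpp_gauss_blur3(dapi_stack * 1.0,
                        p$smooth_sigma_nm / voxel_size_nm[1],
                        p$smooth_sigma_nm / voxel_size_nm[2],
                        p$smooth_sigma_nm / voxel_size_nm[3])
  if (is.null(p$threshold)) {
    rng <- range(sm)
    if (diff(rng) == 0) {
      p$threshold <- rng[2] + 1  # flat stack: nothing above threshold
    } else {
      norm <- (sm - rng[1]) / diff(rng)
      th <- EBImage::otsu(EBImage::Image(matrix(norm, ncol = 1L)),
                          range = c(0, 1))
      p$threshold <- rng[1] + th * diff(rng)
    }
  }
  mask <- sm > p$threshold
  dim(mask) <- dim(dapi_stack)
  labels <- cpp_label3(mask, 6L)
  sizes <- tabulate(labels)
  vox_vol <- prod(vs)
  vols <- sizes * vox_vol
  keep <- which(vols >= p$min_volume_um3 & vols <= p$max_volume_um3)
  dropped <- setdiff(which(sizes > 0), keep)
  if (length(keep) == 0)
    warning("no nuclei found within the volume bounds")

  # relabel kept components 1..n and collect centroids
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  nz <- which(labels > 0)
  labs2 <- labels
  labs2[nz] <- remap[labels[nz]]
  idx <- arrayInd(nz[labs2[nz] > 0], dim(dapi_stack))
  lab_kept <- labs2[nz[labs2[nz] > 0]]
  if (length(lab_kept) > 0) {
    cz <- tapply((idx[, 1] - 0.5) * vs[1], lab_kept, mean)
    cy <- tapply((idx[, 2] - 0.5) * vs[2], lab_kept, mean)
    cx <- tapply((idx[, 3] - 0.5) * vs[3], lab_kept, mean)
    nv <- as.integer(table(lab_kept))
    nuclei <- data.frame(nucleus_id = seq_along(keep),
                         cz = as.numeric(cz), cy = as.numeric(cy),
                         cx = as.numeric(cx), n_voxels = nv,
                         volume_um3 = nv * vox_vol,
                         axial_pos = pmin(
                           as.numeric(cx) / (dim(dapi_stack)[3] * vs[3]), 1))
  } else {
    nuclei <- data.frame(nucleus_id = integer(), cz = numeric(),
                         cy = numeric(), cx = numeric(),
                         n_voxels = integer(), volume_um3 = numeric(),
                         axial_pos = numeric())
  }
  flagged <- data.frame(
    component = dropped,
    volume_um3 = vols[dropped],
    reason = ifelse(vols[dropped] < p$min_volume_um3, "undersized",
                    "oversized")
  )
  structure(list(labels = labs2, nuclei = nuclei, flagged = flagged,
                 voxel_size_nm = voxel_size_nm, params_used = p),
            class = "nucleus_segmentation")
}

#' @export
print.nucleus_segmentation <- function(x, ...) {
  cat("Nucleus segmentation:", nrow(x$nuclei), "nuclei kept,",
      nrow(x$flagged), "components flagged\n")
  invisible(x)
}

modify_defaults <- function(defaults, params) {
  stopifnot(is.list(params))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(params)] <- params
  defaults
}

#' Test whether a 3D point lies in the convex hull of a point cloud
#'
#' Computes the distance from the point to the hull by Frank-Wolfe descent
#' on the convex combination weights (minimising `||Xw - p||` over the
#' simplex) and reports containment when that distance is at most `tol_um`.
#' The distance formulation needs no explicit facet construction, so
#' degenerate (coplanar or collinear) clouds are handled uniformly.
#'
#' @param point length-3 numeric `(z, y, x)` in um.
#' @param cloud matrix of points (rows) spanning the hull, in um.
#' @param tol_um containment tolerance (default 0.05 um, half a typical
#'   voxel edge).
#' @return `TRUE` if the point is within `tol_um` of the convex hull.
#' @export
point_in_convex_hull <- function(point, cloud, tol_um = 0.05) {
  cloud <- as.matrix(cloud)
  stopifnot(length(point) == 3L, ncol(cloud) == 3L, nrow(cloud) >= 1L)
  d0 <- sqrt(rowSums((cloud - rep(point, each = nrow(cloud)))^2))
  cur <- cloud[which.min(d0), ]
  tol2 <- tol_um^2
  for (it in seq_len(500L)) {
    g <- cur - point
    f <- sum(g^2)
    if (f <= tol2) return(TRUE)
    s <- cloud[which.min(cloud %*% g), ]
    d <- s - cur
    gap <- -2 * sum(g * d)  # f(cur) - gap lower-bounds the squared distance
    if (f - gap > tol2) return(FALSE)
    dd <- sum(d^2)
    if (dd == 0) return(FALSE)
    gamma <- min(1, max(0, -sum(g * d) / dd))
    if (gamma == 0) return(FALSE)
    cur <- cur + gamma * d
  }
  sum((cur - point)^2) <= tol2
}

#' Detect fluorescence foci constrained to segmented nuclei
#'
#' Band-pass filters the focus channel with a difference-of-Gaussians
#' (Laplacian-of-Gaussian approximation) at the expected spot scale, takes
#' 3D local maxima above an absolute response threshold, suppresses maxima
#' closer together than `min_sep_um` (keeping the stronger), and discards
#' any candidate lying outside the 3D convex hull of every segmented
#' nucleus's voxel cloud. Each surviving focus is assigned to the nucleus
#' containing it (hull membership; ties broken by nearest centroid).
#'
#' @param signal_stack 3D array `(z, y, x)`, same shape as the segmented
#'   stack.
#' @param nuclei a [segment_nuclei()] result.
#' @param params list of optional parameters: `sigma_xy_nm` (default 130),
#'   `sigma_z_nm` (default 300), `threshold` (absolute response threshold;
#'   default 6 x the median absolute deviation of the response),
#'   `min_sep_um` (default 0.4), `hull_tol_um` (default 0.05).
#' @return an object of class `spot_detection`: `foci` (data frame:
#'   `nucleus_id`, `z, y, x` um, `peak_intensity`, `response`),
#'   `counts` (per-nucleus focus counts, zeros included), `nuclei` (the
#'   segmentation's nucleus table), `flagged`, `params_used`.
#' @export
detect_foci <- function(signal_stack, nuclei, params = list()) {
  stopifnot(inherits(nuclei, "nucleus_segmentation"))
  if (!identical(dim(signal_stack), dim(nuclei$labels)))
    stop("signal stack shape does not match the segmented stack",
         call. = FALSE)
  p <- modify_defaults(list(sigma_xy_nm = 130, sigma_z_nm = 300,
                            threshold = NULL, min_sep_um = 0.4,
                            hull_tol_um = 0.05), params)
  vsn <- nuclei$voxel_size_nm
  vs <- vsn / 1000
  s1 <- c(p$sigma_z_nm, p$sigma_xy_nm, p$sigma_xy_nm) / vsn
  b1 <- cpp_gauss_blur3(signal_stack * 1.0, s1[1], s1[2], s1[3])
  b2 <- cpp_gauss_blur3(signal_stack * 1.0, 1.6 * s1[1], 1.6 * s1[2],
                        1.6 * s1[3])
  resp <- b1 - b2
  if (is.null(p$threshold)) p$threshold <- 6 * stats::mad(resp)
  pk <- cpp_local_max3(resp, p$threshold)
  if (nrow(pk) > 1) {
    # non-maximum suppression within min_sep_um (PSF-scaled: axial
    # distances shrunk by the lateral/axial sigma ratio), strongest first
    pum <- sweep(pk - 0.5, 2, vs, `*`)
    pum[, 1] <- pum[, 1] * (p$sigma_xy_nm / p$sigma_z_nm)
    rv <- resp[pk]
    ord <- order(rv, decreasing = TRUE)
    keep <- logical(nrow(pk))
    for (i in ord) {
      if (any(keep)) {
        dd <- sqrt(colSums((t(pum[keep, , drop = FALSE]) - pum[i, ])^2))
        if (min(dd) < p$min_sep_um) next
      }
      keep[i] <- TRUE
    }
    pk <- pk[keep, , drop = FALSE]
  }

  ntab <- nuclei$nuclei
  labdim <- dim(nuclei$labels)
  # voxel clouds per nucleus, for hull tests on candidates off the mask
  nz <- which(nuclei$labels > 0)
  cl_lab <- nuclei$labels[nz]
  cl_idx <- arrayInd(nz, labdim)
  cl_um <- sweep(cl_idx - 0.5, 2, vs, `*`)

  assign_one <- function(vox, pt) {
    lab <- nuclei$labels[vox[1], vox[2], vox[3]]
    if (lab > 0) return(lab)
    if (nrow(ntab) == 0) return(0L)
    dctr <- sqrt((ntab$cz - pt[1])^2 + (ntab$cy - pt[2])^2 +
                   (ntab$cx - pt[3])^2)
    for (j in order(dctr)) {
      if (dctr[j] > 5) break  # far beyond any nuclear radius
      cloud <- cl_um[cl_lab == ntab$nucleus_id[j], , drop = FALSE]
      if (point_in_convex_hull(pt, cloud, p$hull_tol_um))
        return(ntab$nucleus_id[j])
    }
    0L
  }

  if (nrow(pk) > 0) {
    pum <- sweep(pk - 0.5, 2, vs, `*`)
    owner <- integer(nrow(pk))
    for (i in seq_len(nrow(pk))) owner[i] <- assign_one(pk[i, ], pum[i, ])
    inhull <- owner > 0
    foci <- data.frame(nucleus_id = owner[inhull],
                       z = pum[inhull, 1], y = pum[inhull, 2],
                       x = pum[inhull, 3],
                       peak_intensity = signal_stack[pk[inhull, ,
                                                        drop = FALSE]],
                       response = resp[pk[inhull, , drop = FALSE]])
  } else {
    foci <- data.frame(nucleus_id = integer(), z = numeric(), y = numeric(),
                       x = numeric(), peak_intensity = numeric(),
                       response = numeric())
  }
  counts <- integer(nrow(ntab))
  if (nrow(foci) > 0) {
    tb <- table(factor(foci$nucleus_id, levels = ntab$nucleus_id))
    counts <- as.integer(tb)
  }
  structure(list(foci = foci,
                 counts = data.frame(nucleus_id = ntab$nucleus_id,
                                     axial_pos = ntab$axial_pos,
                                     count = counts),
                 nuclei = ntab, flagged = nuclei$flagged, params_used = p),
            class = "spot_detection")
}

#' @export
print.spot_detection <- function(x, ...) {
  cat("Spot detection:", nrow(x$foci), "foci in", nrow(x$nuclei),
      "nuclei\n")
  invisible(x)
}

#' Per-zone distributions of per-nucleus focus counts
#'
#' Bins nuclei into equal-length zones along the gonad axis and collects
#' each zone's per-nucleus focus counts (nuclei with zero foci included).
#' A manual-override table may replace individual nuclei's counts before
#' summarising, representing the manual-correction step of semi-automated
#' counting.
#'
#' @param result a [detect_foci()] result, or a data frame with columns
#'   `axial_pos` and `count` (and optionally `nucleus_id`).
#' @param n_zones number of zones (default 7, the convention for
#'   recombination-focus profiles).
#' @param override optional data frame `nucleus_id`, `count` of corrected
#'   counts.
#' @return list with `counts` (one integer vector per zone) and `summary`
#'   (data frame: `zone`, `n_nuclei`, `mean`, `q1`, `median`, `q3`).
#' @export
counts_by_zone <- function(result, n_zones = 7L, override = NULL) {
  tab <- if (inherits(result, "spot_detection")) result$counts else result
  stopifnot(is.data.frame(tab), all(c("axial_pos", "count") %in% names(tab)))
  if (!is.null(override)) {
    stopifnot(all(c("nucleus_id", "count") %in% names(override)),
              "nucleus_id" %in% names(tab))
    m <- match(tab$nucleus_id, override$nucleus_id)
    tab$count[!is.na(m)] <- override$count[m[!is.na(m)]]
  }
  zone <- assign_zones(tab$axial_pos, n_zones)
  counts <- lapply(seq_len(n_zones), function(z) tab$count[zone == z])
  summ <- data.frame(
    zone = seq_len(n_zones),
    n_nuclei = lengths(counts),
    mean = vapply(counts, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    q1 = vapply(counts, function(v)
      if (length(v)) unname(quantile(v, 0.25)) else NA_real_, numeric(1)),
    median = vapply(counts, function(v)
      if (length(v)) median(v) else NA_real_, numeric(1)),
    q3 = vapply(counts, function(v)
      if (length(v)) unname(quantile(v, 0.75)) else NA_real_, numeric(1))
  )
  list(counts = counts, summary = summ)
}

#' Exact-when-feasible two-sided rank-sum test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) comparison of two count
#' samples. When the number of group assignments `choose(n1+n2, n1)` is
#' small enough, the permutation null of the rank-sum statistic (average
#' ranks for ties) is enumerated exhaustively and the p-value is the exact
#' probability of a statistic at least as far from its null mean as
#' observed; otherwise the normal approximation with tie correction is
#' used via [stats::wilcox.test()].
#'
#' @param x,y numeric vectors.
#' @param exact_limit enumerate exhaustively when `choose(n1+n2, n1)` is at
#'   most this (default 50000).
#' @return the two-sided p-value.
#' @export
rank_sum_test <- function(x, y, exact_limit = 50000) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty",
                               call. = FALSE)
  n <- n1 + n2
  if (choose(n, n1) <= exact_limit) {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(n1)])
    mu <- n1 * (n + 1) / 2
    cmb <- combn(n, n1)
    w_all <- colSums(matrix(r[cmb], nrow = n1))
    mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value)
  }
}

#' Compare per-zone focus-count distributions between two conditions
#'
#' Two-sided rank-sum test per zone (see [rank_sum_test()]); a zone empty
#' in either condition gets `NA`.
#'
#' @param a,b [counts_by_zone()] results (or bare lists of per-zone count
#'   vectors) with the same number of zones.
#' @return data frame with `zone`, `n_a`, `n_b`, `p`.
#' @export
compare_zone_counts <- function(a, b) {
  ca <- if (is.list(a) && !is.null(a$counts)) a$counts else a
  cb <- if (is.list(b) && !is.null(b$counts)) b$counts else b
  if (length(ca) != length(cb))
    stop("zone counts have different zone numbers", call. = FALSE)
  out <- data.frame(zone = seq_along(ca), n_a = lengths(ca),
                    n_b = lengths(cb), p = NA_real_)
  for (z in seq_along(ca)) {
    if (length(ca[[z]]) == 0 || length(cb[[z]]) == 0) next
    out$p[z] <- rank_sum_test(ca[[z]], cb[[z]])
  }
  out
}

#' Fisher's exact test for double crossover-designation events
#'
#' Tests whether the frequency of nuclei showing two designation foci on a
#' single chromosome axis differs between two conditions — the readout of
#' crossover interference integrity. The 2x2 table (doubles vs. singles per
#' condition) is evaluated with the two-sided Fisher exact test using the
#' point-probability convention: the p-value sums the probabilities of all
#' tables with the observed margins that are no more probable than the
#' observed one.
#'
#' @param n_double_a,n_total_a doubles and total nuclei, condition A.
#' @param n_double_b,n_total_b doubles and total nuclei, condition B.
#' @return an `htest` object; the two-sided p-value is `$p.value`.
#' @examples
#' double_focus_test(1, 227, 3, 189)$p.value  # 0.3338
#' @export
double_focus_test <- function(n_double_a, n_total_a, n_double_b,
                              n_total_b) {
  v <- c(n_double_a, n_total_a, n_double_b, n_total_b)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (n_total_a == 0 || n_total_b == 0)
    stop("totals must be positive", call. = FALSE)
  if (n_double_a > n_total_a || n_double_b > n_total_b)
    stop("doubles cannot exceed totals", call. = FALSE)
  tab <- matrix(c(n_double_a, n_total_a - n_double_a,
                  n_double_b, n_total_b - n_double_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(condition = c("A", "B"),
                                nuclei = c("double", "single")))
  res <- fisher.test(tab, alternative = "two.sided")
  res$data.name <- sprintf("%d/%d vs %d/%d double-focus nuclei",
                           n_double_a, n_total_a, n_double_b, n_total_b)
  res
}
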