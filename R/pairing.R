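#' Assign nuclei to equal-length zones along the gonad axis
#'
#' The distal gonad is divided into `n_zones` equal-length zones so that
#' position along the axis proxies meiotic time. Zones are the half-open
#' intervals `[ (i-1)/n, i/n )` with the last zone closed, so a nucleus at
#' the cellularization boundary (`axial_pos = 1`) falls in the last zone.
#' Zones are numbered 1 (most distal) to `n_zones`.
#'
#' @param axial_pos numeric vector of normalised positions in `[0, 1]`.
#' @param n_zones number of zones (5 for pairing profiles, 7 for
#'   recombination-focus counts, by convention).
#' @return integer vector of zone indices in `1..n_zones`.
#' @examples
#' assign_zones(c(0, 0.5, 1), 5)  # 1, 3, 5
#' @export
assign_zones <- function(axial_pos, n_zones) {
  if (!is.numeric(n_zones) || length(n_zones) != 1L || n_zones < 1)
    stop("`n_zones` must be a single integer >= 1", call. = FALSE)
  if (any(is.na(axial_pos)) || any(axial_pos < 0) || any(axial_pos > 1))
    stop("axial positions must lie in [0, 1]", call. = FALSE)
  pmin(floor(axial_pos * n_zones), n_zones - 1) + 1L
}

#' Score one nucleus's locus signals as paired or unpaired
#'
#' A single (fused) signal is paired by definition; two resolvable signals
#' are paired when their 3D Euclidean distance is at or below the
#' threshold. More than two signals indicate an aberrant nucleus that must
#' be resolved upstream.
#'
#' @param focus_coords a matrix with 1 or 2 rows of `(x, y, z)` coordinates
#'   in um (a bare length-3 vector is taken as one signal).
#' @param threshold_um pairing distance threshold; the default 0.75 um is
#'   the conventional cytological criterion, exposed rather than hard-coded.
#' @return `TRUE` if paired.
#' @export
call_paired <- function(focus_coords, threshold_um = 0.75) {
  if (is.null(dim(focus_coords))) focus_coords <- rbind(focus_coords)
  if (ncol(focus_coords) != 3L)
    stop("focus coordinates must have 3 columns (x, y, z)", call. = FALSE)
  if (nrow(focus_coords) > 2L)
    stop("more than 2 signals for one locus; flag this nucleus upstream",
         call. = FALSE)
  if (nrow(focus_coords) == 1L) return(TRUE)
  sqrt(sum((focus_coords[1, ] - focus_coords[2, ])^2)) <= threshold_um
}

#' Zone-based homolog pairing profile across gonads
#'
#' Computes, for each gonad and zone, the fraction of scoreable nuclei with
#' paired locus signals, then summarises across gonads: the gonad is the
#' replicate unit, so the profile mean and standard deviation are taken
#' over per-gonad fractions, matching how scoring efforts are reported
#' (n gonads per genotype, error bars = SD).
#'
#' Records may carry a logical `paired` column directly, or locus
#' coordinate columns `l1_x, l1_y, l1_z, l2_x, l2_y, l2_z` (um; the second
#' locus all-`NA` for a fused signal), in which case pairing is called with
#' [call_paired()]. A gonad-zone with no scoreable nuclei is excluded from
#' that zone's mean/SD.
#'
#' @param records data frame with `gonad_id`, `axial_pos`, and pairing
#'   information as above.
#' @param n_zones number of equal-length zones (default 5).
#' @param threshold_um pairing distance threshold passed to [call_paired()].
#' @return an object of class `pairing_profile`: list with `per_gonad`
#'   (gonad x zone matrix of fractions), `mean`, `sd`, `n_scored` (per-zone
#'   totals across gonads), and `n_zones`.
#' @export
pairing_profile <- function(records, n_zones = 5L, threshold_um = 0.75) {
  stopifnot(is.data.frame(records))
  need <- c("gonad_id", "axial_pos")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)

  if (!"paired" %in% names(records)) {
    cc <- c("l1_x", "l1_y", "l1_z", "l2_x", "l2_y", "l2_z")
    if (!all(cc %in% names(records)))
      stop("records need a `paired` column or locus coordinates ",
           paste(cc, collapse = ", "), call. = FALSE)
    records$paired <- vapply(seq_len(nrow(records)), function(i) {
      p1 <- as.numeric(records[i, c("l1_x", "l1_y", "l1_z")])
      p2 <- as.numeric(records[i, c("l2_x", "l2_y", "l2_z")])
      pts <- rbind(p1, if (!all(is.na(p2))) p2)
      call_paired(pts, threshold_um)
    }, logical(1))
  }

  zone <- assign_zones(records$axial_pos, n_zones)
  gonads <- sort(unique(records$gonad_id))
  per_gonad <- matrix(NA_real_, nrow = length(gonads), ncol = n_zones,
                      dimnames = list(gonad = as.character(gonads),
                                      zone = seq_len(n_zones)))
  n_scored <- integer(n_zones)
  for (gi in seq_along(gonads)) {
    for (z in seq_len(n_zones)) {
      sel <- records$gonad_id == gonads[gi] & zone == z &
        !is.na(records$paired)
      n <- sum(sel)
      if (n > 0) {
        per_gonad[gi, z] <- mean(records$paired[sel])
        n_scored[z] <- n_scored[z] + n
      }
    }
  }
  structure(list(
    per_gonad = per_gonad,
    mean = apply(per_gonad, 2, mean, na.rm = TRUE),
    sd = apply(per_gonad, 2, sd, na.rm = TRUE),
    n_scored = n_scored,
    n_zones = as.integer(n_zones),
    threshold_um = threshold_um
  ), class = "pairing_profile")
}

#' @export
print.pairing_profile <- function(x, ...) {
  cat("Pairing profile:", nrow(x$per_gonad), "gonads,", x$n_zones,
      "zones (threshold", x$threshold_um, "um)\n")
  print(data.frame(zone = seq_len(x$n_zones),
                   mean = round(x$mean, 4), sd = round(x$sd, 4),
                   n_scored = x$n_scored), row.names = FALSE)
  invisible(x)
}

#' Plot a pairing profile with SD error bars
#'
#' @param x a [pairing_profile()].
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.pairing_profile <- function(x, ...) {
  z <- seq_len(x$n_zones)
  plot(z, 100 * x$mean, type = "b", ylim = c(0, 100), xlab = "zone",
       ylab = "% nuclei with paired signals", xaxt = "n", ...)
  axis(1, at = z)
  s <- !is.na(x$sd) & x$sd > 0
  if (any(s))
    arrows(z[s], 100 * (x$mean[s] - x$sd[s]), z[s],
           100 * (x$mean[s] + x$sd[s]),
           angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Compare two pairing profiles zone by zone
#'
#' Two-tailed two-sample t tests on the per-gonad zone fractions, one per
#' zone (like zones compared between conditions). A zone with fewer than
#' two scored gonads in either profile gets `NA`.
#'
#' @param a,b [pairing_profile()] objects with the same number of zones.
#' @return data frame with `zone`, `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "pairing_profile"), inherits(b, "pairing_profile"))
  if (a$n_zones != b$n_zones)
    stop("profiles have different zone counts", call. = FALSE)
  out <- data.frame(zone = seq_len(a$n_zones), mean_a = a$mean,
                    mean_b = b$mean, t = NA_real_, df = NA_real_,
                    p = NA_real_)
  for (z in seq_len(a$n_zones)) {
    xa <- a$per_gonad[, z]; xa <- xa[!is.na(xa)]
    xb <- b$per_gonad[, z]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) next
    if (sd(xa) == 0 && sd(xb) == 0) {
      # degenerate: no within-group variance; identical means are a perfect
      # null fit, different means a sure difference
      out$p[z] <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
      next
    }
    tt <- t.test(xa, xb, alternative = "two.sided")
    out$t[z] <- unname(tt$statistic)
    out$df[z] <- unname(tt$parameter)
    out$p[z] <- tt$p.value
  }
  out
}
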