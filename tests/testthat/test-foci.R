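make_test_render <- function(seed, n_nuclei = 50,
                             rates = rep(5, 7)) {
  cfg <- sim_config(seed = seed, focus_rate_per_zone = rates)
  g <- simulate_focus_gonad(cfg, n_nuclei = n_nuclei)
  list(cfg = cfg, gonad = g, stacks = render_image_stack(g, cfg))
}

test_that("segmentation finds a single rendered nucleus at its true centroid", {
  cfg <- sim_config(seed = 2, noise_rate = 0,
                    focus_rate_per_zone = rep(0, 7))
  g <- simulate_focus_gonad(cfg, n_nuclei = 1)
  st <- render_image_stack(g, cfg)
  seg <- segment_nuclei(st$dapi, st$voxel_size_nm)
  expect_equal(nrow(seg$nuclei), 1)
  err <- sqrt((seg$nuclei$cz - g$nuclei$cz)^2 +
                (seg$nuclei$cy - g$nuclei$cy)^2 +
                (seg$nuclei$cx - g$nuclei$cx)^2)
  expect_lt(err, max(cfg$voxel_size_nm) / 1000)  # within one voxel
})

test_that("an all-background stack yields zero nuclei with a warning", {
  empty <- array(0, c(8, 20, 20))
  expect_warning(seg <- segment_nuclei(empty, c(z = 125, y = 100, x = 100)),
                 "no nuclei")
  expect_equal(nrow(seg$nuclei), 0)
})

test_that("segmentation flags components outside the physical volume bounds", {
  r <- make_test_render(seed = 6, n_nuclei = 12, rates = rep(0, 7))
  expect_warning(
    seg <- segment_nuclei(r$stacks$dapi, r$stacks$voxel_size_nm,
                          params = list(min_volume_um3 = 1,
                                        max_volume_um3 = 2)),
    "no nuclei")
  # real nuclei (~4 um^3) are all oversized under this deliberate bound
  expect_equal(nrow(seg$nuclei), 0)
  expect_true(all(seg$flagged$reason == "oversized"))
  expect_error(segment_nuclei(r$stacks$dapi, r$stacks$voxel_size_nm,
                              params = list(bogus = 1)), "unknown parameter")
})

test_that("detection is empty without signal and exact for one central focus", {
  cfg <- sim_config(seed = 9, noise_rate = 0, focus_rate_per_zone = rep(0, 7))
  g <- simulate_focus_gonad(cfg, n_nuclei = 3)
  st <- render_image_stack(g, cfg)
  seg <- segment_nuclei(st$dapi, st$voxel_size_nm)
  det0 <- detect_foci(st$signal, seg, params = list(threshold = 1))
  expect_equal(nrow(det0$foci), 0)
  expect_true(all(det0$counts$count == 0))

  g1 <- g
  g1$foci <- data.frame(nucleus_id = 2L, z = g$nuclei$cz[2],
                        y = g$nuclei$cy[2], x = g$nuclei$cx[2])
  st1 <- render_image_stack(g1, cfg)
  seg1 <- segment_nuclei(st1$dapi, st1$voxel_size_nm)
  det1 <- detect_foci(st1$signal, seg1)
  expect_equal(nrow(det1$foci), 1)
  own <- seg1$nuclei$nucleus_id[which.min(
    (seg1$nuclei$cz - g$nuclei$cz[2])^2 +
      (seg1$nuclei$cy - g$nuclei$cy[2])^2 +
      (seg1$nuclei$cx - g$nuclei$cx[2])^2)]
  expect_equal(det1$foci$nucleus_id, own)
  expect_error(detect_foci(st1$signal[, , 1:10], seg1), "shape")
})

test_that("detection meets precision/recall targets and the hull constraint", {
  r <- make_test_render(seed = 101)
  seg <- segment_nuclei(r$stacks$dapi, r$stacks$voxel_size_nm)
  det <- detect_foci(r$stacks$signal, seg)
  pr <- match_precision_recall(r$gonad$foci[, c("z", "y", "x")],
                               det$foci[, c("z", "y", "x")])
  expect_gte(pr["recall"], 0.95)
  expect_gte(pr["precision"], 0.95)

  # every reported focus lies in the convex hull of its nucleus's voxels
  vs <- r$stacks$voxel_size_nm / 1000
  nzv <- which(seg$labels > 0)
  lab <- seg$labels[nzv]
  cloud_um <- sweep(arrayInd(nzv, dim(seg$labels)) - 0.5, 2, vs, `*`)
  for (i in seq_len(nrow(det$foci))) {
    cl <- cloud_um[lab == det$foci$nucleus_id[i], , drop = FALSE]
    expect_true(point_in_convex_hull(
      c(det$foci$z[i], det$foci$y[i], det$foci$x[i]), cl))
  }
})

test_that("point-in-hull handles interior, exterior and degenerate clouds", {
  cube <- as.matrix(expand.grid(z = 0:1, y = 0:1, x = 0:1))
  expect_true(point_in_convex_hull(c(0.5, 0.5, 0.5), cube, tol_um = 1e-9))
  expect_true(point_in_convex_hull(c(0, 0, 0), cube, tol_um = 1e-9))
  expect_false(point_in_convex_hull(c(1.5, 0.5, 0.5), cube, tol_um = 0.05))
  expect_false(point_in_convex_hull(c(-0.2, 0, 0), cube, tol_um = 0.05))
  # coplanar cloud: containment within the in-plane hull plus tolerance
  plane <- as.matrix(expand.grid(z = 0, y = 0:2, x = 0:2))
  expect_true(point_in_convex_hull(c(0, 1, 1), plane, tol_um = 1e-9))
  expect_true(point_in_convex_hull(c(0.04, 1, 1), plane, tol_um = 0.05))
  expect_false(point_in_convex_hull(c(0.5, 1, 1), plane, tol_um = 0.05))
})

test_that("detection is equivariant to whole-voxel translations", {
  r <- make_test_render(seed = 33, n_nuclei = 6, rates = rep(3, 7))
  st <- r$stacks
  shift <- c(2L, 5L, 7L)
  pad <- function(a, s) {
    out <- array(0, dim(a) + s)
    out[s[1] + seq_len(dim(a)[1]), s[2] + seq_len(dim(a)[2]),
        s[3] + seq_len(dim(a)[3])] <- a
    out
  }
  seg1 <- segment_nuclei(st$dapi, st$voxel_size_nm,
                         params = list(threshold = 5))
  det1 <- detect_foci(st$signal, seg1, params = list(threshold = 2))
  seg2 <- segment_nuclei(pad(st$dapi, shift), st$voxel_size_nm,
                         params = list(threshold = 5))
  det2 <- detect_foci(pad(st$signal, shift), seg2,
                      params = list(threshold = 2))
  expect_equal(nrow(det1$foci), nrow(det2$foci))
  vs <- st$voxel_size_nm / 1000
  d1 <- det1$foci[order(det1$foci$z, det1$foci$y, det1$foci$x), ]
  d2 <- det2$foci[order(det2$foci$z, det2$foci$y, det2$foci$x), ]
  expect_equal(d2$z - d1$z, rep(unname(shift[1] * vs[1]), nrow(d1)),
               tolerance = 1e-9)
  expect_equal(d2$y - d1$y, rep(unname(shift[2] * vs[2]), nrow(d1)),
               tolerance = 1e-9)
  expect_equal(d2$x - d1$x, rep(unname(shift[3] * vs[3]), nrow(d1)),
               tolerance = 1e-9)
})

test_that("zone binning of per-nucleus counts matches positions and overrides", {
  tab <- data.frame(nucleus_id = 1:4, axial_pos = c(0.5, 0.1, 0.95, 0.5),
                    count = c(3L, 0L, 1L, 7L))
  zc <- counts_by_zone(tab, n_zones = 7)
  expect_equal(zc$counts[[4]], c(3L, 7L))  # axial 0.5 -> 4th of 7 zones
  expect_equal(zc$counts[[1]], 0L)
  expect_equal(zc$summary$n_nuclei, c(1L, 0L, 0L, 2L, 0L, 0L, 1L))
  expect_true(is.na(zc$summary$mean[2]))

  zc2 <- counts_by_zone(tab, n_zones = 7,
                        override = data.frame(nucleus_id = 4L, count = 0L))
  expect_equal(zc2$counts[[4]], c(3L, 0L))

  allz <- counts_by_zone(data.frame(axial_pos = runif(30), count = 0L), 7)
  expect_true(all(unlist(allz$counts) == 0))
})

test_that("per-zone count recovery from the generator stays within 3 SE", {
  rates <- c(0, 0, 2, 5, 5, 3, 1)
  cfg <- sim_config(seed = 71, focus_rate_per_zone = rates)
  g <- simulate_focus_gonad(cfg, n_nuclei = 700)
  zc <- counts_by_zone(data.frame(axial_pos = g$nuclei$axial_pos,
                                  count = g$nuclei$n_foci), 7)
  for (z in 1:7) {
    n <- zc$summary$n_nuclei[z]
    if (n < 10) next
    se <- sqrt(rates[z] / n)
    expect_lte(abs(zc$summary$mean[z] - rates[z]), max(3 * se, 0.05))
  }
})

test_that("rank-sum comparisons match exact enumeration and handle edge cases", {
  expect_equal(rank_sum_test(rep(0, 5), rep(9, 5)), 2 / choose(10, 5))
  expect_equal(rank_sum_test(c(1, 1, 1), c(1, 1, 1)), 1)

  set.seed(12)
  for (rep in 1:5) {
    x <- sample(0:5, 6, replace = TRUE)
    y <- sample(0:5, 7, replace = TRUE)
    expect_equal(rank_sum_test(x, y), oracle_ranksum_enumerate(x, y))
  }
  # large samples fall back to the corrected normal approximation
  set.seed(13)
  x <- rpois(60, 4); y <- rpois(55, 4)
  expect_equal(rank_sum_test(x, y),
               suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value))
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")

  a <- list(c(0, 0, 1), c(2, 3, 4), integer(0))
  b <- list(c(5, 6, 7), c(2, 3, 4), c(1, 2))
  cmp <- compare_zone_counts(a, b)
  expect_equal(nrow(cmp), 3)
  expect_lt(cmp$p[1], 0.2)
  expect_equal(cmp$p[2], 1)
  expect_true(is.na(cmp$p[3]))
})

test_that("the double-designation Fisher test reproduces exact enumeration", {
  res <- double_focus_test(1, 227, 3, 189)
  expect_equal(round(res$p.value, 4), 0.3338)
  expect_equal(res$p.value, oracle_fisher_enumerate(1, 227, 3, 189),
               tolerance = 1e-9)

  expect_equal(double_focus_test(1, 10, 1, 10)$p.value, 1)
  expect_equal(double_focus_test(0, 5, 5, 5)$p.value,
               oracle_fisher_enumerate(0, 5, 5, 5), tolerance = 1e-9)

  set.seed(4)
  for (rep in 1:10) {
    na <- sample(5:400, 1); nb <- sample(5:400, 1)
    a <- rbinom(1, na, 0.02); b <- rbinom(1, nb, 0.02)
    expect_equal(double_focus_test(a, na, b, nb)$p.value,
                 oracle_fisher_enumerate(a, na, b, nb), tolerance = 1e-9)
  }
  expect_error(double_focus_test(1, 0, 0, 5), "positive")
  expect_error(double_focus_test(6, 5, 0, 5), "exceed")
  expect_error(double_focus_test(-1, 5, 0, 5), "non-negative")
})
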