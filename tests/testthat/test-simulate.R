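test_that("deterministic designation/maturation limits are reproduced", {
  cfg <- sim_config(n_gonads = 2, nuclei_per_gonad = 40, p_designate = 1,
                    p_success = 1, p_merge = 0, seed = 1)
  sim <- simulate_cosa_and_dapi(cfg)
  expect_true(all(sim$nuclei$k_true == 6))
  expect_true(all(sim$nuclei$dapi_count == 6))   # six chiasmate bivalents
  expect_true(all(sim$nuclei$chiasma_inferred == 6))

  cfg0 <- sim_config(n_gonads = 2, nuclei_per_gonad = 40, p_designate = 0,
                     seed = 1)
  sim0 <- simulate_cosa_and_dapi(cfg0)
  expect_true(all(sim0$nuclei$k_true == 0))
  expect_true(all(sim0$nuclei$dapi_count == 12))  # all univalent
})

test_that("empirical thinning ratio matches the analytic mean at large n", {
  cfg <- sim_config(n_gonads = 10, nuclei_per_gonad = 1000,
                    p_designate = 0.5, p_success = 0.85, seed = 99)
  sim <- simulate_cosa_and_dapi(cfg)
  ratio <- mean_count(sim$chiasma) / mean_count(sim$cosa)
  expect_equal(ratio, 0.85, tolerance = 0.01 / 0.85)
})

test_that("count tallies are exact and chiasma inference is exact without merging", {
  cfg <- sim_config(n_gonads = 3, nuclei_per_gonad = 77, p_designate = 0.6,
                    p_success = 0.5, p_merge = 0, seed = 5)
  sim <- simulate_cosa_and_dapi(cfg)
  expect_equal(cd_total(sim$cosa), 3 * 77)
  expect_equal(cd_total(sim$chiasma), 3 * 77)
  # with no touching artifact, 12 - DAPI recovers the true matured count
  expect_identical(sim$nuclei$chiasma_inferred, sim$nuclei$matured_true)
})

test_that("identical seeds reproduce identical count tables", {
  cfg <- sim_config(n_gonads = 2, nuclei_per_gonad = 50, p_designate = 0.7,
                    p_success = 0.4, p_merge = 0.05, seed = 123)
  s1 <- simulate_cosa_and_dapi(cfg)
  s2 <- simulate_cosa_and_dapi(cfg)
  expect_identical(s1$nuclei, s2$nuclei)
  expect_identical(cd_as_vector(s1$cosa), cd_as_vector(s2$cosa))
})

test_that("the touching artifact lowers observed DAPI counts pairwise", {
  cfg <- sim_config(n_gonads = 1, nuclei_per_gonad = 60, p_designate = 1,
                    p_success = 1, p_merge = 1, seed = 3)
  sim <- simulate_cosa_and_dapi(cfg)
  # 6 true bodies, every disjoint pair merged: 6 - 3 = 3 observed
  expect_true(all(sim$nuclei$dapi_true == 6))
  expect_true(all(sim$nuclei$dapi_count == 3))
})

test_that("configuration validation rejects impossible parameters", {
  expect_error(sim_config(p_success = 1.5), "probabilities")
  expect_error(sim_config(p_merge = -0.1), "probabilities")
  expect_error(sim_config(n_gonads = 0), ">= 1")
  expect_error(sim_config(voxel_size_nm = c(0, 100, 100)), "voxel")
})

test_that("pairing gonads honour the zone curve at its extremes", {
  cfg1 <- sim_config(nuclei_per_gonad = 80,
                     pairing_curve = rep(1, 5), seed = 11)
  g1 <- simulate_pairing_gonad(cfg1)
  expect_true(all(g1$nuclei$paired_true))

  cfg0 <- sim_config(nuclei_per_gonad = 80,
                     pairing_curve = rep(0, 5), seed = 11)
  g0 <- simulate_pairing_gonad(cfg0)
  expect_false(any(g0$nuclei$paired_true))
})

test_that("recovered per-zone pairing fractions stay within binomial error", {
  curve <- c(0.1, 0.3, 0.6, 0.9, 1.0)
  cfg <- sim_config(n_gonads = 1, nuclei_per_gonad = 4000,
                    pairing_curve = curve, seed = 21)
  g <- simulate_pairing_gonad(cfg)
  for (z in 1:5) {
    sel <- g$nuclei$zone == z
    n <- sum(sel)
    frac <- mean(g$nuclei$paired_true[sel])
    tol <- 3 * sqrt(curve[z] * (1 - curve[z]) / n)
    expect_lte(abs(frac - curve[z]), max(tol, 1e-12))
  }
})

test_that("generated locus geometry matches the ground-truth pairing flag", {
  cfg <- sim_config(n_gonads = 1, nuclei_per_gonad = 300, seed = 8)
  g <- simulate_pairing_gonad(cfg)
  nuc <- g$nuclei
  d <- sqrt((nuc$l1_x - nuc$l2_x)^2 + (nuc$l1_y - nuc$l2_y)^2 +
              (nuc$l1_z - nuc$l2_z)^2)
  expect_true(all(d[nuc$paired_true] <= 0.75))
  expect_true(all(d[!nuc$paired_true] > 0.75))
})

test_that("focus gonads have resolvable in-nucleus foci at zone-driven rates", {
  cfg <- sim_config(seed = 31, focus_rate_per_zone = c(0, 0, 2, 5, 5, 3, 1))
  g <- simulate_focus_gonad(cfg, n_nuclei = 60)
  # every focus lies inside its nucleus
  m <- match(g$foci$nucleus_id, g$nuclei$nucleus_id)
  d <- sqrt((g$foci$z - g$nuclei$cz[m])^2 + (g$foci$y - g$nuclei$cy[m])^2 +
              (g$foci$x - g$nuclei$cx[m])^2)
  expect_true(all(d < g$nuclei$radius_um[m]))
  # zones 1-2 carry no foci by construction
  expect_true(all(g$nuclei$n_foci[g$nuclei$zone <= 2] == 0))
  # PSF-scaled pairwise separations respect the resolvability floor
  zsc <- cfg$psf_sigma_xy_nm / cfg$psf_sigma_z_nm
  for (id in unique(g$foci$nucleus_id)) {
    pts <- as.matrix(g$foci[g$foci$nucleus_id == id, c("z", "y", "x")])
    if (nrow(pts) < 2) next
    pts[, 1] <- pts[, 1] * zsc
    expect_gte(min(stats::dist(pts)), 0.45)
  }
})

test_that("rendering is deterministic, Poisson-noisy, and peaks at the focus", {
  cfg <- sim_config(seed = 41, noise_rate = 2)
  g <- simulate_focus_gonad(cfg, n_nuclei = 4)
  st1 <- render_image_stack(g, cfg)
  st2 <- render_image_stack(g, cfg)
  expect_identical(st1$signal, st2$signal)
  expect_identical(st1$dapi, st2$dapi)

  # zero foci, zero noise: the focus channel is exactly empty
  cfg0 <- sim_config(seed = 42, noise_rate = 0,
                     focus_rate_per_zone = rep(0, 7))
  g0 <- simulate_focus_gonad(cfg0, n_nuclei = 4)
  st0 <- render_image_stack(g0, cfg0)
  expect_true(all(st0$signal == 0))

  # a single bright focus, zero noise: intensity argmax at its voxel
  cfg1 <- sim_config(seed = 43, noise_rate = 0, focus_intensity = 1e5,
                     focus_rate_per_zone = rep(1, 7))
  g1 <- simulate_focus_gonad(cfg1, n_nuclei = 1)
  vs <- cfg1$voxel_size_nm / 1000
  # place the focus exactly at a voxel centre near the nucleus centre
  at_centre <- function(c0, v) (round(c0 / v) + 0.5) * v
  g1$foci <- data.frame(nucleus_id = 1L,
                        z = at_centre(g1$nuclei$cz[1], vs[1]),
                        y = at_centre(g1$nuclei$cy[1], vs[2]),
                        x = at_centre(g1$nuclei$cx[1], vs[3]))
  st <- render_image_stack(g1, cfg1)
  peak <- arrayInd(which.max(st$signal), dim(st$signal))
  expect_equal(peak[1], as.integer(floor(g1$foci$z / vs[1])) + 1L)
  expect_equal(peak[2], as.integer(floor(g1$foci$y / vs[2])) + 1L)
  expect_equal(peak[3], as.integer(floor(g1$foci$x / vs[3])) + 1L)
})
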