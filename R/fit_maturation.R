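#' Fit the crossover maturation probability by binomial thinning
#'
#' Estimates the per-focus probability `p` that a designated crossover site
#' (COSA-1 focus) matures into a chiasma. The observed focus-count
#' distribution is clamped to `k_max` and rescaled to the total number of
#' nuclei scored for chiasmata (see [clamp_counts()], [normalize_total()]),
#' then thinned forward under each candidate `p` on a grid over `[0, 1]`
#' (see [adjust_distribution()]). The estimate minimises the sum of squared
#' differences, over counts `0..k_max`, between the chiasma-count
#' distribution inferred from DAPI bodies and the thinned focus-count
#' distribution. Grid search is exact at the reporting resolution (the
#' default step 0.01 resolves whole percentages) and ties break toward the
#' smaller `p`.
#'
#' The SSD is computed on (possibly fractional) nucleus counts, not
#' proportions; since the focus distribution is pre-normalised to the
#' chiasma total, the two differ only by a constant factor and give the same
#' minimiser.
#'
#' @param cosa [count_dist] of designated-site (COSA-1 focus) counts per
#'   nucleus, or an integer vector of per-nucleus counts.
#' @param chiasma [count_dist] of chiasma counts per nucleus (typically
#'   `chiasmata_from_dapi()` of DAPI-body counts), or a per-nucleus vector.
#' @param grid_step spacing of the probability grid (default 0.01).
#' @param k_max ceiling on counts (default 6, the *C. elegans* karyotype).
#' @param clamp,normalize preprocessing switches; both default to `TRUE`,
#'   matching the standard workflow (clamp first, then rescale).
#' @return an object of class `maturation_fit` with components
#'   `p_hat` (the estimate), `grid` and `ssd` (the full objective curve),
#'   `cosa` (the preprocessed focus distribution), `chiasma`,
#'   `adjusted` (the thinned distribution at `p_hat`), `grid_step`, `k_max`.
#' @examples
#' cosa <- count_dist(k = 6, weight = 1360)
#' chi  <- adjust_distribution(cosa, 0.39)
#' fit  <- fit_maturation(cosa, chi)
#' coef(fit)  # 0.39
#' @seealso [adjust_distribution()] for the forward model,
#'   [simulate_cosa_and_dapi()] for generating test data.
#' @export
fit_maturation <- function(cosa, chiasma, grid_step = 0.01, k_max = 6L,
                           clamp = TRUE, normalize = TRUE) {
  if (!inherits(cosa, "count_dist")) cosa <- count_dist(cosa, k_max = k_max)
  if (!inherits(chiasma, "count_dist"))
    chiasma <- count_dist(chiasma, k_max = k_max)
  if (!is.numeric(grid_step) || length(grid_step) != 1L ||
      grid_step <= 0 || grid_step > 1)
    stop("`grid_step` must be in (0, 1]", call. = FALSE)
  if (cd_total(cosa) <= 0 || cd_total(chiasma) <= 0)
    stop("both distributions must have positive total weight", call. = FALSE)

  if (clamp) cosa <- clamp_counts(cosa, k_max)
  if (normalize) cosa <- normalize_total(cosa, cd_total(chiasma))

  grid <- seq(0, 1, by = grid_step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  obs <- cd_weights(chiasma, k_max)
  ssd <- vapply(grid, function(p) {
    sum((obs - cd_weights(adjust_distribution(cosa, p), k_max))^2)
  }, numeric(1))

  i <- which.min(ssd)  # first minimum: ties break toward smaller p
  fit <- list(
    p_hat = grid[i],
    grid = grid,
    ssd = ssd,
    cosa = cosa,
    chiasma = chiasma,
    adjusted = adjust_distribution(cosa, grid[i]),
    grid_step = grid_step,
    k_max = as.integer(k_max),
    call = match.call()
  )
  class(fit) <- "maturation_fit"
  fit
}

#' @export
print.maturation_fit <- function(x, ...) {
  cat("Crossover maturation fit (binomial thinning)\n")
  cat("  nuclei scored:", format(cd_total(x$chiasma)),
      " | support: 0..", x$k_max, "\n", sep = "")
  cat("  P_success = ", format(x$p_hat),
      "  (grid step ", format(x$grid_step), ", SSD = ",
      format(min(x$ssd)), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.maturation_fit <- function(object, ...) {
  c(p_success = object$p_hat)
}

#' @export
fitted.maturation_fit <- function(object, ...) object$adjusted

#' Thin the fitted focus distribution at an arbitrary probability
#'
#' @param object a [fit_maturation()] result.
#' @param p maturation probability; defaults to the fitted `p_hat`.
#' @param ... unused.
#' @return the adjusted [count_dist] at `p`.
#' @export
predict.maturation_fit <- function(object, p = object$p_hat, ...) {
  adjust_distribution(object$cosa, p)
}

#' @export
residuals.maturation_fit <- function(object, ...) {
  r <- cd_weights(object$chiasma, object$k_max) -
    cd_weights(object$adjusted, object$k_max)
  names(r) <- as.character(0:object$k_max)
  r
}

#' @export
summary.maturation_fit <- function(object, ...) {
  k <- 0:object$k_max
  tab <- data.frame(
    k = k,
    cosa = cd_weights(object$cosa, object$k_max),
    chiasma = cd_weights(object$chiasma, object$k_max),
    adjusted = cd_weights(object$adjusted, object$k_max)
  )
  out <- list(
    p_hat = object$p_hat,
    grid_step = object$grid_step,
    ssd_min = min(object$ssd),
    n_nuclei = cd_total(object$chiasma),
    mean_cosa = mean_count(object$cosa),
    mean_chiasma = mean_count(object$chiasma),
    table = tab
  )
  class(out) <- "summary.maturation_fit"
  out
}

#' @export
print.summary.maturation_fit <- function(x, ...) {
  cat("Crossover maturation fit\n")
  cat("  P_success = ", format(x$p_hat), " (grid step ", format(x$grid_step),
      ", min SSD = ", format(round(x$ssd_min, 2)), ")\n", sep = "")
  cat("  nuclei:", format(x$n_nuclei),
      "| mean foci/nucleus:", format(round(x$mean_cosa, 3)),
      "| mean chiasmata/nucleus:", format(round(x$mean_chiasma, 3)), "\n")
  cat("  thinning-mean check: p * mean foci =",
      format(round(x$p_hat * x$mean_cosa, 3)), "\n\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot the sum-of-squared-differences curve of a maturation fit
#'
#' Draws SSD against the candidate maturation probability, with the grid
#' minimum marked by an arrow.
#'
#' @param x a [fit_maturation()] result.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.maturation_fit <- function(x, ...) {
  plot(x$grid, x$ssd, type = "l", xlab = "P_success",
       ylab = "sum of squared differences", ...)
  i <- which.min(x$ssd)
  yr <- range(x$ssd)
  arrows(x$grid[i], x$ssd[i] + 0.25 * diff(yr), x$grid[i],
         x$ssd[i] + 0.05 * diff(yr), length = 0.08)
  invisible(x)
}

#' Simulate chiasma-count data from a fitted maturation model
#'
#' Draws per-nucleus focus counts from the fitted (clamped, rescaled) focus
#' distribution and thins each nucleus's foci independently at the fitted
#' `p_hat`, giving replicate chiasma-count data sets under the model.
#'
#' @param object a [fit_maturation()] result.
#' @param nsim number of replicate data sets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data frame with columns `sim`, `nucleus`, `k` (focus count) and
#'   `matured` (simulated chiasma count).
#' @export
simulate.maturation_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- max(1L, round(cd_total(object$chiasma)))
  w <- cd_weights(object$cosa, object$k_max)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    k <- sample(0:object$k_max, n, replace = TRUE, prob = w / sum(w))
    out[[s]] <- data.frame(sim = s, nucleus = seq_len(n), k = k,
                           matured = rbinom(n, size = k, prob = object$p_hat))
  }
  do.call(rbind, out)
}
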