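#' Count distributions over foci or chiasmata per nucleus
#'
#' A `count_dist` maps a non-negative integer count `k` (foci or chiasmata
#' per nucleus) to a weight: the number of nuclei observed with that count.
#' Weights may become fractional after [normalize_total()], which rescales
#' one scored population to the size of another; they are carried exactly,
#' without rounding. The support runs from 0 to the largest represented
#' count; `k_max` records the biologically meaningful ceiling (6 for the six
#' chromosome pairs of *C. elegans*, hence at most six designated crossover
#' sites under complete interference).
#'
#' @param k integer vector of counts, one entry per nucleus (tallied), or
#'   the counts at which `weight` places mass.
#' @param weight optional non-negative weights aligned with `k`; if `NULL`,
#'   `k` is tallied as per-nucleus observations.
#' @param k_max biological ceiling on the count (default 6).
#' @return an object of class `count_dist`: a numeric vector of weights
#'   named by count, with attribute `k_max`.
#' @examples
#' count_dist(c(6, 6, 5, 0))
#' count_dist(k = c(0, 6), weight = c(10, 10))
#' @export
count_dist <- function(k, weight = NULL, k_max = 6L) {
  k_max <- as.integer(k_max)
  if (length(k_max) != 1L || is.na(k_max) || k_max < 1L)
    stop("`k_max` must be a single integer >= 1", call. = FALSE)
  if (length(k) == 0L) stop("`k` must be non-empty", call. = FALSE)
  if (any(is.na(k)) || any(k < 0) || any(k != floor(k)))
    stop("counts `k` must be non-negative integers", call. = FALSE)
  k <- as.integer(k)
  if (is.null(weight)) {
    weight <- rep(1, length(k))
  } else {
    if (length(weight) != length(k))
      stop("`weight` must match `k` in length", call. = FALSE)
    if (any(is.na(weight)) || any(weight < 0))
      stop("weights must be non-negative", call. = FALSE)
  }
  top <- max(k, k_max)
  w <- numeric(top + 1L)
  for (i in seq_along(k)) w[k[i] + 1L] <- w[k[i] + 1L] + weight[i]
  new_count_dist(w, k_max)
}

new_count_dist <- function(weights, k_max) {
  names(weights) <- as.character(seq_along(weights) - 1L)
  structure(weights, k_max = as.integer(k_max), class = "count_dist")
}

#' @export
print.count_dist <- function(x, ...) {
  cat("Per-nucleus count distribution (k_max = ", attr(x, "k_max"),
      ", total weight = ", format(cd_total(x)), ")\n", sep = "")
  m <- rbind(k = as.integer(names(x)), weight = unclass(x))
  print(unname(zapsmall(m, digits = 10)))
  invisible(x)
}

#' Total weight of a count distribution
#'
#' @param dist a [count_dist].
#' @return the summed weight (number of nuclei, possibly fractional).
#' @export
cd_total <- function(dist) {
  stopifnot(inherits(dist, "count_dist"))
  sum(unclass(dist))
}

#' Weighted mean count per nucleus
#'
#' @param dist a [count_dist] with positive total weight.
#' @return the weight-averaged count (e.g. mean chiasmata per nucleus).
#' @export
mean_count <- function(dist) {
  stopifnot(inherits(dist, "count_dist"))
  w <- unclass(dist)
  tot <- sum(w)
  if (tot <= 0) stop("distribution has zero total weight", call. = FALSE)
  k <- seq_along(w) - 1
  sum(k * w) / tot
}

#' Infer chiasma counts from diakinesis DAPI-body counts
#'
#' At diakinesis each chiasma joins two homologs into one bivalent, so with
#' six chromosome pairs a nucleus shows between 6 DAPI-stained bodies (all
#' bivalent) and 12 (all univalent); the chiasma count is `12 - bodies`.
#' Counts above 12 would indicate chromosome fragmentation, which this model
#' does not cover, and are rejected.
#'
#' @param dapi_count integer vector of DAPI-body counts, each in `[1, 12]`.
#' @param n_chromosomes total chromosome number (default 12 = 2 x 6 pairs).
#' @return integer vector of inferred chiasma counts.
#' @examples
#' chiasmata_from_dapi(6)   # fully chiasmate: 6
#' chiasmata_from_dapi(12)  # all univalent: 0
#' @export
chiasmata_from_dapi <- function(dapi_count, n_chromosomes = 12L) {
  if (any(is.na(dapi_count)) || any(dapi_count != floor(dapi_count)))
    stop("DAPI-body counts must be integers", call. = FALSE)
  bad <- dapi_count < 1 | dapi_count > n_chromosomes
  if (any(bad))
    stop("DAPI-body counts must lie in [1, ", n_chromosomes, "]; got ",
         paste(dapi_count[bad], collapse = ", "),
         " (counts above ", n_chromosomes,
         " suggest fragmentation, which is not modelled)", call. = FALSE)
  as.integer(n_chromosomes - dapi_count)
}

#' Clamp counts above the biological ceiling
#'
#' Occasional counts above `k_max` (e.g. 7 or 8 foci where interference
#' allows at most 6) are treated as miscounts of adjacent signals and their
#' weight is moved onto `k_max`. Total weight is preserved exactly.
#'
#' @param dist a [count_dist].
#' @param k_max ceiling; defaults to the distribution's own `k_max`.
#' @return a clamped [count_dist] with support `0..k_max`.
#' @export
clamp_counts <- function(dist, k_max = attr(dist, "k_max")) {
  stopifnot(inherits(dist, "count_dist"))
  k_max <- as.integer(k_max)
  w <- unclass(dist)
  if (length(w) > k_max + 1L) {
    over <- sum(w[(k_max + 2L):length(w)])
    w <- w[seq_len(k_max + 1L)]
    w[k_max + 1L] <- w[k_max + 1L] + over
  } else if (length(w) < k_max + 1L) {
    w <- c(w, numeric(k_max + 1L - length(w)))
  }
  new_count_dist(w, k_max)
}

#' Rescale a count distribution to a target total
#'
#' Used to put two populations scored with different markers on a common
#' footing: the focus-count distribution is rescaled so its total equals the
#' number of nuclei scored for DAPI bodies. Weights become fractional.
#'
#' @param dist a [count_dist] with positive total.
#' @param target_total positive target for the summed weight.
#' @return the rescaled [count_dist].
#' @export
normalize_total <- function(dist, target_total) {
  stopifnot(inherits(dist, "count_dist"))
  if (!is.numeric(target_total) || length(target_total) != 1L ||
      is.na(target_total) || target_total <= 0)
    stop("`target_total` must be a positive number", call. = FALSE)
  tot <- cd_total(dist)
  if (tot <= 0) stop("cannot rescale a zero-total distribution", call. = FALSE)
  new_count_dist(unclass(dist) * (target_total / tot), attr(dist, "k_max"))
}

#' Binomial thinning of a count distribution
#'
#' Applies the forward maturation model: each of a nucleus's `m` designated
#' sites independently matures with probability `p`, so a nucleus
#' contributes to the adjusted count `k` with binomial weight
#' `choose(m, k) p^k (1-p)^(m-k)`. The adjusted weight at `k` is
#' \deqn{N'_k = \sum_{m \ge k} N_m \binom{m}{k} p^k (1-p)^{m-k},}
#' which preserves total weight because each binomial row sums to one.
#'
#' @param dist a [count_dist] with support within `0..k_max` (clamp first
#'   with [clamp_counts()] if needed).
#' @param p maturation probability in `[0, 1]`.
#' @return the thinned [count_dist].
#' @examples
#' adjust_distribution(count_dist(k = 2, weight = 100), p = 0.5)
#' @export
adjust_distribution <- function(dist, p) {
  stopifnot(inherits(dist, "count_dist"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a single probability in [0, 1]", call. = FALSE)
  k_max <- attr(dist, "k_max")
  w <- unclass(dist)
  if (length(w) > k_max + 1L && any(w[(k_max + 2L):length(w)] > 0))
    stop("distribution carries weight above k_max; apply clamp_counts() first",
         call. = FALSE)
  w <- w[seq_len(min(length(w), k_max + 1L))]
  if (length(w) < k_max + 1L) w <- c(w, numeric(k_max + 1L - length(w)))
  out <- numeric(k_max + 1L)
  for (m in 0:k_max) {
    if (w[m + 1L] == 0) next
    out[0:m + 1L] <- out[0:m + 1L] + w[m + 1L] * dbinom(0:m, size = m, prob = p)
  }
  new_count_dist(out, k_max)
}

# weights on fixed support 0..k_max, for internal arithmetic
cd_weights <- function(dist, k_max = attr(dist, "k_max")) {
  w <- unclass(dist)
  if (length(w) < k_max + 1L) w <- c(w, numeric(k_max + 1L - length(w)))
  unname(w[seq_len(k_max + 1L)])
}
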