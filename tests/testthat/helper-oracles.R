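# Independent oracles for the spatial estimators.
#
# The arc-fraction oracle builds the set of angular intervals excluded by
# each window edge and measures their union -- a different algorithm from
# the package's inclusion-exclusion closed form. The K oracle is a literal
# double-sum over ordered pairs of the estimator definition.

# fraction of the circle (center (x, y), radius r) inside [0,W] x [0,H],
# by union of per-edge excluded angular intervals
oracle_arc_fraction <- function(x, y, r, W, H) {
  iv <- list()
  add <- function(lo, hi) {
    if (hi > lo) iv[[length(iv) + 1L]] <<- c(lo, hi)
  }
  if (x < r) {                              # left edge: cos(t) < -x/r
    a <- acos(x / r)
    add(pi - a, pi + a)
  }
  if (W - x < r) {                          # right edge: cos(t) > (W-x)/r
    b <- acos((W - x) / r)
    add(0, b)
    add(2 * pi - b, 2 * pi)
  }
  if (y < r) {                              # bottom edge: sin(t) < -y/r
    cc <- asin(y / r)
    add(pi + cc, 2 * pi - cc)
  }
  if (H - y < r) {                          # top edge: sin(t) > (H-y)/r
    e <- asin((H - y) / r)
    add(e, pi - e)
  }
  if (!length(iv)) return(1)
  m <- do.call(rbind, iv)
  m <- m[order(m[, 1L]), , drop = FALSE]
  total <- 0
  cur <- m[1L, ]
  if (nrow(m) > 1L) {
    for (k in 2L:nrow(m)) {
      if (m[k, 1L] <= cur[2L]) {
        cur[2L] <- max(cur[2L], m[k, 2L])
      } else {
        total <- total + (cur[2L] - cur[1L])
        cur <- m[k, ]
      }
    }
  }
  total <- total + (cur[2L] - cur[1L])
  1 - total / (2 * pi)
}

# blind check of the same fraction by dense angular sampling
oracle_arc_fraction_sampled <- function(x, y, r, W, H, n_angles = 1e6) {
  theta <- (seq_len(n_angles) - 0.5) / n_angles * 2 * pi
  px <- x + r * cos(theta)
  py <- y + r * sin(theta)
  mean(px >= 0 & px <= W & py >= 0 & py <= H)
}

# literal evaluation of K(r) = A n^-2 sum_{i != j} w_ij 1(d_ij <= r)
oracle_k <- function(pattern, r, correction = c("none", "isotropic"),
                     pair_normalisation = c("n2", "unbiased"),
                     max_weight = Inf) {
  correction <- match.arg(correction)
  pair_normalisation <- match.arg(pair_normalisation)
  n <- pattern$n
  W <- pattern$window$width
  H <- pattern$window$height
  rmax <- max(r)
  ds <- ws <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pattern$x[i] - pattern$x[j])^2 +
                  (pattern$y[i] - pattern$y[j])^2)
      if (d > rmax) next
      w <- if (correction == "none" || d == 0) {
        1
      } else {
        min(1 / oracle_arc_fraction(pattern$x[i], pattern$y[i], d, W, H),
            max_weight)
      }
      ds <- c(ds, d)
      ws <- c(ws, w)
    }
  }
  denom <- if (pair_normalisation == "n2") n^2 else n * (n - 1)
  vapply(r, function(rr) sum(ws[ds <= rr]), numeric(1)) *
    pattern$window$area / denom
}

random_pattern <- function(n, window = nc_window(1000), seed = NULL) {
  simulate_csr(n, window, seed = seed)
}
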