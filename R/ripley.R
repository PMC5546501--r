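#' Radius grid for K-function evaluation
#'
#' Nanoclustering analyses of immunogold patterns conventionally evaluate
#' K(r) on an integer nanometre grid from 1 to 240 nm; nanocluster radii
#' themselves are < ~20 nm, and 240 nm keeps the grid well inside the range
#' where the rectangular edge correction is exact.
#'
#' @param rmin,rmax First and last radius in nm.
#' @param by Grid step in nm.
#' @return A strictly increasing numeric vector of radii (> 0).
#' @examples
#' head(r_grid())
#' @export
r_grid <- function(rmin = 1, rmax = 240, by = 1) {
  stopifnot(rmin > 0, rmax >= rmin, by > 0)
  seq(rmin, rmax, by = by)
}

assert_r_grid <- function(r) {
  if (!is.numeric(r) || !length(r) || anyNA(r)) {
    stop("radius grid must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(r <= 0) || any(diff(r) <= 0)) {
    stop("radius grid must be strictly increasing and positive", call. = FALSE)
  }
  as.numeric(r)
}

#' Isotropic edge-correction weight for a rectangular window
#'
#' Ripley's isotropic correction: the weight for an ordered point pair
#' (center `point`, neighbour at range `distance`) is the reciprocal of the
#' fraction of the circle centered at `point` with radius `distance` that
#' lies inside the window. Points near the boundary "miss" part of their
#' neighbourhood, and this weight restores unbiasedness of the pair count.
#'
#' The fraction is computed in closed form by inclusion-exclusion on the
#' rectangle's edges: each edge closer than `distance` excludes an arc of
#' angle `2*acos(d_edge/distance)`, and where the circle reaches past a
#' corner the two adjacent exclusions overlap by
#' `pi/2 - asin(d1/distance) - asin(d2/distance)`, which is added back.
#' This accounting is exact whenever `distance <= min(width, height)/2`
#' (opposite edges can then never both cut the circle), which is enforced.
#'
#' @param point Numeric length-2 vector `c(x, y)` in nm; must lie inside the
#'   window.
#' @param distance Circle radius in nm; > 0.
#' @param window An [nc_window()].
#' @param max_weight Cap applied to the returned weight (`Inf` = no cap).
#' @return A single weight >= 1.
#' @examples
#' w <- nc_window(1000)
#' edge_correction_weight(c(500, 500), 100, w)  # 1: fully interior
#' edge_correction_weight(c(0, 500), 50, w)     # 2: half the circle inside
#' edge_correction_weight(c(0, 0), 50, w)       # 4: quarter circle inside
#' @export
edge_correction_weight <- function(point, distance, window, max_weight = Inf) {
  window <- assert_window(window)
  stopifnot(is.numeric(point), length(point) == 2L,
            is.numeric(distance), length(distance) == 1L, distance > 0)
  if (point[1L] < 0 || point[1L] > window$width ||
      point[2L] < 0 || point[2L] > window$height) {
    stop("`point` lies outside the window", call. = FALSE)
  }
  if (distance > min(window$width, window$height) / 2) {
    stop(sprintf(
      "distance %g nm exceeds min(width, height)/2 = %g nm, beyond which the closed-form rectangular correction is not valid",
      distance, min(window$width, window$height) / 2), call. = FALSE)
  }
  frac <- iso_inside_fraction(point[1L], point[2L], distance,
                              window$width, window$height)
  if (frac <= 0) {
    stop("circle lies entirely outside the window: weight undefined",
         call. = FALSE)
  }
  min(1 / frac, max_weight)
}

# Vectorised inside-fraction of circles centered at (x, y) with radii d,
# for a [0, W] x [0, H] rectangle. Valid for d <= min(W, H) / 2.
iso_inside_fraction <- function(x, y, d, W, H) {
  dl <- x
  dr <- W - x
  db <- y
  dt <- H - y
  edge_arc <- function(de) 2 * acos(pmin(de / d, 1))
  outside <- edge_arc(dl) + edge_arc(dr) + edge_arc(db) + edge_arc(dt)
  corner_overlap <- function(d1, d2) {
    hit <- d1 * d1 + d2 * d2 < d * d
    ov <- (pi / 2 - asin(pmin(d1 / d, 1)) - asin(pmin(d2 / d, 1))) * hit
    ov
  }
  outside <- outside -
    corner_overlap(dl, db) - corner_overlap(dl, dt) -
    corner_overlap(dr, db) - corner_overlap(dr, dt)
  1 - outside / (2 * pi)
}

#' Edge-corrected univariate Ripley K-function
#'
#' Estimates the K-function of a point pattern on a radius grid,
#'
#' \deqn{\hat K(r) = A n^{-2} \sum_{i \ne j} w_{ij}\, 1(\|x_i - x_j\| \le r),}
#'
#' where `A` is the window area, the sum runs over ordered point pairs, and
#' `w_ij` is the isotropic edge-correction weight for center `x_i` at range
#' `||x_i - x_j||` (see [edge_correction_weight()]). The variance-stabilised
#' transform `L(r) - r = sqrt(K(r)/pi) - r` is filled in as well: under
#' complete spatial randomness E\[K(r)\] = pi r^2 and L(r) - r fluctuates
#' around 0; positive values indicate clustering at scale r, negative values
#' dispersion.
#'
#' @param pattern A `point_pattern` with at least 2 points.
#' @param r Radius grid in nm (strictly increasing, positive). For
#'   `correction = "isotropic"` the largest radius must not exceed
#'   `min(width, height)/2`. Default [r_grid()] (1..240 nm).
#' @param correction Edge correction: `"isotropic"` (Ripley's weights,
#'   default), `"toroidal"` (distances wrapped on the torus, unit weights),
#'   or `"none"` (unit weights; negatively biased near the boundary).
#' @param max_weight Cap on individual isotropic weights; bounds the
#'   variance inflation from points in extreme corners at large r.
#'   Default 10; recorded on the returned curve.
#' @param pair_normalisation `"n2"` (default) divides by `n^2`; `"unbiased"`
#'   divides by `n(n-1)`, which makes the estimator exactly unbiased for a
#'   binomial (conditioned-on-n) CSR process. The two differ by the factor
#'   (n-1)/n.
#' @return An object of class `"k_curve"`: list with `r`, `k` (nm^2),
#'   `l_minus_r` (nm), `n`, `image_id`, `condition`, `correction`,
#'   `max_weight`, `pair_normalisation`, `window`.
#' @examples
#' pp <- simulate_csr(200, nc_window(1000), seed = 1)
#' kc <- k_function(pp)
#' kc$l_minus_r[50]  # fluctuates near 0 for CSR
#' @seealso [l_transform()], [csr_envelope()], [average_curves()]
#' @export
k_function <- function(pattern, r = r_grid(),
                       correction = c("isotropic", "toroidal", "none"),
                       max_weight = 10,
                       pair_normalisation = c("n2", "unbiased")) {
  assert_pattern(pattern)
  correction <- match.arg(correction)
  pair_normalisation <- match.arg(pair_normalisation)
  r <- assert_r_grid(r)
  n <- pattern$n
  if (n < 2L) {
    stop("K-function undefined for fewer than 2 points", call. = FALSE)
  }
  W <- pattern$window$width
  H <- pattern$window$height
  A <- pattern$window$area
  rmax <- r[length(r)]
  if (correction == "isotropic" && rmax > min(W, H) / 2) {
    stop(sprintf(
      "largest radius %g nm exceeds min(width, height)/2 = %g nm: closed-form isotropic correction not valid there",
      rmax, min(W, H) / 2), call. = FALSE)
  }

  if (correction == "toroidal") {
    dx <- abs(outer(pattern$x, pattern$x, "-"))
    dy <- abs(outer(pattern$y, pattern$y, "-"))
    dx <- pmin(dx, W - dx)
    dy <- pmin(dy, H - dy)
    dmat <- sqrt(dx * dx + dy * dy)
    d <- dmat[lower.tri(dmat)]
    keep <- d <= rmax
    d <- d[keep]
    wsum <- rep.int(2, length(d))            # both orders, unit weight
  } else {
    d_all <- as.numeric(stats::dist(cbind(pattern$x, pattern$y)))
    keep <- d_all <= rmax
    d <- d_all[keep]
    if (correction == "none") {
      wsum <- rep.int(2, length(d))
    } else {
      idx <- dist_pair_indices(n)
      i <- idx$i[keep]
      j <- idx$j[keep]
      pos <- d > 0
      wi <- wj <- rep.int(1, length(d))      # coincident pairs: weight 1
      if (any(pos)) {
        fi <- iso_inside_fraction(pattern$x[i[pos]], pattern$y[i[pos]],
                                  d[pos], W, H)
        fj <- iso_inside_fraction(pattern$x[j[pos]], pattern$y[j[pos]],
                                  d[pos], W, H)
        wi[pos] <- pmin(1 / fi, max_weight)
        wj[pos] <- pmin(1 / fj, max_weight)
      }
      wsum <- wi + wj
    }
  }

  denom <- if (pair_normalisation == "n2") n * n else n * (n - 1)
  if (length(d)) {
    ord <- order(d)
    cw <- cumsum(wsum[ord])
    cnt <- findInterval(r, d[ord])
    k <- ifelse(cnt > 0L, cw[pmax(cnt, 1L)], 0) * A / denom
  } else {
    k <- numeric(length(r))
  }

  structure(
    list(r = r, k = k, l_minus_r = sqrt(k / pi) - r, n = n,
         image_id = pattern$image_id, condition = pattern$condition,
         correction = correction, max_weight = max_weight,
         pair_normalisation = pair_normalisation,
         window = pattern$window),
    class = "k_curve"
  )
}

#' @export
print.k_curve <- function(x, ...) {
  band <- x$r >= 5 & x$r <= 100
  cat(sprintf("K-function curve: n = %d, %d radii in [%g, %g] nm (%s correction)\n",
              x$n, length(x$r), x$r[1L], x$r[length(x$r)], x$correction))
  if (any(band)) {
    cat(sprintf(" max L(r)-r in 5-100 nm band: %.2f nm at r = %g nm\n",
                max(x$l_minus_r[band]), x$r[band][which.max(x$l_minus_r[band])]))
  }
  invisible(x)
}

is_k_curve <- function(x) inherits(x, "k_curve")

#' Variance-stabilising L transform of a K curve
#'
#' Recomputes `L(r) - r = sqrt(K(r)/pi) - r` from the stored K values. Under
#' CSR, K(r) = pi r^2 in expectation, so L(r) - r is centered near zero with
#' approximately constant variance across r, which is why nanoclustering
#' results are displayed on this scale.
#'
#' @param curve A `k_curve`.
#' @return The curve with `l_minus_r` refilled.
#' @export
l_transform <- function(curve) {
  if (!is_k_curve(curve)) stop("expected a `k_curve`", call. = FALSE)
  if (any(curve$k < 0)) {
    stop("negative K values: cannot apply the L transform", call. = FALSE)
  }
  curve$l_minus_r <- sqrt(curve$k / pi) - curve$r
  curve
}

#' Convert a K curve to a data.frame
#'
#' @param x A `k_curve`.
#' @param ... Unused.
#' @return A data.frame with columns `r`, `k`, `l_minus_r`.
#' @export
as.data.frame.k_curve <- function(x, ...) {
  data.frame(r = x$r, k = x$k, l_minus_r = x$l_minus_r)
}

#' Write a K curve as CSV
#'
#' Columns `r`, `K`, `L_minus_r`, full precision.
#'
#' @param curve A `k_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_k_curve <- function(curve, path) {
  if (!is_k_curve(curve)) stop("expected a `k_curve`", call. = FALSE)
  df <- data.frame(r = curve$r, K = curve$k, L_minus_r = curve$l_minus_r)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

assert_shared_grid <- function(curves) {
  r0 <- curves[[1L]]$r
  for (cv in curves[-1L]) {
    if (length(cv$r) != length(r0) || !isTRUE(all.equal(cv$r, r0))) {
      stop("curves do not share a common radius grid", call. = FALSE)
    }
  }
  r0
}
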