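#' Monte-Carlo CSR envelope for L(r) - r
#'
#' Builds pointwise null bounds for the L(r) - r statistic by simulating
#' complete spatial randomness. Simulations condition on the observed point
#' count (a binomial process with exactly `n` independent uniform points),
#' the usual practice when judging a single observed pattern. For each
#' radius the lower and upper bounds are the `(1-level)/2` and
#' `1-(1-level)/2` empirical quantiles over the simulated curves.
#'
#' A pointwise envelope controls the error rate per radius, not globally
#' over the whole curve; `type = "global"` instead uses the distribution of
#' the maximum absolute deviation over the report band, giving simultaneous
#' bounds for sensitivity analysis.
#'
#' @param n Point count the CSR simulations condition on (>= 2).
#' @param window An [nc_window()].
#' @param r Radius grid in nm. Default [r_grid()].
#' @param n_simulations Number of CSR simulations. Must be at least
#'   `max(39, ceiling(2/(1-level)) - 1)` so the requested tail quantiles are
#'   resolvable (199 for `level = 0.99`). Default 999.
#' @param level Confidence level as a fraction in (0, 1). Default 0.99, the
#'   conventional choice for immunogold nanoclustering calls.
#' @param seed Integer seed; the envelope is bit-identical for a given
#'   (seed, parameters). `NULL` uses the current RNG stream.
#' @param correction,max_weight,pair_normalisation Passed to [k_function()];
#'   use the same settings as for the curves the envelope will judge.
#' @param type `"pointwise"` (default) or `"global"`.
#' @param band Radius band (nm) used for the `"global"` maximum deviation;
#'   ignored for pointwise envelopes. Default `c(5, 100)`.
#' @return An object of class `"csr_envelope"`: list with `r`, `lower`,
#'   `upper`, `level`, `n_simulations`, `conditioning_n`, `type`,
#'   `correction`, `window`, `seed`.
#' @examples
#' env <- csr_envelope(100, nc_window(1000), n_simulations = 199, seed = 1)
#' range(env$upper - env$lower)
#' @export
csr_envelope <- function(n, window, r = r_grid(), n_simulations = 999,
                         level = 0.99, seed = NULL,
                         correction = c("isotropic", "toroidal", "none"),
                         max_weight = 10,
                         pair_normalisation = c("n2", "unbiased"),
                         type = c("pointwise", "global"),
                         band = c(5, 100)) {
  window <- assert_window(window)
  correction <- match.arg(correction)
  pair_normalisation <- match.arg(pair_normalisation)
  type <- match.arg(type)
  r <- assert_r_grid(r)
  stopifnot(n >= 2, level > 0, level < 1)
  min_sims <- max(39L, as.integer(ceiling(2 / (1 - level))) - 1L)
  if (n_simulations < min_sims) {
    stop(sprintf(
      "n_simulations = %d cannot resolve the %g%% envelope quantiles; at least %d simulations are required",
      n_simulations, 100 * level, min_sims), call. = FALSE)
  }
  lmat <- simulate_csr_l_curves(n, window, r, n_simulations, seed,
                                correction, max_weight, pair_normalisation)
  if (type == "pointwise") {
    alpha <- (1 - level) / 2
    qs <- apply(lmat, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    lower <- qs[1L, ]
    upper <- qs[2L, ]
  } else {
    in_band <- r >= band[1L] & r <= band[2L]
    if (!any(in_band)) stop("global band contains no grid radii", call. = FALSE)
    dev <- apply(abs(lmat[, in_band, drop = FALSE]), 1L, max)
    crit <- stats::quantile(dev, probs = level, names = FALSE)
    lower <- rep.int(-crit, length(r))
    upper <- rep.int(crit, length(r))
  }
  structure(
    list(r = r, lower = lower, upper = upper, level = level,
         n_simulations = as.integer(n_simulations),
         conditioning_n = as.integer(n), type = type,
         correction = correction, window = window, seed = seed),
    class = "csr_envelope"
  )
}

# matrix of simulated CSR L(r)-r curves, one row per simulation
simulate_csr_l_curves <- function(n, window, r, n_simulations, seed,
                                  correction, max_weight, pair_normalisation) {
  sim_one <- function(b) {
    pp <- point_pattern(stats::runif(n, 0, window$width),
                        stats::runif(n, 0, window$height), window)
    k_function(pp, r, correction = correction, max_weight = max_weight,
               pair_normalisation = pair_normalisation)$l_minus_r
  }
  body <- function() {
    t(vapply(seq_len(n_simulations), sim_one, numeric(length(r))))
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}

#' @export
print.csr_envelope <- function(x, ...) {
  cat(sprintf(
    "%s %g%% CSR envelope: %d simulations conditioned on n = %d, r in [%g, %g] nm\n",
    x$type, 100 * x$level, x$n_simulations, x$conditioning_n,
    x$r[1L], x$r[length(x$r)]))
  invisible(x)
}

#' Classify a curve against a CSR envelope
#'
#' Compares an observed L(r) - r curve with the null envelope radius by
#' radius and summarises over a report band where nanocluster signal lives
#' (default 5-100 nm): `"clustered"` if the curve exceeds the upper bound at
#' any band radius, otherwise `"dispersed"` if it falls below the lower
#' bound at any band radius, otherwise `"random"`. Exceedance is strict: a
#' curve exactly on a bound is not called.
#'
#' @param curve A `k_curve` on the same radius grid as the envelope.
#' @param envelope A [csr_envelope()].
#' @param band Length-2 numeric: report band in nm. Default `c(5, 100)`.
#' @return An object of class `"envelope_test"`: list with `classification`
#'   (one of `"clustered"`, `"dispersed"`, `"random"`), per-radius logical
#'   vectors `above` and `below`, the `band`, and `r`.
#' @examples
#' env <- csr_envelope(150, nc_window(1000), n_simulations = 199, seed = 1)
#' pp <- simulate_thomas(thomas_params(), nc_window(1000), seed = 2)
#' exceeds_envelope(k_function(pp), env)$classification
#' @export
exceeds_envelope <- function(curve, envelope, band = c(5, 100)) {
  if (!is_k_curve(curve)) stop("expected a `k_curve`", call. = FALSE)
  if (!inherits(envelope, "csr_envelope")) {
    stop("expected a `csr_envelope`", call. = FALSE)
  }
  stopifnot(length(band) == 2L, band[1L] <= band[2L])
  if (length(curve$r) != length(envelope$r) ||
      !isTRUE(all.equal(curve$r, envelope$r))) {
    stop("curve and envelope are on different radius grids", call. = FALSE)
  }
  above <- curve$l_minus_r > envelope$upper
  below <- curve$l_minus_r < envelope$lower
  in_band <- curve$r >= band[1L] & curve$r <= band[2L]
  classification <- if (any(above & in_band)) {
    "clustered"
  } else if (any(below & in_band)) {
    "dispersed"
  } else {
    "random"
  }
  structure(
    list(classification = classification, above = above, below = below,
         band = band, r = curve$r),
    class = "envelope_test"
  )
}

#' @export
print.envelope_test <- function(x, ...) {
  cat(sprintf("envelope test: %s (band %g-%g nm; %d radii above, %d below)\n",
              x$classification, x$band[1L], x$band[2L],
              sum(x$above), sum(x$below)))
  invisible(x)
}

#' Average K curves across replicate images
#'
#' Pointwise weighted mean of a group of per-image curves, the group summary
#' shown for each condition in nanoclustering figures. `"by_point_count"`
#' (default) weights each image by its gold count — patterns with more
#' particles estimate K with less noise — while `"equal"` gives every image
#' the same weight. K and L(r) - r are each averaged pointwise, so on the
#' averaged curve `l_minus_r` is the mean of the member transforms, not the
#' transform of the mean K; the returned object records this via
#' `averaged = TRUE`.
#'
#' @param curves A non-empty list of `k_curve`s sharing one radius grid.
#' @param weighting `"by_point_count"` (default) or `"equal"`.
#' @return A `k_curve` with `n` = total points, attribute fields
#'   `n_curves` and `averaged = TRUE`, and `condition` set when unique.
#' @examples
#' pps <- lapply(1:3, function(s) simulate_csr(150, nc_window(1000), seed = s))
#' avg <- average_curves(lapply(pps, k_function))
#' @export
average_curves <- function(curves, weighting = c("by_point_count", "equal")) {
  weighting <- match.arg(weighting)
  if (!is.list(curves) || !length(curves) ||
      !all(vapply(curves, is_k_curve, logical(1)))) {
    stop("`curves` must be a non-empty list of k_curve objects", call. = FALSE)
  }
  r <- assert_shared_grid(curves)
  w <- if (weighting == "by_point_count") {
    vapply(curves, function(cv) cv$n, numeric(1))
  } else {
    rep.int(1, length(curves))
  }
  w <- w / sum(w)
  kmat <- do.call(rbind, lapply(curves, function(cv) cv$k))
  lmat <- do.call(rbind, lapply(curves, function(cv) cv$l_minus_r))
  conds <- unique(vapply(curves, function(cv) cv$condition, character(1)))
  out <- curves[[1L]]
  out$k <- as.numeric(crossprod(w, kmat))
  out$l_minus_r <- as.numeric(crossprod(w, lmat))
  out$n <- sum(vapply(curves, function(cv) cv$n, numeric(1)))
  out$image_id <- NA_character_
  out$condition <- if (length(conds) == 1L) conds else NA_character_
  out$n_curves <- length(curves)
  out$weighting <- weighting
  out$averaged <- TRUE
  out
}

#' Bootstrap comparison of two groups of K curves
#'
#' Tests whether two conditions differ in their group-mean L(r) - r curves.
#' The observed statistic is the integrated squared difference of the group
#' means over a radius band (trapezoid rule on the grid, units nm^3). The
#' null distribution is built by pooling all curves and resampling two
#' groups of the original sizes with replacement `n_bootstrap` times; the
#' p-value uses the add-one convention
#' `p = (1 + #\{T* >= T_obs\}) / (1 + n_bootstrap)`, so `p >= 1/(1 +
#' n_bootstrap)` always. The resampling unit is the image-level curve,
#' matching the replicate structure of the assay (independent membrane
#' sheets).
#'
#' @param group_a,group_b Lists of `k_curve`s (>= 2 each) on one shared
#'   grid.
#' @param n_bootstrap Number of bootstrap resamples; >= 99 required, 1000
#'   (the study convention) by default.
#' @param seed Integer seed for exact reproducibility; `NULL` uses the
#'   current RNG stream.
#' @param r_band Length-2 numeric: integration band in nm. Default
#'   `c(5, 100)`, where nanocluster signal lives.
#' @param weighting Group-mean weighting, as in [average_curves()].
#' @return An object of class `"group_comparison"`: list with `statistic`
#'   (nm^3), `p_value`, `n_bootstrap`, `seed`, `r_band`, `n_a`, `n_b`,
#'   `weighting`.
#' @examples
#' mk <- function(s) k_function(simulate_csr(150, nc_window(1000), seed = s))
#' a <- lapply(1:4, mk); b <- lapply(5:8, mk)
#' bootstrap_compare(a, b, n_bootstrap = 199, seed = 1)
#' @export
bootstrap_compare <- function(group_a, group_b, n_bootstrap = 1000,
                              seed = NULL, r_band = c(5, 100),
                              weighting = c("by_point_count", "equal")) {
  weighting <- match.arg(weighting)
  check_group <- function(g, nm) {
    if (!is.list(g) || length(g) < 2L ||
        !all(vapply(g, is_k_curve, logical(1)))) {
      stop(sprintf("`%s` must be a list of at least 2 k_curve objects", nm),
           call. = FALSE)
    }
  }
  check_group(group_a, "group_a")
  check_group(group_b, "group_b")
  if (n_bootstrap < 99) {
    stop("n_bootstrap must be at least 99", call. = FALSE)
  }
  r <- assert_shared_grid(c(group_a, group_b))
  stopifnot(length(r_band) == 2L, r_band[1L] <= r_band[2L])
  in_band <- r >= r_band[1L] & r <= r_band[2L]
  if (sum(in_band) < 2L) {
    stop("r_band contains fewer than 2 grid radii", call. = FALSE)
  }
  rb <- r[in_band]

  lmat <- do.call(rbind, lapply(c(group_a, group_b),
                                function(cv) cv$l_minus_r[in_band]))
  wts <- if (weighting == "by_point_count") {
    vapply(c(group_a, group_b), function(cv) cv$n, numeric(1))
  } else {
    rep.int(1, length(group_a) + length(group_b))
  }
  na <- length(group_a)
  nb <- length(group_b)
  ntot <- na + nb

  group_mean <- function(idx) {
    w <- wts[idx]
    as.numeric(crossprod(w / sum(w), lmat[idx, , drop = FALSE]))
  }
  trap <- function(y) {                       # integral of y^2 over the band
    y2 <- y * y
    sum(diff(rb) * (y2[-length(y2)] + y2[-1L]) / 2)
  }
  t_obs <- trap(group_mean(seq_len(na)) - group_mean(na + seq_len(nb)))

  boot <- function() {
    t_star <- numeric(n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      ia <- sample.int(ntot, na, replace = TRUE)
      ib <- sample.int(ntot, nb, replace = TRUE)
      t_star[b] <- trap(group_mean(ia) - group_mean(ib))
    }
    t_star
  }
  t_star <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  p <- (1 + sum(t_star >= t_obs)) / (1 + n_bootstrap)

  structure(
    list(statistic = t_obs, p_value = p,
         n_bootstrap = as.integer(n_bootstrap), seed = seed,
         r_band = r_band, n_a = na, n_b = nb, weighting = weighting),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "bootstrap group comparison: T = %.4g nm^3, p = %.4g (%d resamples, band %g-%g nm, groups %d vs %d)\n",
    x$statistic, x$p_value, x$n_bootstrap, x$r_band[1L], x$r_band[2L],
    x$n_a, x$n_b))
  invisible(x)
}

#' Write a CSR envelope as CSV
#'
#' Columns `r`, `lower`, `upper`.
#'
#' @param envelope A `csr_envelope`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(envelope, path) {
  if (!inherits(envelope, "csr_envelope")) {
    stop("expected a `csr_envelope`", call. = FALSE)
  }
  df <- data.frame(r = envelope$r, lower = envelope$lower,
                   upper = envelope$upper)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
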