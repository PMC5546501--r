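#' Simulate complete spatial randomness (binomial process)
#'
#' Places exactly `n` independent uniform points in the window — the null
#' model behind the Monte-Carlo envelopes, conditioned on the observed
#' point count.
#'
#' @param n Number of points (>= 0).
#' @param window An [nc_window()].
#' @param seed Integer seed for exact reproducibility; `NULL` uses the
#'   current RNG stream.
#' @param image_id,condition Labels for the generated pattern.
#' @return A `point_pattern` with exactly `n` points.
#' @examples
#' simulate_csr(200, nc_window(1000), seed = 1)
#' @export
simulate_csr <- function(n, window, seed = NULL,
                         image_id = NA_character_, condition = "csr") {
  window <- assert_window(window)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  n <- as.integer(n)
  gen <- function() {
    point_pattern(stats::runif(n, 0, window$width),
                  stats::runif(n, 0, window$height),
                  window, image_id, condition)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Parameters of a Thomas cluster process
#'
#' The clustered alternative used throughout the package's validation:
#' Poisson-distributed parents, each spawning a Poisson number of offspring
#' scattered isotropically with Gaussian standard deviation `cluster_sd`.
#' The Gaussian scatter gives closed-form expectations, which is why Thomas
#' rather than Matern is the default. Defaults (20 parents expected in a
#' 1-um^2 window, 15 offspring per parent, 10 nm scatter) produce the tight
#' small-radius clustering signature typical of Ras nanocluster patterns at
#' the scales this package analyses; they are synthetic calibration values,
#' not measurements.
#'
#' @param parent_intensity Parents per nm^2 (kappa). Default 2e-5
#'   (i.e. 20 expected parents per 1000 x 1000 nm window).
#' @param mean_offspring Expected offspring per parent (mu). Default 15.
#' @param cluster_sd Gaussian scatter of offspring around the parent, nm
#'   (sigma). Default 10.
#' @return An object of class `"thomas_params"`.
#' @export
thomas_params <- function(parent_intensity = 2e-5, mean_offspring = 15,
                          cluster_sd = 10) {
  stopifnot(parent_intensity > 0, mean_offspring > 0, cluster_sd > 0)
  structure(
    list(parent_intensity = parent_intensity,
         mean_offspring = mean_offspring, cluster_sd = cluster_sd),
    class = "thomas_params"
  )
}

#' Simulate a Thomas cluster process
#'
#' Parents are Poisson(`parent_intensity * area`) uniform in the window;
#' each spawns Poisson(`mean_offspring`) offspring displaced by an
#' isotropic Gaussian with sd `cluster_sd`. Offspring falling outside the
#' window are discarded (their count is recorded in the attribute
#' `"n_lost_window"`), so the expected retained count is slightly below
#' `kappa * A * mu` when parents sit near the boundary — negligibly so for
#' `cluster_sd` much smaller than the window.
#'
#' @param params A [thomas_params()].
#' @param window An [nc_window()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param image_id,condition Labels for the generated pattern.
#' @return A `point_pattern`; attribute `"n_parents"` records the parent
#'   count drawn and `"n_lost_window"` the offspring discarded.
#' @examples
#' simulate_thomas(thomas_params(), nc_window(1000), seed = 1)
#' @export
simulate_thomas <- function(params, window, seed = NULL,
                            image_id = NA_character_, condition = "thomas") {
  if (!inherits(params, "thomas_params")) {
    stop("`params` must be created with thomas_params()", call. = FALSE)
  }
  window <- assert_window(window)
  gen <- function() {
    n_parents <- stats::rpois(1L, params$parent_intensity * window$area)
    px <- stats::runif(n_parents, 0, window$width)
    py <- stats::runif(n_parents, 0, window$height)
    n_off <- stats::rpois(n_parents, params$mean_offspring)
    cx <- rep.int(px, n_off) + stats::rnorm(sum(n_off), 0, params$cluster_sd)
    cy <- rep.int(py, n_off) + stats::rnorm(sum(n_off), 0, params$cluster_sd)
    keep <- cx >= 0 & cx <= window$width & cy >= 0 & cy <= window$height
    pp <- point_pattern(cx[keep], cy[keep], window, image_id, condition)
    attr(pp, "n_parents") <- n_parents
    attr(pp, "n_lost_window") <- sum(!keep)
    pp
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Immunogold labeling noise model
#'
#' Physical parameters of the labeling step that turns true protein
#' positions into observed gold positions: incomplete labeling (each
#' protein carries a gold with probability `efficiency`), antibody-linker
#' displacement (isotropic Gaussian jitter), and steric exclusion between
#' the 4.5 nm gold particles themselves (hard-core distance).
#'
#' @param efficiency Labeling probability in (0, 1\]. Default 1.
#' @param linker_jitter_sd Gaussian displacement sd in nm. Default 0.
#' @param hardcore_distance Minimum allowed gold-gold distance in nm;
#'   pairs closer than this are thinned. Default 4.5, the gold diameter.
#' @return An object of class `"labeling_model"`.
#' @export
labeling_model <- function(efficiency = 1, linker_jitter_sd = 0,
                           hardcore_distance = 4.5) {
  stopifnot(efficiency > 0, efficiency <= 1,
            linker_jitter_sd >= 0, hardcore_distance >= 0)
  structure(
    list(efficiency = efficiency, linker_jitter_sd = linker_jitter_sd,
         hardcore_distance = hardcore_distance),
    class = "labeling_model"
  )
}

#' Apply labeling noise to a point pattern
#'
#' In order: (1) each point is retained independently with probability
#' `efficiency`; (2) retained points are displaced by isotropic Gaussian
#' jitter — points jittered outside the window are discarded, and the count
#' is recorded in the attribute `"n_lost_window"`; (3) pairs closer than
#' `hardcore_distance` are thinned deterministically, processing offending
#' pairs nearest-first and removing the later (higher-index) point of each,
#' until no pair violates the hard core.
#'
#' With `efficiency = 1`, zero jitter and zero hard core the pattern is
#' returned unchanged.
#'
#' @param pattern A `point_pattern` of true molecule positions.
#' @param model A [labeling_model()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `point_pattern` of observed gold positions; attributes
#'   `"n_lost_window"` and `"n_thinned"` record losses.
#' @export
apply_labeling <- function(pattern, model, seed = NULL) {
  assert_pattern(pattern)
  if (!inherits(model, "labeling_model")) {
    stop("`model` must be created with labeling_model()", call. = FALSE)
  }
  gen <- function() {
    x <- pattern$x
    y <- pattern$y
    if (model$efficiency < 1) {
      keep <- stats::runif(length(x)) < model$efficiency
      x <- x[keep]
      y <- y[keep]
    }
    n_lost <- 0L
    if (model$linker_jitter_sd > 0 && length(x)) {
      x <- x + stats::rnorm(length(x), 0, model$linker_jitter_sd)
      y <- y + stats::rnorm(length(y), 0, model$linker_jitter_sd)
      inside <- x >= 0 & x <= pattern$window$width &
        y >= 0 & y <= pattern$window$height
      n_lost <- sum(!inside)
      x <- x[inside]
      y <- y[inside]
    }
    n_thinned <- 0L
    if (model$hardcore_distance > 0 && length(x) >= 2L) {
      repeat {
        d <- stats::dist(cbind(x, y))
        viol <- which(as.numeric(d) < model$hardcore_distance)
        if (!length(viol)) break
        idx <- dist_pair_indices(length(x))
        worst <- viol[which.min(as.numeric(d)[viol])]
        drop <- max(idx$i[worst], idx$j[worst])
        n_thinned <- n_thinned + 1L
        x <- x[-drop]
        y <- y[-drop]
        if (length(x) < 2L) break
      }
    }
    pp <- point_pattern(x, y, pattern$window, pattern$image_id,
                        pattern$condition)
    attr(pp, "n_lost_window") <- n_lost
    attr(pp, "n_thinned") <- n_thinned
    pp
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a frequency-domain FLIM frame from a lifetime map
#'
#' Forward model of the homodyne measurement for a mono-exponential decay
#' at each pixel: phase `atan(w*tau) + noise` and modulation
#' `1/sqrt(1 + (w*tau)^2) + noise` with `w = 2*pi*frequency`; the noisy
#' modulation is clipped to \[0, 1\]. With zero noise the frame inverts
#' exactly through [lifetimes_from_phase_mod()] under an identity
#' calibration.
#'
#' @param tau_map Numeric matrix of per-pixel lifetimes in **ns** (>= 0).
#' @param frequency Modulation frequency in Hz. Default 4e7.
#' @param phase_noise_sd Gaussian phase noise sd in radians. Default 0.
#' @param mod_noise_sd Gaussian modulation noise sd. Default 0.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param mask Optional logical matrix passed to the frame.
#' @return A [lifetime_frame()].
#' @examples
#' fr <- simulate_flim_frame(matrix(2.5, 4, 4))
#' fr$phase[1, 1]  # atan(2*pi*4e7 * 2.5e-9)
#' @export
simulate_flim_frame <- function(tau_map, frequency = 4e7,
                                phase_noise_sd = 0, mod_noise_sd = 0,
                                seed = NULL, mask = NULL) {
  if (!is.matrix(tau_map) || !is.numeric(tau_map)) {
    stop("`tau_map` must be a numeric matrix of lifetimes in ns",
         call. = FALSE)
  }
  if (any(tau_map < 0)) stop("lifetimes must be non-negative", call. = FALSE)
  stopifnot(phase_noise_sd >= 0, mod_noise_sd >= 0)
  gen <- function() {
    wt <- 2 * pi * frequency * tau_map * 1e-9
    phase <- atan(wt)
    modulation <- 1 / sqrt(1 + wt * wt)
    if (phase_noise_sd > 0) {
      phase <- phase + stats::rnorm(length(phase), 0, phase_noise_sd)
    }
    if (mod_noise_sd > 0) {
      modulation <- modulation + stats::rnorm(length(modulation), 0, mod_noise_sd)
      modulation <- pmin(pmax(modulation, 0), 1)
    }
    lifetime_frame(matrix(phase, nrow(tau_map)),
                   matrix(modulation, nrow(tau_map)),
                   frequency, mask)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a FLIM-FRET experiment at the cell level
#'
#' Emulates the standard design: a donor-only control group and a
#' donor-plus-acceptor group, each with per-cell mean lifetimes. Donor-only
#' cells draw from Normal(`tau_d`, `cell_sd`); donor-acceptor cells from
#' Normal(`tau_d * (1 - true_e/100)`, `cell_sd`); draws are truncated to be
#' strictly positive (redrawn).
#'
#' @param tau_d True mean donor-only lifetime in ns (> 0).
#' @param true_e True FRET efficiency in percent, in \[0, 100).
#' @param n_cells Cells per group. Default 30, the study's typical minimum.
#' @param cell_sd Between-cell lifetime sd in ns (>= 0). Default 0.1.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List of two data.frames, `donor` and `donor_acceptor`, each with
#'   columns `cell_id` and `tau_ns`.
#' @examples
#' sim <- simulate_fret_experiment(2.4, true_e = 20, seed = 1)
#' fret_efficiency(sim$donor_acceptor$tau_ns, mean(sim$donor$tau_ns))
#' @export
simulate_fret_experiment <- function(tau_d, true_e, n_cells = 30,
                                     cell_sd = 0.1, seed = NULL) {
  stopifnot(tau_d > 0, true_e >= 0, true_e < 100, n_cells >= 1, cell_sd >= 0)
  gen <- function() {
    draw <- function(mu) {
      v <- stats::rnorm(n_cells, mu, cell_sd)
      while (any(v <= 0)) {
        v[v <= 0] <- stats::rnorm(sum(v <= 0), mu, cell_sd)
      }
      v
    }
    list(
      donor = data.frame(cell_id = sprintf("D%03d", seq_len(n_cells)),
                         tau_ns = draw(tau_d)),
      donor_acceptor = data.frame(cell_id = sprintf("DA%03d", seq_len(n_cells)),
                                  tau_ns = draw(tau_d * (1 - true_e / 100)))
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
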