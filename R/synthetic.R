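#' Parameters of the synthetic response surface
#'
#' The generator's ground truth for tensile stress at 600% strain (MPa) as a
#' function of the three descriptors. The surface is linear in each feature
#' with a hinge interaction that switches on above a hydrogen-bond strength
#' threshold `tau`, so that at high `eps_h` a small change in `omega`
#' produces a large change in stress:
#'
#' TS = beta0 + beta_h * eps_h + beta_w * omega + beta_nh * eps_nh +
#'      beta_int * omega * max(eps_h - tau, 0)
#'
#' All slope coefficients are non-negative (every descriptor acts positively
#' on stress) and the defaults are fixed so that the mean absolute partial
#' effect over the default sampling box orders eps_h > omega > eps_nh.
#'
#' @param beta0 Baseline stress (MPa).
#' @param beta_h,beta_w,beta_nh Linear coefficients for `eps_h`, `omega`,
#'   `eps_nh` (MPa per unit feature); must be non-negative.
#' @param beta_int Coefficient of the `omega * max(eps_h - tau, 0)`
#'   interaction; non-negative.
#' @param tau Interaction threshold on `eps_h` (kcal/mol).
#' @param noise_sd Gaussian observation noise (MPa). The default `NULL`
#'   resolves to 5% of the surface's range over the sampling box at
#'   generation time.
#' @return An object of class `surface_params`.
#' @export
surface_params <- function(beta0 = 2, beta_h = 4, beta_w = 0.3, beta_nh = 0.1,
                           beta_int = 0.4, tau = 2.5, noise_sd = NULL) {
  betas <- c(beta_h = beta_h, beta_w = beta_w, beta_nh = beta_nh,
             beta_int = beta_int)
  if (any(betas < 0)) {
    stop_stressaug("All slope coefficients must be non-negative.", "spec")
  }
  if (!is.null(noise_sd) && noise_sd < 0) {
    stop_stressaug("`noise_sd` must be non-negative.", "spec")
  }
  structure(
    list(beta0 = beta0, beta_h = beta_h, beta_w = beta_w, beta_nh = beta_nh,
         beta_int = beta_int, tau = tau, noise_sd = noise_sd),
    class = "surface_params"
  )
}

#' Sampling design for the synthetic benchmark
#'
#' Emulates a small molecular-dynamics campaign whose runs concentrate in two
#' regions of the design space: features are drawn from a two-component
#' Gaussian mixture truncated to a box, mimicking the clustered, imbalanced
#' sampling typical of simulation studies.
#'
#' @param n Number of samples (default 86).
#' @param mixture_weights Length-2 positive weights summing to 1.
#' @param centers 2x3 matrix of blob centers, columns (omega, eps_h, eps_nh).
#' @param spreads 2x3 matrix of blob standard deviations.
#' @param bounds 2x3 matrix; row 1 lower, row 2 upper bounds per feature.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n = 86,
                        mixture_weights = c(0.4, 0.6),
                        centers = rbind(c(8, 1.0, 0.3), c(20, 3.4, 0.5)),
                        spreads = rbind(c(3, 0.4, 0.15), c(3.5, 0.7, 0.2)),
                        bounds = rbind(low = c(0, 0.38, 0),
                                       high = c(30, 5, 1))) {
  if (n < 1) stop_stressaug("`n` must be at least 1.", "spec")
  if (length(mixture_weights) != 2 || any(mixture_weights < 0) ||
      abs(sum(mixture_weights) - 1) > 1e-8) {
    stop_stressaug("`mixture_weights` must be two non-negative values summing to 1.",
                   "spec")
  }
  if (any(bounds[1, ] >= bounds[2, ])) {
    stop_stressaug("Degenerate bounds: each lower bound must be below its upper bound.",
                   "spec")
  }
  structure(
    list(n = n, mixture_weights = mixture_weights, centers = centers,
         spreads = spreads, bounds = bounds),
    class = "design_spec"
  )
}

#' Evaluate the noiseless synthetic surface
#'
#' @param omega,eps_h,eps_nh Numeric vectors (recycled to a common length).
#' @param params A [surface_params()] object.
#' @return Numeric vector of noiseless tensile stress (MPa).
#' @examples
#' true_surface(10, 3, 0.5,
#'              surface_params(beta0 = 1, beta_h = 2, beta_w = 0.1,
#'                             beta_nh = 0.05, beta_int = 0.3, tau = 2))
#' @export
true_surface <- function(omega, eps_h, eps_nh, params = surface_params()) {
  stopifnot(inherits(params, "surface_params"))
  params$beta0 + params$beta_h * eps_h + params$beta_w * omega +
    params$beta_nh * eps_nh +
    params$beta_int * omega * pmax(eps_h - params$tau, 0)
}

# Surface range over the bounding box; the hinge surface is monotone in every
# coordinate so the extremes sit at box corners.
surface_range <- function(params, bounds) {
  corners <- expand.grid(omega = bounds[, 1], eps_h = bounds[, 2],
                         eps_nh = bounds[, 3])
  ts <- true_surface(corners$omega, corners$eps_h, corners$eps_nh, params)
  range(ts)
}

resolve_noise_sd <- function(params, spec) {
  if (!is.null(params$noise_sd)) return(params$noise_sd)
  r <- surface_range(params, spec$bounds)
  0.05 * diff(r)
}

#' Draw a clustered feature design
#'
#' Samples `n` feature triples from the two-blob truncated Gaussian mixture.
#' Out-of-box draws are rejected and redrawn (never clipped), with a cap of
#' 1000 rejections per row. Blob membership is returned in a `.blob` column
#' for cluster-recovery checks; drop it before modelling.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed.
#' @return Tibble with columns `omega`, `eps_h`, `eps_nh`, `.blob`.
#' @export
sample_design <- function(spec = design_spec(), seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  with_seed(seed, {
    blob <- sample(1:2, spec$n, replace = TRUE, prob = spec$mixture_weights)
    X <- matrix(NA_real_, spec$n, 3)
    for (i in seq_len(spec$n)) {
      b <- blob[i]
      for (attempt in seq_len(1000L)) {
        x <- rnorm(3, mean = spec$centers[b, ], sd = spec$spreads[b, ])
        if (all(x >= spec$bounds[1, ]) && all(x <= spec$bounds[2, ])) break
        x <- NULL
      }
      if (is.null(x)) {
        stop_stressaug("Rejection sampling exceeded 1000 attempts for a row; blob spread is incompatible with the bounds.",
                       "rejection_cap")
      }
      X[i, ] <- x
    }
    tibble::tibble(omega = X[, 1], eps_h = X[, 2], eps_nh = X[, 3],
                   .blob = blob)
  })
}

#' Generate a synthetic benchmark dataset
#'
#' Draws a clustered design and attaches a noisy target:
#' `ts = true_surface(x) + N(0, noise_sd^2)` per row. This is the stand-in
#' for a small molecular-dynamics campaign (default n = 86 runs) used
#' throughout the package's tests and examples.
#'
#' @param spec A [design_spec()].
#' @param params A [surface_params()].
#' @param seed Integer seed.
#' @param keep_blob Keep the `.blob` membership column?
#' @return Tibble with `omega`, `eps_h`, `eps_nh`, `ts`, `provenance`
#'   (all `"original"`), and optionally `.blob`.
#' @export
generate_dataset <- function(spec = design_spec(), params = surface_params(),
                             seed = NULL, keep_blob = FALSE) {
  noise_sd <- resolve_noise_sd(params, spec)
  with_seed(seed, {
    design <- sample_design(spec)
    mu <- true_surface(design$omega, design$eps_h, design$eps_nh, params)
    design$ts <- mu + rnorm(spec$n, 0, noise_sd)
    design$provenance <- rep("original", spec$n)
    if (!keep_blob) design$.blob <- NULL
    dplyr::relocate(design, dplyr::any_of(".blob"), .after = "provenance")
  })
}

#' Cross-link bond count from sulfur loading
#'
#' Converts a sulfur loading in phr (parts per hundred rubber by mass) into
#' the number of cross-link bonds for a bead-spring network, assuming each
#' bond consumes a fixed number of sulfur atoms (3 for a trisulfide bond):
#' `round((phr/100 * n_chains * chain_molar_mass / sulfur_molar_mass) / s_atoms_per_bond)`.
#'
#' @param phr_sulfur Sulfur loading, parts per hundred rubber (>= 0).
#' @param n_chains Number of polymer chains in the system.
#' @param chain_molar_mass Molar mass of one chain (g/mol).
#' @param sulfur_molar_mass Molar mass of sulfur (g/mol).
#' @param s_atoms_per_bond Sulfur atoms consumed per cross-link bond.
#' @return Integer bond count.
#' @examples
#' crosslink_count(2, 100, 22508.0) # 468 bonds for 2 phr, trisulfide
#' @export
crosslink_count <- function(phr_sulfur, n_chains, chain_molar_mass,
                            sulfur_molar_mass = 32.06, s_atoms_per_bond = 3) {
  if (phr_sulfur < 0) stop_stressaug("`phr_sulfur` must be non-negative.", "spec")
  if (n_chains <= 0 || chain_molar_mass <= 0 || sulfur_molar_mass <= 0 ||
      s_atoms_per_bond <= 0) {
    stop_stressaug("Chain count, molar masses and atoms per bond must be positive.",
                   "spec")
  }
  moles_sulfur <- phr_sulfur / 100 * n_chains * chain_molar_mass / sulfur_molar_mass
  as.integer(round(moles_sulfur / s_atoms_per_bond))
}
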