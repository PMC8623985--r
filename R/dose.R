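#' Organ absorbed doses from time-integrated activities
#'
#' MIRD schema: `D(target) = sum_source a_tilde(source) * S(target <- source)`.
#' Absorbed dose in mGy/MBq is reported numerically as mSv/MBq (radiation
#' weighting factor 1 for beta and gamma).
#'
#' @param tia Data frame from [build_all_tia()] (columns `organ`,
#'   `a_tilde_mbq_s_per_mbq`).
#' @param s An `s_matrix` from [generate_s_matrix()] or [read_s_matrix()].
#' @param remainder_sources Named character vector remapping source organs
#'   that have no column of their own to a pooled source; the default routes
#'   blood-borne activity to the `"total body"` remainder.
#' @return Named numeric vector of absorbed dose (mSv/MBq) per target organ.
#' @export
organ_doses <- function(tia, s, remainder_sources = c(blood = "total body")) {
  doses <- stats::setNames(numeric(nrow(s)), rownames(s))
  for (i in seq_len(nrow(tia))) {
    src <- tia$organ[i]
    if (src %in% names(remainder_sources)) src <- remainder_sources[[src]]
    if (!src %in% colnames(s)) {
      stop("organ_doses: source organ '", tia$organ[i],
           "' is not in the S matrix and has no remainder rule",
           call. = FALSE)
    }
    doses <- doses + tia$a_tilde_mbq_s_per_mbq[i] * s[, src]
  }
  doses
}

#' Non-penetrating absorbed fraction of a unit-density sphere
#'
#' Edge-loss model: electrons emitted within one mean beta range of the
#' sphere surface partially escape, giving
#' `phi_np = 1 - (3/4) (r_range / R_sphere)` for `r_range << R_sphere`,
#' clamped into (0, 1]. `phi_np -> 1` as the mass grows.
#'
#' @param mass_g Sphere mass in grams (unit density, so volume = mass in cc).
#' @param range_um Mean beta range in micrometres.
#' @return Absorbed fraction in (0, 1]; vectorized over `mass_g`.
#' @export
sphere_phi_np <- function(mass_g, range_um = 670) {
  stopifnot(all(mass_g > 0))
  r_sphere_cm <- (3 * mass_g / (4 * pi))^(1 / 3)
  phi <- 1 - 0.75 * (range_um * 1e-4) / r_sphere_cm
  pmin(1, pmax(phi, .Machine$double.eps))
}

#' Self-absorbed dose of a unit-density sphere
#'
#' Sphere model for tumor dosimetry: activity distributed uniformly in a
#' unit-density sphere, dose
#' `D = a_tilde * (delta_np * phi_np + delta_p * phi_p) / mass`,
#' with `phi_np` from the edge-loss model ([sphere_phi_np()]) and `phi_p` a
#' small constant photon absorbed fraction (sub-gram spheres absorb only a
#' few percent of 0.2 MeV photons; default 0.01). Reported in mGy/MBq: no
#' tissue weighting factor applies to a sphere.
#'
#' @param a_tilde Tumor time-integrated activity, MBq s per MBq injected.
#' @param decay A [decay_data()] object.
#' @param mass_g Sphere mass in grams.
#' @param phi_p Photon absorbed fraction of the sphere.
#' @return Absorbed dose in mGy per MBq injected.
#' @export
sphere_dose <- function(a_tilde, decay = lu177_decay_data(), mass_g = 0.5,
                        phi_p = 0.01) {
  stopifnot(mass_g > 0, a_tilde >= 0)
  mev_to_j <- 1.602e-13
  e_j <- (decay$delta_np_mev * sphere_phi_np(mass_g, decay$mean_beta_range_um) +
            decay$delta_p_mev * phi_p) * mev_to_j
  a_tilde * e_j / (mass_g / 1000) * 1e9  # 1e6 decays/MBq s * 1e3 mGy/Gy
}

#' ICRP-60 tissue weighting factors
#'
#' The tissue weighting set used by classic internal-dosimetry software for
#' the effective dose: gonads 0.20; red marrow, colon, lung, stomach 0.12
#' each; bladder, breast, liver, oesophagus, thyroid 0.05 each; skin and
#' bone surface 0.01 each; remainder 0.05. Sums to 1.
#'
#' @return Named numeric vector of weights (names in this package's organ
#'   terms where a measured organ maps onto the tissue; `"remainder"` keyed
#'   explicitly).
#' @export
icrp60_weights <- function() {
  c("gonads" = 0.20,
    "bone marrow" = 0.12,   # red marrow
    "large intestine" = 0.12,  # colon
    "lung" = 0.12,
    "stomach" = 0.12,
    "bladder" = 0.05,
    "breast" = 0.05,
    "liver" = 0.05,
    "oesophagus" = 0.05,
    "thyroid" = 0.05,
    "skin" = 0.01,
    "bone" = 0.01,          # bone surface
    "remainder" = 0.05)
}

#' Effective dose from organ doses
#'
#' `E = sum_T w_T D_T`. Weighted tissues absent from `doses` contribute 0
#' with a warning; the remainder weight is applied to the mean dose of the
#' unweighted organs present (0 if there are none).
#'
#' @param doses Named vector of organ doses (mSv/MBq), e.g. [organ_doses()].
#' @param weights Named weights summing to 1, e.g. [icrp60_weights()].
#' @return Effective dose in mSv/MBq.
#' @export
effective_dose <- function(doses, weights = icrp60_weights()) {
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("effective_dose: weights must sum to 1", call. = FALSE)
  }
  named <- setdiff(names(weights), "remainder")
  e <- 0
  missing_tissues <- character(0)
  for (tis in named) {
    if (tis %in% names(doses)) {
      e <- e + weights[[tis]] * doses[[tis]]
    } else {
      missing_tissues <- c(missing_tissues, tis)
    }
  }
  if (length(missing_tissues) > 0) {
    warning("effective_dose: no dose for weighted tissue(s), using 0: ",
            paste(missing_tissues, collapse = ", "), call. = FALSE)
  }
  if ("remainder" %in% names(weights)) {
    rest <- doses[setdiff(names(doses), c(named, "total body", "tumor"))]
    e <- e + weights[["remainder"]] * (if (length(rest) > 0) mean(rest) else 0)
  }
  unname(e)
}
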