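# shared fixtures and oracles for the test suite

# published intratumoral biodistribution means/SDs (%ID/g), 16 organs x 4
# timepoints; the ground truth the packaged per-animal fixture must summarize
# back to
ref_biodist_means <- function() {
  organs <- c("blood", "heart", "lung", "liver", "stomach",
              "small intestine", "large intestine", "spleen", "pancreas",
              "kidney", "bone", "muscle", "tumor", "bone marrow", "brain",
              "urine")
  m <- rbind(
    c(5.43, 0.16, 0.21, 0.15),
    c(1.14, 0.27, 0.23, 0.17),
    c(2.59, 0.81, 0.62, 0.54),
    c(8.91, 17.68, 10.43, 7.85),
    c(0.59, 0.36, 0.39, 0.31),
    c(0.81, 0.61, 0.74, 0.24),
    c(0.51, 0.20, 0.25, 0.15),
    c(5.99, 8.49, 4.85, 2.53),
    c(0.65, 0.12, 0.13, 0.14),
    c(8.97, 7.04, 4.31, 4.23),
    c(0.65, 0.88, 1.74, 2.20),
    c(0.28, 0.07, 0.10, 0.04),
    c(125.09, 120.08, 35.62, 61.44),
    c(2.12, 0.55, 2.15, 0.00),
    c(0.16, 0.02, 0.02, 0.03),
    c(183.23, 11.41, 2.04, 2.49))
  dimnames(m) <- list(organs, c("4", "24", "48", "72"))
  m
}

# minimal valid per-animal table: one organ, n animals, values given per
# timepoint (recycled over animals unless a matrix)
make_table <- function(values, times = c(4, 24, 48, 72), organ = "liver",
                       n_animals = 1, route = "intratumoral",
                       decay_corrected = TRUE) {
  grid <- expand.grid(animal = seq_len(n_animals), time_h = times)
  biodistribution_table(
    data.frame(animal_id = sprintf("m%02d", grid$animal),
               organ = organ, time_h = grid$time_h,
               pct_id_per_g = rep(values, each = n_animals)),
    route = route, decay_corrected = decay_corrected)
}

# independent numerical-quadrature oracle for integrate_tac(): integrates
# the same piecewise activity model with stats::integrate
tia_quadrature <- function(fit, decay = lu177_decay_data(),
                           peak_handling = "ignore_pre_peak") {
  lam_eff <- fit$lambda_eff_per_h
  expo <- function(t) (fit$A0_pct_ia / 100) * exp(-lam_eff * t)
  if (peak_handling == "ignore_pre_peak") {
    val <- stats::integrate(expo, 0, Inf, rel.tol = 1e-10)$value
    return(3600 * val)
  }
  t_peak <- min(fit$fit_window)
  act <- fit$points$pct_ia / 100
  if (fit$decay_corrected) {
    act <- act * exp(-decay$lambda_phys_per_h * fit$points$time_h)
  }
  pre <- fit$points$time_h <= t_peak
  tpre <- c(0, fit$points$time_h[pre]); apre <- c(0, act[pre])
  ramp <- 0
  if (length(tpre) > 1) {
    for (i in seq_len(length(tpre) - 1)) {
      f <- stats::approxfun(tpre[i:(i + 1)], apre[i:(i + 1)])
      ramp <- ramp + stats::integrate(f, tpre[i], tpre[i + 1],
                                      rel.tol = 1e-10)$value
    }
  }
  tail <- stats::integrate(expo, t_peak, Inf, rel.tol = 1e-10)$value
  3600 * (ramp + tail)
}

# noiseless single-organ uptake points A0 * exp(-lambda * t)
expo_points <- function(A0, lambda, times = c(4, 24, 48, 72)) {
  data.frame(time_h = times, pct_ia = A0 * exp(-lambda * times))
}
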