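#' Fit a mono-exponential time-activity curve for one organ
#'
#' Log-linear least squares on the uptake points from the observed peak
#' onward (`monoexp_from_peak`). The fitted slope is the biological clearance
#' constant when the input is decay-corrected, or the effective constant
#' otherwise; a positive slope (rising uptake, e.g. bone remodeling) is
#' clamped to zero biological clearance, the most conservative admissible
#' kinetics, and the constrained zero-slope fit takes the geometric mean of
#' the window as its level.
#'
#' Window rule: the window starts at the peak (argmax of uptake; ties go to
#' the earlier timepoint) and drops non-positive values, whose logarithm is
#' undefined. If fewer than two positive points remain at or after the peak
#' (a rising curve, or a terminal zero), the window widens to all positive
#' points of the series.
#'
#' @param points Data frame with columns `time_h` and `pct_ia` (human uptake
#'   points for one organ, e.g. one organ's rows of [extrapolate_table()]).
#' @param decay A [decay_data()] object.
#' @param decay_corrected Logical; whether `pct_ia` is corrected to injection
#'   time (physical decay then has to be restored during integration).
#' @param organ Optional organ label stored on the fit.
#' @return Object of class `tac_fit`: `A0_pct_ia` (back-extrapolated
#'   zero-time intercept of the fitted exponential), `lambda_bio_per_h`
#'   (clamped to >= 0), `lambda_eff_per_h = lambda_bio + lambda_phys`,
#'   `method`, `fit_window` (timepoints used), `rms_log_residual`, the input
#'   `points`, and flags `decay_corrected` / `zero_activity`.
#' @export
fit_monoexponential <- function(points, decay = lu177_decay_data(),
                                decay_corrected = TRUE, organ = NA_character_) {
  stopifnot(all(c("time_h", "pct_ia") %in% names(points)))
  t <- points$time_h
  y <- points$pct_ia
  ord <- order(t)
  t <- t[ord]; y <- y[ord]
  if (any(y < 0)) stop("fit_monoexponential: negative uptake", call. = FALSE)

  make_fit <- function(A0, lam_bio, window, rms, zero = FALSE) {
    structure(list(
      organ = organ,
      A0_pct_ia = A0,
      lambda_bio_per_h = lam_bio,
      lambda_eff_per_h = lam_bio + decay$lambda_phys_per_h,
      lambda_phys_per_h = decay$lambda_phys_per_h,
      method = "monoexp_from_peak",
      fit_window = window,
      rms_log_residual = rms,
      points = data.frame(time_h = t, pct_ia = y),
      decay_corrected = decay_corrected,
      zero_activity = zero
    ), class = "tac_fit")
  }

  if (all(y == 0)) {
    return(make_fit(0, 0, numeric(0), NA_real_, zero = TRUE))
  }
  if (length(unique(t)) < 2) {
    stop("fit_monoexponential: need >= 2 distinct timepoints", call. = FALSE)
  }

  ipk <- which.max(y)  # which.max already breaks ties toward the earlier point
  tw <- t[ipk:length(t)]; yw <- y[ipk:length(y)]
  pos <- yw > 0
  tw <- tw[pos]; yw <- yw[pos]
  if (length(tw) < 2) {            # widen to the full series
    pos <- y > 0
    tw <- t[pos]; yw <- y[pos]
  }
  if (length(tw) < 2) {
    stop("fit_monoexponential: fewer than 2 positive points to fit",
         call. = FALSE)
  }

  ly <- log(yw)
  slope <- sum((tw - mean(tw)) * (ly - mean(ly))) / sum((tw - mean(tw))^2)
  if (-slope >= 0) {
    lam_fit <- -slope
    a0 <- exp(mean(ly) - slope * mean(tw))
    resid <- ly - (log(a0) + slope * tw)
  } else {
    # rising curve: clamp to zero clearance; constrained zero-slope LS level
    lam_fit <- 0
    a0 <- exp(mean(ly))
    resid <- ly - mean(ly)
  }
  rms <- sqrt(mean(resid^2))

  if (decay_corrected) {
    lam_bio <- lam_fit
  } else {
    # observed decline already contains physical decay
    lam_bio <- max(0, lam_fit - decay$lambda_phys_per_h)
  }
  make_fit(a0, lam_bio, tw, rms)
}

#' Integrate a fitted time-activity curve
#'
#' Closed-form time-integrated activity (number of disintegrations per unit
#' injected activity) of the fitted organ curve. For decay-corrected input
#' the integrand is `A0 exp(-lambda_eff t)` with
#' `lambda_eff = lambda_bio + lambda_phys`; for raw input the fitted curve
#' already decays effectively. With `"ignore_pre_peak"` the analytic integral
#' runs from t = 0 using the back-extrapolated intercept; with
#' `"trapezoid_pre_peak"` the rise from t = 0 (activity assumed 0) to the
#' peak is integrated by decay-weighted trapezoids over the observed points
#' and the analytic exponential tail is added from the peak onward.
#'
#' @param fit A [fit_monoexponential()] result.
#' @param decay A [decay_data()] object.
#' @param peak_handling `"ignore_pre_peak"` (default) or
#'   `"trapezoid_pre_peak"`.
#' @return Object of class `tia`: `organ`, `a_tilde_mbq_s_per_mbq`
#'   (MBq s per MBq injected; numerically 1e6 disintegrations per MBq), and
#'   the `fit`.
#' @export
integrate_tac <- function(fit, decay = lu177_decay_data(),
                          peak_handling = c("ignore_pre_peak",
                                            "trapezoid_pre_peak")) {
  peak_handling <- match.arg(peak_handling)
  stopifnot(inherits(fit, "tac_fit"))
  lam_eff <- fit$lambda_eff_per_h
  out <- function(a_tilde) {
    structure(list(organ = fit$organ,
                   a_tilde_mbq_s_per_mbq = a_tilde,
                   peak_handling = peak_handling,
                   fit = fit),
              class = "tia")
  }
  if (fit$zero_activity) return(out(0))

  # activity (fraction of injected, decaying) at observed points
  act <- fit$points$pct_ia / 100
  if (fit$decay_corrected) {
    act <- act * exp(-decay$lambda_phys_per_h * fit$points$time_h)
  }
  t_peak <- if (length(fit$fit_window) > 0) min(fit$fit_window) else 0

  if (peak_handling == "ignore_pre_peak") {
    a_tilde_h <- (fit$A0_pct_ia / 100) / lam_eff
  } else {
    tt <- fit$points$time_h
    pre <- tt <= t_peak
    tpre <- c(0, tt[pre]); apre <- c(0, act[pre])
    trap <- sum(diff(tpre) * (utils::head(apre, -1) + apre[-1]) / 2)
    tail <- (fit$A0_pct_ia / 100) * exp(-lam_eff * t_peak) / lam_eff
    a_tilde_h <- trap + tail
  }
  out(3600 * a_tilde_h)
}

#' Fit and integrate every organ of a human-uptake table
#'
#' @param uptake Output of [extrapolate_table()].
#' @param decay A [decay_data()] object.
#' @param peak_handling Passed to [integrate_tac()].
#' @param on_insufficient What to do when an organ cannot be fitted
#'   (fewer than two positive points): `"error"` propagates the fit error;
#'   `"fallback_physical"` assumes zero biological clearance from the single
#'   positive observation (conservative) and records the fallback.
#' @return Data frame, one row per organ, with columns `organ`,
#'   `a_tilde_mbq_s_per_mbq`, `A0_pct_ia`, `lambda_bio_per_h`,
#'   `lambda_eff_per_h`, `method`; the `tia` objects are attached as the
#'   `"tias"` attribute.
#' @export
build_all_tia <- function(uptake, decay = lu177_decay_data(),
                          peak_handling = "ignore_pre_peak",
                          on_insufficient = c("error", "fallback_physical")) {
  on_insufficient <- match.arg(on_insufficient)
  dc <- isTRUE(attr(uptake, "decay_corrected"))
  organs <- unique(uptake$organ)
  tias <- lapply(organs, function(og) {
    pts <- uptake[uptake$organ == og, c("time_h", "pct_ia")]
    fit <- tryCatch(
      fit_monoexponential(pts, decay, decay_corrected = dc, organ = og),
      error = function(e) {
        if (on_insufficient == "error") stop(e)
        i <- which(pts$pct_ia > 0)[1]
        structure(list(organ = og, A0_pct_ia = pts$pct_ia[i],
                       lambda_bio_per_h = 0,
                       lambda_eff_per_h = decay$lambda_phys_per_h,
                       lambda_phys_per_h = decay$lambda_phys_per_h,
                       method = "single_point_physical_fallback",
                       fit_window = pts$time_h[i], rms_log_residual = NA_real_,
                       points = pts, decay_corrected = dc,
                       zero_activity = FALSE),
                  class = "tac_fit")
      })
    integrate_tac(fit, decay, peak_handling = peak_handling)
  })
  res <- data.frame(
    organ = organs,
    a_tilde_mbq_s_per_mbq = vapply(tias, `[[`, numeric(1),
                                   "a_tilde_mbq_s_per_mbq"),
    A0_pct_ia = vapply(tias, function(x) x$fit$A0_pct_ia, numeric(1)),
    lambda_bio_per_h = vapply(tias, function(x) x$fit$lambda_bio_per_h,
                              numeric(1)),
    lambda_eff_per_h = vapply(tias, function(x) x$fit$lambda_eff_per_h,
                              numeric(1)),
    method = vapply(tias, function(x) x$fit$method, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "tias") <- stats::setNames(tias, organs)
  res
}

#' @export
print.tac_fit <- function(x, ...) {
  cat(sprintf(
    "<tac_fit> %s: A0 = %.4g %%IA, lambda_bio = %.4g /h, lambda_eff = %.4g /h (%s)\n",
    x$organ, x$A0_pct_ia, x$lambda_bio_per_h, x$lambda_eff_per_h, x$method))
  invisible(x)
}

#' @export
print.tia <- function(x, ...) {
  cat(sprintf("<tia> %s: a_tilde = %.4g MBq s/MBq (%s)\n",
              x$organ, x$a_tilde_mbq_s_per_mbq, x$peak_handling))
  invisible(x)
}
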