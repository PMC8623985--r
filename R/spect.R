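#' Cylinder calibration factor for SPECT semi-quantification
#'
#' A cylinder of known activity and volume is scanned and its mean ROI
#' intensity measured; the factor converts reconstructed intensity to
#' activity concentration:
#' `factor = source_activity / (roi_intensity * cylinder_volume_cc)`,
#' in (activity per cc) per intensity unit.
#'
#' @param source_activity Activity of the reference cylinder (> 0), in the
#'   same units as injected activities downstream.
#' @param roi_intensity Mean reconstructed ROI intensity of the cylinder
#'   (> 0).
#' @param cylinder_volume_cc Cylinder volume in cc (> 0).
#' @return Object of class `calibration_factor` with fields `factor`,
#'   `source_activity`, `cylinder_volume_cc`, and a `units` note.
#' @export
cylinder_factor <- function(source_activity, roi_intensity,
                            cylinder_volume_cc) {
  if (source_activity <= 0 || roi_intensity <= 0 || cylinder_volume_cc <= 0) {
    stop("cylinder_factor: all inputs must be > 0", call. = FALSE)
  }
  structure(list(
    factor = source_activity / (roi_intensity * cylinder_volume_cc),
    source_activity = source_activity,
    cylinder_volume_cc = cylinder_volume_cc,
    units = "(activity per cc) per ROI intensity unit"
  ), class = "calibration_factor")
}

#' Convert an ROI measurement to %ID/cc
#'
#' `value = 100 * intensity * factor / injected_activity`: the calibrated
#' activity concentration in the ROI as a percentage of the injected
#' activity per cc.
#'
#' @param intensity Mean ROI intensity (>= 0).
#' @param cf A [cylinder_factor()].
#' @param injected_activity Activity administered to the subject (> 0), same
#'   units as the calibration source activity.
#' @return %ID/cc value(s); vectorized over `intensity`.
#' @export
roi_to_pct_id_per_cc <- function(intensity, cf, injected_activity) {
  stopifnot(inherits(cf, "calibration_factor"))
  if (any(injected_activity <= 0)) {
    stop("roi_to_pct_id_per_cc: injected_activity must be > 0",
         call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("roi_to_pct_id_per_cc: intensity must be >= 0", call. = FALSE)
  }
  100 * intensity * cf$factor / injected_activity
}

#' Read ROI measurements from delimited text
#'
#' Header: `subject,region,time_h,intensity,injected_activity`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame of the five columns.
#' @export
read_roi_measurements <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("subject", "region", "time_h", "intensity",
                "injected_activity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("ROI format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$injected_activity <= 0)) {
    stop("ROI validation error: injected_activity must be > 0",
         call. = FALSE)
  }
  df
}

#' Correlate imaging semi-quantification with biodistribution
#'
#' Pearson correlation and ordinary least-squares line between paired
#' imaging (%ID/cc) and biodistribution (%ID/g) series.
#'
#' @param imaging Numeric vector of %ID/cc values.
#' @param biodist Numeric vector of %ID/g values, paired with `imaging` by
#'   (subject, time).
#' @return List with `r` (Pearson, in \[-1, 1\]), `slope`, `intercept`, `n`,
#'   where the line is `biodist = intercept + slope * imaging`.
#' @export
correlate_imaging_biodist <- function(imaging, biodist) {
  if (length(imaging) != length(biodist)) {
    stop("correlate_imaging_biodist: series must have equal length",
         call. = FALSE)
  }
  if (length(imaging) < 3) {
    stop("correlate_imaging_biodist: need >= 3 paired values", call. = FALSE)
  }
  if (stats::sd(imaging) == 0 || stats::sd(biodist) == 0) {
    stop("correlate_imaging_biodist: undefined correlation, a series has ",
         "zero variance", call. = FALSE)
  }
  fit <- stats::lm(biodist ~ imaging)
  list(r = stats::cor(imaging, biodist),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(imaging))
}
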