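#' Tumor-to-organ absorbed dose ratio
#'
#' Ratio of the sphere-model tumor dose (mGy/MBq) to a reference organ's
#' absorbed dose (mSv/MBq); the two units are treated as numerically equal
#' under the radiation weighting factor of 1 for beta/gamma emitters.
#' Computed at full precision; use [format_ratio()] for the display
#' convention.
#'
#' @param report A [dose_report()].
#' @param reference_organ Name of the denominator organ.
#' @return Numeric ratio (0 if the tumor dose is 0).
#' @export
dose_ratio <- function(report, reference_organ) {
  stopifnot(inherits(report, "dose_report"))
  ref <- normalize_organ(reference_organ)
  if (!ref %in% names(report$organ_doses)) {
    stop("dose_ratio: no dose for reference organ '", ref, "'",
         call. = FALSE)
  }
  d_ref <- report$organ_doses[[ref]]
  if (d_ref <= 0) {
    stop("dose_ratio: undefined ratio, reference organ '", ref,
         "' has zero dose", call. = FALSE)
  }
  if (is.na(report$tumor_sphere_dose)) {
    stop("dose_ratio: report has no tumor sphere dose", call. = FALSE)
  }
  report$tumor_sphere_dose / d_ref
}

#' Display rounding for dose ratios
#'
#' Ratios at or above 1 are shown with 1 decimal, ratios below 1 with 2
#' decimals (the usual convention of published dose-ratio tables).
#'
#' @param x Numeric ratios.
#' @return Character vector.
#' @export
format_ratio <- function(x) {
  ifelse(abs(x) >= 1, sprintf("%.1f", x), sprintf("%.2f", x))
}

#' Compare two administration routes organ by organ
#'
#' Pairs the organ doses of two dose reports (e.g. intratumoral vs
#' intravenous), lists organs present in only one report instead of dropping
#' them, and computes the tumor-to-reference dose ratios for both routes.
#'
#' @param it_report,iv_report [dose_report()] objects for the two routes.
#' @param reference_organs Organs for the tumor-to-organ ratios.
#' @return Object of class `route_comparison`: `paired` (data frame organ,
#'   dose_1, dose_2, difference), `ratios` (data frame reference x route),
#'   `only_in` (discrepancy listing), `routes`, `sphere_mass_g`.
#' @export
compare_routes <- function(it_report, iv_report,
                           reference_organs = c("brain", "thyroid")) {
  stopifnot(inherits(it_report, "dose_report"),
            inherits(iv_report, "dose_report"))
  o1 <- names(it_report$organ_doses)
  o2 <- names(iv_report$organ_doses)
  common <- intersect(o1, o2)
  paired <- data.frame(
    organ = common,
    dose_1 = unname(it_report$organ_doses[common]),
    dose_2 = unname(iv_report$organ_doses[common]),
    stringsAsFactors = FALSE
  )
  paired$difference <- paired$dose_1 - paired$dose_2
  ratios <- do.call(rbind, lapply(reference_organs, function(ref) {
    data.frame(reference = normalize_organ(ref),
               ratio_1 = dose_ratio(it_report, ref),
               ratio_2 = dose_ratio(iv_report, ref),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    paired = paired,
    ratios = ratios,
    only_in = list(first = setdiff(o1, o2), second = setdiff(o2, o1)),
    routes = c(it_report$route, iv_report$route),
    sphere_mass_g = c(it_report$sphere_mass_g, iv_report$sphere_mass_g)
  ), class = "route_comparison")
}

#' @export
print.route_comparison <- function(x, ...) {
  cat(sprintf("<route_comparison> %s vs %s\n", x$routes[1], x$routes[2]))
  print(x$paired, row.names = FALSE)
  cat("tumor-to-organ dose ratios:\n")
  r <- x$ratios
  r$ratio_1 <- format_ratio(r$ratio_1)
  r$ratio_2 <- format_ratio(r$ratio_2)
  print(r, row.names = FALSE)
  if (length(x$only_in$first) || length(x$only_in$second)) {
    cat("organs present in one report only:\n")
    if (length(x$only_in$first))
      cat("  first:", paste(x$only_in$first, collapse = ", "), "\n")
    if (length(x$only_in$second))
      cat("  second:", paste(x$only_in$second, collapse = ", "), "\n")
  }
  invisible(x)
}
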