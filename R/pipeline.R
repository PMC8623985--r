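#' Run the full dosimetry pipeline on a biodistribution table
#'
#' Chains the pipeline stages: summarize the %ID/g table over animals;
#' extrapolate each organ mean to whole-organ human uptake; fit and integrate
#' a mono-exponential time-activity curve per organ; multiply the
#' time-integrated activities through the S-value matrix for organ doses;
#' compute the tumor self-dose with the unit-density sphere model; and
#' summarize total-body and effective dose.
#'
#' The tumor is extrapolated with the sphere mass as its target mass and is
#' not a source in the organ S-matrix (its non-penetrating self-dose is the
#' sphere model's job; its photon cross-dose to organs under the uniform-bath
#' model is negligible and omitted). Urine is treated as excreted activity
#' and contributes no dose; blood activity is routed to a total-body
#' remainder source.
#'
#' @param table A [biodistribution_table()].
#' @param species A [species_params()].
#' @param masses Named organ masses from [organ_mass_table()].
#' @param decay A [decay_data()] object.
#' @param tumor_sphere_mass_g Sphere mass for the tumor dose (grams).
#' @param s_model S-matrix model, see [generate_s_matrix()].
#' @param af_body Whole-body photon absorbed fraction for the bath term.
#' @param sphere_phi_p Photon absorbed fraction of the tumor sphere.
#' @param peak_handling Passed to [integrate_tac()].
#' @param exclude Organs excluded from dose sources (default urine).
#' @param on_insufficient Passed to [build_all_tia()]; the pipeline default
#'   falls back to physical-decay-only kinetics for unfittable organs so one
#'   degenerate organ row cannot abort a run.
#' @return Object of class `dose_report`: `route`, `organ_doses` (named,
#'   mSv/MBq), `tumor_sphere_dose` (mGy/MBq), `sphere_mass_g`,
#'   `total_body_dose`, `effective_dose`, `tia` (per-organ fit/integration
#'   table), and `provenance`.
#' @export
run_dosimetry <- function(table,
                          species = species_params(),
                          masses = organ_mass_table(),
                          decay = lu177_decay_data(),
                          tumor_sphere_mass_g = 0.5,
                          s_model = c("local_np_plus_uniform_photon",
                                      "local_np_only"),
                          af_body = 0.3,
                          sphere_phi_p = 0.01,
                          peak_handling = "ignore_pre_peak",
                          exclude = "urine",
                          on_insufficient = "fallback_physical") {
  s_model <- match.arg(s_model)
  summaries <- summarize_biodistribution(table)
  uptake <- extrapolate_table(summaries, species, masses,
                              tumor_mass_g = tumor_sphere_mass_g,
                              exclude = exclude)
  tia <- build_all_tia(uptake, decay, peak_handling = peak_handling,
                       on_insufficient = on_insufficient)

  tumor_row <- tia[tia$organ == "tumor", , drop = FALSE]
  organ_tia <- tia[tia$organ != "tumor", , drop = FALSE]

  s <- generate_s_matrix(decay, masses, model = s_model, af_body = af_body,
                         tbw_kg = species$human_total_body_weight_kg)
  doses <- organ_doses(organ_tia, s)

  tumor_dose <- if (nrow(tumor_row) == 1) {
    sphere_dose(tumor_row$a_tilde_mbq_s_per_mbq, decay,
                mass_g = tumor_sphere_mass_g, phi_p = sphere_phi_p)
  } else {
    NA_real_
  }

  dose_report(
    organ_doses = doses[setdiff(names(doses), "total body")],
    tumor_sphere_dose = tumor_dose,
    sphere_mass_g = tumor_sphere_mass_g,
    route = attr(table, "route"),
    total_body_dose = doses[["total body"]],
    effective_dose = suppressWarnings(
      effective_dose(doses[setdiff(names(doses), "total body")])),
    tia = tia,
    provenance = list(
      s_model = s_model, af_body = af_body, sphere_phi_p = sphere_phi_p,
      peak_handling = peak_handling,
      decay_corrected = attr(table, "decay_corrected"),
      excluded = attr(uptake, "excluded"),
      fit_methods = stats::setNames(tia$method, tia$organ),
      mass_provenance = attr(masses, "provenance")
    )
  )
}

#' Construct a dose report
#'
#' Container for per-target absorbed doses plus the sphere-model tumor dose.
#' Also usable directly to wrap published dose tables (for ratio arithmetic
#' or route comparison) without rerunning the pipeline.
#'
#' @param organ_doses Named numeric vector, absorbed dose per target organ in
#'   mSv/MBq (all finite and >= 0).
#' @param tumor_sphere_dose Tumor self-dose in mGy/MBq (sphere model).
#' @param sphere_mass_g Sphere mass the tumor dose refers to.
#' @param route Administration route label.
#' @param total_body_dose,effective_dose Optional whole-body summaries
#'   (mSv/MBq).
#' @param tia,provenance Optional pipeline diagnostics.
#' @return Object of class `dose_report`.
#' @export
dose_report <- function(organ_doses, tumor_sphere_dose = NA_real_,
                        sphere_mass_g = 0.5, route = NA_character_,
                        total_body_dose = NA_real_,
                        effective_dose = NA_real_,
                        tia = NULL, provenance = NULL) {
  organ_doses <- unlist(organ_doses)
  if (any(!is.finite(organ_doses)) || any(organ_doses < 0)) {
    stop("dose_report: organ doses must be finite and >= 0", call. = FALSE)
  }
  if (!is.na(tumor_sphere_dose) &&
      (!is.finite(tumor_sphere_dose) || tumor_sphere_dose < 0)) {
    stop("dose_report: tumor sphere dose must be finite and >= 0",
         call. = FALSE)
  }
  names(organ_doses) <- normalize_organ(names(organ_doses))
  structure(list(route = route,
                 organ_doses = organ_doses,
                 tumor_sphere_dose = unname(tumor_sphere_dose),
                 sphere_mass_g = sphere_mass_g,
                 total_body_dose = unname(total_body_dose),
                 effective_dose = unname(effective_dose),
                 tia = tia,
                 provenance = provenance),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, digits = 3, ...) {
  cat(sprintf("<dose_report> route: %s\n", x$route))
  df <- data.frame(target_organ = names(x$organ_doses),
                   absorbed_dose_mSv_per_MBq = signif(x$organ_doses, digits))
  rownames(df) <- NULL
  print(df, row.names = FALSE)
  if (!is.na(x$tumor_sphere_dose)) {
    cat(sprintf("tumor sphere (%.3g g): %.*g mGy/MBq\n",
                x$sphere_mass_g, digits, x$tumor_sphere_dose))
  }
  if (!is.na(x$total_body_dose)) {
    cat(sprintf("total body: %.*g mSv/MBq\n", digits, x$total_body_dose))
  }
  if (!is.na(x$effective_dose)) {
    cat(sprintf("effective dose: %.*g mSv/MBq\n", digits, x$effective_dose))
  }
  invisible(x)
}

#' Write a dose report as delimited text
#'
#' Mirrors the layout of a published dose table (target organ, absorbed
#' dose), with the tumor sphere, total body and effective dose appended; a
#' machine-readable full-precision CSV.
#'
#' @param report A [dose_report()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_dose_report <- function(report, path) {
  rows <- data.frame(target_organ = names(report$organ_doses),
                     absorbed_dose = unname(report$organ_doses),
                     unit = "mSv/MBq")
  extra <- data.frame(
    target_organ = c(sprintf("tumor sphere (%g g)", report$sphere_mass_g),
                     "total body", "effective dose"),
    absorbed_dose = c(report$tumor_sphere_dose, report$total_body_dose,
                      report$effective_dose),
    unit = c("mGy/MBq", "mSv/MBq", "mSv/MBq"))
  out <- rbind(rows, extra[!is.na(extra$absorbed_dose), ])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
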