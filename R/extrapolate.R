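#' Species body-weight parameters
#'
#' @param mouse_total_body_weight_kg Mouse total body weight (kg).
#' @param human_total_body_weight_kg Reference adult total body weight (kg).
#' @return Object of class `species_params`.
#' @export
species_params <- function(mouse_total_body_weight_kg = 0.025,
                           human_total_body_weight_kg = 73) {
  stopifnot(mouse_total_body_weight_kg > 0, human_total_body_weight_kg > 0)
  structure(list(mouse_total_body_weight_kg = mouse_total_body_weight_kg,
                 human_total_body_weight_kg = human_total_body_weight_kg),
            class = "species_params")
}

#' Reference adult organ masses
#'
#' Reads an organ-mass configuration (YAML map `organ: grams`). The bundled
#' default holds adult-male phantom reference masses of the Cristy-Eckerman
#' series used by classic internal-dosimetry software, with a provenance note
#' in the file.
#'
#' @param path Path to a YAML file mapping organ names to masses in grams;
#'   defaults to the bundled table.
#' @return Named numeric vector of organ masses in grams, names normalized,
#'   with the file's `provenance` entry attached as an attribute.
#' @export
organ_mass_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "organ_masses_adult_male.yaml",
                        package = "ludosim", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  prov <- cfg$provenance
  cfg$provenance <- NULL
  masses <- unlist(cfg)
  names(masses) <- normalize_organ(names(masses))
  if (any(masses <= 0)) {
    stop("organ_mass_table: all masses must be > 0", call. = FALSE)
  }
  attr(masses, "provenance") <- prov
  masses
}

#' Extrapolate a mouse organ concentration to human whole-organ uptake
#'
#' Mouse-to-human extrapolation of organ uptake:
#' \deqn{(\%IA/organ)_{human} = (\%ID/g)_{mouse} \times
#'   (kg_{TBW})_{mouse} \times g_{organ} / (kg_{TBW})_{human}}
#' i.e. the mouse concentration is converted to a whole-body-normalized
#' concentration and re-distributed over the reference human organ mass.
#'
#' @param conc Mouse concentration in %ID/g (vectorized, >= 0).
#' @param species A [species_params()].
#' @param organ_mass_g Reference human organ mass in grams (> 0).
#' @return Percent of injected activity in the whole human organ (%IA).
#' @export
extrapolate_uptake <- function(conc, species = species_params(),
                               organ_mass_g) {
  stopifnot(all(conc >= 0), all(organ_mass_g > 0))
  conc * species$mouse_total_body_weight_kg * organ_mass_g /
    species$human_total_body_weight_kg
}

#' Extrapolate a summarized biodistribution table to human uptake points
#'
#' Applies [extrapolate_uptake()] to every (organ, time) summary mean. The
#' tumor is extrapolated with the tumor sphere mass as its "organ mass"
#' (the sphere model's target mass); organs in `exclude` (urine by default,
#' which is voided rather than retained) are dropped and listed in the
#' result's `excluded` attribute.
#'
#' @param summaries Output of [summarize_biodistribution()].
#' @param species A [species_params()].
#' @param masses Named vector from [organ_mass_table()].
#' @param tumor_mass_g Sphere mass used as the tumor target mass (grams).
#' @param exclude Organs to leave out of the extrapolation.
#' @return Data frame with columns `organ`, `time_h`, `pct_ia` (one human
#'   uptake point per organ-time), attributes `excluded` and
#'   `decay_corrected`.
#' @export
extrapolate_table <- function(summaries, species = species_params(),
                              masses = organ_mass_table(),
                              tumor_mass_g = 0.5,
                              exclude = "urine") {
  exclude <- normalize_organ(exclude)
  keep <- !(summaries$organ %in% exclude)
  s <- summaries[keep, , drop = FALSE]
  if (nrow(s) == 0) {
    out <- data.frame(organ = character(), time_h = numeric(),
                      pct_ia = numeric())
    attr(out, "excluded") <- exclude
    return(out)
  }
  mass_of <- function(organ) {
    if (organ == "tumor") return(tumor_mass_g)
    if (!organ %in% names(masses)) {
      stop("extrapolate_table: no reference mass for organ '", organ,
           "' (add it to the mass table or exclude it)", call. = FALSE)
    }
    masses[[organ]]
  }
  m <- vapply(s$organ, mass_of, numeric(1))
  out <- data.frame(
    organ = s$organ,
    time_h = s$time_h,
    pct_ia = extrapolate_uptake(s$mean_pct_id_per_g, species, m),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "excluded") <- exclude
  attr(out, "decay_corrected") <- attr(summaries, "decay_corrected")
  out
}
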