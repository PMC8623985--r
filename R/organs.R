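#' Organ vocabulary
#'
#' The controlled vocabulary of organ/tissue names used throughout the
#' package. Matching is case-insensitive and common abbreviations used in
#' biodistribution tables ("Small int.", "BM", ...) are resolved through an
#' alias map. The vocabulary is extensible: unknown names are reported by the
#' readers, never silently dropped.
#'
#' @return Character vector of canonical organ names.
#' @export
organ_vocabulary <- function() {
  c("blood", "heart", "lung", "liver", "stomach", "small intestine",
    "large intestine", "spleen", "pancreas", "kidney", "bone", "muscle",
    "tumor", "bone marrow", "brain", "urine")
}

# alias -> canonical; keys lower-case, punctuation stripped
.organ_aliases <- c(
  "small int"       = "small intestine",
  "small int."      = "small intestine",
  "large int"       = "large intestine",
  "large int."      = "large intestine",
  "sm intestine"    = "small intestine",
  "lg intestine"    = "large intestine",
  "bm"              = "bone marrow",
  "red marrow"      = "bone marrow",
  "kidneys"         = "kidney",
  "lungs"           = "lung",
  "tumour"          = "tumor"
)

#' Normalize organ names against the vocabulary
#'
#' @param organ Character vector of organ names as they appear in a file.
#' @return Character vector of canonical names; names that resolve to
#'   nothing in the vocabulary are returned lower-cased as-is (callers decide
#'   whether to warn).
#' @export
normalize_organ <- function(organ) {
  x <- trimws(tolower(as.character(organ)))
  hit <- match(x, names(.organ_aliases))
  x[!is.na(hit)] <- .organ_aliases[hit[!is.na(hit)]]
  x
}

#' @rdname normalize_organ
#' @return `is_known_organ` returns a logical vector.
#' @export
is_known_organ <- function(organ) {
  normalize_organ(organ) %in% organ_vocabulary()
}
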