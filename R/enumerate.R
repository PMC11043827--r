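#' Enumerate all supplement conditions of a nucleoside screen
#'
#' Crosses every non-empty subset of the supplied deoxynucleosides with every
#' concentration, in canonical order (subset size first, then alphabetically
#' within size), and prepends one DMSO vehicle baseline per concentration.
#' For the full screen of \{A, T, G, C\} this yields the 15 combinations
#' A, C, G, T, AC, AG, AT, CG, CT, GT, ACG, ACT, AGT, CGT, ACGT per
#' concentration.
#'
#' @param nucleosides non-empty character vector, subset of
#'   `c("A","T","G","C")`.
#' @param concentrations numeric vector of concentrations (micromolar).
#' @param serum serum percentage applied to every condition.
#' @param baseline logical; include a DMSO baseline per concentration.
#' @return A list of [screen_condition()] objects.
#' @examples
#' length(enumerate_supplement_conditions(c("A","T","G","C"), 200,
#'                                        baseline = FALSE))  # 15
#' @export
enumerate_supplement_conditions <- function(nucleosides,
                                            concentrations = c(50, 200),
                                            serum = 0.1,
                                            baseline = TRUE) {
  nucleosides <- unique(as.character(nucleosides))
  if (length(nucleosides) == 0L) stop("nucleoside set must be non-empty")
  if (!all(nucleosides %in% c("A", "T", "G", "C")))
    stop("nucleosides must be drawn from {A, T, G, C}")
  nucleosides <- sort(nucleosides)
  n <- length(nucleosides)
  subsets <- list()
  for (size in seq_len(n)) {
    combs <- utils::combn(nucleosides, size, simplify = FALSE)
    # combn on a sorted vector already emits lexicographic order within size
    subsets <- c(subsets, combs)
  }
  out <- list()
  for (conc in concentrations) {
    if (baseline)
      out[[length(out) + 1L]] <- screen_condition(character(0),
                                                  concentration = conc,
                                                  serum = serum)
    for (s in subsets)
      out[[length(out) + 1L]] <- screen_condition(s, concentration = conc,
                                                  serum = serum)
  }
  out
}
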