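# One-call screen analysis: plates in, dependence calls out.

#' Analyze a plate screen end to end
#'
#' Chains [normalize_plate()], [growth_results()] and [call_dependence()]:
#' colony areas are normalized to the on-plate controls, each mutant is
#' compared to wild type per degron with a Mann-Whitney test, and degrons
#' are labeled dependent/independent per mutant.
#'
#' @param plates Long plate tibble (schema of [simulate_plates()]).
#' @param wt_strain Wild-type strain name.
#' @param alpha Significance level for calling.
#' @param correction Multiple-testing correction across degrons within a
#'   mutant (see [growth_results()]).
#' @param sided Test sidedness (see [test_growth_difference()]).
#' @return List with `normalized`, `growth` and `calls` tibbles.
#' @export
analyze_screen <- function(plates, wt_strain = "WT", alpha = 0.05,
                           correction = c("bh", "holm", "bonferroni", "none"),
                           sided = c("two", "one")) {
  correction <- match.arg(correction)
  sided <- match.arg(sided)
  normalized <- normalize_plate(plates)
  growth <- growth_results(normalized, wt_strain = wt_strain, alpha = alpha,
                           correction = correction, sided = sided)
  calls <- call_dependence(growth, alpha = alpha)
  list(normalized = normalized, growth = growth, calls = calls)
}
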