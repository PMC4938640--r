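# Integration of growth and kinetics into per-degron E3-dependence calls.
#
# Dependence is called from the growth readout (the screen's primary
# measurement); the half-life ratio from chase experiments is carried as a
# confirmatory annotation, mirroring the screen-then-chase workflow.

#' Half-life ratio of mutant over wild type
#'
#' @param fit_mut,fit_wt `decay_fit` objects (or bare half-lives in min).
#' @return `t_half_mut / t_half_wt`; `Inf` when the mutant is stable
#'   (report as "greater than chase duration / t_half_wt", not a number).
#' @export
#' @examples
#' halflife_ratio(25.7, 12.6)  # ~2.04
halflife_ratio <- function(fit_mut, fit_wt) {
  th <- function(x) if (inherits(x, "decay_fit")) x$t_half else as.numeric(x)
  t_mut <- th(fit_mut)
  t_wt <- th(fit_wt)
  if (!is.finite(t_wt) || t_wt <= 0) {
    stop("wild-type half-life undefined: cannot form a ratio", call. = FALSE)
  }
  t_mut / t_wt
}

#' Call E3 dependence from growth results
#'
#' A degron is called `dependent` on a mutant's E3 when the growth rescue is
#' significant and in the right direction (`adjusted_p < alpha` and
#' `relative_growth > 0`), `independent` when not significant (or rescue in
#' the wrong direction), and `indeterminate` when the relative growth is
#' undefined (degenerate normalization).
#'
#' @param growth Tibble from [growth_results()].
#' @param ratios Optional tibble with `degron_id`, `mutant`,
#'   `halflife_ratio` to annotate the calls (e.g. built from
#'   [chase_halflives()] via [halflife_ratio()]).
#' @param alpha Significance level (default 0.05, shared with the growth
#'   analysis).
#' @return Tibble: `degron_id`, `mutant`, `relative_growth`, `adjusted_p`,
#'   `halflife_ratio` (NA when not supplied), `label`.
#' @export
call_dependence <- function(growth, ratios = NULL, alpha = 0.05) {
  stopifnot(all(c("degron_id", "mutant", "relative_growth", "adjusted_p")
                %in% names(growth)))
  calls <- growth |>
    tibble::as_tibble() |>
    dplyr::mutate(label = dplyr::case_when(
      is.na(.data$relative_growth) ~ "indeterminate",
      .data$adjusted_p < alpha & .data$relative_growth > 0 ~ "dependent",
      TRUE ~ "independent"
    )) |>
    dplyr::select("degron_id", "mutant", "relative_growth", "adjusted_p",
                  "label")
  if (!is.null(ratios)) {
    stopifnot(all(c("degron_id", "mutant", "halflife_ratio") %in% names(ratios)))
    calls <- dplyr::left_join(calls,
                              dplyr::select(ratios, "degron_id", "mutant",
                                            "halflife_ratio"),
                              by = c("degron_id", "mutant"))
  } else {
    calls$halflife_ratio <- NA_real_
  }
  dplyr::relocate(calls, "halflife_ratio", .before = "label")
}

#' Smallest half-life fold change detectable by growth
#'
#' The minimum finite half-life ratio among degrons called dependent —
#' the empirical detection limit of the growth assay for a given screen.
#'
#' @param calls Tibble from [call_dependence()] with `halflife_ratio`.
#' @return A single ratio, or `NA` (with a message) when no dependent call
#'   carries a finite ratio.
#' @export
detection_threshold <- function(calls) {
  stopifnot(all(c("label", "halflife_ratio") %in% names(calls)))
  r <- calls$halflife_ratio[calls$label == "dependent" &
                              is.finite(calls$halflife_ratio)]
  if (length(r) == 0) {
    message("no dependent calls with finite half-life ratio")
    return(NA_real_)
  }
  min(r)
}

#' Library-wide dependence report
#'
#' One row per degron: sequence features joined with per-mutant relative
#' growth, half-lives and dependence labels, plus a per-mutant summary of
#' the dependent fraction (as the `summary` attribute).
#'
#' @param features Feature tibble (`id`, `peptide`, `length`, `gravy`,
#'   `max_hydrophobic_run`), e.g. from [degron_features()].
#' @param growth Optional tibble from [growth_results()].
#' @param fits Optional tibble from [chase_halflives()].
#' @param calls Optional tibble from [call_dependence()].
#' @return A wide tibble, one row per degron, with attribute `summary`
#'   (tibble: `mutant`, `n_called`, `dependent_fraction`).
#' @export
library_report <- function(features, growth = NULL, fits = NULL, calls = NULL) {
  stopifnot(all(c("id", "peptide") %in% names(features)))
  report <- tibble::as_tibble(features)
  check_ids <- function(tbl, col, what) {
    orphans <- setdiff(unique(tbl[[col]]), c(features$id, "URA3_HA"))
    if (length(orphans) > 0) {
      stop(what, " contains degron ids absent from features: ",
           paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(growth)) {
    check_ids(growth, "degron_id", "growth results")
    wide <- growth |>
      dplyr::select("degron_id", "mutant", "relative_growth") |>
      tidyr::pivot_wider(names_from = "mutant",
                         values_from = "relative_growth",
                         names_prefix = "relgrowth_")
    report <- dplyr::left_join(report, wide, by = c(id = "degron_id"))
  }
  if (!is.null(fits)) {
    check_ids(fits, "degron_id", "decay fits")
    wide <- fits |>
      dplyr::select("degron_id", "strain", "t_half") |>
      tidyr::pivot_wider(names_from = "strain", values_from = "t_half",
                         names_prefix = "thalf_")
    report <- dplyr::left_join(report, wide, by = c(id = "degron_id"))
  }
  summary <- NULL
  if (!is.null(calls)) {
    check_ids(calls, "degron_id", "dependence calls")
    wide <- calls |>
      dplyr::select("degron_id", "mutant", "label") |>
      tidyr::pivot_wider(names_from = "mutant", values_from = "label",
                         names_prefix = "label_")
    report <- dplyr::left_join(report, wide, by = c(id = "degron_id"))
    summary <- calls |>
      dplyr::summarise(
        n_called = dplyr::n(),
        dependent_fraction = mean(.data$label == "dependent"),
        .by = "mutant")
  }
  attr(report, "summary") <- summary
  report
}

#' Strip chart of half-life ratios
#'
#' Plots each degron's mutant/WT half-life ratio on a log-scaled axis,
#' colored by growth-based dependence call, with a dashed line at the
#' growth detection threshold (see [detection_threshold()]).
#'
#' @param calls Tibble from [call_dependence()] with finite
#'   `halflife_ratio` values.
#' @return A ggplot object.
#' @export
plot_halflife_ratios <- function(calls) {
  thr <- suppressMessages(detection_threshold(calls))
  dat <- dplyr::filter(calls, is.finite(.data$halflife_ratio))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$halflife_ratio,
                                         y = .data$mutant,
                                         color = .data$label)) +
    ggplot2::geom_jitter(height = 0.15, width = 0, size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(values = c(dependent = "deeppink",
                                           independent = "black",
                                           indeterminate = "grey60")) +
    ggplot2::labs(x = "half-life ratio (mutant / WT)", y = NULL,
                  color = "growth call") +
    ggplot2::theme_minimal()
  if (is.finite(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                                 color = "deeppink")
  }
  p
}
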