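# Quantitative growth analysis: within-plate normalization to control
# wells, mutant-vs-WT log2 relative growth, Mann-Whitney hit calling, and
# heatmap-matrix export.

#' Normalize colony areas within each plate
#'
#' Anchors every area to the two control roles on its own plate:
#' `normalized = (area - mean(NO_URA3)) / (mean(URA3_HA_REF) - mean(NO_URA3))`,
#' clipped below at 0. The reference wells map to 1 and the floor wells to 0
#' on average, and any multiplicative per-plate effect cancels. Corner and
#' empty wells are flagged `excluded` and should not enter downstream
#' statistics; zero areas are kept as true Ura-minus phenotypes, not
#' treated as missing.
#'
#' @param plates Long plate tibble with at least `plate`, `role`, `area`
#'   (schema of [simulate_plates()]; the same schema is accepted for real
#'   colony-area tables).
#' @return The input with `normalized` and `excluded` columns added.
#' @export
normalize_plate <- function(plates) {
  stopifnot(all(c("plate", "role", "area") %in% names(plates)))
  if (any(plates$area < 0, na.rm = TRUE)) {
    stop("negative colony area", call. = FALSE)
  }
  plates |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$plate) |>
    dplyr::group_modify(function(df, key) {
      floor_wells <- df$area[df$role == "NO_URA3"]
      ref_wells <- df$area[df$role == "URA3_HA_REF"]
      if (length(floor_wells) == 0 || length(ref_wells) == 0) {
        stop("plate ", key$plate, " lacks NO_URA3 and/or URA3_HA_REF control wells",
             call. = FALSE)
      }
      lo <- mean(floor_wells)
      hi <- mean(ref_wells)
      if (hi <= lo) {
        stop("degenerate plate ", key$plate,
             ": reference control mean <= floor control mean", call. = FALSE)
      }
      dplyr::mutate(df,
                    normalized = pmax(0, (.data$area - lo) / (hi - lo)),
                    excluded = .data$role %in% c("EXCLUDED_CORNER", "EMPTY"))
    }) |>
    dplyr::ungroup()
}

#' Log2 relative growth of mutant versus wild type
#'
#' `log2(mean(norm_mut) / mean(norm_wt))`. A non-positive mean makes the
#' ratio undefined; the value is returned as `NA` with a warning rather
#' than silently dropped.
#'
#' @param norm_mut,norm_wt Numeric vectors of normalized colony sizes.
#' @return A single log2 ratio (dimensionless).
#' @export
#' @examples
#' relative_growth(c(2, 2), c(1, 1))  # 1
relative_growth <- function(norm_mut, norm_wt) {
  if (length(norm_mut) == 0 || length(norm_wt) == 0) {
    stop("relative_growth needs non-empty samples", call. = FALSE)
  }
  m_mut <- mean(norm_mut)
  m_wt <- mean(norm_wt)
  if (m_mut <= 0 || m_wt <= 0) {
    warning("relative growth undefined: non-positive mean normalized size",
            call. = FALSE)
    return(NA_real_)
  }
  log2(m_mut / m_wt)
}

#' Mann-Whitney test of a growth difference
#'
#' Wilcoxon rank-sum (Mann-Whitney U) p-value for a mutant-vs-WT growth
#' difference: exact enumeration when the smaller group has at most 8
#' observations and there are no ties, tie-corrected normal approximation
#' otherwise.
#'
#' @param norm_mut,norm_wt Numeric samples of normalized colony sizes.
#' @param sided `"two"` (default) or `"one"`; one-sided tests for more
#'   growth in the mutant, the direction a degradation defect produces.
#' @return The p-value.
#' @export
#' @examples
#' test_growth_difference(c(5, 6, 7, 8), c(1, 2, 3, 4))  # 2/70
test_growth_difference <- function(norm_mut, norm_wt, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (length(norm_mut) == 0 || length(norm_wt) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(norm_mut, norm_wt)) > 0
  exact <- !ties && min(length(norm_mut), length(norm_wt)) <= 8
  alt <- if (sided == "two") "two.sided" else "greater"
  suppressWarnings(
    stats::wilcox.test(norm_mut, norm_wt, alternative = alt,
                       exact = exact, correct = !exact)$p.value
  )
}

#' Per-degron growth results for each mutant strain
#'
#' Pools normalized colony sizes across pinning replicates for each
#' degron x strain, computes the log2 relative growth of each mutant versus
#' the wild-type strain, tests the difference with [test_growth_difference()],
#' and adjusts p-values across degrons within each mutant.
#'
#' @param normalized Output of [normalize_plate()].
#' @param wt_strain Name of the wild-type strain (default `"WT"`).
#' @param alpha Significance level for the `significant` flag.
#' @param correction `"bh"` (Benjamini-Hochberg, default), `"holm"`,
#'   `"bonferroni"` or `"none"` (per-test masking).
#' @param sided Passed to [test_growth_difference()].
#' @return Tibble: `degron_id`, `mutant`, `relative_growth`, `p_value`,
#'   `adjusted_p`, `n_mut`, `n_wt`, `significant`.
#' @export
growth_results <- function(normalized, wt_strain = "WT", alpha = 0.05,
                           correction = c("bh", "holm", "bonferroni", "none"),
                           sided = c("two", "one")) {
  correction <- match.arg(correction)
  sided <- match.arg(sided)
  stopifnot(all(c("strain", "degron_id", "role", "normalized", "excluded")
                %in% names(normalized)))
  dat <- normalized |>
    dplyr::filter(.data$role == "DEGRON", !.data$excluded,
                  !is.na(.data$degron_id))
  if (!wt_strain %in% dat$strain) {
    stop("wild-type strain '", wt_strain, "' not present", call. = FALSE)
  }
  mutants <- setdiff(unique(dat$strain), wt_strain)
  res <- purrr::map_dfr(mutants, function(mt) {
    dplyr::inner_join(
      dat |> dplyr::filter(.data$strain == mt) |>
        dplyr::summarise(mut_vals = list(.data$normalized),
                         .by = "degron_id"),
      dat |> dplyr::filter(.data$strain == wt_strain) |>
        dplyr::summarise(wt_vals = list(.data$normalized),
                         .by = "degron_id"),
      by = "degron_id"
    ) |>
      dplyr::mutate(
        mutant = mt,
        relative_growth = purrr::map2_dbl(
          .data$mut_vals, .data$wt_vals,
          ~ suppressWarnings(relative_growth(.x, .y))),
        p_value = purrr::map2_dbl(.data$mut_vals, .data$wt_vals,
                                  test_growth_difference, sided = sided),
        n_mut = lengths(.data$mut_vals),
        n_wt = lengths(.data$wt_vals)
      ) |>
      dplyr::mutate(adjusted_p = adjust_pvalues(
        .data$p_value,
        method = if (correction == "bh") "BH" else correction)) |>
      dplyr::select("degron_id", "mutant", "relative_growth", "p_value",
                    "adjusted_p", "n_mut", "n_wt")
  })
  dplyr::mutate(res,
                significant = !is.na(.data$adjusted_p) & .data$adjusted_p < alpha)
}

#' Heatmap matrix of significant relative growth
#'
#' One cell per degron x mutant, positioned by the source-plate layout:
#' the relative growth where the adjusted p-value clears `alpha`, 0
#' (masked, rendered white) otherwise.
#'
#' @param results Tibble from [growth_results()].
#' @param layout Layout tibble from [make_plate_layout()] (maps degrons to
#'   plate positions).
#' @param alpha Masking threshold on `adjusted_p`.
#' @return Tibble: `mutant`, `source_plate`, `well`, `row`, `col`,
#'   `degron_id`, `value`.
#' @export
growth_heatmap_table <- function(results, layout, alpha = 0.05) {
  if (anyDuplicated(results[c("degron_id", "mutant")])) {
    stop("duplicate degron x mutant pair in results", call. = FALSE)
  }
  layout |>
    dplyr::filter(.data$role == "DEGRON", !is.na(.data$degron_id)) |>
    dplyr::inner_join(results, by = "degron_id",
                      relationship = "one-to-many") |>
    dplyr::mutate(value = ifelse(!is.na(.data$adjusted_p) &
                                   .data$adjusted_p < alpha,
                                 .data$relative_growth, 0)) |>
    dplyr::select("mutant", "source_plate", "well", "row", "col",
                  "degron_id", "value")
}

#' Plot a relative-growth heatmap
#'
#' Renders [growth_heatmap_table()] output in plate coordinates; deeper
#' pink marks greater growth rescue in the mutant, white no significant
#' difference.
#'
#' @param heat Tibble from [growth_heatmap_table()].
#' @return A ggplot object, faceted by mutant (and source plate if several).
#' @export
plot_growth_heatmap <- function(heat) {
  ggplot2::ggplot(heat, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = pmax(.data$value, 0))) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "deeppink",
                                 name = "log2 relative growth") +
    ggplot2::scale_y_discrete(limits = rev(LETTERS[1:8])) +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::facet_wrap(~ .data$mutant + .data$source_plate) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
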