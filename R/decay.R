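# Cycloheximide-chase quantification and half-life inference.
#
# The substrate signal in each lane is normalized to the loading control,
# expressed as percent remaining relative to t = 0, and fitted with the
# first-order model P = 100 * exp(-lambda * t) by least squares with the
# amplitude fixed at 100 (the model as stated; a free amplitude is
# available behind a flag). Curves are compared with an
# extra-sum-of-squares F-test.

#' Percent protein remaining over a chase
#'
#' For every replicate series, normalizes the substrate signal to the
#' loading control at the same timepoint and expresses it relative to the
#' 0-min timepoint: `P(t) = 100 * [sub(t)/load(t)] / [sub(0)/load(0)]`.
#' `P(0)` is exactly 100, and rescaling both channels by a common constant
#' leaves `P` unchanged. Noise can push `P` above 100 at later timepoints;
#' such points are retained, not clipped.
#'
#' @param chase Tibble with columns `strain`, `degron_id`, `replicate`,
#'   `time_min`, `substrate_signal`, `loading_signal` (schema of
#'   [simulate_chase()]).
#' @return The input with a `pct_remaining` column, grouped computations
#'   done per (strain, degron_id, replicate).
#' @export
percent_remaining <- function(chase) {
  need <- c("strain", "degron_id", "replicate", "time_min",
            "substrate_signal", "loading_signal")
  stopifnot(all(need %in% names(chase)))
  if (any(chase$loading_signal <= 0)) {
    bad <- which(chase$loading_signal <= 0)[1]
    stop("non-positive loading signal (row ", bad,
         "): cannot normalize this point", call. = FALSE)
  }
  chase |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$strain, .data$degron_id, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      i0 <- which(df$time_min == 0)
      if (length(i0) != 1) {
        stop("each replicate series needs exactly one 0-min timepoint",
             call. = FALSE)
      }
      if (df$substrate_signal[i0] <= 0) {
        stop("non-positive substrate signal at t = 0: series rejected",
             call. = FALSE)
      }
      r0 <- df$substrate_signal[i0] / df$loading_signal[i0]
      dplyr::mutate(df, pct_remaining =
                      100 * (.data$substrate_signal / .data$loading_signal) / r0)
    }) |>
    dplyr::ungroup()
}

# Least-squares lambda for P = A * exp(-lambda * t), A fixed (default 100).
# Start from log-linear regression of log(P/A) on t (through the origin when
# the amplitude is fixed); refine with nls(port, lambda >= 0); fall back to
# golden-section search if nls fails. Deterministic, no random restarts.
fit_lambda_ls <- function(t, P, free_amplitude = FALSE) {
  stopifnot(length(t) == length(P), all(P >= 0), all(t >= 0))
  if (length(unique(t)) < 2) {
    stop("ill-posed fit: need at least two distinct timepoints", call. = FALSE)
  }
  pos <- P > 0
  lam0 <- if (sum(pos & t > 0) >= 1) {
    # log-linear start; 0 (the lower bound) when the series does not decay
    max(as.numeric(-stats::coef(stats::lm(log(P[pos] / 100) ~ 0 + t[pos]))), 0)
  } else {
    # everything but t=0 hit zero: decay faster than the first sample
    log(100) / min(t[t > 0])
  }
  ssr <- function(lam, A = 100) sum((P - A * exp(-lam * t))^2)
  if (!free_amplitude && ssr(lam0) < 1e-18) {
    return(list(lambda = lam0, amplitude = 100, ssr = ssr(lam0)))
  }
  df <- data.frame(t = t, P = P)
  fit <- if (free_amplitude) {
    tryCatch(stats::nls(P ~ A * exp(-lambda * t), data = df,
                        start = list(A = max(P), lambda = lam0),
                        algorithm = "port", lower = c(0, 0),
                        control = stats::nls.control(maxiter = 200)),
             error = function(e) NULL)
  } else {
    tryCatch(stats::nls(P ~ 100 * exp(-lambda * t), data = df,
                        start = list(lambda = lam0),
                        algorithm = "port", lower = 0,
                        control = stats::nls.control(maxiter = 200)),
             error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    lam <- unname(cf[["lambda"]])
    A <- if (free_amplitude) unname(cf[["A"]]) else 100
    return(list(lambda = lam, amplitude = A, ssr = ssr(lam, A)))
  }
  if (free_amplitude) {
    stop("nonlinear fit failed to converge (free amplitude)", call. = FALSE)
  }
  opt <- stats::optimize(ssr, interval = c(0, max(4 * lam0, 10)), tol = 1e-10)
  list(lambda = opt$minimum, amplitude = 100, ssr = opt$objective)
}

#' Fit first-order decay to percent-remaining data
#'
#' Minimizes `sum((P - 100 * exp(-lambda * t))^2)` over `lambda >= 0`. With
#' `pool = TRUE` (default) all replicate points are fitted jointly for the
#' headline estimate; per-replicate fits (when a `replicate` column is
#' present) give the spread of the half-life across independent chases.
#'
#' @param points Data frame with columns `time_min` (or `t`) and
#'   `pct_remaining` (or `P`), optionally `replicate`.
#' @param pool Fit all points jointly (TRUE) or refuse multi-replicate
#'   input (FALSE requires a single replicate).
#' @param free_amplitude Fit the amplitude too instead of fixing it at 100.
#' @return An object of class `decay_fit`: `lambda` (min^-1), `t_half`
#'   (min; `Inf` flags a stable protein), `ssr`, `df`, `n_points`,
#'   `lambda_reps`, `t_half_sd`, `amplitude`, `data`.
#' @export
#' @examples
#' pts <- tibble::tibble(time_min = c(0, 5, 10, 20),
#'                       pct_remaining = 100 * exp(-0.1 * c(0, 5, 10, 20)))
#' fit_decay(pts)$lambda
fit_decay <- function(points, pool = TRUE, free_amplitude = FALSE) {
  points <- tibble::as_tibble(points)
  if (!"time_min" %in% names(points) && "t" %in% names(points)) {
    points <- dplyr::rename(points, time_min = "t")
  }
  if (!"pct_remaining" %in% names(points) && "P" %in% names(points)) {
    points <- dplyr::rename(points, pct_remaining = "P")
  }
  stopifnot(all(c("time_min", "pct_remaining") %in% names(points)))
  if (!pool && "replicate" %in% names(points) &&
      length(unique(points$replicate)) > 1) {
    stop("pool = FALSE with multiple replicates: fit them separately",
         call. = FALSE)
  }
  main <- fit_lambda_ls(points$time_min, points$pct_remaining,
                        free_amplitude = free_amplitude)
  n <- nrow(points)
  n_par <- if (free_amplitude) 2L else 1L
  lambda_reps <- NULL
  t_half_sd <- NA_real_
  if ("replicate" %in% names(points) && length(unique(points$replicate)) > 1) {
    lambda_reps <- vapply(split(points, points$replicate), function(df)
      fit_lambda_ls(df$time_min, df$pct_remaining,
                    free_amplitude = free_amplitude)$lambda, numeric(1))
    t_half_sd <- stats::sd(log(2) / lambda_reps[lambda_reps > 0])
  }
  structure(list(
    lambda = main$lambda,
    t_half = half_life(main$lambda),
    amplitude = main$amplitude,
    ssr = main$ssr,
    df = n - n_par,
    n_points = n,
    lambda_reps = lambda_reps,
    t_half_sd = t_half_sd,
    data = points
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  th <- if (is.finite(x$t_half)) sprintf("%.2f min", x$t_half)
        else sprintf("stable (> %.0f min chase)", max(x$data$time_min))
  cat(sprintf("First-order decay fit: lambda = %.4g /min, t1/2 = %s (n = %d points",
              x$lambda, th, x$n_points))
  if (!is.na(x$t_half_sd)) cat(sprintf(", SD(t1/2) = %.2f", x$t_half_sd))
  cat(")\n")
  invisible(x)
}

#' Half-life from a decay constant
#'
#' `ln(2) / lambda`. A non-positive `lambda` means the protein is stable
#' over the chase; the sentinel `Inf` is returned (report it as "longer
#' than the chase window", never as an extrapolated number).
#'
#' @param lambda Decay constant(s), min^-1.
#' @return Half-life in minutes (`Inf` for stable).
#' @export
#' @examples
#' half_life(log(2))      # 1
#' half_life(0.0693147)   # ~10
half_life <- function(lambda) {
  ifelse(lambda > 0, log(2) / lambda, Inf)
}

#' Compare two decay curves with an extra-sum-of-squares F-test
#'
#' Fits the two point sets separately (full model, one `lambda` each) and
#' jointly (reduced model, shared `lambda`), and tests the improvement:
#' `F = [(SSR_red - SSR_full) / 1] / [SSR_full / (nA + nB - 2)]`, with the
#' p-value from the F(1, nA + nB - 2) distribution.
#'
#' @param pointsA,pointsB Point sets as accepted by [fit_decay()].
#' @param labels Length-2 character vector naming the curves.
#' @return Object of class `curve_comparison`: `labels`, `F_stat`, `df1`,
#'   `df2`, `p_value`, the two fits and the reduced fit.
#' @export
compare_decay <- function(pointsA, pointsB, labels = c("A", "B")) {
  fitA <- fit_decay(pointsA)
  fitB <- fit_decay(pointsB)
  joint <- dplyr::bind_rows(
    dplyr::select(fitA$data, "time_min", "pct_remaining"),
    dplyr::select(fitB$data, "time_min", "pct_remaining")
  )
  fitR <- fit_decay(joint)
  n <- fitA$n_points + fitB$n_points
  df2 <- n - 2L
  if (df2 <= 0) stop("degenerate comparison: no residual degrees of freedom",
                     call. = FALSE)
  ssr_full <- fitA$ssr + fitB$ssr
  extra <- max(fitR$ssr - ssr_full, 0)  # reduced is nested: never negative
  F_stat <- if (extra <= 0) 0 else if (ssr_full <= 0) Inf
            else (extra / 1) / (ssr_full / df2)
  p <- if (F_stat == 0) 1
       else stats::pf(F_stat, 1, df2, lower.tail = FALSE)
  structure(list(labels = labels, F_stat = F_stat, df1 = 1L, df2 = df2,
                 p_value = p, fitA = fitA, fitB = fitB, fit_reduced = fitR),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("Decay curve comparison %s vs %s: F(%d, %d) = %.3g, p = %.3g\n",
              x$labels[1], x$labels[2], x$df1, x$df2, x$F_stat, x$p_value))
  invisible(x)
}

#' Adjust p-values for multiple comparisons
#'
#' Thin, validated wrapper over [stats::p.adjust()]. Holm's step-down
#' procedure is the default (monotone, always >= the raw p, <= 1);
#' Bonferroni, Benjamini-Hochberg and no adjustment are selectable.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"holm"`, `"bonferroni"`, `"BH"` or `"none"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' adjust_pvalues(c(0.01, 0.04))  # 0.02, 0.04
adjust_pvalues <- function(p, method = c("holm", "bonferroni", "BH", "none")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Steady-state levels relative to the no-degron reporter
#'
#' Normalizes each blot row's substrate/loading ratio to the mean ratio of
#' the reference construct within the same strain, so the reference sits
#' at 1 by construction.
#'
#' @param blot Tibble with `strain`, `degron_id`, `replicate`,
#'   `substrate_signal`, `loading_signal` (schema of
#'   [simulate_steady_state()]).
#' @param reference `degron_id` of the no-degron reference construct.
#' @return Input tibble with a `ratio` column added.
#' @export
steady_state_ratio <- function(blot, reference = "URA3_HA") {
  stopifnot(all(c("strain", "degron_id", "substrate_signal", "loading_signal")
                %in% names(blot)))
  if (any(blot$loading_signal <= 0)) {
    stop("non-positive loading signal", call. = FALSE)
  }
  if (!reference %in% blot$degron_id) {
    stop("reference construct '", reference, "' not found", call. = FALSE)
  }
  blot |>
    tibble::as_tibble() |>
    dplyr::mutate(.raw = .data$substrate_signal / .data$loading_signal) |>
    dplyr::group_by(.data$strain) |>
    dplyr::group_modify(function(df, key) {
      ref <- df$.raw[df$degron_id == reference]
      if (length(ref) == 0) {
        stop("strain ", key$strain, " lacks reference rows", call. = FALSE)
      }
      dplyr::mutate(df, ratio = .data$.raw / mean(ref))
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".raw")
}

#' Fit half-lives for every strain x degron in a chase table
#'
#' Runs [percent_remaining()] and then a pooled [fit_decay()] per
#' (strain, degron_id), with per-replicate fits supplying the half-life SD.
#'
#' @param chase Chase tibble (schema of [simulate_chase()]).
#' @param free_amplitude Passed to [fit_decay()].
#' @return Tibble: `strain`, `degron_id`, `lambda`, `t_half`, `t_half_sd`,
#'   `n_reps`, `fit` (list column of `decay_fit` objects).
#' @export
chase_halflives <- function(chase, free_amplitude = FALSE) {
  percent_remaining(chase) |>
    dplyr::group_by(.data$strain, .data$degron_id) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_decay(df, pool = TRUE, free_amplitude = free_amplitude)
      tibble::tibble(lambda = fit$lambda, t_half = fit$t_half,
                     t_half_sd = fit$t_half_sd,
                     n_reps = length(unique(df$replicate)),
                     fit = list(fit))
    }) |>
    dplyr::ungroup()
}
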