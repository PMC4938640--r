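chase_tbl <- function(t, sub, load, strain = "WT", id = "d1", rep = 1L) {
  tibble::tibble(strain = strain, degron_id = id, replicate = rep,
                 time_min = t, substrate_signal = sub, loading_signal = load)
}

noiseless_points <- function(lambda, t = c(0, 5, 10, 20)) {
  tibble::tibble(time_min = t, pct_remaining = 100 * exp(-lambda * t))
}

test_that("percent remaining normalizes to loading and the 0-min point", {
  pr <- percent_remaining(chase_tbl(c(0, 10), c(100, 50), c(100, 100)))
  expect_equal(pr$pct_remaining, c(100, 50))
  pr2 <- percent_remaining(chase_tbl(c(0, 10), c(100, 80), c(100, 160)))
  expect_equal(pr2$pct_remaining, c(100, 50))  # (80/160)/(100/100) = 0.5
  # common rescale of both channels changes nothing
  pr3 <- percent_remaining(chase_tbl(c(0, 10), 7.3 * c(100, 80),
                                     7.3 * c(100, 160)))
  expect_equal(pr3$pct_remaining, pr2$pct_remaining)
  expect_equal(pr$pct_remaining[pr$time_min == 0], 100)
  expect_error(percent_remaining(chase_tbl(c(0, 10), c(100, 50), c(100, 0))),
               "loading")
  expect_error(percent_remaining(chase_tbl(c(0, 10), c(0, 50), c(100, 100))),
               "t = 0")
  expect_error(percent_remaining(chase_tbl(c(5, 10), c(100, 50), c(1, 1))),
               "0-min")
})

test_that("decay fitting is exact on noiseless data and bounded at zero", {
  fit <- fit_decay(noiseless_points(0.1))
  expect_equal(fit$lambda, 0.1, tolerance = 1e-9)
  expect_equal(fit$ssr, 0, tolerance = 1e-12)
  # two points: closed form through (0,100), (10,50)
  two <- tibble::tibble(time_min = c(0, 10), pct_remaining = c(100, 50))
  expect_equal(fit_decay(two)$lambda, log(2) / 10, tolerance = 1e-7)
  # constant at 100: stable, lambda 0
  flat <- tibble::tibble(time_min = c(0, 5, 10), pct_remaining = c(100, 100, 100))
  ffit <- fit_decay(flat)
  expect_equal(ffit$lambda, 0, tolerance = 1e-6)
  expect_true(is.infinite(ffit$t_half))
  expect_error(fit_decay(tibble::tibble(time_min = 0, pct_remaining = 100)),
               "distinct timepoints")
  # fitted half-life strictly decreasing in true lambda
  lams <- c(0.02, 0.05, 0.1, 0.3, 0.7)
  fitted <- vapply(lams, function(l) fit_decay(noiseless_points(l))$t_half,
                   numeric(1))
  expect_true(all(diff(fitted) < 0))
})

test_that("free-amplitude fits recover a non-100 plateau", {
  pts <- tibble::tibble(time_min = c(0, 2, 5, 10),
                        pct_remaining = 80 * exp(-0.2 * c(0, 2, 5, 10)))
  fit <- fit_decay(pts, free_amplitude = TRUE)
  expect_equal(fit$amplitude, 80, tolerance = 1e-4)
  expect_equal(fit$lambda, 0.2, tolerance = 1e-5)
})

test_that("pooled and per-replicate fits are reported together", {
  p <- sim_params(blot_sigma = 0.1, timepoints = c(0, 2, 4, 8, 15, 30))
  pr <- percent_remaining(simulate_chase(0.15, p, seed = 81))
  fit <- fit_decay(pr)
  expect_length(fit$lambda_reps, 3)
  expect_false(is.na(fit$t_half_sd))
  expect_equal(fit$n_points, 18)
  tl <- tidy(fit)
  expect_equal(tl$estimate, fit$lambda)
  expect_equal(glance(fit)$n_points, 18)
  expect_s3_class(autoplot(fit), "ggplot")
  hl <- chase_halflives(simulate_chase(0.15, p, seed = 81))
  expect_equal(hl$lambda, fit$lambda)
  expect_equal(hl$n_reps, 3)
})

test_that("half-life converts lambda with a stable sentinel", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.0693147), 10, tolerance = 1e-5)
  expect_true(is.infinite(half_life(0)))
  expect_true(is.infinite(half_life(-0.1)))
})

test_that("curve comparison F-test matches the numerical oracle", {
  pts <- noiseless_points(0.1)
  same <- compare_decay(pts, pts)
  expect_equal(same$F_stat, 0)
  expect_equal(same$p_value, 1)
  set.seed(803)
  mk <- function(lam) {
    d <- noiseless_points(lam, t = c(0, 2, 5, 10, 20))
    d$pct_remaining <- pmax(d$pct_remaining + stats::rnorm(5, 0, 3), 0)
    d
  }
  for (i in 1:10) {
    cmp <- compare_decay(mk(0.1), mk(0.12))
    expect_equal(cmp$p_value,
                 f_pvalue_oracle(cmp$F_stat, cmp$df1, cmp$df2),
                 tolerance = 1e-8)
  }
  expect_s3_class(tidy(cmp), "tbl_df")
})

test_that("F-test is calibrated under its own error model and has power", {
  # iid homoscedastic Gaussian errors: the model the F-test assumes
  set.seed(804)
  t <- c(0, 2, 4, 8, 15, 30)
  mk <- function(lam) {
    d <- expand.grid(replicate = 1:3, time_min = t)
    d$pct_remaining <- pmax(100 * exp(-lam * d$time_min) +
                              stats::rnorm(nrow(d), 0, 1.5), 0)
    d
  }
  pnull <- replicate(400, compare_decay(mk(0.1), mk(0.1))$p_value)
  rej <- mean(pnull < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  # power: lambda 0.1 vs 0.4 through the chase pipeline
  p <- sim_params(blot_sigma = 0.1, timepoints = t)
  ppow <- replicate(40, {
    a <- percent_remaining(simulate_chase(0.1, p))
    b <- percent_remaining(simulate_chase(0.4, p, degron_id = "d2"))
    compare_decay(a, b)$p_value
  })
  expect_lt(stats::median(ppow), 0.01)
})

test_that("Holm adjustment matches the exhaustive definition", {
  expect_equal(adjust_pvalues(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.01)), c(0.02, 0.02))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  set.seed(805)
  base <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  perms <- list(base, rev(base), sample(base), stats::runif(5),
                stats::runif(3), stats::runif(4), stats::runif(2), 0.7)
  for (p in perms) {
    expect_equal(adjust_pvalues(p), holm_oracle(p), info = paste(p, collapse = ","))
  }
})

test_that("steady-state ratios are anchored at the reference", {
  blot <- tibble::tibble(
    strain = "WT",
    degron_id = c("URA3_HA", "URA3_HA", "d1", "d2"),
    replicate = c(1L, 2L, 1L, 1L),
    substrate_signal = c(100, 100, 200, 50),
    loading_signal = c(100, 100, 100, 100))
  r <- steady_state_ratio(blot)
  expect_equal(r$ratio[r$degron_id == "URA3_HA"], c(1, 1))
  expect_equal(r$ratio[r$degron_id == "d1"], 2)
  expect_equal(r$ratio[r$degron_id == "d2"], 0.5)
  expect_error(steady_state_ratio(dplyr::filter(blot, degron_id != "URA3_HA")),
               "reference")
  # a 4x stabilized strain shows ~4x steady-state ratio
  recs <- degron_features(tibble::tibble(id = "d1", peptide = "VVLVVVF"))
  p <- sim_params(blot_sigma = 0.05, blot_replicates = 50L,
                  strains = tibble::tibble(strain = "uba1", pi = 1, f = 4))
  truth <- assign_kinetics(recs, p, seed = 84)
  rr <- steady_state_ratio(simulate_steady_state(truth, p, seed = 85))
  by_strain <- tapply(rr$ratio[rr$degron_id == "d1"],
                      rr$strain[rr$degron_id == "d1"], mean)
  lam <- truth$lambda[truth$strain == "WT"]
  lam_m <- truth$lambda[truth$strain == "uba1"]
  expected <- (1 / (lam_m + p$mu)) / (1 / (lam + p$mu))
  expect_equal(unname(by_strain[["uba1"]] / by_strain[["WT"]]),
               expected, tolerance = 0.1)
})
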