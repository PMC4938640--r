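small_params <- function(...) {
  sim_params(genome_length = 5000L, n_fragments = 30L, ...)
}

test_that("library simulation is deterministic under a fixed seed", {
  a <- simulate_library(small_params(), seed = 11)
  b <- simulate_library(small_params(), seed = 11)
  c <- simulate_library(small_params(), seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$degrons$peptide, c$degrons$peptide))
})

test_that("fragments respect the requested size range and provenance", {
  lib <- simulate_library(sim_params(n_fragments = 100L), seed = 21)
  sizes <- lib$degrons$frag_end - lib$degrons$frag_start
  expect_true(all(sizes >= 50 & sizes <= 400))
  expect_true(all(lib$degrons$frag_start >= 0))
  expect_true(all(lib$degrons$frag_end <= 100000))
  expect_true(all(lib$degrons$strand %in% c("+", "-")))
  expect_true(all(nchar(lib$degrons$peptide) >= 1))
  expect_identical(simulate_library(small_params(n_fragments = 0L),
                                    seed = 1)$degrons$id, character(0))
  expect_error(sim_params(genome_length = 100L), "genome shorter")
})

test_that("kinetics assignment follows the degenerate and Bernoulli limits", {
  recs <- tibble::tibble(id = sprintf("d%04d", 1:2000),
                         gravy = stats::runif(2000, -1, 1),
                         max_hydrophobic_run = sample(0:8, 2000, TRUE))
  p0 <- sim_params(kinetics_a = log(0.3), kinetics_b = 0, kinetics_c = 0,
                   sigma_lambda = 0)
  tr0 <- assign_kinetics(recs, p0, seed = 31)
  expect_true(all(abs(tr0$lambda[tr0$strain == "WT"] - 0.3) < 1e-12))
  # pi = 0: mutant rates identical to WT
  pnone <- sim_params(strains = tibble::tibble(strain = "doa10", pi = 0, f = 8))
  trn <- assign_kinetics(recs, pnone, seed = 32)
  wt <- trn$lambda[trn$strain == "WT"]
  expect_identical(trn$lambda[trn$strain == "doa10"], wt)
  # pi = 0.5: dependent fraction within 3 binomial SE at n = 2000
  ph <- sim_params(strains = tibble::tibble(strain = "doa10", pi = 0.5, f = 8))
  trh <- assign_kinetics(recs, ph, seed = 33)
  frac <- mean(trh$dependent[trh$strain == "doa10"])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
  # steady state decreases with lambda
  expect_true(all(diff(trh$steady_state[order(trh$lambda)]) <= 0))
})

test_that("chase simulation honors noise-free and expectation limits", {
  p <- sim_params(blot_sigma = 0, timepoints = c(0, 5, 10))
  flat <- simulate_chase(0, p, seed = 41)
  expect_true(all(flat$substrate_signal == flat$substrate_signal[1]))
  expect_identical(simulate_chase(0.2, p, seed = 5),
                   simulate_chase(0.2, p, seed = 5))
  expect_error(simulate_chase(-1, p), "lambda")
  expect_error(sim_params(timepoints = c(0, -2)))
  # E[P(1/lambda)] ~ 100 * e^-1, Monte Carlo over many replicates
  lam <- 0.25
  pn <- sim_params(blot_sigma = 0.1, timepoints = c(0, 1 / lam),
                   chase_replicates = 4000L)
  pr <- percent_remaining(simulate_chase(lam, pn, seed = 42))
  m <- mean(pr$pct_remaining[pr$time_min > 0])
  expect_lt(abs(m / (100 * exp(-1)) - 1), 0.02)
})

test_that("plate simulation is mean-exact without noise and shows rescue", {
  recs <- degron_features(tibble::tibble(id = c("fast", "slow"),
                                         peptide = c("VVLVVVF", "QSHMT")))
  p <- sim_params(plate_cv = 0, plate_effect_sd = 0,
                  strains = tibble::tibble(strain = "doa10", pi = 1, f = 8),
                  plate_replicates = 1L)
  truth <- assign_kinetics(recs, p, seed = 51)
  layout <- make_plate_layout(recs$id, p)
  plates <- simulate_plates(truth, layout, p, seed = 52)
  ref <- plates$area[plates$role == "URA3_HA_REF"]
  s_ref <- 1 / p$mu
  expect_equal(unique(ref),
               p$baseline_area + (p$a_max - p$baseline_area) *
                 s_ref / (s_ref + p$k_half))
  expect_equal(unique(plates$area[plates$role == "NO_URA3"]), p$baseline_area)
  # saturation limit: an arbitrarily strong degron approaches the floor area
  truth_fast <- dplyr::mutate(truth, lambda = 1e9,
                              steady_state = 1 / (lambda + p$mu))
  pl2 <- simulate_plates(truth_fast, layout, p, seed = 53)
  deg_area <- pl2$area[pl2$role == "DEGRON"]
  expect_true(all(abs(deg_area - p$baseline_area) < 1e-4))
  # dependent degron: mean area higher in the mutant than in WT
  pn <- sim_params(strains = tibble::tibble(strain = "doa10", pi = 1, f = 8),
                   plate_replicates = 100L)
  pln <- simulate_plates(truth, layout, pn, seed = 54)
  by_strain <- tapply(pln$area[pln$role == "DEGRON"],
                      pln$strain[pln$role == "DEGRON"], mean)
  expect_gt(by_strain[["doa10"]], by_strain[["WT"]])
  expect_error(simulate_plates(truth, dplyr::mutate(layout,
    degron_id = dplyr::if_else(is.na(degron_id), degron_id, "ghost")), p),
    "absent from ground truth")
})

test_that("steady-state tables include the reference and track lambda", {
  recs <- degron_features(tibble::tibble(id = c("a", "b"),
                                         peptide = c("VVLVVVF", "QSHMT")))
  p <- sim_params(blot_sigma = 0,
                  strains = tibble::tibble(strain = "doa10", pi = 0, f = 2))
  truth <- assign_kinetics(recs, p, seed = 61)
  blot <- simulate_steady_state(truth, p, seed = 62)
  expect_true("URA3_HA" %in% blot$degron_id)
  expect_identical(simulate_steady_state(truth, p, seed = 7),
                   simulate_steady_state(truth, p, seed = 7))
})
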