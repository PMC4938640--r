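# Synthetic degron screen with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# random genomic fragments translated in the fusion frame, per-degron
# first-order degradation rate constants with strain-specific stabilization,
# quadruplicate colony areas on 96-position plates with on-plate control
# wells and per-plate multiplicative effects, and multiplicative-noise
# chase/steady-state blot tables with a loading-control channel.

#' Simulation parameters for the synthetic screen
#'
#' Returns the default parameter set, with any element overridable by name.
#'
#' The defaults describe a screen like the one the package analyzes:
#' fragments of 50-400 bp cloned behind the reporter; wild-type decay
#' constants generated as
#' `log(lambda) = a + b * gravy + c * 1[hydrophobic run >= 5] + Normal(0, sigma_lambda)`,
#' centred so that most half-lives fall in the 1-10 min range; a mutant
#' strain panel in which each degron is dependent on a given E3 with
#' probability `pi` and, when dependent, stabilized by factor `f`
#' (`lambda / f`); colony areas following a saturating (Michaelis) function
#' of steady-state reporter level with per-plate multiplicative effects and
#' lognormal well noise; and chase signals with multiplicative lognormal
#' noise on both the substrate and loading channels.
#'
#' @param ... Named overrides of any default element.
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(n_fragments = 50)
#' p$fragment_size_range
sim_params <- function(...) {
  p <- list(
    genome_length = 100000L,
    n_fragments = 200L,
    fragment_size_range = c(50L, 400L),
    # log-lambda model: intercept, gravy slope, hydrophobic-run bump, spread
    kinetics_a = log(0.25),
    kinetics_b = 0.25,
    kinetics_c = 0.4,
    sigma_lambda = 0.4,
    # mutant panel: dependence probability pi and stabilization factor f
    strains = tibble::tibble(
      strain = c("doa10", "ltn1", "san1", "ubr1"),
      pi = c(0.5, 0.3, 0.05, 0.05),
      f = c(8, 4, 2, 1.5)
    ),
    mu = 0.006,            # dilution rate by growth, min^-1 (~2 h doubling)
    a_max = 400,           # colony area at saturating reporter level
    k_half = 20,           # reporter level giving half-maximal area
    baseline_area = 15,    # pinned-cell background area, no-Ura3 wells
    plate_cv = 0.1,        # lognormal sdlog of per-well area noise
    plate_effect_sd = 0.05,# lognormal sdlog of per-plate multiplicative effect
    plate_replicates = 4L, # quadruplicate pinning
    n_ref_wells = 6L,      # Ura3-HA reference control wells per plate
    n_blank_wells = 6L,    # no-Ura3 floor control wells per plate
    timepoints = c(0, 2, 4, 8, 15, 30),  # chase sampling, min
    chase_replicates = 3L,
    blot_sigma = 0.1,      # lognormal sdlog of blot signal noise
    blot_replicates = 3L,
    substrate_scale = 1000,
    loading_scale = 500
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) {
    stop("unknown sim_params field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(over)] <- over
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(
    p$genome_length >= 1, p$n_fragments >= 0,
    length(p$fragment_size_range) == 2,
    p$fragment_size_range[1] >= 1,
    p$fragment_size_range[1] <= p$fragment_size_range[2],
    all(p$strains$pi >= 0 & p$strains$pi <= 1),
    all(p$strains$f >= 1),
    p$mu >= 0, p$sigma_lambda >= 0, p$plate_cv >= 0, p$blot_sigma >= 0,
    all(p$timepoints >= 0), 0 %in% p$timepoints
  )
  if (p$fragment_size_range[2] > p$genome_length) {
    stop("genome shorter than the largest requested fragment", call. = FALSE)
  }
  invisible(p)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
# seed = NULL uses the current stream (still reproducible if the caller set one).
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

revcomp <- function(dna) {
  chartr("ACGT", "TGCA",
         vapply(dna, function(s)
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE))
}

#' Simulate a degron library from a random genome
#'
#' Draws a random genome, samples `n_fragments` uniformly placed fragments
#' with uniform size in `fragment_size_range` and random orientation
#' (forward or reverse complement, probability 1/2 each — blunt cloning is
#' orientation-blind), translates each in the fusion frame with
#' [translate_fusion()], and keeps the fragments whose appended peptide is
#' non-empty.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed for reproducibility (optional).
#' @return A list with `genome` (a nucleotide string) and `degrons`, a
#'   feature-annotated tibble with provenance columns `frag_start`,
#'   `frag_end` (0-based, half-open) and `strand`.
#' @export
simulate_library <- function(params = sim_params(), seed = NULL) {
  validate_sim_params(params)
  with_sim_seed(seed, {
    genome <- paste(sample(c("A", "C", "G", "T"), params$genome_length,
                           replace = TRUE), collapse = "")
    n <- params$n_fragments
    if (n == 0) {
      return(list(genome = genome,
                  degrons = degron_features(
                    tibble::tibble(id = character(), peptide = character())) |>
                    dplyr::mutate(frag_start = integer(), frag_end = integer(),
                                  strand = character())))
    }
    sizes <- sample(seq(params$fragment_size_range[1],
                        params$fragment_size_range[2]), n, replace = TRUE)
    starts <- vapply(sizes, function(sz)
      sample.int(params$genome_length - sz + 1L, 1L) - 1L, integer(1))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    frags <- substring(genome, starts + 1L, starts + sizes)
    frags[strands == "-"] <- revcomp(frags[strands == "-"])
    peptides <- vapply(frags, translate_fusion, character(1), USE.NAMES = FALSE)
    keep <- nchar(peptides) > 0
    recs <- tibble::tibble(
      id = sprintf("deg%04d", seq_len(n)[keep]),
      peptide = peptides[keep],
      frag_start = starts[keep],
      frag_end = starts[keep] + sizes[keep],
      strand = strands[keep]
    )
    list(genome = genome, degrons = degron_features(recs))
  })
}

#' Assign ground-truth degradation kinetics to a degron library
#'
#' Draws a wild-type decay constant for each degron from the log-linear
#' feature model in [sim_params()], then, for each mutant strain, a
#' Bernoulli(`pi`) dependence indicator; a dependent degron's rate is
#' divided by the strain's stabilization factor `f`. Steady-state reporter
#' level follows synthesis/turnover balance `S = 1 / (lambda + mu)` with
#' dilution rate `mu`, so `S` decreases monotonically in `lambda`.
#'
#' @param degrons Feature-annotated degron tibble (needs `id`, `gravy`,
#'   `max_hydrophobic_run`).
#' @param params A [sim_params()] list.
#' @param seed Integer seed (optional).
#' @return Ground-truth tibble: `degron_id`, `strain` (including `"WT"`),
#'   `dependent` (logical; FALSE for WT), `lambda` (min^-1),
#'   `steady_state` (arbitrary units).
#' @export
assign_kinetics <- function(degrons, params = sim_params(), seed = NULL) {
  validate_sim_params(params)
  stopifnot(all(c("id", "gravy", "max_hydrophobic_run") %in% names(degrons)))
  with_sim_seed(seed, {
    n <- nrow(degrons)
    lambda_wt <- exp(params$kinetics_a +
                       params$kinetics_b * degrons$gravy +
                       params$kinetics_c * (degrons$max_hydrophobic_run >= 5) +
                       stats::rnorm(n, 0, params$sigma_lambda))
    wt <- tibble::tibble(degron_id = degrons$id, strain = "WT",
                         dependent = FALSE, lambda = lambda_wt)
    muts <- purrr::pmap_dfr(params$strains, function(strain, pi, f) {
      dep <- stats::runif(n) < pi
      tibble::tibble(degron_id = degrons$id, strain = strain,
                     dependent = dep,
                     lambda = ifelse(dep, lambda_wt / f, lambda_wt))
    })
    dplyr::bind_rows(wt, muts) |>
      dplyr::mutate(steady_state = 1 / (.data$lambda + params$mu))
  })
}

#' Build a 96-position plate layout for a degron set
#'
#' Arrays degrons over as many 8 x 12 source plates as needed. The four
#' corner wells hold reference colonies excluded from analysis; reference
#' (Ura3-HA, no degron) and floor (no Ura3) control wells are spread evenly
#' over each plate; remaining wells carry degrons.
#'
#' @param degron_ids Character vector of degron identifiers.
#' @param params A [sim_params()] list (controls wells per plate).
#' @return Layout tibble: `source_plate`, `well`, `row`, `col`, `role`
#'   (`DEGRON`, `URA3_HA_REF`, `NO_URA3`, `EXCLUDED_CORNER`, `EMPTY`),
#'   `degron_id` (NA for control/empty wells).
#' @export
make_plate_layout <- function(degron_ids, params = sim_params()) {
  rows <- LETTERS[1:8]
  cols <- 1:12
  grid <- tidyr::expand_grid(row = rows, col = cols) |>
    dplyr::mutate(well = sprintf("%s%02d", .data$row, .data$col))
  corner <- grid$well %in% c("A01", "A12", "H01", "H12")
  n_ctl <- params$n_ref_wells + params$n_blank_wells
  per_plate <- nrow(grid) - sum(corner) - n_ctl
  if (per_plate < 1) stop("control wells leave no room for degrons", call. = FALSE)
  n_plates <- max(1L, ceiling(length(degron_ids) / per_plate))
  purrr::map_dfr(seq_len(n_plates), function(pl) {
    g <- dplyr::mutate(grid, source_plate = sprintf("P%02d", pl),
                       role = ifelse(corner, "EXCLUDED_CORNER", "DEGRON"),
                       degron_id = NA_character_)
    open <- which(g$role == "DEGRON")
    # controls at evenly spaced positions so plate gradients hit them too
    ctl_idx <- open[round(seq(1, length(open), length.out = n_ctl))]
    g$role[ctl_idx[seq_len(params$n_ref_wells)]] <- "URA3_HA_REF"
    g$role[ctl_idx[params$n_ref_wells + seq_len(params$n_blank_wells)]] <- "NO_URA3"
    slots <- which(g$role == "DEGRON")
    ids <- degron_ids[(pl - 1L) * per_plate + seq_along(slots)]
    g$degron_id[slots] <- ids
    g$role[slots][is.na(ids)] <- "EMPTY"
    dplyr::select(g, "source_plate", "well", "row", "col", "role", "degron_id")
  })
}

#' Simulate quadruplicate colony-area plates
#'
#' For every strain and pinning replicate, one physical plate is generated:
#' each well's expected area is
#' `baseline + (a_max - baseline) * S / (S + k_half)` for its construct's
#' steady-state level `S` (reference and corner wells carry the no-degron
#' reporter; no-Ura3 wells sit at the baseline area), multiplied by a
#' per-plate lognormal effect and independent per-well lognormal noise. A
#' degron degraded arbitrarily fast therefore converges to the no-Ura3
#' phenotype, and stabilization restores growth.
#'
#' @param truth Ground-truth tibble from [assign_kinetics()].
#' @param layout Layout tibble from [make_plate_layout()].
#' @param params A [sim_params()] list.
#' @param seed Integer seed (optional).
#' @param strains Strains to pin; default WT plus every mutant in `truth`.
#' @return Long tibble, one row per well per plate:
#'   `plate`, `source_plate`, `strain`, `replicate`, `well`, `row`, `col`,
#'   `role`, `degron_id`, `area`.
#' @export
simulate_plates <- function(truth, layout, params = sim_params(), seed = NULL,
                            strains = NULL) {
  validate_sim_params(params)
  if (is.null(strains)) strains <- unique(truth$strain)
  laid <- stats::na.omit(unique(layout$degron_id))
  missing <- setdiff(laid, unique(truth$degron_id))
  if (length(missing) > 0) {
    stop("layout contains degrons absent from ground truth: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  s_ref <- 1 / params$mu  # steady state of the undegraded reporter
  with_sim_seed(seed, {
    purrr::map_dfr(strains, function(st) {
      tr <- dplyr::filter(truth, .data$strain == st)
      purrr::map_dfr(seq_len(params$plate_replicates), function(rep_i) {
        purrr::map_dfr(unique(layout$source_plate), function(sp) {
          lay <- dplyr::filter(layout, .data$source_plate == sp)
          plate_effect <- stats::rlnorm(1, 0, params$plate_effect_sd)
          s <- dplyr::case_when(
            lay$role %in% c("URA3_HA_REF", "EXCLUDED_CORNER") ~ s_ref,
            lay$role == "DEGRON" ~
              tr$steady_state[match(lay$degron_id, tr$degron_id)],
            TRUE ~ NA_real_
          )
          # baseline: pinned cells grow a little even without Ura3, so a
          # construct with lambda -> Inf converges to the no-Ura3 area
          mean_area <- dplyr::case_when(
            lay$role == "NO_URA3" ~ params$baseline_area,
            lay$role == "EMPTY" ~ 0,
            TRUE ~ params$baseline_area +
              (params$a_max - params$baseline_area) * s / (s + params$k_half)
          )
          noise <- stats::rlnorm(nrow(lay), 0, params$plate_cv)
          dplyr::mutate(lay,
                        plate = sprintf("%s_%s_rep%d", sp, st, rep_i),
                        strain = st, replicate = rep_i,
                        area = mean_area * plate_effect * noise) |>
            dplyr::select("plate", "source_plate", "strain", "replicate",
                          "well", "row", "col", "role", "degron_id", "area")
        })
      })
    })
  })
}

#' Simulate replicate cycloheximide-chase time courses
#'
#' Substrate signal decays as `I0 * exp(-lambda * t)` with multiplicative
#' lognormal noise; the loading-control channel is constant with independent
#' lognormal noise. `blot_sigma` parameterizes the noise of the *derived*
#' percent-remaining observation: a point at `t > 0` combines four
#' independent log-noise terms (both channels at `t` and at 0), so each
#' channel draws with sdlog `blot_sigma / 2`, making the percent-remaining
#' series carry multiplicative lognormal noise of sdlog `blot_sigma`
#' exactly (and exactly 100 at `t = 0`).
#'
#' @param lambda Decay constant, min^-1 (>= 0).
#' @param params A [sim_params()] list (`timepoints`, `chase_replicates`,
#'   `blot_sigma`, signal scales).
#' @param seed Integer seed (optional).
#' @param strain,degron_id Labels carried into the output table.
#' @return Tibble: `strain`, `degron_id`, `replicate`, `time_min`,
#'   `substrate_signal`, `loading_signal`.
#' @export
simulate_chase <- function(lambda, params = sim_params(), seed = NULL,
                           strain = "WT", degron_id = "deg") {
  validate_sim_params(params)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  tp <- params$timepoints
  if (any(tp < 0)) stop("negative timepoint", call. = FALSE)
  sdlog <- params$blot_sigma / 2  # per channel; see above
  with_sim_seed(seed, {
    purrr::map_dfr(seq_len(params$chase_replicates), function(r) {
      tibble::tibble(
        strain = strain, degron_id = degron_id, replicate = r,
        time_min = tp,
        substrate_signal = params$substrate_scale * exp(-lambda * tp) *
          stats::rlnorm(length(tp), 0, sdlog),
        loading_signal = params$loading_scale *
          stats::rlnorm(length(tp), 0, sdlog)
      )
    })
  })
}

#' Simulate steady-state blot quantifications
#'
#' One row per strain x construct x replicate, with substrate signal
#' proportional to the ground-truth steady-state level and an independent
#' lognormal loading-control channel. A no-degron reference construct
#' (`URA3_HA`) is included for every strain.
#'
#' @param truth Ground-truth tibble from [assign_kinetics()].
#' @param params A [sim_params()] list.
#' @param seed Integer seed (optional).
#' @return Tibble: `strain`, `degron_id`, `replicate`, `substrate_signal`,
#'   `loading_signal`.
#' @export
simulate_steady_state <- function(truth, params = sim_params(), seed = NULL) {
  validate_sim_params(params)
  s_ref <- 1 / params$mu
  base <- dplyr::bind_rows(
    dplyr::select(truth, "strain", "degron_id", "steady_state"),
    tibble::tibble(strain = unique(truth$strain), degron_id = "URA3_HA",
                   steady_state = s_ref)
  )
  with_sim_seed(seed, {
    tidyr::expand_grid(base, replicate = seq_len(params$blot_replicates)) |>
      dplyr::mutate(
        substrate_signal = params$substrate_scale / s_ref * .data$steady_state *
          stats::rlnorm(dplyr::n(), 0, params$blot_sigma / 2),
        loading_signal = params$loading_scale *
          stats::rlnorm(dplyr::n(), 0, params$blot_sigma / 2)
      ) |>
      dplyr::select("strain", "degron_id", "replicate",
                    "substrate_signal", "loading_signal")
  })
}

#' Simulate a complete screen
#'
#' Convenience wrapper chaining [simulate_library()], [assign_kinetics()],
#' [make_plate_layout()] and [simulate_plates()] with per-stage seeds
#' derived deterministically from one master seed.
#'
#' @param params A [sim_params()] list.
#' @param seed Master integer seed (optional).
#' @return List with `genome`, `degrons`, `truth`, `layout`, `plates`.
#' @export
simulate_screen <- function(params = sim_params(), seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
    as.list((seed + c(101L, 211L, 307L)) %% .Machine$integer.max)
  lib <- simulate_library(params, seed = seeds[[1]])
  truth <- assign_kinetics(lib$degrons, params, seed = seeds[[2]])
  layout <- make_plate_layout(lib$degrons$id, params)
  plates <- simulate_plates(truth, layout, params, seed = seeds[[3]])
  list(genome = lib$genome, degrons = lib$degrons, truth = truth,
       layout = layout, plates = plates)
}
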