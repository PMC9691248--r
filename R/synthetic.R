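#' Scenario configuration for synthetic data generation
#'
#' One self-consistent set of "truth" parameters from which every pipeline
#' input can be generated: the extraction geometry, kinetic and partition
#' truths, ELISA dose-response truth with a hemoglobin interference
#' coefficient, the Soret-band spectral model and the work-distribution
#' parameters for free-energy estimation. Defaults emulate the depletion
#' experiment this package analyses: 3 mL of serum shaken with 0.7 g of
#' hydrophobic ionic liquid (density 1.12 g/mL), hemoglobin around
#' 0.125 mg/mL, equilibrium well inside 5 min, ~95% depletion at low
#' loading, a competitive cotinine curve over 0-100 ng/mL with midpoint
#' 25 ng/mL, and overlapping Gaussian work distributions.
#'
#' @param seed Integer seed; all generators are deterministic given the
#'   configuration.
#' @param system [extraction_system()] truth (default 3 mL serum, 0.7 g IL,
#'   q = 0.375 mg i.e. 0.125 mg/mL hemoglobin).
#' @param k1,k2 Kinetic rate constants, 1/min. Defaults give an equilibrium
#'   separation ratio `k1/k2 = 90` and 95% equilibration in about 3.6 min.
#' @param s0,k_half Partition truth: limiting separation ratio and
#'   half-saturation constant (mg/mL).
#' @param elisa Named list: `a_top`, `a_bottom`, `ic50`, `h` (4PL truth),
#'   `replicate_cv` (multiplicative replicate noise), `hb_bias` (absorbance
#'   depression per mg/mL hemoglobin; models nonspecific binding of free
#'   hemoglobin to the solid phase, which mimics extra analyte).
#' @param spectral Named list: `center` (nm), `width` (nm, Gaussian sigma),
#'   `slope` (absorbance per mg/mL at the peak), `baseline` (flat offset;
#'   default 0, i.e. blank-subtracted spectra), `noise_sd`.
#' @param bar Named list: `dg` (kJ/mol), `sigma` (kJ/mol work spread),
#'   `n` (samples per direction), `temperature` (K).
#' @return An object of class `ilx_scenario`.
#' @export
scenario_config <- function(seed = 1,
                            system = extraction_system(v_aq = 3, q = 0.375,
                                                       il_mass = 0.7),
                            k1 = 0.8, k2 = 0.8 / 90,
                            s0 = 90, k_half = 0.1,
                            elisa = list(a_top = 1.0, a_bottom = 0.1,
                                         ic50 = 25, h = 1.0,
                                         replicate_cv = 0.05,
                                         hb_bias = 0.31),
                            spectral = list(center = 410, width = 18,
                                            slope = 1 / 0.15, baseline = 0,
                                            noise_sd = 0.005),
                            bar = list(dg = 10, sigma = 2, n = 1e5,
                                       temperature = 298)) {
  .check_number(seed, "seed")
  stopifnot(inherits(system, "ilx_system"))
  .check_number(k1, "k1", lower = 0)
  .check_number(k2, "k2", lower = 0)
  .check_number(s0, "s0", lower = 0, strict_lower = TRUE)
  .check_number(k_half, "k_half", lower = 0, strict_lower = TRUE)
  structure(list(seed = as.integer(seed), system = system, k1 = k1, k2 = k2,
                 s0 = s0, k_half = k_half, elisa = elisa,
                 spectral = spectral, bar = bar),
            class = "ilx_scenario")
}

#' Synthetic Soret-band absorbance spectrum
#'
#' Gaussian peak at the Soret center (410 nm) with height proportional to
#' the hemoglobin concentration (`slope * c_hb`), on a 350-500 nm grid at
#' 1 nm, plus a flat baseline and optional Gaussian noise. With the default
#' zero baseline and zero noise, `absorbance_at(spec, 410)` equals
#' `slope * c_hb` exactly (1.0 at 0.15 mg/mL).
#'
#' @param cfg An [scenario_config()].
#' @param c_hb Hemoglobin concentration, mg/mL (>= 0).
#' @param noise_sd Absorbance noise SD; defaults to 0 (noise is opt-in so
#'   that generated spectra are exactly on-model unless asked otherwise).
#' @param seed Seed; defaults to `cfg$seed`.
#' @return An [spectrum_data()] object.
#' @export
make_spectrum <- function(cfg, c_hb, noise_sd = 0, seed = cfg$seed) {
  stopifnot(inherits(cfg, "ilx_scenario"))
  .check_number(c_hb, "c_hb", lower = 0)
  sp <- cfg$spectral
  wl <- seq(350, 500, by = 1)
  mu <- sp$baseline + sp$slope * c_hb * exp(-(wl - sp$center)^2 / (2 * sp$width^2))
  a <- .with_seed(seed, mu + rnorm(length(wl), sd = noise_sd))
  spectrum_data(wl, pmax(a, 0),
                label = sprintf("synthetic serum, %.4g mg/mL hemoglobin", c_hb))
}

#' Synthetic kinetic time course
#'
#' Wraps [simulate_trace()] with the scenario's kinetic truth. The default
#' sampling (8 points over 0-20 min, dense at early times where the
#' relaxation happens, sparse on the plateau) and noise (2% of the initial
#' concentration) mirror a shaking-time optimisation experiment.
#'
#' @param cfg An [scenario_config()].
#' @param times Sampling times, min.
#' @param noise_sd Noise SD in mg/mL; default 2% of `q/V_aq`.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return An [kinetic_trace()].
#' @export
make_kinetic_trace <- function(cfg, times = c(0, 0.25, 0.5, 1, 2, 4, 10, 20),
                               noise_sd = 0.02 * cfg$system$q / cfg$system$v_aq,
                               seed = cfg$seed) {
  stopifnot(inherits(cfg, "ilx_scenario"))
  model <- kinetic_model(cfg$k1, cfg$k2, cfg$system)
  simulate_trace(model, times, noise_sd = noise_sd, seed = seed)
}

#' Synthetic equilibrium isotherm
#'
#' Ionic-liquid concentrations from the scenario's hyperbolic partition
#' truth at a grid of aqueous concentrations, with multiplicative lognormal
#' noise of the given coefficient of variation.
#'
#' @param cfg An [scenario_config()].
#' @param c_aq_grid Aqueous concentrations, mg/mL.
#' @param noise_cv Multiplicative noise CV (default 0.03); 0 gives exactly
#'   on-model data.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return An [isotherm()].
#' @export
make_isotherm <- function(cfg, c_aq_grid = seq(0.01, 1, length.out = 10),
                          noise_cv = 0.03, seed = cfg$seed) {
  stopifnot(inherits(cfg, "ilx_scenario"))
  .check_number(noise_cv, "noise_cv", lower = 0)
  model <- partition_model("hyperbolic", s0 = cfg$s0, k = cfg$k_half)
  mu <- c_il_from_c_aq(model, c_aq_grid)
  y <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    .with_seed(seed, mu * exp(rnorm(length(mu), -sdlog^2 / 2, sdlog)))
  } else mu
  isotherm(c_aq_grid, y,
           metadata = sprintf("synthetic isotherm, S0 = %g, K = %g mg/mL",
                              cfg$s0, cfg$k_half))
}

# Residual hemoglobin fraction after extraction, from the partition truth
# applied to a system loaded at hb_level.
.residual_hb_fraction <- function(cfg, hb_level) {
  if (hb_level <= 0) return(0)
  sys <- cfg$system
  loaded <- extraction_system(v_aq = sys$v_aq, q = hb_level * sys$v_aq,
                              v_il = sys$v_il)
  model <- partition_model("hyperbolic", s0 = cfg$s0, k = cfg$k_half)
  1 - predict_depletion(model, loaded)$efficiency_percent / 100
}

#' Synthetic competitive-ELISA plate
#'
#' Standards (0, 5, 10, 25, 50, 100 ng/mL) and sample replicates generated
#' from the 4PL truth. Free hemoglobin interferes by depressing the sample
#' absorbance by `hb_bias * c_hb` (nonspecific binding mimicking extra
#' analyte, hence a positive concentration bias); plates labelled
#' `extracted = TRUE` carry only the residual bias scaled by
#' `1 - efficiency` from the partition truth. Replicate noise is
#' multiplicative lognormal with CV `noise_cv` on all wells.
#'
#' @param cfg An [scenario_config()].
#' @param nominal Sample spike, ng/mL (default 20).
#' @param hb_level Hemoglobin level in the serum, mg/mL.
#' @param extracted Was the serum depleted before the assay?
#' @param n_replicates Sample replicates (default 3).
#' @param n_standard_replicates Wells per standard (default 2, the usual
#'   duplicate-standard kit layout).
#' @param noise_cv Replicate CV; defaults to the scenario's `replicate_cv`.
#'   0 gives exactly on-model wells.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return Plate data frame (`well`, `role`, `nominal_ng_per_ml`,
#'   `absorbance`) as consumed by [quantify_plate()].
#' @export
make_plate <- function(cfg, nominal = 20, hb_level = 0, extracted = FALSE,
                       n_replicates = 3, n_standard_replicates = 2,
                       noise_cv = cfg$elisa$replicate_cv,
                       seed = cfg$seed) {
  stopifnot(inherits(cfg, "ilx_scenario"))
  .check_number(nominal, "nominal", lower = 0, strict_lower = TRUE)
  .check_number(hb_level, "hb_level", lower = 0)
  .check_number(noise_cv, "noise_cv", lower = 0)
  el <- cfg$elisa
  std_conc <- rep(c(0, 5, 10, 25, 50, 100), each = n_standard_replicates)
  std_a <- fourpl_absorbance(std_conc, el$a_top, el$a_bottom, el$ic50, el$h)

  hb_eff <- if (extracted) hb_level * .residual_hb_fraction(cfg, hb_level)
            else hb_level
  smp_a <- rep(fourpl_absorbance(nominal, el$a_top, el$a_bottom, el$ic50, el$h) -
                 el$hb_bias * hb_eff, n_replicates)
  if (any(smp_a <= el$a_bottom)) {
    .stop_validation("hemoglobin bias pushes sample absorbance below the ",
                     "bottom plateau; reduce hb_bias or hb_level")
  }

  a_all <- c(std_a, smp_a)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    a_all <- .with_seed(seed,
                        a_all * exp(rnorm(length(a_all), -sdlog^2 / 2, sdlog)))
  }
  data.frame(
    well = sprintf("W%02d", seq_along(a_all)),
    role = c(rep("standard", length(std_conc)), rep("sample", n_replicates)),
    nominal_ng_per_ml = c(std_conc, rep(nominal, n_replicates)),
    absorbance = a_all
  )
}

#' Synthetic Crooks-consistent work samples
#'
#' Gaussian forward and reverse work distributions satisfying the Crooks
#' fluctuation theorem for a target free-energy difference `dg`:
#' forward work ~ N(dg + beta sigma^2/2, sigma^2) and reverse work
#' ~ N(-dg + beta sigma^2/2, sigma^2), so the dissipated work
#' `beta sigma^2/2` is the same in both directions and BAR is asymptotically
#' unbiased for `dg`.
#'
#' @param cfg An [scenario_config()].
#' @param n Samples per direction; defaults to the scenario's `bar$n`.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return An [work_samples()] object.
#' @export
make_work_samples <- function(cfg, n = cfg$bar$n, seed = cfg$seed) {
  stopifnot(inherits(cfg, "ilx_scenario"))
  .check_number(n, "n", lower = 1)
  b <- cfg$bar
  beta <- 1 / (.kB * b$temperature)
  diss <- beta * b$sigma^2 / 2
  .with_seed(seed, {
    fw <- rnorm(n, b$dg + diss, b$sigma)
    rv <- rnorm(n, -b$dg + diss, b$sigma)
    work_samples(fw, rv, temperature = b$temperature)
  })
}

#' Write a complete synthetic scenario to disk
#'
#' Generates one input file per pipeline stage (spectrum, kinetic trace,
#' isotherm, ELISA plates before/after extraction, work samples) plus a
#' `manifest.json` recording every truth parameter, so a full analysis can
#' be run from files alone.
#'
#' @param cfg An [scenario_config()].
#' @param dir Output directory (created if needed).
#' @param hb_levels Hemoglobin levels (mg/mL) for the ELISA plates.
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_scenario <- function(cfg, dir, hb_levels = c(0, 0.05, 0.1, 0.2)) {
  stopifnot(inherits(cfg, "ilx_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  spec <- make_spectrum(cfg, c_hb = cfg$system$q / cfg$system$v_aq,
                        noise_sd = cfg$spectral$noise_sd, seed = cfg$seed + 1)
  paths$spectrum <- file.path(dir, "spectrum.csv")
  write_spectrum(spec, paths$spectrum)

  trace <- make_kinetic_trace(cfg, seed = cfg$seed + 2)
  paths$kinetic_trace <- file.path(dir, "kinetic_trace.csv")
  write_kinetic_trace(trace, paths$kinetic_trace)

  iso <- make_isotherm(cfg, seed = cfg$seed + 3)
  paths$isotherm <- file.path(dir, "isotherm.csv")
  write_isotherm(iso, paths$isotherm)

  for (i in seq_along(hb_levels)) {
    hb <- hb_levels[i]
    for (ext in c(FALSE, TRUE)) {
      plate <- make_plate(cfg, hb_level = hb, extracted = ext,
                          seed = cfg$seed + 10 + 2 * i + ext)
      nm <- sprintf("plate_hb%03.0f_%s.csv", 1000 * hb,
                    if (ext) "after" else "before")
      p <- file.path(dir, nm)
      .write_csv_full(plate, p)
      paths[[nm]] <- p
    }
  }

  ws <- make_work_samples(cfg, seed = cfg$seed + 4)
  paths$work_samples <- file.path(dir, "work_samples.csv")
  write_work_samples(ws, paths$work_samples)

  manifest <- list(
    seed = cfg$seed,
    system = cfg$system[c("v_aq", "v_il", "q")],
    kinetics = list(k1 = cfg$k1, k2 = cfg$k2),
    partition = list(s0 = cfg$s0, k_half = cfg$k_half),
    elisa = cfg$elisa,
    spectral = cfg$spectral,
    bar = cfg$bar,
    hb_levels = hb_levels,
    files = lapply(paths, basename)
  )
  paths$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
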