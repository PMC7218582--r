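#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of [generate_cohort()] with defaults that embody the
#' study design the generator emulates: mock communities at two biomass levels
#' separated by a 1-in-1e4 dilution, buffer-specific reagent backgrounds
#' calibrated so low-biomass STGG and Primestore mocks carry about 9.5% and
#' 1.5% background reads, plate-local well-to-well spill-over, extraction-kit
#' lysis bias against gram-positive taxa, specimen biomass rising with
#' participant age, within- and between-run technical repeats, and spurious
#' rare OTUs enriched in low-biomass libraries.
#'
#' @param n_specimens Number of distinct biological specimens.
#' @param n_ntc Number of no-template controls (Primestore buffer).
#' @param n_mock_high,n_mock_low Number of high/low biomass mock libraries
#'   (split evenly over buffer x kit combinations).
#' @param dilution_factor Fold-dilution separating high and low biomass mocks.
#' @param mock_high_copies True biomass of high-biomass mocks (copies/ul).
#' @param n_true_taxa,n_contam_taxa,n_clusters Sizes of the true-taxon pool,
#'   the reagent-contaminant pool, and the number of specimen community types.
#' @param kappa_primestore,kappa_stgg Reagent contaminant pseudo-biomass per
#'   buffer (copies/ul equivalents) in the mixing model w = B/(B + kappa).
#' @param spillover_rate Mean plate-local spill-over fraction epsilon.
#' @param reagent_load_specimen_runs Multiplier on the buffer kappa for
#'   libraries processed in the longitudinal specimen runs (specimens and
#'   their NTCs). The mock-community experiment used freshly pooled buffer
#'   batches and keeps the calibrated buffer kappa; specimen runs span many
#'   reagent batches and carry a proportionally heavier background, which is
#'   what makes sub-500 copies/ul specimens resemble no-template controls.
#' @param kit_bias Named list per kit of lysis multipliers in (0, 1] by gram
#'   class.
#' @param depth_mean,depth_dispersion Negative-binomial read depth model.
#' @param depth_floor,depth_halfsat Depth scaling with biomass: the expected
#'   depth is `depth_mean * (depth_floor + (1 - depth_floor) * B/(B + depth_halfsat))`.
#' @param spurious_rate,spurious_exponent Spurious OTUs per library follow
#'   Poisson(`spurious_rate * (B + 1)^-spurious_exponent`).
#' @param age_beta0,age_beta1,age_sigma Log-biomass model
#'   `ln B = beta0 + beta1 ln(age + 1) + Normal(0, sigma)`.
#' @param age_max_days Ages are log-uniform on \[0, age_max_days\].
#' @param repeat_design Named fractions of specimens processed as within-run
#'   duplicates, between-run duplicates, triplicates and quadruplicates
#'   (must sum to at most 1; the remainder are sequenced once).
#' @param copies_noise_sigma Lognormal sigma of the qPCR measurement noise.
#' @param amplification_sigma Lognormal sigma of the run/extraction-level
#'   amplification effect (shared by re-amplifications of one extract within
#'   a run, re-drawn across runs).
#' @param library_sigma Lognormal sigma of the residual per-library
#'   amplification jitter.
#' @param contam_dirichlet_alpha Dirichlet concentration of each buffer's base
#'   contaminant profile.
#' @param contam_library_concentration Dirichlet concentration of per-
#'   extraction contaminant realizations around the buffer base.
#' @param cluster_concentration Dirichlet concentration of specimen
#'   compositions around their community-type profile.
#' @param mock_reference Name of the built-in mock used for mock samples.
#' @param seed Integer seed; the whole cohort is reproducible bit-for-bit.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_specimens = 150,
                       n_ntc = 10,
                       n_mock_high = 12,
                       n_mock_low = 12,
                       dilution_factor = 1e4,
                       mock_high_copies = 2e6,
                       n_true_taxa = 40,
                       n_contam_taxa = 20,
                       n_clusters = 5,
                       kappa_primestore = 3.05,
                       kappa_stgg = 21,
                       spillover_rate = 0.002,
                       reagent_load_specimen_runs = 50,
                       kit_bias = list(
                         kit_qs = c(gram_positive = 0.7, gram_negative = 1),
                         kit_zb = c(gram_positive = 0.4, gram_negative = 1),
                         none = c(gram_positive = 1, gram_negative = 1)),
                       depth_mean = 10000,
                       depth_dispersion = 5,
                       depth_floor = 0.33,
                       depth_halfsat = 500,
                       spurious_rate = 8,
                       spurious_exponent = 0.25,
                       age_beta0 = 4.5,
                       age_beta1 = 1,
                       age_sigma = 1.5,
                       age_max_days = 400,
                       repeat_design = c(dup_within = 0.45, dup_between = 0.35,
                                         trip_between = 0.10, quad_between = 0.10),
                       copies_noise_sigma = 0.2,
                       amplification_sigma = 0.3,
                       library_sigma = 0.1,
                       contam_dirichlet_alpha = 2,
                       contam_library_concentration = 200,
                       cluster_concentration = 30,
                       mock_reference = "zymobiomics",
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$dilution_factor <= 1) abort("dilution_factor must be > 1")
  if (cfg$kappa_primestore < 0 || cfg$kappa_stgg < 0) abort("kappa must be >= 0")
  if (cfg$spillover_rate < 0 || cfg$spillover_rate >= 1) {
    abort("spillover_rate must lie in [0, 1)")
  }
  if (sum(cfg$repeat_design) > 1 + 1e-9) {
    abort("repeat_design fractions must sum to at most 1")
  }
  if (any(cfg$repeat_design < 0)) abort("repeat_design fractions must be >= 0")
  for (k in names(cfg$kit_bias)) {
    b <- cfg$kit_bias[[k]]
    if (any(b <= 0) || any(b > 1)) {
      abort(sprintf("kit_bias multipliers for %s must lie in (0, 1]", k))
    }
  }
  if (cfg$n_clusters < 1 || cfg$n_true_taxa < 2 * cfg$n_clusters) {
    abort("need at least two true taxa per community cluster")
  }
  if (cfg$mock_high_copies <= 0) abort("mock_high_copies must be > 0")
  if (cfg$reagent_load_specimen_runs <= 0) {
    abort("reagent_load_specimen_runs must be > 0")
  }
  if (is.null(cfg$seed)) abort("sim_config requires an integer seed")
  cfg
}
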