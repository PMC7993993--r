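#' Population parameters for the synthetic cell generator
#'
#' Bundles the distributional description of one strain/imaging condition:
#' length distribution, minicell share, cluster prevalence, the mixture over
#' cluster localization classes, constriction statistics and the nucleoid
#' extent. These are the knobs every downstream recovery test exercises.
#'
#' @param label Short strain/condition label.
#' @param length_mean,length_sd Mean and SD of cell length (um). Lengths are
#'   drawn from a normal distribution truncated below at 0.5 um so the stated
#'   moments are matched without non-physical lengths.
#' @param minicell_fraction Fraction of cells replaced by short DNA-free
#'   minicells (length uniform in 0.6--1.5 um).
#' @param cluster_prevalence Probability that a (non-minicell) cell carries a
#'   single fluorescent cluster.
#' @param localization_mixture Named numeric probabilities over
#'   `c("midcell", "off_center", "subpolar")`; must sum to 1.
#' @param constriction_frequency Fraction of cells with a division
#'   constriction.
#' @param constriction_position_model `"midcell_tight"` (narrow band around
#'   50% of cell length) or `"uniform_over_nucleoid"`.
#' @param nucleoid_span Fraction of cell length occupied by the (centered)
#'   nucleoid; positions outside it are subpolar.
#' @return An object of class `population_params`.
#' @seealso [population_preset()] for the presets used throughout the
#'   package, [sample_cell_population()].
#' @export
population_params <- function(label = "custom",
                              length_mean = 8.0,
                              length_sd = 1.8,
                              minicell_fraction = 0,
                              cluster_prevalence = 0,
                              localization_mixture = c(midcell = 0.5,
                                                       off_center = 0.5,
                                                       subpolar = 0),
                              constriction_frequency = 0.15,
                              constriction_position_model = c("midcell_tight",
                                                              "uniform_over_nucleoid"),
                              nucleoid_span = 0.8) {
  constriction_position_model <- match.arg(constriction_position_model)
  if (!is.numeric(length_mean) || length_mean <= 0)
    stop_input("length_mean must be > 0")
  if (!is.numeric(length_sd) || length_sd < 0)
    stop_input("length_sd must be >= 0")
  check_prob(minicell_fraction, "minicell_fraction")
  check_prob(cluster_prevalence, "cluster_prevalence")
  check_prob(constriction_frequency, "constriction_frequency")
  if (!is.numeric(nucleoid_span) || nucleoid_span <= 0 || nucleoid_span > 1)
    stop_input("nucleoid_span must be in (0, 1]")
  want <- c("midcell", "off_center", "subpolar")
  if (is.null(names(localization_mixture)) ||
      !setequal(names(localization_mixture), want))
    stop_input("localization_mixture must be named: midcell, off_center, subpolar")
  localization_mixture <- localization_mixture[want]
  if (any(localization_mixture < 0) ||
      abs(sum(localization_mixture) - 1) > 1e-9)
    stop_input("localization_mixture must be non-negative and sum to 1")
  structure(list(label = label,
                 length_mean = length_mean,
                 length_sd = length_sd,
                 minicell_fraction = minicell_fraction,
                 cluster_prevalence = cluster_prevalence,
                 localization_mixture = localization_mixture,
                 constriction_frequency = constriction_frequency,
                 constriction_position_model = constriction_position_model,
                 nucleoid_span = nucleoid_span),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population parameters:", x$label, "\n")
  cat(sprintf("  length        %.1f +/- %.1f um (minicell fraction %.2f)\n",
              x$length_mean, x$length_sd, x$minicell_fraction))
  cat(sprintf("  clusters      prevalence %.2f; mixture midcell %.2f / off-center %.2f / subpolar %.2f\n",
              x$cluster_prevalence, x$localization_mixture[["midcell"]],
              x$localization_mixture[["off_center"]],
              x$localization_mixture[["subpolar"]]))
  cat(sprintf("  constriction  frequency %.2f (%s); nucleoid span %.2f\n",
              x$constriction_frequency, x$constriction_position_model,
              x$nucleoid_span))
  invisible(x)
}

#' Strain presets for the synthetic generator
#'
#' Measured population parameters for the strains the package's recovery
#' analyses emulate. Cell lengths: wild type 8.0 +/- 1.8 um; the division-site
#' positioning mutant (`"dPomX"`) is filamentous at 13.1 +/- 6.1 um and
#' produces DNA-free minicells. Cluster prevalence: mCherry-tagged full-length
#' scaffold protein forms a single cluster in 94% of wild-type and 93% of
#' deletion-background cells; the C-terminal domain fusion in 90% of
#' merodiploid cells; the K13A R15A ATPase-activating-peptide mutant in 76%
#' (24% of cells lack a visible cluster) with about half of its clusters in
#' DNA-free subpolar regions.
#'
#' @param name One of `"WT"`, `"dPomX"`, `"dPomX_mChPomXWT"`,
#'   `"PomXC_pomXplus"`, `"K13AR15A"`.
#' @return A [population_params()] object.
#' @export
population_preset <- function(name = c("WT", "dPomX", "dPomX_mChPomXWT",
                                       "PomXC_pomXplus", "K13AR15A")) {
  name <- match.arg(name)
  switch(name,
    WT = population_params(
      label = "WT / mCh-PomX(WT)",
      length_mean = 8.0, length_sd = 1.8,
      minicell_fraction = 0, cluster_prevalence = 0.94),
    dPomX = population_params(
      label = "dPomX (no fusion)",
      length_mean = 13.1, length_sd = 6.1,
      minicell_fraction = 0.05, cluster_prevalence = 0,
      constriction_frequency = 0.10,
      constriction_position_model = "uniform_over_nucleoid"),
    dPomX_mChPomXWT = population_params(
      label = "dPomX / mCh-PomX(WT) complemented",
      length_mean = 8.0, length_sd = 1.8,
      minicell_fraction = 0, cluster_prevalence = 0.93),
    PomXC_pomXplus = population_params(
      label = "pomX+ / mCh-PomX(C)",
      length_mean = 8.0, length_sd = 1.8,
      minicell_fraction = 0, cluster_prevalence = 0.90),
    K13AR15A = population_params(
      label = "mCh-PomX(K13A R15A)",
      length_mean = 10.0, length_sd = 4.0,
      minicell_fraction = 0.03, cluster_prevalence = 0.76,
      localization_mixture = c(midcell = 0.1, off_center = 0.4,
                               subpolar = 0.5),
      constriction_position_model = "uniform_over_nucleoid"))
}

#' Physical constants of the NADH-coupled ATPase assay
#'
#' The coupled assay reads ATP hydrolysis as stoichiometric NADH oxidation
#' (one NADH per ADP through pyruvate kinase / lactate dehydrogenase), i.e. a
#' decrease in absorbance at 340 nm. Conversion between absorbance slope and
#' ADP production rate uses Beer-Lambert with the NADH extinction coefficient
#' 6220 per molar per cm and the experimentally determined plate light path
#' of 0.248 cm.
#'
#' @param epsilon_nadh Extinction coefficient of NADH at 340 nm
#'   (M^-1 cm^-1).
#' @param light_path Optical path length in the well (cm).
#' @param nadh_start_mM Initial NADH concentration (mM); sets the starting
#'   absorbance and the depletion limit.
#' @param atp_start_mM Initial ATP concentration (mM).
#' @return Object of class `assay_constants`.
#' @export
assay_constants <- function(epsilon_nadh = 6220,
                            light_path = 0.248,
                            nadh_start_mM = 0.5,
                            atp_start_mM = 1) {
  if (epsilon_nadh <= 0 || light_path <= 0)
    stop_input("epsilon_nadh and light_path must be > 0")
  structure(list(epsilon_nadh = epsilon_nadh, light_path = light_path,
                 nadh_start_mM = nadh_start_mM, atp_start_mM = atp_start_mM),
            class = "assay_constants")
}

#' Ground-truth description of one ATPase assay well
#'
#' @param specific_activity ATP turned over per enzyme per hour (hr^-1).
#' @param enzyme_conc Enzyme concentration (uM).
#' @param dna_conc Non-specific DNA concentration (ug/ml).
#' @param aap Label of the ATPase-activating protein/peptide added.
#' @param aap_conc Its concentration (uM).
#' @param control_drift Baseline absorbance drift (absorbance per hour)
#'   modelling spontaneous ATP hydrolysis and UV-induced NADH decomposition;
#'   present in both sample and no-enzyme control wells.
#' @param noise_sd Per-read Gaussian absorbance noise SD.
#' @return Object of class `kinetic_truth`.
#' @seealso [kinetic_preset()], [simulate_atpase_trace()].
#' @export
kinetic_truth <- function(specific_activity,
                          enzyme_conc = 4,
                          dna_conc = 0,
                          aap = "none",
                          aap_conc = 0,
                          control_drift = -0.02,
                          noise_sd = 0.003) {
  if (specific_activity < 0) stop_input("specific_activity must be >= 0")
  if (enzyme_conc < 0) stop_input("enzyme_conc must be >= 0")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  structure(list(specific_activity = specific_activity,
                 enzyme_conc = enzyme_conc, dna_conc = dna_conc,
                 aap = aap, aap_conc = aap_conc,
                 control_drift = control_drift, noise_sd = noise_sd),
            class = "kinetic_truth")
}

#' Kinetic presets: measured specific activities
#'
#' Specific activities at 4 uM enzyme: 7 hr^-1 with no DNA (basal), ~15 hr^-1
#' at saturating DNA (60 ug/ml), 44 hr^-1 with 15 uM full-length activating
#' protein + DNA, 43 hr^-1 with its N-terminal domain, and 27 hr^-1 with the
#' 22-residue N-terminal activating peptide alone.
#'
#' @param name One of `"basal"`, `"dna_saturated"`, `"pomx_wt"`, `"pomx_n"`,
#'   `"npep"`.
#' @return A [kinetic_truth()] object.
#' @export
kinetic_preset <- function(name = c("basal", "dna_saturated", "pomx_wt",
                                    "pomx_n", "npep")) {
  name <- match.arg(name)
  switch(name,
    basal = kinetic_truth(7, dna_conc = 0),
    dna_saturated = kinetic_truth(15, dna_conc = 60),
    pomx_wt = kinetic_truth(44, dna_conc = 60, aap = "PomX_WT", aap_conc = 15),
    pomx_n = kinetic_truth(43, dna_conc = 60, aap = "PomX_N", aap_conc = 15),
    npep = kinetic_truth(27, dna_conc = 60, aap = "NPEP", aap_conc = 15))
}

#' DNA dose-response of basal ATPase stimulation
#'
#' Hyperbolic stimulation of the enzyme's specific activity by non-specific
#' DNA, rising from the basal rate to a plateau, parameterized by the dose at
#' which 90% of the plateau increment is reached (default 40 ug/ml, i.e. a
#' half-saturation constant of 40/9 ug/ml).
#'
#' @param dose DNA concentration(s), ug/ml.
#' @param basal,plateau Specific activities (hr^-1) at zero and saturating
#'   DNA.
#' @param saturation_dose Dose reaching 90% of the plateau increment (ug/ml).
#' @return Specific activity (hr^-1) at each dose.
#' @export
dna_stimulation_activity <- function(dose, basal = 7, plateau = 15,
                                     saturation_dose = 40) {
  K <- saturation_dose / 9
  basal + (plateau - basal) * dose / (K + dose)
}
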