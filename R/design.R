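#' Define a factorial leukocyte-assay experiment
#'
#' Describes the layout of one plate experiment: which fish (biological
#' replicates) were used, the two exposure durations, LPS stimulation arms,
#' the nominal concentration series of the test chemical, and how many
#' technical replicate wells each treatment received.
#'
#' @param fish_ids character or integer vector of fish identifiers; the first
#'   fish is the reference level of the per-fish base effects.
#' @param concentrations numeric vector of nominal concentrations, strictly
#'   increasing; the first element must be exactly 0 (the control).
#'   Units (uM or mM) are whatever the chemical's series uses and are carried
#'   through unchanged.
#' @param n_technical integer, technical replicate wells per treatment
#'   (default 3, the usual plate layout).
#' @param endpoint name of the measured immune parameter, e.g.
#'   `"phagocytosis"` or `"respiratory_burst"`.
#' @param time_points exposure durations; default `c("3h", "19h")`
#'   (short- and long-term exposure).
#' @param lps_levels LPS stimulation arms; default `c("no", "yes")`.
#'
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design(paste0("F", 1:6), c(0, 1, 5, 10))
#' @export
experiment_design <- function(fish_ids, concentrations, n_technical = 3L,
                              endpoint = "phagocytosis",
                              time_points = c("3h", "19h"),
                              lps_levels = c("no", "yes")) {
  fish_ids <- as.character(fish_ids)
  if (length(fish_ids) < 1L) stop_lk("at least one fish is required")
  if (anyDuplicated(fish_ids)) stop_lk("fish_ids must be unique")
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) < 1L || concentrations[1L] != 0) {
    stop_lk("the first concentration must be exactly 0 (control)")
  }
  if (any(concentrations < 0)) stop_lk("concentrations must be non-negative")
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop_lk("concentrations must be strictly increasing")
  }
  n_technical <- as.integer(n_technical)
  if (n_technical < 1L) stop_lk("n_technical must be >= 1")
  structure(
    list(
      fish_ids = fish_ids,
      time_points = time_points,
      lps_levels = lps_levels,
      concentrations = concentrations,
      n_technical = n_technical,
      endpoint = endpoint
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Leukocyte assay design:", x$endpoint, "\n")
  cat("  fish:", length(x$fish_ids), paste0("(", paste(x$fish_ids, collapse = ", "), ")"), "\n")
  cat("  time points:", paste(x$time_points, collapse = ", "),
      "| LPS:", paste(x$lps_levels, collapse = ", "), "\n")
  cat("  concentrations:", paste(x$concentrations, collapse = ", "), "\n")
  cat("  technical replicates per treatment:", x$n_technical, "\n")
  invisible(x)
}

# Non-control concentrations (the set C of the factorial model).
nonzero_conc <- function(design) design$concentrations[design$concentrations > 0]

#' True effect parameters for the factorial assay simulator
#'
#' Holds the generating coefficients of the factorial model: a per-fish base
#' level (reference fish fixed at 0), additive exposure-time, LPS and
#' concentration effects, the three interaction families
#' (time x LPS, time x concentration, LPS x concentration), and two noise
#' components — a biological residual per treatment cell and technical
#' well-to-well noise.
#'
#' Effect maps (`fish_effects`, `conc_effects`, `time_conc_interactions`,
#' `lps_conc_interactions`) are named numeric vectors; concentration-keyed
#' maps must be keyed by exactly the non-control concentrations of `design`.
#'
#' @param design an [experiment_design()].
#' @param intercept base response of the reference fish at 3 h, no LPS,
#'   control concentration.
#' @param fish_effects named offsets per fish; the reference (first) fish must
#'   be 0. Defaults to 0 for every fish.
#' @param time_effect,lps_effect scalar main effects of the 19 h time point
#'   and of LPS stimulation.
#' @param conc_effects named main effects per non-control concentration
#'   (default 0).
#' @param time_lps_interaction scalar time x LPS interaction.
#' @param time_conc_interactions,lps_conc_interactions named interaction
#'   effects per non-control concentration (default 0).
#' @param residual_sd biological residual standard deviation per treatment
#'   cell; must be > 0 for model fitting to be meaningful, 0 is accepted for
#'   noise-free checks.
#' @param technical_sd well-to-well technical noise standard deviation
#'   (>= 0); this is what technical-replicate averaging suppresses.
#'
#' @return An object of class `effect_parameters`.
#' @examples
#' d <- experiment_design(paste0("F", 1:6), c(0, 1, 5, 10))
#' effect_parameters(d, intercept = 1, lps_effect = 0.5, residual_sd = 0.2)
#' @export
effect_parameters <- function(design,
                              intercept = 0,
                              fish_effects = NULL,
                              time_effect = 0,
                              lps_effect = 0,
                              conc_effects = NULL,
                              time_lps_interaction = 0,
                              time_conc_interactions = NULL,
                              lps_conc_interactions = NULL,
                              residual_sd = 1,
                              technical_sd = 0) {
  stopifnot(inherits(design, "experiment_design"))
  cset <- as.character(nonzero_conc(design))
  zero_map <- function(keys) stats::setNames(numeric(length(keys)), keys)
  check_map <- function(m, keys, what) {
    if (is.null(m)) return(zero_map(keys))
    if (is.null(names(m)) || !setequal(names(m), keys)) {
      missing_keys <- setdiff(keys, names(m) %||% character())
      extra <- setdiff(names(m) %||% character(), keys)
      stop_lk(what, " must be keyed by the design's non-control concentrations; ",
              if (length(missing_keys)) paste0("missing: ", paste(missing_keys, collapse = ", "), " ") else "",
              if (length(extra)) paste0("unexpected: ", paste(extra, collapse = ", ")) else "")
    }
    as.numeric(m)[match(keys, names(m))] -> v
    stats::setNames(v, keys)
  }
  fish_effects <- if (is.null(fish_effects)) {
    zero_map(design$fish_ids)
  } else {
    if (!setequal(names(fish_effects) %||% character(), design$fish_ids)) {
      stop_lk("fish_effects must be keyed by the design's fish_ids")
    }
    stats::setNames(as.numeric(fish_effects)[match(design$fish_ids, names(fish_effects))],
                    design$fish_ids)
  }
  if (fish_effects[[1L]] != 0) {
    stop_lk("the reference (first) fish effect must be 0")
  }
  if (!(residual_sd >= 0)) stop_lk("residual_sd must be non-negative")
  if (!(technical_sd >= 0)) stop_lk("technical_sd must be non-negative")
  structure(
    list(
      intercept = intercept,
      fish_effects = fish_effects,
      time_effect = time_effect,
      lps_effect = lps_effect,
      conc_effects = check_map(conc_effects, cset, "conc_effects"),
      time_lps_interaction = time_lps_interaction,
      time_conc_interactions = check_map(time_conc_interactions, cset,
                                         "time_conc_interactions"),
      lps_conc_interactions = check_map(lps_conc_interactions, cset,
                                        "lps_conc_interactions"),
      residual_sd = residual_sd,
      technical_sd = technical_sd
    ),
    class = "effect_parameters"
  )
}

#' True parameters of the sigmoidal viability decline
#'
#' Generative stand-in for a cytotoxicity range-finding curve: viability
#' declines from `top` (control level, conventionally 1) along a decreasing
#' Hill function with midpoint `ec50` and steepness `hill`.
#'
#' @param ec50 concentration of half-maximal viability loss (> 0).
#' @param hill Hill slope (> 0).
#' @param top control viability (default 1.0).
#' @param noise_sd Gaussian measurement noise on the viability scale (>= 0).
#' @return An object of class `viability_truth`.
#' @export
viability_truth <- function(ec50, hill = 1, top = 1, noise_sd = 0) {
  if (!(ec50 > 0)) stop_lk("ec50 must be positive")
  if (!(hill > 0)) stop_lk("hill must be positive")
  if (!(noise_sd >= 0)) stop_lk("noise_sd must be non-negative")
  structure(list(ec50 = ec50, hill = hill, top = top, noise_sd = noise_sd),
            class = "viability_truth")
}

#' True parameters of the qPCR Ct-level generator
#'
#' Ct tables are generated at the cycle-threshold level: each sample draws a
#' reference-gene Ct around `ref_ct_mean`, and each target gene sits a true
#' dCt above it, shifted by `treatment_shift` cycles (the true ddCt) in
#' treated samples. Measurement noise applies per technical duplicate.
#'
#' @param ref_ct_mean mean reference-gene Ct (cycles), default 20.
#' @param ref_ct_sd between-sample SD of the reference Ct (>= 0).
#' @param delta_ct_control named numeric: true dCt (target minus reference)
#'   in control samples, one entry per target gene.
#' @param treatment_shift named numeric: true ddCt (cycles) added in treated
#'   samples; +1 cycle halves expression, -1 doubles it. Keys must match
#'   `delta_ct_control`.
#' @param ct_noise_sd per-duplicate measurement noise SD in cycles (>= 0).
#' @param reference_gene reference gene name, default `"EF1a"` (elongation
#'   factor 1 alpha).
#' @return An object of class `qpcr_truth`.
#' @export
qpcr_truth <- function(ref_ct_mean = 20, ref_ct_sd = 0.3,
                       delta_ct_control = c(IL1b = 6),
                       treatment_shift = c(IL1b = 0),
                       ct_noise_sd = 0.2,
                       reference_gene = "EF1a") {
  if (!(ref_ct_sd >= 0) || !(ct_noise_sd >= 0)) {
    stop_lk("ref_ct_sd and ct_noise_sd must be non-negative")
  }
  if (is.null(names(delta_ct_control)) ||
      !setequal(names(delta_ct_control), names(treatment_shift) %||% character())) {
    stop_lk("delta_ct_control and treatment_shift must be named by the same target genes")
  }
  treatment_shift <- treatment_shift[names(delta_ct_control)]
  structure(
    list(ref_ct_mean = ref_ct_mean, ref_ct_sd = ref_ct_sd,
         delta_ct_control = delta_ct_control,
         treatment_shift = treatment_shift,
         ct_noise_sd = ct_noise_sd,
         reference_gene = reference_gene),
    class = "qpcr_truth"
  )
}
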