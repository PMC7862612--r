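# Equilibrium-partitioning prediction of baseline (narcosis) cytotoxicity.
# Baseline toxicants share a critical membrane concentration of about
# 69 mmol per litre of membrane lipid at which 10% cytotoxicity occurs; a
# mass balance over the assay compartments (water, medium and cell protein,
# medium and cell lipid, headspace) converts it to a nominal IC10 in the
# dosing medium. Distribution ratios are consumed as given at pH 7.4.

#' Partitioning profile of a test chemical
#'
#' @param name chemical name.
#' @param d_lipw lipid-water distribution ratio at pH 7.4 (dimensionless,
#'   volume basis; > 0).
#' @param d_protw protein-water distribution ratio at pH 7.4 (>= 0).
#' @param k_aw air-water partition ratio (>= 0).
#' @param concentrations optional tested concentration grid (first element
#'   0) carried along for reporting.
#' @return An object of class `chemical_profile`.
#' @examples
#' chemical_profile("bisphenol A", d_lipw = 10^3.6, d_protw = 10^2.9,
#'                  k_aw = 1e-9, concentrations = c(0, 0.5, 1, 2.5, 5))
#' @export
chemical_profile <- function(name, d_lipw, d_protw, k_aw = 0,
                             concentrations = NULL) {
  if (!(d_lipw > 0)) stop_lk("d_lipw must be positive")
  if (!(d_protw >= 0)) stop_lk("d_protw must be non-negative")
  if (!(k_aw >= 0)) stop_lk("k_aw must be non-negative")
  structure(list(name = name, d_lipw = d_lipw, d_protw = d_protw,
                 k_aw = k_aw, concentrations = concentrations),
            class = "chemical_profile")
}

#' Compartment system of an in vitro well
#'
#' Volumes of the phases among which a chemical equilibrates in a well.
#' Any consistent volume unit works; nominal concentrations refer to the
#' liquid dose volume (water plus medium and cell protein and lipid), with
#' the headspace counted as a sink only.
#'
#' @param v_water aqueous volume (> 0).
#' @param v_protein_medium,v_lipid_medium serum-derived protein and lipid
#'   volumes in the medium (>= 0).
#' @param v_protein_cell,v_lipid_cell cellular protein and membrane-lipid
#'   volumes (>= 0).
#' @param v_air headspace volume (>= 0).
#' @param c_mem_crit critical membrane concentration in mmol per litre of
#'   membrane lipid; default 69, the narcosis threshold for 10%
#'   cytotoxicity.
#' @return An object of class `compartment_system`.
#' @export
compartment_system <- function(v_water, v_protein_medium = 0,
                               v_lipid_medium = 0, v_protein_cell = 0,
                               v_lipid_cell = 0, v_air = 0,
                               c_mem_crit = 69) {
  vols <- c(v_water, v_protein_medium, v_lipid_medium, v_protein_cell,
            v_lipid_cell, v_air)
  if (any(vols < 0)) stop_lk("volumes must be non-negative")
  if (!(v_water > 0)) stop_lk("v_water must be positive")
  if (!(c_mem_crit > 0)) stop_lk("c_mem_crit must be positive")
  structure(list(v_water = v_water, v_protein_medium = v_protein_medium,
                 v_lipid_medium = v_lipid_medium,
                 v_protein_cell = v_protein_cell,
                 v_lipid_cell = v_lipid_cell, v_air = v_air,
                 c_mem_crit = c_mem_crit),
            class = "compartment_system")
}

#' Illustrative default well configuration
#'
#' A documented stub for a 96-well assay with 200 uL of medium containing
#' 0.5% serum and 2e5 cells under 150 uL headspace. The protein and lipid
#' volumes are order-of-magnitude values for that setup, intended for
#' demonstrations and property checks, not for reproducing any published
#' prediction (which requires system-specific measured contents).
#'
#' @return A [compartment_system()]. Volumes in litres.
#' @export
default_compartment_system <- function() {
  compartment_system(
    v_water = 2.0e-4,           # 200 uL medium, almost all aqueous
    v_protein_medium = 4.4e-8,  # 0.5% FBS protein
    v_lipid_medium = 2.4e-9,    # 0.5% FBS lipid
    v_protein_cell = 4.0e-8,    # 2e5 cells, ~20% protein by volume
    v_lipid_cell = 1.0e-8,      # 2e5 cells, ~5% lipid by volume
    v_air = 1.5e-4              # headspace under the plate lid
  )
}

# Partition capacities (volume x distribution ratio) per compartment.
capacities <- function(chem, sys) {
  c(water = sys$v_water,
    protein = chem$d_protw * (sys$v_protein_medium + sys$v_protein_cell),
    lipid = chem$d_lipw * (sys$v_lipid_medium + sys$v_lipid_cell),
    air = chem$k_aw * sys$v_air)
}

# Liquid dose volume on which nominal concentrations are defined.
dose_volume <- function(sys) {
  sys$v_water + sys$v_protein_medium + sys$v_lipid_medium +
    sys$v_protein_cell + sys$v_lipid_cell
}

#' Equilibrium mass fractions over the well compartments
#'
#' With free aqueous concentration `C_w`, the compartment masses are
#' `C_w * V_water`, `D_protw * C_w * V_protein`, `D_lipw * C_w * V_lipid`
#' and `K_aw * C_w * V_air`; the fractions are these normalised to their
#' total and always sum to 1.
#'
#' @param chem a [chemical_profile()].
#' @param sys a [compartment_system()].
#' @return Named numeric vector with fractions `water`, `protein`, `lipid`,
#'   `air`.
#' @export
equilibrium_fractions <- function(chem, sys) {
  stopifnot(inherits(chem, "chemical_profile"),
            inherits(sys, "compartment_system"))
  caps <- capacities(chem, sys)
  total <- sum(caps)
  if (total <= 0) stop_lk("all partition capacities are zero")
  caps / total
}

#' Nominal baseline-toxicity IC10 from the critical membrane concentration
#'
#' Converts the critical membrane concentration `c_mem_crit`
#' (mmol / L membrane lipid) to the nominal medium concentration at which
#' the membrane-lipid phase reaches it:
#' `IC10 = c_mem_crit / D_lipw * (sum of capacities) / V_dose`,
#' where the capacities include the headspace (a loss term) and `V_dose` is
#' the liquid dose volume. Reported in uM.
#'
#' @inheritParams equilibrium_fractions
#' @param volatile_threshold air-loss fraction above which the chemical is
#'   flagged volatile (default 0.10) and should be excluded from baseline
#'   comparison.
#' @return An object of class `baseline_prediction`: list with `chemical`,
#'   `ic10_uM`, `fractions`, `air_loss`, `volatile`.
#' @examples
#' chem <- chemical_profile("butanol", d_lipw = 10^0.9, d_protw = 10^0.4,
#'                          k_aw = 3.6e-4)
#' predict_ic10(chem, default_compartment_system())
#' @export
predict_ic10 <- function(chem, sys, volatile_threshold = 0.10) {
  stopifnot(inherits(chem, "chemical_profile"),
            inherits(sys, "compartment_system"))
  if (!(chem$d_lipw > 0)) stop_lk("d_lipw must be positive")
  if (sys$v_lipid_cell + sys$v_lipid_medium <= 0) {
    stop_lk("a lipid compartment is required to predict IC10")
  }
  caps <- capacities(chem, sys)
  v_dose <- dose_volume(sys)
  # c_mem_crit is mmol/L lipid = mM; factor 1000 converts to uM nominal
  ic10_uM <- sys$c_mem_crit / chem$d_lipw * sum(caps) / v_dose * 1000
  al <- air_loss_fraction(chem, sys, volatile_threshold)
  structure(
    list(chemical = chem$name, ic10_uM = ic10_uM,
         fractions = caps / sum(caps),
         air_loss = al$fraction, volatile = al$volatile),
    class = "baseline_prediction"
  )
}

#' @export
print.baseline_prediction <- function(x, ...) {
  cat(sprintf("Baseline-toxicity IC10 for %s: %.4g uM\n", x$chemical, x$ic10_uM))
  cat("  equilibrium fractions:",
      paste(sprintf("%s %.3g", names(x$fractions), x$fractions), collapse = ", "),
      "\n")
  if (x$volatile) {
    cat(sprintf("  WARNING: volatile (%.0f%% lost to headspace); exclude from baseline comparison\n",
                100 * x$air_loss))
  }
  invisible(x)
}

#' Evaporative loss to the headspace
#'
#' Fraction of the chemical sitting in the headspace at equilibrium,
#' `K_aw * V_air / (sum of capacities)`. A fraction above the threshold
#' raises the volatile flag, which excludes the chemical from baseline
#' comparison (an equilibrium model without evaporation control is not
#' meaningful when a large share of the dose escapes the liquid phase).
#'
#' @inheritParams predict_ic10
#' @param threshold flag threshold on the air fraction, default 0.10.
#' @return List with `fraction` and `volatile`.
#' @export
air_loss_fraction <- function(chem, sys, threshold = 0.10) {
  stopifnot(inherits(chem, "chemical_profile"),
            inherits(sys, "compartment_system"))
  caps <- capacities(chem, sys)
  frac <- if (sum(caps) > 0) unname(caps["air"]) / sum(caps) else 0
  list(fraction = frac, volatile = frac > threshold)
}
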