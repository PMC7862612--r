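# Synthetic plate-data generators. These emulate the factorial structure the
# downstream statistics assume: per-fish base levels, additive time/LPS/
# concentration effects with the three interaction families, a biological
# residual per treatment cell and technical well-to-well noise.

# Linear predictor of the factorial model for vectors of factor levels.
# Reference levels: first fish, first time point, first LPS level, conc 0.
linear_predictor <- function(design, params, fish, time, lps, conc) {
  t2 <- if (length(design$time_points) > 1L) design$time_points[2L] else NA_character_
  l2 <- if (length(design$lps_levels) > 1L) design$lps_levels[2L] else NA_character_
  is_t2 <- !is.na(t2) & time == t2
  is_l2 <- !is.na(l2) & lps == l2
  ckey <- as.character(conc)
  cmap <- function(m) {
    v <- rep(0, length(ckey))
    hit <- conc > 0
    v[hit] <- m[ckey[hit]]
    v
  }
  params$intercept +
    params$fish_effects[fish] +
    params$time_effect * is_t2 +
    params$lps_effect * is_l2 +
    cmap(params$conc_effects) +
    params$time_lps_interaction * (is_t2 & is_l2) +
    cmap(params$time_conc_interactions) * is_t2 +
    cmap(params$lps_conc_interactions) * is_l2
}

# Full factorial grid of treatment cells for a design (no replicates).
design_cells <- function(design) {
  expand.grid(
    fish_id = design$fish_ids,
    time = design$time_points,
    lps = design$lps_levels,
    concentration = design$concentrations,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
}

#' Simulate a plate of factorial immune-assay measurements
#'
#' Generates one well row per fish x time x LPS x concentration x technical
#' replicate. Each well equals the factorial linear predictor plus a
#' biological residual drawn once per treatment cell
#' (`N(0, residual_sd^2)` — the model error of the averaged observation) plus
#' independent technical noise per well (`N(0, technical_sd^2)`). Averaging
#' the technical replicates therefore suppresses only the technical
#' component, which is what makes the averaging step consequential.
#'
#' @param design an [experiment_design()].
#' @param params an [effect_parameters()] built for the same design
#'   (mismatched concentration keys are rejected).
#' @param seed integer seed; identical inputs and seed give an identical
#'   table. The caller's RNG state is restored afterwards.
#'
#' @return A long-format `data.frame` with columns `fish_id`, `time`, `lps`,
#'   `concentration`, `endpoint`, `replicate`, `value`, `role`
#'   (all rows `"sample"`).
#' @examples
#' d <- experiment_design(paste0("F", 1:3), c(0, 1, 10), n_technical = 3)
#' p <- effect_parameters(d, intercept = 1, lps_effect = 0.8,
#'                        residual_sd = 0.2, technical_sd = 0.1)
#' head(simulate_assay(d, p, seed = 1))
#' @export
simulate_assay <- function(design, params, seed) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "effect_parameters"))
  cset <- as.character(nonzero_conc(design))
  pset <- names(params$conc_effects)
  if (!setequal(cset, pset)) {
    miss <- c(setdiff(cset, pset), setdiff(pset, cset))
    stop_lk("concentration keys of design and parameters disagree; mismatched: ",
            paste(miss, collapse = ", "))
  }
  cells <- design_cells(design)
  mu <- linear_predictor(design, params, cells$fish_id, cells$time,
                         cells$lps, cells$concentration)
  n_cells <- nrow(cells)
  n_rep <- design$n_technical
  with_seed(seed, {
    cell_resid <- stats::rnorm(n_cells, 0, params$residual_sd)
    idx <- rep(seq_len(n_cells), each = n_rep)
    tech <- stats::rnorm(n_cells * n_rep, 0, params$technical_sd)
    out <- cells[idx, , drop = FALSE]
    out$endpoint <- design$endpoint
    out$replicate <- rep(seq_len(n_rep), times = n_cells)
    out$value <- mu[idx] + cell_resid[idx] + tech
    out$role <- "sample"
    rownames(out) <- NULL
    out
  })
}

#' Simulate a cytotoxicity range-finding viability table
#'
#' Mean viability at concentration `c` follows the decreasing Hill curve
#' `top / (1 + (c / ec50)^hill)`; the control concentration has mean `top`.
#' One row is generated per fish x time x LPS x concentration x technical
#' replicate, with Gaussian noise of SD `truth$noise_sd` per well.
#'
#' @param design an [experiment_design()] (concentrations must be
#'   non-negative, which the constructor guarantees).
#' @param truth a [viability_truth()].
#' @param seed integer seed.
#' @return A `data.frame` with columns `fish_id`, `time`, `lps`,
#'   `concentration`, `replicate`, `viability`.
#' @export
simulate_viability <- function(design, truth, seed) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "viability_truth"))
  if (any(design$concentrations < 0)) stop_lk("negative concentrations are not allowed")
  cells <- design_cells(design)
  mu <- hill_viability(cells$concentration, truth)
  n_rep <- design$n_technical
  idx <- rep(seq_len(nrow(cells)), each = n_rep)
  with_seed(seed, {
    out <- cells[idx, , drop = FALSE]
    out$replicate <- rep(seq_len(n_rep), times = nrow(cells))
    out$viability <- mu[idx] + stats::rnorm(length(idx), 0, truth$noise_sd)
    rownames(out) <- NULL
    out
  })
}

# Decreasing Hill curve; exactly `top` at c = 0.
hill_viability <- function(conc, truth) {
  truth$top / (1 + (conc / truth$ec50)^truth$hill)
}

#' Simulate a qPCR Ct table
#'
#' Following the screening protocol, only the control and the highest
#' concentration of each scenario are quantified. Per sample (fish x time x
#' LPS x treatment) a reference-gene Ct is drawn as
#' `N(ref_ct_mean, ref_ct_sd^2)`; each target gene's true Ct is the sample's
#' reference Ct plus its control dCt, plus `treatment_shift` (the true ddCt)
#' when the sample is treated. Every gene is measured in two technical
#' duplicates with `N(0, ct_noise_sd^2)` measurement noise.
#'
#' @param design an [experiment_design()]; the highest concentration is the
#'   treated level.
#' @param truth a [qpcr_truth()].
#' @param seed integer seed.
#' @return A `data.frame` with columns `sample_id`, `fish_id`, `time`, `lps`,
#'   `concentration`, `gene`, `duplicate`, `ct`. All Ct values are checked to
#'   lie in (0, 45] (the run length in cycles).
#' @export
simulate_qpcr <- function(design, truth, seed) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "qpcr_truth"))
  top_conc <- max(design$concentrations)
  if (top_conc <= 0) stop_lk("design needs a non-zero treated concentration")
  samples <- expand.grid(
    fish_id = design$fish_ids,
    time = design$time_points,
    lps = design$lps_levels,
    concentration = c(0, top_conc),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  samples$sample_id <- paste(samples$fish_id, samples$time, samples$lps,
                             samples$concentration, sep = "_")
  genes <- c(truth$reference_gene, names(truth$delta_ct_control))
  n_dup <- 2L
  with_seed(seed, {
    ref_true <- stats::rnorm(nrow(samples), truth$ref_ct_mean, truth$ref_ct_sd)
    rows <- vector("list", length(genes))
    for (g in seq_along(genes)) {
      gene <- genes[g]
      true_ct <- if (gene == truth$reference_gene) {
        ref_true
      } else {
        ref_true + truth$delta_ct_control[[gene]] +
          truth$treatment_shift[[gene]] * (samples$concentration > 0)
      }
      idx <- rep(seq_len(nrow(samples)), each = n_dup)
      rows[[g]] <- data.frame(
        sample_id = samples$sample_id[idx],
        fish_id = samples$fish_id[idx],
        time = samples$time[idx],
        lps = samples$lps[idx],
        concentration = samples$concentration[idx],
        gene = gene,
        duplicate = rep(seq_len(n_dup), times = nrow(samples)),
        ct = true_ct[idx] + stats::rnorm(length(idx), 0, truth$ct_noise_sd),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (any(out$ct <= 0 | out$ct > 45)) {
      stop_lk("generated Ct values fall outside (0, 45]; ",
              "choose truth parameters within the 45-cycle run")
    }
    out
  })
}
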