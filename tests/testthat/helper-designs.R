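# Shared builders for factorial fixtures. All randomness is seeded at the
# call site.

make_design <- function(n_fish = 6, concs = c(0, 1, 5, 10), n_technical = 3,
                        endpoint = "phagocytosis") {
  experiment_design(paste0("F", seq_len(n_fish)), concs,
                    n_technical = n_technical, endpoint = endpoint)
}

# Effect parameters with distinct, recognisable true values so recovery
# failures are visible.
make_params <- function(design, residual_sd = 0.5, technical_sd = 0) {
  cpos <- design$concentrations[design$concentrations > 0]
  nm <- as.character(cpos)
  k <- length(cpos)
  fish <- stats::setNames(c(0, seq_len(length(design$fish_ids) - 1) * 0.1),
                          design$fish_ids)
  effect_parameters(
    design,
    intercept = 1.0,
    fish_effects = fish,
    time_effect = 0.30,
    lps_effect = 0.80,
    conc_effects = stats::setNames(-0.2 * seq_len(k), nm),
    time_lps_interaction = 0.25,
    time_conc_interactions = stats::setNames(0.05 * seq_len(k), nm),
    lps_conc_interactions = stats::setNames(-0.07 * seq_len(k), nm),
    residual_sd = residual_sd,
    technical_sd = technical_sd
  )
}

# Random effect parameters for property-style checks.
rand_params <- function(design, residual_sd = 0.5, technical_sd = 0) {
  cpos <- design$concentrations[design$concentrations > 0]
  nm <- as.character(cpos)
  k <- length(cpos)
  rn <- function(n) stats::rnorm(n, 0, 1)
  fish <- stats::setNames(c(0, rn(length(design$fish_ids) - 1)),
                          design$fish_ids)
  effect_parameters(
    design,
    intercept = rn(1), fish_effects = fish,
    time_effect = rn(1), lps_effect = rn(1),
    conc_effects = stats::setNames(rn(k), nm),
    time_lps_interaction = rn(1),
    time_conc_interactions = stats::setNames(rn(k), nm),
    lps_conc_interactions = stats::setNames(rn(k), nm),
    residual_sd = residual_sd, technical_sd = technical_sd
  )
}

# True coefficient vector in the design-matrix naming scheme.
true_beta <- function(design, params) {
  cpos <- design$concentrations[design$concentrations > 0]
  nm <- as.character(cpos)
  out <- c("(Intercept)" = params$intercept)
  for (f in design$fish_ids[-1]) {
    out[paste0("fish:", f)] <- params$fish_effects[[f]]
  }
  out[paste0("time:", design$time_points[2])] <- params$time_effect
  out[paste0("lps:", design$lps_levels[2])] <- params$lps_effect
  for (cc in nm) out[paste0("conc:", cc)] <- params$conc_effects[[cc]]
  out["time:lps"] <- params$time_lps_interaction
  for (cc in nm) {
    out[paste0("time:conc:", cc)] <- params$time_conc_interactions[[cc]]
  }
  for (cc in nm) {
    out[paste0("lps:conc:", cc)] <- params$lps_conc_interactions[[cc]]
  }
  out
}

# Reference linear-model fit via stats::lm with matching factor coding;
# returns estimates/covariance keyed by this package's coefficient names.
lm_oracle <- function(avg) {
  df <- avg
  df$fish_id <- factor(df$fish_id)
  df$time <- factor(df$time, levels = intersect(c("3h", "19h"),
                                                unique(df$time)))
  df$lps <- factor(df$lps, levels = intersect(c("no", "yes"),
                                              unique(df$lps)))
  df$conc <- factor(df$concentration)
  has_conc <- nlevels(df$conc) > 1
  fml <- if (has_conc) {
    value ~ fish_id + time + lps + conc + time:lps + time:conc + lps:conc
  } else {
    value ~ fish_id + time + lps + time:lps
  }
  m <- stats::lm(fml, data = df)
  nm <- names(stats::coef(m))
  # translate lm names to this package's scheme
  tr <- nm
  tr <- sub("^fish_id", "fish:", tr)
  tr <- sub("^time19h$", "time:19h", tr)
  tr <- sub("^lpsyes$", "lps:yes", tr)
  tr <- sub("^conc", "conc:", tr)
  tr <- sub("^time19h:lpsyes$", "time:lps", tr)
  tr <- sub("^time19h:conc", "time:conc:", tr)
  tr <- sub("^lpsyes:conc", "lps:conc:", tr)
  cf <- stats::setNames(stats::coef(m), tr)
  V <- stats::vcov(m)
  dimnames(V) <- list(tr, tr)
  list(coef = cf, vcov = V, sigma2 = summary(m)$sigma^2,
       df = stats::df.residual(m))
}

# Contrast p value computed from an lm_oracle fit for a named weight vector.
oracle_contrast_p <- function(orc, w) {
  est <- sum(orc$coef[names(w)] * w)
  se <- sqrt(drop(t(w) %*% orc$vcov[names(w), names(w), drop = FALSE] %*% w))
  2 * stats::pt(-abs(est / se), df = orc$df)
}

# Weight vector (named) for a standard comparison, mirroring its definition
# as a difference of cell means.
comparison_weights <- function(comparison, time, conc = NULL) {
  late <- identical(time, "19h")
  if (comparison == "lps_vs_control") {
    w <- c("lps:yes" = 1)
    if (late) w <- c(w, "time:lps" = 1)
    return(w)
  }
  w <- stats::setNames(1, paste0("conc:", conc))
  if (late) w <- c(w, stats::setNames(1, paste0("time:conc:", conc)))
  if (comparison == "conc_vs_control_LPS") {
    w <- c(w, stats::setNames(1, paste0("lps:conc:", conc)))
  }
  w
}
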