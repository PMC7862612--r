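# Factorial linear model for immune endpoints:
#   Y = b0 + fish base levels + time + LPS + concentration
#       + time:LPS + time:concentration + LPS:concentration + eps,
#   eps ~ N(0, sigma^2),
# in reference-level indicator coding (first fish, first time point, LPS "no",
# concentration 0 absorbed into the intercept). Fitting is ordinary least
# squares via a pivoted QR decomposition; inference is by Wald tests on
# linear combinations of the coefficients.

#' Build the indicator design matrix of the factorial immune model
#'
#' Expands averaged treatment-cell observations into a 0/1 design matrix with
#' reference-level (treatment) coding: intercept; one column per
#' non-reference fish; time (late time point); LPS (stimulated);
#' one column per non-control concentration; and the three interaction
#' families time x LPS, time x concentration, LPS x concentration.
#' Concentrations are unordered factor levels — no dose-trend term.
#' Factors with a single observed level contribute no columns (a message is
#' emitted); duplicate treatment rows are rejected.
#'
#' @param data averaged records with columns `fish_id`, `time`, `lps`,
#'   `concentration`, `value` (one row per treatment cell, e.g. from
#'   [average_technical_replicates()]).
#' @return An object of class `immune_design`: list with the model matrix
#'   `X`, response `y`, `row_meta`, and the factor level sets used.
#' @examples
#' d <- experiment_design(paste0("F", 1:7), c(0, 1, 5, 10))
#' p <- effect_parameters(d, residual_sd = 0.5)
#' avg <- average_technical_replicates(simulate_assay(d, p, seed = 1))
#' dm <- build_design_matrix(avg)
#' ncol(dm$X)  # 19 for 7 fish and 3 non-control concentrations
#' @export
build_design_matrix <- function(data) {
  need <- c("fish_id", "time", "lps", "concentration", "value")
  stopifnot(is.data.frame(data), all(need %in% names(data)))
  key <- paste(data$fish_id, data$time, data$lps, data$concentration)
  if (anyDuplicated(key)) {
    stop_lk("duplicate treatment rows; average technical replicates first")
  }
  lv <- list(
    fish = sort(unique(as.character(data$fish_id))),
    time = sort_time_levels(unique(as.character(data$time))),
    lps = sort_lps_levels(unique(as.character(data$lps))),
    conc = sort(unique(as.numeric(data$concentration)))
  )
  for (f in c("fish", "time", "lps")) {
    if (length(lv[[f]]) == 1L) {
      message("factor '", f, "' has a single level; no column generated")
    }
  }
  if (!any(lv$conc > 0)) {
    message("no non-control concentration; no concentration columns generated")
  }
  X <- make_model_matrix(data, lv)
  structure(
    list(X = X, y = as.numeric(data$value),
         row_meta = data[c("fish_id", "time", "lps", "concentration")],
         levels = lv),
    class = "immune_design"
  )
}

# "3h" before "19h"; otherwise keep sorted order. Reference = first.
sort_time_levels <- function(x) {
  if (setequal(x, c("3h", "19h"))) c("3h", "19h") else sort(x)
}
sort_lps_levels <- function(x) {
  if (setequal(x, c("no", "yes"))) c("no", "yes") else sort(x)
}

# Indicator expansion shared by fitting and prediction.
make_model_matrix <- function(meta, lv) {
  n <- nrow(meta)
  fish <- as.character(meta$fish_id)
  time <- as.character(meta$time)
  lps <- as.character(meta$lps)
  conc <- as.numeric(meta$concentration)
  cols <- list("(Intercept)" = rep(1, n))
  if (length(lv$fish) > 1L) {
    for (f in lv$fish[-1L]) cols[[paste0("fish:", f)]] <- as.numeric(fish == f)
  }
  has_time <- length(lv$time) > 1L
  has_lps <- length(lv$lps) > 1L
  t2 <- if (has_time) lv$time[2L] else NULL
  l2 <- if (has_lps) lv$lps[2L] else NULL
  if (has_time) cols[[paste0("time:", t2)]] <- as.numeric(time == t2)
  if (has_lps) cols[[paste0("lps:", l2)]] <- as.numeric(lps == l2)
  cpos <- lv$conc[lv$conc > 0]
  for (cc in cpos) cols[[paste0("conc:", cc)]] <- as.numeric(conc == cc)
  if (has_time && has_lps) {
    cols[["time:lps"]] <- as.numeric(time == t2 & lps == l2)
  }
  if (has_time) {
    for (cc in cpos) {
      cols[[paste0("time:conc:", cc)]] <- as.numeric(time == t2 & conc == cc)
    }
  }
  if (has_lps) {
    for (cc in cpos) {
      cols[[paste0("lps:conc:", cc)]] <- as.numeric(lps == l2 & conc == cc)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Fit the factorial immune model by least squares
#'
#' Ordinary least squares through a pivoted QR decomposition. Rank-deficient
#' designs are handled by aliasing: redundant columns get `NA` coefficients
#' and are reported in `$aliased`; fitted values are the unique least-squares
#' projection either way. The coefficient covariance is
#' `sigma2 * (X'X)^-` on the estimable columns.
#'
#' @param x either an averaged-records `data.frame` (passed to
#'   [build_design_matrix()]) or an `immune_design`.
#' @param ... unused.
#' @return An object of class `immune_lm` with components `coefficients`
#'   (named, `NA` for aliased), `sigma2` (residual variance, RSS / df),
#'   `cov` (coefficient covariance), `df` (residual degrees of freedom),
#'   `rank`, `aliased`, `fitted`, `residuals`, and the `immune_design`.
#' @examples
#' d <- experiment_design(paste0("F", 1:6), c(0, 1, 10))
#' p <- effect_parameters(d, lps_effect = 1, residual_sd = 0.3)
#' fit <- fit_immune_lm(average_technical_replicates(simulate_assay(d, p, 7)))
#' summary(fit)
#' @export
fit_immune_lm <- function(x, ...) UseMethod("fit_immune_lm")

#' @export
fit_immune_lm.data.frame <- function(x, ...) {
  fit_immune_lm(build_design_matrix(x), ...)
}

#' @export
fit_immune_lm.immune_design <- function(x, ...) {
  X <- x$X
  y <- x$y
  n <- nrow(X)
  p <- ncol(X)
  qx <- qr(X)
  r <- qx$rank
  df <- n - r
  if (df <= 0L) stop_lk("saturated model: no residual degrees of freedom")
  beta <- qr.coef(qx, y)
  fitted <- drop(qr.fitted(qx, y))
  resid <- y - fitted
  sigma2 <- sum(resid^2) / df
  used <- qx$pivot[seq_len(r)]
  aliased <- if (r < p) colnames(X)[qx$pivot[(r + 1L):p]] else character()
  R <- qr.R(qx)[seq_len(r), seq_len(r), drop = FALSE]
  Rinv <- backsolve(R, diag(r))
  vcov_used <- sigma2 * (Rinv %*% t(Rinv))
  V <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  V[used, used] <- vcov_used
  structure(
    list(coefficients = beta, sigma2 = sigma2, cov = V, df = df,
         rank = r, aliased = aliased, fitted = fitted, residuals = resid,
         design = x),
    class = "immune_lm"
  )
}

#' @export
coef.immune_lm <- function(object, ...) object$coefficients

#' @export
vcov.immune_lm <- function(object, ...) object$cov

#' @export
fitted.immune_lm <- function(object, ...) object$fitted

#' @export
residuals.immune_lm <- function(object, ...) object$residuals

#' @export
df.residual.immune_lm <- function(object, ...) object$df

#' @export
model.matrix.immune_lm <- function(object, ...) object$design$X

#' @export
print.immune_lm <- function(x, ...) {
  cat("Factorial immune linear model\n")
  cat(sprintf("  %d observations, rank %d, residual df %d, sigma^2 = %.4g\n",
              length(x$fitted), x$rank, x$df, x$sigma2))
  if (length(x$aliased)) {
    cat("  aliased:", paste(x$aliased, collapse = ", "), "\n")
  }
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @describeIn fit_immune_lm coefficient table with standard errors, t
#'   statistics and two-sided p values.
#' @param object an `immune_lm` fit.
#' @export
summary.immune_lm <- function(object, ...) {
  est <- object$coefficients
  se <- sqrt(diag(object$cov))
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = object$df)
  tab <- cbind(Estimate = est, `Std. Error` = se,
               `t value` = tval, `Pr(>|t|)` = pval)
  structure(list(coefficients = tab, sigma2 = object$sigma2, df = object$df,
                 aliased = object$aliased),
            class = "summary.immune_lm")
}

#' @export
print.summary.immune_lm <- function(x, ...) {
  cat("Coefficients:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE,
                      na.print = "NA")
  cat(sprintf("\nResidual variance %.4g on %d degrees of freedom\n",
              x$sigma2, x$df))
  invisible(x)
}

#' @export
predict.immune_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  need <- c("fish_id", "time", "lps", "concentration")
  stopifnot(is.data.frame(newdata), all(need %in% names(newdata)))
  lv <- object$design$levels
  bad_fish <- setdiff(unique(as.character(newdata$fish_id)), lv$fish)
  if (length(bad_fish)) {
    stop_lk("unknown fish in newdata: ", paste(bad_fish, collapse = ", "))
  }
  Xn <- make_model_matrix(newdata, lv)
  beta <- object$coefficients
  beta[is.na(beta)] <- 0  # aliased columns carry no unique contribution
  drop(Xn %*% beta)
}

#' @export
simulate.immune_lm <- function(object, nsim = 1, seed = NULL, ...) {
  sim_one <- function() {
    object$fitted + stats::rnorm(length(object$fitted), 0, sqrt(object$sigma2))
  }
  run <- function() {
    out <- as.data.frame(replicate(nsim, sim_one()))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Wald test of a linear combination of model coefficients
#'
#' Computes `estimate = c'beta`, `SE = sqrt(c' V c)` from the coefficient
#' covariance, the t statistic and the two-sided Student-t p value on the
#' residual degrees of freedom. A contrast with zero variance, all-zero
#' weights, or weight on an aliased coefficient is rejected as
#' non-estimable.
#'
#' @param fit an [fit_immune_lm()] result.
#' @param contrast either a full-length numeric vector aligned with
#'   `coef(fit)`, or a named numeric vector giving the non-zero weights by
#'   coefficient name.
#' @param label optional label describing the comparison.
#' @return One-row `data.frame`: `label`, `estimate`, `se`, `t`, `p`.
#' @examples
#' d <- experiment_design(paste0("F", 1:6), c(0, 1, 10))
#' p <- effect_parameters(d, lps_effect = 1, residual_sd = 0.3)
#' fit <- fit_immune_lm(average_technical_replicates(simulate_assay(d, p, 7)))
#' wald_contrast(fit, c("lps:yes" = 1), label = "LPS effect at 3 h")
#' @export
wald_contrast <- function(fit, contrast, label = NULL) {
  stopifnot(inherits(fit, "immune_lm"))
  cn <- names(fit$coefficients)
  if (!is.null(names(contrast))) {
    unknown <- setdiff(names(contrast), cn)
    if (length(unknown)) {
      stop_lk("unknown coefficient names in contrast: ",
              paste(unknown, collapse = ", "))
    }
    cv <- stats::setNames(numeric(length(cn)), cn)
    cv[names(contrast)] <- as.numeric(contrast)
  } else {
    if (length(contrast) != length(cn)) {
      stop_lk("contrast length ", length(contrast),
              " does not match ", length(cn), " coefficients")
    }
    cv <- stats::setNames(as.numeric(contrast), cn)
  }
  if (all(cv == 0)) stop_lk("non-estimable contrast: all weights zero")
  if (any(cv != 0 & is.na(fit$coefficients))) {
    stop_lk("non-estimable contrast: weight on aliased coefficient")
  }
  nz <- cv != 0
  est <- sum(cv[nz] * fit$coefficients[nz])
  var_c <- drop(t(cv[nz]) %*% fit$cov[nz, nz, drop = FALSE] %*% cv[nz])
  if (!is.finite(var_c) || var_c <= 0) {
    stop_lk("non-estimable contrast: zero variance")
  }
  se <- sqrt(var_c)
  tval <- est / se
  data.frame(label = label %||% NA_character_, estimate = est, se = se,
             t = tval, p = 2 * stats::pt(-abs(tval), df = fit$df),
             stringsAsFactors = FALSE)
}

#' Standard screening comparisons
#'
#' Emits, per time point, the three families of Wald contrasts used to read a
#' screening experiment: (i) LPS-stimulated control versus non-stimulated
#' control; (ii) each concentration versus control without LPS; (iii) each
#' concentration versus control with LPS. At the late time point each
#' contrast includes the corresponding interaction coefficients, so every
#' row is the model's estimate of a difference of cell means.
#'
#' @param fit an [fit_immune_lm()] result on a factorial design.
#' @param concentrations optional subset of concentrations to test; absent
#'   concentrations are skipped with a message.
#' @param alpha unused here; significance interpretation is left to
#'   [determine_loec()].
#' @return A `data.frame` with columns `comparison`
#'   (`"lps_vs_control"`, `"conc_vs_control_noLPS"`,
#'   `"conc_vs_control_LPS"`), `time`, `concentration` (`NA` for the LPS
#'   row), `estimate`, `se`, `t`, `p`.
#' @export
standard_comparisons <- function(fit, concentrations = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "immune_lm"))
  lv <- fit$design$levels
  has_time <- length(lv$time) > 1L
  has_lps <- length(lv$lps) > 1L
  t2 <- if (has_time) lv$time[2L] else NULL
  cpos <- lv$conc[lv$conc > 0]
  if (!is.null(concentrations)) {
    skip <- setdiff(concentrations, cpos)
    if (length(skip)) {
      message("requested concentrations not in the design, skipped: ",
              paste(skip, collapse = ", "))
    }
    cpos <- intersect(cpos, concentrations)
  }
  rows <- list()
  add <- function(comparison, time, conc, w) {
    ct <- wald_contrast(fit, w)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, time = time,
      concentration = conc, estimate = ct$estimate, se = ct$se,
      t = ct$t, p = ct$p, stringsAsFactors = FALSE
    )
  }
  for (tp in lv$time) {
    late <- has_time && tp == t2
    if (has_lps) {
      w <- c("lps:yes" = 1)
      if (late) w <- c(w, "time:lps" = 1)
      add("lps_vs_control", tp, NA_real_, w)
    }
    for (cc in cpos) {
      w <- stats::setNames(1, paste0("conc:", cc))
      if (late) w <- c(w, stats::setNames(1, paste0("time:conc:", cc)))
      add("conc_vs_control_noLPS", tp, cc, w)
      if (has_lps) {
        wl <- c(w, stats::setNames(1, paste0("lps:conc:", cc)))
        add("conc_vs_control_LPS", tp, cc, wl)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lowest observed effect concentration
#'
#' The LOEC is the smallest tested concentration whose contrast against the
#' control reaches `p <= alpha`; when none does the endpoint is "not
#' determinable" for that scenario. The direction of the effect is the sign
#' of the estimate at the LOEC. Non-monotone p-value sequences are allowed:
#' the definition takes the minimum significant concentration.
#'
#' @param contrasts `data.frame` with columns `concentration`, `p`,
#'   `estimate` for a single scenario; sorted internally by concentration.
#' @param alpha significance threshold, default 0.05.
#' @return An object of class `loec_result`: list with `loec` (numeric or
#'   `NA`), `determinable`, `direction` (`"increase"`/`"decrease"`/`NA`),
#'   `alpha`.
#' @examples
#' x <- data.frame(concentration = c(1, 5, 10), p = c(0.2, 0.03, 0.01),
#'                 estimate = c(0.1, -0.4, -0.9))
#' determine_loec(x)$loec  # 5
#' @export
determine_loec <- function(contrasts, alpha = 0.05) {
  stopifnot(is.data.frame(contrasts),
            all(c("concentration", "p", "estimate") %in% names(contrasts)))
  x <- contrasts[order(contrasts$concentration), , drop = FALSE]
  hit <- which(x$p <= alpha)
  if (length(hit) == 0L) {
    res <- list(loec = NA_real_, determinable = FALSE,
                direction = NA_character_, alpha = alpha)
  } else {
    i <- hit[1L]
    res <- list(loec = x$concentration[i], determinable = TRUE,
                direction = if (x$estimate[i] >= 0) "increase" else "decrease",
                alpha = alpha)
  }
  structure(res, class = "loec_result")
}

#' @export
print.loec_result <- function(x, ...) {
  if (x$determinable) {
    cat(sprintf("LOEC = %g (%s) at alpha = %g\n", x$loec, x$direction, x$alpha))
  } else {
    cat(sprintf("LOEC not determinable at alpha = %g\n", x$alpha))
  }
  invisible(x)
}

#' Per-scenario LOEC table from standard comparisons
#'
#' Applies [determine_loec()] to each time x LPS scenario of a
#' [standard_comparisons()] table.
#'
#' @param comparisons result of [standard_comparisons()].
#' @param alpha significance threshold.
#' @return `data.frame` with columns `time`, `lps`, `loec`, `determinable`,
#'   `direction`.
#' @export
scenario_loecs <- function(comparisons, alpha = 0.05) {
  cc <- comparisons[comparisons$comparison != "lps_vs_control", , drop = FALSE]
  rows <- list()
  for (tp in unique(cc$time)) {
    for (cmp in unique(cc$comparison)) {
      sub <- cc[cc$time == tp & cc$comparison == cmp, , drop = FALSE]
      if (nrow(sub) == 0L) next
      r <- determine_loec(sub, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        time = tp,
        lps = if (cmp == "conc_vs_control_LPS") "yes" else "no",
        loec = r$loec, determinable = r$determinable,
        direction = r$direction %||% NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
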