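# Cytotoxicity range derivation: calcein/DAPI viability fractions, EC20 (the
# concentration where viability drops below 80% of control) by log-linear
# interpolation between tested levels, and the admissible non-cytotoxic
# concentration range that gates the immune assays.

#' Normalised viability fractions from calcein / DAPI signals
#'
#' Blank-corrects calcein (live-cell esterase activity) and DAPI (total cell
#' number) signals per scenario, forms the calcein/DAPI ratio per treatment,
#' and normalises it to the control ratio so the control is exactly 1.
#' Negative blank-corrected signals are clipped at 0 with a warning;
#' treatments with non-positive DAPI are excluded with a message.
#'
#' @param records `data.frame` with columns `scenario` (e.g. "3h_LPS"),
#'   `concentration`, `calcein`, `dapi`, `role` (`"sample"` or `"blank"`).
#'   Blank rows carry the dye-free background per scenario.
#' @return `data.frame` with one row per scenario x concentration:
#'   `scenario`, `concentration`, `viability`.
#' @export
viability_fraction <- function(records) {
  need <- c("scenario", "concentration", "calcein", "dapi", "role")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  out <- list()
  for (sc in unique(records$scenario)) {
    x <- records[records$scenario == sc, , drop = FALSE]
    bl <- x[x$role == "blank", , drop = FALSE]
    sm <- x[x$role != "blank", , drop = FALSE]
    cal_bg <- if (nrow(bl)) mean(bl$calcein) else 0
    dapi_bg <- if (nrow(bl)) mean(bl$dapi) else 0
    cal <- sm$calcein - cal_bg
    dap <- sm$dapi - dapi_bg
    if (any(cal < 0)) {
      warning("negative blank-corrected calcein signals clipped at 0 (", sc, ")")
      cal[cal < 0] <- 0
    }
    agg_cal <- tapply(cal, sm$concentration, mean)
    agg_dap <- tapply(dap, sm$concentration, mean)
    conc <- as.numeric(names(agg_cal))
    bad <- agg_dap <= 0
    if (any(bad)) {
      message("treatments excluded for non-positive DAPI signal (", sc, "): ",
              paste(conc[bad], collapse = ", "))
    }
    ratio <- as.numeric(agg_cal[!bad]) / as.numeric(agg_dap[!bad])
    conc <- conc[!bad]
    if (!any(conc == 0)) stop_lk("no control (concentration 0) in scenario ", sc)
    viab <- ratio / ratio[conc == 0]
    out[[sc]] <- data.frame(scenario = sc, concentration = conc,
                            viability = viab, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scenario, res$concentration), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' EC20 from a tested viability series
#'
#' The EC20 is the concentration at which viability crosses below
#' `threshold` (default 0.8, i.e. 20% cytotoxicity), found by linear
#' interpolation in log10 concentration between the bracketing tested
#' levels. A level measured exactly at the threshold is itself the EC20.
#' When no tested level falls below the threshold the result is censored
#' (`"> max tested"`). The control (concentration 0) anchors the
#' normalisation but is excluded from log interpolation; a crossing below
#' the lowest non-zero level reports that level as an upper bound. With
#' multiple crossings the first from low concentration is used and the
#' result flagged non-monotone.
#'
#' @param concentration,viability numeric vectors of tested levels (must
#'   include the control and at least two non-zero concentrations) and their
#'   viability fractions.
#' @param threshold viability threshold, default 0.8.
#' @return An object of class `ec20_result`: list with `ec20`, `censored`
#'   (logical, TRUE when `> max tested`), `bound` (`"gt_max"`, `"lt_min"` or
#'   `"none"`), `max_tested`, `nonmonotone`, `threshold` and the input
#'   series.
#' @examples
#' v <- 1 / (1 + c(0, 1, 3, 10, 30) / 10)  # Hill curve, ec50 = 10
#' estimate_ec20(c(0, 1, 3, 10, 30), v)
#' @export
estimate_ec20 <- function(concentration, viability, threshold = 0.8) {
  stopifnot(length(concentration) == length(viability),
            any(concentration == 0))
  ord <- order(concentration)
  conc <- concentration[ord]
  viab <- viability[ord]
  pos <- conc > 0
  if (sum(pos) < 2L) stop_lk("need viability at two or more non-zero concentrations")
  cpos <- conc[pos]
  vpos <- viab[pos]
  max_tested <- max(cpos)
  below <- vpos < threshold
  at <- vpos == threshold
  nonmono <- FALSE
  mk <- function(ec20, censored, bound) {
    structure(list(ec20 = ec20, censored = censored, bound = bound,
                   max_tested = max_tested, nonmonotone = nonmono,
                   threshold = threshold,
                   series = data.frame(concentration = conc, viability = viab)),
              class = "ec20_result")
  }
  if (!any(below | at)) {
    return(mk(NA_real_, TRUE, "gt_max"))
  }
  # count distinct down-crossings to flag non-monotone series
  state <- vpos >= threshold
  crossings <- sum(state[-length(state)] & !state[-1L])
  if (crossings > 1L) {
    nonmono <- TRUE
    warning("multiple threshold crossings; first from low concentration used")
  }
  first_at <- which(at)
  first_below <- which(below)
  i <- min(c(first_at, first_below))
  if (i %in% first_at) return(mk(cpos[i], FALSE, "none"))
  if (i == 1L) {
    # already below threshold at the lowest non-zero level
    return(mk(cpos[1L], FALSE, "lt_min"))
  }
  lo <- i - 1L
  frac <- (vpos[lo] - threshold) / (vpos[lo] - vpos[i])
  log_ec20 <- log10(cpos[lo]) + frac * (log10(cpos[i]) - log10(cpos[lo]))
  mk(10^log_ec20, FALSE, "none")
}

#' @export
print.ec20_result <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("EC20 > %g (censored; all viabilities >= %g)\n",
                x$max_tested, x$threshold))
  } else if (x$bound == "lt_min") {
    cat(sprintf("EC20 <= %g (below lowest tested non-zero level)\n", x$ec20))
  } else {
    cat(sprintf("EC20 = %g\n", x$ec20))
  }
  invisible(x)
}

#' Non-cytotoxic concentration range
#'
#' The admissible concentrations for the immune assays: tested levels
#' strictly below the EC20 (the whole grid when the EC20 is censored above
#' the maximum tested level). An empty admissible set — no non-zero
#' concentration below the EC20 — is an error.
#'
#' @param ec20 an [estimate_ec20()] result.
#' @param grid tested concentration grid (including the control 0).
#' @return Numeric vector of admissible concentrations.
#' @export
noncytotoxic_range <- function(ec20, grid) {
  stopifnot(inherits(ec20, "ec20_result"), is.numeric(grid))
  adm <- if (ec20$censored) grid else grid[grid < ec20$ec20]
  if (!any(adm > 0)) {
    stop_lk("no non-cytotoxic concentration in the tested grid")
  }
  adm
}

#' Per-scenario EC20 table
#'
#' Applies [estimate_ec20()] to each scenario of a [viability_fraction()]
#' table.
#'
#' @param viab output of [viability_fraction()].
#' @param threshold viability threshold, default 0.8.
#' @return `data.frame` with columns `scenario`, `ec20`, `censored`,
#'   `max_tested`.
#' @export
ec20_by_scenario <- function(viab, threshold = 0.8) {
  rows <- lapply(unique(viab$scenario), function(sc) {
    x <- viab[viab$scenario == sc, , drop = FALSE]
    r <- estimate_ec20(x$concentration, x$viability, threshold)
    data.frame(scenario = sc, ec20 = r$ec20, censored = r$censored,
               max_tested = r$max_tested, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
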