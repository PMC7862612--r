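# Toxic-ratio / specificity-ratio classification. TR compares the predicted
# baseline IC10 with the measured EC20 (TR <= 10: cytotoxicity is
# non-specific baseline action; TR > 10: specific mode of action). SR
# compares the EC20 with the LOEC of an immune endpoint (SR < 10: the
# immune effect is no more potent than baseline cytotoxicity). Censored
# inputs (EC20 "> max tested", LOEC "n.d.") never yield a finite ratio;
# where a censoring limit exists the ratio is reported as a bound.

#' Toxic ratio
#'
#' `TR = IC10_baseline / EC20`. Classification is `"specific"` iff TR > 10;
#' TR <= 10 means the observed cytotoxicity is explained by non-specific
#' baseline toxicity. Table output is rounded to one decimal
#' (half away from zero); the full-precision ratio is retained.
#'
#' @param ic10 predicted baseline IC10 (uM, > 0).
#' @param ec20 measured average EC20 (uM, > 0), or `NA` when censored.
#' @param ec20_censored logical; `TRUE` when the EC20 is only known to
#'   exceed `censoring_limit`.
#' @param censoring_limit the maximum tested concentration when
#'   `ec20_censored`; the TR is then reported only as the bound
#'   `ic10 / censoring_limit`.
#' @return An object of class `toxic_ratio`: list with `tr`, `tr_rounded`,
#'   `classification` (`"specific"` / `"non-specific"` / `NA`),
#'   `determinable`, `bound` (numeric bound when censored, else `NA`),
#'   `borderline` (`TRUE` within half a rounding unit of the threshold).
#' @examples
#' toxic_ratio(1515, 400)$tr_rounded   # 3.8
#' toxic_ratio(5044, 463)$tr_rounded   # 10.9, borderline specific
#' @export
toxic_ratio <- function(ic10, ec20, ec20_censored = FALSE,
                        censoring_limit = NA_real_) {
  if (!(ic10 > 0) || !is.finite(ic10)) stop_lk("ic10 must be positive and finite")
  if (ec20_censored) {
    bound <- if (is.finite(censoring_limit) && censoring_limit > 0) {
      ic10 / censoring_limit
    } else {
      NA_real_
    }
    return(structure(list(tr = NA_real_, tr_rounded = NA_real_,
                          classification = NA_character_,
                          determinable = FALSE, bound = bound,
                          borderline = FALSE),
                     class = "toxic_ratio"))
  }
  if (is.na(ec20)) stop_lk("ec20 is NA but not flagged censored")
  if (ec20 == 0) stop_lk("ec20 must be positive")
  if (!(ec20 > 0) || !is.finite(ec20)) stop_lk("ec20 must be positive and finite")
  tr <- ic10 / ec20
  structure(list(tr = tr, tr_rounded = round_half_away(tr, 1L),
                 classification = if (tr > 10) "specific" else "non-specific",
                 determinable = TRUE, bound = NA_real_,
                 borderline = abs(tr - 10) <= 1),
            class = "toxic_ratio")
}

#' @export
print.toxic_ratio <- function(x, ...) {
  if (!x$determinable) {
    if (is.finite(x$bound)) {
      cat(sprintf("TR not determinable (EC20 censored); bound TR >= %.1f\n", x$bound))
    } else {
      cat("TR not determinable (EC20 censored)\n")
    }
  } else {
    cat(sprintf("TR = %.1f (%s%s)\n", x$tr_rounded, x$classification,
                if (x$borderline) ", borderline" else ""))
  }
  invisible(x)
}

#' Specificity ratio
#'
#' `SR = EC20 / LOEC`. Classification is `"specific"` when SR >= 10;
#' SR < 10 indicates the immune effect is not more potent than non-specific
#' cytotoxicity. A non-determinable LOEC (`NA`) propagates to a
#' non-determinable SR; a censored EC20 yields a lower bound
#' `censoring_limit / loec`.
#'
#' @param ec20 measured EC20 (uM, > 0), or `NA` when censored.
#' @param loec lowest observed effect concentration (uM, > 0), or `NA` when
#'   not determinable.
#' @inheritParams toxic_ratio
#' @return An object of class `specificity_ratio`: list with `sr`,
#'   `sr_rounded`, `classification`, `determinable`, `bound`.
#' @examples
#' specificity_ratio(400, 2)$sr  # 200, specific
#' @export
specificity_ratio <- function(ec20, loec, ec20_censored = FALSE,
                              censoring_limit = NA_real_) {
  nd <- structure(list(sr = NA_real_, sr_rounded = NA_real_,
                       classification = NA_character_, determinable = FALSE,
                       bound = NA_real_),
                  class = "specificity_ratio")
  if (is.na(loec)) return(nd)
  if (loec == 0) stop_lk("loec must be positive")
  if (ec20_censored) {
    if (is.finite(censoring_limit) && censoring_limit > 0) {
      nd$bound <- censoring_limit / loec
    }
    return(nd)
  }
  if (is.na(ec20) || !(ec20 > 0)) stop_lk("ec20 must be positive")
  sr <- ec20 / loec
  structure(list(sr = sr, sr_rounded = round_half_away(sr, 1L),
                 classification = if (sr < 10) "non-specific" else "specific",
                 determinable = TRUE, bound = NA_real_),
            class = "specificity_ratio")
}

#' @export
print.specificity_ratio <- function(x, ...) {
  if (!x$determinable) {
    if (is.finite(x$bound)) {
      cat(sprintf("SR not determinable; bound SR > %.1f\n", x$bound))
    } else {
      cat("SR not determinable\n")
    }
  } else {
    cat(sprintf("SR = %.1f (%s)\n", x$sr_rounded, x$classification))
  }
  invisible(x)
}

#' Average over exposure scenarios with censoring
#'
#' Arithmetic mean over the determinable scenario values (short- and
#' long-term exposure, each without and with LPS). When every scenario is
#' censored the average is censored too, with the largest censoring limit
#' as its limit.
#'
#' @param values numeric scenario values (`NA` where censored or not
#'   determinable).
#' @param censored logical vector marking censored entries; defaults to
#'   `is.na(values)`.
#' @param limits censoring limits aligned with `values` (e.g. the maximum
#'   tested concentration).
#' @return List with `value` (mean or `NA`), `censored`, `limit`, `n_used`.
#' @examples
#' scenario_average(c(100, 300, NA, NA))$value  # 200
#' @export
scenario_average <- function(values, censored = is.na(values),
                             limits = rep(NA_real_, length(values))) {
  stopifnot(length(censored) == length(values),
            length(limits) == length(values))
  ok <- !censored & !is.na(values)
  if (!any(ok)) {
    lim <- if (all(is.na(limits))) NA_real_ else max(limits, na.rm = TRUE)
    return(list(value = NA_real_, censored = TRUE, limit = lim, n_used = 0L))
  }
  list(value = mean(values[ok]), censored = FALSE, limit = NA_real_,
       n_used = sum(ok))
}

#' Signed p-value category
#'
#' Bins p values into the usual display categories (`***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, `ns` otherwise), annotated with the effect
#' direction taken from the sign of the estimate.
#'
#' @param p p value(s).
#' @param estimate contrast estimate(s), same length.
#' @return Character vector like `"*, decrease"` or `"ns"`.
#' @export
p_category <- function(p, estimate) {
  stopifnot(length(p) == length(estimate))
  stars <- ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                  ifelse(p < 0.05, "*", "ns")))
  dirn <- ifelse(estimate >= 0, "increase", "decrease")
  ifelse(stars == "ns", "ns", paste0(stars, ", ", dirn))
}

#' Assemble the screening summary bundle
#'
#' Combines baseline predictions, per-scenario EC20s and per-scenario LOECs
#' into (a) a toxicity table (IC10, average EC20, TR and classification, one
#' row per chemical), (b) a specificity table (average LOEC and SR per
#' chemical x endpoint), and optionally (c) a signed p-category matrix of
#' the standard comparisons. SRs are computed per scenario and then
#' averaged; the ratio of the averaged columns is emitted alongside for
#' comparison (`sr_of_averages`).
#'
#' @param ic10_tbl `data.frame` with columns `chemical`, `ic10`.
#' @param ec20_tbl `data.frame` with columns `chemical`, `scenario`, `ec20`
#'   (`NA` when censored), `censored`, `max_tested`.
#' @param loec_tbl `data.frame` with columns `chemical`, `endpoint`,
#'   `scenario`, `loec` (`NA` when not determinable).
#' @param comparisons optional `data.frame` of contrasts with columns
#'   `chemical`, `scenario`, `comparison`, `concentration`, `p`, `estimate`.
#' @return An object of class `specificity_summary`: list with `toxicity`,
#'   `specificity`, `p_matrix` data frames.
#' @export
build_summary <- function(ic10_tbl, ec20_tbl, loec_tbl, comparisons = NULL) {
  stopifnot(all(c("chemical", "ic10") %in% names(ic10_tbl)),
            all(c("chemical", "scenario", "ec20", "censored", "max_tested")
                %in% names(ec20_tbl)),
            all(c("chemical", "endpoint", "scenario", "loec")
                %in% names(loec_tbl)))
  sets <- list(ic10 = unique(ic10_tbl$chemical),
               ec20 = unique(ec20_tbl$chemical),
               loec = unique(loec_tbl$chemical))
  all_chem <- sort(unique(unlist(sets)))
  bad <- vapply(sets, function(s) !setequal(s, all_chem), logical(1))
  if (any(bad)) {
    detail <- vapply(names(sets)[bad], function(nm) {
      paste0(nm, " missing: ", paste(setdiff(all_chem, sets[[nm]]), collapse = ", "))
    }, character(1))
    stop_lk("inconsistent chemical sets across inputs; ",
            paste(detail, collapse = "; "))
  }
  chems <- sets$ic10

  tox <- do.call(rbind, lapply(chems, function(ch) {
    e <- ec20_tbl[ec20_tbl$chemical == ch, , drop = FALSE]
    avg <- scenario_average(e$ec20, e$censored, e$max_tested)
    tr <- toxic_ratio(ic10_tbl$ic10[ic10_tbl$chemical == ch][1L],
                      avg$value, avg$censored, avg$limit)
    data.frame(chemical = ch,
               ic10 = ic10_tbl$ic10[ic10_tbl$chemical == ch][1L],
               ec20_avg = avg$value, ec20_censored = avg$censored,
               ec20_limit = avg$limit,
               tr = tr$tr_rounded, tr_full = tr$tr, tr_bound = tr$bound,
               classification = tr$classification %||% NA_character_,
               borderline = tr$borderline, stringsAsFactors = FALSE)
  }))

  spec_rows <- list()
  for (ch in chems) {
    e <- ec20_tbl[ec20_tbl$chemical == ch, , drop = FALSE]
    lt <- loec_tbl[loec_tbl$chemical == ch, , drop = FALSE]
    for (ep in unique(lt$endpoint)) {
      l <- lt[lt$endpoint == ep, , drop = FALSE]
      m <- match(l$scenario, e$scenario)
      srs <- mapply(function(ec20, cens, lim, loec) {
        if (is.na(loec)) return(NA_real_)
        r <- specificity_ratio(ec20, loec, cens, lim)
        if (r$determinable) r$sr else NA_real_
      }, e$ec20[m], e$censored[m], e$max_tested[m], l$loec)
      loec_avg <- scenario_average(l$loec)
      sr_avg <- scenario_average(srs)
      ec20_avg <- scenario_average(e$ec20, e$censored, e$max_tested)
      sr_of_avg <- if (!loec_avg$censored && !ec20_avg$censored) {
        ec20_avg$value / loec_avg$value
      } else {
        NA_real_
      }
      spec_rows[[length(spec_rows) + 1L]] <- data.frame(
        chemical = ch, endpoint = ep,
        loec_avg = loec_avg$value,
        sr_avg = if (sr_avg$censored) NA_real_ else round_half_away(sr_avg$value, 1L),
        sr_of_averages = sr_of_avg,
        classification = if (sr_avg$censored) NA_character_
                         else if (sr_avg$value < 10) "non-specific" else "specific",
        stringsAsFactors = FALSE
      )
    }
  }
  spec <- do.call(rbind, spec_rows)

  pm <- NULL
  if (!is.null(comparisons)) {
    need <- c("chemical", "scenario", "comparison", "p", "estimate")
    stopifnot(all(need %in% names(comparisons)))
    pm <- comparisons
    pm$category <- p_category(pm$p, pm$estimate)
  }

  structure(list(toxicity = tox, specificity = spec, p_matrix = pm),
            class = "specificity_summary")
}

#' @export
print.specificity_summary <- function(x, ...) {
  cat("Toxicity classification (TR = IC10_baseline / average EC20):\n")
  print(x$toxicity[c("chemical", "ic10", "ec20_avg", "tr", "classification")],
        row.names = FALSE)
  cat("\nSpecificity (SR = EC20 / LOEC, per-scenario average):\n")
  print(x$specificity, row.names = FALSE)
  if (!is.null(x$p_matrix)) {
    cat("\nContrast categories:\n")
    print(utils::head(x$p_matrix[c("chemical", "scenario", "comparison",
                                   "category")], 20), row.names = FALSE)
  }
  invisible(x)
}

#' Published screening reference values
#'
#' Reads the packaged table of per-chemical screening values for seven test
#' chemicals (predicted baseline IC10 and average measured EC20 in uM, with
#' the benzo(a)pyrene EC20 censored above its maximum tested concentration)
#' used in worked examples and consistency checks.
#'
#' @return `data.frame` with columns `chemical`, `abbrev`, `ic10_uM`,
#'   `ec20_uM`, `ec20_censored`, `max_tested_uM`.
#' @export
screening_reference <- function() {
  path <- system.file("extdata", "chemical_screening_values.csv",
                      package = "leukotox", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
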