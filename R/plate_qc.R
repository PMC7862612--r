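# Plate-level preprocessing: blank normalisation, technical-replicate
# averaging, and the LPS positive-control validity rule.

#' Subtract plate blanks from sample wells
#'
#' Within each blank grouping (by default endpoint x time, mirroring separate
#' plates per immune parameter and exposure duration), the mean of the blank
#' wells is subtracted from every non-blank well. Blank rows are removed from
#' the output.
#'
#' @param records long-format well table with at least the columns in
#'   `group_by`, plus `value` and `role` (`"blank"` marks blank wells).
#' @param group_by columns defining a blank grouping; default
#'   `c("endpoint", "time")`.
#' @return `records` without blank rows and with `value` blank-corrected.
#' @examples
#' x <- data.frame(endpoint = "burst", time = "3h",
#'                 role = c("sample", "blank", "blank"),
#'                 value = c(10, 2, 2))
#' blank_normalize(x)$value  # 8
#' @export
blank_normalize <- function(records, group_by = c("endpoint", "time")) {
  stopifnot(is.data.frame(records), all(c("value", "role") %in% names(records)))
  missing_cols <- setdiff(group_by, names(records))
  if (length(missing_cols)) {
    stop_lk("grouping columns absent from records: ",
            paste(missing_cols, collapse = ", "))
  }
  key <- interaction(records[group_by], drop = TRUE, sep = " / ")
  is_blank <- records$role == "blank"
  out <- records
  for (g in levels(key)) {
    in_g <- key == g
    b <- records$value[in_g & is_blank]
    if (length(b) == 0L) {
      stop_lk("no blank wells for grouping: ", g)
    }
    out$value[in_g] <- records$value[in_g] - mean(b)
  }
  out <- out[!is_blank, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average technical replicate wells
#'
#' Collapses replicate wells to one row per fish x time x LPS x concentration
#' x endpoint treatment cell, carrying the replicate mean, the
#' within-treatment SD (0 when a single replicate) and the replicate count.
#' This is the averaging step that precedes model fitting.
#'
#' @param records long-format well table with columns `fish_id`, `time`,
#'   `lps`, `concentration`, `endpoint`, `value`.
#' @return A `data.frame` with one row per treatment cell and columns
#'   `fish_id`, `time`, `lps`, `concentration`, `endpoint`, `value` (mean),
#'   `replicate_sd`, `n_replicates`.
#' @export
average_technical_replicates <- function(records) {
  keys <- c("fish_id", "time", "lps", "concentration", "endpoint")
  stopifnot(is.data.frame(records), all(c(keys, "value") %in% names(records)))
  f <- interaction(records[keys], drop = TRUE, lex.order = TRUE)
  split_vals <- split(records$value, f)
  first <- !duplicated(f)
  out <- records[first, keys, drop = FALSE]
  ord <- as.character(f[first])
  out$value <- vapply(split_vals, mean, numeric(1))[ord]
  out$replicate_sd <- vapply(split_vals, function(v) {
    if (length(v) > 1L) stats::sd(v) else 0
  }, numeric(1))[ord]
  out$n_replicates <- vapply(split_vals, length, integer(1))[ord]
  rownames(out) <- NULL
  out
}

#' LPS positive-control validity rule
#'
#' A fish's data for an endpoint are valid only if LPS stimulated its control
#' cells: the stimulated-control mean must exceed the non-stimulated-control
#' mean by more than `k` times the technical error, defined as the pooled SD
#' of that fish's control technical replicates (both LPS arms). Fish failing
#' the rule — or missing either control arm — are flagged for exclusion.
#'
#' @param records well-level table (before averaging) with columns `fish_id`,
#'   `time`, `lps`, `concentration`, `endpoint`, `value`; control wells are
#'   those with `concentration == 0`.
#' @param k multiplier on the technical error (default 1).
#' @return A `data.frame` with one row per fish x endpoint:
#'   `fish_id`, `endpoint`, `valid`, `stimulated_control_mean`,
#'   `unstimulated_control_mean`, `technical_error`, `margin` (the difference
#'   minus `k * technical_error`), `reason` (`""` when valid).
#' @export
lps_quality_control <- function(records, k = 1) {
  keys <- c("fish_id", "time", "lps", "concentration", "endpoint", "value")
  stopifnot(is.data.frame(records), all(keys %in% names(records)), k > 0)
  combos <- unique(records[c("fish_id", "endpoint")])
  res <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    fid <- combos$fish_id[i]
    ep <- combos$endpoint[i]
    ctl <- records[records$fish_id == fid & records$endpoint == ep &
                     records$concentration == 0, , drop = FALSE]
    stim <- ctl$value[ctl$lps == "yes"]
    unstim <- ctl$value[ctl$lps == "no"]
    if (length(stim) == 0L || length(unstim) == 0L) {
      res[[i]] <- data.frame(
        fish_id = fid, endpoint = ep, valid = FALSE,
        stimulated_control_mean = NA_real_,
        unstimulated_control_mean = NA_real_,
        technical_error = NA_real_, margin = NA_real_,
        reason = "incomplete controls", stringsAsFactors = FALSE
      )
      next
    }
    # pool replicate SD within each control treatment cell (time x LPS)
    grp <- paste(ctl$time, ctl$lps)
    te <- pooled_sd(ctl$value, grp)
    diff <- mean(stim) - mean(unstim)
    valid <- diff > k * te
    res[[i]] <- data.frame(
      fish_id = fid, endpoint = ep, valid = valid,
      stimulated_control_mean = mean(stim),
      unstimulated_control_mean = mean(unstim),
      technical_error = te, margin = diff - k * te,
      reason = if (valid) "" else "LPS stimulation not above technical error",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Drop fish that failed the LPS quality control
#'
#' @param records well- or treatment-level table with `fish_id` and
#'   `endpoint` columns.
#' @param qc result of [lps_quality_control()].
#' @return `records` restricted to valid fish x endpoint combinations.
#' @export
apply_qc <- function(records, qc) {
  stopifnot(is.data.frame(qc), all(c("fish_id", "endpoint", "valid") %in% names(qc)))
  bad <- qc[!qc$valid, c("fish_id", "endpoint"), drop = FALSE]
  if (nrow(bad) == 0L) return(records)
  drop <- paste(records$fish_id, records$endpoint) %in%
    paste(bad$fish_id, bad$endpoint)
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
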