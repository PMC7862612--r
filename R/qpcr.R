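# Relative qPCR quantification by the 2^-ddCt method: technical duplicates
# are averaged, target Cts are normalised to a reference gene (dCt), each
# fish's treated sample is compared with its own control (ddCt), and fold
# change is 2^-ddCt. Statistics downstream run on the dCt scale, not on
# fold changes. Amplification efficiency is fixed at 2 (no efficiency
# correction).

#' Average technical qPCR duplicates
#'
#' Collapses the 1-2 technical duplicates of each sample x gene to their
#' arithmetic mean Ct. Duplicate pairs whose spread exceeds `spread_cutoff`
#' cycles are flagged (`spread_flag`), not dropped.
#'
#' @param records Ct table with columns `sample_id`, `gene`, `ct` and the
#'   annotation columns `fish_id`, `time`, `lps`, `concentration`
#'   (as from [simulate_qpcr()]).
#' @param spread_cutoff maximal acceptable duplicate spread in cycles
#'   (default 1).
#' @return One row per sample x gene with `ct` (mean), `spread` and
#'   `spread_flag`.
#' @export
collapse_duplicates <- function(records, spread_cutoff = 1) {
  need <- c("sample_id", "gene", "ct")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  f <- paste(records$sample_id, records$gene, sep = "\r")
  first <- !duplicated(f)
  keep <- intersect(c("sample_id", "fish_id", "time", "lps", "concentration",
                      "gene"), names(records))
  out <- records[first, keep, drop = FALSE]
  sp <- split(records$ct, f)
  ord <- f[first]
  n_dup <- vapply(sp, length, integer(1))[ord]
  if (any(n_dup > 2L)) stop_lk("more than two technical duplicates for a sample x gene")
  out$ct <- vapply(sp, mean, numeric(1))[ord]
  out$spread <- vapply(sp, function(v) diff(range(v)), numeric(1))[ord]
  out$spread_flag <- out$spread > spread_cutoff
  rownames(out) <- NULL
  out
}

#' Reference-gene normalisation (dCt)
#'
#' Computes `dCt = Ct_target - Ct_reference` per sample. Samples without a
#' reference-gene measurement are excluded with a message naming them.
#'
#' @param collapsed output of [collapse_duplicates()].
#' @param reference_gene reference gene name, default `"EF1a"`.
#' @return One row per sample x target gene with column `delta_ct`
#'   (annotation columns carried through).
#' @export
delta_ct <- function(collapsed, reference_gene = "EF1a") {
  stopifnot(is.data.frame(collapsed),
            all(c("sample_id", "gene", "ct") %in% names(collapsed)))
  ref <- collapsed[collapsed$gene == reference_gene, , drop = FALSE]
  tgt <- collapsed[collapsed$gene != reference_gene, , drop = FALSE]
  if (nrow(ref) == 0L) stop_lk("no rows for reference gene '", reference_gene, "'")
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  missing_ref <- setdiff(unique(tgt$sample_id), names(ref_ct))
  if (length(missing_ref)) {
    message("samples excluded for missing reference gene: ",
            paste(missing_ref, collapse = ", "))
    tgt <- tgt[!tgt$sample_id %in% missing_ref, , drop = FALSE]
  }
  tgt$delta_ct <- tgt$ct - ref_ct[tgt$sample_id]
  rownames(tgt) <- NULL
  tgt
}

#' Fold change relative to each fish's own control (2^-ddCt)
#'
#' For every fish x gene x scenario (time x LPS), `ddCt` is the treated
#' sample's dCt minus the same fish's control (concentration 0) dCt in the
#' same scenario, and fold change is `2^-ddCt`; control samples map to fold
#' change 1 by construction. Per protocol only the control and the highest
#' concentration are quantified; other concentrations are accepted but
#' flagged `off_protocol`.
#'
#' @param dct output of [delta_ct()] with annotation columns `fish_id`,
#'   `time`, `lps`, `concentration`.
#' @return The input with columns `delta_delta_ct`, `fold_change`,
#'   `off_protocol` added.
#' @export
fold_change <- function(dct) {
  need <- c("sample_id", "fish_id", "time", "lps", "concentration",
            "gene", "delta_ct")
  stopifnot(is.data.frame(dct), all(need %in% names(dct)))
  grp <- paste(dct$fish_id, dct$time, dct$lps, dct$gene, sep = "\r")
  ctrl <- dct$concentration == 0
  ctrl_dct <- stats::setNames(dct$delta_ct[ctrl], grp[ctrl])
  if (anyDuplicated(grp[ctrl])) {
    stop_lk("multiple control samples for one fish x scenario x gene")
  }
  no_ctrl <- !(grp %in% names(ctrl_dct))
  if (any(no_ctrl)) {
    ex <- unique(paste0(dct$fish_id[no_ctrl], " (", dct$time[no_ctrl], ", LPS ",
                        dct$lps[no_ctrl], ")"))
    stop_lk("no matching control for: ", paste(ex, collapse = "; "))
  }
  out <- dct
  out$delta_delta_ct <- dct$delta_ct - ctrl_dct[grp]
  out$fold_change <- 2^(-out$delta_delta_ct)
  top <- max(dct$concentration)
  out$off_protocol <- !(dct$concentration %in% c(0, top))
  if (any(out$off_protocol)) {
    message("intermediate concentrations quantified; flagged off_protocol")
  }
  rownames(out) <- NULL
  out
}

#' Full qPCR expression pipeline
#'
#' Chains [collapse_duplicates()], [delta_ct()] and [fold_change()].
#'
#' @inheritParams collapse_duplicates
#' @inheritParams delta_ct
#' @return Expression table with `delta_ct`, `delta_delta_ct`,
#'   `fold_change` per sample x target gene.
#' @examples
#' d <- experiment_design(paste0("F", 1:3), c(0, 10))
#' tr <- qpcr_truth(delta_ct_control = c(IL1b = 6),
#'                  treatment_shift = c(IL1b = -2), ct_noise_sd = 0)
#' ct <- simulate_qpcr(d, tr, seed = 1)
#' ex <- qpcr_expression(ct)
#' # treated samples show fold change 4 (ddCt = -2)
#' unique(round(ex$fold_change[ex$concentration > 0], 10))
#' @export
qpcr_expression <- function(records, reference_gene = "EF1a",
                            spread_cutoff = 1) {
  fold_change(delta_ct(collapse_duplicates(records, spread_cutoff),
                       reference_gene))
}
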