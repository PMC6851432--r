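#' Inflate a B-factor by a coordinate-error estimate
#'
#' Adds `(8 * pi^2 / 3) * error^2` to the baseline B-factor: smearing an
#' atom's electron density over its positional uncertainty, which
#' downweights unreliable parts of a model in molecular replacement.
#'
#' @param error_estimate RMS coordinate error estimate(s), Angstrom
#'   (>= 0).
#' @param baseline_b Baseline B-factor, Angstrom^2 (default 0: the pure
#'   error term).
#' @return Inflated B-factor(s), Angstrom^2.
#' @export
inflate_b <- function(error_estimate, baseline_b = 0) {
  if (any(!is.na(error_estimate) & error_estimate < 0))
    stop("negative coordinate-error estimate")
  baseline_b + (8 * pi^2 / 3) * error_estimate^2
}

#' Median coordinate-error estimate of a model
#'
#' Median of the B-factor column interpreted as per-atom RMS error
#' estimates, over all non-hydrogen atoms.
#'
#' @param x A `StructureRecord` whose B column carries error estimates.
#' @return Median error in Angstrom.
#' @export
median_error <- function(x) {
  stopifnot(inherits(x, "StructureRecord"))
  a <- x$atoms
  stats::median(a$b[!(a$element %in% c("H", "D"))])
}

#' Rewrite the B-factor column for molecular replacement
#'
#' Three interpretations of the submitted B column:
#' `"constant"` sets every B to `constant_b`; `"error_estimate"` treats
#' the column as RMS coordinate error and replaces it with
#' [inflate_b()]`(B, baseline_b)`; `"b_factor"` leaves it untouched
#' (control calculation).
#'
#' @param x A `StructureRecord`.
#' @param mode `"constant"`, `"error_estimate"` or `"b_factor"`.
#' @param constant_b Value used by `"constant"` mode (Angstrom^2).
#' @param baseline_b Baseline for `"error_estimate"` mode (Angstrom^2).
#' @return The transformed `StructureRecord`.
#' @export
apply_b_mode <- function(x, mode = c("constant", "error_estimate", "b_factor"),
                         constant_b = 20, baseline_b = 0) {
  stopifnot(inherits(x, "StructureRecord"))
  mode <- match.arg(mode)
  if (mode == "constant") {
    x$atoms$b <- constant_b
  } else if (mode == "error_estimate") {
    x$atoms$b <- inflate_b(x$atoms$b, baseline_b)
  }
  x
}

#' Quality filter for molecular-replacement candidates
#'
#' Models with GDT_TS below 30 or a median coordinate-error estimate
#' above 3 Angstrom are rejected (MR calculations become unstable for
#' such models) and assigned an LLG gain of zero; accepted models pass
#' their LLG gain through.  Both thresholds are non-strict at the
#' boundary (GDT_TS = 30 and median error = 3 are accepted).
#'
#' @param gdt_ts GDT_TS score(s), 0-100.  `NA` is an error: the filter
#'   is undecidable without it.
#' @param med_err Median coordinate-error estimate(s), Angstrom
#'   (`NA` allowed when no error estimates are in play; only the GDT_TS
#'   criterion then applies).
#' @param llg_gain LLG gain(s) from an external MR engine (optional).
#' @return Data frame with `accepted` and `llg_assigned` (0 when
#'   rejected, the input LLG otherwise).
#' @export
mr_filter <- function(gdt_ts, med_err = NA_real_, llg_gain = NA_real_) {
  if (any(is.na(gdt_ts)))
    stop("GDT_TS missing: MR filter undecidable")
  if (any(!is.na(gdt_ts) & (gdt_ts < 0 | gdt_ts > 100)))
    stop("GDT_TS outside [0, 100]")
  n <- max(length(gdt_ts), length(med_err), length(llg_gain))
  gdt_ts <- rep_len(gdt_ts, n)
  med_err <- rep_len(med_err, n)
  llg_gain <- rep_len(llg_gain, n)
  rejected <- gdt_ts < 30 | (!is.na(med_err) & med_err > 3)
  data.frame(accepted = !rejected,
             llg_assigned = ifelse(rejected, 0, llg_gain))
}

#' Is a molecular-replacement search predicted to succeed?
#'
#' An LLG gain of 60 or more almost always indicates a successful
#' search.
#'
#' @param llg_gain LLG gain value(s).
#' @return Logical vector.
#' @export
mr_success <- function(llg_gain) {
  stopifnot(all(is.finite(llg_gain)))
  llg_gain >= 60
}

#' Pick the best MR model per group/target
#'
#' Applies [mr_filter()] to all candidate models (typically the five
#' submissions of one group for one target) and returns, per
#' group/target, the row with the highest assigned LLG gain, ties
#' broken by lowest model index.  Groups whose models are all rejected
#' score an LLG of 0.
#'
#' @param records Data frame with columns `group`, `target`,
#'   `model_index`, `gdt_ts`, `med_err` (optional), `llg_gain`.
#' @return Data frame with one row per (group, target): the selected
#'   `model_index` (`NA` if every model was rejected), `llg_gain` after
#'   filtering, `accepted` and `success`.
#' @export
best_of_models <- function(records) {
  stopifnot(all(c("group", "target", "model_index", "gdt_ts", "llg_gain")
                %in% names(records)))
  if (!"med_err" %in% names(records)) records$med_err <- NA_real_
  flt <- mr_filter(records$gdt_ts, records$med_err, records$llg_gain)
  records$accepted <- flt$accepted
  records$llg_assigned <- flt$llg_assigned
  spl <- split(seq_len(nrow(records)),
               paste(records$group, records$target, sep = "\r"))
  rows <- lapply(spl, function(i) {
    r <- records[i, , drop = FALSE]
    if (!any(r$accepted)) {
      data.frame(group = r$group[1], target = r$target[1],
                 model_index = NA_integer_, llg_gain = 0,
                 accepted = FALSE, success = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      r <- r[r$accepted, , drop = FALSE]
      best <- r[order(-r$llg_assigned, r$model_index)[1], , drop = FALSE]
      data.frame(group = best$group, target = best$target,
                 model_index = best$model_index,
                 llg_gain = best$llg_assigned, accepted = TRUE,
                 success = mr_success(best$llg_assigned),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an MR filter/selection report as CSV
#'
#' @param records Data frame as for [best_of_models()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mr_report <- function(records, path) {
  flt <- mr_filter(records$gdt_ts,
                   if ("med_err" %in% names(records)) records$med_err else NA_real_,
                   records$llg_gain)
  records$accepted <- flt$accepted
  records$llg_assigned <- flt$llg_assigned
  records$success <- !is.na(flt$llg_assigned) & flt$llg_assigned >= 60
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
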