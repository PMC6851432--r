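# Metric orientation: TRUE when larger raw values are better.  Lower-is
# -better metrics are negated before z-scoring so that larger adjusted z
# always means better.
.metric_orientation <- c(GDT_HA = TRUE, GDT_TS = TRUE, lDDT = TRUE,
                         CADaa = TRUE, SG = TRUE, ASE = TRUE,
                         clashscore = FALSE, mean_backbone = FALSE,
                         mean_sidechain = FALSE)

#' Adjusted z-scores with outlier pruning and negative clipping
#'
#' The two-pass protocol used for CASP-style ranking: (1) orient values
#' so that higher is better; (2) compute initial z-scores from the mean
#' and SD of all values; (3) drop values with initial z below -2 as
#' potential outliers (one shot, no iteration); (4) recompute mean/SD on
#' the pruned set and re-score **all** values against them; (5) clip
#' negative z-scores to zero.  If the SD of a pass is zero the z-scores
#' of that pass are defined as 0.
#'
#' @param values Numeric vector (one entry per model), length >= 2.
#'   `NA` entries get z = 0 (a missing metric contributes nothing).
#' @param higher_is_better Orientation of the raw metric.
#' @param sd_type `"sample"` (divide by n-1; default) or
#'   `"population"` (divide by n).
#' @param prune_z Initial-z pruning threshold (default -2, strict `<`).
#' @return Numeric vector of adjusted z-scores, all >= 0.
#' @export
adjusted_z <- function(values, higher_is_better = TRUE,
                       sd_type = c("sample", "population"), prune_z = -2) {
  sd_type <- match.arg(sd_type)
  if (length(values) < 2) stop("need at least 2 values")
  v <- if (higher_is_better) values else -values
  ok <- !is.na(v)
  zfun <- function(x, pop) {
    m <- mean(pop)
    s <- stats::sd(pop)
    if (sd_type == "population")
      s <- s * sqrt((length(pop) - 1) / length(pop))
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - m) / s
  }
  z1 <- rep(NA_real_, length(v))
  z1[ok] <- zfun(v[ok], v[ok])
  keep <- ok & !is.na(z1) & z1 >= prune_z
  z2 <- rep(0, length(v))
  if (sum(keep) >= 1)
    z2[ok] <- zfun(v[ok], v[keep])
  pmax(z2, 0)
}

#' Combined ranking-score weights
#'
#' The fixed linear combinations of per-metric adjusted z-scores:
#' \itemize{
#'   \item `S_CASP12`: `z_GDT_HA/3 + (z_lDDT + z_CADaa + z_SG)/9 + z_ASE/3`
#'   \item `S_CASP12-ASE`: `z_GDT_HA/2 + (z_lDDT + z_CADaa + z_SG)/6`
#'   \item `S_torsion`: `2/3 z_backbone + 1/3 z_sidechain`
#'   \item `S_geom`: `(z_lDDT + z_CADaa + z_SG + z_sidechain)/16 +
#'     (z_clash + z_backbone)/8 + (z_GDT_HA + z_ASE)/4`
#' }
#' Backbone/sidechain/clash z-scores are computed on the negated metric
#' (lower raw value is better).
#'
#' @param scheme One of `"S_CASP12"`, `"S_CASP12-ASE"`, `"S_torsion"`,
#'   `"S_geom"`.
#' @return Named numeric vector of weights keyed by metric column name.
#' @export
scheme_weights <- function(scheme) {
  switch(scheme,
         "S_CASP12" = c(GDT_HA = 1 / 3, lDDT = 1 / 9, CADaa = 1 / 9,
                        SG = 1 / 9, ASE = 1 / 3),
         "S_CASP12-ASE" = c(GDT_HA = 1 / 2, lDDT = 1 / 6, CADaa = 1 / 6,
                            SG = 1 / 6),
         "S_torsion" = c(mean_backbone = 2 / 3, mean_sidechain = 1 / 3),
         "S_geom" = c(lDDT = 1 / 16, CADaa = 1 / 16, SG = 1 / 16,
                      mean_sidechain = 1 / 16, clashscore = 1 / 8,
                      mean_backbone = 1 / 8, GDT_HA = 1 / 4, ASE = 1 / 4),
         stop("unknown scheme: ", scheme))
}

#' Combine per-metric adjusted z-scores into a ranking score
#'
#' Missing z columns contribute 0 (with a message), consistent with the
#' reset-to-zero philosophy of the adjusted-z protocol.
#'
#' @param z Named numeric vector, or a data frame whose columns are
#'   named by metric (e.g. `GDT_HA`), holding adjusted z-scores.
#' @param scheme Scheme name, see [scheme_weights()].
#' @param quiet Suppress the missing-column message.
#' @return Numeric score (vector if `z` is a data frame).
#' @export
combine_z <- function(z, scheme = "S_CASP12", quiet = FALSE) {
  w <- scheme_weights(scheme)
  if (is.data.frame(z)) {
    miss <- setdiff(names(w), names(z))
    if (length(miss) && !quiet)
      message("metrics absent, contributing 0: ", paste(miss, collapse = ", "))
    out <- rep(0, nrow(z))
    for (m in intersect(names(w), names(z))) {
      col <- z[[m]]
      col[is.na(col)] <- 0
      out <- out + w[[m]] * col
    }
    out
  } else {
    miss <- setdiff(names(w), names(z))
    if (length(miss) && !quiet)
      message("metrics absent, contributing 0: ", paste(miss, collapse = ", "))
    sum(w[intersect(names(w), names(z))] * z[intersect(names(w), names(z))])
  }
}

#' Rank predictor groups over a per-model metric table
#'
#' For every target, adjusted z-scores are computed per metric over the
#' model population (by default, all models submitted for that target),
#' combined into the chosen scheme, and the per-group ranking score is
#' the sum over targets of the combined score of the selected model
#' (`"model_1"`: the designated model 1; `"best_of_5"`: the best
#' submitted model).  Ties are broken by group label for determinism.
#'
#' @param table Data frame with columns `group`, `target`,
#'   `model_index` and any subset of the metric columns `GDT_HA`,
#'   `GDT_TS`, `lDDT`, `CADaa`, `SG`, `ASE`, `clashscore`,
#'   `mean_backbone`, `mean_sidechain`.
#' @param scheme Scheme name, see [scheme_weights()].
#' @param model_selection `"model_1"` or `"best_of_5"`.
#' @param population `"all_models"` (default) or `"model_1"`: which rows
#'   enter the per-target mean/SD.
#' @param sd_type Passed to [adjusted_z()].
#' @return List with `models` (the de-duplicated input plus `z_<metric>`
#'   columns and `combined`) and `groups` (data frame `group`, `score`,
#'   `rank`, sorted best first).
#' @export
rank_groups <- function(table, scheme = "S_CASP12",
                        model_selection = c("model_1", "best_of_5"),
                        population = c("all_models", "model_1"),
                        sd_type = "sample") {
  model_selection <- match.arg(model_selection)
  population <- match.arg(population)
  stopifnot(all(c("group", "target", "model_index") %in% names(table)))
  metrics <- intersect(names(.metric_orientation), names(table))
  if (!length(metrics)) stop("no recognized metric columns in table")
  key <- paste(table$group, table$target, table$model_index, sep = "\r")
  table <- table[!duplicated(key), , drop = FALSE]
  table <- table[order(table$target, table$group, table$model_index), ,
                 drop = FALSE]
  for (m in metrics) table[[paste0("z_", m)]] <- NA_real_
  for (tg in unique(table$target)) {
    rows <- which(table$target == tg)
    pop_rows <- if (population == "model_1")
      rows[table$model_index[rows] == 1] else rows
    for (m in metrics) {
      vals <- table[[m]][pop_rows]
      if (sum(!is.na(vals)) < 2) {
        table[[paste0("z_", m)]][rows] <- 0
        next
      }
      z_pop <- adjusted_z(vals, .metric_orientation[[m]], sd_type = sd_type)
      # score rows outside the population against the population stats
      # by appending them is unnecessary here: population defaults to
      # all rows; for model_1 populations the other rows keep z = 0.
      table[[paste0("z_", m)]][pop_rows] <- z_pop
      table[[paste0("z_", m)]][setdiff(rows, pop_rows)] <- 0
    }
  }
  zdf <- table[, paste0("z_", metrics), drop = FALSE]
  names(zdf) <- metrics
  table$combined <- combine_z(zdf, scheme, quiet = TRUE)
  sel <- if (model_selection == "model_1") {
    table[table$model_index == 1, , drop = FALSE]
  } else {
    spl <- split(seq_len(nrow(table)),
                 paste(table$group, table$target, sep = "\r"))
    idx <- vapply(spl, function(i) {
      i[order(-table$combined[i], table$model_index[i])][1]
    }, 1L)
    table[idx, , drop = FALSE]
  }
  if (!nrow(sel)) stop("model selection produced no rows")
  score <- tapply(sel$combined, sel$group, sum)
  groups <- data.frame(group = names(score), score = as.numeric(score),
                       stringsAsFactors = FALSE)
  groups <- groups[order(-groups$score, groups$group), , drop = FALSE]
  groups$rank <- seq_len(nrow(groups))
  rownames(groups) <- NULL
  list(models = table, groups = groups)
}

#' Read a per-model metric table from CSV/TSV
#'
#' @param path File path; the delimiter is sniffed from the header line.
#' @return Data frame suitable for [rank_groups()].
#' @export
read_metric_table <- function(path) {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("group", "target", "model_index") %in% names(df)))
  df
}

#' Write ranking results to CSV
#'
#' @param ranking Result of [rank_groups()].
#' @param models_path,groups_path Output CSV paths (`NULL` to skip one).
#' @return `ranking`, invisibly.
#' @export
write_ranking <- function(ranking, models_path = NULL, groups_path = NULL) {
  if (!is.null(models_path))
    utils::write.csv(ranking$models, models_path, row.names = FALSE)
  if (!is.null(groups_path))
    utils::write.csv(ranking$groups, groups_path, row.names = FALSE)
  invisible(ranking)
}
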