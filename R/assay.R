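#' Tidy secretion table
#'
#' Validates a hormone-secretion assay table. Each row is one technical
#' replicate of one incubation batch: `hormone` (glucagon or somatostatin),
#' `species` (human or mouse), `glucose_mM`, `condition` (treatment label,
#' e.g. `"baseline"`, `"forskolin"`, `"forskolin_glyh"`), `experiment_id`
#' (donor or pooled-islet experiment — the unit of independent replication),
#' `replicate_id` (technical replicate within experiment) and `value`
#' (hormone concentration, assay units, >= 0).
#'
#' @param df data.frame with the columns above.
#' @param baseline Label of the baseline condition that must be present in
#'   every (hormone, species, glucose) block. Default `"baseline"`.
#' @return The validated data.frame with class `secretion_table`.
#' @export
secretion_table <- function(df, baseline = "baseline") {
  req <- c("hormone", "species", "glucose_mM", "condition",
           "experiment_id", "replicate_id", "value")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("secretion table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(df$value)) || any(df$value < 0))
    stop("values must be finite and >= 0")
  blocks <- unique(df[, c("hormone", "species", "glucose_mM")])
  for (i in seq_len(nrow(blocks))) {
    sub <- merge(df, blocks[i, , drop = FALSE])
    if (!baseline %in% sub$condition)
      stop(sprintf("block (%s, %s, %g mM) lacks the baseline condition '%s'",
                   blocks$hormone[i], blocks$species[i],
                   blocks$glucose_mM[i], baseline))
  }
  structure(df, class = c("secretion_table", "data.frame"))
}

## Per-experiment means within each block x condition: technical
## replicates are pooled first so that dispersion is computed over
## independent experiments, not over quadruplicates.
experiment_means <- function(table) {
  agg <- stats::aggregate(
    value ~ hormone + species + glucose_mM + condition + experiment_id,
    data = table, FUN = mean)
  agg
}

#' Per-condition descriptive summary
#'
#' Mean and standard error per (hormone, species, glucose, condition).
#' Technical replicates are first averaged within each experiment; the SEM
#' is then computed over the N independent experiments (donors or pooled-
#' islet preparations), never over technical quadruplicates. With a single
#' experiment the SEM is reported as `NA`.
#'
#' @param table A [secretion_table()] (or plain data.frame with its
#'   columns).
#' @return data.frame with `mean`, `sem`, `n_experiments` per condition.
#' @export
condition_summary <- function(table) {
  em <- experiment_means(table)
  agg <- stats::aggregate(
    value ~ hormone + species + glucose_mM + condition, data = em,
    FUN = function(v) c(mean = mean(v),
                        sem = if (length(v) > 1)
                          stats::sd(v) / sqrt(length(v)) else NA_real_,
                        n = length(v)))
  out <- cbind(agg[, 1:4], as.data.frame(agg$value))
  names(out)[5:7] <- c("mean", "sem", "n_experiments")
  out$n_experiments <- as.integer(out$n_experiments)
  out
}

#' Fold change relative to a baseline condition
#'
#' Within each (hormone, species, glucose) block: the ratio of condition
#' mean to baseline mean, computed on per-experiment means. Uncertainty is
#' propagated from the two SEMs by the delta method for a ratio:
#' `se(fold) = fold * sqrt((sem_c/mean_c)^2 + (sem_b/mean_b)^2)`.
#' Cross-glucose folds are not defined; each block is compared only to its
#' own baseline, whose fold is identically 1.
#'
#' @param table A [secretion_table()].
#' @param baseline Baseline condition label. Default `"baseline"`.
#' @return data.frame with per-block, per-condition `fold` and `fold_se`.
#' @export
fold_change <- function(table, baseline = "baseline") {
  cs <- condition_summary(table)
  blocks <- unique(cs[, c("hormone", "species", "glucose_mM")])
  rows <- list()
  for (i in seq_len(nrow(blocks))) {
    sub <- merge(cs, blocks[i, , drop = FALSE])
    b <- sub[sub$condition == baseline, ]
    if (!nrow(b))
      stop("baseline condition absent from block")
    if (b$mean == 0) stop("zero baseline mean; fold change undefined")
    rel_b <- if (is.na(b$sem)) 0 else (b$sem / b$mean)^2
    for (j in seq_len(nrow(sub))) {
      fold <- sub$mean[j] / b$mean
      rel_c <- if (is.na(sub$sem[j])) 0 else (sub$sem[j] / sub$mean[j])^2
      rows[[length(rows) + 1L]] <- cbind(
        sub[j, c("hormone", "species", "glucose_mM", "condition")],
        data.frame(fold = fold,
                   fold_se = if (sub$condition[j] == baseline) 0
                             else fold * sqrt(rel_c + rel_b),
                   n_experiments = sub$n_experiments[j]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-cell image with mask
#'
#' @param intensity Numeric matrix of fluorescence intensities (arbitrary
#'   units).
#' @param mask Logical/0-1 matrix of the same dimension: the cell region.
#' @param pixel_size_um Pixel edge length (micrometers).
#' @return Object of class `cell_image`.
#' @export
cell_image <- function(intensity, mask, pixel_size_um) {
  if (!is.matrix(intensity) || !is.matrix(mask) ||
      !identical(dim(intensity), dim(mask)))
    stop("intensity and mask must be matrices of identical dimension")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (!any(mask > 0)) stop("mask is empty")
  structure(list(intensity = intensity, mask = (mask > 0) * 1,
                 pixel_size_um = pixel_size_um),
            class = "cell_image")
}

#' Membrane-to-cytosol intensity ratio
#'
#' The ratio P1/P2 between the mean fluorescence intensity in the plasma-
#' membrane region (P1) and in the cytosolic region (P2) of a masked single
#' cell. The membrane region is the band of the mask within
#' `membrane_width_um` (default 0.5 micrometers) of the mask boundary,
#' computed inward by the Euclidean distance transform; the cytosolic
#' region is the remaining interior. Signal outside the mask is ignored.
#'
#' @param img A [cell_image()].
#' @param membrane_width_um Width of the plasma-membrane band
#'   (micrometers). Default 0.5.
#' @return List with `P1`, `P2`, `ratio`.
#' @export
membrane_cytosol_ratio <- function(img, membrane_width_um = 0.5) {
  stopifnot(inherits(img, "cell_image"))
  if (membrane_width_um <= 0) stop("membrane_width_um must be > 0")
  dist_px <- EBImage::distmap(img$mask)
  width_px <- membrane_width_um / img$pixel_size_um
  band <- img$mask > 0 & dist_px <= width_px
  interior <- img$mask > 0 & dist_px > width_px
  if (!any(interior))
    stop("no cytosolic interior remains after removing the membrane band")
  P1 <- mean(img$intensity[band])
  P2 <- mean(img$intensity[interior])
  list(P1 = P1, P2 = P2, ratio = P1 / P2)
}
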