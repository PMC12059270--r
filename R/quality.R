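#' Signal statistics within an ROI
#'
#' @param volume 3D numeric array
#' @param roi_mask logical 3D array, non-empty
#' @param label ROI label ("tumor", "muscle" or "background")
#' @return an `roi_stats` list with `si` (mean signal), `sd` (standard
#'   deviation within the ROI), `n_voxels`, `label`
#' @export
roi_stats <- function(volume, roi_mask, label = "tumor") {
  assert_that(any(roi_mask), "ROI mask is empty")
  v <- volume[roi_mask]
  structure(list(si = mean(v), sd = if (length(v) > 1) sd(v) else 0,
                 n_voxels = length(v), label = label),
            class = "roi_stats")
}

#' Triplicate ROI measurement with optional jitter
#'
#' Emulates repeated manual outlining: the ROI is measured `repeats` times,
#' each time translated by a random integer offset of up to `jitter` voxels
#' per axis, and the signal statistics are averaged. `jitter = 0` reduces to
#' a single measurement.
#'
#' @inheritParams roi_stats
#' @param repeats number of repeated measurements
#' @param jitter maximum per-axis translation in voxels
#' @param seed RNG seed
#' @return an `roi_stats` list of averaged statistics
#' @export
measure_roi_stats <- function(volume, roi_mask, repeats = 3, jitter = 0,
                              seed = 1L, label = "tumor") {
  assert_that(any(roi_mask), "ROI mask is empty")
  if (jitter == 0) {
    s <- roi_stats(volume, roi_mask, label)
    return(s)
  }
  dims <- dim(roi_mask)
  idx <- which(roi_mask, arr.ind = TRUE)
  sis <- sds <- ns <- numeric(repeats)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      off <- sample(seq(-jitter, jitter), 3, replace = TRUE)
      shifted <- sweep(idx, 2, off, "+")
      keep <- shifted[, 1] >= 1 & shifted[, 1] <= dims[1] &
        shifted[, 2] >= 1 & shifted[, 2] <= dims[2] &
        shifted[, 3] >= 1 & shifted[, 3] <= dims[3]
      shifted <- shifted[keep, , drop = FALSE]
      if (nrow(shifted) == 0) stop("ROI empty after jitter", call. = FALSE)
      m <- array(FALSE, dim = dims)
      m[shifted] <- TRUE
      s <- roi_stats(volume, m, label)
      sis[r] <- s$si; sds[r] <- s$sd; ns[r] <- s$n_voxels
    }
  })
  structure(list(si = mean(sis), sd = mean(sds),
                 n_voxels = round(mean(ns)), label = label),
            class = "roi_stats")
}

#' Signal-to-noise ratio of a lesion ROI
#'
#' SNR = SI_tumor / SD_tumor, where SD is the standard deviation within the
#' lesion ROI itself.
#'
#' @param tumor an [roi_stats()]
#' @return SNR value
#' @export
snr <- function(tumor) {
  assert_that(tumor$sd > 0, "SNR undefined: ROI standard deviation is zero")
  tumor$si / tumor$sd
}

#' Contrast-to-noise ratio between lesion and reference tissue
#'
#' CNR = (SI_tumor - SI_muscle) / sqrt(SD_tumor^2 + SD_muscle^2).
#'
#' @param tumor,muscle [roi_stats()] for the two ROIs
#' @return CNR value
#' @export
cnr <- function(tumor, muscle) {
  denom <- sqrt(tumor$sd^2 + muscle$sd^2)
  assert_that(denom > 0, "CNR undefined: both ROI standard deviations are zero")
  (tumor$si - muscle$si) / denom
}

#' Friedman test with Dunn-Bonferroni post hoc across the three sequences
#'
#' Takes per-subject values of one quality metric under S1, S2 and S3,
#' runs the Friedman rank test, and performs Dunn's pairwise z-tests on the
#' mean within-subject ranks with a Bonferroni factor of 3 (adjusted p capped
#' at 1). Subjects with missing cells are dropped with a message.
#'
#' @param tbl data frame with columns `subject_id`, `sequence`, `value`
#' @return list with `friedman_chisq`, `friedman_p`, and a `pairwise` data
#'   frame (pairs S1-S2, S2-S3, S1-S3 with z and Bonferroni-adjusted p)
#' @export
compare_quality <- function(tbl) {
  assert_that(all(c("subject_id", "sequence", "value") %in% names(tbl)),
              "tbl needs columns subject_id, sequence, value")
  seqs <- c("S1", "S2", "S3")
  wide <- tapply(tbl$value, list(tbl$subject_id, tbl$sequence), mean)
  assert_that(all(seqs %in% colnames(wide)), "all three sequences are required")
  wide <- wide[, seqs, drop = FALSE]
  complete <- stats::complete.cases(wide)
  if (!all(complete)) {
    message(sum(!complete), " subject(s) dropped for missing sequences")
    wide <- wide[complete, , drop = FALSE]
  }
  n <- nrow(wide)
  assert_that(n >= 3, "need at least 3 complete subjects")
  ft <- friedman.test(as.matrix(wide))
  if (is.nan(ft$statistic)) {
    # all within-subject ranks tied: no condition effect by construction
    ft$statistic[] <- 0
    ft$p.value <- 1
  }
  ranks <- t(apply(wide, 1, rank))
  mean_ranks <- colMeans(ranks)
  k <- 3
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- list(c("S1", "S2"), c("S2", "S3"), c("S1", "S3"))
  pw <- data.frame(
    pair = vapply(pairs, paste, "", collapse = "-"),
    z = vapply(pairs, function(p) {
      (mean_ranks[p[1]] - mean_ranks[p[2]]) / se
    }, 0),
    stringsAsFactors = FALSE
  )
  pw$p_adj <- pmin(2 * pnorm(-abs(pw$z)) * length(pairs), 1)
  list(friedman_chisq = unname(ft$statistic), friedman_p = ft$p.value,
       pairwise = pw)
}
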