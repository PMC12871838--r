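## End-to-end orchestration: volume -> contours -> splines -> ellipse fits
## -> per-object summaries -> gated group statistics, with per-object
## failure isolation, a run manifest, and deterministic per-object seeds.

#' Build a morphometrics run configuration
#'
#' Defaults follow the analysis constants of the pipeline: arc-length
#' filter 50 px, 200 spline samples, 500 bootstrap iterations, seed 42,
#' normality alpha 0.05, strict (>) confidence thresholds. Every value is
#' recorded in the run manifest.
#'
#' @param minArcPx arc-length retention threshold (px).
#' @param nSamples spline samples per contour.
#' @param nBoot bootstrap iterations.
#' @param seed master seed; per-object seeds derive deterministically as
#'   seed + object label.
#' @param alpha normality-gate level for group comparisons.
#' @param excludeLowConfidence drop Low-tier objects from comparisons?
#' @param strictThresholds strict reading of the arc-length boundary.
#' @return list of class "lysoMorphConfig".
#' @export
morphometricsConfig <- function(minArcPx = 50, nSamples = 200L,
                                nBoot = 500L, seed = 42L, alpha = 0.05,
                                excludeLowConfidence = FALSE,
                                strictThresholds = TRUE) {
  structure(list(minArcPx = minArcPx, nSamples = nSamples, nBoot = nBoot,
                 seed = seed, alpha = alpha,
                 excludeLowConfidence = excludeLowConfidence,
                 strictThresholds = strictThresholds),
            class = "lysoMorphConfig")
}

.slice_record <- function(label, z, reason) {
  data.frame(object_label = label, z_index = z, n_points = NA_integer_,
             arc_length_px = NA_real_, perimeter_px = NA_real_,
             bbox_w = NA_real_, bbox_h = NA_real_,
             aspect_ratio = NA_real_, centroid_x = NA_real_,
             centroid_y = NA_real_, abs_mean_kappa = NA_real_,
             abs_max_kappa = NA_real_, a = NA_real_, b = NA_real_,
             r_squared = NA_real_, rmse_px = NA_real_,
             was_closed = NA, retained = FALSE, rejection_reason = reason)
}

.process_slice <- function(mask, z, label, config) {
  skel <- skeletonizeSlice(mask)
  if (isTRUE(attr(skel, "empty")))
    return(.slice_record(label, z, "empty_mask"))
  if (sum(skel) <= 3L)
    return(.slice_record(label, z, "too_short"))
  contour <- withCallingHandlers(
    orderSkeletonPoints(skel, zIndex = z),
    warning = function(w) invokeRestart("muffleWarning"))
  spline <- tryCatch(fitContourSpline(contour, nSamples = config$nSamples),
                     lysoContourTooShort = function(e) NULL)
  if (is.null(spline))
    return(.slice_record(label, z, "too_short"))
  metrics <- sliceShapeMetrics(spline)
  curv <- signedCurvature(spline)
  retained <- passesLengthFilter(spline, config$minArcPx,
                                 strict = config$strictThresholds)
  rec <- data.frame(object_label = label, z_index = z,
                    n_points = nrow(contourPoints(contour)),
                    arc_length_px = arcLength(spline), metrics,
                    abs_mean_kappa = curv@absMean,
                    abs_max_kappa = curv@absMax,
                    a = NA_real_, b = NA_real_, r_squared = NA_real_,
                    rmse_px = NA_real_, was_closed = wasClosed(contour),
                    retained = retained,
                    rejection_reason = if (retained) "" else "arc_too_short")
  if (!retained) return(rec)
  fit <- tryCatch(fitEllipse(splineSamples(spline)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    rec$retained <- FALSE
    rec$rejection_reason <- "ellipse_fit_failed"
    return(rec)
  }
  rec$a <- fit@params@a; rec$b <- fit@params@b
  rec$r_squared <- rSquared(fit); rec$rmse_px <- rmse(fit)
  attr(rec, "spline") <- spline
  rec
}

#' Run the slice-wise morphometrics pipeline over a labeled volume
#'
#' For each object label: slices are extracted, thinned to centerlines,
#' ordered as open arcs, spline-fit, filtered by arc length, ellipse-fit
#' (two-stage), bootstrapped (on the median retained slice's spline
#' samples) and aggregated into a per-object summary. A failure on one
#' object drops that object with a reason and never aborts the run. The
#' manifest records parameters, seed and per-object disposition.
#'
#' @param vol a [LabeledVolume-class]
#' @param config a [morphometricsConfig()] list.
#' @return list(slices = per-slice data.frame, objects = per-object
#'   data.frame, manifest = list).
#' @export
runMorphometrics <- function(vol, config = morphometricsConfig()) {
  stopifnot(is(vol, "LabeledVolume"))
  labels <- objectLabels(vol)
  sliceRows <- list()
  objRows <- list()
  events <- list()
  for (label in labels) {
    res <- tryCatch({
      stack <- extractObjectSlices(vol, label)
      recs <- list()
      splinesByRow <- list()
      for (s in slices(stack)) {
        rec <- .process_slice(s$mask, s$z, label, config)
        splinesByRow[[length(recs) + 1L]] <- attr(rec, "spline")
        attr(rec, "spline") <- NULL
        recs[[length(recs) + 1L]] <- rec
      }
      sliceTab <- do.call(rbind, recs)
      valid <- sliceTab[sliceTab$retained & !is.na(sliceTab$a), ,
                        drop = FALSE]
      if (nrow(valid) == 0L)
        stop("no valid slice fits")
      summary <- summarizeObject(valid, zExtent(stack), voxelSize(vol),
                                 objectLabel = label,
                                 excludeLow = config$excludeLowConfidence)
      ## bootstrap CI on the median retained slice (by arc length rank)
      medRow <- order(valid$z_index)[ceiling(nrow(valid) / 2)]
      medZ <- valid$z_index[medRow]
      medIdx <- which(sliceTab$z_index == medZ)
      medSpline <- splinesByRow[[medIdx]]
      ci <- bootstrapEllipseCI(splineSamples(medSpline),
                               nBoot = config$nBoot,
                               seed = (config$seed + label) %% .Machine$integer.max)
      summary$a_ci_lo <- ci@loA; summary$a_ci_hi <- ci@hiA
      summary$b_ci_lo <- ci@loB; summary$b_ci_hi <- ci@hiB
      summary$ci_slice_z <- medZ
      summary$seed <- config$seed
      summary$n_boot <- config$nBoot
      list(sliceTab = sliceTab, summary = summary,
           event = list(label = label, status = "retained"))
    }, error = function(e) {
      list(sliceTab = NULL, summary = NULL,
           event = list(label = label, status = "dropped",
                        reason = conditionMessage(e)))
    })
    if (!is.null(res$sliceTab))
      sliceRows[[length(sliceRows) + 1L]] <- res$sliceTab
    if (!is.null(res$summary))
      objRows[[length(objRows) + 1L]] <- res$summary
    events[[length(events) + 1L]] <- res$event
  }
  if (!length(labels))
    warning("volume has no labeled objects")
  list(slices = if (length(sliceRows)) do.call(rbind, sliceRows)
         else .slice_record(NA_integer_, NA_integer_, "no_objects")[0, ],
       objects = if (length(objRows)) do.call(rbind, objRows)
         else NULL,
       manifest = list(parameters = unclass(config),
                       voxel_size_nm = voxelSize(vol),
                       inplane_isotropic_assumed = TRUE,
                       n_labels = length(labels), events = events,
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

#' Gated group comparisons over per-object summaries
#'
#' For each morphometric metric and each pair of conditions, runs the
#' normality-gated two-sample comparison with Cohen's d; p-values are
#' Benjamini-Hochberg adjusted within each condition pair (the metric
#' family). Low-confidence objects are excluded when the config says so.
#'
#' @param objects per-object data.frame from [runMorphometrics()].
#' @param conditions character/factor vector, one condition per object row.
#' @param config a [morphometricsConfig()] list.
#' @param metrics metric columns to compare.
#' @return data.frame, one row per (condition pair, metric).
#' @export
runComparison <- function(objects, conditions,
                          config = morphometricsConfig(),
                          metrics = c("mean_ellipse_area_nm2",
                                      "mean_perimeter_nm",
                                      "equivalent_diameter_nm")) {
  stopifnot(nrow(objects) == length(conditions))
  keep <- if (config$excludeLowConfidence)
    objects$confidence != "Low" else rep(TRUE, nrow(objects))
  objects <- objects[keep, , drop = FALSE]
  conditions <- as.character(conditions)[keep]
  levs <- unique(conditions)
  if (length(levs) < 2L) stop("need >= 2 conditions")
  out <- list()
  for (i in seq_len(length(levs) - 1L)) for (j in (i + 1L):length(levs)) {
    rows <- list()
    for (m in metrics) {
      x <- objects[conditions == levs[i], m]
      y <- objects[conditions == levs[j], m]
      cmp <- tryCatch(compareGroups(x, y, alpha = config$alpha,
                                    metricName = m),
                      error = function(e) NULL)
      if (is.null(cmp)) {
        rows[[m]] <- data.frame(metric = m, n1 = length(x),
                                n2 = length(y), normal1 = NA, normal2 = NA,
                                test_used = NA_character_,
                                statistic = NA_real_, p_value = NA_real_,
                                p_adjusted = NA_real_, cohens_d = NA_real_)
      } else {
        rows[[m]] <- as.data.frame(cmp)
      }
    }
    fam <- do.call(rbind, rows)
    ok <- !is.na(fam$p_value)
    fam$p_adjusted[ok] <- bhAdjust(fam$p_value[ok])
    fam <- cbind(condition_a = levs[i], condition_b = levs[j], fam)
    out[[length(out) + 1L]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
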