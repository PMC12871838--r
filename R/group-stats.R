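## Normality-gated two-sample comparisons, effect sizes, FDR correction
## and the liposome leakage normalization.

#' Cohen's d effect size
#'
#' (mean(x) - mean(y)) / pooled SD, with the standard pooled-variance
#' formula sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)). Undefined
#' (NA) when the pooled SD is zero.
#'
#' @param x,y numeric samples, n >= 2 each.
#' @return numeric(1)
#' @export
cohensD <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2)
}

.is_normal <- function(x, alpha) {
  ## Shapiro-Wilk is defined for 3..5000 observations; larger samples are
  ## thinned to 5000 evenly spaced order statistics (deterministic).
  if (length(unique(x)) < 3L) return(FALSE)
  if (length(x) > 5000L)
    x <- sort(x)[round(seq(1, length(x), length.out = 5000L))]
  p <- tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  !is.na(p) && p > alpha
}

#' Normality-gated two-sample comparison
#'
#' Shapiro-Wilk normality is tested on each group at `alpha` (default
#' 0.05). If both groups pass, a two-sided Welch t-test is used; otherwise
#' a two-sided Mann-Whitney U test. Cohen's d is always reported.
#'
#' @param x,y numeric samples with n >= 3 each.
#' @param alpha normality test level (default 0.05).
#' @param metricName label carried into the result.
#' @return a [GroupComparison-class]
#' @export
compareGroups <- function(x, y, alpha = 0.05, metricName = "") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3L || length(y) < 3L)
    stop("comparison refused: need n >= 3 per group (got ",
         length(x), ", ", length(y), ")")
  norm1 <- .is_normal(x, alpha)
  norm2 <- .is_normal(y, alpha)
  if (norm1 && norm2) {
    tt <- t.test(x, y, var.equal = FALSE)
    used <- "t"; stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    used <- "mann_whitney"; stat <- unname(wt$statistic); p <- wt$p.value
  }
  new("GroupComparison", metricName = metricName,
      n1 = length(x), n2 = length(y), normal1 = norm1, normal2 = norm2,
      alpha = alpha, testUsed = used, statistic = stat, pValue = p,
      pAdjusted = NA_real_, cohensD = cohensD(x, y))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (monotone, clipped at 1), preserving
#' input order.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pValues) {
  p <- as.numeric(pValues)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Liposome leakage percentage
#'
#' Leakage(%) = (F_sample - F_control) / (F_Triton - F_control) * 100,
#' where the Triton X-100 trace defines maximum (100%) leakage and the
#' liposome-alone trace the no-leakage control. Time series are handled
#' pointwise; values outside [0, 100] are reported raw (not clipped).
#'
#' @param fSample,fControl,fTriton fluorescence values (arbitrary units),
#'   scalars or equal-length series (scalars recycle).
#' @return numeric leakage percentages.
#' @export
leakagePercent <- function(fSample, fControl, fTriton) {
  n <- max(length(fSample), length(fControl), length(fTriton))
  fSample <- rep_len(fSample, n)
  fControl <- rep_len(fControl, n)
  fTriton <- rep_len(fTriton, n)
  if (any(fTriton == fControl))
    stop("leakage undefined: detergent and control traces coincide")
  (fSample - fControl) / (fTriton - fControl) * 100
}

#' Read a plate-reader leakage trace and compute leakage percentages
#'
#' Expects a plain CSV with columns time, f_sample, f_control, f_triton.
#'
#' @param path CSV path.
#' @return the input data.frame with an added `leakage_percent` column.
#' @export
readLeakageCsv <- function(path) {
  d <- read.csv(path)
  need <- c("time", "f_sample", "f_control", "f_triton")
  if (!all(need %in% names(d)))
    stop("leakage CSV needs columns: ", paste(need, collapse = ", "))
  d$leakage_percent <- leakagePercent(d$f_sample, d$f_control, d$f_triton)
  d
}
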