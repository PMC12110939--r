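#' @include pattern.R
NULL

#' Welch comparison of VBS between two groups
#'
#' Independent-samples comparison of per-pair VBS values with unequal
#' variances assumed (Welch t, Welch--Satterthwaite degrees of freedom,
#' 95 percent confidence interval of the mean difference). The Welch flavor
#' reduces to the classical pooled test under equal variances and is the
#' safer default when only "independent samples t-test" is specified.
#'
#' @param a,b numeric vectors of VBS values (um), each of length >= 2, all
#'   finite. Groups that are both constant (zero variance) are refused.
#' @param names length-2 character, group names for display.
#' @return a [GroupComparison-class].
#' @examples
#' compareGroups(c(5, 6, 7), c(10, 12, 11))
#' @export
compareGroups <- function(a, b, names = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop(sprintf("each group needs n >= 2 (got %d and %d)",
                 length(a), length(b)))
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("all VBS values must be finite")
  }
  if (stats::var(a) + stats::var(b) == 0) {
    stop("both groups have zero variance; the t statistic is undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, conf.level = 0.95)
  new("GroupComparison",
      mean = stats::setNames(c(mean(a), mean(b)), names),
      sd = stats::setNames(c(stats::sd(a), stats::sd(b)), names),
      n = stats::setNames(c(length(a), length(b)), names),
      diff = mean(a) - mean(b),
      confInt = as.numeric(tt$conf.int),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      pValue = tt$p.value)
}

#' Threshold sweep of screening performance
#'
#' For each VBS threshold, a pair is called positive iff its VBS strictly
#' exceeds the threshold. Reports confusion counts and sensitivity,
#' specificity, PPV and NPV per threshold; rates with an empty denominator
#' (e.g. PPV when nothing is called positive) are \code{NA}, never 0 or 1.
#' The rows double as an ROC point list: sensitivity is non-increasing and
#' specificity non-decreasing in the threshold.
#'
#' @param values numeric VBS values, one per eye pair.
#' @param labels diagnosis labels, same length; character/factor (compared
#'   against \code{positive}) or logical.
#' @param thresholds numeric thresholds to sweep (um).
#' @param positive the label counted as disease (default
#'   \code{"keratoconus"}).
#' @return data.frame with columns \code{threshold_um, TP, FP, TN, FN,
#'   sensitivity, specificity, ppv, npv}.
#' @examples
#' screenThresholds(c(5, 12), c("normal", "keratoconus"), 11.3)
#' @export
screenThresholds <- function(values, labels, thresholds,
                             positive = "keratoconus") {
  values <- as.numeric(values)
  if (length(values) != length(labels)) {
    stop(sprintf("values (%d) and labels (%d) differ in length",
                 length(values), length(labels)))
  }
  truth <- if (is.logical(labels)) labels else tolower(as.character(labels)) == tolower(positive)
  if (all(truth) || !any(truth)) {
    stop("labels contain a single class; screening rates are undefined")
  }
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- do.call(rbind, lapply(thresholds, function(th) {
    pred <- values > th
    TP <- sum(pred & truth); FP <- sum(pred & !truth)
    TN <- sum(!pred & !truth); FN <- sum(!pred & truth)
    data.frame(threshold_um = th, TP = TP, FP = FP, TN = TN, FN = FN,
               sensitivity = rate(TP, TP + FN),
               specificity = rate(TN, TN + FP),
               ppv = rate(TP, TP + FP), npv = rate(TN, TN + FN))
  }))
  rownames(out) <- NULL
  out
}

setMethod("show", "GroupComparison", function(object) {
  cat("GroupComparison (Welch)\n")
  for (k in 1:2) {
    cat(sprintf("  %s: mean %.3f um, sd %.3f, n %d\n",
                names(object@mean)[k], object@mean[k], object@sd[k],
                object@n[k]))
  }
  cat(sprintf("  difference %.3f um, 95%% CI [%.3f, %.3f]\n",
              object@diff, object@confInt[1], object@confInt[2]))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3g\n",
              object@statistic, object@df, object@pValue))
})
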