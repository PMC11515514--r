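# Regression and calibration metrics: R^2, NLPD, relative error,
# confidence-percentile analysis, calibration correlation and
# applicability-domain bucketing by Tanimoto distance to the training set.

#' Coefficient of determination
#'
#' \code{1 - SS_res / SS_tot}.
#'
#' @param y observed labels (at least 2, non-constant).
#' @param yHat predictions.
#' @return scalar R^2.
#' @export
rSquared <- function(y, yHat) {
    if (length(y) != length(yHat)) stop("y and yHat lengths differ")
    if (length(y) < 2L) stop("need at least 2 points")
    ssTot <- sum((y - mean(y))^2)
    if (ssTot == 0) stop("y is constant: R^2 undefined")
    1 - sum((y - yHat)^2) / ssTot
}

#' Negative log predictive density (per point)
#'
#' Mean over targets of \code{-log N(y_j; mu_j, sigma2_j)}; lower is
#' better. The per-point convention makes values comparable across target
#' set sizes.
#'
#' @param pred a \linkS4class{PredictiveGaussian}.
#' @param y observed labels.
#' @return scalar NLPD.
#' @export
nlpd <- function(pred, y) {
    if (length(y) != length(predMean(pred)))
        stop("prediction and label lengths differ")
    -logPredictiveDensity(pred, y) / length(y)
}

#' Relative error in percent
#'
#' \code{|(y - yHat) / y| * 100} per point. Points with y == 0 are excluded
#' with a warning (the ratio is undefined there); for probabilistic models
#' pass the predictive mean as \code{yHat}.
#'
#' @param y observed labels.
#' @param yHat predictions (or predictive means).
#' @return numeric vector of relative errors for the points with y != 0,
#'   with the surviving indices as names.
#' @export
relativeError <- function(y, yHat) {
    if (length(y) != length(yHat)) stop("y and yHat lengths differ")
    keep <- y != 0
    if (any(!keep))
        warning(sum(!keep), " point(s) with y = 0 excluded from relative error")
    re <- abs((y[keep] - yHat[keep]) / y[keep]) * 100
    names(re) <- which(keep)
    re
}

#' Group targets into confidence percentiles
#'
#' Ranks target points by predicted variance, ascending (most confident
#' first; ties broken by stable original index), partitions them into
#' \code{nGroups} equal groups (the last group absorbs any remainder) and
#' computes the mean squared error and mean predicted variance per group.
#'
#' @param pred a \linkS4class{PredictiveGaussian}.
#' @param y observed labels.
#' @param nGroups number of percentile groups (default 100; with 2500
#'   targets this gives groups of 25).
#' @return data frame with columns \code{group}, \code{size}, \code{mse},
#'   \code{meanVariance}, ordered by ascending predicted variance.
#' @export
confidencePercentiles <- function(pred, y, nGroups = 100L) {
    mu <- predMean(pred); v <- predVar(pred)
    if (length(y) != length(mu)) stop("prediction and label lengths differ")
    Tn <- length(y)
    if (Tn < nGroups) stop("need at least nGroups target points")
    ord <- order(v)                       # stable in R: ties keep input order
    sq <- (y - mu)^2
    size <- Tn %/% nGroups
    grp <- pmin(((seq_len(Tn) - 1L) %/% size) + 1L, nGroups)
    data.frame(group = seq_len(nGroups),
               size = as.integer(tabulate(grp, nGroups)),
               mse = as.numeric(tapply(sq[ord], grp, mean)),
               meanVariance = as.numeric(tapply(v[ord], grp, mean)))
}

#' Calibration correlation across confidence percentiles
#'
#' Pearson correlation between log mean MSE and log mean predicted variance
#' across percentile groups. A well-calibrated model shows a strong
#' positive correlation (predicted uncertainty tracks realized error).
#' Groups with non-positive mean MSE or variance are dropped with a warning
#' (their logarithm is undefined).
#'
#' @param summary the data frame returned by
#'   \code{\link{confidencePercentiles}}.
#' @return scalar Pearson correlation.
#' @export
calibrationCorrelation <- function(summary) {
    keep <- summary$mse > 0 & summary$meanVariance > 0
    if (any(!keep))
        warning(sum(!keep), " group(s) with non-positive mean dropped")
    if (sum(keep) < 3L) stop("need at least 3 usable groups")
    stats::cor(log(summary$mse[keep]), log(summary$meanVariance[keep]))
}

#' Applicability-domain buckets by Tanimoto distance
#'
#' Assigns each test molecule to one of 20 buckets of Tanimoto distance
#' (1 - similarity to its closest training neighbour), each bucket covering
#' a 0.05-wide interval of [0, 1] (half-open, the last bucket closed at 1),
#' and summarizes the distribution of relative errors within each bucket.
#'
#' @param testFps test-set fingerprints (\linkS4class{Fingerprints} or
#'   binary matrix).
#' @param trainFps nonempty training-set fingerprints.
#' @param predictions predicted values (means for probabilistic models),
#'   one per test molecule.
#' @param labels observed values, one per test molecule.
#' @return list with \code{buckets} (data frame: bucket, lower, upper,
#'   count, and quartiles of the relative-error distribution) and
#'   \code{perMolecule} (distance, bucket and relative error per molecule
#'   with y != 0).
#' @export
adBuckets <- function(testFps, trainFps, predictions, labels) {
    d <- 1 - maxSimilarityToReference(testFps, trainFps)
    if (length(labels) != length(d) || length(predictions) != length(d))
        stop("predictions/labels must align with the test fingerprints")
    re <- relativeError(labels, predictions)
    keep <- as.integer(names(re))
    d <- d[keep]
    bucket <- as.integer(pmin(floor(d / 0.05), 19)) + 1L  # last bucket closed at 1.0
    per <- data.frame(index = keep, distance = d, bucket = bucket,
                      relativeError = as.numeric(re))
    qs <- function(b, p) if (any(bucket == b))
        stats::quantile(re[bucket == b], p, names = FALSE) else NA_real_
    buckets <- data.frame(
        bucket = 1:20,
        lower = (0:19) * 0.05, upper = (1:20) * 0.05,
        count = as.integer(tabulate(bucket, 20)),
        q25 = vapply(1:20, qs, numeric(1), p = 0.25),
        median = vapply(1:20, qs, numeric(1), p = 0.5),
        q75 = vapply(1:20, qs, numeric(1), p = 0.75))
    list(buckets = buckets, perMolecule = per)
}

#' Write a metric report as TSV
#' @param report a data frame (e.g. from \code{\link{confidencePercentiles}}
#'   or \code{\link{adBuckets}}\code{$buckets}).
#' @param path output path.
#' @export
writeMetricReport <- function(report, path) {
    utils::write.table(report, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}
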