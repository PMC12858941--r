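# Pooled cross-validation scoring and variant comparison.

#' Score pooled observed-vs-predicted pairs
#'
#' Pearson r, RMSE, nRMSE (RMSE normalized by the observed range by
#' default; by mean or IQR selectable) and R^2 = 1 - SSE/SST, pooled and per
#' stratum. A zero observed range leaves nRMSE undefined (NA with a
#' warning).
#'
#' @param observed,predicted equal-length finite numeric vectors (n >= 2).
#' @param strata optional stratum id per pair for per-stratum breakdowns.
#' @param normalization nRMSE denominator: \code{"range"} (default),
#'   \code{"mean"} (absolute mean) or \code{"iqr"}.
#' @return list of class \code{metricsReport}: \code{r}, \code{rmse},
#'   \code{nrmse}, \code{r2}, \code{n}, \code{normalization},
#'   \code{perStratum} (data.frame).
#' @export
computeMetrics <- function(observed, predicted, strata = NULL,
                           normalization = c("range", "mean", "iqr")) {
  normalization <- match.arg(normalization)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) < 2L) stop("need n >= 2 pairs", call. = FALSE)
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("non-finite values in inputs", call. = FALSE)
  }
  one <- function(o, p) {
    rmse <- sqrt(mean((o - p)^2))
    denom <- switch(normalization,
                    range = diff(range(o)),
                    mean = abs(mean(o)),
                    iqr = diff(quantile(o, c(0.25, 0.75), names = FALSE)))
    nrmse <- if (denom > 0) rmse / denom else NA_real_
    sst <- sum((o - mean(o))^2)
    list(r = if (sd(o) > 0 && sd(p) > 0) cor(o, p) else NA_real_,
         rmse = rmse, nrmse = nrmse,
         r2 = if (sst > 0) 1 - sum((o - p)^2) / sst else NA_real_,
         n = length(o))
  }
  pooled <- one(observed, predicted)
  if (is.na(pooled$nrmse)) {
    warning("zero observed ", normalization, ": nRMSE undefined", call. = FALSE)
  }
  per <- NULL
  if (!is.null(strata)) {
    keep <- !is.na(strata)
    per <- do.call(rbind, lapply(split(which(keep), strata[keep]), function(idx) {
      if (length(idx) < 2L) return(NULL)
      m <- one(observed[idx], predicted[idx])
      data.frame(stratum = strata[idx[1]], r = m$r, rmse = m$rmse,
                 nrmse = m$nrmse, r2 = m$r2, n = m$n)
    }))
    if (!is.null(per)) rownames(per) <- NULL
  }
  structure(c(pooled, list(normalization = normalization, perStratum = per)),
            class = "metricsReport")
}

#' @export
print.metricsReport <- function(x, ...) {
  cat(sprintf("Metrics (n = %d): r = %.4f, nRMSE = %.4f (%s), R2 = %.4f\n",
              x$n, x$r, x$nrmse, x$normalization, x$r2))
  invisible(x)
}

#' Compare model variants across trait data subsets
#'
#' Deltas of r, nRMSE, mean COV and percent-inside-AOA between subset pairs
#' (COMB - SCI and COMB - CIT where present).
#'
#' @param reports named list of \code{metricsReport}s keyed by subset
#'   (e.g. SCI, CIT, COMB), all for the same trait and resolution.
#' @param products optional named list of [UncertaintyProduct-class]s keyed
#'   the same way.
#' @return data.frame with one row per compared pair.
#' @export
compareVariants <- function(reports, products = NULL) {
  if (!"COMB" %in% names(reports)) {
    stop("comparison requires a COMB report", call. = FALSE)
  }
  others <- intersect(c("SCI", "CIT"), names(reports))
  if (length(others) == 0L) stop("nothing to compare against COMB", call. = FALSE)
  rows <- lapply(others, function(s) {
    covDelta <- aoaDelta <- NA_real_
    if (!is.null(products) && all(c("COMB", s) %in% names(products))) {
      covDelta <- mean(products$COMB@cov, na.rm = TRUE) -
        mean(products[[s]]@cov, na.rm = TRUE)
      aoaDelta <- products$COMB@pctInsideAOA - products[[s]]@pctInsideAOA
    }
    data.frame(pair = paste0("COMB-", s),
               deltaR = reports$COMB$r - reports[[s]]$r,
               deltaNRMSE = reports$COMB$nrmse - reports[[s]]$nrmse,
               deltaMeanCOV = covDelta, deltaPctAOA = aoaDelta,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
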