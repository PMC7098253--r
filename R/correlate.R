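# Spatial (inter-electrode distance) and temporal (inter-signal)
# correlation analyses of processed feature time series.

#' Pairwise channel correlation versus inter-electrode distance
#'
#' For every unordered channel pair of a standardized feature series,
#' computes the absolute Pearson correlation of the two channels' time
#' series and pairs it with their inter-electrode distance. Zero-variance
#' channels are excluded (with a message).
#'
#' @param series A [feature_series()] at stage `"standardized"` (the
#'   decoder-input representation) with at least 2 channels, or a
#'   `feature_extract`.
#' @param geometry An [array_geometry()] covering the series' channels.
#' @return A data frame of class `distance_correlation` with columns
#'   `channel_a`, `channel_b`, `distance_mm`, `abs_r`.
#' @export
spatial_correlation <- function(series, geometry) {
  if (inherits(series, "feature_extract")) series <- series$series
  .check_stage(series, "standardized", "spatial_correlation")
  v <- series$values
  if (ncol(v) < 2) stop("need at least 2 channels")
  ids <- series$channel_ids
  keep <- apply(v, 2, function(x) stats::var(x) > 0)
  if (!all(keep)) {
    message("excluding zero-variance channel(s): ",
            paste(ids[!keep], collapse = ", "))
    v <- v[, keep, drop = FALSE]; ids <- ids[keep]
  }
  d <- pairwise_distances(geometry, ids)
  r <- abs(cor(v))
  ut <- upper.tri(r)
  idx <- which(ut, arr.ind = TRUE)
  out <- data.frame(channel_a = ids[idx[, 1]], channel_b = ids[idx[, 2]],
                    distance_mm = d[ut], abs_r = r[ut])
  class(out) <- c("distance_correlation", "data.frame")
  out
}

#' Polynomial summary of correlation versus distance
#'
#' Least-squares 3rd-order polynomial fit of `abs_r` against distance, the
#' standard summary curve for distance-correlation profiles.
#'
#' @param tbl A [spatial_correlation()] table.
#' @param degree Polynomial degree (default 3).
#' @return List with the `lm` fit, its `coefficients`, and `predict(d)`,
#'   a function evaluating the fitted curve.
#' @export
distance_profile <- function(tbl, degree = 3) {
  fit <- lm(abs_r ~ poly(distance_mm, degree, raw = TRUE), data = tbl)
  list(fit = fit, coefficients = coef(fit),
       predict = function(d)
         predict(fit, newdata = data.frame(distance_mm = d)))
}

#' Inter-signal correlation matrix across feature kinds
#'
#' For each day and each pair of feature kinds, computes the mean over
#' channels of the absolute Pearson correlation between the two kinds'
#' same-channel time series; the overall matrix averages the per-day
#' matrices. All series of a day must share bins and channels.
#'
#' @param days List with one element per day; each element is a named list
#'   mapping feature kind to a [feature_series()] (or `feature_extract`).
#' @return An object of class `inter_signal_correlation`: `matrix` (kinds x
#'   kinds mean absolute correlation, symmetric, unit diagonal), `per_day`
#'   (kinds x kinds x days array) and `kinds`.
#' @export
inter_signal_correlation <- function(days) {
  if (length(days) == 0) stop("no days supplied")
  as_mat <- function(s) {
    if (inherits(s, "feature_extract")) s <- s$series
    if (inherits(s, "feature_series")) s$values else s
  }
  kinds <- names(days[[1]])
  if (is.null(kinds)) stop("each day must be a named list of feature kinds")
  K <- length(kinds)
  per_day <- array(NA_real_, c(K, K, length(days)),
                   dimnames = list(kinds, kinds, NULL))
  for (di in seq_along(days)) {
    mats <- lapply(days[[di]][kinds], as_mat)
    dims <- vapply(mats, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all series of a day must share bin and channel counts")
    for (i in seq_len(K)) for (j in i:K) {
      rs <- vapply(seq_len(dims[2, 1]), function(ch) {
        suppressWarnings(abs(cor(mats[[i]][, ch], mats[[j]][, ch])))
      }, numeric(1))
      per_day[i, j, di] <- per_day[j, i, di] <- mean(rs, na.rm = TRUE)
    }
  }
  overall <- apply(per_day, c(1, 2), mean)
  diag(overall) <- 1
  structure(list(matrix = overall, per_day = per_day, kinds = kinds),
            class = "inter_signal_correlation")
}

#' @export
print.inter_signal_correlation <- function(x, ...) {
  cat(sprintf("<inter_signal_correlation> %d kinds, %d day(s)\n",
              length(x$kinds), dim(x$per_day)[3]))
  print(round(x$matrix, 3))
  invisible(x)
}
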