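#' Percentile-fence thresholds for outlier downweighting
#'
#' Computes the 10th and 90th sample percentiles of a variable and expands
#' them into a pair of fences,
#' \deqn{t_{low} = p_{10} - 1.5 (p_{90} - p_{10}), \quad
#'       t_{high} = p_{90} + 1.5 (p_{90} - p_{10}),}
#' outside which observations are smoothly downweighted by
#' [outlier_weight()]. Percentiles use linear interpolation between order
#' statistics (R's default `type = 7` convention); the convention matters
#' because p10/p90 definitions differ across software and is therefore fixed
#' and documented here.
#'
#' @param values numeric vector with at least 2 finite values.
#' @return An object of class `mnv_fences`: a list with elements `p10`,
#'   `p90`, `t_low`, `t_high` and a logical `degenerate` flag set when
#'   `p10 == p90` (all-equal or near-constant samples). Degenerate fences
#'   cause [outlier_weight()] to return weight 1 for every observation.
#' @seealso [outlier_weight()], [combine_weights()]
#' @examples
#' fence_thresholds(0:10)   # p10 = 1, p90 = 9, fences at -11 and 21
#' @export
fence_thresholds <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("fence_thresholds() needs at least 2 finite values", call. = FALSE)
  }
  qs <- stats::quantile(values, c(0.1, 0.9), type = 7, names = FALSE)
  p10 <- qs[1L]
  p90 <- qs[2L]
  spread <- p90 - p10
  structure(
    list(
      p10 = p10, p90 = p90,
      t_low = p10 - 1.5 * spread,
      t_high = p90 + 1.5 * spread,
      degenerate = (spread <= 0)
    ),
    class = "mnv_fences"
  )
}

#' @export
print.mnv_fences <- function(x, ...) {
  cat(sprintf(
    "percentile fences: p10 = %.4g, p90 = %.4g -> [%.4g, %.4g]%s\n",
    x$p10, x$p90, x$t_low, x$t_high,
    if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

#' Gaussian-kernel outlier weight relative to percentile fences
#'
#' Weight 1 inside the closed fence interval, smooth Gaussian decay outside:
#' \deqn{w(x) = \exp\left(-\tfrac12 \left(
#'   \frac{\max(0,\; t_{low}-x,\; x-t_{high})}{0.5\,(t_{high}-t_{low})}
#' \right)^2\right).}
#' The excess distance beyond the nearer fence is normalized by half the
#' fence width, so an observation half a fence-width beyond a fence receives
#' weight `exp(-0.5)`. The weight is continuous, symmetric in the two tails,
#' monotone non-increasing in the distance to the interval, and tends to 0
#' as `|x|` grows. This normalization is kept in one place so that an
#' alternative reading of the kernel is a single-line change.
#'
#' @param x numeric vector of observations.
#' @param fences an `mnv_fences` object from [fence_thresholds()].
#' @return numeric vector of weights in (0, 1].
#' @export
outlier_weight <- function(x, fences) {
  stopifnot(inherits(fences, "mnv_fences"))
  if (fences$degenerate) {
    warning("degenerate fences (p10 == p90); returning unit weights")
    return(rep(1, length(x)))
  }
  half_width <- 0.5 * (fences$t_high - fences$t_low)
  excess <- pmax(0, fences$t_low - x, x - fences$t_high)
  exp(-0.5 * (excess / half_width)^2)
}

#' Combine per-variable weights by geometric mean
#'
#' One observation typically carries one fence weight per variable involved
#' in a model (dependent, independent, confounder); the observation's
#' regression weight is their geometric mean. With no involved variables the
#' weight is 1.
#'
#' @param w numeric matrix (rows = observations, columns = variables) or a
#'   numeric vector treated as a single observation's per-variable weights.
#' @return numeric vector of combined weights, one per observation.
#' @export
combine_weights <- function(w) {
  if (is.null(dim(w))) {
    if (length(w) == 0L) return(1)
    w <- matrix(w, nrow = 1L)
  }
  if (ncol(w) == 0L) return(rep(1, nrow(w)))
  if (any(w <= 0 | w > 1, na.rm = TRUE)) {
    stop("weights must lie in (0, 1]", call. = FALSE)
  }
  out <- exp(rowMeans(log(w)))
  # geometric mean of values in (0,1] can pick up tiny fp excursions above 1
  pmin(out, 1)
}

#' Fence-based observation weights for a set of variables
#'
#' Convenience wrapper: computes fences per variable and returns the
#' geometric-mean combined weight per row, together with the fences used.
#'
#' @param data data.frame containing the variables.
#' @param vars character vector of column names entering the model.
#' @return list with `weights` (numeric, length `nrow(data)`) and `fences`
#'   (named list of `mnv_fences`).
#' @export
fence_weights <- function(data, vars) {
  stopifnot(is.data.frame(data), all(vars %in% names(data)))
  if (length(vars) == 0L) {
    return(list(weights = rep(1, nrow(data)), fences = list()))
  }
  fences <- lapply(vars, function(v) fence_thresholds(data[[v]]))
  names(fences) <- vars
  wm <- vapply(
    vars,
    function(v) {
      f <- fences[[v]]
      if (f$degenerate) rep(1, nrow(data)) else outlier_weight(data[[v]], f)
    },
    numeric(nrow(data))
  )
  if (nrow(data) == 1L) wm <- matrix(wm, nrow = 1L)
  list(weights = combine_weights(wm), fences = fences)
}
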