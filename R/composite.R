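## Robust smoothing and multi-tree compositing. The 21-year Tukey biweight
## mean serves two purposes: it emphasises the decadal/multi-decadal component
## of the proxy, and it absorbs both age-model error and the occasional rogue
## measurement by smoothly downweighting outliers.

#' Tukey biweight location of a sample
#'
#' Iteratively reweighted location estimate: starting from the median,
#' `M <- sum(w*x)/sum(w)` with `u = (x - M)/(c*S)`, `w = (1 - u^2)^2` for
#' `|u| < 1` and 0 otherwise, where `S` is the median absolute deviation from
#' the current `M` scaled by 1/0.6745. A zero MAD (a majority of identical
#' values) returns the median.
#'
#' @param x numeric values.
#' @param tuning_c biweight tuning constant (default 9).
#' @param max_iter maximum number of reweighting iterations (default 10).
#' @param tol stop early when the location moves by less than `tol`.
#' @return the biweight location (scalar).
#' @export
biweight_location <- function(x, tuning_c = 9, max_iter = 10, tol = 1e-12) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty sample", call. = FALSE)
  M <- stats::median(x)
  for (i in seq_len(max_iter)) {
    S <- stats::median(abs(x - M)) / 0.6745
    if (S <= 0) return(M)
    u <- (x - M) / (tuning_c * S)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    M_new <- sum(w * x) / sum(w)
    if (abs(M_new - M) < tol) return(M_new)
    M <- M_new
  }
  M
}

#' Windowed biweight smoothing of a dated series onto an annual grid
#'
#' For each grid year Y, the Tukey biweight location of all samples dated
#' within `[Y - h, Y + h]` (`h = (window_years - 1)/2`; the default 21-year
#' window spans the decade before and after Y). Windows truncated at the ends
#' of the record use the available samples; grid years whose window holds no
#' sample are omitted from the output.
#'
#' @param dated data frame with columns `year` and `delta13C` (any dated,
#'   corrected series).
#' @param window_years odd window width in years (default 21).
#' @param tuning_c,max_iter passed to [biweight_location()].
#' @param grid integer years CE at which to evaluate; defaults to every year
#'   spanned by the series.
#' @return data frame with columns `year` and `value` (smoothed per mille).
#' @export
biweight_smooth <- function(dated, window_years = 21, tuning_c = 9,
                            max_iter = 10, grid = NULL) {
  stopifnot(is.data.frame(dated), all(c("year", "delta13C") %in% names(dated)))
  if (window_years %% 2 != 1 || window_years < 1)
    stop("window_years must be an odd positive integer", call. = FALSE)
  ord <- order(dated$year)
  yrs <- dated$year[ord]
  val <- dated$delta13C[ord]
  if (is.null(grid))
    grid <- seq(ceiling(min(yrs)), floor(max(yrs)))
  h <- (window_years - 1) / 2
  lo <- findInterval(grid - h, yrs, left.open = TRUE) + 1L
  hi <- findInterval(grid + h, yrs)
  keep <- hi >= lo
  out_val <- vapply(which(keep), function(i) {
    biweight_location(val[lo[i]:hi[i]], tuning_c = tuning_c,
                      max_iter = max_iter)
  }, numeric(1))
  data.frame(year = grid[keep], value = out_val)
}

#' Composite several smoothed tree series on a common annual grid
#'
#' Per grid year: the arithmetic mean across contributing trees, the standard
#' error `s/sqrt(k)` where `k >= 2` trees contribute (NA for a single tree),
#' and the tree count. Years with no contributing tree are dropped.
#'
#' @param smoothed named list of data frames (`year`, `value`), one per tree,
#'   as returned by [biweight_smooth()].
#' @return a `composite_record` data frame: `year`, `value`, `se`, `n_trees`.
#' @export
build_composite <- function(smoothed) {
  if (!length(smoothed)) stop("no smoothed series supplied", call. = FALSE)
  years <- sort(unique(unlist(lapply(smoothed, `[[`, "year"))))
  mat <- vapply(smoothed, function(s) {
    s$value[match(years, s$year)]
  }, numeric(length(years)))
  mat <- matrix(mat, nrow = length(years))
  k <- rowSums(!is.na(mat))
  keep <- k >= 1
  mat <- mat[keep, , drop = FALSE]; years <- years[keep]; k <- k[keep]
  value <- rowMeans(mat, na.rm = TRUE)
  se <- apply(mat, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2) stats::sd(r) / sqrt(length(r)) else NA_real_
  })
  .log_msg("composite", "%d trees, %d grid years (%d with >= 2 trees)",
           ncol(mat), length(years), sum(k >= 2))
  structure(data.frame(year = years, value = value, se = se, n_trees = k),
            class = c("composite_record", "data.frame"))
}

#' Centered moving average
#'
#' Arithmetic mean over a centered window, truncated (renormalised) at the
#' record ends. Even window widths use the standard climatological half-weight
#' scheme: the two outermost years each carry weight 1/2, so the window stays
#' symmetric and a linear series passes through unchanged in the interior.
#'
#' @param x data frame with columns `year` and `value` on a regular annual
#'   grid, or a plain numeric vector.
#' @param window_years window width in years (default 10).
#' @return object of the same shape as `x` with smoothed values.
#' @export
moving_average <- function(x, window_years = 10) {
  vec_in <- !is.data.frame(x)
  v <- if (vec_in) as.numeric(x) else x$value
  n <- length(v)
  if (n == 0L) stop("empty series", call. = FALSE)
  if (window_years > n)
    stop("window exceeds series span", call. = FALSE)
  if (window_years %% 2 == 1) {
    h <- (window_years - 1) / 2
    wts <- rep(1, window_years)
  } else {
    h <- window_years / 2
    wts <- c(0.5, rep(1, window_years - 1), 0.5)
  }
  sm <- vapply(seq_len(n), function(i) {
    j <- max(1, i - h):min(n, i + h)
    w <- wts[j - i + h + 1]
    sum(w * v[j]) / sum(w)
  }, numeric(1))
  if (vec_in) sm else {x$value <- sm; x}
}
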