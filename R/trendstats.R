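## Trend, changepoint and correlation statistics for composite proxy records.

#' Mann-Kendall trend test
#'
#' Non-parametric monotone-trend test. `S = sum_{i<j} sign(x_j - x_i)`;
#' `var(S)` uses the tie correction
#' `[n(n-1)(2n+5) - sum_ties t(t-1)(2t+5)] / 18`; `Z` applies the +/-1
#' continuity correction and the two-sided p-value is normal.
#'
#' @param x numeric series in time order (`n >= 4`).
#' @return list with `S`, `varS`, `Z`, `p` and `n`. A constant series returns
#'   `S = 0`, `p = 1`.
#' @export
mann_kendall <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("Mann-Kendall needs n >= 4", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values", call. = FALSE)
  S <- sum(sign(outer(x, x, "-"))[lower.tri(matrix(0, n, n))])
  t_ties <- table(x)
  t_ties <- t_ties[t_ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(t_ties * (t_ties - 1) * (2 * t_ties + 5))) / 18
  if (S == 0 || varS <= 0) {
    Z <- 0; p <- 1
  } else {
    Z <- (S - sign(S)) / sqrt(varS)
    p <- 2 * stats::pnorm(-abs(Z))
  }
  list(S = S, varS = varS, Z = Z, p = p, n = n)
}

#' Least-squares linear trend
#'
#' Ordinary least squares of value on year, reporting the slope (per mille per
#' year for isotope series), intercept, coefficient of determination, the
#' F statistic `F = (n - 2) R^2 / (1 - R^2)` and its p-value.
#'
#' @param year,value equal-length numeric vectors (`n >= 3`); `year` must not
#'   be constant.
#' @return list with `slope`, `intercept`, `F`, `R2`, `p` and `n`.
#' @export
ols_trend <- function(year, value) {
  n <- length(year)
  if (n < 3 || length(value) != n)
    stop("ols_trend needs equal-length vectors, n >= 3", call. = FALSE)
  if (stats::var(year) == 0) stop("constant year vector", call. = FALSE)
  fit <- stats::lm(value ~ year)
  tss <- sum((value - mean(value))^2)
  R2 <- if (tss == 0) 0 else 1 - sum(stats::resid(fit)^2) / tss
  R2 <- min(max(R2, 0), 1)
  Fst <- if (R2 >= 1) Inf else (n - 2) * R2 / (1 - R2)
  p <- stats::pf(Fst, 1, n - 2, lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F = Fst, R2 = R2, p = p, n = n)
}

## ---- changepoint detection (mean shift, SSE cost) -------------------------

## segment cost: residual sum of squares, O(1) via cumulative sums
.make_sse <- function(x) {
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  function(i, j) { # 1-based inclusive
    n <- j - i + 1
    cs2[j + 1] - cs2[i] - (cs[j + 1] - cs[i])^2 / n
  }
}

## penalty per changepoint; variance estimated from first differences, which
## is robust to a small number of mean shifts
.penalty_value <- function(penalty, x) {
  if (is.numeric(penalty)) {
    if (penalty <= 0) stop("penalty must be positive", call. = FALSE)
    return(penalty)
  }
  n <- length(x)
  sigsq <- mean(diff(x)^2) / 2
  if (sigsq == 0) sigsq <- .Machine$double.eps
  switch(match.arg(penalty, c("mbic", "bic")),
         bic = 2 * sigsq * log(n),
         mbic = 3 * sigsq * log(n))
}

.pelt <- function(x, beta, min_seglen = 1) {
  n <- length(x)
  sse <- .make_sse(x)
  F <- c(-beta, rep(Inf, n))      # F[t+1] = optimal cost of x[1..t]
  cp_prev <- integer(n + 1)       # last changepoint before t
  cand <- 0L                      # candidate last-segment starts (as t indices)
  for (t in seq_len(n)) {
    if (t < min_seglen) next
    ok <- cand[t - cand >= min_seglen]
    if (!length(ok)) next
    costs <- vapply(ok, function(s) F[s + 1] + sse(s + 1, t) + beta, numeric(1))
    best <- which.min(costs)
    F[t + 1] <- costs[best]
    cp_prev[t + 1] <- ok[best]
    ## prune eligible candidates that can never be optimal again; candidates
    ## still too recent to be eligible are kept for later t
    keep <- ok[costs - beta <= F[t + 1]]
    cand <- c(keep, cand[t - cand < min_seglen], t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- cp_prev[t + 1]
    if (s > 0) cps <- c(s, cps)
    t <- s
  }
  cps
}

.binseg <- function(x, beta, min_seglen = 1) {
  sse <- .make_sse(x)
  split_seg <- function(i, j) {
    ## best single split of x[i..j]; returns c(gain, split index) or NULL
    if (j - min_seglen < i + min_seglen - 1) return(NULL)
    ks <- seq(i + min_seglen - 1, j - min_seglen)
    gains <- sse(i, j) - vapply(ks, function(k) sse(i, k) + sse(k + 1, j),
                                numeric(1))
    k <- ks[which.max(gains)]
    c(max(gains), k)
  }
  cps <- integer(0)
  segs <- list(c(1L, length(x)))
  repeat {
    best <- NULL; best_seg <- 0L
    for (si in seq_along(segs)) {
      sp <- split_seg(segs[[si]][1], segs[[si]][2])
      if (!is.null(sp) && (is.null(best) || sp[1] > best[1])) {
        best <- sp; best_seg <- si
      }
    }
    if (is.null(best) || best[1] <= beta) break
    k <- as.integer(best[2])
    seg <- segs[[best_seg]]
    segs[[best_seg]] <- c(seg[1], k)
    segs[[length(segs) + 1L]] <- c(k + 1L, seg[2])
    cps <- sort(c(cps, k))
  }
  cps
}

#' Mean-shift changepoint detection
#'
#' Segments a series into constant-mean pieces by minimising the total
#' within-segment sum of squares plus a penalty `beta` per changepoint.
#' `"pelt"` solves the penalised problem exactly with pruning; `"binseg"` is
#' the classical greedy binary segmentation.
#'
#' @param x numeric series (`n >= 10`), or a data frame with `year` and
#'   `value` columns, in which case change years are reported on that grid.
#' @param penalty `"mbic"` (default), `"bic"`, or a positive number used
#'   directly as `beta`. The named penalties scale `log(n)` by a variance
#'   estimated from first differences (2x for BIC, 3x for the stricter MBIC).
#' @param method `"pelt"` (default, exact) or `"binseg"`.
#' @param min_seglen minimum segment length (default 2 observations).
#' @return a `changepoint_result` list: `change_years` (first year of each new
#'   segment; equals indices when `x` is a bare vector), `change_indices`,
#'   `segments` (data frame with `start`, `end`, `mean`, `length` on the year
#'   grid), `penalty_value`, `method`.
#' @export
changepoint_mean <- function(x, penalty = "mbic", method = c("pelt", "binseg"),
                             min_seglen = 2) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    years <- x$year
    v <- x$value
  } else {
    v <- as.numeric(x)
    years <- seq_along(v)
  }
  n <- length(v)
  if (n < 10) stop("changepoint detection needs n >= 10", call. = FALSE)
  beta <- .penalty_value(penalty, v)
  cps <- if (method == "pelt") .pelt(v, beta, min_seglen)
         else .binseg(v, beta, min_seglen)
  bounds <- c(0, cps, n)
  segments <- do.call(rbind, lapply(seq_len(length(bounds) - 1L), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    data.frame(start = years[idx[1]], end = years[idx[length(idx)]],
               mean = mean(v[idx]), length = length(idx))
  }))
  structure(list(change_years = years[cps + 1L],   # first year of new segment
                 change_indices = cps,
                 segments = segments,
                 penalty_value = beta,
                 method = method),
            class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat(sprintf("<changepoint_result> %s, penalty %.4g: %d changepoint(s)%s\n",
              x$method, x$penalty_value, length(x$change_years),
              if (length(x$change_years))
                paste0(" at ", paste(x$change_years, collapse = ", ")) else ""))
  invisible(x)
}

#' Pearson correlation between a composite record and a forcing index
#'
#' Both series are aligned on common integer years (pairwise complete),
#' optionally restricted to a window and smoothed identically on each side,
#' then correlated. p-values are two-sided and uncorrected for
#' autocorrelation; the lag-1 autocorrelation of each aligned side is reported
#' so the effective sample size can be judged.
#'
#' @param composite a [build_composite()] record (or any data frame with
#'   `year` and `value`).
#' @param forcing an [annual_record()] (or data frame with `year`, `value`).
#' @param window optional `c(start_CE, end_CE)` restriction.
#' @param pre_smoothing optional moving-average width in years applied to both
#'   sides before correlating (see [moving_average()]).
#' @return a `correlation_result` list: `r`, `p`, `n`, `window`,
#'   `pre_smoothing`, `lag1_composite`, `lag1_forcing`.
#' @export
correlate_with_forcing <- function(composite, forcing, window = NULL,
                                   pre_smoothing = NULL) {
  a <- data.frame(year = composite$year, a = composite$value)
  b <- data.frame(year = forcing$year, b = forcing$value)
  m <- merge(a, b, by = "year")
  if (!is.null(window))
    m <- m[m$year >= window[1] & m$year <= window[2], , drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (!is.null(pre_smoothing) && nrow(m) >= pre_smoothing) {
    m$a <- moving_average(m$a, pre_smoothing)
    m$b <- moving_average(m$b, pre_smoothing)
  }
  if (nrow(m) < 3) stop("fewer than 3 overlapping years", call. = FALSE)
  ct <- stats::cor.test(m$a, m$b, method = "pearson")
  lag1 <- function(v) if (length(v) > 2) stats::cor(v[-1], v[-length(v)]) else NA_real_
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m),
                 window = if (is.null(window)) range(m$year) else window,
                 pre_smoothing = pre_smoothing,
                 lag1_composite = lag1(m$a), lag1_forcing = lag1(m$b)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d..%d CE, n = %d: r = %.3f, p = %.3g (lag-1 acf %.2f / %.2f)\n",
              x$window[1], x$window[2], x$n, x$r, x$p,
              x$lag1_composite, x$lag1_forcing))
  invisible(x)
}
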