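# Distribution-level comparison of per-punctum intensities across
# conditions: ECDFs, Gaussian-kernel densities, and the two-sample
# Kolmogorov-Smirnov test with the standard asymptotic p-value.

#' Empirical cumulative distribution function of a sample
#'
#' Right-continuous step function `F(x) = #(values <= x) / n`.
#'
#' @param values numeric sample, n >= 1, finite.
#' @return object of class `punctum_ecdf` with `values` (sorted), `n`, and
#'   `fun` (vectorized evaluator).
#' @export
make_ecdf <- function(values) {
  if (length(values) == 0) stop("cannot build an ECDF from an empty sample")
  if (!all(is.finite(values))) stop("ECDF sample must be finite")
  s <- sort(values)
  structure(list(values = s, n = length(s), fun = stats::ecdf(s)),
            class = "punctum_ecdf")
}

#' @export
print.punctum_ecdf <- function(x, ...) {
  cat(sprintf("<punctum_ecdf> n = %d, range [%.4g, %.4g]\n",
              x$n, x$values[1], x$values[x$n]))
  invisible(x)
}

# Kolmogorov's asymptotic tail probability
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
.kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  total <- 0
  sign <- 1
  term2 <- -2 * lambda^2
  for (k in 1:1000) {
    term <- sign * exp(term2 * k^2)
    total <- total + term
    if (abs(term) < 1e-12 * abs(total) || abs(term) < 1e-300) break
    sign <- -sign
  }
  min(max(2 * total, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is `D = sup_x |F1(x) - F2(x)|`, evaluated over the pooled
#' sample points. The default p-value uses the asymptotic Kolmogorov
#' distribution with the standard small-sample correction,
#' `lambda = D * (sqrt(ne) + 0.12 + 0.11 / sqrt(ne))` with
#' `ne = n1 n2 / (n1 + n2)`; the test is two-sided. An exact-distribution
#' option is available for `n1 * n2 <= 1e4`.
#'
#' @param x,y numeric samples (n >= 1, finite).
#' @param alpha significance level (default 0.05).
#' @param method "asymptotic" (default) or "exact".
#' @return object of class `ks_result`: `D, p_value, n1, n2, alpha,
#'   significant, method`.
#' @export
ks_two_sample <- function(x, y, alpha = 0.05,
                          method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("samples must contain only finite values")
  }
  n1 <- length(x)
  n2 <- length(y)
  sx <- sort(x)
  sy <- sort(y)
  z <- sort(c(sx, sy))
  d_all <- abs(findInterval(z, sx) / n1 - findInterval(z, sy) / n2)
  D <- max(d_all)
  if (method == "exact") {
    if (n1 * n2 > 1e4) {
      stop("exact method limited to n1 * n2 <= 1e4; use method = 'asymptotic'")
    }
    p <- stats::ks.test(x, y, exact = TRUE)$p.value
  } else {
    ne <- n1 * n2 / (n1 + n2)
    lambda <- D * (sqrt(ne) + 0.12 + 0.11 / sqrt(ne))
    p <- .kolmogorov_q(lambda)
  }
  structure(
    list(D = D, p_value = p, n1 = n1, n2 = n2, alpha = alpha,
         significant = p < alpha, method = method),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "Two-sample Kolmogorov-Smirnov: D = %.4f, p = %.4g (n1 = %d, n2 = %d)%s\n",
    x$D, x$p_value, x$n1, x$n2,
    if (x$significant) sprintf("  [significant at %.3g]", x$alpha) else ""
  ))
  invisible(x)
}

#' Gaussian-kernel density estimate of an intensity sample
#'
#' Silverman's rule-of-thumb bandwidth unless overridden; the grid spans
#' `[min - 3h, max + 3h]` so the estimate integrates to 1 (trapezoid rule,
#' within 1e-3).
#'
#' @param values numeric sample, n >= 2.
#' @param bw optional fixed bandwidth (um or intensity units of the
#'   sample).
#' @param n_grid grid resolution.
#' @return a `stats::density` object.
#' @export
density_distribution <- function(values, bw = NULL, n_grid = 512) {
  if (length(values) < 2) stop("density estimate needs n >= 2")
  if (!all(is.finite(values))) stop("sample must be finite")
  if (is.null(bw)) {
    if (stats::sd(values) == 0) {
      stop("zero-variance sample: supply a fixed bandwidth via bw =")
    }
    bw <- stats::bw.nrd0(values)
  }
  stats::density(values, bw = bw, kernel = "gaussian", n = n_grid, cut = 3)
}

#' Pairwise Kolmogorov-Smirnov comparison matrix across conditions
#'
#' One row per unordered pair of conditions, in the order the conditions
#' are supplied (first condition varies slowest), formatted like the
#' published comparison table: pair label "A vs. B", p-value, and a
#' Yes/No significance call at `alpha`. No multiplicity correction is
#' applied across the matrix, matching the published presentation.
#'
#' @param samples named list (>= 2 conditions) of numeric samples.
#' @param alpha significance level.
#' @param method passed to [ks_two_sample].
#' @return data.frame `pair, D, p_value, significant`.
#' @export
pairwise_comparison_matrix <- function(samples, alpha = 0.05,
                                       method = "asymptotic") {
  if (length(samples) < 2 || is.null(names(samples))) {
    stop("need a named list of at least 2 conditions")
  }
  empty <- names(samples)[vapply(samples, length, integer(1)) == 0]
  if (length(empty)) {
    stop("condition(s) with no observations: ", paste(empty, collapse = ", "))
  }
  cn <- names(samples)
  idx <- utils::combn(length(cn), 2)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]
    j <- idx[2, k]
    r <- ks_two_sample(samples[[i]], samples[[j]], alpha = alpha,
                       method = method)
    data.frame(pair = sprintf("%s vs. %s", cn[i], cn[j]),
               D = r$D, p_value = r$p_value,
               significant = if (r$significant) "Yes" else "No")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descriptive summary (mean, SEM, n) per condition
#'
#' @param samples named list of numeric samples (each n >= 1).
#' @return data.frame `condition, n, mean, sem`.
#' @export
group_summary <- function(samples) {
  if (is.null(names(samples))) stop("samples must be named by condition")
  out <- do.call(rbind, lapply(names(samples), function(cn) {
    v <- samples[[cn]]
    data.frame(condition = cn, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_, sem = sem(v))
  }))
  rownames(out) <- NULL
  out
}
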