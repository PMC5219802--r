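# Ks age-distribution statistics: histograms, goodness of fit against a
# constant birth-death null (truncated exponential ages), and SiZer
# significance maps locating WGD peaks.

#' Histogram of Ks values on (0, max_ks]
#'
#' Right-closed bins `(a, a + w]`; a value equal to `max_ks` falls in the
#' last bin. Values outside `(0, max_ks]` are an error (they are filtered
#' upstream).
#'
#' @param values Ks values in `(0, max_ks]`.
#' @param bin_width bin width (default 0.05).
#' @param subset tag describing the subset (`"all"`, `"WGD"`, `"tandem"`,
#'   or a GO term restriction).
#' @param max_ks histogram ceiling (default 2).
#' @return object of class `ks_histogram`: `bin_edges`, `mids`, `counts`,
#'   `subset`, `n`.
#' @export
build_histogram <- function(values, bin_width = 0.05, subset = "all",
                            max_ks = 2) {
  if (any(values <= 0 | values > max_ks))
    stop("values outside (0, ", max_ks, "] are not allowed")
  edges <- seq(0, max_ks, by = bin_width)
  if (edges[length(edges)] < max_ks) edges <- c(edges, max_ks)
  counts <- tabulate(findInterval(values, edges, left.open = TRUE,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  structure(list(bin_edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, subset = subset, n = length(values)),
            class = "ks_histogram")
}

#' @export
print.ks_histogram <- function(x, ...) {
  cat("ks_histogram (", x$subset, "): ", x$n, " values in ",
      length(x$counts), " bins of width ",
      signif(x$bin_edges[2] - x$bin_edges[1], 3), "\n", sep = "")
  invisible(x)
}

# ---- truncated-exponential null (constant birth and death) -------------

# mean of a truncated exponential on (0, M] as a function of the rate;
# valid for negative rates too (growing density), stable near zero
trunc_exp_mean <- function(lambda, M) {
  ifelse(abs(lambda) < 1e-8,
         M / 2 - M^2 * lambda / 12,
         1 / lambda - M / expm1(M * lambda))
}

# maximum-likelihood rate of a truncated exponential on (0, M]
fit_trunc_exp <- function(x, M = 2) {
  m <- mean(x)
  stopifnot(m > 0, m < M)
  if (abs(m - M / 2) < 1e-12) return(0)
  uniroot(function(l) trunc_exp_mean(l, M) - m,
          lower = -500, upper = 5000, tol = 1e-12)$root
}

ptrunc_exp <- function(q, lambda, M = 2) {
  if (abs(lambda) < 1e-8) return(pmin(pmax(q / M, 0), 1))
  pmin(pmax(-expm1(-lambda * q) / -expm1(-lambda * M), 0), 1)
}

rtrunc_exp <- function(n, lambda, M = 2) {
  u <- runif(n)
  if (abs(lambda) < 1e-8) return(u * M)
  -log1p(u * expm1(-lambda * M)) / lambda
}

ks_sup_distance <- function(x, cdf) {
  xs <- sort(x)
  n <- length(xs)
  Fx <- cdf(xs)
  max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1L) / n)
}

#' Goodness of fit of a Ks age distribution to a constant birth-death null
#'
#' Under constant duplicate birth and a constant per-pair death rate, the
#' age (Ks) density of surviving duplicates is exponential; truncated to
#' the observable window `(0, max_ks]` this gives the null model. The rate
#' is fitted by maximum likelihood, `D` is the Kolmogorov-Smirnov
#' sup-distance between the empirical CDF and the fitted truncated
#' exponential, and the p-value comes from a parametric bootstrap
#' (Lilliefors-style: the rate is refitted on every simulated dataset,
#' accounting for the estimated parameter). `type = "two-sample"` instead
#' compares the data against one simulated null sample of equal size with
#' the classic two-sample statistic, again with a parametric bootstrap.
#'
#' @param values Ks values in `(0, max_ks]`, at least 30.
#' @param n_boot bootstrap replicates (default 200).
#' @param max_ks truncation point of the null (default 2).
#' @param type `"one-sample"` (default) or `"two-sample"`.
#' @return object of class `ks_gof`: `D`, `p_value`, `rate` (fitted
#'   birth-death decay rate), `n`, `n_boot`, `type`.
#' @export
ks_gof_test <- function(values, n_boot = 200, max_ks = 2,
                        type = c("one-sample", "two-sample")) {
  type <- match.arg(type)
  n <- length(values)
  if (n < 30) stop("need at least 30 values, got ", n)
  if (var(values) == 0) stop("degenerate data: all values identical")
  if (any(values <= 0 | values > max_ks))
    stop("values outside (0, ", max_ks, "]")
  rate <- fit_trunc_exp(values, max_ks)
  if (type == "one-sample") {
    D <- ks_sup_distance(values, function(q) ptrunc_exp(q, rate, max_ks))
    boot <- vapply(seq_len(n_boot), function(b) {
      xb <- rtrunc_exp(n, rate, max_ks)
      rb <- fit_trunc_exp(xb, max_ks)
      ks_sup_distance(xb, function(q) ptrunc_exp(q, rb, max_ks))
    }, numeric(1))
  } else {
    null_sample <- rtrunc_exp(n, rate, max_ks)
    D <- unname(suppressWarnings(
      stats::ks.test(values, null_sample)$statistic))
    boot <- vapply(seq_len(n_boot), function(b) {
      xb <- rtrunc_exp(n, rate, max_ks)
      rb <- fit_trunc_exp(xb, max_ks)
      unname(suppressWarnings(
        stats::ks.test(xb, rtrunc_exp(n, rb, max_ks))$statistic))
    }, numeric(1))
  }
  structure(list(D = D, p_value = (1 + sum(boot >= D)) / (n_boot + 1),
                 rate = rate, n = n, n_boot = n_boot, type = type),
            class = "ks_gof")
}

#' @export
print.ks_gof <- function(x, ...) {
  cat("Kolmogorov-Smirnov test vs constant birth-death null (",
      x$type, ")\n", sep = "")
  cat("  D = ", signif(x$D, 4), ", p = ", signif(x$p_value, 4),
      " (", x$n_boot, " bootstraps), fitted decay rate = ",
      signif(x$rate, 4), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

# ---- SiZer -------------------------------------------------------------

#' SiZer significance map of a Ks age histogram
#'
#' Local-linear Gaussian-kernel regression of histogram counts on bin
#' centers (degree 1, first derivative), over a log-spaced grid of
#' bandwidths `h` and a linear grid of locations `x`. Each (x, h) cell is
#' classified from the pointwise confidence interval of the local slope:
#' `increasing` if the lower bound is positive, `decreasing` if the upper
#' bound is negative, `flat` otherwise, and `sparse` where the effective
#' sample size (sum of kernel weights relative to the peak weight) is
#' below `ess_min`.
#'
#' @param values Ks values in `(0, max_ks]`.
#' @param h_range bandwidth range (default `c(0.05, 5)`).
#' @param n_h number of bandwidths (log-spaced; default 21).
#' @param n_x number of evaluation points (default 41).
#' @param bin_width histogram bin width (default 0.05).
#' @param max_ks histogram ceiling (default 2).
#' @param conf pointwise confidence level (default 0.95).
#' @param bonferroni apply a Bonferroni correction across the x grid
#'   (simultaneous-band variant; default FALSE, pointwise).
#' @param ess_min sparseness threshold on the effective sample size
#'   (default 5).
#' @return object of class `sizer_map`, see [sizer_map_xy()].
#' @export
sizer_map <- function(values, h_range = c(0.05, 5), n_h = 21, n_x = 41,
                      bin_width = 0.05, max_ks = 2, conf = 0.95,
                      bonferroni = FALSE, ess_min = 5) {
  if (length(values) < 50)
    stop("need at least 50 values for a SiZer map, got ", length(values))
  hist <- build_histogram(values, bin_width = bin_width, max_ks = max_ks)
  sizer_map_xy(hist$mids, hist$counts, h_range = h_range, n_h = n_h,
               n_x = n_x, conf = conf, bonferroni = bonferroni,
               ess_min = ess_min)
}

#' @rdname sizer_map
#' @param x,y scatterplot to smooth (for [sizer_map()]: bin centers and
#'   counts).
#' @export
sizer_map_xy <- function(x, y, h_range = c(0.05, 5), n_h = 21, n_x = 41,
                         conf = 0.95, bonferroni = FALSE, ess_min = 5) {
  if (h_range[1] >= h_range[2]) stop("h_range must be increasing")
  stopifnot(length(x) == length(y), length(x) >= 3)
  hs <- exp(seq(log(h_range[1]), log(h_range[2]), length.out = n_h))
  xg <- seq(min(x), max(x), length.out = n_x)
  states <- matrix("flat", n_h, n_x)
  slope <- matrix(NA_real_, n_h, n_x)
  ci_hw <- matrix(NA_real_, n_h, n_x)
  alpha <- 1 - conf
  if (bonferroni) alpha <- alpha / n_x
  for (i in seq_len(n_h)) {
    h <- hs[i]
    for (j in seq_len(n_x)) {
      w <- dnorm((x - xg[j]) / h)
      ess <- sum(w) / dnorm(0)
      if (ess < ess_min) { states[i, j] <- "sparse"; next }
      xc <- x - xg[j]
      sw <- sum(w); swx <- sum(w * xc); swx2 <- sum(w * xc^2)
      det <- sw * swx2 - swx^2
      if (det <= .Machine$double.eps * sw * max(swx2, 1)) {
        states[i, j] <- "sparse"; next
      }
      b1 <- (sw * sum(w * xc * y) - swx * sum(w * y)) / det
      b0 <- (sum(w * y) - b1 * swx) / sw
      r <- y - b0 - b1 * xc
      df <- max(ess - 2, 1)
      sigma2 <- sum(w * r^2) / df
      # var(b1) = [ (X'WX)^-1 X'W^2X (X'WX)^-1 ]_{22} * sigma2
      a11 <- sum(w^2); a12 <- sum(w^2 * xc); a22 <- sum(w^2 * xc^2)
      # row 2 of (X'WX)^-1 is (-swx, sw)/det
      v <- (swx^2 * a11 - 2 * swx * sw * a12 + sw^2 * a22) / det^2
      se <- max(sqrt(max(sigma2 * v, 0)), 1e-12)
      q <- qt(1 - alpha / 2, df)
      slope[i, j] <- b1
      ci_hw[i, j] <- q * se
      if (b1 - q * se > 0) states[i, j] <- "increasing"
      else if (b1 + q * se < 0) states[i, j] <- "decreasing"
    }
  }
  structure(list(x = xg, h = hs, states = states, slope = slope,
                 ci_halfwidth = ci_hw, n = length(x)),
            class = "sizer_map")
}

#' @export
print.sizer_map <- function(x, ...) {
  tab <- table(factor(x$states,
                      levels = c("increasing", "decreasing", "flat",
                                 "sparse")))
  cat("SiZer map: ", length(x$h), " bandwidths x ", length(x$x),
      " locations\n  ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tabular export of a SiZer map
#'
#' @param map a `sizer_map`.
#' @return data.frame in long format: `h`, `x`, `state`, `slope`,
#'   `ci_halfwidth`.
#' @export
sizer_as_table <- function(map) {
  data.frame(h = rep(map$h, times = length(map$x)),
             x = rep(map$x, each = length(map$h)),
             state = as.vector(map$states),
             slope = as.vector(map$slope),
             ci_halfwidth = as.vector(map$ci_halfwidth),
             stringsAsFactors = FALSE)
}
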