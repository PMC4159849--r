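#' Cluster frequency vector over a fixed cluster space
#'
#' Counts of each cluster divided by the number of labels, over the full
#' global cluster space (clusters never observed get zero).  Using one
#' fixed space for every sample makes frequency vectors from different
#' conditions comparable.
#'
#' @param labels vector of cluster labels.
#' @param cluster_space vector of all admissible cluster ids.
#' @return Named numeric probability vector over `cluster_space`.
#' @export
frequency_vector <- function(labels, cluster_space) {
  labels <- as.character(labels)
  cluster_space <- as.character(cluster_space)
  if (length(labels) == 0) abort("no labels supplied")
  bad <- setdiff(unique(labels), cluster_space)
  if (length(bad) > 0) {
    abort(paste0("labels outside the cluster space: ",
                 paste(bad, collapse = ", ")))
  }
  tab <- table(factor(labels, levels = cluster_space))
  setNames(as.numeric(tab) / length(labels), cluster_space)
}

#' Pearson correlation between two frequency vectors
#'
#' Standard centred product-moment correlation; errors on degenerate
#' (zero-variance) input rather than returning a silent value.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("need two vectors of equal length >= 2")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Pearson correlation undefined for zero-variance input")
  }
  cor(x, y)
}

#' Subsampled correlation between cluster-frequency distributions
#'
#' For each subsample size `n`, repeatedly (`n_permutations` times) draws
#' simulations without replacement, converts each draw to a cluster
#' frequency vector over the global cluster space, and records the Pearson
#' correlation between the two vectors.  In `"cross"` mode the two draws
#' of size `n` come independently from two pools (two conditions); in
#' `"auto"` mode two disjoint draws of size `n` come from one pool, which
#' measures sampling completeness of that single condition.  Degenerate
#' draws with zero variance yield `NA` and are reported as such.
#'
#' @param labelsA label pool of the first condition.
#' @param labelsB label pool of the second condition (`NULL` in auto mode).
#' @param n_values subsample sizes.
#' @param n_permutations draws per size (default 1000).
#' @param seed RNG seed.
#' @param mode `"cross"` or `"auto"`.
#' @param cluster_space global cluster space (default: union of the pools).
#' @return Object of class `correlation_curve`: tibble (n, mean_r, sd_r,
#'   n_valid) with attributes `mode` and `n_permutations`.
#' @export
subsampled_correlation <- function(labelsA, labelsB = NULL, n_values,
                                   n_permutations = 1000L, seed = 1L,
                                   mode = c("cross", "auto"),
                                   cluster_space = NULL) {
  mode <- match.arg(mode)
  labelsA <- as.character(labelsA)
  if (mode == "auto") {
    if (is.null(labelsB)) labelsB <- labelsA
    if (!identical(as.character(labelsB), labelsA)) {
      abort("auto mode uses a single label pool")
    }
  } else if (is.null(labelsB)) {
    abort("cross mode needs two label pools")
  }
  labelsB <- as.character(labelsB)
  cluster_space <- as.character(
    cluster_space %||% sort(unique(c(labelsA, labelsB))))
  set.seed(seed)
  rows <- map(n_values, function(n) {
    if (mode == "auto" && 2 * n > length(labelsA)) {
      abort(sprintf("auto mode needs 2n <= pool size (n = %d)", n))
    }
    if (mode == "cross" && (n > length(labelsA) || n > length(labelsB))) {
      abort(sprintf("n = %d exceeds a pool size", n))
    }
    rs <- vapply(seq_len(n_permutations), function(p) {
      if (mode == "auto") {
        idx <- sample.int(length(labelsA), 2 * n)
        xs <- labelsA[idx[seq_len(n)]]
        ys <- labelsA[idx[n + seq_len(n)]]
      } else {
        xs <- labelsA[sample.int(length(labelsA), n)]
        ys <- labelsB[sample.int(length(labelsB), n)]
      }
      fx <- frequency_vector(xs, cluster_space)
      fy <- frequency_vector(ys, cluster_space)
      sx <- sd(fx); sy <- sd(fy)
      if (length(fx) < 2 || is.na(sx) || is.na(sy) || sx == 0 || sy == 0) {
        return(NA_real_)
      }
      cor(fx, fy)
    }, numeric(1))
    tibble(n = n, mean_r = mean(rs, na.rm = TRUE),
           sd_r = sd(rs, na.rm = TRUE), n_valid = sum(!is.na(rs)))
  })
  out <- bind_rows(rows)
  class(out) <- c("correlation_curve", class(out))
  attr(out, "mode") <- mode
  attr(out, "n_permutations") <- n_permutations
  out
}

#' @export
autoplot.correlation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n, .data$mean_r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                                      ymax = .data$mean_r + .data$sd_r),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "subsample size n", y = "mean Pearson r")
}

# internal: model function of the saturating double exponential
double_exp_model <- function(n, a, b, c, d) {
  a * (1 - exp(-b * n)) + c * (1 - exp(-d * n))
}

#' Fit a saturating double exponential to a correlation curve
#'
#' Least-squares fit of `r(n) = a (1 - exp(-b n)) + c (1 - exp(-d n))`
#' with all four parameters constrained non-negative; the fitted
#' large-`n` limit is `a + c`.  When the curve carries positive
#' permutation standard deviations and `weighted = TRUE`, residuals are
#' weighted by `1 / sd^2`.  A fixed grid of start values (multistart) is
#' screened and the best converged fit returned; the two exponential terms
#' are reported with the faster rate first (`b >= d`).
#'
#' @param curve a [subsampled_correlation()] result, or any tibble with
#'   columns `n`, `mean_r` and optionally `sd_r`.
#' @param weighted use `1/sd^2` weights where sds are available and
#'   positive.
#' @return Object of class `double_exp_fit`: list with `a`, `b`, `c`,
#'   `d`, `limit` (= a + c), `fitted`, `residuals`, `converged`, `data`.
#' @export
fit_double_exponential <- function(curve, weighted = TRUE) {
  df <- as_tibble(curve)[, intersect(c("n", "mean_r", "sd_r"), names(curve))]
  df <- df[is.finite(df$mean_r), ]
  if (nrow(df) < 5) abort("need at least 5 curve points to fit")
  w <- rep(1, nrow(df))
  if (weighted && "sd_r" %in% names(df) &&
      all(is.finite(df$sd_r)) && all(df$sd_r > 0)) {
    w <- 1 / df$sd_r^2
  }
  # degenerate constant curves have no identifiable rates; report the
  # constant as the saturated fast term
  if (sd(df$mean_r) == 0) {
    v <- max(df$mean_r[1], 0)
    return(structure(list(
      a = v, b = 0, c = 0, d = 0, limit = v,
      fitted = rep(df$mean_r[1], nrow(df)),
      residuals = rep(0, nrow(df)),
      converged = TRUE, rss = 0, data = df
    ), class = "double_exp_fit"))
  }
  plateau <- max(df$mean_r)
  starts <- expand.grid(
    frac = c(0.3, 0.5, 0.7),
    b = c(0.3, 0.1, 0.05),
    d = c(0.05, 0.02, 0.005)
  )
  best <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    st <- list(a = max(plateau * starts$frac[i], 1e-3),
               b = starts$b[i],
               c = max(plateau * (1 - starts$frac[i]), 1e-3),
               d = starts$d[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        mean_r ~ a * (1 - exp(-b * n)) + c * (1 - exp(-d * n)),
        data = df, start = st, weights = w,
        lower = c(a = 0, b = 0, c = 0, d = 0),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  if (is.null(best)) abort("double-exponential fit failed to converge from any start")
  p <- stats::coef(best)
  if (p[["b"]] < p[["d"]]) {      # canonical order: fast term first
    p <- c(a = p[["c"]], b = p[["d"]], c = p[["a"]], d = p[["b"]])
  }
  structure(list(
    a = unname(p[["a"]]), b = unname(p[["b"]]),
    c = unname(p[["c"]]), d = unname(p[["d"]]),
    limit = unname(p[["a"]] + p[["c"]]),
    fitted = double_exp_model(df$n, p[["a"]], p[["b"]], p[["c"]], p[["d"]]),
    residuals = df$mean_r -
      double_exp_model(df$n, p[["a"]], p[["b"]], p[["c"]], p[["d"]]),
    converged = TRUE, rss = best_rss, data = df
  ), class = "double_exp_fit")
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat(sprintf(
    "double-exponential fit: a = %.4f, b = %.4f, c = %.4f, d = %.4f; limit a + c = %.4f\n",
    x$a, x$b, x$c, x$d, x$limit))
  invisible(x)
}

#' @export
tidy.double_exp_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c", "d"),
         estimate = c(x$a, x$b, x$c, x$d))
}

#' @export
glance.double_exp_fit <- function(x, ...) {
  tibble(limit = x$limit, rss = x$rss, n_points = nrow(x$data),
         converged = x$converged)
}

#' @export
autoplot.double_exp_fit <- function(object, ...) {
  grid <- tibble(n = seq(min(object$data$n), max(object$data$n),
                         length.out = 200))
  grid$r <- double_exp_model(grid$n, object$a, object$b, object$c, object$d)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$n, .data$mean_r)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$n, .data$r),
                       colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$limit, linetype = 2) +
    ggplot2::labs(x = "subsample size n", y = "mean Pearson r")
}
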