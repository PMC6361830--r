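#' Per-cell spike-time statistics across trials
#'
#' For every cell index, the mean, standard deviation and coefficient of
#' variation (CV = SD/mean) of its first-spike times across trials —
#' the scalar-property summary. Also fits SD on mean by least squares:
#' under scalar variability the SD grows in proportion to the mean, so the
#' fit should be near-linear with a small intercept.
#'
#' @param records a `trial_set` from [run_trials()], or a data frame with
#'   columns `trial`, `cell`, `time` (one row per first spike).
#' @param min_trials cells observed in fewer trials are omitted (with a
#'   count in the `n_omitted` attribute); at least 2 trials are needed for
#'   an SD.
#' @param fit_cells optional integer vector restricting the SD-on-mean fit
#'   (e.g. `10:60` to skip the early transient); `NULL` fits all reported
#'   cells.
#' @return A data frame (class `scalar_stats`) with columns `cell`, `n`,
#'   `mean`, `sd`, `cv`, and attributes `slope`, `intercept`, `r_squared`
#'   (SD-on-mean fit), `cv_asymptotic` (median CV over the last half of
#'   the reported cells), `n_omitted` and `n_excluded_trials` (when a
#'   `trial_set` was supplied).
#' @examples
#' rec <- data.frame(trial = rep(1:4, each = 2),
#'                   cell = rep(1:2, 4),
#'                   time = c(100, 210, 102, 205, 98, 190, 101, 202))
#' scalar_stats(rec)
#' @export
scalar_stats <- function(records, min_trials = 2, fit_cells = NULL) {
  n_excl <- NA_integer_
  if (inherits(records, "trial_set")) {
    n_excl <- records$n_excluded
    records <- records$records
  }
  stopifnot(is.data.frame(records),
            all(c("trial", "cell", "time") %in% names(records)),
            min_trials >= 2)
  # first spike per (trial, cell) in case a full raster is supplied
  ord <- order(records$cell, records$trial, records$time)
  records <- records[ord, ]
  first <- !duplicated(records[c("cell", "trial")])
  records <- records[first, ]

  cells <- sort(unique(records$cell))
  out <- do.call(rbind, lapply(cells, function(k) {
    tt <- records$time[records$cell == k]
    data.frame(cell = k, n = length(tt), mean = mean(tt),
               sd = if (length(tt) >= 2) sd(tt) else NA_real_)
  }))
  omitted <- sum(out$n < min_trials)
  out <- out[out$n >= min_trials, ]
  out$cv <- out$sd / out$mean

  fit_rows <- if (is.null(fit_cells)) seq_len(nrow(out))
              else which(out$cell %in% fit_cells)
  if (length(fit_rows) >= 3) {
    fit <- lm(sd ~ mean, data = out[fit_rows, ])
    attr(out, "slope") <- unname(coef(fit)[2])
    attr(out, "intercept") <- unname(coef(fit)[1])
    attr(out, "r_squared") <- summary(fit)$r.squared
  } else {
    attr(out, "slope") <- attr(out, "intercept") <- attr(out, "r_squared") <- NA_real_
  }
  last_half <- out$cell > max(out$cell) / 2
  attr(out, "cv_asymptotic") <- if (any(last_half)) median(out$cv[last_half]) else NA_real_
  attr(out, "n_omitted") <- omitted
  attr(out, "n_excluded_trials") <- n_excl
  class(out) <- c("scalar_stats", "data.frame")
  out
}

#' @export
print.scalar_stats <- function(x, ...) {
  cat(sprintf("<scalar_stats> %d cells; SD ~ mean: slope %.4f, intercept %.1f, R^2 %.3f\n",
              nrow(x), attr(x, "slope"), attr(x, "intercept"),
              attr(x, "r_squared")))
  cat(sprintf("  asymptotic CV (median over last half): %.4f\n",
              attr(x, "cv_asymptotic")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Mean-normalized spike-time histograms and superposition test
#'
#' Divides each trial's spike time for a cell by that cell's mean spike
#' time and bins the normalized samples on a grid shared by all requested
#' cells. Under timescale invariance the normalized distributions of
#' different cells superpose; superposition is quantified by the two-sample
#' Kolmogorov-Smirnov statistic for every cell pair.
#'
#' @param records as in [scalar_stats()].
#' @param cells cell indices to compare (default 30 and 40).
#' @param n_bins number of bins on the normalized axis (default 20).
#' @return An object of class `normalized_histograms`: list with
#'   `histograms` (per cell: `cell`, `breaks`, `mass` summing to 1, `n`),
#'   `ks` (data frame `cell_a`, `cell_b`, `statistic`, `p_value`) and
#'   `samples` (the normalized samples, named list).
#' @examples
#' set.seed(1)
#' rec <- data.frame(trial = rep(1:50, 2), cell = rep(c(3, 4), each = 50),
#'                   time = c(rnorm(50, 300, 30), rnorm(50, 400, 40)))
#' nh <- normalized_histograms(rec, cells = c(3, 4))
#' nh$ks
#' @export
normalized_histograms <- function(records, cells = c(30, 40), n_bins = 20) {
  if (inherits(records, "trial_set")) records <- records$records
  stopifnot(is.data.frame(records), length(cells) >= 1, n_bins >= 2)
  samples <- lapply(cells, function(k) {
    tt <- records$time[records$cell == k]
    if (!length(tt)) stop("no spikes recorded for cell ", k)
    tt / mean(tt)
  })
  names(samples) <- paste0("cell_", cells)
  rng <- range(unlist(samples))
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  histograms <- lapply(seq_along(cells), function(i) {
    cnt <- tabulate(findInterval(samples[[i]], breaks,
                                 rightmost.closed = TRUE), n_bins)
    list(cell = cells[i], breaks = breaks, mass = cnt / sum(cnt),
         n = length(samples[[i]]))
  })
  ks <- NULL
  if (length(cells) >= 2) {
    pairs <- utils::combn(seq_along(cells), 2)
    ks <- do.call(rbind, apply(pairs, 2, function(ij) {
      kt <- suppressWarnings(ks.test(samples[[ij[1]]], samples[[ij[2]]]))
      data.frame(cell_a = cells[ij[1]], cell_b = cells[ij[2]],
                 statistic = unname(kt$statistic),
                 p_value = kt$p.value)
    }))
  }
  structure(list(histograms = histograms, ks = ks, samples = samples),
            class = "normalized_histograms")
}

#' @export
print.normalized_histograms <- function(x, ...) {
  cat("<normalized_histograms>",
      paste(vapply(x$histograms, function(h)
        sprintf("cell %g (n=%d)", h$cell, h$n), character(1)),
        collapse = ", "), "\n")
  if (!is.null(x$ks)) {
    cat("  Kolmogorov-Smirnov superposition:\n")
    for (i in seq_len(nrow(x$ks)))
      cat(sprintf("    cell %g vs %g : D = %.3f, p = %.3f\n",
                  x$ks$cell_a[i], x$ks$cell_b[i],
                  x$ks$statistic[i], x$ks$p_value[i]))
  }
  invisible(x)
}

#' Analytic null: sum of identical independent intervals
#'
#' If a timed interval is the sum of `n_terms` independent
#' `Normal(mu_isi, sigma_isi)` inter-spike intervals, the sum has mean
#' `n*mu`, SD `sqrt(n)*sigma` and CV `sigma/(mu*sqrt(n))`: the CV shrinks
#' like `1/sqrt(n)`, so scalar variability does **not** hold for
#' independent identical intervals. This is the square-root-compression
#' null the chain mechanism must escape.
#'
#' @param n_terms number of summed intervals (>= 1).
#' @param mu_isi,sigma_isi mean and SD of one interval.
#' @return A list with `mean`, `sd`, `cv`.
#' @examples
#' sum_of_normals_null(4, 1000, 100)  # mean 4000, sd 200, cv 0.05
#' @export
sum_of_normals_null <- function(n_terms, mu_isi, sigma_isi) {
  stopifnot(n_terms >= 1, mu_isi > 0, sigma_isi >= 0)
  list(mean = n_terms * mu_isi,
       sd = sqrt(n_terms) * sigma_isi,
       cv = sigma_isi / (mu_isi * sqrt(n_terms)))
}

#' Monte-Carlo null: independent intervals with growing means
#'
#' Cumulative sums of independent `Normal(mu_k, cv_per_isi * mu_k)`
#' intervals: each interval individually satisfies the scalar property,
#' yet the cumulative times do not — their CV still falls with `k`
#' (analytically `cv * sqrt(sum(mu^2)) / sum(mu)` at each `k`). Lengthening
#' intervals alone therefore cannot produce scalar variability; the chain
#' model's trial-correlated sensitivity can.
#'
#' @param isi_means positive, non-decreasing interval means.
#' @param cv_per_isi per-interval CV.
#' @param n_draws Monte-Carlo sample size.
#' @return A data frame `k`, `mean`, `sd`, `cv` (simulated), with the
#'   closed-form CV in column `cv_analytic`.
#' @examples
#' increasing_isi_null(100 * (1:10), 0.1, n_draws = 2000)
#' @export
increasing_isi_null <- function(isi_means, cv_per_isi, n_draws = 10000) {
  stopifnot(all(isi_means > 0), !is.unsorted(isi_means), cv_per_isi >= 0,
            n_draws >= 2)
  K <- length(isi_means)
  draws <- matrix(rnorm(n_draws * K, mean = rep(isi_means, each = n_draws),
                        sd = rep(cv_per_isi * isi_means, each = n_draws)),
                  nrow = n_draws)
  cum <- t(apply(draws, 1, cumsum))
  if (K == 1) cum <- matrix(cum, ncol = 1)
  mu <- colMeans(cum)
  sdv <- apply(cum, 2, sd)
  data.frame(k = seq_len(K), mean = mu, sd = sdv, cv = sdv / mu,
             cv_analytic = cv_per_isi * sqrt(cumsum(isi_means^2)) /
                           cumsum(isi_means))
}
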