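#' Monte Carlo permutation test for a difference in means
#'
#' Statistic: difference of means (a minus b). The null distribution is
#' built by sign-flipping the paired differences (paired design) or by
#' random re-assignment of group labels (unpaired). The two-sided p-value
#' uses the standard add-one correction, so it can never be exactly zero:
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + n_perm)`.
#'
#' @param a,b numeric samples; equal length when `paired`.
#' @param paired logical.
#' @param n_perm number of Monte Carlo permutations (>= 100).
#' @param seed integer seed.
#' @return list of class `bg_test`: `statistic`, `p_value`,
#'   `n_permutations`, `method`.
#' @export
permutation_test <- function(a, b, paired = TRUE, n_perm = 5000,
                             seed = NULL) {
  if (n_perm < 100) stopf("n_perm must be >= 100 (got %d)", n_perm)
  if (paired && length(a) != length(b)) {
    stopf("paired test requires equal lengths (%d vs %d)", length(a), length(b))
  }
  obs <- mean(a) - mean(b)
  if (isTRUE(all.equal(stats::var(c(a, b)), 0))) {
    warnf("degenerate all-equal input; p = 1")
    return(structure(list(statistic = 0, p_value = 1,
                          n_permutations = n_perm, method = "permutation"),
                     class = "bg_test"))
  }
  null <- with_seed(seed, {
    if (paired) {
      d <- a - b
      n <- length(d)
      flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      as.vector(flips %*% d) / n
    } else {
      pooled <- c(a, b)
      na <- length(a)
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(pooled), na)
        mean(pooled[idx]) - mean(pooled[-idx])
      }, numeric(1))
    }
  })
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 method = "permutation"),
            class = "bg_test")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `alpha`; returns the rejection mask and the
#' monotone adjusted p-values.
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list with `rejected` (logical), `adjusted` (numeric), `alpha`.
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(list(rejected = logical(0), adjusted = numeric(0), alpha = alpha))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(rejected = adjusted <= alpha, adjusted = adjusted, alpha = alpha)
}

#' Cluster-based permutation test across frequency bins
#'
#' For dependent (bin-wise) comparisons of paired spectra. Bin-wise paired
#' t statistics are thresholded at `cluster_alpha` (two-sided); contiguous
#' supra-threshold bins of common sign form clusters whose masses are the
#' sums of their t values. The permutation null flips condition labels
#' within units and records the maximum absolute cluster mass, which
#' corrects for multiple comparisons across the spectrum.
#'
#' @param spectra_a,spectra_b matrices (units x frequency bins), matched
#'   rows.
#' @param freqs optional frequency grid for reporting.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param cluster_alpha bin-level threshold (default 0.05).
#' @return list of clusters, each with `bins`, `freqs`, `mass`, `p_value`;
#'   empty list when no bin exceeds the threshold.
#' @export
cluster_permutation <- function(spectra_a, spectra_b, freqs = NULL,
                                n_perm = 1000, seed = NULL,
                                cluster_alpha = 0.05) {
  stopifnot(is.matrix(spectra_a), is.matrix(spectra_b),
            all(dim(spectra_a) == dim(spectra_b)))
  n_units <- nrow(spectra_a)
  if (n_units < 2) stopf("cluster permutation requires >= 2 units (got %d)", n_units)
  d <- spectra_a - spectra_b
  t_crit <- stats::qt(1 - cluster_alpha / 2, df = n_units - 1)
  bin_t <- function(dm) {
    mu <- colMeans(dm)
    se <- apply(dm, 2, stats::sd) / sqrt(nrow(dm))
    ifelse(se > 0, mu / se, 0)
  }
  find_clusters <- function(tv) {
    supra <- abs(tv) > t_crit
    if (!any(supra)) return(list())
    sign_v <- sign(tv)
    r <- rle(supra & TRUE)
    out <- list()
    pos <- 1
    idx <- 1
    for (k in seq_along(r$lengths)) {
      bins <- pos:(pos + r$lengths[k] - 1)
      if (r$values[k]) {
        # split runs by sign
        sr <- rle(sign_v[bins])
        p2 <- bins[1]
        for (m in seq_along(sr$lengths)) {
          sub <- p2:(p2 + sr$lengths[m] - 1)
          out[[idx]] <- list(bins = sub, mass = sum(tv[sub]))
          idx <- idx + 1
          p2 <- p2 + sr$lengths[m]
        }
      }
      pos <- pos + r$lengths[k]
    }
    out
  }
  t_obs <- bin_t(d)
  clusters <- find_clusters(t_obs)
  if (length(clusters) == 0) return(list())
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      flips <- sample(c(-1, 1), n_units, replace = TRUE)
      cl <- find_clusters(bin_t(d * flips))
      if (length(cl) == 0) return(0)
      max(vapply(cl, function(c) abs(c$mass), numeric(1)))
    }, numeric(1))
  })
  lapply(clusters, function(cl) {
    cl$p_value <- (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
    cl$freqs <- if (!is.null(freqs)) freqs[cl$bins] else cl$bins
    cl
  })
}

#' Lilliefors test of composite normality (Monte Carlo)
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with
#' estimated mean and standard deviation; the null distribution of the
#' statistic is obtained by Monte Carlo simulation (normality with
#' estimated parameters invalidates the standard KS tables).
#'
#' @param x numeric sample (n >= 4).
#' @param n_mc Monte Carlo replicates (default 1000).
#' @param seed integer seed.
#' @return list with `statistic` (D) and `p_value`.
#' @export
lilliefors_test <- function(x, n_mc = 1000, seed = NULL) {
  n <- length(x)
  if (n < 4) stopf("Lilliefors test needs n >= 4 (got %d)", n)
  ks_d <- function(v) {
    v <- sort(v)
    z <- stats::pnorm(v, mean(v), stats::sd(v))
    i <- seq_len(length(v))
    max(pmax(i / length(v) - z, z - (i - 1) / length(v)))
  }
  d_obs <- ks_d(x)
  d_null <- with_seed(seed, {
    vapply(seq_len(n_mc), function(i) ks_d(stats::rnorm(n)), numeric(1))
  })
  list(statistic = d_obs,
       p_value = (1 + sum(d_null >= d_obs)) / (1 + n_mc))
}

#' Average per-hemisphere estimates into one value per subject
#'
#' The clinical severity score is a global, per-subject quantity, so
#' neurophysiological estimates are averaged across each subject's
#' available hemispheres before correlation. Subjects with a single
#' hemisphere pass through unchanged; subjects with no hemisphere are
#' dropped with a warning.
#'
#' @param df data.frame with a `subject_id` column, one row per
#'   hemisphere; all numeric columns are averaged.
#' @return data.frame with one row per subject.
#' @export
aggregate_hemispheres <- function(df) {
  stopifnot("subject_id" %in% names(df))
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  present <- !is.na(df$subject_id)
  if (any(!present)) warnf("dropping %d rows with missing subject_id", sum(!present))
  agg <- stats::aggregate(df[present, num_cols, drop = FALSE],
                          by = list(subject_id = df$subject_id[present]),
                          FUN = mean, na.rm = TRUE)
  agg[order(agg$subject_id), , drop = FALSE]
}

#' Pearson correlation of a per-subject estimate with symptom severity
#'
#' Screens both variables for normality with the Monte Carlo Lilliefors
#' test (a violation is flagged, not fatal — the correlation is reported
#' either way), then computes Pearson's R with its two-sided p-value on
#' the per-subject table.
#'
#' @param table data.frame with one row per subject, a `severity` column
#'   and the named estimate column; no missing values in either.
#' @param column name of the estimate column.
#' @param severity_col severity column name.
#' @param n_mc,seed forwarded to [lilliefors_test()].
#' @return list of class `bg_test`: `statistic` (R), `p_value`, `n`,
#'   `normality_ok`, `normality_p`, `method`.
#' @export
correlate_with_severity <- function(table, column, severity_col = "severity",
                                    n_mc = 1000, seed = NULL) {
  if (!column %in% names(table)) stopf("column '%s' not found", column)
  x <- table[[column]]
  y <- table[[severity_col]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need >= 3 subjects with complete data (got %d)", length(x))
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stopf("zero variance in '%s' or severity; correlation undefined",
          column)
  }
  seeds <- derive_seeds(seed %||% 0L, 2)
  lx <- lilliefors_test(x, n_mc, if (is.null(seed)) NULL else seeds[1])
  ly <- lilliefors_test(y, n_mc, if (is.null(seed)) NULL else seeds[2])
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(statistic = unname(ct$estimate), p_value = ct$p.value,
         n = length(x),
         normality_ok = (lx$p_value > 0.05) && (ly$p_value > 0.05),
         normality_p = c(estimate = lx$p_value, severity = ly$p_value),
         method = "pearson"),
    class = "bg_test"
  )
}

#' @export
print.bg_test <- function(x, ...) {
  cat(sprintf("<bg_test> %s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}
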