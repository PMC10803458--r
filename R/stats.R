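# Reliability / validity statistics (ICC(2,k), Pearson r, Welch's t) and
# k-means++ stratification.

#' Intraclass correlation ICC(2,k)
#'
#' Two-way random-effects, absolute-agreement, average-measures intraclass
#' correlation from the two-way ANOVA mean squares of an n x k matrix
#' (rows = targets, columns = raters/repetitions):
#' ICC = (MS_rows - MS_error) / (MS_rows + (MS_cols - MS_error) / n).
#' The qualitative band follows the conventional reliability cutoffs:
#' below 0.40 poor, 0.40-0.60 fair, 0.60-0.75 good, 0.75 and above
#' excellent.
#'
#' @param mat Numeric matrix, n targets x k raters, n >= 2, k >= 2,
#'   no missing cells.
#' @return List with `icc`, `band`, and the mean squares `ms_rows`,
#'   `ms_cols`, `ms_error`.
#' @export
icc_2k <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("ICC needs at least 2 targets and 2 raters", call. = FALSE)
  if (anyNA(mat)) stop("ICC matrix must be complete", call. = FALSE)
  grand <- mean(mat)
  if (sum((mat - grand)^2) == 0) {
    stop("undefined ICC: matrix has zero total variance", call. = FALSE)
  }
  row_means <- rowMeans(mat); col_means <- colMeans(mat)
  ms_rows <- k * sum((row_means - grand)^2) / (n - 1)
  ms_cols <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((mat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  ms_error <- sse / ((n - 1) * (k - 1))
  icc <- (ms_rows - ms_error) / (ms_rows + (ms_cols - ms_error) / n)
  list(icc = icc, band = icc_band(icc), ms_rows = ms_rows,
       ms_cols = ms_cols, ms_error = ms_error)
}

#' Qualitative reliability band for an ICC value
#' @param icc ICC value in `[-1, 1]`.
#' @return `"poor"`, `"fair"`, `"good"` or `"excellent"`.
#' @export
icc_band <- function(icc) {
  if (icc < 0.40) "poor"
  else if (icc < 0.60) "fair"
  else if (icc < 0.75) "good"
  else "excellent"
}

#' Pearson validity with qualitative band
#'
#' Sample Pearson correlation with its two-sided p value (t transform, via
#' [stats::cor.test()]) and the conventional correlation-strength band:
#' below 0.30 negligible, 0.30-0.50 low, 0.50-0.70 moderate, 0.70-0.90
#' high, 0.90-1.00 very high (band uses the value of r, preserving sign).
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `r`, `p`, `band`.
#' @export
pearson_validity <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with at least 3 values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, band = r_band(r))
}

#' Qualitative correlation-strength band for r
#' @param r Correlation in `[-1, 1]`.
#' @return One of `"negligible"`, `"low"`, `"moderate"`, `"high"`,
#'   `"very high"`.
#' @export
r_band <- function(r) {
  if (r < 0.30) "negligible"
  else if (r < 0.50) "low"
  else if (r < 0.70) "moderate"
  else if (r < 0.90) "high"
  else "very high"
}

#' Welch's t-test from group summary statistics
#'
#' t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2) with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p value. Useful
#' when only published group means and SDs are available.
#'
#' @param mean1,sd1,n1 Summary of group 1 (sd >= 0, n >= 2).
#' @param mean2,sd2,n2 Summary of group 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 < 0 || sd2 < 0) stop("sds must be non-negative", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  if (v1 + v2 == 0) stop("degenerate test: both sds are zero", call. = FALSE)
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Welch screen over a two-group parameter table
#'
#' Runs a per-column Welch's t-test (via [stats::t.test()]) between the two
#' groups of a parameter table and flags significance at p < `alpha`.
#'
#' @param table data.frame of numeric parameter columns plus a `group`
#'   column with exactly two levels.
#' @param group_col Name of the group column (default `"group"`).
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per parameter: `parameter`, `t`, `df`,
#'   `p`, `significant`.
#' @export
welch_screen <- function(table, group_col = "group", alpha = 0.05) {
  g <- factor(table[[group_col]])
  if (nlevels(g) != 2) stop("table must contain exactly two groups", call. = FALSE)
  if (min(table(g)) < 2) stop("insufficient data: a group has < 2 rows", call. = FALSE)
  cols <- names(table)[vapply(table, is.numeric, logical(1))]
  res <- lapply(cols, function(cn) {
    tt <- stats::t.test(table[[cn]][g == levels(g)[1]],
                        table[[cn]][g == levels(g)[2]], var.equal = FALSE)
    data.frame(parameter = cn, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               significant = tt$p.value < alpha)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' k-means++ clustering of a parameter table
#'
#' Z-scores the numeric feature columns (optional), seeds centroids with
#' the k-means++ scheme (first centroid uniform, later centroids sampled
#' with probability proportional to the squared distance to the nearest
#' chosen centroid), then runs Lloyd iterations until the largest centroid
#' shift is below `tol` or `max_iter` is reached. The seeding/Lloyd cycle
#' is restarted `n_init` times (sub-seeds derived from `seed`) and the
#' solution with the lowest final within-cluster sum of squares is kept,
#' the standard guard against poor local optima. The WSS is recorded
#' after every Lloyd iteration of the winning run and is non-increasing.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param table data.frame; all numeric columns are used as features.
#' @param k Number of clusters (default 3).
#' @param seed Integer RNG seed.
#' @param standardize Z-score features first (default `TRUE`; without it,
#'   columns in mm would dominate columns in seconds).
#' @param tol Convergence threshold on the largest centroid shift
#'   (standardized units, default 1e-8).
#' @param max_iter Maximum Lloyd iterations (default 300).
#' @param n_init Number of restarts (default 10).
#' @return An object of class `cluster_report`: `k`, `assignments`,
#'   `centroids` (k x p, standardized space), `wss_trace`, `sizes`,
#'   `seed`, `features`, `scaling` (centre/sd per feature).
#' @export
kmeanspp_cluster <- function(table, k = 3, seed = 1, standardize = TRUE,
                             tol = 1e-8, max_iter = 300, n_init = 10) {
  feats <- names(table)[vapply(table, is.numeric, logical(1))]
  x <- as.matrix(table[, feats, drop = FALSE])
  if (anyNA(x)) stop("feature columns must be complete", call. = FALSE)
  n <- nrow(x)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k exceeds the number of rows", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (standardize) {
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  res <- NULL
  for (init in seq_len(max(1, n_init))) {
    centers <- with_preserved_rng(seed + init - 1, kmeanspp_seed(x, k))
    cand <- lloyd_iterate(x, centers, tol, max_iter)
    if (is.null(res) ||
        cand$wss_trace[length(cand$wss_trace)] <
          res$wss_trace[length(res$wss_trace)]) {
      res <- cand
    }
  }
  structure(
    list(k = k, assignments = res$assign, centroids = res$centers,
         wss_trace = res$wss_trace, sizes = tabulate(res$assign, k),
         seed = seed, features = feats,
         scaling = list(center = ctr, sd = scl)),
    class = "cluster_report"
  )
}

# Run expr with a private RNG stream, restoring the caller's state.
with_preserved_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

kmeanspp_seed <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

lloyd_iterate <- function(x, centers, tol, max_iter) {
  k <- nrow(centers)
  wss_trace <- numeric(0)
  assign <- nearest_center(x, centers)
  for (it in seq_len(max_iter)) {
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (length(members) > 0) {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        # re-seed an empty cluster at the point farthest from its centroid
        far <- which.max(rowSums((x - centers[assign, , drop = FALSE])^2))
        new_centers[j, ] <- x[far, ]
      }
    }
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    assign <- nearest_center(x, centers)
    wss_trace <- c(wss_trace, sum((x - centers[assign, , drop = FALSE])^2))
    if (shift < tol) break
  }
  list(centers = centers, assign = assign, wss_trace = wss_trace)
}

nearest_center <- function(x, centers) {
  d <- matrix(NA_real_, nrow(x), nrow(centers))
  for (j in seq_len(nrow(centers))) {
    d[, j] <- rowSums(sweep(x, 2, centers[j, ])^2)
  }
  max.col(-d, ties.method = "first")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> k = %d, sizes: %s (seed %s)\n",
              x$k, paste(x$sizes, collapse = "/"), x$seed))
  invisible(x)
}
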