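#' Bin a cartilage surface into angular regions
#'
#' Divides the surface into `span_deg`-wide bands from the posterior to the
#' anterior end. Each vertex's angle is the atan2 of its position (relative to
#' the joint center) projected into the plane normal to the medial-lateral
#' axis, measured from the posterior extreme of the surface; values are pooled
#' across the medial-lateral direction within each band.
#'
#' @param surface `TriSurface`.
#' @param axis list with `center` (joint center, mm), `ml_axis`
#'   (medial-lateral rotation axis) and `posterior_axis` (posterior reference
#'   direction); typically derived from [anatomical_frame()].
#' @param span_deg angular span per region (default 20).
#' @param mask optional logical per-vertex mask; masked-out vertices get
#'   region NA.
#' @return object of class `RegionBinning`: `region` (integer id per vertex,
#'   1 = most posterior), `angle_deg`, `boundaries_deg`, `n_regions`.
#' @export
bin_regions <- function(surface, axis, span_deg = 20, mask = NULL) {
  ml <- unit(axis$ml_axis)
  post <- axis$posterior_axis - sum(axis$posterior_axis * ml) * ml
  if (vnorm(post) < 1e-9) stop("degenerate axis: posterior axis parallel to ML axis")
  post <- unit(post)
  third <- cross3(ml, post)
  V <- sweep(surface$vertices, 2, axis$center)
  u <- as.numeric(V %*% post)
  w <- as.numeric(V %*% third)
  ang <- rad2deg(atan2(w, u))          # 0 at posterior axis, increasing anterior
  keep <- if (is.null(mask)) rep(TRUE, length(ang)) else mask
  if (!any(keep)) stop("empty unmasked surface")
  a0 <- min(ang[keep])
  rel <- ang - a0
  extent <- max(rel[keep])
  if (extent < span_deg)
    warning("surface angular extent below one span; single region")
  region <- ifelse(keep, pmin(floor(rel / span_deg) + 1,
                              max(1, ceiling(extent / span_deg))), NA_integer_)
  n_regions <- max(region, na.rm = TRUE)
  structure(list(region = as.integer(region), angle_deg = rel,
                 boundaries_deg = seq(0, n_regions * span_deg, by = span_deg),
                 n_regions = as.integer(n_regions), span_deg = span_deg,
                 angle_origin = a0),
            class = "RegionBinning")
}

#' Area-weighted regional means of a per-vertex map
#'
#' @param values per-vertex numeric map (NA = undefined).
#' @param binning `RegionBinning`.
#' @param area_weights per-vertex areas (uniform if omitted).
#' @return data.frame with `region`, `mean`, `area`, `n_vertices`, and
#'   logical `empty` flag (regions with no defined vertices are flagged, not
#'   dropped).
#' @export
regional_means <- function(values, binning, area_weights = NULL) {
  stopifnot(length(values) == length(binning$region))
  w <- if (is.null(area_weights)) rep(1, length(values)) else area_weights
  out <- lapply(seq_len(binning$n_regions), function(k) {
    sel <- !is.na(binning$region) & binning$region == k & !is.na(values)
    if (!any(sel))
      data.frame(region = k, mean = NA_real_, area = 0, n_vertices = 0L,
                 empty = TRUE)
    else
      data.frame(region = k, mean = sum(values[sel] * w[sel]) / sum(w[sel]),
                 area = sum(w[sel]), n_vertices = sum(sel), empty = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @return list with `r`, `p` (two-sided, t transform with n - 2 df), `n`,
#'   `significant` at the 0.05 level.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in correlation input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n, significant = p < 0.05)
}

#' Intraclass correlation coefficient for agreement designs
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC(2,1)
#' (Shrout & Fleiss), the conventional statistic for intra-/inter-observer
#' agreement, with the F-based 95% confidence interval of McGraw & Wong.
#' The consistency form ICC(3,1) is reported alongside.
#'
#' @param measurements n_subjects x k_raters numeric matrix, complete design.
#' @param design label carried on the result (`"intra"` or `"inter"`).
#' @param conf confidence level.
#' @return object of class `ReliabilityResult`: `icc`, `ci` (length 2),
#'   `icc31`, mean squares, `design`.
#' @export
icc <- function(measurements, design = c("inter", "intra"), conf = 0.95) {
  design <- match.arg(design)
  M <- as.matrix(measurements)
  if (anyNA(M)) stop("complete design required: missing cells")
  n <- nrow(M); k <- ncol(M)
  if (k < 2 || n < 5) stop("need >= 2 raters and >= 5 subjects")
  mu <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  ss_r <- k * sum((row_m - mu)^2)
  ss_c <- n * sum((col_m - mu)^2)
  ss_t <- sum((M - mu)^2)
  ss_e <- ss_t - ss_r - ss_c
  msr <- ss_r / (n - 1)
  msc <- ss_c / (k - 1)
  mse <- ss_e / ((n - 1) * (k - 1))
  icc21 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc31 <- (msr - mse) / (msr + (k - 1) * mse)
  # McGraw & Wong CI for ICC(2,1) ("A,1")
  alpha <- 1 - conf
  a <- k * icc21 / (n * (1 - icc21))
  b <- 1 + k * icc21 * (n - 1) / (n * (1 - icc21))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc21, ci = c(lo, hi), icc31 = icc31,
                 msr = msr, msc = msc, mse = mse,
                 n = n, k = k, design = design, conf = conf),
            class = "ReliabilityResult")
}

#' @export
print.ReliabilityResult <- function(x, ...) {
  cat(sprintf("ICC(2,1) [%s-observer]: %.3f (%.0f%% CI: %.3f, %.3f); ICC(3,1) %.3f\n",
              x$design, x$icc, 100 * x$conf, x$ci[1], x$ci[2], x$icc31))
  invisible(x)
}

#' Root-mean-square differences of matched measurement sets
#'
#' For each comparison (pair of matched sample vectors) the RMS of the paired
#' differences is computed; the summary across comparisons is mean +/- SD.
#'
#' @param pairs list of comparisons, each a list/data.frame with two matched
#'   numeric vectors.
#' @return list with `rms` (per comparison), `mean`, `sd`.
#' @export
rms_difference <- function(pairs) {
  rms <- vapply(pairs, function(p) {
    a <- p[[1]]; b <- p[[2]]
    if (length(a) != length(b)) stop("length mismatch in matched samples")
    sqrt(mean((a - b)^2))
  }, numeric(1))
  list(rms = rms, mean = mean(rms), sd = if (length(rms) > 1) sd(rms) else 0)
}

#' Pre/post regional table with strain and T2* deltas
#'
#' Joins regional means of cumulative strain and projected T2* for two
#' sessions into the long-format table used for the regional correlation.
#' Delta columns are exactly `post - pre`. Regions with undefined strain or
#' T2* coverage in either session are flagged (`incomplete`), not dropped;
#' the correlation step excludes them.
#'
#' @param strain_pre,strain_post,t2_pre,t2_post data.frames from
#'   [regional_means()].
#' @param shoulder_id,side identifier columns.
#' @return data.frame (`RegionalTable` layout).
#' @export
regional_table <- function(strain_pre, strain_post, t2_pre, t2_post,
                           shoulder_id = "s1", side = "humeral") {
  k <- strain_pre$region
  df <- data.frame(shoulder_id = shoulder_id, side = side, region = k,
                   strain_pre = strain_pre$mean, strain_post = strain_post$mean,
                   t2_pre = t2_pre$mean, t2_post = t2_post$mean,
                   area_mm2 = strain_pre$area)
  df$delta_strain <- df$strain_post - df$strain_pre
  df$delta_t2 <- df$t2_post - df$t2_pre
  df$incomplete <- strain_pre$empty | strain_post$empty | t2_pre$empty | t2_post$empty |
    is.na(df$delta_strain) | is.na(df$delta_t2)
  df
}

#' Pooled regional correlation between strain change and T2* change
#'
#' @param table `RegionalTable` data.frame (possibly row-bound across
#'   shoulders); incomplete regions are excluded.
#' @return [pearson()] result plus `n_excluded`.
#' @export
correlate_regions <- function(table) {
  use <- !table$incomplete
  res <- pearson(table$delta_strain[use], table$delta_t2[use])
  res$n_excluded <- sum(!use)
  res
}
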