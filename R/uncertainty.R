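#' Normal-theory confidence ellipse of a planar point set
#'
#' The region \eqn{(x - \mu)^T \Sigma^{-1} (x - \mu) \le q} where \eqn{\mu}
#' is the point mean, \eqn{\Sigma} the sample covariance and q the `level`
#' quantile of the chi-square distribution with 2 degrees of freedom. Its
#' area is \eqn{\pi q \sqrt{det \Sigma}}.
#'
#' @param points Numeric matrix (or data frame) with 2 columns and at least
#'   3 rows.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A list with `center`, `cov`, `level`, `q` and `area`. A singular
#'   covariance (e.g. coincident points) yields a degenerate ellipse of area
#'   0 with a warning.
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must be planar (2 columns)")
  if (nrow(points) < 3L) stop("need at least 3 points for an ellipse")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  mu <- colMeans(points)
  sigma <- stats::cov(points)
  q <- stats::qchisq(level, df = 2L)
  dt <- det(sigma)
  if (!is.finite(dt) || dt <= .Machine$double.eps^2 * max(1, sum(diag(sigma)))^2) {
    warning("singular covariance: degenerate ellipse with zero area")
    area <- 0
  } else {
    area <- pi * q * sqrt(dt)
  }
  list(center = mu, cov = sigma, level = level, q = q, area = area)
}

# shoelace area of an ordered polygon (0 for fewer than 3 vertices)
polygon_area <- function(v) {
  n <- nrow(v)
  if (is.null(n) || n < 3L) return(0)
  x <- v[, 1L]; y <- v[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Convex hull of a planar point set
#'
#' The minimal convex polygon containing all points, with its area by the
#' shoelace formula. Collinear or degenerate inputs return a segment or
#' point with area 0.
#'
#' @param points Numeric matrix with 2 columns and at least 1 row.
#' @return A list with `vertices` (ordered coordinate matrix) and `area`.
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must be planar (2 columns)")
  if (nrow(points) < 1L) stop("need at least 1 point")
  idx <- grDevices::chull(points[, 1L], points[, 2L])
  v <- points[idx, , drop = FALSE]
  list(vertices = v, area = polygon_area(v))
}

#' Per-individual uncertainty regions of an MI-MFA compromise
#'
#' Each individual is represented by M points: its coordinates in each of
#' the M configurations projected onto the compromise axes (the
#' trajectories), restricted to the first two compromise dimensions. A 95%
#' confidence ellipse and a convex hull are computed from those M points for
#' every individual -- including fully observed ones, since changing any
#' imputed row perturbs the whole configuration. Larger areas flag
#' individuals whose placement is more uncertain.
#'
#' @param result A [run_mi_mfa()] result.
#' @param level Ellipse confidence level (default 0.95).
#' @return An object of class `uncertainty_report`: a list with `regions`
#'   (one entry per individual: `individual_id`, `points`, `ellipse`,
#'   `hull`, `imputed`) and `summary` (data frame with per-individual
#'   ellipse and hull areas). With M < 3, ellipses are skipped with a
#'   warning and hulls are still computed.
#' @export
uncertainty_report <- function(result, level = 0.95) {
  if (!inherits(result, "mi_mfa")) stop("`result` must be a run_mi_mfa() result")
  traj <- result$compromise$trajectories
  M <- length(traj)
  if (ncol(traj[[1L]]) < 2L)
    stop("uncertainty regions need at least 2 compromise dimensions")
  ids <- rownames(traj[[1L]])
  do_ellipse <- M >= 3L
  if (!do_ellipse)
    warning("M = ", M, " < 3: ellipses skipped, hulls still computed")
  imputed <- imputed_individuals(result)

  regions <- vector("list", length(ids))
  names(regions) <- ids
  summary <- data.frame(individual_id = ids,
                        imputed = ids %in% imputed,
                        ellipse_area = NA_real_,
                        hull_area = NA_real_)
  for (i in seq_along(ids)) {
    pts <- t(vapply(traj, function(tm) tm[i, 1:2], numeric(2L)))
    hull <- convex_hull(pts)
    ell <- if (do_ellipse) suppressWarnings(confidence_ellipse(pts, level))
           else NULL
    regions[[i]] <- list(individual_id = ids[i], points = pts,
                         ellipse = ell, hull = hull,
                         imputed = ids[i] %in% imputed)
    summary$ellipse_area[i] <- if (do_ellipse) ell$area else NA_real_
    summary$hull_area[i] <- hull$area
  }
  structure(list(regions = regions, summary = summary, level = level, M = M),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("uncertainty_report: %d individuals, M = %d projections each\n",
              nrow(s), x$M))
  for (grp in c(FALSE, TRUE)) {
    sub <- s[s$imputed == grp, ]
    if (!nrow(sub)) next
    cat(sprintf("  %-9s n = %2d  mean ellipse area %.4g  mean hull area %.4g\n",
                if (grp) "imputed:" else "observed:", nrow(sub),
                mean(sub$ellipse_area), mean(sub$hull_area)))
  }
  invisible(x)
}

#' Export uncertainty regions to CSV
#'
#' One row per individual: ellipse center, covariance entries and area, hull
#' area, and the hull vertices JSON-encoded in a single column.
#'
#' @param report An [uncertainty_report()] result.
#' @param path Output CSV path.
#' @export
write_uncertainty <- function(report, path) {
  rows <- lapply(report$regions, function(r) {
    e <- r$ellipse
    data.frame(
      individual_id = r$individual_id,
      imputed = r$imputed,
      center_x = if (is.null(e)) NA_real_ else e$center[1L],
      center_y = if (is.null(e)) NA_real_ else e$center[2L],
      cov_xx = if (is.null(e)) NA_real_ else e$cov[1L, 1L],
      cov_xy = if (is.null(e)) NA_real_ else e$cov[1L, 2L],
      cov_yy = if (is.null(e)) NA_real_ else e$cov[2L, 2L],
      ellipse_area = if (is.null(e)) NA_real_ else e$area,
      hull_area = r$hull$area,
      hull_vertices = as.character(jsonlite::toJSON(unname(r$hull$vertices),
                                                    digits = NA))
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = ",",
                     row.names = FALSE, quote = TRUE)
  invisible(path)
}
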