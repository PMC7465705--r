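# signal_detection module, phases 2-3: natural cubic smoothing splines on
# the per-chromosome Wald statistics,
#   S(g) = sum_i { y_i - g(x_i) }^2 + lambda * int g''(x)^2 dx,
# with lambda chosen by generalized cross validation over a log grid;
# inflection points where g'' changes sign; concave-down intervals between
# consecutive inflection points called as peaks with their heights.

# Default GCV grid for the penalty on the [0,1]-scaled position axis.
default_lambda_grid <- function() 10^seq(-8, 6, by = 0.25)

# Roughness structure of a knot vector (Green & Silverman): band matrices
# Q (n x (n-2)) and R ((n-2) x (n-2)) with penalty K = Q R^{-1} Q',
# eigendecomposed once per chromosome (positions do not change across
# permutations). Mg = R^{-1} Q' maps fitted knot values to the second
# derivatives at the interior knots (natural ends are zero).
penalty_structure <- function(x_scaled) {
  n <- length(x_scaled)
  stopifnot(n >= 3L, all(diff(x_scaled) > 0))
  h <- diff(x_scaled)
  Q <- matrix(0, n, n - 2L)
  R <- matrix(0, n - 2L, n - 2L)
  for (j in seq_len(n - 2L)) {
    Q[j, j] <- 1 / h[j]
    Q[j + 1L, j] <- -1 / h[j] - 1 / h[j + 1L]
    Q[j + 2L, j] <- 1 / h[j + 1L]
    R[j, j] <- (h[j] + h[j + 1L]) / 3
    if (j < n - 2L) {
      R[j, j + 1L] <- h[j + 1L] / 6
      R[j + 1L, j] <- h[j + 1L] / 6
    }
  }
  Mg <- solve(R, t(Q))
  Kpen <- Q %*% Mg
  ek <- eigen((Kpen + t(Kpen)) / 2, symmetric = TRUE)
  list(x = x_scaled, h = h, V = ek$vectors, d = pmax(ek$values, 0), Mg = Mg)
}

# Numerical noise floor for the second derivative: the map from fitted
# values to gamma amplifies rounding by ~1/h^2 (h ~ 1/n on the scaled
# axis), so degenerate inputs (constant or collinear data) leave gamma
# with tiny nonzero residue. Values below this tolerance are treated as
# exactly zero so that flat curves yield no inflections or peaks. Genuine
# curvature on the scaled axis is orders of magnitude above this floor.
gamma_tolerance <- function(g) {
  n <- length(g)
  (1e-4 + 4e-9 * n^2) * diff(range(g)) + 1e-6 * max(1, max(abs(g)))
}

# Evaluate the fitted natural cubic spline (knot values g, second
# derivatives gam on the same axis as x) at points xout.
eval_spline <- function(x, g, gam, xout) {
  n <- length(x)
  i <- findInterval(xout, x, rightmost.closed = TRUE, all.inside = TRUE)
  h <- x[i + 1L] - x[i]
  t <- xout - x[i]
  u <- x[i + 1L] - xout
  gam[i] * u^3 / (6 * h) + gam[i + 1L] * t^3 / (6 * h) +
    (g[i] / h - gam[i] * h / 6) * u + (g[i + 1L] / h - gam[i + 1L] * h / 6) * t
}

#' Fit a cubic smoothing spline to per-chromosome association statistics
#'
#' Minimizes the penalized residual sum of squares
#' `sum(y_i - g(x_i))^2 + lambda * int g''^2` over natural cubic splines.
#' Positions are rescaled to `[0, 1]` before fitting (for numerical
#' conditioning; `lambda` is reported on the scaled axis). `lambda` is
#' chosen by generalized cross validation over a log grid unless supplied;
#' the GCV degrees-of-freedom charge is inflated by the usual factor 1.4
#' to guard against occasional undersmoothing of heavy-tailed statistics
#' (chi-squared distributed Wald values). Tied positions are jittered by
#' +1 bp.
#'
#' @param positions bp positions (knots); at least 10 values.
#' @param values association statistics (e.g. Wald statistics) at the
#'   positions.
#' @param lambda `"gcv"` (default) or a fixed non-negative penalty on the
#'   scaled axis.
#' @param chrom chromosome label carried through to the result.
#' @param lambda_grid GCV search grid (scaled axis).
#' @param grid_points dense evaluation grid size; default
#'   `max(10 * length(positions), 1000)`.
#' @return object of class `spline_curve`: knots (`x` bp, `x_scaled`),
#'   inputs `y`, fitted knot values `g`, second derivatives `gamma`
#'   (scaled axis), `lambda`, the objective `objective`
#'   (`rss + lambda * penalty`), effective degrees of freedom `edf`, and a
#'   dense evaluation grid (`grid`, `g_grid`, `g2_grid`; the latter on the
#'   bp axis).
#' @export
fit_spline <- function(positions, values, lambda = "gcv", chrom = NA_character_,
                       lambda_grid = default_lambda_grid(),
                       grid_points = NULL) {
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  stopifnot(length(positions) == length(values))
  o <- order(positions)
  positions <- positions[o]
  values <- values[o]
  n <- length(positions)
  if (n < 10L) {
    pf_stop("need >= 10 SNPs to fit a smoothing spline (got ", n, ")")
  }
  while (any(dup <- duplicated(positions))) {
    pf_warn("jittering ", sum(dup), " tied position(s) by +1 bp")
    positions[dup] <- positions[dup] + 1
    o2 <- order(positions)
    positions <- positions[o2]
    values <- values[o2]
  }
  span <- positions[n] - positions[1]
  xs <- (positions - positions[1]) / span
  ps <- penalty_structure(xs)
  lam_fixed <- if (identical(lambda, "gcv")) -1 else as.numeric(lambda)
  fit <- spline_fit_cpp(ps$V, ps$d, values, lambda_grid, lam_fixed)
  g <- drop(fit$g)
  gam <- c(0, drop(ps$Mg %*% g), 0)
  gam[abs(gam) < gamma_tolerance(g)] <- 0
  ng <- grid_points %||% max(10L * n, 1000L)
  grid_s <- seq(0, 1, length.out = ng)
  g_grid <- eval_spline(xs, g, gam, grid_s)
  g2_grid_scaled <- stats::approx(xs, gam, xout = grid_s)$y
  structure(list(chrom = as.character(chrom), x = positions, x_scaled = xs,
                 y = values, g = g, gamma = gam, lambda = fit$lambda,
                 rss = fit$rss, penalty = fit$penalty,
                 objective = fit$rss + fit$lambda * fit$penalty,
                 edf = fit$edf, span = span, x0 = positions[1],
                 grid = positions[1] + grid_s * span, g_grid = g_grid,
                 g2_grid = g2_grid_scaled / span^2),
            class = "spline_curve")
}

#' @export
print.spline_curve <- function(x, ...) {
  cat(sprintf(
    "spline_curve (chrom %s): %d knots, lambda = %.3g, edf = %.1f\n",
    x$chrom, length(x$x), x$lambda, x$edf))
  invisible(x)
}

#' Inflection points of a fitted spline curve
#'
#' The fitted second derivative of a natural cubic spline is piecewise
#' linear in the knots, so interior sign changes are located exactly by
#' linear root finding between adjacent knots (no grid tolerance). The
#' natural boundary condition forces `g'' = 0` at the end knots, so a
#' curve end is reported as an inflection only when the interior second
#' derivative, extrapolated to the end, also vanishes (relative tolerance
#' `end_tol` of the maximum interior `|g''|`) -- i.e. when the underlying
#' curvature genuinely reaches zero at the end rather than being clamped
#' there.
#'
#' @param curve a [fit_spline()] result.
#' @param end_tol relative tolerance for end-knot inflections.
#' @return ascending numeric vector of bp positions where `g''` vanishes
#'   with a curvature change (possibly empty).
#' @export
find_inflections <- function(curve, end_tol = 0.02) {
  stopifnot(inherits(curve, "spline_curve"))
  x <- curve$x_scaled
  gam <- curve$gamma
  n <- length(x)
  out <- numeric(0)
  for (i in seq_len(n - 1L)) {
    a <- gam[i]; b <- gam[i + 1L]
    if ((a < 0 && b > 0) || (a > 0 && b < 0)) {
      out <- c(out, x[i] + (x[i + 1L] - x[i]) * (-a) / (b - a))
    }
  }
  # a knot where gamma touches zero between opposite signs is a crossing
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (gam[i] == 0 && gam[i - 1L] != 0 && gam[i + 1L] != 0 &&
          sign(gam[i - 1L]) != sign(gam[i + 1L])) {
        out <- c(out, x[i])
      }
    }
  }
  # end knots: extrapolate the interior gamma line to the end position
  gmax <- max(abs(gam))
  if (gmax > 0 && n >= 4L) {
    left <- gam[2] - (gam[3] - gam[2]) / (x[3] - x[2]) * (x[2] - x[1])
    right <- gam[n - 1L] +
      (gam[n - 1L] - gam[n - 2L]) / (x[n - 1L] - x[n - 2L]) * (x[n] - x[n - 1L])
    if (abs(left) <= end_tol * gmax) out <- c(out, x[1])
    if (abs(right) <= end_tol * gmax) out <- c(out, x[n])
  }
  curve$x0 + sort(unique(out)) * curve$span
}

# Internal: boundary nodes for peak delineation = chromosome ends plus all
# points where the piecewise-linear gamma crosses or touches zero.
peak_boundaries <- function(curve) {
  x <- curve$x_scaled
  gam <- curve$gamma
  n <- length(x)
  nodes <- x[1]
  for (i in seq_len(n - 1L)) {
    a <- gam[i]; b <- gam[i + 1L]
    if ((a < 0 && b > 0) || (a > 0 && b < 0)) {
      nodes <- c(nodes, x[i] + (x[i + 1L] - x[i]) * (-a) / (b - a))
    } else if (a != 0 && b == 0 && i + 1L < n) {
      nodes <- c(nodes, x[i + 1L])
    }
  }
  sort(unique(c(nodes, x[n])))
}

# Internal: exact maximum of the fitted spline on [L, U] (scaled axis).
spline_max_on <- function(curve, L, U) {
  x <- curve$x_scaled; g <- curve$g; gam <- curve$gamma
  best_v <- -Inf; best_x <- L
  consider <- function(xx) {
    vv <- eval_spline(x, g, gam, xx)
    if (vv > best_v) { best_v <<- vv; best_x <<- xx }
  }
  for (i in seq_len(length(x) - 1L)) {
    a <- max(L, x[i]); b <- min(U, x[i + 1L])
    if (b <= a) next
    h <- x[i + 1L] - x[i]
    consider(a); consider(b)
    # stationary points of the cubic piece: g'(s) = A s^2 + B s + C
    A <- (gam[i + 1L] - gam[i]) / (2 * h)
    B <- gam[i]
    C <- (g[i + 1L] - g[i]) / h - h * (2 * gam[i] + gam[i + 1L]) / 6
    roots <- if (abs(A) < 1e-300) {
      if (abs(B) > 1e-300) -C / B else numeric(0)
    } else {
      disc <- B^2 - 4 * A * C
      if (disc >= 0) (-B + c(-1, 1) * sqrt(disc)) / (2 * A) else numeric(0)
    }
    for (r in roots) {
      xx <- x[i] + r
      if (xx > a && xx < b) consider(xx)
    }
  }
  list(height = best_v, apex = best_x)
}

#' Call peaks from a fitted spline curve
#'
#' Each maximal interval between consecutive inflection points (or a
#' chromosome end) on which `g'' < 0` throughout becomes a peak; the apex
#' is the argmax of `g` on the interval and the height is `g(apex)`.
#' Intervals truncated by a chromosome end are flagged as boundary peaks.
#' Peaks are disjoint and reported in position order.
#'
#' @param curve a [fit_spline()] result.
#' @return data.frame with columns `chrom`, `left`, `right` (bp inflection
#'   boundaries), `apex_pos`, `height`, `n_snps` (knots within
#'   `[left, right]`), `boundary`.
#' @export
call_peaks <- function(curve) {
  stopifnot(inherits(curve, "spline_curve"))
  nodes <- peak_boundaries(curve)
  x <- curve$x_scaled
  gam <- curve$gamma
  res <- list()
  for (k in seq_len(length(nodes) - 1L)) {
    L <- nodes[k]; U <- nodes[k + 1L]
    if (U - L <= 0) next
    inner <- gam[x > L & x < U]
    s <- if (length(inner) && any(inner != 0)) {
      inner[which.max(abs(inner))]
    } else {
      # no interior knot: interpolate gamma at the midpoint
      stats::approx(x, gam, xout = (L + U) / 2)$y
    }
    if (!is.finite(s) || s >= 0) next
    mx <- spline_max_on(curve, L, U)
    res[[length(res) + 1L]] <- data.frame(
      chrom = curve$chrom,
      left = curve$x0 + L * curve$span,
      right = curve$x0 + U * curve$span,
      apex_pos = curve$x0 + mx$apex * curve$span,
      height = mx$height,
      n_snps = sum(x >= L & x <= U),
      boundary = (L <= x[1]) || (U >= x[length(x)]),
      stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), left = numeric(),
                      right = numeric(), apex_pos = numeric(),
                      height = numeric(), n_snps = integer(),
                      boundary = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
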