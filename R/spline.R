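#' Fit a smooth channel spline through clinician waypoints
#'
#' Fits a C2 cubic interpolating spline through the waypoints
#' (chord-length parameterised) and resamples it to uniform arc-length
#' steps. End tangents are clamped to the tangent of the circumcircle of
#' the first/last three waypoints, which reproduces circular-arc
#' channels to well under 0.1 mm; with two waypoints the channel is the
#' straight segment.
#'
#' @param waypoints A [waypoint_list()].
#' @param sample_step Arc-length resampling step in mm (default 0.5).
#' @param bore_diameter Channel bore diameter in mm (default 2.6).
#' @param tip_diameter Exit diameter of the tapered tip in mm (default
#'   2.2 for interstitial channels, otherwise equal to the bore).
#' @param taper_length Length of the linear taper in mm (default 10;
#'   interstitial channels only).
#' @return A `channel_plan`: the waypoints plus `samples`, the uniform
#'   arc-length polyline through them, and the bore/taper specification.
#' @export
fit_spline <- function(waypoints, sample_step = 0.5,
                       bore_diameter = 2.6,
                       tip_diameter = if (waypoints$role == "interstitial")
                         2.2 else bore_diameter,
                       taper_length = 10) {
  stopifnot(inherits(waypoints, "waypoint_list"))
  if (sample_step <= 0) abort("sample_step must be > 0")
  if (tip_diameter > bore_diameter || tip_diameter <= 0)
    abort("need bore_diameter >= tip_diameter > 0")
  p <- waypoints$points
  n <- nrow(p)
  chord <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))

  if (n == 2) {
    eval_at <- function(tt) {
      s <- tt / chord[2]
      cbind(p[1, 1] + s * (p[2, 1] - p[1, 1]),
            p[1, 2] + s * (p[2, 2] - p[1, 2]),
            p[1, 3] + s * (p[2, 3] - p[1, 3]))
    }
  } else {
    d0 <- circumcircle_tangent(p[1, ], p[2, ], p[3, ], end = "first")
    d1 <- circumcircle_tangent(p[n - 2, ], p[n - 1, ], p[n, ], end = "last")
    coefs <- lapply(1:3, function(j)
      clamped_cubic_coefs(chord, p[, j], d0[j], d1[j]))
    eval_at <- function(tt) {
      sapply(coefs, function(cf) eval_clamped_cubic(cf, tt))
    }
  }

  # dense evaluation -> arc length -> uniform resampling
  dense_t <- seq(0, chord[n], length.out = max(8 * n, 200))
  dense <- eval_at(dense_t)
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  total <- arc[length(arc)]
  n_samp <- max(ceiling(total / sample_step) + 1, 2)
  s_targets <- seq(0, total, length.out = n_samp)
  t_at_s <- approx(arc, dense_t, xout = s_targets, ties = "ordered")$y
  samples <- eval_at(t_at_s)

  structure(
    list(label = waypoints$label, role = waypoints$role,
         waypoints = p, samples = samples,
         sample_step = total / (n_samp - 1),
         arc_length = total,
         bore_diameter = bore_diameter, tip_diameter = tip_diameter,
         taper_length = taper_length,
         spline_eval = eval_at, knots = chord),
    class = "channel_plan"
  )
}

#' @export
print.channel_plan <- function(x, ...) {
  cat("<channel_plan> '", x$label, "' (", x$role, "): ",
      nrow(x$waypoints), " waypoints, arc length ",
      format(x$arc_length, digits = 6), " mm, bore ", x$bore_diameter,
      " mm", sep = "")
  if (x$tip_diameter < x$bore_diameter)
    cat(", taper to ", x$tip_diameter, " mm over ", x$taper_length, " mm",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Construct a channel plan from pre-computed centreline samples
#'
#' Builds a `channel_plan` directly from points sampled on an exactly
#' known curve (ordered, approximately uniformly spaced), bypassing the
#' spline fit; used for analytically defined channels such as the
#' circular arcs of the calibration template.
#'
#' @param label Channel label.
#' @param role Channel role (`"intracavitary"`, `"interstitial"`,
#'   `"loop"`).
#' @param samples n x 3 matrix of centreline points (mm).
#' @param bore_diameter,tip_diameter,taper_length Channel bore
#'   specification, as in [fit_spline()].
#' @return A `channel_plan`.
#' @export
channel_plan_from_samples <- function(label, role, samples,
                                      bore_diameter = 2.6,
                                      tip_diameter = bore_diameter,
                                      taper_length = 10) {
  samples <- as.matrix(samples)
  seg <- sqrt(rowSums(diff(samples)^2))
  structure(
    list(label = label, role = role,
         waypoints = samples[c(1, nrow(samples)), , drop = FALSE],
         samples = samples,
         sample_step = mean(seg), arc_length = sum(seg),
         bore_diameter = bore_diameter, tip_diameter = tip_diameter,
         taper_length = taper_length,
         spline_eval = NULL, knots = NULL),
    class = "channel_plan"
  )
}

# Tangent of the circle through three points, taken at the first or last
# of them; exact for points on a circle, chord direction for collinear
# triples.
circumcircle_tangent <- function(p1, p2, p3, end = c("first", "last")) {
  end <- match.arg(end)
  u <- p2 - p1; w <- p3 - p1
  nrm <- c(u[2] * w[3] - u[3] * w[2],
           u[3] * w[1] - u[1] * w[3],
           u[1] * w[2] - u[2] * w[1])
  n2 <- sum(nrm^2)
  chord_dir <- if (end == "first") p2 - p1 else p3 - p2
  chord_dir <- chord_dir / sqrt(sum(chord_dir^2))
  if (n2 < 1e-18 * max(sum(u^2), sum(w^2))^2) return(chord_dir)
  # circumcentre: c = p1 + (|w|^2 (u x w) x u + |u|^2 w x (u x w)) / (2 |u x w|^2)
  a2 <- sum(u^2); b2 <- sum(w^2)
  uxw <- nrm
  t1 <- cross3(matrix(uxw, 1), matrix(u, 1)) * b2
  t2 <- cross3(matrix(w, 1), matrix(uxw, 1)) * a2
  centre <- p1 + as.vector(t1 + t2) / (2 * n2)
  at <- if (end == "first") p1 else p3
  tangent <- cross3(matrix(nrm, 1), matrix(at - centre, 1))
  tangent <- as.vector(tangent)
  tangent <- tangent / sqrt(sum(tangent^2))
  if (sum(tangent * chord_dir) < 0) tangent <- -tangent
  tangent
}

# Natural-spline linear system with clamped (first-derivative) ends;
# returns knots, values and second derivatives for evaluation.
clamped_cubic_coefs <- function(x, y, d0, d1) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 2 * h[1]; A[1, 2] <- h[1]
  b[1] <- 6 * ((y[2] - y[1]) / h[1] - d0)
  if (n > 2) {
    for (i in 2:(n - 1)) {
      A[i, i - 1] <- h[i - 1]
      A[i, i] <- 2 * (h[i - 1] + h[i])
      A[i, i + 1] <- h[i]
      b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
    }
  }
  A[n, n - 1] <- h[n - 1]; A[n, n] <- 2 * h[n - 1]
  b[n] <- 6 * (d1 - (y[n] - y[n - 1]) / h[n - 1])
  list(x = x, y = y, M = solve(A, b), h = h)
}

eval_clamped_cubic <- function(cf, xout) {
  x <- cf$x; y <- cf$y; M <- cf$M; h <- cf$h
  n <- length(x)
  idx <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  hi <- h[idx]
  t <- xout - x[idx]
  dy <- diff(y)
  y[idx] + (dy[idx] / hi - hi * (2 * M[idx] + M[idx + 1]) / 6) * t +
    M[idx] * t^2 / 2 + (M[idx + 1] - M[idx]) / (6 * hi) * t^3
}
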