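# The early-stage elliptical path on the Ramachandran map and the
# parametric t angle (measured clockwise from an anchor in the lower-right
# quadrant).

#' Define an elliptical early-stage path on the Ramachandran map
#'
#' @param center numeric 2-vector `(phi0, psi0)` in degrees.
#' @param semi_axes numeric 2-vector `(a, b)` in degrees; reordered so the
#'   major axis comes first (the tilt is rotated by 90 degrees if swapped).
#' @param tilt rotation of the major axis in degrees (counterclockwise from
#'   the phi axis), stored in (-90, 90].
#' @param t_zero_anchor optional point `(phi, psi)` on the ellipse where
#'   `t = 0`; defaults to the rightmost point (maximal phi), which for a
#'   Ramachandran-like tilt lies in the lower-right quadrant. A warning is
#'   emitted if the anchor falls outside that quadrant.
#' @return object of class `ellipse_spec`.
#' @export
ellipse_spec <- function(center, semi_axes, tilt, t_zero_anchor = NULL) {
  stopifnot(length(center) == 2, length(semi_axes) == 2, length(tilt) == 1)
  a <- semi_axes[[1]]; b <- semi_axes[[2]]
  if (a <= 0 || b <= 0) abort("semi-axes must be positive")
  if (b > a) {
    tmp <- a; a <- b; b <- tmp
    tilt <- tilt + 90
  }
  tilt <- wrap_angle(tilt)
  if (tilt <= -90) tilt <- tilt + 180
  if (tilt > 90) tilt <- tilt - 180
  e <- structure(
    list(center = as.numeric(center), a = a, b = b, tilt = tilt,
         u0 = NA_real_, anchor = NULL),
    class = "ellipse_spec"
  )
  if (is.null(t_zero_anchor)) {
    # parameter of the maximal-phi point: d(phi)/du = 0 has two roots;
    # take the one with the larger phi
    th <- deg2rad(tilt)
    u1 <- atan2(-b * sin(th), a * cos(th))
    cand <- c(u1, u1 + pi)
    phis <- vapply(cand, function(u) ellipse_xy(e, u)[1], numeric(1))
    e$u0 <- cand[[which.max(phis)]] %% (2 * pi)
  } else {
    e$u0 <- ellipse_param_of(e, t_zero_anchor, tol = 1e-9)
  }
  e$anchor <- ellipse_xy(e, e$u0)
  if (!(e$anchor[1] > 0 && e$anchor[2] < 0)) {
    warn(sprintf(
      "t-zero anchor (%.1f, %.1f) is not in the lower-right Ramachandran quadrant",
      e$anchor[1], e$anchor[2]
    ))
  }
  e
}

#' @export
print.ellipse_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<ellipse_spec> center (%.2f, %.2f), semi-axes (%.2f, %.2f), ",
      "tilt %.2f deg\n  t = 0 at (%.2f, %.2f), clockwise\n"
    ),
    x$center[1], x$center[2], x$a, x$b, x$tilt, x$anchor[1], x$anchor[2]
  ))
  invisible(x)
}

#' @export
tidy.ellipse_spec <- function(x, ...) {
  tibble::tibble(
    term = c("phi0", "psi0", "a", "b", "tilt", "anchor_phi", "anchor_psi"),
    estimate = c(x$center, x$a, x$b, x$tilt, x$anchor)
  )
}

# point on the ellipse at internal parameter u (radians, counterclockwise)
ellipse_xy <- function(e, u) {
  th <- deg2rad(e$tilt)
  x <- e$a * cos(u); y <- e$b * sin(u)
  e$center + c(cos(th) * x - sin(th) * y, sin(th) * x + cos(th) * y)
}

# map a (phi, psi) point into the ellipse frame (centered, de-tilted)
ellipse_frame <- function(e, p) {
  th <- deg2rad(e$tilt)
  d <- c(p[1] - e$center[1], p[2] - e$center[2])
  c(cos(th) * d[1] + sin(th) * d[2], -sin(th) * d[1] + cos(th) * d[2])
}

# internal parameter u of a point asserted to lie on the ellipse
ellipse_param_of <- function(e, p, tol = 1e-6) {
  q <- ellipse_frame(e, p)
  resid <- abs((q[1] / e$a)^2 + (q[2] / e$b)^2 - 1)
  if (resid > tol) abort("not on ellipse")
  atan2(q[2] / e$b, q[1] / e$a) %% (2 * pi)
}

#' Parametric t angle of a point on the ellipse
#'
#' `t` is measured clockwise along the path, in degrees in `[0, 360)`,
#' starting from the spec's t-zero anchor.
#'
#' @param point numeric 2-vector `(phi, psi)` on the ellipse.
#' @param e an [ellipse_spec()].
#' @param tol tolerance on the implicit ellipse equation.
#' @return t in degrees.
#' @export
t_angle <- function(point, e, tol = 1e-6) {
  u <- ellipse_param_of(e, point, tol = tol)
  (rad2deg(e$u0 - u)) %% 360
}

#' Point on the ellipse at a given t angle
#'
#' Inverse of [t_angle()].
#'
#' @param e an [ellipse_spec()].
#' @param t parametric angle in degrees (clockwise from the anchor).
#' @return numeric 2-vector `(phi, psi)`.
#' @export
ellipse_point_at_t <- function(e, t) {
  ellipse_xy(e, e$u0 - deg2rad(t))
}

# squared distance from the frame point q to the ellipse point at u,
# plus derivatives in u (all in the de-tilted frame)
proj_f <- function(u, q, a, b) {
  dx <- a * cos(u) - q[1]; dy <- b * sin(u) - q[2]
  dx * dx + dy * dy
}
proj_df <- function(u, q, a, b) {
  -2 * a * sin(u) * (a * cos(u) - q[1]) + 2 * b * cos(u) * (b * sin(u) - q[2])
}
proj_ddf <- function(u, q, a, b) {
  -2 * a * cos(u) * (a * cos(u) - q[1]) + 2 * a^2 * sin(u)^2 +
    2 * b^2 * cos(u)^2 - 2 * b * sin(u) * (b * sin(u) - q[2])
}

project_one <- function(e, phi, psi) {
  q <- ellipse_frame(e, c(phi, psi))
  # coarse scan then Newton refinement from the best starts
  grid <- seq(0, 2 * pi, length.out = 181)[-181]
  fg <- vapply(grid, proj_f, numeric(1), q = q, a = e$a, b = e$b)
  starts <- unique(c(grid[order(fg)][1:3], seq(0, 2 * pi, length.out = 9)[-9]))
  best_u <- NA_real_; best_f <- Inf
  for (u in starts) {
    for (it in 1:60) {
      d1 <- proj_df(u, q, e$a, e$b)
      d2 <- proj_ddf(u, q, e$a, e$b)
      if (!is.finite(d2) || abs(d2) < 1e-14) break
      step <- d1 / d2
      step <- max(min(step, 0.5), -0.5)
      u <- u - step
      if (abs(step) < 1e-13) break
    }
    fu <- proj_f(u, q, e$a, e$b)
    if (fu < best_f - 1e-12) {
      best_f <- fu; best_u <- u %% (2 * pi)
    } else if (fu < best_f + 1e-12) {
      # tie: keep the candidate with the smaller t
      tu <- (rad2deg(e$u0 - u)) %% 360
      tb <- (rad2deg(e$u0 - best_u)) %% 360
      if (tu < tb) { best_f <- min(best_f, fu); best_u <- u %% (2 * pi) }
    }
  }
  p <- ellipse_xy(e, best_u)
  c(phi_e = p[1], psi_e = p[2], t = (rad2deg(e$u0 - best_u)) %% 360)
}

#' Project Ramachandran points onto the elliptical path
#'
#' Each `(phi, psi)` point (wrapped into the (-180, 180] square) is mapped
#' to the nearest point of the ellipse in the Euclidean degree metric, via
#' a coarse parametric scan refined by Newton iteration; ties (e.g. the
#' exact center) are broken toward the smaller t.
#'
#' @param phi,psi numeric vectors of backbone dihedrals in degrees
#'   (`NA` allowed; propagated).
#' @param e an [ellipse_spec()].
#' @return tibble with columns `phi_e`, `psi_e`, `t`.
#' @export
project_to_ellipse <- function(phi, psi, e) {
  stopifnot(length(phi) == length(psi))
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  out <- matrix(NA_real_, nrow = length(phi), ncol = 3)
  ok <- which(is.finite(phi) & is.finite(psi))
  for (i in ok) out[i, ] <- project_one(e, phi[i], psi[i])
  tibble::tibble(phi_e = out[, 1], psi_e = out[, 2], t = out[, 3])
}

# --- algebraic (conic) ellipse fitting --------------------------------------

# Direct least-squares ellipse fit (Halir & Flusser's numerically stable
# variant of Fitzgibbon's method). Returns conic coefficients
# (A, B, C, D, E, F) with the ellipse constraint 4AC - B^2 > 0 enforced.
fit_conic_ellipse <- function(x, y) {
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) abort("not elliptical: degenerate design"))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0) abort("not elliptical: no valid conic")
  a1 <- V[, idx[[1]]]
  c(a1, as.numeric(Tm %*% a1))
}

conic_to_spec <- function(co) {
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) abort("not elliptical: conic is not an ellipse")
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  Fc <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  ev <- eigen(Q, symmetric = TRUE)
  axes2 <- -Fc / ev$values
  if (any(axes2 <= 0)) abort("not elliptical: degenerate axes")
  semi <- sqrt(axes2)
  major <- which.max(semi)
  tilt <- rad2deg(atan2(ev$vectors[2, major], ev$vectors[1, major]))
  ellipse_spec(
    center = c(x0, y0),
    semi_axes = c(semi[major], semi[-major]),
    tilt = tilt
  )
}

#' Derive the elliptical path from a corpus of domain structures
#'
#' Pools per-pentapeptide (lnR, V) curvature points over the corpus, fits
#' the quadratic lnR-vs-V trend, keeps the (phi, psi) of windows whose
#' residual lies within `residual_band` of the trend ("relaxed" backbone
#' fragments), and fits an algebraic least-squares conic constrained to an
#' ellipse through the retained points.
#'
#' @param corpus list of [domain_structure()] objects.
#' @param residual_band lnR tolerance around the fitted polynomial.
#' @param min_points minimum number of retained points.
#' @return an [ellipse_spec()].
#' @export
derive_ellipse <- function(corpus, residual_band = 0.5, min_points = 50) {
  pts <- purrr::map(corpus, function(d) {
    tryCatch(pentapeptide_curvature(d), error = function(e) NULL)
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter(
      is.finite(.data$lnR), is.finite(.data$V),
      is.finite(.data$phi), is.finite(.data$psi)
    )
  if (nrow(pts) < 3) abort("cannot derive ellipse: too few curvature points")
  fit <- lnr_polynomial_fit(pts)
  pred <- fit$a * pts$V^2 + fit$b * pts$V + fit$c
  keep <- abs(pts$lnR - pred) <= residual_band
  if (sum(keep) < min_points) {
    abort(sprintf(
      "cannot derive ellipse: only %d on-path points (need %d)",
      sum(keep), min_points
    ))
  }
  conic_to_spec(fit_conic_ellipse(pts$phi[keep], pts$psi[keep]))
}

# --- packaged default -------------------------------------------------------

the <- new.env(parent = emptyenv())

# designed reference path used by the synthetic calibration corpus: passes
# through the alpha-helical and beta basins with its rightmost point in the
# lower-right quadrant
calibration_path_spec <- function() {
  ellipse_spec(center = c(-40, 30), semi_axes = c(134, 73), tilt = -40)
}

#' Default elliptical path
#'
#' The package's default ellipse is derived at first use (then memoized) by
#' running [derive_ellipse()] on a seeded synthetic calibration corpus whose
#' torsions emulate relaxed backbone fragments arranged along an elliptical
#' Ramachandran path (see [calibration_corpus()]). Real-data analyses should
#' derive their own spec from their own corpus.
#'
#' @return an [ellipse_spec()].
#' @export
default_ellipse <- function() {
  if (is.null(the$default_ellipse)) {
    the$default_ellipse <- derive_ellipse(calibration_corpus(), residual_band = 0.75)
  }
  the$default_ellipse
}
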