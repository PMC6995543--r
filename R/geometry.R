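# Backbone geometry: torsion angles, peptide-plane aperture, and the
# pentapeptide radius of curvature feeding the elliptical-path derivation.

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: cis = 0, trans = 180; value in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  for (b in list(b1, b2, b3)) {
    if (vnorm(b) < 1e-10) abort("degenerate geometry: coincident consecutive points")
  }
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-12 || vnorm(n2) < 1e-12) {
    abort("degenerate geometry: collinear points")
  }
  m1 <- vcross(n1, b2 / vnorm(b2))
  ang <- -rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

# atoms needed: phi(i) = C(i-1), N(i), CA(i), C(i); psi(i) = N(i), CA(i), C(i), N(i+1)
# an angle is defined only when all four atoms exist and the residues are
# consecutive in chain position

#' Backbone dihedral series (phi, psi) of a domain
#'
#' `phi[i]` uses C(i-1), N(i), CA(i), C(i); `psi[i]` uses N(i), CA(i), C(i),
#' N(i+1). Angles are `NA` wherever a needed atom is missing or the flanking
#' residue is not the chain neighbour, so `phi` is undefined at the first
#' residue of a run and `psi` at the last.
#'
#' @param domain a [domain_structure()].
#' @return tibble with columns `index`, `aa`, `phi`, `psi` (degrees).
#' @export
compute_dihedrals <- function(domain) {
  n <- nrow(domain)
  if (n < 2) abort("no dihedrals: need at least 2 residues")
  N <- atom_xyz(domain, "N")
  CA <- atom_xyz(domain, "CA")
  C <- atom_xyz(domain, "C")
  adjacent <- c(FALSE, diff(domain$index) == 1)
  has <- function(m, i) all(!is.na(m[i, ]))
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && adjacent[i] && has(C, i - 1) && has(N, i) && has(CA, i) && has(C, i)) {
      phi[i] <- dihedral(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    }
    if (i < n && adjacent[i + 1] && has(N, i) && has(CA, i) && has(C, i) && has(N, i + 1)) {
      psi[i] <- dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
    }
  }
  if (all(is.na(phi)) && all(is.na(psi))) abort("no dihedrals: no computable angle")
  tibble::tibble(index = domain$index, aa = domain$aa, phi = phi, psi = psi)
}

peptide_plane_normal <- function(CA_i, C_i, N_next) {
  unitv(vcross(C_i - CA_i, N_next - C_i), "peptide-plane normal")
}

#' Aperture angle between adjacent peptide-bond planes
#'
#' The peptide plane of the bond i -> i+1 is spanned by CA(i), C(i), N(i+1);
#' the aperture at residue `i` is the unsigned angle between the normals of
#' the planes i -> i+1 and i+1 -> i+2, in `[0, 180]` degrees (0 for coplanar
#' planes with consistent orientation).
#'
#' @param domain a [domain_structure()].
#' @param i residue position (row) at which the first plane starts.
#' @return angle in degrees.
#' @export
aperture_angle <- function(domain, i) {
  if (i < 1 || i + 2 > nrow(domain)) abort("undefined aperture: out of range")
  rows <- i:(i + 2)
  if (!all(domain$complete[rows]) || any(diff(domain$index[rows]) != 1)) {
    abort("undefined aperture: missing atoms or chain break")
  }
  CA <- atom_xyz(domain, "CA")
  C <- atom_xyz(domain, "C")
  N <- atom_xyz(domain, "N")
  n1 <- peptide_plane_normal(CA[i, ], C[i, ], N[i + 1, ])
  n2 <- peptide_plane_normal(CA[i + 1, ], C[i + 1, ], N[i + 2, ])
  rad2deg(acos(clamp1(sum(n1 * n2))))
}

#' Radius of curvature of five consecutive CA positions
#'
#' The five points are projected onto their best-fit plane (orthogonal to
#' the smallest-variance principal axis) and a least-squares (Kasa) circle
#' is fitted; the fit is exact for points on a circle and recovers the
#' cylinder radius of low-pitch helical fragments. Collinear input yields
#' the `+Inf` sentinel (a straight chain has no curvature).
#'
#' @param ca_coords 5 x 3 numeric matrix of CA coordinates (Angstrom).
#' @return radius in Angstrom (possibly `Inf`).
#' @export
curvature_radius <- function(ca_coords) {
  P <- as.matrix(ca_coords)
  if (nrow(P) != 5 || ncol(P) != 3) abort("need exactly 5 CA points")
  if (anyNA(P)) abort("degenerate geometry: missing coordinates")
  d <- as.matrix(stats::dist(P))
  if (any(d[upper.tri(d)] < 1e-8)) abort("degenerate geometry: duplicate points")
  Pc <- sweep(P, 2, colMeans(P))
  ev <- eigen(crossprod(Pc), symmetric = TRUE)
  # collinear: only one principal direction carries variance
  if (ev$values[2] < 1e-10 * max(ev$values[1], 1)) return(Inf)
  basis <- ev$vectors[, 1:2, drop = FALSE]
  xy <- Pc %*% basis
  x <- xy[, 1]; y <- xy[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3) return(Inf)
  sol <- qr.coef(qrA, rhs)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(Inf)
  sqrt(r2)
}

#' Per-pentapeptide curvature and aperture profile
#'
#' Slides a 5-residue window along the chain; for each fully complete,
#' chain-contiguous window reports the natural log of the CA radius of
#' curvature, the aperture angle of the central residue's flanking peptide
#' planes, and the central residue's (phi, psi).
#'
#' @param domain a [domain_structure()].
#' @return tibble with columns `center` (chain position of the middle
#'   residue), `lnR`, `V`, `phi`, `psi`.
#' @export
pentapeptide_curvature <- function(domain) {
  n <- nrow(domain)
  if (n < 5) abort("too short: need at least 5 residues")
  CA <- atom_xyz(domain, "CA")
  dih <- compute_dihedrals(domain)
  rows <- purrr::map(seq_len(n - 4), function(i) {
    win <- i:(i + 4)
    if (!all(domain$complete[win]) || any(diff(domain$index[win]) != 1)) return(NULL)
    R <- curvature_radius(CA[win, ])
    V <- tryCatch(aperture_angle(domain, i + 1), error = function(e) NA_real_)
    mid <- i + 2
    tibble::tibble(
      center = mid, lnR = log(R), V = V,
      phi = dih$phi[mid], psi = dih$psi[mid]
    )
  })
  dplyr::bind_rows(rows)
}

#' Quadratic fit of ln(R) against the aperture angle V
#'
#' Least-squares fit of `lnR = a V^2 + b V + c` over curvature points with
#' finite `lnR`; the fitted trend defines the "relaxed" backbone band used
#' to select points for the elliptical-path derivation.
#'
#' @param points data frame with columns `V` and `lnR`.
#' @return object of class `lnr_fit`: list with `a`, `b`, `c`, `rms`, `n`
#'   and the underlying `lm` fit.
#' @export
lnr_polynomial_fit <- function(points) {
  pts <- dplyr::filter(
    tibble::as_tibble(points),
    is.finite(.data$lnR), is.finite(.data$V)
  )
  if (nrow(pts) < 3 || length(unique(pts$V)) < 3) {
    abort("underdetermined: need at least 3 points with distinct V")
  }
  fit <- lm(lnR ~ I(V^2) + V, data = pts)
  co <- coef(fit)
  structure(
    list(
      a = unname(co[["I(V^2)"]]), b = unname(co[["V"]]),
      c = unname(co[["(Intercept)"]]),
      rms = sqrt(mean(fit$residuals^2)), n = nrow(pts), fit = fit
    ),
    class = "lnr_fit"
  )
}

#' @export
print.lnr_fit <- function(x, ...) {
  cat(sprintf(
    "<lnr_fit> lnR = %.4g V^2 + %.4g V + %.4g  (n = %d, rms = %.4g)\n",
    x$a, x$b, x$c, x$n, x$rms
  ))
  invisible(x)
}

#' @export
tidy.lnr_fit <- function(x, ...) {
  tibble::tibble(term = c("V^2", "V", "intercept"), estimate = c(x$a, x$b, x$c))
}

#' @export
glance.lnr_fit <- function(x, ...) {
  tibble::tibble(n = x$n, rms = x$rms)
}
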