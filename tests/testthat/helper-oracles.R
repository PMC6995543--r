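# Shared oracles and fixture builders, independent of the code paths they
# check.

# dense parametric scan of the ellipse: brute-force nearest point
dense_scan_projection <- function(e, phi, psi, step = 0.001) {
  tg <- seq(0, 360 - step, by = step)
  u <- e$u0 - tg * pi / 180
  th <- e$tilt * pi / 180
  x <- e$a * cos(u); y <- e$b * sin(u)
  px <- e$center[1] + cos(th) * x - sin(th) * y
  py <- e$center[2] + sin(th) * x + cos(th) * y
  dd <- (px - phi)^2 + (py - psi)^2
  i <- which.min(dd)
  c(phi_e = px[i], psi_e = py[i], t = tg[i])
}

# random proper rotation matrix (det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion to every backbone atom of a domain
transform_domain <- function(domain, rot = diag(3), shift = c(0, 0, 0)) {
  for (atom in c("n", "ca", "c")) {
    cols <- paste(atom, c("x", "y", "z"), sep = "_")
    m <- as.matrix(domain[cols]) %*% t(rot)
    domain[cols] <- sweep(m, 2, shift, "+")
  }
  domain
}

# 3-residue domain built from explicit backbone atoms (rows: N, CA, C per
# residue), for targeted plane/aperture constructions
domain_from_atoms <- function(N, CA, C, aa = "A") {
  n <- nrow(CA)
  domain_structure(tibble::tibble(
    index = seq_len(n), aa = rep_len(aa, n),
    n_x = N[, 1], n_y = N[, 2], n_z = N[, 3],
    ca_x = CA[, 1], ca_y = CA[, 2], ca_z = CA[, 3],
    c_x = C[, 1], c_y = C[, 2], c_z = C[, 3]
  ))
}

# conic fit oracle with the F = 1 normalization (ordinary least squares),
# independent of the constrained eigen-solver under test
conic_fit_f1 <- function(x, y) {
  X <- cbind(x^2, x * y, y^2, x, y)
  co <- as.numeric(qr.solve(X, rep(-1, length(x))))
  c(co, 1)
}
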