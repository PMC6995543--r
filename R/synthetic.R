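# Seeded synthetic-data generators: Ramachandran torsion mixtures, backbone
# reconstruction from internal coordinates, planted hydrophobic cores and
# planted tetrapeptide code-frequency signals. These emulate the statistical
# structure the analysis assumes, so every stage is testable without any
# structure database.

# ideal backbone internal coordinates (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7

#' Torsion mixture specification
#'
#' A mixture of Gaussian (phi, psi) basins on the Ramachandran map; the
#' peptide-bond omega is fixed at 180 (trans). Noise is Gaussian on each
#' angle independently, wrapped into (-180, 180] after sampling.
#'
#' @param components tibble with columns `phi`, `psi` (basin centers,
#'   degrees), `sd` (degrees) and `weight` (positive; normalized to sum 1).
#' @return object of class `torsion_mixture`.
#' @export
torsion_mixture <- function(components) {
  cmp <- tibble::as_tibble(components)
  stopifnot(all(c("phi", "psi", "sd", "weight") %in% names(cmp)))
  if (nrow(cmp) == 0 || any(cmp$weight <= 0)) abort("invalid spec: weights must be positive")
  cmp$weight <- cmp$weight / sum(cmp$weight)
  structure(list(components = cmp, omega = 180), class = "torsion_mixture")
}

#' Standard Ramachandran basin mixture
#'
#' Right-handed alpha helix, beta sheet, polyproline II and left-handed
#' helix basins with literature-typical centers and protein-like weights.
#'
#' @param sd basin standard deviation in degrees.
#' @return a [torsion_mixture()].
#' @export
ramachandran_mixture <- function(sd = 12) {
  torsion_mixture(tibble::tibble(
    phi = c(-63, -120, -75, 57),
    psi = c(-43, 135, 150, 40),
    sd = sd,
    weight = c(0.45, 0.3, 0.15, 0.1)
  ))
}

# mixture whose components sit on the designed calibration path: emulates
# relaxed backbone fragments arranged along an elliptical Ramachandran path
calibration_mixture <- function(sd = 6) {
  path <- calibration_path_spec()
  ts <- c(15, 60, 98, 135, 175, 215, 260, 310)
  pts <- t(vapply(ts, function(t) ellipse_point_at_t(path, t), numeric(2)))
  torsion_mixture(tibble::tibble(
    phi = pts[, 1], psi = pts[, 2], sd = sd,
    weight = rep(1 / length(ts), length(ts))
  ))
}

#' Sample (phi, psi) torsions from a mixture
#'
#' @param spec a [torsion_mixture()].
#' @param n number of residues.
#' @param seed integer seed (all randomness is local to the call).
#' @return tibble with columns `phi`, `psi`, `component`.
#' @export
sample_torsions <- function(spec, n, seed = 1) {
  if (!inherits(spec, "torsion_mixture")) abort("invalid spec")
  if (n < 1) abort("n must be >= 1")
  cmp <- spec$components
  withr::with_seed(seed, {
    z <- sample.int(nrow(cmp), n, replace = TRUE, prob = cmp$weight)
    tibble::tibble(
      phi = wrap_angle(rnorm(n, cmp$phi[z], cmp$sd[z])),
      psi = wrap_angle(rnorm(n, cmp$psi[z], cmp$sd[z])),
      component = z
    )
  })
}

# place a new atom given three predecessors, a bond length, a bond angle at
# `c` (degrees) and the torsion a-b-c-new (degrees); NeRF construction
place_atom <- function(a, b, c, length, angle, torsion) {
  th <- deg2rad(angle)
  chi <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- length * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  c + bc * d[1] + m * d[2] + n * d[3]
}

#' Reconstruct a backbone from torsion angles
#'
#' Places N, CA, C atoms sequentially from fixed ideal bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom) and ideal bond angles, with
#' the supplied (phi, psi) and a fixed omega; the first residue sits in a
#' canonical frame. `compute_dihedrals()` on the result recovers the input
#' torsions (phi of the first and psi of the last residue are not
#' realizable and are ignored).
#'
#' @param torsions data frame with columns `phi`, `psi` (degrees), one row
#'   per residue.
#' @param omega peptide-bond torsion (trans = 180).
#' @param aa amino-acid letters (recycled; default poly-alanine).
#' @param id domain identifier.
#' @return a [domain_structure()].
#' @export
build_backbone <- function(torsions, omega = 180, aa = "A", id = "synthetic") {
  ts <- tibble::as_tibble(torsions)
  stopifnot(all(c("phi", "psi") %in% names(ts)))
  n <- nrow(ts)
  if (n < 1) abort("need at least one torsion pair")
  aa <- rep_len(aa, n)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  ang <- deg2rad(ANGLE_N_CA_C)
  C[1, ] <- CA[1, ] + BOND_CA_C * c(cos(pi - ang), sin(pi - ang), 0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_N, ANGLE_CA_C_N, ts$psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], BOND_N_CA, ANGLE_C_N_CA, omega)
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], BOND_CA_C, ANGLE_N_CA_C, ts$phi[i + 1])
    }
  }
  domain_structure(
    tibble::tibble(
      index = seq_len(n), aa = aa,
      n_x = N[, 1], n_y = N[, 2], n_z = N[, 3],
      ca_x = CA[, 1], ca_y = CA[, 2], ca_z = CA[, 3],
      c_x = C[, 1], c_y = C[, 2], c_z = C[, 3]
    ),
    id = id
  )
}

#' Synthetic calibration corpus for the elliptical-path derivation
#'
#' Chains whose torsions are drawn from [calibration_mixture()] — basins
#' arranged along the designed elliptical reference path — reconstructed
#' into backbones. [derive_ellipse()] on this corpus yields the package's
#' default ellipse.
#'
#' @param n_chains number of chains.
#' @param len residues per chain.
#' @param seed integer seed.
#' @return named list of [domain_structure()]s.
#' @export
calibration_corpus <- function(n_chains = 36, len = 40, seed = 20191212) {
  mix <- calibration_mixture()
  purrr::map(seq_len(n_chains), function(k) {
    ts <- sample_torsions(mix, len, seed = seed + k)
    build_backbone(ts, id = sprintf("cal_%03d", k))
  }) |>
    rlang::set_names(sprintf("cal_%03d", seq_len(n_chains)))
}

#' Synthetic fuzzy-oil-drop test case
#'
#' Samples a compact globular CA cloud from an isotropic Gaussian and
#' assigns amino acids by distance from the centroid using the rank
#' hydrophobicity scale: `"compliant"` places the most hydrophobic residues
#' innermost (rank-matched to a centric core), `"anti"` reverses the
#' matching (hydrophobic residues outside), `"random"` assigns uniformly.
#'
#' @param mode `"compliant"`, `"anti"` or `"random"`.
#' @param n number of residues (>= 20).
#' @param seed integer seed.
#' @param sd_cloud per-axis standard deviation of the cloud in Angstrom.
#' @return list with `domain` (a [domain_structure()]), `scale` (the rank
#'   scale) and `aa` (the assignment).
#' @export
make_fod_case <- function(mode = c("compliant", "anti", "random"), n = 60,
                          seed = 1, sd_cloud = 7) {
  mode <- match.arg(mode)
  if (n < 20) abort("n must be >= 20")
  scale <- hydrophobicity_scale("rank")
  withr::with_seed(seed, {
    pts <- matrix(rnorm(3 * n, sd = sd_cloud), n, 3)
    d <- sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))
    aa_by_hr_desc <- names(sort(scale, decreasing = TRUE))
    bucket <- ceiling(rank(d, ties.method = "first") * 20 / n)
    aa <- switch(mode,
      compliant = aa_by_hr_desc[bucket],
      anti = rev(aa_by_hr_desc)[bucket],
      random = sample(aa_alphabet(), n, replace = TRUE)
    )
  })
  domain <- domain_structure(
    tibble::tibble(
      index = seq_len(n), aa = aa,
      n_x = pts[, 1] - 1.2, n_y = pts[, 2] + 0.5, n_z = pts[, 3],
      ca_x = pts[, 1], ca_y = pts[, 2], ca_z = pts[, 3],
      c_x = pts[, 1] + 1.0, c_y = pts[, 2] + 0.9, c_z = pts[, 3] + 0.3
    ),
    id = sprintf("fod_%s_%d", mode, seed)
  )
  list(domain = domain, scale = scale, aa = aa)
}

#' Plant a polar-core anomaly into a compliant FOD case
#'
#' Replaces the amino acids of the `k` innermost residues of a compliant
#' synthetic case with the least hydrophobic letter, carving a polar hole
#' into the hydrophobic core. The trimming classifier should remove
#' (predominantly) these positions.
#'
#' @param case result of `make_fod_case("compliant", ...)`.
#' @param k number of innermost residues to invert.
#' @return `case` with modified `domain`/`aa` plus `planted` (chain
#'   indices of the inverted residues).
#' @export
plant_polar_core <- function(case, k = 12) {
  d <- case$domain
  ca <- atom_xyz(d, "CA")
  dist <- sqrt(rowSums(sweep(ca, 2, colMeans(ca))^2))
  planted <- order(dist)[seq_len(k)]
  aa_min <- names(case$scale)[which.min(case$scale)]
  d$aa[planted] <- aa_min
  case$domain <- d
  case$aa <- d$aa
  case$planted <- sort(d$index[planted])
  case
}

#' Planted-corpus specification
#'
#' @param n_null number of null tetrapeptide sequences (shared code-profile
#'   in both classes).
#' @param signal_seqs character vector of signal tetrapeptides; `NULL`
#'   draws `n_signal` random ones.
#' @param n_signal number of signal sequences when `signal_seqs` is `NULL`.
#' @param m_windows multinomial window draws per sequence per class.
#' @param effect in `(0, 1]`: the noncompliant signal profile is
#'   `(1 - effect) * base + effect * rank-reversed(base)`.
#' @param seed integer seed.
#' @return list of class `planted_corpus_spec`.
#' @export
planted_corpus_spec <- function(n_null = 50, signal_seqs = NULL, n_signal = 3,
                                m_windows = 6000, effect = 1, seed = 1) {
  if (effect <= 0 || effect > 1) abort("effect must be in (0, 1]")
  if (effect < 0.25) warn("effect may be too small to plant a detectable signal")
  structure(
    list(
      n_null = n_null, signal_seqs = signal_seqs, n_signal = n_signal,
      m_windows = m_windows, effect = effect, seed = seed
    ),
    class = "planted_corpus_spec"
  )
}

# rank-reversed reassignment of a probability profile: the cell holding the
# k-th smallest weight receives the k-th largest, making the population
# Pearson correlation with the base profile strongly negative
reverse_ranks <- function(w) {
  out <- numeric(length(w))
  out[order(w)] <- sort(w, decreasing = TRUE)
  out
}

#' Generate paired corpora with planted tetrapeptide code-frequency signals
#'
#' Each tetrapeptide sequence gets a base code-4-mer profile drawn from a
#' symmetric Dirichlet over the 2401 code states. The compliant class draws
#' multinomial window counts from the base profile for every sequence; the
#' noncompliant class reuses the base profile for null sequences (so their
#' between-class correlation is positive) and a rank-reversed profile for
#' signal sequences (anti-correlated by construction). Rows are 4-residue
#' (aa_seq, code_seq) chains, each contributing exactly one window.
#'
#' @param spec a [planted_corpus_spec()].
#' @return tibble with columns `aa_seq`, `code_seq`, `label`, `count`;
#'   attribute `signal_seqs` lists the planted sequences.
#' @export
make_planted_corpus <- function(spec = planted_corpus_spec()) {
  stopifnot(inherits(spec, "planted_corpus_spec"))
  n_states <- 7^4
  codes <- code4_unrank(0:(n_states - 1))
  withr::with_seed(spec$seed, {
    all_seqs <- character(0)
    signal <- spec$signal_seqs
    if (is.null(signal) && spec$n_signal > 0) {
      signal <- seq4_unrank(sample.int(20^4, spec$n_signal) - 1L)
    }
    signal <- signal %||% character(0)
    nulls <- character(0)
    if (spec$n_null > 0) {
      repeat {
        nulls <- unique(seq4_unrank(sample.int(20^4, spec$n_null * 2) - 1L))
        nulls <- setdiff(nulls, signal)[seq_len(spec$n_null)]
        if (!anyNA(nulls)) break
      }
    }
    seqs <- c(signal, nulls)
    rows <- purrr::map(seqs, function(s) {
      w <- rgamma(n_states, shape = 1)
      w <- w / sum(w)
      w_non <- w
      if (s %in% signal) {
        w_non <- (1 - spec$effect) * w + spec$effect * reverse_ranks(w)
      }
      x <- as.integer(rmultinom(1, spec$m_windows, w))
      y <- as.integer(rmultinom(1, spec$m_windows, w_non))
      dplyr::bind_rows(
        tibble::tibble(
          aa_seq = s, code_seq = codes[x > 0], label = "compliant",
          count = x[x > 0]
        ),
        tibble::tibble(
          aa_seq = s, code_seq = codes[y > 0], label = "noncompliant",
          count = y[y > 0]
        )
      )
    })
  })
  structure(dplyr::bind_rows(rows), signal_seqs = signal)
}

#' Build the compliant / noncompliant tables from a planted corpus
#'
#' @param corpus result of [make_planted_corpus()].
#' @return list with `compliant` and `noncompliant` [build_table()] results.
#' @export
corpus_tables <- function(corpus) {
  mk <- function(lab) {
    build_table(
      corpus |>
        dplyr::filter(.data$label == lab) |>
        dplyr::transmute(seq4 = .data$aa_seq, code4 = .data$code_seq, count = .data$count),
      label = lab
    )
  }
  list(compliant = mk("compliant"), noncompliant = mk("noncompliant"))
}
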