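# Fuzzy-oil-drop model: theoretical (T), observed (O) and uniform (R_u)
# hydrophobicity densities, the Kullback-Leibler based RD statistic, the
# iterative worst-residue trimming classifier, and the >=4 status-run filter.

KD_RAW <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Intrinsic hydrophobicity scales
#'
#' `"kd_normalized"` is the Kyte-Doolittle hydropathy index min-max scaled
#' to `[0, 1]` — a documented stand-in default, since FOD results depend on
#' relative hydrophobicity only. `"rank"` assigns the 20 amino acids (in
#' alphabetical order) the equally spaced values 0, 1/19, ..., 1 and is the
#' scale the synthetic generators use, so tests are independent of any
#' published scale.
#'
#' @param name one of `"kd_normalized"`, `"rank"`.
#' @return named numeric vector over the 20 standard letters, values in
#'   `[0, 1]`.
#' @export
hydrophobicity_scale <- function(name = c("kd_normalized", "rank")) {
  name <- match.arg(name)
  if (name == "kd_normalized") {
    s <- (KD_RAW - min(KD_RAW)) / (max(KD_RAW) - min(KD_RAW))
    return(s[order(names(s))])
  }
  stats::setNames(seq(0, 1, length.out = 20), aa_alphabet())
}

#' Read a hydrophobicity scale from a two-column TSV (aa, Hr)
#' @param path TSV path with columns `aa` and `Hr`.
#' @return named numeric vector.
#' @export
read_hydrophobicity_scale <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_scale(stats::setNames(tab$Hr, tab$aa))
}

validate_scale <- function(scale) {
  if (!all(aa_alphabet() %in% names(scale))) {
    abort("hydrophobicity scale must cover all 20 standard amino acids")
  }
  if (any(!is.finite(scale)) || any(scale < 0)) {
    abort("hydrophobicity values must be finite and nonnegative")
  }
  scale
}

#' Effective interaction points of a domain
#'
#' One point per residue carries the residue's hydrophobicity; with
#' backbone-only structures the CA position is the effective point.
#' Incomplete residues are skipped with a warning.
#'
#' @param domain a [domain_structure()].
#' @param mode effective-point mode; only `"CA"` is available for
#'   backbone-only structures.
#' @return list with `points` (k x 3 matrix) and `index` (chain positions
#'   retained).
#' @export
effective_positions <- function(domain, mode = "CA") {
  if (!identical(mode, "CA")) {
    abort("unsupported mode: backbone-only structures provide CA positions only")
  }
  if (nrow(domain) == 0) abort("empty domain")
  CA <- atom_xyz(domain, "CA")
  ok <- rowSums(is.na(CA)) == 0
  if (!any(ok)) abort("empty domain: no CA coordinates")
  if (!all(ok)) {
    warn(sprintf("skipping %d residue(s) without CA coordinates", sum(!ok)))
  }
  list(points = CA[ok, , drop = FALSE], index = domain$index[ok])
}

#' Theoretical (3D Gaussian) hydrophobicity density
#'
#' Points are centered at their mean and rotated to principal axes; the
#' per-axis sigma follows the three-sigma rule (max absolute coordinate
#' along the axis divided by 3). The density of the axis-aligned Gaussian
#' is evaluated at each point and normalized to sum to one — the idealized
#' centric hydrophobic core.
#'
#' @param points n x 3 matrix of effective positions.
#' @return numeric vector `T` summing to 1.
#' @export
theoretical_distribution <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 2) abort("need at least 2 points")
  Pc <- sweep(P, 2, colMeans(P))
  if (max(abs(Pc)) < 1e-9) abort("degenerate spread: all points coincide")
  ev <- eigen(crossprod(Pc), symmetric = TRUE)
  X <- Pc %*% ev$vectors
  sig <- pmax(apply(abs(X), 2, max) / 3, 1e-9)
  logt <- -rowSums(sweep(X^2, 2, 2 * sig^2, "/"))
  t_raw <- exp(logt - max(logt))
  t_raw / sum(t_raw)
}

# Levitt's sigmoid contact polynomial on x = r / cutoff
contact_kernel <- function(x) {
  g <- 1 - 0.5 * (7 * x^2 - 9 * x^4 + 5 * x^6 - x^8)
  g[x > 1] <- 0
  g
}

#' Observed hydrophobicity density
#'
#' Each residue collects hydrophobicity from all residues within the
#' cutoff: `O_i` is proportional to the sum over j (including j = i) of
#' `(Hr_i + Hr_j) * g(r_ij / c)` where g is the sigmoid contact polynomial
#' `g(x) = 1 - (7x^2 - 9x^4 + 5x^6 - x^8)/2` for `x <= 1`, else 0. The
#' result is normalized to a density.
#'
#' @param points n x 3 matrix of effective positions.
#' @param aas character vector of one-letter codes aligned with `points`.
#' @param scale named hydrophobicity vector (see [hydrophobicity_scale()]).
#' @param cutoff contact cutoff c in Angstrom.
#' @return numeric vector `O` summing to 1.
#' @export
observed_distribution <- function(points, aas, scale = hydrophobicity_scale(), cutoff = 9) {
  P <- as.matrix(points)
  stopifnot(nrow(P) == length(aas))
  h <- unname(scale[aas])
  if (anyNA(h)) abort(paste("unknown amino acid(s):", paste(unique(aas[is.na(h)]), collapse = ", ")))
  if (all(h == 0)) abort("zero hydrophobicity: all Hr are 0")
  D <- as.matrix(stats::dist(P)) / cutoff
  G <- contact_kernel(D)
  diag(G) <- 1
  o_raw <- as.numeric(G %*% h) + h * rowSums(G)
  unname(o_raw / sum(o_raw))
}

#' Kullback-Leibler divergence in bits
#'
#' `sum(P * log2(P / Q))` with the convention `0 * log(0/q) = 0`.
#'
#' @param p,q densities of equal length (each summing to 1).
#' @param base logarithm base (2 for bits).
#' @return divergence (nonnegative).
#' @export
kl_divergence <- function(p, q, base = 2) {
  stopifnot(length(p) == length(q))
  pos <- p > 0
  if (any(q[pos] == 0)) abort("unbounded divergence: P > 0 where Q = 0")
  sum(p[pos] * log(p[pos] / q[pos], base = base))
}

#' Relative distance RD of an observed distribution
#'
#' `RD = D(O|T) / (D(O|T) + D(O|R_u))`; the structure is FOD-compliant when
#' RD falls below the threshold (0.5). RD is invariant to the logarithm
#' base of the divergence.
#'
#' @param o,t_dens,r_u densities of equal length; `r_u` defaults to the
#'   uniform reference `1/N`.
#' @param base log base passed to [kl_divergence()].
#' @return list with `rd`, `d_ot`, `d_or` (divergences in the chosen base).
#' @export
compute_rd <- function(o, t_dens, r_u = NULL, base = 2) {
  r_u <- r_u %||% rep(1 / length(o), length(o))
  d_ot <- kl_divergence(o, t_dens, base = base)
  d_or <- kl_divergence(o, r_u, base = base)
  if (d_ot + d_or == 0) {
    warn("O, T and R_u coincide; RD defined as 0")
    return(list(rd = 0, d_ot = d_ot, d_or = d_or))
  }
  list(rd = d_ot / (d_ot + d_or), d_ot = d_ot, d_or = d_or)
}

#' Full FOD profile of a domain
#'
#' @param domain a [domain_structure()].
#' @param scale named hydrophobicity vector.
#' @param cutoff contact cutoff in Angstrom.
#' @return object of class `fod_profile`: list with `id`, `n`, `rd`,
#'   `d_ot`, `d_or` and a per-residue tibble `residues` (index, aa, t_dens,
#'   o_dens, r_u).
#' @export
fod_profile <- function(domain, scale = hydrophobicity_scale(), cutoff = 9) {
  validate_scale(scale)
  eff <- effective_positions(domain)
  aas <- domain$aa[match(eff$index, domain$index)]
  t_dens <- theoretical_distribution(eff$points)
  o_dens <- observed_distribution(eff$points, aas, scale, cutoff)
  n <- length(t_dens)
  r_u <- rep(1 / n, n)
  rd <- compute_rd(o_dens, t_dens, r_u)
  structure(
    list(
      id = domain_id(domain), n = n,
      rd = rd$rd, d_ot = rd$d_ot, d_or = rd$d_or,
      residues = tibble::tibble(
        index = eff$index, aa = aas,
        t_dens = t_dens, o_dens = o_dens, r_u = r_u
      )
    ),
    class = "fod_profile"
  )
}

#' @export
print.fod_profile <- function(x, ...) {
  cat(sprintf(
    "<fod_profile> id=%s  n=%d  RD=%.4f (D_OT=%.4f, D_OR=%.4f bits) -> %s\n",
    x$id, x$n, x$rd, x$d_ot, x$d_or,
    if (x$rd < 0.5) "compliant" else "noncompliant"
  ))
  invisible(x)
}

#' @export
tidy.fod_profile <- function(x, ...) x$residues

#' @export
glance.fod_profile <- function(x, ...) {
  tibble::tibble(
    id = x$id, n = x$n, rd = x$rd, d_ot = x$d_ot, d_or = x$d_or,
    compliant = x$rd < 0.5
  )
}

#' Iterative worst-residue trimming classifier
#'
#' Recomputes the FOD profile on the retained residues; while the RD is at
#' or above the threshold, the residue with the largest absolute difference
#' between theoretical and observed hydrophobicity density (ties broken to
#' the lowest index) is removed and both distributions (including the
#' Gaussian parameters) are recomputed. Removed residues are labelled
#' noncompliant, retained ones compliant. If fewer than `min_keep` residues
#' remain without the RD dropping below the threshold, every residue is
#' labelled noncompliant and `never_compliant` is set.
#'
#' @param domain a [domain_structure()].
#' @param scale named hydrophobicity vector.
#' @param threshold RD threshold (0.5).
#' @param cutoff contact cutoff in Angstrom.
#' @param min_keep smallest retained set the loop may reach.
#' @return object of class `compliance_status`: list with `id`,
#'   `original_rd`, `final_rd`, `never_compliant`, `removal_order` (chain
#'   indices in removal order) and per-residue tibble `status` (index, aa,
#'   status in {"C", "N"}).
#' @export
trim_classify <- function(domain, scale = hydrophobicity_scale(), threshold = 0.5,
                          cutoff = 9, min_keep = 5) {
  validate_scale(scale)
  eff <- effective_positions(domain)
  aas <- domain$aa[match(eff$index, domain$index)]
  keep <- rep(TRUE, length(eff$index))
  removal <- integer(0)
  original_rd <- NA_real_
  final_rd <- NA_real_
  never <- FALSE
  repeat {
    P <- eff$points[keep, , drop = FALSE]
    a <- aas[keep]
    t_dens <- theoretical_distribution(P)
    o_dens <- observed_distribution(P, a, scale, cutoff)
    rd <- compute_rd(o_dens, t_dens)$rd
    if (is.na(original_rd)) original_rd <- rd
    if (rd < threshold) {
      final_rd <- rd
      break
    }
    if (sum(keep) - 1 < min_keep) {
      never <- TRUE
      final_rd <- rd
      keep[] <- FALSE
      removal <- eff$index
      break
    }
    worst <- which.max(abs(t_dens - o_dens)) # ties: which.max takes lowest index
    pos <- which(keep)[worst]
    removal <- c(removal, eff$index[pos])
    keep[pos] <- FALSE
  }
  status <- tibble::tibble(
    index = eff$index,
    aa = aas,
    status = ifelse(keep, "C", "N")
  )
  structure(
    list(
      id = domain_id(domain), original_rd = original_rd, final_rd = final_rd,
      never_compliant = never, removal_order = removal, status = status
    ),
    class = "compliance_status"
  )
}

#' @export
print.compliance_status <- function(x, ...) {
  cat(sprintf(
    "<compliance_status> id=%s  original RD=%.4f  removed %d/%d  final RD=%.4f%s\n",
    x$id, x$original_rd, length(x$removal_order), nrow(x$status), x$final_rd,
    if (x$never_compliant) "  [never compliant]" else ""
  ))
  invisible(x)
}

#' @export
tidy.compliance_status <- function(x, ...) x$status

#' @export
glance.compliance_status <- function(x, ...) {
  tibble::tibble(
    id = x$id, n = nrow(x$status), original_rd = x$original_rd,
    final_rd = x$final_rd, n_removed = length(x$removal_order),
    never_compliant = x$never_compliant
  )
}

#' Maximal constant-status runs of a minimum length
#'
#' @param status character vector of per-residue labels (`"C"`/`"N"`), or a
#'   `compliance_status` object.
#' @param min_len minimum run length to keep (4).
#' @return tibble with columns `status`, `start`, `end` (chain positions,
#'   inclusive) in chain order.
#' @export
status_runs <- function(status, min_len = 4) {
  if (inherits(status, "compliance_status")) status <- status$status$status
  if (length(status) == 0) {
    return(tibble::tibble(status = character(), start = integer(), end = integer()))
  }
  r <- rle(status)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- tibble::tibble(status = r$values, start = starts, end = ends)
  out[r$lengths >= min_len, ]
}

#' Intrinsic hydrophobicity profile of a sequence window
#'
#' @param sequence string or character vector over the 20-letter alphabet.
#' @param scale named hydrophobicity vector.
#' @return tibble with columns `position`, `aa`, `hr`.
#' @export
hydrophobicity_profile <- function(sequence, scale = hydrophobicity_scale()) {
  aas <- if (length(sequence) == 1) strsplit(sequence, "")[[1]] else sequence
  if (!all(aas %in% aa_alphabet())) {
    abort(paste("unknown letter(s):", paste(setdiff(aas, aa_alphabet()), collapse = ", ")))
  }
  tibble::tibble(position = seq_along(aas), aa = aas, hr = unname(scale[aas]))
}

#' Write a per-domain FOD report as JSON
#'
#' @param profile a [fod_profile()].
#' @param status optional [trim_classify()] result for the same domain.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fod_report <- function(profile, status = NULL, path) {
  res <- profile$residues
  if (!is.null(status)) {
    res$status <- status$status$status[match(res$index, status$status$index)]
  }
  jsonlite::write_json(
    list(
      id = profile$id, n = profile$n, d_ot = profile$d_ot,
      d_or = profile$d_or, rd = profile$rd, residues = res
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
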