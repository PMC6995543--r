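# Structural codes A-G: integer t-angle intervals, histogramming, and the
# per-domain encoder.

#' Structural-code interval table
#'
#' The default seven intervals over the integer t angles 0..359:
#' A 0-50, B 51-85, C 86-110, D 111-150, E 151-193, F 194-225, G 226-359
#' (inclusive on both ends, jointly covering 0..359 with no overlap).
#'
#' @param entries optional tibble with columns `code`, `from`, `to`
#'   overriding the default.
#' @return tibble of class `code_table`.
#' @export
code_interval_table <- function(entries = NULL) {
  tab <- entries %||% tibble::tibble(
    code = c("A", "B", "C", "D", "E", "F", "G"),
    from = c(0L, 51L, 86L, 111L, 151L, 194L, 226L),
    to   = c(50L, 85L, 110L, 150L, 193L, 225L, 359L)
  )
  tab <- tibble::as_tibble(tab)
  stopifnot(all(c("code", "from", "to") %in% names(tab)))
  covered <- unlist(purrr::map2(tab$from, tab$to, seq))
  if (anyDuplicated(covered) || !setequal(covered, 0:359)) {
    abort("code intervals must partition the integers 0..359")
  }
  structure(tab, class = c("code_table", class(tab)))
}

code_lookup_vector <- function(table) {
  lut <- character(360)
  for (i in seq_len(nrow(table))) {
    lut[(table$from[i]:table$to[i]) + 1L] <- table$code[i]
  }
  lut
}

#' Assign structural codes to t angles
#'
#' A t value is wrapped modulo 360 and assigned the code of the integer
#' interval containing `floor(t)` (intervals are integer-closed, so real t
#' bins are half-open `[from, to + 1)`).
#'
#' @param t numeric vector of parametric angles in degrees (`NA` allowed,
#'   propagated; `NaN` is an error).
#' @param table a [code_interval_table()].
#' @return character vector of codes (`NA` where t is `NA`).
#' @export
assign_code <- function(t, table = code_interval_table()) {
  if (any(is.nan(t))) abort("undefined t: NaN supplied")
  lut <- code_lookup_vector(table)
  out <- rep(NA_character_, length(t))
  ok <- !is.na(t)
  out[ok] <- lut[floor(t[ok] %% 360) + 1L]
  out
}

#' One-degree histogram of t angles
#'
#' @param ts numeric vector of t angles in degrees, each in `[0, 360)`
#'   (`NA` dropped).
#' @return object of class `t_histogram`: tibble with columns `bin`
#'   (0..359, bin i covers `[i, i+1)`) and `count`; `sum(count)` equals the
#'   number of finite inputs.
#' @export
build_t_histogram <- function(ts) {
  ts <- ts[is.finite(ts)]
  if (any(ts < 0 | ts >= 360)) abort("t values must lie in [0, 360)")
  counts <- tabulate(floor(ts) + 1L, nbins = 360L)
  structure(
    tibble::tibble(bin = 0:359, count = counts),
    class = c("t_histogram", class(tibble::tibble())),
    n = length(ts)
  )
}

circular_moving_average <- function(x, window) {
  if (window %% 2 != 1) abort("smoothing window must be odd")
  if (window == 1) return(x)
  h <- (window - 1) / 2
  n <- length(x)
  ext <- c(tail(x, h), x, head(x, h))
  vapply(seq_len(n), function(i) mean(ext[i:(i + window - 1)]), numeric(1))
}

#' Local maxima of a t histogram
#'
#' Smooths the histogram with a circular moving average and reports bins
#' that dominate their circular neighbourhood (radius `neighborhood`);
#' boundaries between adjacent code intervals are proposed at the minima
#' between consecutive maxima.
#'
#' @param h a [build_t_histogram()] result.
#' @param smoothing_window odd integer window for the circular moving
#'   average (1 disables smoothing).
#' @param neighborhood a maximum must be the largest smoothed value within
#'   this many bins on either side (suppresses sampling-noise twins).
#' @return tibble with one row per maximum: `peak` (bin), `height`
#'   (smoothed count), `boundary_from`, `boundary_to` (proposed interval,
#'   inclusive integer bins).
#' @export
find_local_maxima <- function(h, smoothing_window = 5, neighborhood = 10) {
  x <- h$count
  if (sum(x) == 0 || length(unique(x)) == 1) abort("no maxima: flat histogram")
  s <- circular_moving_average(as.numeric(x), smoothing_window)
  if (length(unique(round(s, 12))) == 1) abort("no maxima: flat histogram")
  n <- length(s)
  r <- max(1L, as.integer(neighborhood))
  is_peak <- vapply(seq_len(n), function(i) {
    win <- ((i - 1 + seq(-r, r)) %% n) + 1L
    s[i] >= max(s[win]) && i == win[which.max(s[win])]
  }, logical(1))
  peaks <- which(is_peak) - 1L
  # merge candidates closer than the neighbourhood radius (circular)
  if (length(peaks) > 1) {
    keep <- rep(TRUE, length(peaks))
    for (i in seq_along(peaks)) {
      for (j in seq_along(peaks)) {
        if (i != j && keep[i] && keep[j]) {
          dd <- min(abs(peaks[i] - peaks[j]), n - abs(peaks[i] - peaks[j]))
          if (dd <= r && s[peaks[j] + 1L] > s[peaks[i] + 1L]) keep[i] <- FALSE
        }
      }
    }
    peaks <- peaks[keep]
  }
  if (length(peaks) == 0) abort("no maxima: flat histogram")
  k <- length(peaks)
  if (k == 1) {
    return(tibble::tibble(
      peak = peaks, height = s[peaks + 1L],
      boundary_from = 0L, boundary_to = 359L
    ))
  }
  # minimum between each consecutive pair of peaks (circular)
  cuts <- integer(k)
  for (j in seq_len(k)) {
    a <- peaks[j]
    b <- if (j < k) peaks[j + 1] else peaks[1] + 360L
    span <- (a + 1):(b - 1)
    idx <- (span %% 360L) + 1L
    cuts[j] <- span[which.min(s[idx])] %% 360L
  }
  starts <- c(cuts[k] + 1L, cuts[-k] + 1L) %% 360L
  ends <- cuts
  tibble::tibble(
    peak = peaks, height = s[peaks + 1L],
    boundary_from = as.integer(starts), boundary_to = as.integer(ends)
  )
}

#' Encode a domain into early-stage structural codes
#'
#' Computes backbone dihedrals, projects each defined (phi, psi) onto the
#' elliptical path, and assigns the structural code of the resulting t
#' angle. Residues without both dihedrals (chain termini, breaks, missing
#' atoms) get `NA` codes.
#'
#' @param domain a [domain_structure()] with at least 5 residues.
#' @param e an [ellipse_spec()]; defaults to [default_ellipse()].
#' @param table a [code_interval_table()].
#' @return tibble with columns `index`, `aa`, `phi`, `psi`, `phi_e`,
#'   `psi_e`, `t`, `code`, carrying the domain id as attribute `id`.
#' @export
encode_domain <- function(domain, e = default_ellipse(), table = code_interval_table()) {
  if (nrow(domain) < 5) abort("too short: domain has fewer than 5 residues")
  dih <- compute_dihedrals(domain)
  proj <- project_to_ellipse(dih$phi, dih$psi, e)
  out <- dplyr::bind_cols(dih, proj)
  out$code <- assign_code(out$t, table)
  if (all(is.na(out$code))) abort("no dihedrals: nothing to encode")
  structure(out, id = domain_id(domain), class = class(out))
}

#' Collapse an encoding to a plain code string
#'
#' @param encoding result of [encode_domain()].
#' @param undefined character used for residues without a code.
#' @return single string.
#' @export
code_string <- function(encoding, undefined = "-") {
  paste(ifelse(is.na(encoding$code), undefined, encoding$code), collapse = "")
}

#' Write a per-domain encoding as TSV
#'
#' @param encoding result of [encode_domain()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_encoding <- function(encoding, path) {
  readr::write_tsv(encoding, path, progress = FALSE)
  invisible(path)
}
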