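# Sequence-structure contingency tables over the 4-position window:
# 160,000 (= 20^4) tetrapeptide sequence columns by 2401 (= 7^4)
# structural-code rows, the size-ratio scaling, and the
# correlation-significance screen.

#' The seven-letter structural-code alphabet
#' @return character vector `A`..`G`.
#' @export
code_alphabet <- function() LETTERS[1:7]

#' Canonical enumeration of 4-mers over an alphabet
#'
#' Lexicographic order; rank 0 is the first 4-mer (`"AAAA"`).
#'
#' @param alphabet character vector of letters (sorted).
#' @return character vector of all `length(alphabet)^4` 4-mers in
#'   lexicographic order.
#' @export
enumerate_4mers <- function(alphabet) {
  k <- length(alphabet)
  idx <- expand.grid(
    p4 = seq_len(k), p3 = seq_len(k), p2 = seq_len(k), p1 = seq_len(k)
  )
  paste0(
    alphabet[idx$p1], alphabet[idx$p2], alphabet[idx$p3], alphabet[idx$p4]
  )
}

fourmer_rank <- function(x, alphabet) {
  k <- length(alphabet)
  m <- matrix(match(unlist(strsplit(x, "")), alphabet) - 1L, nrow = 4)
  if (anyNA(m)) abort("invalid key: letter outside the alphabet")
  as.integer(m[1, ] * k^3 + m[2, ] * k^2 + m[3, ] * k + m[4, ])
}

fourmer_unrank <- function(r, alphabet) {
  k <- length(alphabet)
  p1 <- r %/% k^3; r2 <- r %% k^3
  p2 <- r2 %/% k^2; r3 <- r2 %% k^2
  p3 <- r3 %/% k; p4 <- r3 %% k
  paste0(alphabet[p1 + 1], alphabet[p2 + 1], alphabet[p3 + 1], alphabet[p4 + 1])
}

#' Lexicographic rank of sequence / code 4-mers
#'
#' `seq4_rank()` maps amino-acid 4-mers to `0..159999`; `code4_rank()` maps
#' structural-code 4-mers to `0..2400`. `seq4_unrank()` / `code4_unrank()`
#' invert them.
#'
#' @param x character vector of 4-mers.
#' @param r integer vector of ranks.
#' @return integer ranks or character 4-mers.
#' @export
seq4_rank <- function(x) fourmer_rank(x, aa_alphabet())

#' @rdname seq4_rank
#' @export
seq4_unrank <- function(r) fourmer_unrank(r, aa_alphabet())

#' @rdname seq4_rank
#' @export
code4_rank <- function(x) fourmer_rank(x, code_alphabet())

#' @rdname seq4_rank
#' @export
code4_unrank <- function(r) fourmer_unrank(r, code_alphabet())

#' Extract sequence-structure window pairs from an encoded domain
#'
#' Slides a 4-position window along the aligned amino-acid and code
#' sequences. Windows containing an undefined code or an `X` residue are
#' dropped. For an originally compliant domain every surviving window joins
#' the compliant set; for an originally noncompliant domain a window is
#' kept only when it lies entirely inside one qualifying constant-status
#' run (length >= `min_run`) and joins that run's set.
#'
#' @param aa_seq amino-acid sequence (string or character vector).
#' @param code_seq structural-code sequence, same length (`NA` or `"-"`
#'   marks undefined positions).
#' @param status optional per-residue status labels (`"C"`/`"N"`) or a
#'   [trim_classify()] result; used when `origin_compliant` is `FALSE`.
#' @param origin_compliant was the whole domain compliant before trimming?
#' @param min_run minimum qualifying run length.
#' @return tibble with columns `seq4`, `code4`, `set_label`.
#' @export
extract_windows <- function(aa_seq, code_seq, status = NULL,
                            origin_compliant = TRUE, min_run = 4) {
  aa <- if (length(aa_seq) == 1) strsplit(aa_seq, "")[[1]] else aa_seq
  cd <- if (length(code_seq) == 1) strsplit(code_seq, "")[[1]] else code_seq
  stopifnot(length(aa) == length(cd))
  n <- length(aa)
  empty <- tibble::tibble(
    seq4 = character(), code4 = character(), set_label = character()
  )
  if (n < 4) return(empty)
  cd[cd == "-"] <- NA_character_
  ok <- aa %in% aa_alphabet() & cd %in% code_alphabet()
  starts <- seq_len(n - 3)
  valid <- vapply(starts, function(i) all(ok[i:(i + 3)]), logical(1))
  if (origin_compliant) {
    lab <- rep("compliant", length(starts))
    keep <- valid
  } else {
    if (is.null(status)) abort("status labels required for a noncompliant-origin domain")
    runs <- status_runs(status, min_len = min_run)
    runs <- runs[runs$status %in% c("C", "N"), ]
    lab <- rep(NA_character_, length(starts))
    keep <- rep(FALSE, length(starts))
    for (j in seq_len(nrow(runs))) {
      inside <- starts >= runs$start[j] & (starts + 3) <= runs$end[j]
      lab[inside] <- if (runs$status[j] == "C") "compliant" else "noncompliant"
      keep <- keep | inside
    }
    keep <- keep & valid
  }
  i <- starts[keep]
  if (length(i) == 0) return(empty)
  sub4 <- function(v, i) {
    vapply(i, function(s) paste(v[s:(s + 3)], collapse = ""), character(1))
  }
  tibble::tibble(seq4 = sub4(aa, i), code4 = sub4(cd, i), set_label = lab[keep])
}

#' Build a sequence-structure contingency table
#'
#' Aggregates window pairs into sparse counts keyed by (seq4, code4); the
#' logical table has 160,000 sequence columns and 2401 code rows regardless
#' of sparsity.
#'
#' @param pairs tibble with columns `seq4`, `code4` and optionally `count`
#'   (default 1 per row).
#' @param label set label (`"compliant"` / `"noncompliant"`).
#' @return object of class `contingency_table`: tibble `(seq4, code4, n)`
#'   with attributes `total`, `label`, `scale_factor`.
#' @export
build_table <- function(pairs, label = "compliant") {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) > 0) {
    seq4_rank(pairs$seq4) # validates the sequence alphabet
    code4_rank(pairs$code4)
    if (any(nchar(pairs$seq4) != 4) || any(nchar(pairs$code4) != 4)) {
      abort("invalid key: 4-mers required")
    }
  }
  if (!"count" %in% names(pairs)) pairs$count <- 1
  tab <- pairs |>
    dplyr::group_by(.data$seq4, .data$code4) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$seq4, .data$code4)
  structure(
    tab,
    total = sum(tab$n), label = label, scale_factor = 1,
    class = c("contingency_table", class(tab))
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf(
    "<contingency_table> label=%s  total=%.6g  %d occupied cells (of 160000 x 2401)  scale=%.4g\n",
    attr(x, "label"), attr(x, "total"), nrow(x), attr(x, "scale_factor")
  ))
  NextMethod()
}

#' @export
glance.contingency_table <- function(x, ...) {
  tibble::tibble(
    label = attr(x, "label"), total = attr(x, "total"),
    occupied = nrow(x), scale_factor = attr(x, "scale_factor"),
    n_seq_columns = 20^4, n_code_rows = 7^4
  )
}

table_total <- function(x) attr(x, "total")

#' Scale the smaller table up to the larger set's size
#'
#' Multiplies every count of the smaller-total table by the size ratio
#' (larger total / smaller total); counts stay real-valued.
#'
#' @param small,large two `contingency_table`s (order-insensitive: the
#'   smaller-total one is scaled).
#' @return the scaled copy of the smaller table, with `scale_factor` set.
#' @export
scale_table <- function(small, large) {
  ts <- table_total(small); tl <- table_total(large)
  if (ts == 0 || tl == 0) abort("empty set: both tables need positive totals")
  if (ts > tl) return(scale_table(large, small))
  factor <- tl / ts
  out <- small
  out$n <- out$n * factor
  attr(out, "total") <- sum(out$n)
  attr(out, "scale_factor") <- factor
  out
}

#' Dense column / row vectors of a contingency table
#'
#' `column_vector()` returns the counts of one tetrapeptide sequence over
#' all 2401 code 4-mers in canonical (lexicographic) order;
#' `row_vector()` returns the counts of one code 4-mer over all 160,000
#' sequences.
#'
#' @param table a `contingency_table`.
#' @param seq4,code4 the fixed key.
#' @return dense numeric vector (zeros for absent cells).
#' @export
column_vector <- function(table, seq4) {
  seq4_rank(seq4)
  v <- numeric(7^4)
  sel <- table$seq4 == seq4
  v[code4_rank(table$code4[sel]) + 1L] <- table$n[sel]
  v
}

#' @rdname column_vector
#' @export
row_vector <- function(table, code4) {
  code4_rank(code4)
  v <- numeric(20^4)
  sel <- table$code4 == code4
  v[seq4_rank(table$seq4[sel]) + 1L] <- table$n[sel]
  v
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (length >= 3, nonconstant).
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("insufficient n: need length >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort("undefined correlation: constant vector")
  cor(x, y)
}

#' Large-sample significance of a correlation coefficient
#'
#' The test statistic `z = r * sqrt(n - 2) / sqrt(1 - r^2)` is compared
#' with the two-sided large-sample critical value (1.96 at alpha = 0.05);
#' `|r| = 1` is significant by convention.
#'
#' @param r correlation coefficient.
#' @param n vector length the correlation was computed over.
#' @param alpha significance level.
#' @param critical critical value; default is the two-sided normal quantile
#'   at `alpha`, rounded to two decimals (1.96 for 0.05).
#' @return list with `z_stat`, `significant`, `critical`.
#' @export
significance <- function(r, n, alpha = 0.05, critical = NULL) {
  if (n < 3) abort("insufficient n")
  critical <- critical %||% round(qnorm(1 - alpha / 2), 2)
  if (abs(r) >= 1) {
    return(list(z_stat = sign(r) * Inf, significant = TRUE, critical = critical))
  }
  z <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(z_stat = z, significant = abs(z) >= critical, critical = critical)
}

# sparse per-key sums of two tables along one dimension
screen_sums <- function(compliant, noncompliant, key_col, other_col) {
  a <- tibble::as_tibble(compliant)[c(key_col, other_col, "n")]
  b <- tibble::as_tibble(noncompliant)[c(key_col, other_col, "n")]
  names(a) <- c("key", "other", "x")
  names(b) <- c("key", "other", "y")
  j <- dplyr::full_join(a, b, by = c("key", "other"))
  j$x[is.na(j$x)] <- 0
  j$y[is.na(j$y)] <- 0
  j |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      sx = sum(.data$x), sy = sum(.data$y),
      sxx = sum(.data$x^2), syy = sum(.data$y^2), sxy = sum(.data$x * .data$y),
      nz_joint = sum(.data$x > 0 & .data$y > 0),
      .groups = "drop"
    )
}

#' Correlation-significance screen over the two contingency tables
#'
#' For each occupied key — a tetrapeptide sequence in `"columns"` mode, a
#' structural-code 4-mer in `"rows"` mode — the Pearson correlation between
#' the compliant and noncompliant count vectors is computed over all
#' canonical cells (2401 or 160,000; zeros included), or over jointly
#' nonzero cells with `cells = "joint_nonzero"`. The noncompliant table is
#' scaled to the compliant total first (the factor cannot change any r).
#'
#' @param compliant,noncompliant `contingency_table`s.
#' @param mode `"columns"` (fixed sequence) or `"rows"` (fixed code 4-mer).
#' @param alpha significance level.
#' @param cells `"all"` or `"joint_nonzero"` (which cells enter each
#'   vector, hence n).
#' @param critical optional critical value override.
#' @return object of class `code_screen`: tibble with columns `key`, `r`,
#'   `z_stat`, `n`, `significant`, `sign`, sorted by key; attributes
#'   `mode`, `alpha`, `critical`, `scale_factor`.
#' @export
correlation_screen <- function(compliant, noncompliant, mode = c("columns", "rows"),
                               alpha = 0.05, cells = c("all", "joint_nonzero"),
                               critical = NULL) {
  mode <- match.arg(mode)
  cells <- match.arg(cells)
  if (table_total(compliant) == 0 && table_total(noncompliant) == 0) {
    abort("nothing to screen: both tables empty")
  }
  scaled <- scale_table(noncompliant, compliant)
  factor <- attr(scaled, "scale_factor")
  if (table_total(scaled) <= table_total(compliant) * (1 + 1e-12)) {
    noncompliant <- scaled
  } else {
    compliant <- scaled
  }
  key_col <- if (mode == "columns") "seq4" else "code4"
  other_col <- if (mode == "columns") "code4" else "seq4"
  n_cells <- if (mode == "columns") 7^4 else 20^4
  sums <- screen_sums(compliant, noncompliant, key_col, other_col)
  critical <- critical %||% round(qnorm(1 - alpha / 2), 2)
  if (cells == "all") {
    recs <- purrr::pmap(sums, function(key, sx, sy, sxx, syy, sxy, nz_joint) {
      n <- n_cells
      cov <- sxy - sx * sy / n
      vx <- sxx - sx^2 / n
      vy <- syy - sy^2 / n
      if (vx <= 0 || vy <= 0) {
        return(tibble::tibble(
          key = key, r = NA_real_, z_stat = NA_real_, n = n,
          significant = FALSE, sign = "none"
        ))
      }
      r <- clamp1(cov / sqrt(vx * vy))
      sig <- significance(r, n, alpha = alpha, critical = critical)
      tibble::tibble(
        key = key, r = r,
        z_stat = sig$z_stat, n = n, significant = sig$significant,
        sign = if (!sig$significant) "none" else if (r > 0) "positive" else "negative"
      )
    })
  } else {
    recs <- purrr::map(sums$key, function(k) {
      x <- compliant$n[compliant[[key_col]] == k]
      xo <- compliant[[other_col]][compliant[[key_col]] == k]
      y <- noncompliant$n[noncompliant[[key_col]] == k]
      yo <- noncompliant[[other_col]][noncompliant[[key_col]] == k]
      shared <- intersect(xo, yo)
      n <- length(shared)
      if (n < 3) {
        return(tibble::tibble(
          key = k, r = NA_real_, z_stat = NA_real_, n = n,
          significant = FALSE, sign = "none"
        ))
      }
      xv <- x[match(shared, xo)]
      yv <- y[match(shared, yo)]
      if (sd(xv) == 0 || sd(yv) == 0) {
        return(tibble::tibble(
          key = k, r = NA_real_, z_stat = NA_real_, n = n,
          significant = FALSE, sign = "none"
        ))
      }
      r <- cor(xv, yv)
      sig <- significance(r, n, alpha = alpha, critical = critical)
      tibble::tibble(
        key = k, r = r, z_stat = sig$z_stat, n = n, significant = sig$significant,
        sign = if (!sig$significant) "none" else if (r > 0) "positive" else "negative"
      )
    })
  }
  out <- dplyr::bind_rows(recs) |> dplyr::arrange(.data$key)
  structure(
    out,
    mode = mode, alpha = alpha, critical = critical, scale_factor = factor,
    class = c("code_screen", class(out))
  )
}

#' @export
print.code_screen <- function(x, ...) {
  cat(sprintf(
    "<code_screen> mode=%s  alpha=%g  critical=%.2f  %d keys (%d significant negative)\n",
    attr(x, "mode"), attr(x, "alpha"), attr(x, "critical"), nrow(x),
    sum(x$sign == "negative", na.rm = TRUE)
  ))
  NextMethod()
}

#' @export
glance.code_screen <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"), alpha = attr(x, "alpha"),
    critical = attr(x, "critical"), n_keys = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_negative = sum(x$sign == "negative", na.rm = TRUE),
    n_positive = sum(x$sign == "positive", na.rm = TRUE)
  )
}

#' Significantly negative tetrapeptides of a screen
#'
#' The real-data analogue of this report is a short list of tetrapeptide
#' sequences whose code-frequency profiles are anti-correlated between the
#' compliant and noncompliant sets.
#'
#' @param screen a [correlation_screen()] result.
#' @return tibble of the negative-significant records, sorted by key.
#' @export
negative_keys <- function(screen) {
  dplyr::filter(tibble::as_tibble(screen), .data$sign == "negative") |>
    dplyr::arrange(.data$key)
}

#' Persist / restore a contingency table as TSV + JSON sidecar
#'
#' @param table a `contingency_table`.
#' @param path TSV path (`path` + `.json` holds total, label, scale factor).
#' @return `path` (write) or the restored table (read).
#' @export
write_contingency <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  jsonlite::write_json(
    list(
      total = attr(table, "total"), label = attr(table, "label"),
      scale_factor = attr(table, "scale_factor")
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_contingency
#' @export
read_contingency <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    tab,
    total = meta$total, label = meta$label, scale_factor = meta$scale_factor,
    class = c("contingency_table", class(tab))
  )
}
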