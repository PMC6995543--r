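# Domain structures are tibbles with one row per residue:
#   index   1-based position within the domain
#   resno   author residue number (provenance; equals index for synthetic chains)
#   aa      one-letter amino-acid code, "X" for nonstandard
#   n_x..c_z  backbone atom coordinates in Angstrom (NA when the atom is absent)
#   complete  TRUE iff N, CA and C are all present

AA1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  # common nonstandard residues with a standard parent
  MSE = "M", HSD = "H", HSE = "H", HSP = "H", SEP = "S", TPO = "T",
  PTR = "Y", CSO = "C", PCA = "Q"
)

AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK"
)

#' The 20-letter amino-acid alphabet (sorted)
#' @return character vector of length 20.
#' @export
aa_alphabet <- function() sort(unname(AA1[1:20]))

backbone_cols <- c(
  "n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z", "c_x", "c_y", "c_z"
)

new_domain_structure <- function(residues, id) {
  res <- tibble::as_tibble(residues)
  structure(res, id = id, class = c("domain_structure", class(res)))
}

#' Construct a domain structure from per-residue backbone coordinates
#'
#' @param residues data frame with columns `index`, `aa` and backbone
#'   coordinate columns `n_x`,`n_y`,`n_z`,`ca_x`,`ca_y`,`ca_z`,`c_x`,`c_y`,`c_z`
#'   (Angstrom; `NA` marks a missing atom). An optional `resno` column keeps
#'   the author residue numbering.
#' @param id domain identifier string.
#' @return a `domain_structure` tibble (one row per residue) with a
#'   recomputed `complete` flag.
#' @export
domain_structure <- function(residues, id = "domain") {
  res <- tibble::as_tibble(residues)
  need <- c("index", "aa", backbone_cols)
  missing_cols <- setdiff(need, names(res))
  if (length(missing_cols) > 0) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(res) == 0) abort("no backbone: empty residue set")
  if (is.unsorted(res$index, strictly = TRUE)) {
    abort("residue indices must be strictly increasing")
  }
  if (!"resno" %in% names(res)) res$resno <- res$index
  res$complete <- rowSums(is.na(as.matrix(res[backbone_cols]))) == 0
  res <- res[c("index", "resno", "aa", backbone_cols, "complete")]
  new_domain_structure(res, id)
}

#' @export
print.domain_structure <- function(x, ...) {
  cat(sprintf(
    "<domain_structure> id=%s  %d residues (%d complete)\n",
    attr(x, "id"), nrow(x), sum(x$complete)
  ))
  NextMethod()
}

domain_id <- function(domain) attr(domain, "id") %||% "domain"

#' Amino-acid sequence of a domain
#' @param domain a `domain_structure`.
#' @return single string of one-letter codes.
#' @export
domain_sequence <- function(domain) paste(domain$aa, collapse = "")

# coordinates of one backbone atom as an n x 3 matrix
atom_xyz <- function(domain, atom = c("N", "CA", "C")) {
  atom <- match.arg(atom)
  pre <- c(N = "n", CA = "ca", C = "c")[[atom]]
  m <- as.matrix(domain[paste(pre, c("x", "y", "z"), sep = "_")])
  dimnames(m) <- NULL
  m
}

#' Read a protein chain from a PDB file
#'
#' Parses ATOM records via [bio3d::read.pdb()], keeping altloc `''`/`'A'`
#' conformers, ordering residues by (residue number, insertion code) and
#' mapping nonstandard residues to their parent amino acid where one exists
#' (else `X`). Residues missing any of N, CA, C are kept with
#' `complete = FALSE`; geometry operations skip them.
#'
#' @param path PDB file path.
#' @param chain chain identifier; `NULL` takes the first chain in the file.
#' @return a [domain_structure()] tibble with 1-based `index` and the
#'   author numbering in `resno`.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) abort(paste("cannot parse PDB file:", conditionMessage(e)))
  )
  at <- tibble::as_tibble(pdb$atom)
  at <- dplyr::filter(
    at, .data$type == "ATOM",
    is.na(.data$alt) | .data$alt %in% c("", " ", "A")
  )
  if (nrow(at) == 0) abort("no backbone: file has no ATOM records")
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[[1]]
  if (!chain %in% chains) abort(paste0("chain not found: '", chain, "'"))
  at <- dplyr::filter(at, .data$chain == !!chain, .data$elety %in% c("N", "CA", "C"))
  at$insert <- ifelse(is.na(at$insert), "", at$insert)

  res <- at |>
    tidyr::pivot_wider(
      id_cols = c("resno", "insert", "resid"),
      names_from = "elety",
      values_from = c("x", "y", "z"),
      values_fn = dplyr::first
    ) |>
    dplyr::arrange(.data$resno, .data$insert)
  grab <- function(col) if (col %in% names(res)) res[[col]] else rep(NA_real_, nrow(res))
  out <- tibble::tibble(
    index = seq_len(nrow(res)),
    resno = res$resno,
    aa = unname(ifelse(res$resid %in% names(AA1), AA1[res$resid], "X")),
    n_x = grab("x_N"), n_y = grab("y_N"), n_z = grab("z_N"),
    ca_x = grab("x_CA"), ca_y = grab("y_CA"), ca_z = grab("z_CA"),
    c_x = grab("x_C"), c_y = grab("y_C"), c_z = grab("z_C")
  )
  d <- domain_structure(out, id = sub("\\.pdb$", "", basename(path)))
  if (!any(d$complete)) abort("no backbone: no residue has all of N, CA, C")
  d
}

#' Write a domain structure as PDB ATOM records
#'
#' Serializes N, CA, C backbone atoms (three ATOM lines per residue) in
#' fixed-width PDB format; coordinates keep three decimals, so a
#' read-after-write round trip reproduces them to 0.001 Angstrom.
#'
#' @param domain a `domain_structure`; all residues must be complete.
#' @param path output file path.
#' @param chain chain identifier to write (single character).
#' @return `path`, invisibly.
#' @export
write_structure <- function(domain, path, chain = "A") {
  if (nrow(domain) == 0) abort("cannot serialize: empty domain")
  if (!all(domain$complete)) {
    abort("cannot serialize: domain contains incomplete residues")
  }
  serial <- 0L
  lines <- character(0)
  for (i in seq_len(nrow(domain))) {
    res3 <- AA3[[if (domain$aa[i] %in% names(AA3)) domain$aa[i] else "X"]]
    for (atom in c("N", "CA", "C")) {
      serial <- serial + 1L
      pre <- c(N = "n", CA = "ca", C = "c")[[atom]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, atom, res3, chain, domain$resno[i],
        domain[[paste0(pre, "_x")]][i],
        domain[[paste0(pre, "_y")]][i],
        domain[[paste0(pre, "_z")]][i],
        1, 0, substr(atom, 1, 1)
      ))
    }
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

#' Slice a residue range out of a chain
#'
#' @param domain a `domain_structure`.
#' @param start,end inclusive author residue numbers (`resno`).
#' @param id identifier for the sliced domain; default appends the range.
#' @return a `domain_structure` with residues renumbered from 1 (`resno`
#'   keeps the original numbering).
#' @export
slice_domain <- function(domain, start, end, id = NULL) {
  if (start > end) abort("invalid range: start > end")
  keep <- domain$resno >= start & domain$resno <= end
  if (!any(keep)) abort(sprintf("empty domain: no residues in [%d, %d]", start, end))
  out <- domain[keep, ]
  out$index <- seq_len(nrow(out))
  new_domain_structure(out, id %||% sprintf("%s_%d-%d", domain_id(domain), start, end))
}

#' Read a domain range configuration table
#'
#' A TSV with columns `file`, `chain`, `start`, `end`, `domain_id` replaces a
#' structural-domain database lookup: each row names one domain to slice out
#' of a chain.
#'
#' @param path TSV file path.
#' @return tibble with the five columns, validated (start <= end, no
#'   overlapping ranges within one file+chain).
#' @export
read_domain_ranges <- function(path) {
  cfg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("file", "chain", "start", "end", "domain_id")
  if (!all(need %in% names(cfg))) {
    abort(paste("range config must have columns:", paste(need, collapse = ", ")))
  }
  if (any(cfg$start > cfg$end)) abort("invalid range: start > end")
  overlap <- cfg |>
    dplyr::group_by(.data$file, .data$chain) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      bad = dplyr::n() > 1 && any(.data$start[-1] <= head(.data$end, -1)),
      .groups = "drop"
    )
  if (any(overlap$bad)) abort("overlapping ranges within one chain")
  cfg[need]
}

#' Load all domains named by a range configuration
#'
#' @param ranges tibble from [read_domain_ranges()].
#' @param base_dir directory that relative `file` paths are resolved against.
#' @return named list of `domain_structure` objects.
#' @export
load_domains <- function(ranges, base_dir = ".") {
  purrr::pmap(ranges, function(file, chain, start, end, domain_id) {
    p <- if (file.exists(file)) file else file.path(base_dir, file)
    slice_domain(read_structure(p, chain), start, end, id = domain_id)
  }) |>
    rlang::set_names(ranges$domain_id)
}
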