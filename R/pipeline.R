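# End-to-end orchestration: structures -> codes -> FOD statuses -> tables
# -> correlation screen, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' Defaults are the analysis constants: RD threshold 0.5, minimum status-run
#' length 4, window length 4, alpha 0.05, critical value 1.96.
#'
#' @param rd_threshold FOD compliance threshold on RD.
#' @param min_run minimum constant-status run length entering the
#'   noncompliant-origin window selection.
#' @param window sliding-window length (fixed at 4).
#' @param alpha significance level of the correlation screen.
#' @param critical critical value of the large-sample test statistic.
#' @param cells `"all"` or `"joint_nonzero"` (see [correlation_screen()]).
#' @param cutoff FOD contact cutoff in Angstrom.
#' @param scale hydrophobicity scale name (see [hydrophobicity_scale()]).
#' @param seed integer seed recorded in the manifest.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(rd_threshold = 0.5, min_run = 4, window = 4,
                            alpha = 0.05, critical = 1.96, cells = "all",
                            cutoff = 9, scale = "kd_normalized", seed = 1) {
  if (window != 4) abort("the sliding window is fixed at 4 positions")
  structure(
    list(
      rd_threshold = rd_threshold, min_run = min_run, window = window,
      alpha = alpha, critical = critical, cells = cells, cutoff = cutoff,
      scale = scale, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Run the full early-stage / FOD / screen pipeline
#'
#' For every input domain: encode structural codes, classify FOD compliance
#' with the trimming procedure, and extract sequence-structure windows
#' (whole-domain compliant windows for domains whose original RD is below
#' the threshold, status-run windows otherwise). The pooled windows feed the
#' two contingency tables; the smaller is scaled up and both column- and
#' row-mode correlation screens are run. All outputs are written to
#' `out_dir` along with a manifest; runs are deterministic given the inputs
#' and config.
#'
#' @param domains named list of [domain_structure()] objects.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param ellipse an [ellipse_spec()]; defaults to [default_ellipse()].
#' @return (invisibly) list with `tables`, `screens`, `statuses`,
#'   `manifest`.
#' @export
run_pipeline <- function(domains, config = pipeline_config(), out_dir,
                         ellipse = default_ellipse()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(domains))) {
    names(domains) <- vapply(domains, domain_id, character(1))
  }
  scale <- hydrophobicity_scale(config$scale)
  processed <- list()
  skipped <- list()
  windows <- list()
  statuses <- list()
  for (nm in names(domains)) {
    d <- domains[[nm]]
    result <- tryCatch({
      enc <- encode_domain(d, e = ellipse)
      st <- trim_classify(
        d, scale = scale, threshold = config$rd_threshold, cutoff = config$cutoff
      )
      origin_ok <- st$original_rd < config$rd_threshold
      # align status labels to chain rows (residues outside the effective set
      # count as undefined and never enter a qualifying window)
      lab <- rep("U", nrow(d))
      lab[match(st$status$index, d$index)] <- st$status$status
      code <- enc$code
      w <- extract_windows(
        d$aa, ifelse(is.na(code), "-", code),
        status = lab,
        origin_compliant = origin_ok, min_run = config$min_run
      )
      write_encoding(enc, file.path(out_dir, paste0(nm, "_codes.tsv")))
      write_fod_report(
        fod_profile(d, scale = scale, cutoff = config$cutoff), st,
        file.path(out_dir, paste0(nm, "_fod.json"))
      )
      list(windows = w, status = st)
    }, error = function(e) e)
    if (inherits(result, "error")) {
      skipped[[nm]] <- conditionMessage(result)
    } else {
      processed[[nm]] <- nm
      windows[[nm]] <- result$windows
      statuses[[nm]] <- result$status
    }
  }
  if (length(processed) == 0) {
    abort(paste0(
      "no domain survived: ",
      paste(sprintf("%s (%s)", names(skipped), unlist(skipped)), collapse = "; ")
    ))
  }
  all_w <- dplyr::bind_rows(windows)
  tab_c <- build_table(dplyr::filter(all_w, .data$set_label == "compliant"),
    label = "compliant"
  )
  tab_n <- build_table(dplyr::filter(all_w, .data$set_label == "noncompliant"),
    label = "noncompliant"
  )
  write_contingency(tab_c, file.path(out_dir, "table_compliant.tsv"))
  write_contingency(tab_n, file.path(out_dir, "table_noncompliant.tsv"))
  screens <- list()
  for (mode in c("columns", "rows")) {
    scr <- tryCatch(
      correlation_screen(
        tab_c, tab_n, mode = mode, alpha = config$alpha,
        cells = config$cells, critical = config$critical
      ),
      error = function(e) NULL
    )
    if (!is.null(scr)) {
      readr::write_tsv(
        tibble::as_tibble(scr),
        file.path(out_dir, paste0("screen_", mode, ".tsv")),
        progress = FALSE
      )
    }
    screens[[mode]] <- scr
  }
  manifest <- list(
    package = "earlyfold",
    version = as.character(utils::packageVersion("earlyfold")),
    config = unclass(config),
    seed = config$seed,
    n_domains = length(domains),
    processed = unname(unlist(processed)),
    skipped = skipped,
    n_windows_compliant = attr(tab_c, "total"),
    n_windows_noncompliant = attr(tab_n, "total"),
    scale_factor = if (!is.null(screens$columns)) attr(screens$columns, "scale_factor") else NA
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(list(
    tables = list(compliant = tab_c, noncompliant = tab_n),
    screens = screens, statuses = statuses, manifest = manifest
  ))
}
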