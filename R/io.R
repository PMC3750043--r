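# Table readers/writers and the end-to-end pipeline.
#
# CSV dialect throughout: comma-separated, UTF-8, header row, "." decimal.
# Concentrations are serialized in uM and effects in % of control.

response_cols <- c("chemical", "endpoint", "concentration_uM", "replicate",
                   "response_pct")

#' Read a concentration-response table
#'
#' Expects columns `chemical, endpoint, concentration_uM, replicate,
#' response_pct`; rows with concentration 0 are controls. Malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @return a named list of response dataset tibbles, one per
#'   chemical:endpoint combination.
#' @export
read_response_table <- function(path) {
  if (!file.exists(path))
    mh_stop(sprintf("file not found: %s", path), "mixhill_parse_error")
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0)
    mh_stop(sprintf("empty response table: %s", path),
            "mixhill_parse_error")
  check_columns(df, response_cols, sprintf("response table %s", path))
  num <- function(col) suppressWarnings(as.numeric(df[[col]]))
  conc <- num("concentration_uM")
  resp <- num("response_pct")
  bad <- which(!is.finite(conc) | !is.finite(resp) | conc < 0 | resp <= 0)
  if (length(bad) > 0)
    mh_stop(
      sprintf("invalid concentration/response values at line(s) %s of %s",
              paste(bad + 1L, collapse = ", "), path),
      "mixhill_parse_error")
  df$concentration_uM <- conc
  df$response_pct <- resp
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  key <- paste(df$chemical, df$endpoint, sep = ":")
  lapply(split(tibble::as_tibble(df), key), identity)
}

#' Write response datasets to CSV
#'
#' @param datasets a response dataset tibble or list of them.
#' @param path output CSV path.
#' @export
write_response_table <- function(datasets, path) {
  if (!is.data.frame(datasets)) datasets <- dplyr::bind_rows(datasets)
  readr::write_csv(datasets, path)
  invisible(path)
}

#' Read a mixture definition table
#'
#' Expects columns `chemical, mass_fraction` and optionally
#' `molecular_weight`. Fractions summing to e.g. 0.999 (rounding in the
#' source composition) produce a warning, not an error.
#'
#' @param path CSV file path.
#' @param name mixture label; defaults to the file name stem.
#' @return a `mixture_definition`.
#' @export
read_mixture_table <- function(path, name = NULL) {
  if (!file.exists(path))
    mh_stop(sprintf("file not found: %s", path), "mixhill_parse_error")
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("chemical", "mass_fraction"),
                sprintf("mixture table %s", path))
  s <- sum(df$mass_fraction)
  if (abs(s - 1) > 1e-12 && s >= 0.99 && s <= 1.01)
    warning(sprintf("mixture fractions in %s sum to %.4g, not 1", path, s),
            call. = FALSE)
  mixture_definition(df, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Path to a packaged mixture composition fixture
#'
#' @param which "mixture1" (12 components) or "mixture2" (5 components).
#' @return file path inside the installed package.
#' @export
mixhill_example <- function(which = c("mixture1", "mixture2")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, ".csv"), package = "mixhill",
              mustWork = TRUE)
}

#' Gate and fit every dataset in a response table
#'
#' Runs the Kruskal-Wallis gate on each dataset and fits a constrained Hill
#' curve where the gate passes; failing datasets get a `direction = "none"`
#' record instead of a curve.
#'
#' @param datasets named list of response dataset tibbles (see
#'   [read_response_table()]).
#' @param alpha significance level for the gate.
#' @return list with `fits` (named list of `hill_fit`, keyed by chemical)
#'   and `table` (one summary row per dataset).
#' @export
fit_table <- function(datasets, alpha = 0.05) {
  fits <- list()
  rows <- lapply(datasets, function(d) {
    g <- significance_gate(d, alpha)
    chem <- d$chemical[1]
    endp <- if ("endpoint" %in% names(d)) d$endpoint[1] else NA_character_
    if (g$significant) {
      # a dataset can clear the gate yet have no resolvable direction
      # (means straddle control with no dominant trend); record it as
      # unfit rather than aborting the whole table
      f <- tryCatch(fit_hill(d, alpha = alpha, gate = FALSE),
                    mixhill_direction_error = function(e)
                      hill_fit(chem, endpoint = endp, direction = "none"))
      f$p_value <- g$p_value
    } else {
      f <- hill_fit(chem, endpoint = endp, direction = "none")
      f$p_value <- g$p_value
    }
    fits[[chem]] <<- f
    tibble::tibble(
      chemical = chem, endpoint = endp, significant = g$significant,
      p_value = g$p_value, direction = f$direction, top_pct = f$top,
      ec50_uM = f$ec50, rss = f$rss
    )
  })
  list(fits = fits, table = dplyr::bind_rows(rows))
}

#' Write / read the fit summary table
#'
#' @param table the `table` element returned by [fit_table()].
#' @param path CSV path.
#' @export
write_fit_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_fit_table
#' @return `read_fit_table`: a named list of `hill_fit` records.
#' @export
read_fit_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("chemical", "direction", "top_pct", "ec50_uM"),
                sprintf("fit table %s", path))
  fits <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    f <- hill_fit(row$chemical, top = row$top_pct, ec50 = row$ec50_uM,
                  endpoint = row$endpoint %||% NA_character_,
                  direction = row$direction)
    if ("p_value" %in% names(df)) f$p_value <- row$p_value
    if ("rss" %in% names(df)) f$rss <- row$rss
    f
  })
  stats::setNames(fits, df$chemical)
}

#' Validate a pipeline run configuration
#'
#' @param response_path CSV of single-chemical responses.
#' @param mixture_path CSV mixture definition.
#' @param endpoint hormone label to analyse.
#' @param mixture_response_path optional CSV of experimental mixture
#'   responses for band comparison.
#' @param alpha significance level in (0, 1).
#' @param fraction_convention "mass" (use composition fractions as shares of
#'   the total molar concentration, the default convention) or "molar"
#'   (convert via molecular weights first).
#' @param conc_grid,effect_grid optional prediction grids.
#' @param band_method,nboot confidence band options for the experimental
#'   mixture fit.
#' @param seed RNG seed for the band bootstrap.
#' @param out_dir output directory (created if absent).
#' @return a validated `run_config` list.
#' @export
run_config <- function(response_path, mixture_path, endpoint,
                       mixture_response_path = NULL, alpha = 0.05,
                       fraction_convention = c("mass", "molar"),
                       conc_grid = NULL, effect_grid = NULL,
                       band_method = "bootstrap", nboot = 1000,
                       seed = 1L, out_dir = tempfile("mixhill_run")) {
  fraction_convention <- match.arg(fraction_convention)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    mh_stop("alpha must be a single number in (0, 1)",
            "mixhill_config_error")
  for (p in c(response_path, mixture_path, mixture_response_path)) {
    if (!is.null(p) && !file.exists(p))
      mh_stop(sprintf("input file not found: %s", p),
              "mixhill_config_error")
  }
  structure(
    list(response_path = response_path, mixture_path = mixture_path,
         endpoint = endpoint,
         mixture_response_path = mixture_response_path, alpha = alpha,
         fraction_convention = fraction_convention, conc_grid = conc_grid,
         effect_grid = effect_grid, band_method = band_method,
         nboot = nboot, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Reads the single-chemical table, gates and fits each dataset, checks
#' mixture applicability, computes CA/IA/GCA predictions where allowed,
#' contribution curves for every effective component, and — when
#' experimental mixture data are supplied — a confidence band around the
#' mixture fit and band-location verdicts for every curve. All tables are
#' written as CSV under `config$out_dir`, along with a plain-text run log.
#'
#' @param config a [run_config()].
#' @return (invisibly) a result bundle: fits, applicability report,
#'   prediction and contribution curves, band comparisons, file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("mixhill %s pipeline run, %s",
            as.character(utils::packageVersion("mixhill")),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("R %s", getRversion()),
    sprintf("seed: %d, alpha: %g, fractions: %s, endpoint: %s",
            config$seed, config$alpha, config$fraction_convention,
            config$endpoint),
    sprintf("inputs: %s | %s | %s", config$response_path,
            config$mixture_path, config$mixture_response_path %||% "(none)")
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      mh_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), "mixhill_pipeline_error")
    })
  }

  datasets <- stage("read", {
    d <- read_response_table(config$response_path)
    d[vapply(d, function(x) x$endpoint[1] == config$endpoint, logical(1))]
  })
  if (length(datasets) == 0)
    mh_stop(sprintf("no datasets for endpoint '%s'", config$endpoint),
            "mixhill_pipeline_error")
  mixture <- stage("read", read_mixture_table(config$mixture_path))
  if (config$fraction_convention == "molar")
    mixture <- mass_to_molar(mixture)

  ft <- stage("fit", fit_table(datasets, config$alpha))
  write_fit_table(ft$table, file.path(config$out_dir, "fits.csv"))

  eff <- stage("applicability", effective_components(ft$fits, mixture))
  report <- check_applicability(eff, endpoint = config$endpoint)
  readr::write_csv(
    tibble::tibble(endpoint = config$endpoint, verdict = report$verdict,
                   models_allowed = paste(report$models_allowed,
                                          collapse = ";")),
    file.path(config$out_dir, "applicability.csv"))
  log_lines <- c(log_lines, sprintf("applicability: %s", report$verdict))

  predictions <- list()
  contributions <- list()
  comparisons <- list()
  band <- NULL

  if (length(report$models_allowed) > 0) {
    predictions <- stage("predict", {
      out <- list()
      if ("CA" %in% report$models_allowed)
        out$CA <- ca_predict(eff, mixture, config$effect_grid)
      if ("IA" %in% report$models_allowed)
        out$IA <- ia_predict(eff, mixture, config$conc_grid)
      if ("GCA" %in% report$models_allowed)
        out$GCA <- gca_predict(eff, mixture, config$conc_grid)
      out
    })
    pred_df <- dplyr::bind_rows(lapply(names(predictions), function(m) {
      tibble::tibble(model = m,
                     concentration_uM = predictions[[m]]$concentration_uM,
                     effect_pct = predictions[[m]]$effect_pct,
                     truncated = isTRUE(attr(predictions[[m]], "truncated")))
    }))
    readr::write_csv(pred_df, file.path(config$out_dir, "predictions.csv"))

    grid <- config$conc_grid %||% lseq(1e-3, 1e3, 200)
    p <- component_fractions(mixture)
    contributions <- stage("contributions", {
      lapply(eff, function(f) contribution_curve(f, p[[f$chemical]], grid))
    })
    readr::write_csv(dplyr::bind_rows(contributions),
                     file.path(config$out_dir, "contributions.csv"))
  } else {
    log_lines <- c(log_lines,
                   "warning: no prediction model applicable; predictions skipped")
  }

  if (!is.null(config$mixture_response_path)) {
    mix_data <- stage("read", {
      d <- read_response_table(config$mixture_response_path)
      d[[1]]
    })
    mix_fit <- stage("fit", fit_hill(mix_data, alpha = config$alpha))
    band_grid <- lseq(min(mix_data$concentration_uM[mix_data$concentration_uM > 0]),
                      max(mix_data$concentration_uM), 50)
    band <- stage("band", confidence_band(
      mix_fit, grid = band_grid, method = config$band_method,
      nboot = config$nboot, seed = config$seed))
    readr::write_csv(tibble::as_tibble(band),
                     file.path(config$out_dir, "mixture_band.csv"))
    comparisons <- stage("compare", {
      curves <- c(predictions, contributions)
      lapply(curves, compare_to_band, band = band)
    })
    comp_df <- dplyr::bind_rows(lapply(names(comparisons), function(nm) {
      cmp <- comparisons[[nm]]
      tibble::tibble(curve = nm, verdict = cmp$verdict,
                     frac_inside = cmp$frac_inside, n_left = cmp$n_left,
                     n_right = cmp$n_right)
    }))
    readr::write_csv(comp_df, file.path(config$out_dir, "comparisons.csv"))
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(
    fits = ft$fits, fit_table = ft$table, applicability = report,
    predictions = predictions, contributions = contributions,
    band = band, comparisons = comparisons, out_dir = config$out_dir
  ))
}
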