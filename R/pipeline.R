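#' Read a cohort CSV
#'
#' Comma-separated, UTF-8, header row, decimal point. Every cell must be
#' numeric and present; errors name the offending row and column. Values
#' round-trip through [write_cohort()] at full precision.
#'
#' @param path Path to the CSV file.
#' @param criterion Name of the criterion column (must exist in the file).
#' @return A validated cohort tibble with the `criterion` attribute set.
#' @export
read_cohort <- function(path, criterion) {
  df <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    # problems() counts file lines, so subtract the header to get data rows
    stop("parse error at row ", probs$row[1] - 1L, ", column ", probs$col[1],
         ": expected ", probs$expected[1], ", got '", probs$actual[1], "'",
         call. = FALSE)
  }
  validate_cohort(df, criterion)
}

#' Write a cohort CSV
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated list: the
#' screening thresholds, the per-block factor-reduction gates, the grey
#' relational settings, and the synthetic-cohort controls. Thresholds are
#' range-checked up front so a bad configuration fails before any
#' computation.
#'
#' @param criterion Criterion column name.
#' @param blocks Named list mapping block name to a character vector of
#'   indicator columns, or `NULL` to skip factor reduction.
#' @param mean_threshold,sd_max Screening thresholds (see [screen_items()]).
#' @param kmo_min,bartlett_alpha,eigen_cut,loading_threshold Factor gates
#'   (see [reduce_block()]).
#' @param p,strong_cut,weak_cut Grey relational settings (see [run_gra()]).
#' @param n,seed Synthetic-cohort size and seed, used when the pipeline is
#'   run in synthetic mode.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(criterion = "pre_jump_height", blocks = NULL,
                            mean_threshold = 3.5, sd_max = 1.0,
                            kmo_min = 0.5, bartlett_alpha = 0.05,
                            eigen_cut = 1.0, loading_threshold = 0.4,
                            p = 0.5, strong_cut = 0.9, weak_cut = 0.8,
                            n = 40, seed = NULL) {
  chk <- function(val, lo, hi, name) {
    if (!is.numeric(val) || length(val) != 1 || val < lo || val > hi) {
      stop("config: ", name, " must be a number in [", lo, ", ", hi, "]",
           call. = FALSE)
    }
  }
  chk(mean_threshold, 0, 5, "mean_threshold")
  chk(sd_max, 0, Inf, "sd_max")
  chk(kmo_min, 0, 1, "kmo_min")
  chk(bartlett_alpha, 0, 1, "bartlett_alpha")
  chk(eigen_cut, 0, Inf, "eigen_cut")
  chk(loading_threshold, 0, 1, "loading_threshold")
  chk(p, 0, 1, "p")
  chk(strong_cut, 0, 1, "strong_cut")
  chk(weak_cut, 0, 1, "weak_cut")
  if (weak_cut > strong_cut) stop("config: weak_cut must not exceed strong_cut",
                                  call. = FALSE)
  if (!is.null(blocks)) {
    if (is.null(names(blocks)) || any(names(blocks) == "")) {
      stop("config: blocks must be a named list", call. = FALSE)
    }
  }
  structure(
    list(criterion = criterion, blocks = blocks,
         mean_threshold = mean_threshold, sd_max = sd_max,
         kmo_min = kmo_min, bartlett_alpha = bartlett_alpha,
         eigen_cut = eigen_cut, loading_threshold = loading_threshold,
         p = p, strong_cut = strong_cut, weak_cut = weak_cut,
         n = n, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full indicator-ranking pipeline
#'
#' Executes the stages in protocol order — expert screening (when a panel is
#' supplied), cohort input or synthesis, per-block factor reduction (when
#' blocks are configured), and grey relational analysis — and writes every
#' report plus a run manifest to `out_dir`. Given the same configuration and
#' seed the run is fully deterministic, so any report can be regenerated
#' bit-identically from the manifest.
#'
#' Outputs written to `out_dir`: `screening.csv` (when a panel is given),
#' `cohort.csv`, one `factor_<block>.csv` per configured block plus
#' `factor_diagnostics.csv`, `gra_report.csv`, and `manifest.yaml`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if absent.
#' @param cohort A cohort data frame, or `NULL` to synthesize one.
#' @param panel Optional expert-panel data frame for the screening stage.
#' @param spec A [moment_spec()] for synthetic mode; defaults to
#'   [trampoline_moments()].
#' @return A list with elements `screening`, `cohort`, `factor_solutions`,
#'   `gra` and `manifest`, invisibly mirroring the files written.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL, panel = NULL,
                         spec = trampoline_moments()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  result <- list()

  if (!is.null(panel)) {
    scr <- screen_items(panel, mean_threshold = config$mean_threshold,
                        sd_max = config$sd_max)
    readr::write_csv(tibble::as_tibble(scr), file.path(out_dir, "screening.csv"))
    result$screening <- scr
  }

  if (is.null(cohort)) {
    if (is.null(config$seed)) {
      stop("stage 'synthesize': synthetic mode requires a seed in the config",
           call. = FALSE)
    }
    m <- nrow(spec$indicators) + 1L
    cohort <- if (config$n >= m + 2L) {
      generate_exact(spec, n = config$n, seed = config$seed)
    } else {
      generate_sampled(spec, n = config$n, seed = config$seed)
    }
  }
  cohort <- withCallingHandlers(
    validate_cohort(cohort, config$criterion),
    error = function(e) stop("stage 'cohort': ", conditionMessage(e), call. = FALSE)
  )
  unknown <- setdiff(unlist(config$blocks), names(cohort))
  if (length(unknown) > 0) {
    stop("stage 'validate': block column(s) not in cohort: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  result$cohort <- cohort

  gra_input <- cohort
  if (!is.null(config$blocks)) {
    sols <- purrr::imap(config$blocks, function(cols, nm) {
      reduce_block(cohort, cols, block_name = nm,
                   kmo_min = config$kmo_min,
                   bartlett_alpha = config$bartlett_alpha,
                   eigen_cut = config$eigen_cut,
                   loading_threshold = config$loading_threshold)
    })
    diag_tbl <- purrr::map_dfr(sols, glance)
    readr::write_csv(diag_tbl, file.path(out_dir, "factor_diagnostics.csv"))
    for (nm in names(sols)) {
      readr::write_csv(factor_solution_table(sols[[nm]]),
                       file.path(out_dir, paste0("factor_", nm, ".csv")))
    }
    result$factor_solutions <- sols
    reps <- purrr::map(sols, function(s) {
      if (isTRUE(s$diagnostics_passed)) {
        stats::na.omit(s$representatives$representative)
      } else {
        s$indicator_names    # block kept whole when diagnostics refuse reduction
      }
    })
    keep <- unique(c(config$criterion, unlist(reps)))
    gra_input <- cohort[keep]
    attr(gra_input, "criterion") <- config$criterion
  }

  gra <- run_gra(gra_input, criterion = config$criterion, p = config$p,
                 strong_cut = config$strong_cut, weak_cut = config$weak_cut)
  readr::write_csv(gra$table, file.path(out_dir, "gra_report.csv"))
  result$gra <- gra

  manifest <- list(
    config = unclass(config),
    n_athletes = nrow(cohort),
    package_version = as.character(utils::packageVersion("prejump")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  result$manifest <- manifest
  invisible(result)
}

# Flat per-component table mirroring the published block summaries:
# component code, percent contribution, representative, other indicators.
factor_solution_table <- function(sol) {
  if (!isTRUE(sol$diagnostics_passed) || sol$n_retained == 0) {
    return(tibble::tibble(component = integer(0), contribution = numeric(0),
                          representative = character(0), others = character(0)))
  }
  reps <- sol$representatives
  tibble::tibble(
    component = reps$component,
    contribution = unname(sol$contributions[reps$component]),
    representative = reps$representative,
    others = purrr::map_chr(reps$others, paste, collapse = "; ")
  )
}
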