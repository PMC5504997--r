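#' Validate and normalize a table of weight-age records
#'
#' @param x Data frame with columns `animal_id`, `age_days`, `weight_kg`.
#' @return Tibble sorted by animal and age, after checking that ages are
#'   non-negative and unique within animal and weights strictly positive.
#' @export
as_growth_records <- function(x) {
  need <- c("animal_id", "age_days", "weight_kg")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("Missing required column(s): %s.", paste(miss, collapse = ", ")),
          class = "growthqr_format_error")
  }
  x <- tibble::as_tibble(x[need])
  if (!is.numeric(x$age_days) || any(is.na(x$age_days)) || any(x$age_days < 0)) {
    abort("`age_days` must be non-negative numbers.", class = "growthqr_format_error")
  }
  if (!is.numeric(x$weight_kg) || any(is.na(x$weight_kg)) || any(x$weight_kg <= 0)) {
    abort("`weight_kg` must be strictly positive numbers.",
          class = "growthqr_format_error")
  }
  dup <- x |>
    dplyr::count(.data$animal_id, .data$age_days) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate (animal, age) pairs, e.g. (%s, %g).",
                  dup$animal_id[1L], dup$age_days[1L]),
          class = "growthqr_duplicate_age")
  }
  dplyr::arrange(x, .data$animal_id, .data$age_days)
}

#' Read a weight-age phenotype file
#'
#' Reads a delimited text file (comma by default, tab accepted) with header
#' columns `animal_id`, `age_days`, `weight_kg`, one row per weighing.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` (default) tries comma then tab.
#' @return Validated tibble of records, sorted by animal and age
#'   (see [as_growth_records()]). Row count is conserved.
#' @export
read_phenotypes <- function(path, delim = NULL) {
  x <- read_delim_quiet(path, delim)
  for (col in c("age_days", "weight_kg")) {
    if (col %in% names(x) && !is.numeric(x[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[col]]))))[1L]
      abort(sprintf("Non-numeric `%s` at data row %d of %s.", col, bad, path),
            class = "growthqr_format_error")
    }
  }
  as_growth_records(x)
}

read_delim_quiet <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s.", path), class = "growthqr_io_error")
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Construct a genotype panel
#'
#' Bundles an `n x p` matrix of SNP calls coded 2 (AA), 1 (Aa), 0 (aa) with
#' a genetic map. Markers are reordered by (chromosome, position).
#'
#' @param calls Integer matrix, animals in rows (rownames = animal ids),
#'   markers in columns (colnames = marker ids), values in `{0, 1, 2}`.
#' @param map Data frame with columns `marker_id`, `chr`, `pos_cM` covering
#'   every column of `calls`.
#' @return Object of class `genotype_panel`: list with elements `calls`,
#'   `map` (tibble sorted by chromosome and position), `animal_ids`,
#'   `marker_ids`.
#' @export
genotype_panel <- function(calls, map) {
  calls <- as.matrix(calls)
  if (is.null(colnames(calls)) || is.null(rownames(calls))) {
    abort("`calls` needs row names (animals) and column names (markers).",
          class = "growthqr_format_error")
  }
  if (anyDuplicated(colnames(calls))) {
    abort("Duplicate marker ids.", class = "growthqr_format_error")
  }
  map <- tibble::as_tibble(map)
  miss <- setdiff(colnames(calls), map$marker_id)
  if (length(miss) > 0) {
    abort(sprintf("Marker(s) absent from map: %s.",
                  paste(head(miss, 5L), collapse = ", ")),
          class = "growthqr_format_error")
  }
  bad <- !(calls %in% c(0L, 1L, 2L))
  dim(bad) <- dim(calls)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    abort(sprintf("Genotype call outside {0,1,2} for animal %s, marker %s.",
                  rownames(calls)[i[1L]], colnames(calls)[i[2L]]),
          class = "growthqr_format_error")
  }
  map <- map |>
    dplyr::filter(.data$marker_id %in% colnames(calls)) |>
    dplyr::arrange(.data$chr, .data$pos_cM, .data$marker_id)
  calls <- calls[, map$marker_id, drop = FALSE]
  storage.mode(calls) <- "integer"
  structure(
    list(calls = calls, map = map,
         animal_ids = rownames(calls), marker_ids = colnames(calls)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d animals x %d markers on %d chromosome(s)\n",
              length(x$animal_ids), length(x$marker_ids),
              dplyr::n_distinct(x$map$chr)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

#' Read genotype and map files into a panel
#'
#' The genotype file has animals in rows (first column `animal_id`) and one
#' column per marker with calls in `{0, 1, 2}` or `NA`; the map file has
#' columns `marker_id`, `chr`, `pos_cM`.
#'
#' @param geno_path,map_path File paths (delimited text; comma or tab).
#' @param missing_policy `"error"` (default) fails on any missing call,
#'   naming the animal and marker; `"mode_impute"` replaces each `NA` by the
#'   marker's most frequent observed call, ties going to the smallest call
#'   value.
#' @return A [genotype_panel()], markers ordered by (chromosome, position).
#' @export
read_genotypes <- function(geno_path, map_path,
                           missing_policy = c("error", "mode_impute")) {
  missing_policy <- match.arg(missing_policy)
  geno <- read_delim_quiet(geno_path)
  map <- read_delim_quiet(map_path)
  need <- setdiff(c("marker_id", "chr", "pos_cM"), names(map))
  if (length(need) > 0) {
    abort(sprintf("Map file missing column(s): %s.", paste(need, collapse = ", ")),
          class = "growthqr_format_error")
  }
  if (!"animal_id" %in% names(geno)) {
    abort("Genotype file missing column `animal_id`.", class = "growthqr_format_error")
  }
  ids <- as.character(geno$animal_id)
  calls <- as.matrix(geno[setdiff(names(geno), "animal_id")])
  storage.mode(calls) <- "integer"
  rownames(calls) <- ids
  if (anyNA(calls)) {
    if (missing_policy == "error") {
      i <- which(is.na(calls), arr.ind = TRUE)[1L, ]
      abort(sprintf("Missing genotype call for animal %s at marker %s.",
                    ids[i[1L]], colnames(calls)[i[2L]]),
            class = "growthqr_missing_genotype")
    }
    calls <- apply_mode_impute(calls)
  }
  genotype_panel(calls, map)
}

## replace NA calls with the per-marker modal call; ties -> smallest call
apply_mode_impute <- function(calls) {
  for (j in seq_len(ncol(calls))) {
    col <- calls[, j]
    if (anyNA(col)) {
      obs <- col[!is.na(col)]
      if (length(obs) == 0L) {
        abort(sprintf("Marker %s has no observed calls to impute from.",
                      colnames(calls)[j]),
              class = "growthqr_missing_genotype")
      }
      counts <- table(factor(obs, levels = 0:2))
      mode_call <- as.integer(names(counts)[which.max(counts)])
      calls[is.na(col), j] <- mode_call
    }
  }
  calls
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the two-step pipeline. Defaults follow
#' the analysis this package implements: quantiles 0.2/0.5/0.8, penalty grid
#' 0 to 50 in steps of 0.5, 200 bootstrap replicates, top 2.5% of markers
#' reported.
#'
#' @param quantiles Quantile levels, each strictly inside (0, 1).
#' @param lambda_grid Non-negative penalty grid, ascending.
#' @param bootstrap_reps Bootstrap replicates (>= 2).
#' @param top_fraction Fraction of markers reported as most relevant, in (0, 1].
#' @param seed Integer seed used for every randomized step.
#' @param age_grid Ages (days) at which genomic curves are evaluated.
#' @return List of class `growthqr_config`.
#' @export
growthqr_config <- function(quantiles = c(0.2, 0.5, 0.8),
                            lambda_grid = seq(0, 50, by = 0.5),
                            bootstrap_reps = 200L,
                            top_fraction = 0.025,
                            seed = 1L,
                            age_grid = seq(0, 150, by = 5)) {
  for (tau in quantiles) stop_if_not_scalar_prob(tau, "quantiles")
  if (any(lambda_grid < 0) || is.unsorted(lambda_grid)) {
    abort("`lambda_grid` must be non-negative and ascending.",
          class = "growthqr_domain_error")
  }
  if (bootstrap_reps < 2L) {
    abort("`bootstrap_reps` must be at least 2.", class = "growthqr_domain_error")
  }
  if (top_fraction <= 0 || top_fraction > 1) {
    abort("`top_fraction` must lie in (0, 1].", class = "growthqr_domain_error")
  }
  structure(
    list(quantiles = quantiles, lambda_grid = lambda_grid,
         bootstrap_reps = as.integer(bootstrap_reps),
         top_fraction = top_fraction, seed = as.integer(seed),
         age_grid = age_grid),
    class = "growthqr_config"
  )
}

#' Write pipeline results to delimited files
#'
#' Writes per-(trait, quantile) marker-effect tables, a model-fit summary
#' (selected penalty, predictive capacity, pseudo-R1), and genomic-curve
#' tables as CSV files. Re-reading the files reproduces the tabular values
#' bit-exactly (full-precision formatting).
#'
#' @param effects Tibble of ranked or full marker effects with columns
#'   `trait`, `tau`, `marker_id`, `effect`, `se`, `p_value`, `chr`, `pos_cM`
#'   (e.g. from [rank_markers()] rows bound together); may have zero rows.
#' @param summary Tibble with one row per (trait, tau): `trait`, `tau`,
#'   `lambda`, `capacity`, `pseudo_r1`, `n_nonzero`; may have zero rows.
#' @param curves Tibble with columns `tau`, `age`, `mean`, `low`, `high`;
#'   may have zero rows.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written (named character vector).
#' @export
write_report <- function(effects, summary, curves, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) {
    abort(sprintf("Cannot create output directory %s.", out_dir),
          class = "growthqr_io_error")
  }
  paths <- c(
    effects = file.path(out_dir, "marker_effects.csv"),
    summary = file.path(out_dir, "fit_summary.csv"),
    curves = file.path(out_dir, "genomic_curves.csv")
  )
  write_full_precision(effects, paths[["effects"]])
  write_full_precision(summary, paths[["summary"]])
  write_full_precision(curves, paths[["curves"]])
  invisible(paths)
}

## readr round-trips doubles losslessly at 17 significant digits
write_full_precision <- function(x, path) {
  x <- tibble::as_tibble(x)
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(col) formatC(col, digits = 17, format = "g"))
  readr::write_csv(x, path, progress = FALSE)
}

#' Read back a report table written by [write_report()]
#'
#' Uses the C library's correctly-rounded decimal parser, so the 17
#' significant digits written by [write_report()] restore every double
#' bit-exactly.
#'
#' @param path Path to one of the CSV files written by [write_report()].
#' @return Tibble with numeric columns restored.
#' @export
read_report_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
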