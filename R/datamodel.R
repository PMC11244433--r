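#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

# Columns every table must carry; trait columns are everything numeric beyond
# these in the trait table (or an explicit `trait_cols`).
.id_cols_traits <- c("plot_id", "treatment", "species_id", "individual_id")
.id_cols_comp <- c("plot_id", "species_id", "relative_biomass")
.id_cols_plots <- c("plot_id", "treatment")

#' Detect trait columns of a trait table
#'
#' Trait columns are all columns of `traits` that are not identifier or
#' design columns (`plot_id`, `treatment`, `species_id`, `individual_id`).
#'
#' @param traits A trait table (see [load_tables()]).
#' @return Character vector of trait column names.
#' @export
trait_names <- function(traits) {
  setdiff(names(traits), .id_cols_traits)
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

.check_numeric <- function(df, cols, what) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      # readr parses a column with stray text as character; locate the bad cell
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      if (length(bad) > 0) {
        stop(sprintf(
          "%s: column '%s' has unparsable numeric value at row %d ('%s')",
          what, col, bad[1], v[bad[1]]
        ), call. = FALSE)
      }
      df[[col]] <- num
    }
    if (anyNA(df[[col]])) {
      bad <- which(is.na(df[[col]]))
      stop(sprintf(
        "%s: column '%s' has missing value at row %d",
        what, col, bad[1]
      ), call. = FALSE)
    }
  }
  df
}

#' Load the three pipeline input tables from CSV files
#'
#' Reads the individual trait measurements, the community composition and the
#' plot metadata from comma-delimited UTF-8 files with one header row.
#' Missing values in required numeric columns are rejected.  Extra columns
#' are preserved but ignored by the analysis.
#'
#' @param trait_path CSV with columns `plot_id`, `treatment`, `species_id`,
#'   `individual_id` and one numeric column per trait (e.g. `H` in cm, `LA`
#'   in cm2, `LDMC` in g/g, `SLA` in m2/kg).
#' @param composition_path CSV with columns `plot_id`, `species_id`,
#'   `relative_biomass`.
#' @param plot_path CSV with columns `plot_id`, `treatment` and optionally
#'   `anpp` (aboveground net primary productivity, g/m2).
#' @param trait_cols Optional character vector naming the trait columns;
#'   defaults to every non-identifier column of the trait table.
#' @return A list with elements `traits`, `composition`, `plots` (tibbles)
#'   and `trait_cols`.
#' @export
#' @examples
#' d <- generate_dataset(scenario_presets("paper-like", seed = 1))
#' tmp <- tempfile(); dir.create(tmp)
#' write_tables(d, tmp)
#' tabs <- load_tables(
#'   file.path(tmp, "traits.csv"),
#'   file.path(tmp, "composition.csv"),
#'   file.path(tmp, "plots.csv")
#' )
#' tabs$trait_cols
load_tables <- function(trait_path, composition_path, plot_path,
                        trait_cols = NULL) {
  for (p in c(trait_path, composition_path, plot_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  traits <- readr::read_csv(trait_path, show_col_types = FALSE,
                            progress = FALSE)
  comp <- readr::read_csv(composition_path, show_col_types = FALSE,
                          progress = FALSE)
  plots <- readr::read_csv(plot_path, show_col_types = FALSE,
                           progress = FALSE)

  .check_columns(traits, .id_cols_traits, "trait table")
  .check_columns(comp, .id_cols_comp, "composition table")
  .check_columns(plots, .id_cols_plots, "plot table")

  if (is.null(trait_cols)) trait_cols <- trait_names(traits)
  if (length(trait_cols) == 0) {
    stop("trait table has no trait columns", call. = FALSE)
  }
  traits <- .check_numeric(traits, trait_cols, "trait table")
  comp <- .check_numeric(comp, "relative_biomass", "composition table")
  if ("anpp" %in% names(plots) && !all(is.na(plots$anpp))) {
    plots <- .check_numeric(plots, "anpp", "plot table")
  }
  traits$plot_id <- as.character(traits$plot_id)
  comp$plot_id <- as.character(comp$plot_id)
  plots$plot_id <- as.character(plots$plot_id)
  list(
    traits = tibble::as_tibble(traits),
    composition = tibble::as_tibble(comp),
    plots = tibble::as_tibble(plots),
    trait_cols = trait_cols
  )
}

#' Write pipeline tables to CSV
#'
#' Inverse of [load_tables()]: writes `traits.csv`, `composition.csv` and
#' `plots.csv` under `dir`.  Load-write-load is the identity on all tables.
#'
#' @param tables A list with elements `traits`, `composition`, `plots`, as
#'   returned by [load_tables()] or [generate_dataset()].
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    traits = file.path(dir, "traits.csv"),
    composition = file.path(dir, "composition.csv"),
    plots = file.path(dir, "plots.csv")
  )
  readr::write_csv(tables$traits, paths[["traits"]], progress = FALSE)
  readr::write_csv(tables$composition, paths[["composition"]], progress = FALSE)
  readr::write_csv(tables$plots, paths[["plots"]], progress = FALSE)
  invisible(paths)
}

#' Normalize relative biomasses to unit sum per plot
#'
#' Divides each plot's biomass values by the plot total so that downstream
#' code can assume exact unit sums.  Idempotent and scale-invariant; applied
#' even to pre-normalized inputs.
#'
#' @param comp Composition table with columns `plot_id`, `species_id`,
#'   `relative_biomass`.
#' @return The composition table with `relative_biomass` summing to 1 per
#'   plot (within 1e-9).
#' @export
normalize_abundances <- function(comp) {
  .check_columns(comp, .id_cols_comp, "composition table")
  if (any(comp$relative_biomass <= 0)) {
    stop("relative_biomass must be strictly positive", call. = FALSE)
  }
  totals <- tapply(comp$relative_biomass, comp$plot_id, sum)
  if (any(totals <= 0)) {
    stop(sprintf(
      "plot(s) with zero total biomass: %s",
      paste(names(totals)[totals <= 0], collapse = ", ")
    ), call. = FALSE)
  }
  comp$relative_biomass <-
    comp$relative_biomass / as.numeric(totals[as.character(comp$plot_id)])
  comp
}

#' Cross-validate the three input tables
#'
#' Checks referential integrity across the trait, composition and plot
#' tables.  Problems that invalidate the analysis (duplicate keys,
#' non-positive trait values, plots missing from the plot table, trait rows
#' for species absent from the composition) are errors; recoverable
#' findings (species in the composition lacking trait measurements, species
#' with a single measured individual) are warnings.  Nothing is thrown: all
#' findings are routed into the report.
#'
#' @param traits,comp,plots Tables as returned by [load_tables()].
#' @param trait_cols Trait column names (default: detected).
#' @return A `validation_report`: list with `errors`, `warnings` (each a
#'   tibble of `code`, `message`, `keys`) and `is_valid` (TRUE iff no
#'   errors).
#' @export
validate_dataset <- function(traits, comp, plots, trait_cols = NULL) {
  if (is.null(trait_cols)) trait_cols <- trait_names(traits)
  findings <- list()
  add <- function(severity, code, message, keys = "") {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      severity = severity, code = code, message = message, keys = keys
    )
  }

  key <- paste(traits$plot_id, traits$species_id, traits$individual_id)
  if (anyDuplicated(key)) {
    add("error", "duplicate_individual",
        "duplicate (plot_id, species_id, individual_id) in trait table",
        paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  for (tc in trait_cols) {
    bad <- !is.finite(traits[[tc]]) | traits[[tc]] <= 0
    if (any(bad)) {
      add("error", "nonpositive_trait",
          sprintf("trait '%s' has non-finite or non-positive values", tc),
          paste(key[bad], collapse = "; "))
    }
  }
  # one treatment per plot
  tt <- unique(traits[, c("plot_id", "treatment")])
  multi <- tt$plot_id[duplicated(tt$plot_id)]
  if (length(multi) > 0) {
    add("error", "ambiguous_treatment",
        "plot(s) mapped to more than one treatment in trait table",
        paste(unique(multi), collapse = "; "))
  }
  ckey <- paste(comp$plot_id, comp$species_id)
  if (anyDuplicated(ckey)) {
    add("error", "duplicate_composition",
        "duplicate (plot_id, species_id) in composition table",
        paste(unique(ckey[duplicated(ckey)]), collapse = "; "))
  }
  if (anyDuplicated(plots$plot_id)) {
    add("error", "duplicate_plot",
        "duplicate plot_id in plot table",
        paste(unique(plots$plot_id[duplicated(plots$plot_id)]),
              collapse = "; "))
  }
  if ("anpp" %in% names(plots)) {
    bad <- !is.na(plots$anpp) & plots$anpp < 0
    if (any(bad)) {
      add("error", "negative_anpp", "anpp must be >= 0 when present",
          paste(plots$plot_id[bad], collapse = "; "))
    }
  }
  orphan_plots <- setdiff(unique(traits$plot_id), plots$plot_id)
  if (length(orphan_plots) > 0) {
    add("error", "plot_missing",
        "trait-table plot(s) absent from plot table",
        paste(orphan_plots, collapse = "; "))
  }
  tkey <- unique(paste(traits$plot_id, traits$species_id))
  orphan_sp <- setdiff(tkey, ckey)
  if (length(orphan_sp) > 0) {
    add("error", "composition_missing",
        "measured (plot, species) absent from composition table",
        paste(orphan_sp, collapse = "; "))
  }
  unmeasured <- setdiff(ckey, tkey)
  if (length(unmeasured) > 0) {
    add("warning", "species_unmeasured",
        paste("species present in composition but lacking trait",
              "measurements; excluded from indices, abundances",
              "renormalized over measured species"),
        paste(unmeasured, collapse = "; "))
  }
  n_ind <- table(key_ps <- paste(traits$plot_id, traits$species_id))
  singletons <- names(n_ind)[n_ind < 2]
  if (length(singletons) > 0) {
    add("warning", "single_individual",
        paste("species with fewer than 2 measured individuals in a plot;",
              "within-species variance is 0 by definition"),
        paste(singletons, collapse = "; "))
  }

  all_f <- if (length(findings) > 0) dplyr::bind_rows(findings) else
    tibble::tibble(severity = character(), code = character(),
                   message = character(), keys = character())
  report <- list(
    errors = all_f[all_f$severity == "error",
                   c("code", "message", "keys"), drop = FALSE],
    warnings = all_f[all_f$severity == "warning",
                     c("code", "message", "keys"), drop = FALSE],
    is_valid = !any(all_f$severity == "error")
  )
  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "validation report: %s (%d error(s), %d warning(s))\n",
    if (x$is_valid) "VALID" else "INVALID",
    nrow(x$errors), nrow(x$warnings)
  ))
  if (nrow(x$errors) > 0) {
    cat("errors:\n")
    for (i in seq_len(nrow(x$errors))) {
      cat(sprintf("  [%s] %s\n", x$errors$code[i], x$errors$message[i]))
    }
  }
  if (nrow(x$warnings) > 0) {
    cat("warnings:\n")
    for (i in seq_len(nrow(x$warnings))) {
      cat(sprintf("  [%s] %s\n", x$warnings$code[i], x$warnings$message[i]))
    }
  }
  invisible(x)
}

#' Restrict composition to measured species and renormalize
#'
#' Indices are computed on the measured species subset: species in a plot's
#' composition with no trait measurements in that plot are dropped and the
#' remaining abundances renormalized to unit sum (the field convention when
#' traits are measured for species covering most of the biomass).  Set
#' `renormalize = FALSE` to keep the original weights of the retained
#' species (weights then sum to less than 1 where species were dropped).
#'
#' @param traits,comp Tables as returned by [load_tables()].
#' @param renormalize Renormalize retained abundances to unit sum
#'   (default TRUE).
#' @return Composition table restricted to measured (plot, species) pairs.
#' @export
align_composition <- function(traits, comp, renormalize = TRUE) {
  measured <- unique(paste(traits$plot_id, traits$species_id))
  keep <- paste(comp$plot_id, comp$species_id) %in% measured
  out <- comp[keep, , drop = FALSE]
  if (renormalize) out <- normalize_abundances(out) else {
    out <- normalize_abundances(comp)[keep, , drop = FALSE]
  }
  out
}
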