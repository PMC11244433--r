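# End-to-end orchestration: load or simulate -> validate -> within-community
# indices -> among-community means -> treatment ANOVA / Tukey / letters ->
# SS decomposition -> CSV outputs, run manifest and Markdown summary.

#' Assemble a pipeline run configuration
#'
#' Either the three input CSV paths or a generator preset must be given.
#'
#' @param trait_path,composition_path,plot_path Input CSVs (see
#'   [load_tables()]); ignored when `preset` is set.
#' @param preset A [scenario_presets()] name; the dataset is generated with
#'   `seed` instead of being read from files.
#' @param trait_cols Trait columns to analyse (default: detected).
#' @param level_order Treatment level order for tests, letters and outputs
#'   (default: order of first appearance in the plot table).
#' @param alpha Significance level for Tukey flags and letters.
#' @param divisor Within-species variance divisor (see
#'   [species_plot_stats()]).
#' @param divide_fixed_by_s CM fixed-component divisor switch (see
#'   [cm_components()]).
#' @param denominator Contribution-percentage denominator (see
#'   [contribution_percentages()]).
#' @param renormalize Renormalize abundances over measured species (see
#'   [align_composition()]).
#' @param log_witv Log-transform the within-community indices before their
#'   treatment ANOVA (variance indices are often right-skewed); default
#'   FALSE, i.e. untransformed values are analysed.
#' @param out_dir Output directory; NULL suppresses file output.
#' @param seed Integer seed (used only when simulating).
#' @return A list of class `run_config`.
#' @export
run_config <- function(trait_path = NULL, composition_path = NULL,
                       plot_path = NULL, preset = NULL, trait_cols = NULL,
                       level_order = NULL, alpha = 0.05,
                       divisor = "population", divide_fixed_by_s = TRUE,
                       denominator = "total", renormalize = TRUE,
                       log_witv = FALSE, out_dir = NULL, seed = 1) {
  if (is.null(preset) &&
      (is.null(trait_path) || is.null(composition_path) ||
       is.null(plot_path))) {
    stop("give either the three input paths or a preset", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  structure(list(
    trait_path = trait_path, composition_path = composition_path,
    plot_path = plot_path, preset = preset, trait_cols = trait_cols,
    level_order = level_order, alpha = alpha, divisor = divisor,
    divide_fixed_by_s = divide_fixed_by_s, denominator = denominator,
    renormalize = renormalize, log_witv = log_witv,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full trait-partitioning pipeline
#'
#' Executes every stage for every trait and both weighting schemes:
#' validation, within-community indices, among-community mean components,
#' per-index treatment ANOVA with Tukey HSD and compact letters, the SS
#' decomposition with contribution percentages, and — when ANPP is present
#' in the plot table — the treatment ANOVA of ANPP.  Warnings from
#' validation are carried in the bundle and echoed to the summary; errors
#' abort.  When `out_dir` is set, writes `within_indices.csv`,
#' `community_means.csv`, `anova_results.csv`, `tukey_results.csv`,
#' `letters.csv`, `decomposition.csv`, `summary.md` and `manifest.json`.
#' Re-running with the same config (and seed, if simulating) reproduces
#' every output byte for byte.
#'
#' @param cfg A [run_config()].
#' @return A list of class `result_bundle` with elements `tables` (the
#'   inputs used), `validation`, `within_indices`, `community_means`,
#'   `anova`, `tukey`, `letters`, `decomposition`, `anpp_anova` (or NULL)
#'   and `manifest`.
#' @export
#' @examples
#' bundle <- run_pipeline(run_config(preset = "paper-like", seed = 1))
#' bundle$decomposition[, c("trait", "scheme", "percent_fixed",
#'                          "percent_intra", "percent_cov")]
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[traitpart] %-18s %6.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  tables <- stage("load", {
    if (!is.null(cfg$preset)) {
      d <- generate_dataset(scenario_presets(cfg$preset, seed = cfg$seed))
      list(traits = d$traits, composition = d$composition, plots = d$plots,
           trait_cols = d$trait_cols, ground_truth = d$ground_truth)
    } else {
      load_tables(cfg$trait_path, cfg$composition_path, cfg$plot_path,
                  cfg$trait_cols)
    }
  })
  trait_cols <- cfg$trait_cols %||% tables$trait_cols
  level_order <- cfg$level_order %||% unique(tables$plots$treatment)

  report <- stage("validate", validate_dataset(
    tables$traits, tables$composition, tables$plots, trait_cols
  ))
  if (!report$is_valid) {
    stop(paste0("validation failed:\n", paste(
      sprintf("  [%s] %s (%s)", report$errors$code, report$errors$message,
              report$errors$keys),
      collapse = "\n"
    )), call. = FALSE)
  }

  within <- stage("within-community", within_community_indices(
    tables$traits, tables$composition, tables$plots, trait_cols,
    divisor = cfg$divisor, renormalize = cfg$renormalize
  ))
  means <- stage("among-community", community_means(
    tables$traits, tables$composition, tables$plots, trait_cols,
    divide_fixed_by_s = cfg$divide_fixed_by_s,
    renormalize = cfg$renormalize
  ))

  # one index family per column: witv_intra/witv_inter and the six
  # scheme-component series
  witv_for_tests <- within
  if (cfg$log_witv) {
    witv_for_tests$witv_intra <- log(witv_for_tests$witv_intra)
    witv_for_tests$witv_inter <- log(witv_for_tests$witv_inter)
  }
  means_wide <- tidyr::pivot_wider(
    means, id_cols = c("plot_id", "treatment", "trait"),
    names_from = "scheme",
    values_from = c("specific", "fixed", "intra"),
    names_glue = "{scheme}_{.value}"
  )
  tests <- stage("treatment-tests", {
    tw <- treatment_tests(witv_for_tests, alpha = cfg$alpha,
                          level_order = level_order)
    tm <- treatment_tests(means_wide, alpha = cfg$alpha,
                          level_order = level_order)
    list(
      anova = dplyr::bind_rows(tw$anova, tm$anova),
      tukey = dplyr::bind_rows(tw$tukey, tm$tukey),
      letters = dplyr::bind_rows(tw$letters, tm$letters)
    )
  })

  decomposition <- stage("decomposition", decompose_traits(
    means, tables$plots, denominator = cfg$denominator
  ))

  anpp_anova <- NULL
  if ("anpp" %in% names(tables$plots) && !all(is.na(tables$plots$anpp))) {
    anpp_anova <- stage("anpp-anova", {
      groups <- split(tables$plots$anpp,
                      factor(tables$plots$treatment, levels = level_order))
      fit <- one_way_anova(groups)
      tk <- tukey_hsd(groups, alpha = cfg$alpha)
      cld <- compact_letter_display(tk, alpha = cfg$alpha)
      list(anova = fit, tukey = tk, letters = cld)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("traitpart")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), NULL)],
    n_plots = nrow(tables$plots),
    n_individuals = nrow(tables$traits),
    traits = trait_cols,
    input_md5 = if (is.null(cfg$preset)) {
      as.list(tools::md5sum(c(cfg$trait_path, cfg$composition_path,
                              cfg$plot_path)))
    } else {
      list(preset = cfg$preset)
    },
    warnings = report$warnings$message
  )

  bundle <- structure(list(
    tables = tables, validation = report, within_indices = within,
    community_means = means, anova = tests$anova, tukey = tests$tukey,
    letters = tests$letters, decomposition = decomposition,
    anpp_anova = anpp_anova, manifest = manifest
  ), class = "result_bundle")

  if (!is.null(cfg$out_dir)) {
    stage("write", write_result_bundle(bundle, cfg$out_dir))
  }
  bundle
}

#' Write a result bundle to disk
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @param dir Output directory, created if absent.  Input files are never
#'   touched; everything goes under `dir`.
#' @return Invisibly, the directory.
#' @export
write_result_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) readr::write_csv(x, file.path(dir, f), progress = FALSE)
  w(bundle$within_indices, "within_indices.csv")
  w(bundle$community_means, "community_means.csv")
  anova_tab <- bundle$anova
  if (!is.null(bundle$anpp_anova)) {
    a <- bundle$anpp_anova$anova
    anova_tab <- dplyr::bind_rows(anova_tab, tibble::tibble(
      trait = "ANPP", index = "anpp",
      ss_between = a$ss_between, ss_within = a$ss_within,
      df_between = a$df_between, df_within = a$df_within,
      f_stat = a$f_stat, p_value = a$p_value, degenerate = a$degenerate
    ))
  }
  w(anova_tab, "anova_results.csv")
  w(bundle$tukey, "tukey_results.csv")
  w(bundle$letters, "letters.csv")
  w(bundle$decomposition, "decomposition.csv")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  writeLines(.summary_md(bundle), file.path(dir, "summary.md"))
  invisible(dir)
}

.summary_md <- function(bundle) {
  dec <- bundle$decomposition
  lines <- c(
    "# Trait-partitioning run summary", "",
    sprintf("- plots: %d, individuals measured: %d",
            bundle$manifest$n_plots, bundle$manifest$n_individuals),
    sprintf("- traits: %s", paste(bundle$manifest$traits, collapse = ", ")),
    ""
  )
  if (length(bundle$manifest$warnings) > 0) {
    lines <- c(lines, "## Validation warnings",
               paste0("- ", bundle$manifest$warnings), "")
  }
  lines <- c(lines, "## Treatment-explained trait variation (%)", "",
             "| trait | scheme | fixed | intra | cov | p(specific) |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(dec))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %.1f | %.1f | %.1f | %.4f |",
      dec$trait[i], toupper(dec$scheme[i]), dec$percent_fixed[i],
      dec$percent_intra[i], dec$percent_cov[i], dec$p_specific[i]
    ))
  }
  if (!is.null(bundle$anpp_anova)) {
    a <- bundle$anpp_anova$anova
    lines <- c(lines, "", sprintf(
      "ANPP treatment ANOVA: F(%d, %d) = %.2f, p = %.4f",
      a$df_between, a$df_within, a$f_stat, a$p_value
    ))
  }
  lines
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf(
    "traitpart result bundle: %d plots, %d traits, %d decomposition rows\n",
    x$manifest$n_plots, length(x$manifest$traits), nrow(x$decomposition)
  ))
  invisible(x)
}

#' Stacked-bar figure of the variance decomposition
#'
#' One stacked bar per trait and scheme showing the treatment-explained
#' interspecific (fixed) and intraspecific contribution percentages, an
#' overlaid marker at the total (specific) percentage, and the covariation
#' effect as the gap between bar top and marker (marker above the bar:
#' positive covariation; marker inside the bar: negative).
#'
#' @param decomposition Output of [decompose_traits()].
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomposition) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_decomposition needs the ggplot2 package", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    decomposition[, c("trait", "scheme", "percent_fixed", "percent_intra")],
    cols = c("percent_fixed", "percent_intra"),
    names_to = "component", values_to = "percent"
  )
  long$component <- sub("percent_", "", long$component)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait, y = .data$percent,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(
      data = decomposition,
      mapping = ggplot2::aes(x = .data$trait, y = .data$percent_specific),
      inherit.aes = FALSE, shape = 95, size = 8
    ) +
    ggplot2::facet_wrap(~scheme, labeller = ggplot2::as_labeller(toupper)) +
    ggplot2::labs(y = "treatment-explained variation (%)", x = NULL,
                  fill = NULL)
}
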