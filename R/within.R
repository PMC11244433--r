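# Within-community variance indices: abundance-weighted intraspecific and
# interspecific trait variation per plot.
#
# wITV_intra = sum_i a_i * (1/Nind_i) sum_j (x_ji - xbar_i)^2
# wITV_inter = sum_i a_i * (xbar_i - sum_i a_i xbar_i)^2
#
# with a_i the relative biomass of species i renormalized over the measured
# species of the plot, xbar_i the plot-local species mean, and the inner
# variance a population variance (divisor Nind_i).

#' Per-(plot, species, trait) summary statistics
#'
#' Computes, for every measured species in every plot and every trait, the
#' number of individuals, the mean, and the within-species variance.  The
#' default variance uses the population divisor `n` (so a species with a
#' single individual has variance 0); `divisor = "sample"` switches to the
#' unbiased `n - 1` divisor (undefined, hence 0, at n = 1).
#'
#' @param traits Trait table (see [load_tables()]).
#' @param trait_cols Trait column names (default: detected).
#' @param divisor `"population"` (divide by n, the default) or `"sample"`
#'   (divide by n - 1).
#' @return Tibble with columns `plot_id`, `species_id`, `trait`,
#'   `n_individuals`, `mean`, `variance`.
#' @export
#' @examples
#' d <- generate_dataset(scenario_presets("paper-like", seed = 1))
#' species_plot_stats(d$traits)
species_plot_stats <- function(traits, trait_cols = NULL,
                               divisor = c("population", "sample")) {
  divisor <- match.arg(divisor)
  if (is.null(trait_cols)) trait_cols <- trait_names(traits)
  long <- tidyr::pivot_longer(
    traits[, c("plot_id", "species_id", trait_cols)],
    cols = dplyr::all_of(trait_cols),
    names_to = "trait", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$plot_id, .data$species_id, .data$trait),
    n_individuals = dplyr::n(),
    mean = mean(.data$value),
    variance = if (divisor == "population") {
      sum((.data$value - mean(.data$value))^2) / dplyr::n()
    } else {
      if (dplyr::n() > 1) stats::var(.data$value) else 0
    },
    .groups = "drop"
  )
  out
}

# Join one plot's species stats with its (renormalized) abundances for one
# trait; errors if the plot is unknown.
.plot_trait_slice <- function(stats, comp, plot, trait) {
  s <- stats[stats$plot_id == plot & stats$trait == trait, , drop = FALSE]
  if (nrow(s) == 0) {
    stop(sprintf("plot '%s' (trait '%s') absent from species stats",
                 plot, trait), call. = FALSE)
  }
  a <- comp[comp$plot_id == plot, , drop = FALSE]
  m <- merge(s, a[, c("species_id", "relative_biomass")], by = "species_id")
  if (nrow(m) != nrow(s)) {
    missing <- setdiff(s$species_id, a$species_id)
    stop(sprintf("species without abundance in plot '%s': %s",
                 plot, paste(missing, collapse = ", ")), call. = FALSE)
  }
  m$relative_biomass <- m$relative_biomass / sum(m$relative_biomass)
  m
}

#' Abundance-weighted intraspecific variability within one community
#'
#' The abundance-weighted mean of the within-species (population) variances:
#' `sum_i a_i * var_i`.  Trait-squared units.  Smaller values indicate
#' stronger convergence of individuals on their species means.
#'
#' @param stats Output of [species_plot_stats()].
#' @param comp Composition table, normalized over the measured species.
#' @param plot,trait Plot id and trait name.
#' @return A single non-negative number.
#' @export
witv_intra <- function(stats, comp, plot, trait) {
  m <- .plot_trait_slice(stats, comp, plot, trait)
  sum(m$relative_biomass * m$variance)
}

#' Abundance-weighted interspecific variability within one community
#'
#' The abundance-weighted variance of the species means around the
#' community weighted mean: `sum_i a_i * (xbar_i - CWM)^2` with
#' `CWM = sum_i a_i xbar_i`.  Trait-squared units.
#'
#' @inheritParams witv_intra
#' @return A single non-negative number.
#' @export
witv_inter <- function(stats, comp, plot, trait) {
  m <- .plot_trait_slice(stats, comp, plot, trait)
  cwm <- sum(m$relative_biomass * m$mean)
  sum(m$relative_biomass * (m$mean - cwm)^2)
}

#' Within-community indices for every plot and trait
#'
#' Convenience wrapper computing [witv_intra()] and [witv_inter()] for every
#' (plot, trait) combination, with treatments attached.  Composition is
#' restricted to measured species and renormalized first (see
#' [align_composition()]).
#'
#' @param traits,comp,plots Tables as returned by [load_tables()].
#' @param trait_cols Trait column names (default: detected).
#' @param divisor Within-species variance divisor, see
#'   [species_plot_stats()].
#' @param renormalize Passed to [align_composition()].
#' @return Tibble with columns `plot_id`, `treatment`, `trait`,
#'   `witv_intra`, `witv_inter`.
#' @export
#' @examples
#' d <- generate_dataset(scenario_presets("paper-like", seed = 1))
#' head(within_community_indices(d$traits, d$composition, d$plots))
within_community_indices <- function(traits, comp, plots, trait_cols = NULL,
                                     divisor = "population",
                                     renormalize = TRUE) {
  if (is.null(trait_cols)) trait_cols <- trait_names(traits)
  comp <- align_composition(traits, comp, renormalize = renormalize)
  stats <- species_plot_stats(traits, trait_cols, divisor = divisor)
  grid <- expand.grid(
    plot_id = unique(traits$plot_id), trait = trait_cols,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  res <- tibble::as_tibble(grid)
  res$witv_intra <- mapply(
    function(p, tr) witv_intra(stats, comp, p, tr),
    res$plot_id, res$trait
  )
  res$witv_inter <- mapply(
    function(p, tr) witv_inter(stats, comp, p, tr),
    res$plot_id, res$trait
  )
  res <- dplyr::left_join(res, plots[, c("plot_id", "treatment")],
                          by = "plot_id")
  res[, c("plot_id", "treatment", "trait", "witv_intra", "witv_inter")]
}
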