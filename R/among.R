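# Among-community trait means and their specific / fixed / intraspecific
# components under two weighting schemes:
#
#   CWM (abundance-weighted): specific = sum_i a_i xbar_i
#                             fixed    = sum_i a_i xavg_i
#   CM  (equal-weight):       specific = (1/S) sum_i xbar_i
#                             fixed    = (1/S) sum_i xavg_i
#   intra = specific - fixed        (both schemes)
#
# xbar_i is the plot-local species mean; xavg_i the grand mean of species i
# pooled over all individuals in all plots.  The fixed component tracks
# species-composition change only; intra tracks within-species trait shifts
# across communities.

#' Grand species means pooled over all communities
#'
#' For each species and trait, the simple mean over all measured individuals
#' pooled across every plot and treatment (not a mean of plot means —
#' plots with more individuals weigh more).
#'
#' @param traits Trait table (see [load_tables()]).
#' @param trait_cols Trait column names (default: detected).
#' @return Tibble with columns `species_id`, `trait`, `grand_mean`.
#' @export
grand_species_means <- function(traits, trait_cols = NULL) {
  if (is.null(trait_cols)) trait_cols <- trait_names(traits)
  long <- tidyr::pivot_longer(
    traits[, c("species_id", trait_cols)],
    cols = dplyr::all_of(trait_cols),
    names_to = "trait", values_to = "value"
  )
  dplyr::summarise(
    dplyr::group_by(long, .data$species_id, .data$trait),
    grand_mean = mean(.data$value), .groups = "drop"
  )
}

#' Abundance-weighted community mean components for one plot and trait
#'
#' Returns the specific, fixed and intraspecific components of the community
#' weighted mean: `specific` weights plot-local species means by relative
#' biomass, `fixed` weights the grand species means instead, and
#' `intra = specific - fixed` exactly.
#'
#' @param stats Output of [species_plot_stats()].
#' @param comp Composition table normalized over measured species.
#' @param grand Output of [grand_species_means()].
#' @param plot,trait Plot id and trait name.
#' @return Named numeric vector `c(specific, fixed, intra)` in trait units.
#' @export
cwm_components <- function(stats, comp, grand, plot, trait) {
  m <- .plot_trait_slice(stats, comp, plot, trait)
  g <- grand[grand$trait == trait, , drop = FALSE]
  gm <- g$grand_mean[match(m$species_id, g$species_id)]
  if (anyNA(gm)) {
    stop(sprintf(
      "species without grand mean in plot '%s': %s",
      plot, paste(m$species_id[is.na(gm)], collapse = ", ")
    ), call. = FALSE)
  }
  specific <- sum(m$relative_biomass * m$mean)
  fixed <- sum(m$relative_biomass * gm)
  c(specific = specific, fixed = fixed, intra = specific - fixed)
}

#' Non-weighted community mean components for one plot and trait
#'
#' Every measured species gets equal weight 1/S: `specific` is the simple
#' mean of plot-local species means, `fixed` the simple mean of grand
#' species means, `intra = specific - fixed`.  The fixed component depends
#' only on which species are present, never on abundances.
#' `divide_fixed_by_s = FALSE` gives the undivided sum of grand means
#' instead of their mean (see the methods vignette for why the divided form
#' is the default).
#'
#' @param stats Output of [species_plot_stats()].
#' @param grand Output of [grand_species_means()].
#' @param plot,trait Plot id and trait name.
#' @param divide_fixed_by_s Divide the fixed component by the species count
#'   S (default TRUE).
#' @return Named numeric vector `c(specific, fixed, intra)`.
#' @export
cm_components <- function(stats, grand, plot, trait,
                          divide_fixed_by_s = TRUE) {
  s <- stats[stats$plot_id == plot & stats$trait == trait, , drop = FALSE]
  if (nrow(s) == 0) {
    stop(sprintf("plot '%s' (trait '%s') has no measured species",
                 plot, trait), call. = FALSE)
  }
  g <- grand[grand$trait == trait, , drop = FALSE]
  gm <- g$grand_mean[match(s$species_id, g$species_id)]
  if (anyNA(gm)) {
    stop(sprintf(
      "species without grand mean in plot '%s': %s",
      plot, paste(s$species_id[is.na(gm)], collapse = ", ")
    ), call. = FALSE)
  }
  S <- nrow(s)
  specific <- mean(s$mean)
  fixed <- if (divide_fixed_by_s) mean(gm) else sum(gm)
  c(specific = specific, fixed = fixed, intra = specific - fixed)
}

#' Community mean components for every plot, trait and scheme
#'
#' Computes the specific, fixed and intraspecific components of the
#' community trait mean for every plot and trait, under the
#' abundance-weighted (`cwm`) and/or equal-weight (`cm`) scheme, with
#' treatments attached.
#'
#' @param traits,comp,plots Tables as returned by [load_tables()].
#' @param trait_cols Trait column names (default: detected).
#' @param schemes Subset of `c("cwm", "cm")`.
#' @param divide_fixed_by_s Passed to [cm_components()].
#' @param renormalize Passed to [align_composition()].
#' @return Tibble with columns `plot_id`, `treatment`, `trait`, `scheme`,
#'   `specific`, `fixed`, `intra`.
#' @export
#' @examples
#' d <- generate_dataset(scenario_presets("paper-like", seed = 1))
#' head(community_means(d$traits, d$composition, d$plots))
community_means <- function(traits, comp, plots, trait_cols = NULL,
                            schemes = c("cwm", "cm"),
                            divide_fixed_by_s = TRUE,
                            renormalize = TRUE) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (is.null(trait_cols)) trait_cols <- trait_names(traits)
  comp <- align_composition(traits, comp, renormalize = renormalize)
  stats <- species_plot_stats(traits, trait_cols)
  grand <- grand_species_means(traits, trait_cols)
  grid <- expand.grid(
    plot_id = unique(traits$plot_id), trait = trait_cols, scheme = schemes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  comp_rows <- mapply(function(p, tr, sc) {
    if (sc == "cwm") cwm_components(stats, comp, grand, p, tr)
    else cm_components(stats, grand, p, tr, divide_fixed_by_s)
  }, grid$plot_id, grid$trait, grid$scheme)
  res <- tibble::as_tibble(grid)
  res$specific <- comp_rows["specific", ]
  res$fixed <- comp_rows["fixed", ]
  res$intra <- comp_rows["intra", ]
  res <- dplyr::left_join(res, plots[, c("plot_id", "treatment")],
                          by = "plot_id")
  res[, c("plot_id", "treatment", "trait", "scheme",
          "specific", "fixed", "intra")]
}
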