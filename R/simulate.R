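# Synthetic alpine-grassland communities with known ground truth.
#
# The generator emulates a fertilization-gradient field design: a set of
# treatments with replicate plots, a species pool with base trait means and
# base abundances, treatment-driven abundance turnover (multipliers),
# treatment-driven intraspecific trait shifts, Gaussian individual noise,
# optional species loss at extreme treatments, and a productivity variable
# (ANPP) linear in the plot's true abundance-weighted trait means.
# Everything is driven by one seed through hierarchical substreams so that
# adding a species or plot never perturbs the draws of the others.

# deterministic substream seed from a base seed and string/int identifiers,
# kept below 2^31 - 1
.substream <- function(seed, ...) {
  ids <- unlist(lapply(list(...), as.character))
  h <- as.double(seed %% 2147483647)
  for (id in ids) {
    for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

.default_species <- function() {
  tibble::tibble(
    species_id = paste0("sp", 1:6),
    base_abundance = c(0.40, 0.25, 0.15, 0.10, 0.06, 0.04),
    H = c(4, 20, 10, 8, 6, 5),          # cm
    LA = c(0.6, 2.5, 1.2, 1.8, 2.2, 1.5),  # cm2
    LDMC = c(0.42, 0.38, 0.40, 0.30, 0.33, 0.35),  # g/g
    SLA = c(9, 14, 11, 18, 16, 15)      # m2/kg
  )
}

# per-trait relative shift profile across the 5 default treatments and the
# abundance multipliers of the default turnover scenario
.default_shift_profiles <- function(direction = 1) {
  list(
    H = direction * c(0, 0.03, 0.07, 0.12, 0.18),
    LA = direction * c(0, 0.02, 0.05, 0.09, 0.13),
    LDMC = direction * -c(0, 0.01, 0.025, 0.045, 0.06),
    SLA = direction * c(0, 0.015, 0.04, 0.07, 0.10)
  )
}

.default_multipliers <- function() {
  # rows = species (sp1..sp6), cols = treatments; the tall grass (sp2)
  # expands with fertilization, the short dominant (sp1) and the rare
  # species contract
  rbind(
    c(1, 0.92, 0.78, 0.58, 0.42),
    c(1, 1.20, 1.55, 2.10, 2.90),
    c(1, 1.05, 1.10, 1.05, 0.95),
    c(1, 0.98, 0.95, 0.90, 0.85),
    c(1, 0.95, 0.85, 0.75, 0.65),
    c(1, 0.90, 0.78, 0.58, 0.45)
  )
}

#' Build a synthetic-community configuration
#'
#' Assembles the full parameter set of the generator.  Defaults mirror a
#' five-level nitrogen-addition gradient (labels CK, N2.5, N5, N10, N20)
#' with four replicate plots per level, six species with realistic alpine
#' meadow trait scales (H in cm, LA in cm2, LDMC in g/g, SLA in m2/kg),
#' eight measured individuals per species per plot, species-specific
#' abundance turnover, proportional intraspecific trait shifts along the
#' gradient, and individual noise of roughly 10 percent of typical trait
#' values.
#'
#' @param treatments Character vector of treatment labels, in gradient
#'   order.
#' @param n_replicates Plots per treatment.
#' @param species Tibble with `species_id`, `base_abundance` and one column
#'   per trait holding the species base mean.
#' @param trait_cols Trait column names in `species`.
#' @param abundance_multipliers Species x treatment matrix of positive
#'   multipliers applied to `base_abundance` (rows follow `species` order).
#' @param trait_shifts Named list (per trait) of species x treatment
#'   matrices of additive shifts of the species mean, in trait units.
#' @param noise_sd Named numeric vector (per trait) of the individual-level
#'   Gaussian noise SD, in trait units.
#' @param n_individuals Measured individuals per species per plot.
#' @param loss_threshold Relative abundance below which a species drops out
#'   of a plot entirely (absent from composition and traits); NULL disables
#'   species loss.
#' @param anpp List with `intercept`, `coefficients` (named per trait) and
#'   `noise_sd`: ANPP is a linear function of the plot's true
#'   abundance-weighted trait means plus noise, floored at 0.
#' @param dirichlet_jitter Dirichlet concentration for replicate-level
#'   composition noise (abundances drawn around the treatment expectation);
#'   NULL (default) keeps abundances deterministic given the config.
#' @param seed Integer seed driving all randomness.
#' @param scenario Free-text tag stored in the ground truth.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    treatments = c("CK", "N2.5", "N5", "N10", "N20"),
    n_replicates = 4,
    species = .default_species(),
    trait_cols = c("H", "LA", "LDMC", "SLA"),
    abundance_multipliers = NULL,
    trait_shifts = NULL,
    noise_sd = c(H = 1.5, LA = 0.25, LDMC = 0.03, SLA = 1.5),
    n_individuals = 8,
    loss_threshold = NULL,
    anpp = list(
      intercept = 20,
      coefficients = c(H = 3, LA = 10, LDMC = -100, SLA = 1),
      noise_sd = 8
    ),
    dirichlet_jitter = NULL,
    seed = 1,
    scenario = "mixed") {
  n_sp <- nrow(species)
  n_tr <- length(treatments)
  if (is.null(abundance_multipliers)) {
    abundance_multipliers <- matrix(1, n_sp, n_tr)
  }
  if (is.null(trait_shifts)) {
    trait_shifts <- lapply(setNames(trait_cols, trait_cols),
                           function(tc) matrix(0, n_sp, n_tr))
  }
  stopifnot(
    nrow(abundance_multipliers) == n_sp,
    ncol(abundance_multipliers) == n_tr,
    all(abundance_multipliers > 0),
    all(noise_sd[trait_cols] >= 0),
    all(vapply(trait_shifts, function(m)
      nrow(m) == n_sp && ncol(m) == n_tr, logical(1))),
    is.null(anpp) || anpp$noise_sd >= 0,
    n_individuals >= 1, n_replicates >= 1
  )
  structure(list(
    treatments = treatments, n_replicates = n_replicates,
    species = species, trait_cols = trait_cols,
    abundance_multipliers = abundance_multipliers,
    trait_shifts = trait_shifts, noise_sd = noise_sd,
    n_individuals = n_individuals, loss_threshold = loss_threshold,
    anpp = anpp, dirichlet_jitter = dirichlet_jitter,
    seed = as.integer(seed), scenario = scenario
  ), class = "synthetic_config")
}

#' Named scenario presets for the generator
#'
#' Configurations whose dominant decomposition component and covariation
#' sign are known by construction:
#'
#' * `"composition-only"` — abundance turnover along the gradient, no
#'   intraspecific shifts: treatment effects on community means are purely
#'   interspecific (fixed).
#' * `"plasticity-only"` — identical abundances everywhere, intraspecific
#'   shifts along the gradient: the abundance-weighted fixed component is
#'   constant across plots, so treatment effects are purely intraspecific.
#' * `"mixed-positive-cov"` — turnover and shifts push every trait the same
#'   way, producing positive between-treatment covariation.
#' * `"mixed-negative-cov"` — shifts oppose the turnover-driven change,
#'   producing negative covariation.
#' * `"paper-like"` — turnover, shifts, species loss at the high end of the
#'   gradient, and a trait-linked ANPP, at the design scale of a 5 x 4 plot
#'   field experiment.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param noise_sd Optional override of the per-trait individual noise SD
#'   (recycled over traits if unnamed scalar).
#' @return A `synthetic_config`.
#' @export
#' @examples
#' cfg <- scenario_presets("plasticity-only", seed = 7)
#' d <- generate_dataset(cfg)
#' nrow(d$plots)
scenario_presets <- function(name = c("composition-only", "plasticity-only",
                                      "mixed-positive-cov",
                                      "mixed-negative-cov", "paper-like"),
                             seed = 1, noise_sd = NULL) {
  name <- match.arg(name)
  species <- .default_species()
  trait_cols <- c("H", "LA", "LDMC", "SLA")
  shifts_from_profile <- function(direction) {
    profs <- .default_shift_profiles(direction)
    lapply(setNames(trait_cols, trait_cols), function(tc) {
      outer(species[[tc]], profs[[tc]])
    })
  }
  cfg <- switch(name,
    "composition-only" = synthetic_config(
      abundance_multipliers = .default_multipliers(),
      trait_shifts = NULL, seed = seed, scenario = "composition-only"
    ),
    "plasticity-only" = synthetic_config(
      abundance_multipliers = NULL,
      trait_shifts = shifts_from_profile(1),
      seed = seed, scenario = "plasticity-only"
    ),
    "mixed-positive-cov" = synthetic_config(
      abundance_multipliers = .default_multipliers(),
      trait_shifts = shifts_from_profile(1),
      seed = seed, scenario = "mixed"
    ),
    "mixed-negative-cov" = synthetic_config(
      abundance_multipliers = .default_multipliers(),
      trait_shifts = shifts_from_profile(-1),
      seed = seed, scenario = "mixed"
    ),
    "paper-like" = synthetic_config(
      abundance_multipliers = .default_multipliers(),
      trait_shifts = shifts_from_profile(1),
      loss_threshold = 0.025,
      seed = seed, scenario = "mixed"
    )
  )
  if (!is.null(noise_sd)) {
    if (is.null(names(noise_sd))) {
      noise_sd <- setNames(rep_len(noise_sd, length(trait_cols)), trait_cols)
    }
    cfg$noise_sd[names(noise_sd)] <- noise_sd
  }
  cfg
}

#' Generate a synthetic dataset with ground truth
#'
#' Realizes a `synthetic_config` into the three analysis input tables plus
#' the ground truth that produced them.  Each individual trait value is
#' species base mean + treatment shift + Gaussian noise, floored at 1
#' percent of the species base mean (traits are positive); the number of
#' floored values is recorded in `ground_truth$n_clipped`.  Plot abundances
#' are base x treatment multiplier, renormalized; species falling below
#' `loss_threshold` are omitted from both composition and traits.  ANPP is
#' the configured linear function of the plot's true abundance-weighted
#' trait means.  Output is fully determined by the config (same config,
#' same bytes).
#'
#' @param cfg A `synthetic_config` (see [synthetic_config()],
#'   [scenario_presets()]).
#' @return List with `traits`, `composition`, `plots` (analysis input
#'   tables), `trait_cols`, and `ground_truth` (realized abundances, true
#'   species means before noise, true abundance-weighted community means,
#'   scenario tag, clip count, config echo).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  sp <- cfg$species
  n_sp <- nrow(sp)
  trait_cols <- cfg$trait_cols

  plot_rows <- list(); comp_rows <- list(); trait_rows <- list()
  truth_ab <- list(); truth_mean <- list(); truth_cwm <- list()
  n_clipped <- 0L

  for (ti in seq_along(cfg$treatments)) {
    trt <- cfg$treatments[ti]
    # expected relative abundances for this treatment
    w <- sp$base_abundance * cfg$abundance_multipliers[, ti]
    rel_exp <- w / sum(w)
    for (r in seq_len(cfg$n_replicates)) {
      plot <- sprintf("%s-%d", trt, r)
      rel <- rel_exp
      if (!is.null(cfg$dirichlet_jitter)) {
        set.seed(.substream(cfg$seed, "abund", plot))
        g <- stats::rgamma(n_sp, shape = cfg$dirichlet_jitter * rel_exp)
        rel <- g / sum(g)
      }
      keep <- rep(TRUE, n_sp)
      if (!is.null(cfg$loss_threshold)) {
        keep <- rel >= cfg$loss_threshold
        if (!any(keep)) {
          stop(sprintf("loss threshold leaves plot '%s' empty", plot),
               call. = FALSE)
        }
        rel <- ifelse(keep, rel, 0)
        rel <- rel / sum(rel)
      }
      comp_rows[[plot]] <- tibble::tibble(
        plot_id = plot, species_id = sp$species_id[keep],
        relative_biomass = rel[keep]
      )
      truth_ab[[plot]] <- tibble::tibble(
        plot_id = plot, treatment = trt, species_id = sp$species_id[keep],
        relative_abundance = rel[keep]
      )
      # true per-species means in this plot, then noisy individuals
      tm <- sapply(trait_cols, function(tc) {
        sp[[tc]] + cfg$trait_shifts[[tc]][, ti]
      })
      for (si in which(keep)) {
        set.seed(.substream(cfg$seed, "ind", plot, sp$species_id[si]))
        vals <- sapply(trait_cols, function(tc) {
          x <- tm[si, tc] +
            stats::rnorm(cfg$n_individuals, 0, cfg$noise_sd[[tc]])
          floor_at <- 0.01 * sp[[tc]][si]
          n_clipped <<- n_clipped + sum(x < floor_at)
          pmax(x, floor_at)
        })
        vals <- matrix(vals, nrow = cfg$n_individuals,
                       dimnames = list(NULL, trait_cols))
        trait_rows[[paste(plot, si)]] <- tibble::tibble(
          plot_id = plot, treatment = trt,
          species_id = sp$species_id[si],
          individual_id = sprintf("ind%02d", seq_len(cfg$n_individuals)),
          !!!as.data.frame(vals)
        )
      }
      truth_mean[[plot]] <- tibble::tibble(
        plot_id = plot, treatment = trt,
        species_id = rep(sp$species_id[keep], times = length(trait_cols)),
        trait = rep(trait_cols, each = sum(keep)),
        true_mean = as.vector(tm[keep, trait_cols])
      )
      cwm_true <- colSums(rel[keep] * tm[keep, , drop = FALSE])
      truth_cwm[[plot]] <- tibble::tibble(
        plot_id = plot, treatment = trt, trait = trait_cols,
        true_cwm_specific = unname(cwm_true[trait_cols])
      )
      anpp_val <- NA_real_
      if (!is.null(cfg$anpp)) {
        set.seed(.substream(cfg$seed, "anpp", plot))
        mu <- cfg$anpp$intercept +
          sum(cfg$anpp$coefficients[trait_cols] * cwm_true[trait_cols])
        anpp_val <- max(0, mu + stats::rnorm(1, 0, cfg$anpp$noise_sd))
      }
      plot_rows[[plot]] <- tibble::tibble(
        plot_id = plot, treatment = trt, anpp = anpp_val
      )
    }
  }

  traits <- dplyr::bind_rows(trait_rows)
  list(
    traits = traits,
    composition = dplyr::bind_rows(comp_rows),
    plots = dplyr::bind_rows(plot_rows),
    trait_cols = trait_cols,
    ground_truth = list(
      scenario = cfg$scenario,
      abundances = dplyr::bind_rows(truth_ab),
      true_species_means = dplyr::bind_rows(truth_mean),
      true_cwm = dplyr::bind_rows(truth_cwm),
      n_clipped = n_clipped,
      config = cfg
    )
  )
}
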