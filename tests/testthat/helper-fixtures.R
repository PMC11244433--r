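# Shared fixtures and independent oracles.

# A tiny hand-built dataset: 2 treatments x 2 plots, 2 species, 1 trait.
tiny_dataset <- function() {
  traits <- tibble::tibble(
    plot_id = rep(c("p1", "p2"), each = 4),
    treatment = rep(c("T1", "T2"), each = 4),
    species_id = rep(rep(c("A", "B"), each = 2), 2),
    individual_id = rep(c("i1", "i2"), 4),
    H = c(1, 3, 4, 4, 2, 2, 5, 7)
  )
  comp <- tibble::tibble(
    plot_id = rep(c("p1", "p2"), each = 2),
    species_id = rep(c("A", "B"), 2),
    relative_biomass = c(0.5, 0.5, 0.25, 0.75)
  )
  plots <- tibble::tibble(
    plot_id = c("p1", "p2"), treatment = c("T1", "T2"),
    anpp = c(100, 150)
  )
  list(traits = traits, composition = comp, plots = plots)
}

# Random small community for oracle comparisons: a list of per-species
# individual values plus normalized abundances.
random_community <- function(seed) {
  set.seed(seed)
  n_sp <- sample(1:5, 1)
  values <- lapply(seq_len(n_sp), function(i) {
    stats::runif(sample(1:6, 1), min = 0.5, max = 20)
  })
  names(values) <- paste0("sp", seq_len(n_sp))
  a <- stats::runif(n_sp, 0.05, 1)
  list(values = values, abundances = a / sum(a))
}

# Naive double-loop evaluation of the within-community indices, written
# directly from their defining sums and kept independent of the package's
# vectorized path.
naive_witv <- function(values, abundances) {
  S <- length(values)
  intra <- 0
  cwm <- 0
  for (i in seq_len(S)) {
    xi <- values[[i]]
    n_i <- length(xi)
    xbar <- sum(xi) / n_i
    acc <- 0
    for (j in seq_len(n_i)) acc <- acc + (xi[j] - xbar)^2
    intra <- intra + abundances[i] * acc / n_i
    cwm <- cwm + abundances[i] * xbar
  }
  inter <- 0
  for (i in seq_len(S)) {
    xbar <- sum(values[[i]]) / length(values[[i]])
    inter <- inter + abundances[i] * (xbar - cwm)^2
  }
  c(intra = intra, inter = inter, cwm = cwm)
}

# Package tables for one single-plot community, so the vectorized path can
# be run on the same random community the naive oracle sees.
community_as_tables <- function(comm, plot = "p1", treatment = "T1") {
  sp <- names(comm$values)
  traits <- dplyr::bind_rows(lapply(seq_along(sp), function(i) {
    tibble::tibble(
      plot_id = plot, treatment = treatment, species_id = sp[i],
      individual_id = paste0("i", seq_along(comm$values[[i]])),
      H = comm$values[[i]]
    )
  }))
  comp <- tibble::tibble(
    plot_id = plot, species_id = sp,
    relative_biomass = comm$abundances
  )
  plots <- tibble::tibble(plot_id = plot, treatment = treatment)
  list(traits = traits, composition = comp, plots = plots)
}

# Random small generator config: 2-3 treatments, 2 replicates, 3 species,
# 2 traits, random turnover, shifts and noise.
random_small_config <- function(seed) {
  set.seed(seed)
  n_tr <- sample(2:3, 1)
  species <- tibble::tibble(
    species_id = c("a", "b", "c"),
    base_abundance = as.vector(stats::runif(3, 0.1, 1)),
    t1 = stats::runif(3, 5, 20),
    t2 = stats::runif(3, 0.2, 2)
  )
  synthetic_config(
    treatments = paste0("L", seq_len(n_tr)),
    n_replicates = 2,
    species = species,
    trait_cols = c("t1", "t2"),
    abundance_multipliers = matrix(stats::runif(3 * n_tr, 0.5, 2), 3, n_tr),
    trait_shifts = list(
      t1 = matrix(stats::rnorm(3 * n_tr, 0, 2), 3, n_tr),
      t2 = matrix(stats::rnorm(3 * n_tr, 0, 0.2), 3, n_tr)
    ),
    noise_sd = c(t1 = 0.8, t2 = 0.1),
    n_individuals = 4,
    anpp = list(intercept = 10, coefficients = c(t1 = 2, t2 = 5),
                noise_sd = 3),
    seed = seed
  )
}

# Random grouped values for ANOVA/Tukey oracle comparisons; balanced or not.
random_groups <- function(seed) {
  set.seed(seed)
  k <- sample(2:5, 1)
  balanced <- stats::runif(1) < 0.5
  ns <- if (balanced) rep(sample(3:6, 1), k) else sample(2:7, k, replace = TRUE)
  v <- lapply(seq_len(k), function(i) {
    stats::rnorm(ns[i], mean = stats::rnorm(1, 0, 2))
  })
  names(v) <- paste0("g", seq_len(k))
  v
}

# Reference ANOVA and Tukey via stats::aov / stats::TukeyHSD.
reference_anova_tukey <- function(values_by_level) {
  df <- data.frame(
    y = unlist(values_by_level),
    g = factor(rep(names(values_by_level),
                   vapply(values_by_level, length, integer(1))))
  )
  fit <- stats::aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(
    f = s[["F value"]][1], p = s[["Pr(>F)"]][1],
    ss_between = s[["Sum Sq"]][1], ss_within = s[["Sum Sq"]][2],
    tukey = tk
  )
}
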