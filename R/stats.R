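# Treatment-effect statistics: fixed-effects one-way ANOVA, Tukey-Kramer
# HSD, compact letter displays, and the sum-of-squares decomposition of
# treatment-induced community-mean variation into interspecific (fixed),
# intraspecific and covariation effects.

.as_values_by_level <- function(values_by_level) {
  if (!is.list(values_by_level) || is.null(names(values_by_level))) {
    stop("values_by_level must be a named list of numeric vectors",
         call. = FALSE)
  }
  lapply(values_by_level, as.numeric)
}

#' One-way fixed-effects ANOVA
#'
#' Textbook one-way ANOVA on a named list of per-level value vectors.  The
#' p value comes from the F distribution with (k - 1, N - k) degrees of
#' freedom.  Degenerate inputs are flagged rather than erroring: zero
#' within-group SS with non-zero between-group SS gives F = Inf, p = 0;
#' all values identical gives F = 0, p = 1.
#'
#' @param values_by_level Named list, one numeric vector per factor level;
#'   at least 2 levels, each non-empty, at least one with 2+ values.
#' @return List of class `anova_fit` with `ss_between`, `ss_within`,
#'   `ss_total`, `df_between`, `df_within`, `f_stat`, `p_value`,
#'   `degenerate` (logical), plus `level_means` and `level_ns` used by
#'   [tukey_hsd()].
#' @export
#' @examples
#' one_way_anova(list(T1 = c(1, 2), T2 = c(3, 4)))
one_way_anova <- function(values_by_level) {
  v <- .as_values_by_level(values_by_level)
  k <- length(v)
  if (k < 2) stop("need at least 2 levels", call. = FALSE)
  ns <- vapply(v, length, integer(1))
  if (any(ns < 1)) stop("every level needs at least 1 value", call. = FALSE)
  if (!any(ns >= 2)) {
    stop("at least one level needs 2 or more values", call. = FALSE)
  }
  n_tot <- sum(ns)
  means <- vapply(v, mean, numeric(1))
  grand <- sum(unlist(v)) / n_tot
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(v, function(x) sum((x - mean(x))^2), numeric(1)))
  df_between <- k - 1
  df_within <- n_tot - k
  degenerate <- FALSE
  if (ss_within <= 0 && ss_between > 0) {
    f_stat <- Inf
    p_value <- 0
    degenerate <- TRUE
  } else if (ss_between <= 0 && ss_within <= 0) {
    f_stat <- 0
    p_value <- 1
    degenerate <- TRUE
  } else {
    f_stat <- (ss_between / df_between) / (ss_within / df_within)
    p_value <- stats::pf(f_stat, df_between, df_within, lower.tail = FALSE)
  }
  structure(list(
    ss_between = ss_between, ss_within = ss_within,
    ss_total = ss_between + ss_within,
    df_between = df_between, df_within = df_within,
    f_stat = f_stat, p_value = p_value, degenerate = degenerate,
    level_means = means, level_ns = ns
  ), class = "anova_fit")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf(
    "one-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
    x$df_between, x$df_within, x$f_stat, x$p_value,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Tukey-Kramer honestly-significant-difference test
#'
#' All pairwise comparisons of level means after a one-way ANOVA, using the
#' studentized-range distribution on the pooled within-group variance.
#' Unequal group sizes are handled with the Kramer correction
#' (`se = sqrt(MSE/2 * (1/n_a + 1/n_b))`).  With two levels the adjusted p
#' equals the ANOVA p.  If the pooled variance is zero the fit is flagged
#' degenerate and any non-zero mean difference is marked significant
#' (p = 0); zero differences get p = 1.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level for the `significant` flag
#'   (default 0.05).
#' @return Tibble with one row per unordered level pair: `level_a`,
#'   `level_b`, `mean_diff` (a minus b), `q_stat`, `p_adj`, `significant`.
#' @export
#' @examples
#' tukey_hsd(list(A = c(1, 2), B = c(3, 4), C = c(5, 6)))
tukey_hsd <- function(values_by_level, alpha = 0.05) {
  v <- .as_values_by_level(values_by_level)
  fit <- one_way_anova(v)
  k <- length(v)
  mse <- fit$ss_within / fit$df_within
  pairs <- utils::combn(names(v), 2)
  res <- tibble::tibble(
    level_a = pairs[1, ], level_b = pairs[2, ],
    mean_diff = unname(fit$level_means[pairs[1, ]] -
                         fit$level_means[pairs[2, ]]),
    q_stat = NA_real_, p_adj = NA_real_
  )
  for (i in seq_len(nrow(res))) {
    na <- fit$level_ns[[res$level_a[i]]]
    nb <- fit$level_ns[[res$level_b[i]]]
    if (mse <= 0) {
      res$q_stat[i] <- if (res$mean_diff[i] == 0) 0 else Inf
      res$p_adj[i] <- if (res$mean_diff[i] == 0) 1 else 0
    } else {
      se <- sqrt(mse / 2 * (1 / na + 1 / nb))
      res$q_stat[i] <- abs(res$mean_diff[i]) / se
      res$p_adj[i] <- stats::ptukey(res$q_stat[i], k, fit$df_within,
                                    lower.tail = FALSE)
    }
  }
  res$significant <- res$p_adj < alpha
  attr(res, "alpha") <- alpha
  attr(res, "level_means") <- fit$level_means
  res
}

#' Compact letter display for pairwise comparisons
#'
#' Assigns lowercase letters to factor levels so that two levels share a
#' letter if and only if the pairwise table does not call them
#' significantly different (the insert-and-absorb algorithm: start from one
#' group holding every level, split it on each significant pair, absorb
#' subset groups).  Levels are ordered by descending mean — the level with
#' the largest mean gets "a" — when means are available (they are attached
#' by [tukey_hsd()]); otherwise by first appearance.
#'
#' @param pairwise Output of [tukey_hsd()], or any data frame with columns
#'   `level_a`, `level_b` and either `significant` or `p_adj`.
#' @param alpha Significance level used when only `p_adj` is present
#'   (default: the attribute stored by [tukey_hsd()], else 0.05).
#' @param level_means Optional named vector of level means used to order
#'   letter assignment.
#' @return Named character vector: one letter string per level.
#' @export
#' @examples
#' cld <- compact_letter_display(tukey_hsd(list(
#'   A = c(1.0, 1.1), B = c(1.05, 1.15), C = c(9, 9.1)
#' )))
#' cld
compact_letter_display <- function(pairwise, alpha = NULL,
                                   level_means = NULL) {
  if (is.null(alpha)) alpha <- attr(pairwise, "alpha") %||% 0.05
  if (is.null(level_means)) level_means <- attr(pairwise, "level_means")
  sig <- if ("significant" %in% names(pairwise)) {
    pairwise$significant
  } else {
    pairwise$p_adj < alpha
  }
  levels <- unique(c(pairwise$level_a, pairwise$level_b))
  if (!is.null(level_means)) {
    levels <- levels[order(-level_means[levels])]
  }
  # insert-and-absorb on the set system of mutually non-significant groups
  groups <- list(levels)
  sig_pairs <- pairwise[sig, c("level_a", "level_b"), drop = FALSE]
  for (i in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$level_a[i]
    b <- sig_pairs$level_b[i]
    new_groups <- list()
    for (g in groups) {
      if (a %in% g && b %in% g) {
        new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
      } else {
        new_groups <- c(new_groups, list(g))
      }
    }
    # absorb: drop empty groups, duplicates, and groups contained in another
    new_groups <- new_groups[vapply(new_groups, length, integer(1)) > 0]
    new_groups <- unique(lapply(new_groups, sort))
    keep <- vapply(seq_along(new_groups), function(p) {
      !any(vapply(seq_along(new_groups), function(q) {
        q != p && all(new_groups[[p]] %in% new_groups[[q]]) &&
          length(new_groups[[q]]) > length(new_groups[[p]])
      }, logical(1)))
    }, logical(1))
    groups <- new_groups[keep]
  }
  # order groups by their best-ranked member so "a" goes to the top mean
  rank_of <- setNames(seq_along(levels), levels)
  groups <- groups[order(vapply(groups, function(g) min(rank_of[g]),
                                numeric(1)))]
  out <- setNames(rep("", length(levels)), levels)
  for (gi in seq_along(groups)) {
    letter <- letters[gi]
    for (lv in groups[[gi]]) out[lv] <- paste0(out[lv], letter)
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Decompose treatment-induced community-mean variation
#'
#' Runs a one-way treatment ANOVA separately on the per-plot `specific`,
#' `fixed` and `intra` series of one trait under one weighting scheme, and
#' derives the covariation effect in every stratum (between-treatment,
#' within-treatment, total) as
#' `ss_cov = ss_specific - ss_fixed - ss_intra`.  A positive between-stratum
#' covariation means composition change and intraspecific shifts push the
#' community mean the same way under the treatment; a negative one means
#' they oppose.  No test is attached to the covariation term.
#'
#' @param means Output of [community_means()] (or any table with columns
#'   `plot_id`, `treatment`, `trait`, `scheme`, `specific`, `fixed`,
#'   `intra`).
#' @param plots Plot table; used only to fill treatments if `means` lacks
#'   them.  May be NULL when `means` carries a `treatment` column.
#' @param trait,scheme Which trait and scheme (`"cwm"` or `"cm"`) to
#'   decompose.
#' @return List of class `ss_decomposition`: tibble `ss` (rows = strata
#'   `between`, `within`, `total`; columns `ss_specific`, `ss_fixed`,
#'   `ss_intra`, `ss_cov`), `p_specific`, `p_fixed`, `p_intra`,
#'   `f_specific`, `f_fixed`, `f_intra`, plus `trait` and `scheme`.
#' @export
#' @examples
#' d <- generate_dataset(scenario_presets("paper-like", seed = 1))
#' cm <- community_means(d$traits, d$composition, d$plots)
#' ss_decompose(cm, d$plots, trait = "H", scheme = "cwm")
ss_decompose <- function(means, plots = NULL, trait, scheme = "cwm") {
  rows <- means[means$trait == trait & means$scheme == scheme, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop(sprintf("no community means for trait '%s', scheme '%s'",
                 trait, scheme), call. = FALSE)
  }
  if (!("treatment" %in% names(rows)) || all(is.na(rows$treatment))) {
    if (is.null(plots)) stop("treatments unavailable", call. = FALSE)
    rows$treatment <- NULL
    rows <- dplyr::left_join(rows, plots[, c("plot_id", "treatment")],
                             by = "plot_id")
  }
  if (length(unique(rows$treatment)) < 2) {
    stop("need at least 2 treatments to decompose", call. = FALSE)
  }
  fits <- lapply(c("specific", "fixed", "intra"), function(col) {
    one_way_anova(split(rows[[col]], rows$treatment))
  })
  names(fits) <- c("specific", "fixed", "intra")
  ss <- tibble::tibble(
    stratum = c("between", "within", "total"),
    ss_specific = c(fits$specific$ss_between, fits$specific$ss_within,
                    fits$specific$ss_total),
    ss_fixed = c(fits$fixed$ss_between, fits$fixed$ss_within,
                 fits$fixed$ss_total),
    ss_intra = c(fits$intra$ss_between, fits$intra$ss_within,
                 fits$intra$ss_total)
  )
  ss$ss_cov <- ss$ss_specific - ss$ss_fixed - ss$ss_intra
  structure(list(
    trait = trait, scheme = scheme, ss = ss,
    f_specific = fits$specific$f_stat, p_specific = fits$specific$p_value,
    f_fixed = fits$fixed$f_stat, p_fixed = fits$fixed$p_value,
    f_intra = fits$intra$f_stat, p_intra = fits$intra$p_value,
    anovas = fits
  ), class = "ss_decomposition")
}

#' @export
print.ss_decomposition <- function(x, ...) {
  cat(sprintf("SS decomposition: trait %s, scheme %s\n",
              x$trait, toupper(x$scheme)))
  print(as.data.frame(x$ss), row.names = FALSE)
  cat(sprintf(
    "p(specific) = %.4g, p(fixed) = %.4g, p(intra) = %.4g\n",
    x$p_specific, x$p_fixed, x$p_intra
  ))
  pct <- attr(x, "percent")
  if (!is.null(pct)) {
    cat(sprintf(
      "treatment-explained: fixed %.1f%%, intra %.1f%%, cov %.1f%% (of %s SS)\n",
      pct["fixed"], pct["intra"], pct["cov"], attr(x, "denominator")
    ))
  }
  invisible(x)
}

#' Contribution percentages of the decomposition components
#'
#' Expresses the between-treatment (treatment-explained) fixed,
#' intraspecific and covariation sums of squares as percentages.  The
#' default denominator is the total SS of the specific series (between +
#' within), so fixed + intra + cov sums to the share of total variation the
#' treatment explains; `denominator = "explained"` uses only the
#' between-treatment specific SS, so the three percentages sum to 100.  The
#' covariation percentage may be negative.
#'
#' @param d An `ss_decomposition` from [ss_decompose()].
#' @param denominator `"total"` (default) or `"explained"`.
#' @return `d` with attributes `percent` (named vector `fixed`, `intra`,
#'   `cov`, `specific`) and `denominator`; `NA` percentages with a
#'   `degenerate` attribute when the denominator SS is 0.
#' @export
contribution_percentages <- function(d,
                                     denominator = c("total", "explained")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(d, "ss_decomposition"))
  between <- d$ss[d$ss$stratum == "between", , drop = FALSE]
  denom <- if (denominator == "total") {
    d$ss$ss_specific[d$ss$stratum == "total"]
  } else {
    between$ss_specific
  }
  if (denom <= 0) {
    pct <- c(fixed = NA_real_, intra = NA_real_, cov = NA_real_,
             specific = NA_real_)
    attr(d, "degenerate") <- TRUE
  } else {
    pct <- 100 * c(
      fixed = between$ss_fixed, intra = between$ss_intra,
      cov = between$ss_cov, specific = between$ss_specific
    ) / denom
  }
  attr(d, "percent") <- pct
  attr(d, "denominator") <- denominator
  d
}

#' Decomposition table for every trait and scheme
#'
#' Applies [ss_decompose()] and [contribution_percentages()] to every
#' (trait, scheme) combination present in `means` and flattens the result.
#'
#' @inheritParams ss_decompose
#' @param denominator Passed to [contribution_percentages()].
#' @return Tibble, one row per (trait, scheme): between/within/total SS of
#'   each component, percentages, F and p of the three component ANOVAs.
#' @export
decompose_traits <- function(means, plots = NULL,
                             denominator = c("total", "explained")) {
  denominator <- match.arg(denominator)
  combos <- unique(means[, c("trait", "scheme")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    d <- ss_decompose(means, plots, combos$trait[i], combos$scheme[i])
    d <- contribution_percentages(d, denominator)
    b <- d$ss[d$ss$stratum == "between", ]
    w <- d$ss[d$ss$stratum == "within", ]
    t <- d$ss[d$ss$stratum == "total", ]
    pct <- attr(d, "percent")
    tibble::tibble(
      trait = d$trait, scheme = d$scheme,
      ss_specific_between = b$ss_specific, ss_fixed_between = b$ss_fixed,
      ss_intra_between = b$ss_intra, ss_cov_between = b$ss_cov,
      ss_specific_within = w$ss_specific, ss_fixed_within = w$ss_fixed,
      ss_intra_within = w$ss_intra, ss_cov_within = w$ss_cov,
      ss_specific_total = t$ss_specific, ss_fixed_total = t$ss_fixed,
      ss_intra_total = t$ss_intra, ss_cov_total = t$ss_cov,
      percent_fixed = pct[["fixed"]], percent_intra = pct[["intra"]],
      percent_cov = pct[["cov"]], percent_specific = pct[["specific"]],
      f_specific = d$f_specific, p_specific = d$p_specific,
      f_fixed = d$f_fixed, p_fixed = d$p_fixed,
      f_intra = d$f_intra, p_intra = d$p_intra
    )
  })
  dplyr::bind_rows(rows)
}

#' Treatment ANOVA, Tukey HSD and letters for an index table
#'
#' Runs, for each index column of a long per-plot index table, the one-way
#' treatment ANOVA, the Tukey-Kramer comparisons and the compact letter
#' display, per trait.
#'
#' @param indices Long tibble with columns `plot_id`, `treatment`, `trait`
#'   and one or more numeric index columns (e.g. the output of
#'   [within_community_indices()] or a pivoted [community_means()] table).
#' @param index_cols Which columns to test (default: every numeric column
#'   other than the identifiers).
#' @param alpha Significance level (default 0.05).
#' @param level_order Optional character vector fixing the treatment order
#'   in the output (default: order of first appearance).
#' @return List of tibbles: `anova` (trait x index F, p, SS), `tukey`
#'   (pairwise rows), `letters` (trait x index x treatment letter).
#' @export
treatment_tests <- function(indices, index_cols = NULL, alpha = 0.05,
                            level_order = NULL) {
  id_cols <- c("plot_id", "treatment", "trait", "scheme")
  if (is.null(index_cols)) {
    index_cols <- setdiff(names(indices)[vapply(indices, is.numeric,
                                                logical(1))], id_cols)
  }
  if (is.null(level_order)) level_order <- unique(indices$treatment)
  anova_rows <- list()
  tukey_rows <- list()
  letter_rows <- list()
  for (tr in sort(unique(indices$trait))) {
    sub <- indices[indices$trait == tr, , drop = FALSE]
    for (ic in index_cols) {
      groups <- split(sub[[ic]], factor(sub$treatment, levels = level_order))
      groups <- groups[vapply(groups, length, integer(1)) > 0]
      fit <- one_way_anova(groups)
      anova_rows[[length(anova_rows) + 1]] <- tibble::tibble(
        trait = tr, index = ic,
        ss_between = fit$ss_between, ss_within = fit$ss_within,
        df_between = fit$df_between, df_within = fit$df_within,
        f_stat = fit$f_stat, p_value = fit$p_value,
        degenerate = fit$degenerate
      )
      tk <- tukey_hsd(groups, alpha = alpha)
      tk <- tibble::add_column(tk, trait = tr, index = ic, .before = 1)
      tukey_rows[[length(tukey_rows) + 1]] <- tk
      cld <- compact_letter_display(tk, alpha = alpha)
      letter_rows[[length(letter_rows) + 1]] <- tibble::tibble(
        trait = tr, index = ic,
        treatment = factor(names(cld), levels = level_order),
        letters = unname(cld)
      )
    }
  }
  letters_tab <- dplyr::bind_rows(letter_rows)
  letters_tab <- letters_tab[order(letters_tab$trait, letters_tab$index,
                                   letters_tab$treatment), ]
  letters_tab$treatment <- as.character(letters_tab$treatment)
  list(
    anova = dplyr::bind_rows(anova_rows),
    tukey = dplyr::bind_rows(tukey_rows),
    letters = letters_tab
  )
}
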