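test_that("one_way_anova reproduces hand-worked sums of squares", {
  f <- one_way_anova(list(T1 = c(1, 2), T2 = c(3, 4)))
  expect_equal(f$ss_between, 4)
  expect_equal(f$ss_within, 1)
  expect_equal(f$f_stat, 8.0)
  expect_equal(f$df_between, 1)
  expect_equal(f$df_within, 2)

  f2 <- one_way_anova(list(A = c(1, 3), B = c(2, 4)))
  expect_equal(f2$ss_between, 1)
  expect_equal(f2$ss_within, 4)
  expect_equal(f2$f_stat, 0.5)

  f3 <- one_way_anova(list(T1 = c(1, 2), T2 = c(1, 2)))
  expect_equal(f3$ss_between, 0)
  expect_equal(f3$f_stat, 0)

  # degenerate branches
  f4 <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_true(f4$degenerate)
  expect_equal(f4$p_value, 0)
  expect_equal(f4$f_stat, Inf)
  f5 <- one_way_anova(list(a = c(3, 3), b = c(3, 3)))
  expect_true(f5$degenerate)
  expect_equal(f5$p_value, 1)
  expect_error(one_way_anova(list(a = 1:3)), "2 levels")
})

test_that("tukey_hsd matches known identities and flags", {
  # two groups: Tukey p equals the ANOVA p (q = sqrt(2) |t|)
  v <- list(A = c(1, 2, 4), B = c(3, 5, 6))
  f <- one_way_anova(v)
  tk <- tukey_hsd(v)
  expect_lt(abs(tk$p_adj - f$p_value), 1e-6)
  # identical group means: diff 0, p 1
  tk0 <- tukey_hsd(list(A = c(1, 3), B = c(1, 3)))
  expect_equal(tk0$mean_diff, 0)
  expect_equal(tk0$p_adj, 1)
  # zero pooled variance: nonzero differences significant
  tkd <- tukey_hsd(list(a = c(1, 1), b = c(2, 2), c = c(1, 1)))
  expect_equal(tkd$p_adj[tkd$level_a == "a" & tkd$level_b == "b"], 0)
  expect_equal(tkd$p_adj[tkd$level_a == "a" & tkd$level_b == "c"], 1)
})

test_that("anova and tukey agree with the stats::aov / TukeyHSD reference", {
  for (seed in 1:60) {
    v <- random_groups(seed)
    mine <- one_way_anova(v)
    tk <- tukey_hsd(v)
    ref <- reference_anova_tukey(v)
    expect_lt(abs(mine$f_stat - ref$f) / max(1, abs(ref$f)), 1e-8)
    expect_lt(abs(mine$p_value - ref$p), 1e-8)
    expect_lt(abs(mine$ss_between - ref$ss_between) /
                max(1, ref$ss_between), 1e-8)
    # match rows: TukeyHSD labels pairs "b-a" with diff mean(b) - mean(a)
    key_ref <- rownames(ref$tukey)
    for (i in seq_len(nrow(tk))) {
      k1 <- paste0(tk$level_b[i], "-", tk$level_a[i])
      k2 <- paste0(tk$level_a[i], "-", tk$level_b[i])
      j <- match(k1, key_ref)
      sign <- -1
      if (is.na(j)) { j <- match(k2, key_ref); sign <- 1 }
      expect_false(is.na(j))
      expect_lt(abs(sign * tk$mean_diff[i] - ref$tukey[j, "diff"]), 1e-8)
      expect_lt(abs(tk$p_adj[i] - ref$tukey[j, "p adj"]), 1e-6)
    }
  }
})

test_that("compact letter display implements insert-and-absorb correctly", {
  # p(AB) = p(AC) = 0.01, p(BC) = 0.9 -> A alone, B and C together
  pw <- tibble::tibble(
    level_a = c("A", "A", "B"), level_b = c("B", "C", "C"),
    p_adj = c(0.01, 0.01, 0.9)
  )
  cld <- compact_letter_display(pw, alpha = 0.05,
                                level_means = c(A = 10, B = 5, C = 4))
  expect_equal(unname(cld["A"]), "a")
  expect_equal(unname(cld["B"]), "b")
  expect_equal(unname(cld["C"]), "b")
  # all nonsignificant -> single letter
  pw$p_adj <- c(0.5, 0.5, 0.5)
  expect_true(all(compact_letter_display(pw, alpha = 0.05) == "a"))
  # all significant -> three letters
  pw$p_adj <- c(0.001, 0.001, 0.001)
  expect_setequal(unname(compact_letter_display(
    pw, alpha = 0.05, level_means = c(A = 3, B = 2, C = 1))), c("a", "b", "c"))
})

test_that("letters share iff the pair is not significant, on random patterns", {
  set.seed(42)
  for (rep in 1:40) {
    k <- sample(3:6, 1)
    lv <- LETTERS[1:k]
    pairs <- t(utils::combn(lv, 2))
    pw <- tibble::tibble(
      level_a = pairs[, 1], level_b = pairs[, 2],
      significant = stats::runif(nrow(pairs)) < 0.4
    )
    cld <- compact_letter_display(pw)
    share <- function(a, b) {
      any(strsplit(cld[[a]], "")[[1]] %in% strsplit(cld[[b]], "")[[1]])
    }
    for (i in seq_len(nrow(pw))) {
      expect_identical(share(pw$level_a[i], pw$level_b[i]),
                       !pw$significant[i])
    }
    expect_true(all(nchar(cld) >= 1))
  }
})

test_that("ss_decompose reproduces the hand-worked two-treatment fixture", {
  means <- tibble::tibble(
    plot_id = paste0("p", 1:4),
    treatment = c("T1", "T1", "T2", "T2"),
    trait = "H", scheme = "cwm",
    specific = c(3, 3, 5, 5),
    fixed = c(2, 2, 3, 3)
  )
  means$intra <- means$specific - means$fixed
  d <- ss_decompose(means, NULL, "H", "cwm")
  b <- d$ss[d$ss$stratum == "between", ]
  expect_equal(b$ss_specific, 4)
  expect_equal(b$ss_fixed, 1)
  expect_equal(b$ss_intra, 1)
  expect_equal(b$ss_cov, 2)
  d <- contribution_percentages(d)   # total denominator; within SS is 0
  pct <- attr(d, "percent")
  expect_equal(unname(pct[c("fixed", "intra", "cov")]), c(25, 25, 50))
  expect_output(print(d), "decomposition")
  expect_error(ss_decompose(means[means$treatment == "T1", ], NULL,
                            "H", "cwm"), "2 treatments")
})

test_that("decomposition additivity and covariation sign behave as constructed", {
  # intra identically 0: fixed carries everything, cov 0
  means0 <- tibble::tibble(
    plot_id = paste0("p", 1:6),
    treatment = rep(c("a", "b", "c"), each = 2),
    trait = "t", scheme = "cwm",
    specific = c(1, 1.2, 2, 2.1, 3, 3.3)
  )
  means0$fixed <- means0$specific
  means0$intra <- 0
  d0 <- ss_decompose(means0, NULL, "t", "cwm")
  expect_equal(d0$ss$ss_intra, rep(0, 3))
  expect_equal(d0$ss$ss_cov, rep(0, 3), tolerance = 1e-12)
  expect_equal(d0$ss$ss_fixed, d0$ss$ss_specific, tolerance = 1e-12)

  # anticorrelated fixed and intra treatment profiles: negative covariation
  meansn <- tibble::tibble(
    plot_id = paste0("p", 1:4),
    treatment = c("T1", "T1", "T2", "T2"),
    trait = "t", scheme = "cwm",
    fixed = c(2, 2, 4, 4),
    intra = c(1, 1, -2, -2)
  )
  meansn$specific <- meansn$fixed + meansn$intra
  dn <- ss_decompose(meansn, NULL, "t", "cwm")
  expect_lt(dn$ss$ss_cov[dn$ss$stratum == "between"], 0)
  dn <- contribution_percentages(dn)
  pct <- attr(dn, "percent")
  expect_lt(pct[["cov"]], 0)
  expect_equal(pct[["fixed"]] + pct[["intra"]] + pct[["cov"]],
               pct[["specific"]], tolerance = 1e-9)

  # additivity on random inputs, every stratum; percentages flagged when
  # the denominator SS is zero
  set.seed(7)
  for (rep in 1:30) {
    n <- 8
    m <- tibble::tibble(
      plot_id = paste0("p", 1:n),
      treatment = rep(c("x", "y"), each = n / 2),
      trait = "t", scheme = "cm",
      specific = stats::rnorm(n), fixed = stats::rnorm(n)
    )
    m$intra <- m$specific - m$fixed
    d <- ss_decompose(m, NULL, "t", "cm")
    expect_equal(d$ss$ss_cov,
                 d$ss$ss_specific - d$ss$ss_fixed - d$ss$ss_intra,
                 tolerance = 1e-15)
  }
  mflat <- tibble::tibble(
    plot_id = paste0("p", 1:4), treatment = c("u", "u", "v", "v"),
    trait = "t", scheme = "cwm", specific = 1, fixed = 1, intra = 0
  )
  dflat <- contribution_percentages(ss_decompose(mflat, NULL, "t", "cwm"))
  expect_true(isTRUE(attr(dflat, "degenerate")))
  expect_true(all(is.na(attr(dflat, "percent"))))
})

test_that("treatment_tests runs per trait and index and permuting plots changes nothing", {
  d <- generate_dataset(scenario_presets("paper-like", seed = 2))
  w <- within_community_indices(d$traits, d$composition, d$plots)
  tt <- treatment_tests(w, level_order = unique(d$plots$treatment))
  expect_equal(nrow(tt$anova), 4 * 2)   # 4 traits x 2 indices
  expect_equal(nrow(tt$letters), 4 * 2 * 5)
  expect_true(all(tt$anova$p_value >= 0 & tt$anova$p_value <= 1))
  w2 <- w[sample(nrow(w)), ]
  tt2 <- treatment_tests(w2, level_order = unique(d$plots$treatment))
  expect_equal(tt2$anova, tt$anova, tolerance = 1e-12)
  expect_equal(tt2$letters, tt$letters)
})
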