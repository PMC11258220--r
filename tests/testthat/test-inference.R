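# Exhaustive permutation oracle for tiny samples: enumerate all equal-size
# label assignments over the merged sample.
exhaustive_peak_p <- function(target_vals, neighbor_vals) {
  merged <- c(target_vals, neighbor_vals)
  n <- length(target_vals)
  obs <- mean(target_vals) - mean(neighbor_vals)
  combos <- utils::combn(2 * n, n)
  deltas <- apply(combos, 2, function(idx)
    mean(merged[idx]) - mean(merged[-idx]))
  mean(deltas >= obs - 1e-15)
}

# Spectrum matrix with a controlled bump at the target bin.
toy_spectrum <- function(n_subj, bump, seed = 1, nbins = 9, target = 5) {
  set.seed(seed)
  m <- matrix(rnorm(n_subj * nbins, mean = 1, sd = 0.2), n_subj, nbins)
  m[, target] <- m[, target] + bump
  m
}

test_that("the permutation peak test is calibrated on exchangeable data and detects bumps", {
  freqs <- 1:9
  m0 <- matrix(2, 4, 9)                     # all observations identical
  p0 <- permutation_peak_test(m0, freqs, 5, "bilateral3", 1000, seed = 1)
  expect_equal(p0$delta, 0)
  expect_gt(p0$p, 0.99)
  # a large bump is detected at the permutation floor
  m1 <- toy_spectrum(10, bump = 5)
  p1 <- permutation_peak_test(m1, freqs, 5, "bilateral3", 1000, seed = 2)
  expect_equal(p1$p, 1 / 1001, tolerance = 1e-12)
  expect_equal(p1$n_obs, 20L)
  # left3 uses only left neighbors: right-side bins are irrelevant
  m2 <- toy_spectrum(10, bump = 0)
  m2r <- m2; m2r[, 6:9] <- m2r[, 6:9] + 10
  p2a <- permutation_peak_test(m2, freqs, 5, "left3", 1000, seed = 3)
  p2b <- permutation_peak_test(m2r, freqs, 5, "left3", 1000, seed = 3)
  expect_identical(p2a$p, p2b$p)
  expect_identical(p2a$delta, p2b$delta)
  expect_error(permutation_peak_test(m1, freqs, 2, "bilateral3", 1000),
               "edge")
  expect_error(permutation_peak_test(m1, freqs, 5, n_perm = 99), ">= 1000")
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration on 3-subject toys", {
  tv <- c(3, 5, 4)
  nv <- c(2, 3, 1)
  p_ex <- exhaustive_peak_p(tv, nv)
  m <- cbind(nv, nv, nv, tv, nv, nv, nv)   # neighbors all equal per subject
  pt <- permutation_peak_test(m, 1:7, 4, "bilateral3", n_perm = 10000,
                              seed = 11)
  expect_equal(pt$delta, mean(tv) - mean(nv))
  expect_lt(abs(pt$p - p_ex), 0.02)
})

test_that("permutation p is invariant under shift and positive rescaling", {
  m <- toy_spectrum(8, bump = 0.4, seed = 6)
  base <- permutation_peak_test(m, 1:9, 5, "bilateral3", 2000, seed = 9)$p
  shift <- permutation_peak_test(m + 7, 1:9, 5, "bilateral3", 2000,
                                 seed = 9)$p
  scale <- permutation_peak_test(m * 3.5, 1:9, 5, "bilateral3", 2000,
                                 seed = 9)$p
  expect_equal(base, shift)
  expect_equal(base, scale)
})

test_that("detection power grows with the bump-to-noise ratio", {
  freqs <- 1:9
  rate <- vapply(c(0, 0.15, 0.6), function(b) {
    mean(vapply(1:30, function(s) {
      m <- toy_spectrum(10, bump = b, seed = 100 + s)
      permutation_peak_test(m, freqs, 5, "bilateral3", 1000,
                            seed = s)$p < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_lt(rate[1], 0.3)
  expect_gt(rate[3], 0.9)
})

test_that("paired comparisons match the closed-form paired t and BH behaves", {
  x <- c(0.30, 0.25, 0.41, 0.28)
  y <- c(0.22, 0.24, 0.30, 0.27)
  m <- cbind(A = x, B = y, C = y + 0.01)
  res <- pairwise_itpc_tests(m, pairs = list(c("A", "B")))
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t[1], t_oracle, tolerance = 1e-10)
  expect_equal(res$df[1], 3)
  expect_equal(res$delta[1], mean(d))
  expect_equal(res$p[1], 2 * pt(-abs(t_oracle), 3), tolerance = 1e-12)
  # identical columns: t = 0, p = 1
  res0 <- pairwise_itpc_tests(cbind(A = x, B = x), list(c("A", "B")))
  expect_equal(res0$t[1], 0)
  expect_equal(res0$p[1], 1)
  # BH fixed point under equal p, and never decreases p
  full <- pairwise_itpc_tests(m)
  expect_true(all(full$p_fdr >= full$p))
  expect_equal(order(full$p), order(full$p_fdr))
  expect_equal(p.adjust(rep(0.01, 5), "BH"), rep(0.01, 5))
  # missing cell errors with names
  mm <- m; mm[2, "B"] <- NA
  expect_error(pairwise_itpc_tests(mm), "B")
})

test_that("the 2x2 repeated-measures ANOVA matches the aov oracle", {
  set.seed(42)
  n <- 6
  cells <- expand.grid(subject = sprintf("s%d", 1:n),
                       seq = c(FALSE, TRUE), struct = c(FALSE, TRUE))
  cells$value <- rnorm(nrow(cells), sd = 0.3) + 0.4 * cells$seq +
    0.7 * cells$struct + 0.25 * (cells$seq & cells$struct) +
    rep(rnorm(n, sd = 0.5), 4)
  a <- rm_anova_2x2(cells)
  fit <- summary(stats::aov(value ~ seq * struct +
                              Error(subject / (seq * struct)),
                            data = cells))
  f_or <- c(fit[[2]][[1]][1, 4], fit[[3]][[1]][1, 4], fit[[4]][[1]][1, 4])
  p_or <- c(fit[[2]][[1]][1, 5], fit[[3]][[1]][1, 5], fit[[4]][[1]][1, 5])
  expect_equal(a$F, f_or, tolerance = 1e-8)
  expect_equal(a$p, p_or, tolerance = 1e-8)
  expect_equal(a$df_effect, rep(1L, 3))
  expect_equal(a$df_error, rep(n - 1L, 3))
})

test_that("ANOVA degenerate and invariance properties hold", {
  n <- 5
  base <- expand.grid(subject = sprintf("s%d", 1:n),
                      seq = c(FALSE, TRUE), struct = c(FALSE, TRUE))
  # all cells equal -> F = 0
  flat <- base; flat$value <- 3
  a0 <- rm_anova_2x2(flat)
  expect_equal(a0$F, rep(0, 3))
  # per-subject constants do not change F (within-subject centering)
  set.seed(8)
  cells <- base
  cells$value <- rnorm(nrow(cells)) + 0.5 * cells$seq
  shifted <- cells
  shifted$value <- shifted$value +
    rep(c(10, -4, 3, 0.5, 100), 4)[match(shifted$subject,
                                         sprintf("s%d", 1:n))]
  expect_equal(rm_anova_2x2(cells)$F, rm_anova_2x2(shifted)$F,
               tolerance = 1e-9)
  # 20 subjects -> error df 19 on every effect
  big <- expand.grid(subject = sprintf("s%d", 1:20),
                     seq = c(FALSE, TRUE), struct = c(FALSE, TRUE))
  big$value <- rnorm(80)
  expect_equal(unique(rm_anova_2x2(big)$df_error), 19L)
  # incomplete table rejected
  expect_error(rm_anova_2x2(cells[-1, ]), "incomplete")
})

test_that("EMM contrasts are paired differences with Tukey adjustment", {
  set.seed(3)
  n <- 7
  cells <- expand.grid(subject = sprintf("s%d", 1:n),
                       seq = c(FALSE, TRUE), struct = c(FALSE, TRUE))
  cells$value <- rnorm(nrow(cells)) + 0.6 * cells$seq
  em <- emm_posthoc(cells)
  expect_equal(nrow(em), 6L)
  expect_equal(em$t, em$beta / em$se, tolerance = 1e-12)
  expect_equal(unique(em$df), n - 1L)
  expect_true(all(em$p_adj >= 0 & em$p_adj <= 1))
  # a named contrast equals its hand computation
  wide <- tapply(cells$value,
                 list(cells$subject,
                      paste0(ifelse(cells$seq, "+", "-"), "seq:",
                             ifelse(cells$struct, "+", "-"), "struct")),
                 mean)
  d <- wide[, "+seq:+struct"] - wide[, "-seq:+struct"]
  row <- em[em$contrast == "+seq:+struct - -seq:+struct" |
              em$contrast == "-seq:+struct - +seq:+struct", ]
  expect_equal(abs(row$beta), abs(mean(d)), tolerance = 1e-12)
  expect_equal(abs(row$t), abs(mean(d) / (sd(d) / sqrt(n))),
               tolerance = 1e-12)
  expect_equal(row$p_adj,
               ptukey(sqrt(2) * abs(row$t), 4, n - 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical cells -> beta 0, p_adj 1
  flat <- cells; flat$value <- 2
  em0 <- emm_posthoc(flat)
  expect_true(all(em0$beta == 0))
  expect_true(all(em0$p_adj == 1))
  # a 2-cell family reduces Tukey to the unadjusted paired t
  fam <- list(c("+seq:+struct", "-seq:+struct"))
  em2 <- emm_posthoc(cells, family = fam)
  t2 <- em2$t[1]
  expect_equal(em2$p_adj[1], 2 * pt(-abs(t2), n - 1), tolerance = 1e-6)
  expect_error(emm_posthoc(cells, family = list()), "empty")
})

test_that("transitional probabilities are count ratios with proper errors", {
  counts <- matrix(0L, 3, 3, dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c")))
  counts["a", "b"] <- 3L
  counts["a", "c"] <- 1L
  counts["b", "a"] <- 2L
  tab <- structure(list(pair_counts = counts, words = c("a", "b", "c"),
                        n_tokens = 7L), class = "bigram_table")
  expect_equal(bigram_tp(tab, "a", "b"), 0.75)
  expect_equal(bigram_tp(tab, "b", "a"), 1.0)     # single continuation
  expect_equal(bigram_tp(tab, "a", "a"), 0.0)     # unseen pair, seen w1
  expect_error(bigram_tp(tab, "c", "a"), "never occurs")
  expect_error(bigram_tp(tab, "z", "a"), "unknown word")
  # conditional distributions sum to 1 on generated corpora
  b <- simulate_bigram_corpus(6, 2000, seed = 2)
  tot <- rowSums(b$pair_counts)
  tp_rows <- b$pair_counts[tot > 0, ] / tot[tot > 0]
  expect_equal(unname(rowSums(tp_rows)), rep(1, sum(tot > 0)))
})

test_that("the TP regression matches the normal-equations oracle", {
  tp_map <- c(A = 0.10, B = 0.30, C = 0.55)
  obs <- data.frame(subject = rep(sprintf("s%d", 1:5), 3),
                    condition = rep(c("A", "B", "C"), each = 5))
  set.seed(14)
  obs$itpc <- 0.2 + 0.4 * tp_map[obs$condition] + rnorm(15, sd = 0.05)
  fit <- tp_regression(obs, tp_map)
  # closed-form OLS
  x <- unname(tp_map[obs$condition]); y <- obs$itpc
  bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  res <- y - (mean(y) - bx * mean(x)) - bx * x
  se <- sqrt(sum(res^2) / (length(y) - 2) / sum((x - mean(x))^2))
  expect_equal(fit$slope, bx, tolerance = 1e-10)
  expect_equal(fit$se, se, tolerance = 1e-10)
  expect_equal(fit$df, length(y) - 2L)
  expect_equal(fit$t, bx / se, tolerance = 1e-10)
  # perfectly linear data: adjusted R^2 = 1
  obs2 <- obs; obs2$itpc <- 1 + 2 * tp_map[obs2$condition]
  fit2 <- suppressWarnings(tp_regression(obs2, tp_map))
  expect_equal(fit2$r2_adj, 1, tolerance = 1e-9)
  expect_lt(fit2$p, 1e-12)
  # df structure at 60 observations (20 subjects x 3 conditions)
  obs3 <- data.frame(subject = rep(sprintf("s%d", 1:20), 3),
                     condition = rep(c("A", "B", "C"), each = 20),
                     itpc = rnorm(60))
  expect_equal(tp_regression(obs3, tp_map)$df, 58L)
  # zero predictor variance rejected
  expect_error(tp_regression(obs, c(A = 0.2, B = 0.2, C = 0.2)),
               "zero variance")
  expect_error(tp_regression(obs[1:2, ], tp_map), "3 observations")
})
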