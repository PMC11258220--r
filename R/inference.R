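#' Permutation test for a spectral peak against neighboring bins
#'
#' Tests whether the value at a target frequency exceeds the average of
#' neighboring frequency bins. Each subject contributes two observations:
#' the target-bin value and the average over the neighbor bins. Under the
#' null the group labels ("target"/"neighbor") are exchangeable, so they
#' are reshuffled freely across the merged sample of `2n` observations;
#' the test statistic is the difference in group means,
#' \eqn{\Delta = \bar{x}_{target} - \bar{x}_{neighbor}}, and the one-sided
#' p-value is `(1 + #permutations with Delta* >= Delta_obs) / (1 + n_perm)`.
#'
#' Neighbor rules: `"left3"` uses the 3 bins immediately left of the
#' target (appropriate for power spectra, honoring the 1/f trend);
#' `"bilateral3"` uses 3 bins on each side (appropriate for ITPC).
#'
#' @param values_by_subject numeric matrix, subjects x frequency bins, of
#'   channel-reduced spectrum values.
#' @param freqs frequency grid (Hz) labeling the columns.
#' @param target_freq target frequency (must fall on a bin).
#' @param neighbor_rule `"bilateral3"` or `"left3"`.
#' @param n_perm number of permutations (>= 1000).
#' @param seed integer seed for the permutation draws.
#' @return An object of class `peak_test`: `target_freq`,
#'   `neighbor_rule`, `delta` (observed), `p`, `n_perm`, `n_obs`.
#' @export
permutation_peak_test <- function(values_by_subject, freqs, target_freq,
                                  neighbor_rule = c("bilateral3", "left3"),
                                  n_perm = 10000L, seed = NULL) {
  neighbor_rule <- match.arg(neighbor_rule)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1000L) stop("n_perm must be >= 1000", call. = FALSE)
  m <- as.matrix(values_by_subject)
  if (ncol(m) != length(freqs))
    stop("freqs length must match the number of columns", call. = FALSE)
  j <- bin_index(freqs, target_freq)
  nb <- switch(neighbor_rule,
               left3 = (j - 3L):(j - 1L),
               bilateral3 = c((j - 3L):(j - 1L), (j + 1L):(j + 3L)))
  if (any(nb < 1L) || any(nb > ncol(m)))
    stop("target bin too close to the spectrum edge for rule '",
         neighbor_rule, "'", call. = FALSE)
  tv <- m[, j]
  nv <- rowMeans(m[, nb, drop = FALSE])
  n <- length(tv)
  merged <- c(tv, nv)
  delta_obs <- mean(tv) - mean(nv)
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(2L * n)
      d <- mean(merged[idx[seq_len(n)]]) - mean(merged[idx[(n + 1L):(2L * n)]])
      if (d >= delta_obs - 1e-15) exceed <- exceed + 1L
    }
    structure(list(target_freq = target_freq, neighbor_rule = neighbor_rule,
                   delta = delta_obs, p = (1 + exceed) / (1 + n_perm),
                   n_perm = n_perm, n_obs = 2L * n),
              class = "peak_test")
  })
}

#' @export
print.peak_test <- function(x, ...) {
  cat(sprintf(
    "Permutation peak test at %g Hz (%s neighbors): Delta = %.4g, p = %.4g (%d permutations, %d observations)\n",
    x$target_freq, x$neighbor_rule, x$delta, x$p, x$n_perm, x$n_obs))
  invisible(x)
}

#' Pairwise condition comparisons of ITPC with FDR correction
#'
#' Paired-samples t-tests on per-subject ITPC at the target frequency for
#' each requested condition pair, followed by Benjamini-Hochberg
#' false-discovery-rate adjustment over the tested family.
#'
#' @param itpc_by_condition numeric matrix, subjects x conditions (column
#'   names = condition labels), of ITPC at the target frequency.
#' @param pairs list of length-2 character vectors; default all pairs.
#' @return A data frame of class `pairwise_tests` with columns `a`, `b`,
#'   `delta` (mean a - b), `t`, `df`, `p`, `p_fdr`.
#' @export
pairwise_itpc_tests <- function(itpc_by_condition, pairs = NULL) {
  m <- as.matrix(itpc_by_condition)
  conds <- colnames(m)
  if (is.null(conds)) stop("condition columns must be named", call. = FALSE)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing ITPC for subject ", rownames(m)[idx[1]] %||% idx[1],
         ", condition ", conds[idx[2]], call. = FALSE)
  }
  if (is.null(pairs)) {
    cb <- utils::combn(conds, 2L)
    pairs <- lapply(seq_len(ncol(cb)), function(i) cb[, i])
  }
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% conds))
      stop("unknown condition in pair: ", paste(pr, collapse = " vs "),
           call. = FALSE)
    x <- m[, pr[1]]; y <- m[, pr[2]]
    d <- x - y
    if (sd(d) == 0) {
      # degenerate pairing: constant difference
      tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      tt <- list(statistic = tval, parameter = length(d) - 1L,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- t.test(x, y, paired = TRUE)
    }
    data.frame(a = pr[1], b = pr[2], delta = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  class(out) <- c("pairwise_tests", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cells: data.frame with columns subject, seq (logical), struct (logical),
# value; validated complete 2x2 within-subject table.
check_cells <- function(cells) {
  need <- c("subject", "seq", "struct", "value")
  if (!all(need %in% names(cells)))
    stop("cells must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  cells$seq <- as.logical(cells$seq)
  cells$struct <- as.logical(cells$struct)
  tab <- table(cells$subject, interaction(cells$seq, cells$struct))
  if (ncol(tab) != 4L || any(tab != 1L))
    stop("incomplete 2x2 within-subject table: every subject needs ",
         "exactly one value per cell", call. = FALSE)
  if (length(unique(cells$subject)) < 2L)
    stop("need at least 2 subjects", call. = FALSE)
  cells
}

#' Two-way repeated-measures ANOVA on a 2x2 within-subject design
#'
#' Classical within-subject decomposition: each effect (sequential
#' regularity, structural regularity, their interaction) is tested
#' against its own effect-by-subject interaction,
#' `F = MS_effect / MS_(effect x subject)`, with effect df 1 and error df
#' `n_subjects - 1`.
#'
#' @param cells data frame with columns `subject`, `seq` (logical),
#'   `struct` (logical), `value`; one value per subject per cell.
#' @return An object of class `rm_anova`: data frame with rows `seq`,
#'   `struct`, `seq:struct` and columns `F`, `df_effect`, `df_error`,
#'   `p`; attribute `cell_means` (2x2).
#' @export
rm_anova_2x2 <- function(cells) {
  cells <- check_cells(cells)
  n <- length(unique(cells$subject))
  gm <- mean(cells$value)
  ms <- tapply(cells$value, cells$subject, mean)
  ma <- tapply(cells$value, cells$seq, mean)
  mb <- tapply(cells$value, cells$struct, mean)
  mab <- tapply(cells$value, list(cells$seq, cells$struct), mean)
  msa <- tapply(cells$value, list(cells$subject, cells$seq), mean)
  msb <- tapply(cells$value, list(cells$subject, cells$struct), mean)
  a_eff <- ma - gm
  b_eff <- mb - gm
  ab_eff <- sweep(sweep(mab, 1, ma, "-"), 2, mb, "-") + gm
  ss_a <- 2 * n * sum(a_eff^2)
  ss_b <- 2 * n * sum(b_eff^2)
  ss_ab <- n * sum(ab_eff^2)
  ss_as <- 2 * sum(sweep(sweep(msa, 2, ma, "-"), 1, ms - gm, "-")^2)
  ss_bs <- 2 * sum(sweep(sweep(msb, 2, mb, "-"), 1, ms - gm, "-")^2)
  # residual: y - cell - subject-within-factor effects + lower terms
  y <- cells$value
  si <- as.character(cells$subject)
  ai <- as.character(cells$seq)
  bi <- as.character(cells$struct)
  fit <- mab[cbind(ai, bi)] + ms[si] - gm +
    (msa[cbind(si, ai)] - ms[si] - ma[ai] + gm) +
    (msb[cbind(si, bi)] - ms[si] - mb[bi] + gm)
  ss_abs <- sum((y - fit)^2)
  dfe <- n - 1L
  fr <- function(ss_eff, ss_err) {
    if (ss_eff == 0) return(0)           # no effect variance at all
    (ss_eff / 1) / (ss_err / dfe)
  }
  Fv <- c(seq = fr(ss_a, ss_as),
          struct = fr(ss_b, ss_bs),
          `seq:struct` = fr(ss_ab, ss_abs))
  out <- data.frame(effect = names(Fv), F = unname(Fv),
                    df_effect = 1L, df_error = dfe,
                    p = stats::pf(unname(Fv), 1, dfe, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "cell_means") <- mab
  attr(out, "n_subjects") <- n
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA (2 x 2 within-subject)\n")
  df <- as.data.frame(x)
  df$F <- signif(df$F, 5); df$p <- signif(df$p, 4)
  print(df, row.names = FALSE)
  cat("\nCell means (rows: seq FALSE/TRUE; cols: struct FALSE/TRUE):\n")
  print(signif(attr(x, "cell_means"), 5))
  invisible(x)
}

#' Post-hoc contrasts on estimated marginal means, Tukey-adjusted
#'
#' For a balanced 2x2 within-subject design the estimated marginal means
#' coincide with the cell means. Each contrast is a paired difference:
#' `beta` is the difference of cell means, `SE` the paired differences'
#' sample SD over `sqrt(n)`, `t = beta/SE` with `df = n - 1`, and the
#' p-value is adjusted via the studentized-range distribution over the
#' cell means spanned by the family (Tukey's method; with a 2-cell family
#' this reduces to the unadjusted paired t-test).
#'
#' @param cells as in [rm_anova_2x2()].
#' @param family list of contrasts, each a length-2 character vector of
#'   cell labels in the form `"+seq:+struct"` / `"-seq:-struct"`; default
#'   all 6 pairs.
#' @return A data frame of class `emm_contrasts` with columns `contrast`,
#'   `beta`, `se`, `t`, `df`, `p_adj`.
#' @export
emm_posthoc <- function(cells, family = NULL) {
  cells <- check_cells(cells)
  n <- length(unique(cells$subject))
  lab <- function(s, b) paste0(ifelse(s, "+", "-"), "seq:",
                               ifelse(b, "+", "-"), "struct")
  cells$cell <- lab(cells$seq, cells$struct)
  levs <- sort(unique(cells$cell))
  if (is.null(family)) {
    cb <- utils::combn(levs, 2L)
    family <- lapply(seq_len(ncol(cb)), function(i) cb[, i])
  }
  if (length(family) == 0L) stop("empty contrast family", call. = FALSE)
  nmeans <- length(unique(unlist(family)))
  wide <- tapply(cells$value, list(cells$subject, cells$cell), mean)
  rows <- lapply(family, function(pr) {
    if (!all(pr %in% levs))
      stop("unknown cell label in contrast: ", paste(pr, collapse = " - "),
           call. = FALSE)
    d <- wide[, pr[1]] - wide[, pr[2]]
    beta <- mean(d)
    se <- sd(d) / sqrt(n)
    tval <- if (se == 0) { if (beta == 0) 0 else sign(beta) * Inf }
      else beta / se
    p_adj <- if (nmeans < 2L || tval == 0) 1 else
      ptukey(sqrt(2) * abs(tval), nmeans = nmeans, df = n - 1L,
             lower.tail = FALSE)
    data.frame(contrast = paste(pr, collapse = " - "), beta = beta,
               se = se, t = tval, df = n - 1L, p_adj = p_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("emm_contrasts", "data.frame")
  out
}

#' Bigram transitional probability
#'
#' The conditional probability of the second word given the first,
#' \eqn{P(w_2 | w_1) = P(w_1 w_2) / P(w_1 \#)}: the count of the pair
#' divided by the count of all pairs starting with `w1`.
#'
#' @param table a `bigram_table` (see [simulate_bigram_corpus()]).
#' @param w1,w2 word labels.
#' @return The transitional probability in \[0, 1\]. Errors if `w1` never
#'   occurs as a first word (undefined conditional); an unseen pair with
#'   a seen `w1` yields 0.
#' @export
bigram_tp <- function(table, w1, w2) {
  stopifnot(inherits(table, "bigram_table"))
  if (!w1 %in% table$words) stop("unknown word '", w1, "'", call. = FALSE)
  if (!w2 %in% table$words) stop("unknown word '", w2, "'", call. = FALSE)
  tot <- sum(table$pair_counts[w1, ])
  if (tot == 0)
    stop("word '", w1, "' never occurs as a first word; P(w2|w1) undefined",
         call. = FALSE)
  table$pair_counts[w1, w2] / tot
}

#' Transitional-probability control regression
#'
#' Ordinary least-squares regression of per-observation ITPC on the
#' condition-mean transitional probability, the control analysis asking
#' whether differences in phrase-rate tracking across grammatical
#' conditions are explained by bigram statistics. The observation unit is
#' subject x condition (60 observations for 20 subjects x 3 grammatical
#' conditions, giving slope df 58).
#'
#' @param itpc_obs data frame with columns `subject`, `condition`, `itpc`
#'   (per-subject ITPC at the phrase rate).
#' @param mean_tp_by_condition named numeric vector of condition-mean
#'   transitional probabilities.
#' @return An object of class `tp_regression`: `slope`, `intercept`,
#'   `se` (of the slope), `t`, `df` (`n - 2`), `p`, `r2_adj`, and the
#'   underlying `lm` fit in `$fit`.
#' @export
tp_regression <- function(itpc_obs, mean_tp_by_condition) {
  need <- c("subject", "condition", "itpc")
  if (!all(need %in% names(itpc_obs)))
    stop("itpc_obs must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(unique(itpc_obs$condition), names(mean_tp_by_condition))
  if (length(miss))
    stop("no mean TP for condition(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(itpc_obs) < 3L) stop("need at least 3 observations",
                                call. = FALSE)
  tp <- unname(mean_tp_by_condition[itpc_obs$condition])
  if (sd(tp) == 0)
    stop("zero variance in the TP predictor", call. = FALSE)
  fit <- lm(itpc_obs$itpc ~ tp)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 se = sm$coefficients[2, 2],
                 t = sm$coefficients[2, 3],
                 df = fit$df.residual,
                 p = sm$coefficients[2, 4],
                 r2_adj = sm$adj.r.squared,
                 fit = fit),
            class = "tp_regression")
}

#' @export
print.tp_regression <- function(x, ...) {
  cat(sprintf(
    "TP control regression: beta = %.4g (SE %.4g), t(%d) = %.4g, p = %.4g, adj. R^2 = %.4g\n",
    x$slope, x$se, x$df, x$t, x$p, x$r2_adj))
  invisible(x)
}
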