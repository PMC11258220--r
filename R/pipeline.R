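#' Build a pipeline configuration
#'
#' Assembles (and fills defaults for) the configuration of a full
#' analysis run: generator parameters, channel region of interest, ITPC
#' convention, peak-test settings, the ANOVA cell mapping, the
#' transitional-probability control settings, seeds and an optional
#' output directory. Configurations can also be loaded from YAML with
#' [load_config()].
#'
#' @param sim an [eeg_sim_params()] object or a list of overrides for it.
#' @param roi `"all"` or a character vector of channel labels.
#' @param itpc_convention `"normalized"` or `"printed_formula"`.
#' @param peak list: `n_perm`, `alpha`, `rule_power`, `rule_itpc`.
#' @param anova_map named character vector mapping four condition names
#'   onto the 2x2 cells `"+seq:+struct"`, `"-seq:+struct"`,
#'   `"+seq:-struct"`, `"-seq:-struct"` (a bijection).
#' @param tp list: `vocab_size`, `n_tokens`, `n_pairs`, `zipf_s`,
#'   `markov_conc` for the synthetic bigram corpus.
#' @param seed master seed of the run.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), roi = "all",
                            itpc_convention = "normalized",
                            peak = list(), anova_map = NULL,
                            tp = list(), seed = 1L, out_dir = NULL) {
  if (!inherits(sim, "eeg_sim_params"))
    sim <- do.call(eeg_sim_params, sim)
  peak <- modifyList(list(n_perm = 1000L, alpha = 0.05,
                          rule_power = "left3", rule_itpc = "bilateral3"),
                     peak)
  tp <- modifyList(list(vocab_size = 200L, n_tokens = 50000L,
                        n_pairs = 288L, zipf_s = 1, markov_conc = 50),
                   tp)
  if (is.null(anova_map))
    anova_map <- c("V-Adv" = "+seq:+struct", "V-Adv-alt" = "-seq:+struct",
                   "N-R" = "+seq:-struct", "R-R" = "-seq:-struct")
  cfg <- structure(list(sim = sim, roi = roi,
                        itpc_convention = itpc_convention, peak = peak,
                        anova_map = anova_map, tp = tp,
                        seed = as.integer(seed), out_dir = out_dir),
                   class = "pipeline_config")
  validate_config(cfg)
}

#' List configuration violations without stopping
#'
#' @param config a `pipeline_config` (or plain list with its fields).
#' @return Character vector of violations, each naming the offending
#'   field; empty when the configuration is valid.
#' @export
config_errors <- function(config) {
  errs <- character(0)
  p <- config$peak
  if (!is.numeric(p$alpha) || p$alpha <= 0 || p$alpha >= 1)
    errs <- c(errs, "peak$alpha: must be in (0, 1)")
  if (!is.numeric(p$n_perm) || p$n_perm < 1000)
    errs <- c(errs, "peak$n_perm: must be >= 1000")
  if (!p$rule_power %in% c("left3", "bilateral3"))
    errs <- c(errs, "peak$rule_power: must be 'left3' or 'bilateral3'")
  if (!p$rule_itpc %in% c("left3", "bilateral3"))
    errs <- c(errs, "peak$rule_itpc: must be 'left3' or 'bilateral3'")
  if (!config$itpc_convention %in% c("normalized", "printed_formula"))
    errs <- c(errs, "itpc_convention: unknown convention")
  cells <- c("+seq:+struct", "-seq:+struct", "+seq:-struct", "-seq:-struct")
  am <- config$anova_map
  if (length(am) != 4L || !setequal(unname(am), cells) ||
      anyDuplicated(unname(am)) || is.null(names(am)) ||
      !all(names(am) %in% condition_designs()$name))
    errs <- c(errs,
              "anova_map: must map four known conditions bijectively onto the 2x2 cells")
  simv <- tryCatch({ validate_sim_params(config$sim); character(0) },
                   error = function(e) paste0("sim: ", conditionMessage(e)))
  errs <- c(errs, simv)
  if (!is.numeric(config$seed)) errs <- c(errs, "seed: must be an integer")
  errs
}

#' Validate a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @return The config, invisibly, when valid; otherwise an error listing
#'   every violation with a path into the configuration.
#' @export
validate_config <- function(config) {
  errs <- config_errors(config)
  if (length(errs))
    stop("invalid pipeline configuration:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  invisible(config)
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified fields are filled with the package defaults (including
#' seeds), and the merged configuration is validated.
#'
#' @param path YAML file; top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("sim", "roi", "itpc_convention", "peak", "tp", "seed",
              "out_dir"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$anova_map)) args$anova_map <- unlist(y$anova_map)
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  cfg <- config
  cfg$sim <- unclass(cfg$sim)
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Run the full frequency-tagging analysis pipeline
#'
#' Executes, for a synthetic cohort defined by `config$sim`: per-subject
#' epoch generation (streamed one subject-condition at a time to bound
#' memory), spectral estimation (evoked power and ITPC, channel-reduced
#' over the configured ROI), permutation peak tests at the 1-Hz phrase
#' rate and 2-Hz word rate for every condition and both statistics,
#' pairwise paired-t comparisons (with FDR correction) among the
#' conditions whose 1-Hz ITPC peak is significant, the 2x2
#' repeated-measures ANOVA with Tukey-adjusted EMM contrasts on the
#' configured cell mapping, and the transitional-probability control
#' regression over the grammatical conditions. All randomness derives
#' from `config$seed`; rerunning with the same configuration reproduces
#' the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  params <- config$sim
  conds <- condition_designs()
  ns <- params$n_subjects
  if (ns < 2L) stop("pipeline needs n_subjects >= 2", call. = FALSE)
  with_seed(config$seed, {
    mult <- exp(rnorm(ns, 0, params$between_subject_sd))
    seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                               ns * nrow(conds)), ns, nrow(conds))
    perm_seeds <- sample.int(.Machine$integer.max - 1L, 100L)
    tp_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  })
  ids <- sprintf("S%02d", seq_len(ns))
  itpc_mats <- power_mats <- setNames(vector("list", nrow(conds)),
                                      conds$name)
  freqs <- NULL
  for (ci in seq_len(nrow(conds))) {
    im <- pm <- NULL
    for (s in seq_len(ns)) {
      ep <- simulate_epochs(params, conds[ci, ], seeds[s, ci],
                            amp_scale = mult[s])
      fset <- fourier_transform(ep)
      isp <- channel_reduce(itpc(fset, config$itpc_convention), config$roi)
      psp <- channel_reduce(evoked_power(ep), config$roi)
      if (is.null(freqs)) freqs <- isp$freqs
      im <- rbind(im, isp$values[1, ])
      pm <- rbind(pm, psp$values[1, ])
    }
    rownames(im) <- rownames(pm) <- ids
    itpc_mats[[ci]] <- im
    power_mats[[ci]] <- pm
  }
  # peak tests: condition x statistic x frequency
  pk <- list(); r <- 1L
  peak_rows <- list()
  for (ci in seq_len(nrow(conds))) {
    for (stat in c("itpc", "power")) {
      mat <- if (stat == "itpc") itpc_mats[[ci]] else power_mats[[ci]]
      rule <- if (stat == "itpc") config$peak$rule_itpc else
        config$peak$rule_power
      for (f in c(1, 2)) {
        pt <- permutation_peak_test(mat, freqs, f, neighbor_rule = rule,
                                    n_perm = config$peak$n_perm,
                                    seed = perm_seeds[r])
        peak_rows[[r]] <- data.frame(
          condition = conds$name[ci], statistic = stat, freq = f,
          delta = pt$delta, p = pt$p, rule = rule,
          significant = pt$p < config$peak$alpha,
          stringsAsFactors = FALSE)
        r <- r + 1L
      }
    }
  }
  peaks <- do.call(rbind, peak_rows)
  # gate: pairwise family = conditions with significant 1-Hz ITPC peak
  gate <- peaks$condition[peaks$statistic == "itpc" & peaks$freq == 1 &
                            peaks$significant]
  i1 <- bin_index(freqs, 1)
  itpc1 <- vapply(itpc_mats, function(m) m[, i1], numeric(ns))
  pairwise <- NULL
  if (length(gate) >= 2L)
    pairwise <- pairwise_itpc_tests(itpc1[, gate, drop = FALSE])
  # 2x2 RM-ANOVA + EMM contrasts on the configured cell mapping
  am <- config$anova_map
  cells <- do.call(rbind, lapply(names(am), function(cn) {
    cell <- am[[cn]]
    data.frame(subject = ids,
               seq = grepl("\\+seq", cell),
               struct = grepl("\\+struct", cell),
               value = itpc1[, cn], stringsAsFactors = FALSE)
  }))
  anova_tab <- rm_anova_2x2(cells)
  emm <- emm_posthoc(cells)
  # TP control regression over the grammatical conditions
  gram <- conds$name[conds$structural]
  corpus <- simulate_bigram_corpus(config$tp$vocab_size,
                                   config$tp$n_tokens, seed = tp_seed,
                                   zipf_s = config$tp$zipf_s,
                                   markov_conc = config$tp$markov_conc)
  mean_tp <- condition_mean_tp(corpus, gram, n_pairs = config$tp$n_pairs,
                               seed = tp_seed)
  itpc_obs <- do.call(rbind, lapply(gram, function(cn)
    data.frame(subject = ids, condition = cn, itpc = itpc1[, cn],
               stringsAsFactors = FALSE)))
  tp_fit <- tp_regression(itpc_obs, mean_tp)
  report <- structure(list(
    peaks = peaks, gate = gate, pairwise = pairwise, anova = anova_tab,
    emm = emm, tp = tp_fit, mean_tp = mean_tp, itpc_at_1hz = itpc1,
    freqs = freqs, itpc_by_condition = itpc_mats,
    power_by_condition = power_mats,
    provenance = list(seed = config$seed, config_md5 = config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("phrasetrack")))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Draw condition-specific phrase inventories and their mean TP
#'
#' Samples `n_pairs` bigram tokens (weighted by corpus counts, without
#' replacement across conditions) as each condition's phrase inventory
#' and returns the mean transitional probability per condition.
#'
#' @param corpus a `bigram_table`.
#' @param conditions condition names to draw inventories for.
#' @param n_pairs phrases per condition.
#' @param seed integer seed.
#' @return Named numeric vector of condition-mean TPs.
#' @export
condition_mean_tp <- function(corpus, conditions, n_pairs = 288L,
                              seed = 1L) {
  counts <- corpus$pair_counts
  seen <- which(counts > 0, arr.ind = TRUE)
  if (nrow(seen) < n_pairs * length(conditions))
    stop("corpus too small: fewer observed bigram types than needed",
         call. = FALSE)
  w <- counts[seen]
  with_seed(seed, {
    picked <- sample.int(nrow(seen), n_pairs * length(conditions),
                         prob = w)
    out <- numeric(length(conditions))
    names(out) <- conditions
    for (i in seq_along(conditions)) {
      idx <- picked[(i - 1L) * n_pairs + seq_len(n_pairs)]
      tps <- vapply(idx, function(j) {
        counts[seen[j, 1], seen[j, 2]] / sum(counts[seen[j, 1], ])
      }, numeric(1))
      out[i] <- mean(tps)
    }
    out
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("Frequency-tagging pipeline report\n")
  cat("=================================\n\n")
  cat("Peak tests (permutation, alpha-gated pairwise family):\n")
  df <- x$peaks
  df$delta <- signif(df$delta, 4); df$p <- signif(df$p, 4)
  print(df, row.names = FALSE)
  cat("\nConditions with a significant 1-Hz ITPC peak: ",
      if (length(x$gate)) paste(x$gate, collapse = ", ") else "(none)",
      "\n", sep = "")
  if (!is.null(x$pairwise)) {
    cat("\nPairwise ITPC comparisons at 1 Hz (paired t, BH-FDR):\n")
    pw <- as.data.frame(x$pairwise)
    pw$delta <- signif(pw$delta, 4); pw$t <- signif(pw$t, 4)
    pw$p <- signif(pw$p, 4); pw$p_fdr <- signif(pw$p_fdr, 4)
    print(pw, row.names = FALSE)
  }
  cat("\n"); print(x$anova)
  cat("\nEMM contrasts (Tukey-adjusted):\n")
  em <- as.data.frame(x$emm)
  for (cc in c("beta", "se", "t", "p_adj")) em[[cc]] <- signif(em[[cc]], 4)
  print(em, row.names = FALSE)
  cat("\n"); print(x$tp)
  cat("\nProvenance: seed ", x$provenance$seed, ", config md5 ",
      x$provenance$config_md5, ", phrasetrack ",
      x$provenance$package_version, "\n", sep = "")
  invisible(x)
}

#' Write a run report to CSV tables and a JSON summary
#'
#' Each table carries a provenance header (config hash, seed) as comment
#' lines, so identical configurations produce byte-identical outputs.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("# phrasetrack %s | seed %s | config %s",
                  report$provenance$package_version,
                  report$provenance$seed, report$provenance$config_md5)
  put <- function(df, fn) {
    path <- file.path(dir, fn)
    con <- file(path, "w")
    writeLines(prov, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  put(report$peaks, "peak_tests.csv")
  if (!is.null(report$pairwise))
    put(as.data.frame(report$pairwise), "pairwise.csv")
  put(as.data.frame(report$anova), "anova.csv")
  put(as.data.frame(report$emm), "emm.csv")
  tp <- report$tp
  put(data.frame(slope = tp$slope, intercept = tp$intercept, se = tp$se,
                 t = tp$t, df = tp$df, p = tp$p, r2_adj = tp$r2_adj),
      "tp_regression.csv")
  jsonlite::write_json(
    list(provenance = report$provenance, gate = report$gate,
         mean_tp = as.list(report$mean_tp),
         anova = as.data.frame(report$anova),
         peaks = report$peaks),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
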