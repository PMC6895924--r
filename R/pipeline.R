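# End-to-end scenario study: simulate -> FST scan on the training
# generation's phenotypic tails -> top-k prioritization -> weighting
# scenarios -> weighted VanRaden G over sampled training + validation
# animals -> AI-REML GBLUP -> accuracy / bias / relationship summaries,
# replicated under deterministic per-replicate seeds.

#' Deterministic seed for one replicate
#'
#' @param base_seed Integer base seed of the experiment.
#' @param replicate Replicate number (1-based).
#' @return Integer seed; replicate r depends only on `(base_seed, r)`.
#' @export
replicate_seed <- function(base_seed, replicate) {
  as.integer((base_seed %% 2000000L) * 1000L + replicate)
}

#' Plan a weighting-scenario study
#'
#' Bundles the simulation configuration, scenario list and sampling design of
#' a replicated study. The defaults form the package's reduced standard
#' plan: the default [sim_config()] genome (20,000 SNPs, 100 QTL, seven
#' selected generations of 3,000), training on 2,000 animals sampled from
#' the next-to-last generation, validation on 1,000 of the last generation,
#' and prioritization of the top 1,000 SNPs (5% of the panel) by FST score
#' computed from the 5%/95% phenotypic tails of the full training
#' generation.
#'
#' @param config A [sim_config()].
#' @param scenarios Character vector of scenario names or list of
#'   [weighting_scenario()] objects (default [default_scenarios()]).
#' @param n_replicates Number of replicate simulations.
#' @param base_seed Base seed; replicate seeds come from [replicate_seed()].
#' @param n_train,n_val Animals sampled for training (next-to-last
#'   generation) and validation (last generation).
#' @param top_k Number of prioritized SNPs.
#' @param q_low,q_high Phenotypic tail quantiles for the FST scan.
#' @param blend Identity blend used when fitting (see [gblup()]).
#' @return An object of class `"experiment_plan"`.
#' @export
experiment_plan <- function(config = sim_config(),
                            scenarios = default_scenarios(),
                            n_replicates = 5L,
                            base_seed = 1L,
                            n_train = 2000L,
                            n_val = 1000L,
                            top_k = 1000L,
                            q_low = 0.05,
                            q_high = 0.95,
                            blend = 0.01) {
  validate_sim_config(config)
  if (is.character(scenarios))
    scenarios <- stats::setNames(lapply(scenarios, weighting_scenario),
                                 scenarios)
  if (length(scenarios) == 0L) stop("empty scenario list", call. = FALSE)
  stopifnot(all(vapply(scenarios, inherits, logical(1), "weighting_scenario")))
  if (config$n_offspring_generations < 1L)
    stop("the plan needs at least one selected generation", call. = FALSE)
  if (n_train > config$offspring_per_generation ||
      n_val > config$offspring_per_generation)
    stop("training/validation samples exceed the generation size", call. = FALSE)
  if (top_k > config$n_snp) stop("'top_k' exceeds the SNP panel", call. = FALSE)
  structure(list(
    config = config, scenarios = scenarios,
    n_replicates = as.integer(n_replicates), base_seed = as.integer(base_seed),
    n_train = as.integer(n_train), n_val = as.integer(n_val),
    top_k = as.integer(top_k), q_low = q_low, q_high = q_high, blend = blend,
    train_generation = config$n_offspring_generations - 1L,
    val_generation = config$n_offspring_generations
  ), class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat("Weighting-scenario study plan\n")
  cat(sprintf("  scenarios: %s\n", paste(names(x$scenarios), collapse = ", ")))
  cat(sprintf("  %d replicates, base seed %d\n", x$n_replicates, x$base_seed))
  cat(sprintf("  train %d of G%d, validate %d of G%d; top-k %d; tails (%.2f, %.2f)\n",
              x$n_train, x$train_generation, x$n_val, x$val_generation,
              x$top_k, x$q_low, x$q_high))
  invisible(x)
}

# One replicate: returns list(results = data.frame, hist = data.frame).
.run_replicate <- function(plan, r, verbose = FALSE) {
  cfg <- plan$config
  cfg$seed <- replicate_seed(plan$base_seed, r)
  tg <- plan$train_generation
  vg <- plan$val_generation
  sim <- simulate_population(cfg, keep_genotypes = c(tg, vg))
  rec <- sim$records
  rec_t <- rec[rec$generation == tg, ]
  rec_v <- rec[rec$generation == vg, ]

  # FST from the full training generation, before analysis sampling; QTL are
  # not genotyped, so their rows are discarded from the score table
  split <- partition_tails(stats::setNames(rec_t$phenotype, rec_t$id),
                           q_low = plan$q_low, q_high = plan$q_high)
  g_t <- sim$geno[[paste0("G", tg)]]
  scores <- fst_scores(g_t, split)
  scores <- scores[!g_t$map$is_qtl, , drop = FALSE]
  top <- fst_top_k(scores, plan$top_k)

  train_ids <- sort(sample(rec_t$id, plan$n_train))
  val_ids <- sort(sample(rec_v$id, plan$n_val))
  snp_cols <- which(!g_t$map$is_qtl)
  M <- rbind(g_t$dosages[train_ids, snp_cols, drop = FALSE],
             sim$geno[[paste0("G", vg)]]$dosages[val_ids, snp_cols,
                                                 drop = FALSE])
  y_train <- stats::setNames(rec_t$phenotype[match(train_ids, rec_t$id)],
                             train_ids)
  tbv_val <- stats::setNames(rec_v$tbv[match(val_ids, rec_v$id)], val_ids)
  rm(sim, g_t); gc(FALSE)

  p_all <- colMeans(M) / 2
  poly <- p_all > 0 & p_all < 1
  panel <- colnames(M)[poly]
  p <- p_all[poly]
  fst_panel <- stats::setNames(scores$fst, scores$locus)[panel]
  in_top <- panel %in% top
  if (!any(in_top)) stop("no prioritized locus is polymorphic in the ",
                         "analysis sample", call. = FALSE)
  nP <- length(panel)
  k <- sum(in_top)
  idn <- list(rownames(M), rownames(M))
  Z <- M[, poly, drop = FALSE] - matrix(2 * p, nrow(M), nP, byrow = TRUE)
  rm(M); gc(FALSE)
  need_rest <- any(vapply(plan$scenarios, function(s) s$panel == "full",
                          logical(1)))
  K_top <- .weighted_gram(Z[, in_top, drop = FALSE])
  sumpq_top <- sum(p[in_top] * (1 - p[in_top]))
  if (need_rest) {
    K_rest <- .weighted_gram(Z[, !in_top, drop = FALSE])
    sumpq_rest <- sum(p[!in_top] * (1 - p[!in_top]))
  }

  scenario_G <- function(sc) {
    if (sc$panel == "top") {
      w <- scenario_weights(fst_panel[in_top], panel[in_top], sc)
      G <- .weighted_gram(Z[, in_top, drop = FALSE], w) /
        (2 * sum(w * p[in_top] * (1 - p[in_top])))
    } else if (sc$name == "equal") {
      G <- (K_top + K_rest) / (2 * (sumpq_top + sumpq_rest))
    } else if (sc$within == "equal") {
      w_t <- sc$top_share / 100 * nP / k
      w_r <- sc$rest_share / 100 * nP / (nP - k)
      G <- (w_t * K_top + w_r * K_rest) /
        (2 * (w_t * sumpq_top + w_r * sumpq_rest))
    } else {
      w <- scenario_weights(fst_panel, top, sc)
      G <- .weighted_gram(Z, w) / (2 * sum(w * p * (1 - p)))
    }
    dimnames(G) <- idn
    G
  }

  res <- list(); hist <- list()
  for (sn in names(plan$scenarios)) {
    sc <- plan$scenarios[[sn]]
    row <- tryCatch({
      G <- scenario_G(sc)
      fit <- gblup(y_train, G, ids = train_ids, blend = plan$blend)
      acc <- evaluate_accuracy(tbv_val, predict(fit, val_ids))
      h <- offdiag_histogram(G, train_ids, val_ids)
      hist[[sn]] <- data.frame(scenario = sn, replicate = r, bin = h$bin,
                               percent = h$percent, stringsAsFactors = FALSE)
      data.frame(
        scenario = sn, replicate = r, seed = cfg$seed,
        n_panel = if (sc$panel == "top") k else nP,
        sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2, h2 = fit$h2,
        minus2logL = fit$minus2logL, converged = fit$converged,
        accuracy = acc$accuracy, intercept = acc$intercept,
        slope = acc$slope, od_gt_003 = attr(h, "mass_above"),
        stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("scenario '%s' failed in replicate %d: %s", sn, r,
                      conditionMessage(e)), call. = FALSE)
      data.frame(scenario = sn, replicate = r, seed = cfg$seed,
                 n_panel = NA_integer_, sigma_u2 = NA_real_,
                 sigma_e2 = NA_real_, h2 = NA_real_, minus2logL = NA_real_,
                 converged = FALSE, accuracy = NA_real_,
                 intercept = NA_real_, slope = NA_real_,
                 od_gt_003 = NA_real_, stringsAsFactors = FALSE)
    })
    res[[sn]] <- row
    if (verbose)
      message(sprintf("  replicate %d scenario %-9s acc = %s", r, sn,
                      ifelse(is.na(row$accuracy), "failed",
                             sprintf("%.3f", row$accuracy))))
  }
  list(results = do.call(rbind, c(res, list(make.row.names = FALSE))),
       hist = do.call(rbind, c(hist, list(make.row.names = FALSE))))
}

#' Run a replicated weighting-scenario study
#'
#' Executes the full chain per replicate (simulation, tail FST scan, top-k
#' prioritization, per-scenario weighted relationship matrix, REML fit, GEBV
#' prediction, accuracy/bias evaluation, training-by-validation relationship
#' histogram) and collects per-replicate and across-replicate summaries.
#' Scenario failures inside a replicate are logged as warnings and reported
#' as missing cells rather than aborting the study.
#'
#' @param plan An [experiment_plan()].
#' @param replicates Which replicates to run (default all in the plan);
#'   replicate `r` is fully determined by `(base_seed, r)`.
#' @param out_dir Optional directory: when given, the summary tables are
#'   written there as CSV via [write_report()].
#' @param verbose Print per-scenario progress.
#' @return An object of class `"gs_experiment"`: `results` (one row per
#'   scenario x replicate), `hist` (relationship histograms in long format),
#'   `plan`, `elapsed` (seconds).
#' @export
run_experiment <- function(plan, replicates = seq_len(plan$n_replicates),
                           out_dir = NULL, verbose = interactive()) {
  stopifnot(inherits(plan, "experiment_plan"))
  t0 <- proc.time()[3L]
  out <- lapply(replicates, function(r) {
    if (verbose) message("replicate ", r)
    .run_replicate(plan, r, verbose = verbose)
  })
  obj <- structure(list(
    results = do.call(rbind, c(lapply(out, `[[`, "results"),
                               list(make.row.names = FALSE))),
    hist = do.call(rbind, c(lapply(out, `[[`, "hist"),
                            list(make.row.names = FALSE))),
    plan = plan, elapsed = proc.time()[3L] - t0
  ), class = "gs_experiment")
  if (!is.null(out_dir)) write_report(obj, out_dir)
  obj
}

#' @export
print.gs_experiment <- function(x, ...) {
  cat(sprintf("Weighting-scenario study: %d scenarios x %d replicate(s), %.1f s\n",
              length(unique(x$results$scenario)),
              length(unique(x$results$replicate)), x$elapsed))
  print(summary(x)$fig1, digits = 3)
  invisible(x)
}

#' @export
summary.gs_experiment <- function(object, ...) {
  res <- object$results
  agg <- function(var) {
    m <- tapply(res[[var]], res$scenario, mean, na.rm = TRUE)
    s <- tapply(res[[var]], res$scenario, stats::sd, na.rm = TRUE)
    ord <- names(object$plan$scenarios)
    data.frame(scenario = ord, mean = as.numeric(m[ord]),
               sd = as.numeric(s[ord]), stringsAsFactors = FALSE)
  }
  varcomps <- data.frame(
    scenario = names(object$plan$scenarios),
    genetic_variance = agg("sigma_u2")$mean, genetic_variance_sd = agg("sigma_u2")$sd,
    residual_variance = agg("sigma_e2")$mean, residual_variance_sd = agg("sigma_e2")$sd,
    heritability = agg("h2")$mean, heritability_sd = agg("h2")$sd,
    stringsAsFactors = FALSE)
  fit_bias <- data.frame(
    scenario = names(object$plan$scenarios),
    residual_variance = agg("sigma_e2")$mean,
    intercept = agg("intercept")$mean, intercept_sd = agg("intercept")$sd,
    slope = agg("slope")$mean, slope_sd = agg("slope")$sd,
    minus2logL = agg("minus2logL")$mean, minus2logL_sd = agg("minus2logL")$sd,
    stringsAsFactors = FALSE)
  fig1 <- data.frame(
    scenario = names(object$plan$scenarios),
    accuracy = agg("accuracy")$mean, accuracy_sd = agg("accuracy")$sd,
    od_gt_003 = agg("od_gt_003")$mean,
    stringsAsFactors = FALSE)
  h <- object$hist
  hist_mean <- NULL
  if (!is.null(h) && nrow(h)) {
    hist_mean <- stats::aggregate(percent ~ scenario + bin, data = h, FUN = mean)
    bin_order <- unique(h$bin)
    hist_mean <- hist_mean[order(match(hist_mean$scenario,
                                       names(object$plan$scenarios)),
                                 match(hist_mean$bin, bin_order)), ]
    rownames(hist_mean) <- NULL
  }
  structure(list(varcomps = varcomps, fit_bias = fit_bias, fig1 = fig1,
                 hist = hist_mean), class = "summary.gs_experiment")
}

#' @export
print.summary.gs_experiment <- function(x, ...) {
  cat("Variance components (across-replicate mean, SD over replicates):\n")
  print(x$varcomps, digits = 3)
  cat("\nAccuracy by scenario:\n")
  print(x$fig1, digits = 3)
  cat("\nFit and dispersion bias:\n")
  print(x$fit_bias, digits = 4)
  invisible(x)
}

#' Write the study summary tables as CSV
#'
#' Emits `table1.csv` (variance components and heritability per scenario),
#' `table2_3.csv` (mean training-by-validation relationship histograms),
#' `table4.csv` (residual variance, bias regression and deviance) and
#' `fig1.csv` (accuracies), plus `results.csv` with the raw
#' per-scenario-per-replicate rows.
#'
#' @param x A `"gs_experiment"`.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "gs_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- summary(x)
  paths <- c(
    table1 = file.path(dir, "table1.csv"),
    table2_3 = file.path(dir, "table2_3.csv"),
    table4 = file.path(dir, "table4.csv"),
    fig1 = file.path(dir, "fig1.csv"),
    results = file.path(dir, "results.csv"))
  utils::write.csv(s$varcomps, paths["table1"], row.names = FALSE)
  if (!is.null(s$hist))
    utils::write.csv(s$hist, paths["table2_3"], row.names = FALSE)
  utils::write.csv(s$fit_bias, paths["table4"], row.names = FALSE)
  utils::write.csv(s$fig1, paths["fig1"], row.names = FALSE)
  utils::write.csv(x$results, paths["results"], row.names = FALSE)
  log_path <- file.path(dir, "log.txt")
  writeLines(c(
    utils::capture.output(print(x$plan)),
    sprintf("replicates run: %s",
            paste(sort(unique(x$results$replicate)), collapse = ", ")),
    sprintf("failed scenario cells: %d", sum(is.na(x$results$accuracy))),
    sprintf("elapsed: %.1f s", x$elapsed)
  ), log_path)
  invisible(c(paths, log = log_path))
}

#' @export
plot.gs_experiment <- function(x, ...) {
  s <- summary(x)$fig1
  bp <- graphics::barplot(s$accuracy, names.arg = s$scenario, las = 2,
                          ylim = c(0, max(s$accuracy + s$accuracy_sd,
                                          na.rm = TRUE) * 1.15),
                          ylab = "validation accuracy (cor(TBV, GEBV))",
                          main = "Accuracy by weighting scenario", ...)
  ok <- !is.na(s$accuracy_sd) & s$accuracy_sd > 0
  if (any(ok))
    graphics::arrows(bp[ok], s$accuracy[ok] - s$accuracy_sd[ok], bp[ok],
                     s$accuracy[ok] + s$accuracy_sd[ok], angle = 90,
                     code = 3, length = 0.04)
  invisible(x)
}
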