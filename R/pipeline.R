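#' Analysis configuration for the end-to-end pipeline
#'
#' Bundles every knob of a full cost-effectiveness run: the cohort (a
#' panel, or a synthetic generator configuration to draw one), the
#' follow-up horizon (with an optional shorter contrast horizon), the
#' reference strategy, the analysis variants, bootstrap settings and the
#' costing mode.
#'
#' @param generator a \code{generator_config} used when no panel is
#'   given.
#' @param panel optional \code{trajectory_panel} of observed data.
#' @param horizon primary follow-up in days (default 100).
#' @param contrast_horizon optional shorter horizon (e.g. 30) for the
#'   cost contrast; \code{NULL} skips it.
#' @param reference reference arm (default \code{"PVI-T1"}).
#' @param variants analysis variants to run.
#' @param bootstrap_B bootstrap replicates for 95\% CIs on mean cost and
#'   effectiveness (0 skips CIs; the default, since full re-estimation
#'   per replicate is costly).
#' @param seed master seed for simulation and bootstrap.
#' @param costing_mode \code{"occupancy_daily"} or
#'   \code{"per_entry_event"}.
#' @param cost_table a \code{cost_table} (default: the shipped base-case
#'   table).
#' @param out_dir directory for CSV outputs; \code{NULL} writes nothing.
#' @return An object of class \code{analysis_config}.
#' @export
analysis_config <- function(generator = default_arm_profiles(),
                            panel = NULL, horizon = 100L,
                            contrast_horizon = NULL,
                            reference = "PVI-T1",
                            variants = c("simulated_global",
                                         "simulated_alive",
                                         "observed_global"),
                            bootstrap_B = 0L, seed = 1L,
                            costing_mode = "occupancy_daily",
                            cost_table = build_cost_table(mode = costing_mode),
                            out_dir = NULL) {
  variants <- match.arg(variants, several.ok = TRUE)
  if (horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  structure(list(generator = generator, panel = panel,
                 horizon = as.integer(horizon),
                 contrast_horizon = contrast_horizon,
                 reference = reference, variants = variants,
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), costing_mode = costing_mode,
                 cost_table = cost_table, out_dir = out_dir),
            class = "analysis_config")
}

# internal: polynomial rolling hash of a deparsed object (provenance
# stamp only, no cryptographic intent)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# internal: truncate a panel to a shorter horizon on the daily grid, so
# subjects alive past the new horizon are censored there (not at their
# last compressed record)
truncate_panel <- function(panel, horizon) {
  g <- state_grid(panel)
  grid_to_panel(g[, seq_len(horizon + 1L), drop = FALSE],
                arm = attr(g, "arm"), horizon = horizon,
                ids = rownames(g))
}

# internal: per-arm summaries for one variant at one horizon
variant_summaries <- function(variant, arms, panel, config, horizon) {
  out <- list()
  for (a in arms) {
    df <- as.data.frame(panel)
    arm_panel <- trajectory_panel(df[df$arm == a, , drop = FALSE],
                                  horizon = attr(panel, "horizon"),
                                  validate = FALSE)
    if (horizon < attr(panel, "horizon"))
      arm_panel <- truncate_panel(arm_panel, horizon)
    if (variant == "observed_global") {
      x <- arm_panel
    } else {
      fit <- fit_multistate(arm_panel)
      sim <- simulate_cohort(fit, n = n_subjects(arm_panel),
                             seed = config$seed * 100L +
                               match(a, arms))
      x <- if (variant == "simulated_alive") alive_variant(sim) else sim
    }
    smry <- summarize_cohort(x, cost_table = config$cost_table,
                             variant = if (variant == "observed_global")
                               "observed_global" else variant)
    if (config$bootstrap_B > 0L) {
      ct <- config$cost_table
      bs_cost <- bootstrap_statistic(
        x, function(p) mean_cost_per_patient(observed_prevalence(p), ct,
                                             arm = a),
        B = config$bootstrap_B, seed = config$seed + 7L,
        jackknife = FALSE)
      bs_eff <- bootstrap_statistic(
        x, function(p) ever_in_states_per_1000(p),
        B = config$bootstrap_B, seed = config$seed + 11L,
        jackknife = FALSE)
      smry$cost_ci <- c(bs_cost$ci_low, bs_cost$ci_high)
      smry$effectiveness_ci <- c(bs_eff$ci_low, bs_eff$ci_high)
    }
    out[[a]] <- smry
  }
  out
}

#' Run the full cost-effectiveness pipeline
#'
#' End-to-end runner: obtains a cohort (generating a synthetic one when
#' no panel is supplied), applies the censoring rules, fits the
#' multi-state model per arm, runs the configured analysis variants
#' (model simulation on the global and alive patient samples, plus the
#' observed cohort), prices every summary, compares each arm to the
#' reference strategy, and -- when a contrast horizon is configured --
#' reports the per-arm cost difference between the two horizons.
#' Outputs are deterministic given the configuration; CSV files embed
#' the configuration hash and seed.
#'
#' @param config an \code{analysis_config}.
#' @return A list of class \code{cea_report}: \code{summaries} (per
#'   variant, per arm), \code{comparisons} (per variant, per non-reference
#'   arm), \code{horizon_contrast} (per arm, or NULL), \code{tables}
#'   (per-variant data.frames), \code{hash}, \code{seed}, \code{files}.
#' @export
run_pipeline <- function(config = analysis_config()) {
  panel <- config$panel
  if (is.null(panel)) panel <- generate_panel(config$generator)
  panel <- apply_censoring_rules(panel, horizon = config$horizon)
  arms <- sort(unique(panel$arm))
  if (!config$reference %in% arms)
    stop("reference arm ", config$reference, " absent from the panel",
         call. = FALSE)
  missing_cost <- setdiff(arms, rownames(config$cost_table))
  if (length(missing_cost))
    stop("no cost column for arm(s): ",
         paste(missing_cost, collapse = ", "), call. = FALSE)

  summaries <- lapply(stats::setNames(config$variants, config$variants),
                      variant_summaries, arms = arms, panel = panel,
                      config = config, horizon = config$horizon)
  comparisons <- lapply(summaries, function(smrys) {
    ref <- smrys[[config$reference]]
    lapply(smrys[setdiff(arms, config$reference)], function(alt) {
      res <- compare_strategies(ref, alt)
      if (!is.null(ref$cost_ci))
        res <- classify_significance(res, ref, alt)
      res
    })
  })

  contrast <- NULL
  if (!is.null(config$contrast_horizon)) {
    v <- config$variants[1L]
    short <- variant_summaries(v, arms, panel, config,
                               horizon = config$contrast_horizon)
    contrast <- vapply(arms, function(a)
      horizon_contrast(summaries[[v]][[a]], short[[a]]), numeric(1))
  }

  tables <- lapply(summaries, function(smrys) {
    ref <- smrys[[config$reference]]
    do.call(rbind, lapply(smrys, function(s) {
      cmp <- if (identical(s$arm, config$reference)) NULL else
        compare_strategies(ref, s)
      data.frame(arm = s$arm,
                 mean_cost = s$mean_cost_per_patient,
                 cost_lo = if (is.null(s$cost_ci)) NA else s$cost_ci[1],
                 cost_hi = if (is.null(s$cost_ci)) NA else s$cost_ci[2],
                 effectiveness = s$effectiveness_per_1000,
                 eff_lo = if (is.null(s$effectiveness_ci)) NA else
                   s$effectiveness_ci[1],
                 eff_hi = if (is.null(s$effectiveness_ci)) NA else
                   s$effectiveness_ci[2],
                 delta_cost = if (is.null(cmp)) NA else cmp$delta_cost,
                 delta_effectiveness = if (is.null(cmp)) NA else
                   cmp$delta_effectiveness,
                 icer = if (is.null(cmp)) NA else cmp$icer,
                 dominance = if (is.null(cmp)) "reference" else
                   cmp$dominance)
    }))
  })

  hash <- config_hash(config[c("horizon", "contrast_horizon", "reference",
                               "variants", "bootstrap_B", "seed",
                               "costing_mode")])
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (v in names(tables)) {
      f <- file.path(config$out_dir, paste0("cea_", v, ".csv"))
      con <- file(f, "w")
      writeLines(sprintf("# config %s seed %d", hash, config$seed), con)
      utils::write.csv(tables[[v]], con, row.names = FALSE)
      close(con)
      files <- c(files, f)
    }
    if (!is.null(contrast)) {
      f <- file.path(config$out_dir, "horizon_contrast.csv")
      con <- file(f, "w")
      writeLines(sprintf("# config %s seed %d", hash, config$seed), con)
      utils::write.csv(data.frame(arm = names(contrast),
                                  cost_short_minus_long = contrast),
                       con, row.names = FALSE)
      close(con)
      files <- c(files, f)
    }
  }
  structure(list(summaries = summaries, comparisons = comparisons,
                 horizon_contrast = contrast, tables = tables,
                 hash = hash, seed = config$seed, files = files),
            class = "cea_report")
}

#' @export
print.cea_report <- function(x, ...) {
  cat("cost-effectiveness report (config ", x$hash, ", seed ", x$seed,
      ")\n", sep = "")
  for (v in names(x$tables)) {
    cat("\n== ", v, " ==\n", sep = "")
    tab <- x$tables[[v]]
    tab$mean_cost <- round(tab$mean_cost)
    tab$effectiveness <- round(tab$effectiveness, 2)
    tab$delta_cost <- round(tab$delta_cost)
    tab$delta_effectiveness <- round(tab$delta_effectiveness, 2)
    tab$icer <- round(tab$icer)
    print(tab[, c("arm", "mean_cost", "effectiveness", "delta_cost",
                  "delta_effectiveness", "icer", "dominance")],
          row.names = FALSE)
  }
  if (!is.null(x$horizon_contrast)) {
    cat("\ncost difference, short vs long horizon:\n")
    print(round(x$horizon_contrast))
  }
  invisible(x)
}
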