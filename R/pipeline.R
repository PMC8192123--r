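#' Default end-to-end run configuration
#'
#' Assembles the configuration consumed by [run_end_to_end()]. Every field
#' can be overridden; defaults reproduce a complete small-scale analysis:
#' dynamics fitting on the chosen cell-line fixture, EMT/pEMT scoring of a
#' simulated single-cell experiment, and signature derivation plus survival
#' stratification on a simulated cohort.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; stage seeds are derived from it.
#' @param fixture `"HCT116"` or `"SW480"`.
#' @param scorer `"zscore"` or `"rank"` gene-set scorer.
#' @param hybrid_q Top-pEMT fraction flagged as hybrid.
#' @param mes_q Top fraction annotated mes-like.
#' @param r_threshold Signature-derivation correlation threshold.
#' @param grouping `"tertile"` or `"kmeans"` patient grouping.
#' @param sc,cohort Optional [sc_sim_config()] / [cohort_sim_config()]
#'   overrides; defaults are built from the master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, fixture = c("HCT116", "SW480"),
                       scorer = c("zscore", "rank"), hybrid_q = 0.1,
                       mes_q = 0.097, r_threshold = 0.3,
                       grouping = c("tertile", "kmeans"),
                       sc = NULL, cohort = NULL) {
  fixture <- match.arg(fixture)
  scorer <- match.arg(scorer)
  grouping <- match.arg(grouping)
  seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, seed = seed, fixture = fixture, scorer = scorer,
         hybrid_q = hybrid_q, mes_q = mes_q, r_threshold = r_threshold,
         grouping = grouping,
         sc = if (is.null(sc)) sc_sim_config(seed = seed + 1L) else sc,
         cohort = if (is.null(cohort)) cohort_sim_config(seed = seed + 2L) else cohort),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML file whose top-level keys match the arguments of
#' [run_config()]; `sc:` and `cohort:` sub-sections override the
#' corresponding simulator defaults. Paths referenced by the file are
#' checked at load time.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  sc <- if (!is.null(y$sc)) do.call(sc_sim_config, c(y$sc, list(seed = seed + 1L)))
  cohort <- if (!is.null(y$cohort)) do.call(cohort_sim_config, c(y$cohort, list(seed = seed + 2L)))
  run_config(
    out_dir = out_dir %||% y$out_dir %||% stop("config must set out_dir"),
    seed = seed,
    fixture = y$fixture %||% "HCT116",
    scorer = y$scorer %||% "zscore",
    hybrid_q = y$hybrid_q %||% 0.1,
    mes_q = y$mes_q %||% 0.097,
    r_threshold = y$r_threshold %||% 0.3,
    grouping = y$grouping %||% "tertile",
    sc = sc, cohort = cohort
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_digest <- function(config) {
  # digest the analysis-relevant configuration only: output paths must not
  # change the fingerprint, or identical runs in different directories
  # would disagree
  config$out_dir <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Executes generate -> fit -> score -> derive -> stratify on synthetic
#' inputs and writes a machine-readable summary plus a run log:
#' \enumerate{
#'   \item FACS stage: simulates noiseless pure-start cultures under the
#'     chosen fixture, fits doubling times (transitions disabled) and then
#'     transition rates (growth fixed), and checks the closed-form
#'     equilibrium against long-horizon integration.
#'   \item Single-cell stage: simulates counts along a latent EMT axis,
#'     normalizes, scores E/M/EMT/pEMT, flags hybrid cells, and locates the
#'     smoothed mid-axis peak of the first midpeak gene.
#'   \item Cohort stage: simulates the mixed cohort, derives the
#'     tumor-cell-intrinsic signature in the epithelial compartment,
#'     annotates mes-like cells, groups tumors by the derived meta-gene,
#'     and runs the Kaplan-Meier / log-rank comparison.
#' }
#' Outputs under `config$out_dir`: `summary.json` (all fitted parameters,
#' statistics and group sizes, with seed and config digest), `run_log.txt`,
#' and CSV/GMT side files for the main tables.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @return The summary list, invisibly.
#' @export
run_end_to_end <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  cat(sprintf("emtstate %s | seed %d | config %s\n",
              as.character(utils::packageVersion("emtstate")),
              config$seed, config_digest(config)),
      file = log_path)

  stage <- function(name, expr) {
    logf("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  ## ---- dynamics -----------------------------------------------------------
  dyn <- stage("fit-dynamics", {
    fx <- cell_line_fixture(config$fixture)
    growth_only_hi <- state_params(fx$T_hi, fx$T_lo, 0, 0)
    tc_grow_hi <- generate_facs_timecourse(facs_sim_config(
      growth_only_hi, "pure_hi", sample_times = 0:10,
      measurement_depth = NULL, seed = config$seed))
    tc_grow_lo <- generate_facs_timecourse(facs_sim_config(
      growth_only_hi, "pure_lo", sample_times = 0:10,
      measurement_depth = NULL, seed = config$seed))
    Ts <- fit_doubling_times(tc_grow_hi, tc_grow_lo)
    tc_hi <- generate_facs_timecourse(facs_sim_config(
      fx, "pure_hi", measurement_depth = NULL, seed = config$seed))
    tc_lo <- generate_facs_timecourse(facs_sim_config(
      fx, "pure_lo", measurement_depth = NULL, seed = config$seed))
    write_timecourse(tc_hi, file.path(config$out_dir, "timecourse_pure_hi.csv"))
    write_timecourse(tc_lo, file.path(config$out_dir, "timecourse_pure_lo.csv"))
    rates <- fit_transition_rates(tc_hi, tc_lo, Ts$T_hi, Ts$T_lo)
    eq <- equilibrium_lo_fraction(fx)
    eq_ode <- utils::tail(simulate_deterministic(fx, c(hi = 1, lo = 0), c(0, 200))$fraction_lo, 1)
    list(fixture = config$fixture, T_hi = Ts$T_hi, T_lo = Ts$T_lo,
         k_HL = rates$k_HL, k_LH = rates$k_LH, p_HL = rates$p_HL,
         p_LH = rates$p_LH, ratio = rates$ratio, objective = rates$objective,
         equilibrium_lo = eq, equilibrium_lo_ode = eq_ode)
  })

  ## ---- single cell --------------------------------------------------------
  sc <- stage("score-emt", {
    sim <- generate_sc_counts(config$sc)
    norm <- normalize_counts(sim$counts)
    E <- score_gene_set(norm, sim$gene_sets$epithelial, method = config$scorer, set_name = "E")
    M <- score_gene_set(norm, sim$gene_sets$mesenchymal, method = config$scorer, set_name = "M")
    scores <- emt_pemt(E, M)
    hyb <- hybrid_cells(scores, config$hybrid_q)
    write_cell_scores(scores, file.path(config$out_dir, "cell_scores.csv"), hybrid = hyb)
    write_gmt(sim$gene_sets[c("epithelial", "mesenchymal")],
              file.path(config$out_dir, "em_gene_sets.gmt"))
    mid <- smooth_trend(norm, sim$gene_sets$midpeak[1], scores$rank)
    list(n_cells = nrow(scores),
         spearman_emt_axis = stats::cor(scores$EMT, sim$cells$t_true, method = "spearman"),
         hybrid_n = sum(hyb),
         midpeak_argmax_quantile = which.max(mid$smoothed) / nrow(scores))
  })

  ## ---- cohort -------------------------------------------------------------
  coh <- stage("derive-and-stratify", {
    sim <- generate_cohort(config$cohort)
    sig <- derive_epithelial_signature(sim$sc$values, sim$sc$cells$compartment,
                                       sim$gene_sets$reference, config$r_threshold)
    write_gmt(list(derived_tc_signature = sig$members),
              file.path(config$out_dir, "derived_signature.gmt"))
    utils::write.csv(
      data.frame(gene = names(sig$r), r = as.numeric(sig$r)),
      file.path(config$out_dir, "derived_signature_r.csv"), row.names = FALSE)
    et <- sim$sc$cells$compartment == "epithelial_tumor"
    mes <- annotate_mes_like(
      metagene(sim$sc$values[, et, drop = FALSE], sig$members, "derived"),
      q = config$mes_q)
    track <- metagene(sim$bulk, sig$members, "derived")
    groups <- if (config$grouping == "tertile") {
      expression_groups_tertiles(track)
    } else {
      expression_groups_kmeans(track, seed = config$seed)
    }
    surv <- sim$survival
    surv$group <- groups[surv$sample_id]
    write_survival(surv, file.path(config$out_dir, "survival_groups.csv"))
    km <- km_logrank(surv)
    recall <- mean(sim$gene_sets$planted %in% sig$members)
    list(n_derived = length(sig$members), planted_recall = recall,
         mes_like_n = sum(mes == "mes-like"),
         group_sizes = as.list(table(groups)),
         logrank_chisq = km$chisq, logrank_df = km$df, logrank_p = km$p)
  })

  summary <- list(
    package_version = as.character(utils::packageVersion("emtstate")),
    seed = config$seed, config_digest = config_digest(config),
    dynamics = dyn, single_cell = sc, cohort = coh
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done; summary written to %s", file.path(config$out_dir, "summary.json"))
  invisible(summary)
}
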