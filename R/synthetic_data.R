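#' Configuration for simulated sorting/re-analysis experiments
#'
#' Describes a FACS-style plasticity experiment: cells sorted into a pure
#' (or mixed) starting composition, grown in culture, and re-analyzed by
#' flow cytometry at a series of time points.
#'
#' @param params A [state_params()] object for the cultured line.
#' @param initial_state `"pure_hi"`, `"pure_lo"`, or `"mixed"`.
#' @param fraction_lo Initial lo fraction when `initial_state = "mixed"`.
#' @param sample_times Strictly increasing sampling times in days (>= 2).
#' @param initial_cells Positive number of plated cells.
#' @param measurement_depth Number of cytometer events used to re-measure
#'   the lo fraction at each time point (binomial resampling), or `NULL`
#'   for noise-free read-out. Default 10000 events.
#' @param mode `"deterministic"` (exact ODE expectation) or `"stochastic"`
#'   (division/switching as binomial events per cell).
#' @param step Step size in days for stochastic mode.
#' @param seed Integer seed.
#' @return A `facs_sim_config` list.
#' @export
facs_sim_config <- function(params,
                            initial_state = c("pure_hi", "pure_lo", "mixed"),
                            fraction_lo = NULL,
                            sample_times = c(0, 3, 7, 14, 21, 28),
                            initial_cells = 1e4,
                            measurement_depth = 10000,
                            mode = c("deterministic", "stochastic"),
                            step = 0.05,
                            seed = 1L) {
  stopifnot(inherits(params, "state_params"))
  initial_state <- match.arg(initial_state)
  mode <- match.arg(mode)
  if (length(sample_times) < 2L || any(diff(sample_times) <= 0)) {
    stop("sample_times must be >= 2 strictly increasing values (days)")
  }
  if (!(initial_cells >= 1)) stop("initial_cells must be >= 1")
  if (!is.null(measurement_depth) && !(measurement_depth >= 1)) {
    stop("measurement_depth must be a positive integer or NULL")
  }
  f0 <- switch(initial_state,
    pure_hi = 0, pure_lo = 1,
    mixed = {
      if (is.null(fraction_lo) || fraction_lo < 0 || fraction_lo > 1) {
        stop("mixed start requires fraction_lo in [0, 1]")
      }
      fraction_lo
    }
  )
  structure(
    list(params = params, initial_state = initial_state, fraction_lo0 = f0,
         sample_times = sample_times, initial_cells = initial_cells,
         measurement_depth = measurement_depth, mode = mode, step = step,
         seed = as.integer(seed)),
    class = "facs_sim_config"
  )
}

#' Generate a FACS-style subpopulation time course
#'
#' Simulates the sorted-culture experiment described by a
#' [facs_sim_config()]: two-state growth with stochastic (or expected)
#' state switching, followed by optional binomial resampling of the lo
#' fraction at a finite cytometer event depth. With deterministic mode and
#' `measurement_depth = NULL` the output equals the exact ODE solution.
#'
#' @param config A [facs_sim_config()].
#' @return A `timecourse` data frame (`time_days`, `count_hi`, `count_lo`,
#'   `fraction_lo`); `fraction_lo` is the measured value, while the
#'   underlying true fractions are kept in attribute `"true_fraction_lo"`.
#' @export
generate_facs_timecourse <- function(config) {
  stopifnot(inherits(config, "facs_sim_config"))
  set.seed(config$seed)
  init <- c(
    hi = config$initial_cells * (1 - config$fraction_lo0),
    lo = config$initial_cells * config$fraction_lo0
  )
  tc <- if (config$mode == "deterministic") {
    simulate_deterministic(config$params, init, config$sample_times)
  } else {
    simulate_stochastic(config$params, round(init), config$sample_times,
                        step = config$step)
  }
  true_frac <- tc$fraction_lo
  if (!is.null(config$measurement_depth)) {
    d <- config$measurement_depth
    tc$fraction_lo <- stats::rbinom(nrow(tc), d, true_frac) / d
  }
  attr(tc, "true_fraction_lo") <- true_frac
  attr(tc, "seed") <- config$seed
  tc
}

# logistic decay / rise / Gaussian bump gene mean shapes on the EMT axis
.gene_shape <- function(t, class, scale = 0.1, width = 0.15) {
  switch(class,
    epithelial = 1 - stats::plogis((t - 0.5) / scale),
    mesenchymal = stats::plogis((t - 0.5) / scale),
    midpeak = exp(-(t - 0.5)^2 / (2 * width^2)),
    background = rep(1, length(t))
  )
}

#' Configuration for the single-cell count simulator
#'
#' Parameters of the negative-binomial single-cell count generator
#' structured along a latent EMT axis `t` in `[0, 1]` (0 = fully
#' epithelial, 1 = fully mesenchymal). Two populations mimic sorted
#' EpCAM-hi and EpCAM-lo cells: the hi-like population sits near the
#' epithelial end (`t ~ Beta(2, 8)`), the lo-like near the mesenchymal end
#' (`t ~ Beta(6, 2)`) with a 10% mid-axis hybrid component. Four gene
#' classes are simulated: epithelial (logistic decay in `t`), mesenchymal
#' (logistic rise), midpeak (Gaussian bump at `t = 0.5`, width 0.15;
#' SPARC-like partial-EMT markers), and unstructured background genes.
#'
#' @param n_cells_per_population Named vector `c(hi = , lo = )`.
#' @param n_genes Named vector with entries `epithelial`, `mesenchymal`,
#'   `midpeak`, `background`; all positive. Defaults 51/56/10/150 (the E/M
#'   sizes match the curated E and M gene sets used for scoring).
#' @param axis_beta List of Beta parameters for the hi- and lo-population
#'   axis distributions.
#' @param lo_mid_fraction Fraction of lo-like cells drawn from the
#'   mid-axis hybrid component (`Beta(8, 8)`).
#' @param base_mean,amp_mean Baseline and amplitude (counts at unit library
#'   factor) of structured gene means; per-gene amplitudes vary uniformly
#'   within +/- 50% of `amp_mean`.
#' @param background_mean Mean of unstructured genes.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param libsize_range Range of the per-cell library-size factor; factors
#'   are log-uniform on this interval.
#' @param seed Integer seed.
#' @return An `sc_sim_config` list.
#' @export
sc_sim_config <- function(n_cells_per_population = c(hi = 300, lo = 300),
                          n_genes = c(epithelial = 51, mesenchymal = 56,
                                      midpeak = 10, background = 150),
                          axis_beta = list(hi = c(2, 8), lo = c(6, 2)),
                          lo_mid_fraction = 0.1,
                          base_mean = 0.2, amp_mean = 8,
                          background_mean = 2, dispersion = 0.5,
                          libsize_range = c(0.5, 2), seed = 1L) {
  n_genes <- unlist(n_genes)
  n_cells_per_population <- unlist(n_cells_per_population)
  need <- c("epithelial", "mesenchymal", "midpeak", "background")
  if (!all(need %in% names(n_genes))) {
    stop("n_genes must name counts for: ", paste(need, collapse = ", "))
  }
  if (any(n_genes[need] < 1)) stop("every gene class needs at least one gene")
  if (any(n_cells_per_population < 1)) stop("need >= 1 cell per population")
  stopifnot(base_mean > 0, amp_mean > 0, background_mean > 0, dispersion > 0,
            length(libsize_range) == 2L, all(libsize_range > 0),
            lo_mid_fraction >= 0, lo_mid_fraction <= 1)
  structure(
    list(n_cells = n_cells_per_population, n_genes = n_genes[need],
         axis_beta = axis_beta, lo_mid_fraction = lo_mid_fraction,
         base_mean = base_mean, amp_mean = amp_mean,
         background_mean = background_mean, dispersion = dispersion,
         libsize_range = libsize_range, seed = as.integer(seed)),
    class = "sc_sim_config"
  )
}

#' Generate single-cell counts along a latent EMT axis
#'
#' Draws per-cell axis positions, per-gene mean curves, and
#' negative-binomial counts as configured by [sc_sim_config()]. Structured
#' gene means are monotone decreasing (epithelial), monotone increasing
#' (mesenchymal), or peaked at mid-axis (midpeak) in the latent position.
#'
#' @param config An [sc_sim_config()].
#' @return A list with:
#'   \item{counts}{integer matrix, genes x cells;}
#'   \item{cells}{data frame `cell_id`, `population`, `t_true` (ground-truth
#'     axis position), `lib_factor`;}
#'   \item{gene_sets}{named list of gene-identifier vectors per class
#'     (usable directly as E and M scoring sets).}
#' @export
generate_sc_counts <- function(config = sc_sim_config()) {
  stopifnot(inherits(config, "sc_sim_config"))
  set.seed(config$seed)
  n_hi <- config$n_cells[["hi"]]; n_lo <- config$n_cells[["lo"]]
  t_hi <- stats::rbeta(n_hi, config$axis_beta$hi[1], config$axis_beta$hi[2])
  mid <- stats::runif(n_lo) < config$lo_mid_fraction
  t_lo <- ifelse(mid,
                 stats::rbeta(n_lo, 8, 8),
                 stats::rbeta(n_lo, config$axis_beta$lo[1], config$axis_beta$lo[2]))
  t_all <- c(t_hi, t_lo)
  n_cells <- n_hi + n_lo
  cells <- data.frame(
    cell_id = sprintf("cell%04d", seq_len(n_cells)),
    population = rep(c("hi", "lo"), c(n_hi, n_lo)),
    t_true = t_all,
    lib_factor = exp(stats::runif(n_cells, log(config$libsize_range[1]),
                                  log(config$libsize_range[2])))
  )

  ng <- config$n_genes
  gene_sets <- list(
    epithelial = sprintf("EPI%03d", seq_len(ng[["epithelial"]])),
    mesenchymal = sprintf("MES%03d", seq_len(ng[["mesenchymal"]])),
    midpeak = sprintf("MID%03d", seq_len(ng[["midpeak"]])),
    background = sprintf("BG%03d", seq_len(ng[["background"]]))
  )
  classes <- rep(names(gene_sets), times = lengths(gene_sets))
  genes <- unlist(gene_sets, use.names = FALSE)
  amp <- stats::runif(length(genes), 0.5, 1.5) * config$amp_mean
  bg_mu <- config$background_mean *
    exp(stats::rnorm(length(genes), 0, 0.3))

  size <- 1 / config$dispersion
  counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, cells$cell_id))
  for (g in seq_along(genes)) {
    mu <- if (classes[g] == "background") {
      rep(bg_mu[g], n_cells)
    } else {
      config$base_mean + amp[g] * .gene_shape(t_all, classes[g])
    }
    counts[g, ] <- stats::rnbinom(n_cells, mu = mu * cells$lib_factor, size = size)
  }
  list(counts = counts, cells = cells, gene_sets = gene_sets)
}

#' Configuration for the synthetic tumor cohort
#'
#' Parameters of a generator for a mixed epithelial/stromal colon-cancer
#' cohort with a planted prognostic meta-gene effect, used to validate
#' tumor-cell signature derivation and survival stratification end to end.
#' It produces (a) a single-cell compartment matrix with labeled
#' epithelial-tumor, epithelial-normal and stromal cells in which a
#' stroma-associated reference program and a planted tumor-cell-intrinsic
#' program share a latent per-cell mesenchymal score, (b) a bulk expression
#' matrix whose planted genes track a per-tumor mesenchymal score, and (c)
#' survival times with hazard increasing multiplicatively in that score.
#'
#' @param n_tumors Number of bulk tumors.
#' @param n_cells Named vector of single-cell compartment sizes
#'   (`epithelial_tumor`, `epithelial_normal`, `stromal`).
#' @param n_reference_genes,n_planted_genes,n_background_genes Sizes of the
#'   reference (stroma-associated) set, the planted tumor-cell set, and the
#'   unstructured background.
#' @param effect_size Multiplier on the latent-score loading of reference
#'   and planted genes; 0 gives a null cohort.
#' @param stromal_beta,meslike_beta Beta parameters of the per-tumor
#'   stromal fraction and of the per-cell / per-tumor mesenchymal scores.
#' @param baseline_hazard Events per month at average score.
#' @param hazard_coef Log-hazard increase per SD of the planted meta-gene
#'   score.
#' @param censor_horizon Upper bound (months) of the independent uniform
#'   censoring time.
#' @param noise_sd Residual SD of expression values (log scale).
#' @param seed Integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_tumors = 200,
                              n_cells = c(epithelial_tumor = 300,
                                          epithelial_normal = 100,
                                          stromal = 150),
                              n_reference_genes = 40,
                              n_planted_genes = 50,
                              n_background_genes = 200,
                              effect_size = 1,
                              stromal_beta = c(2, 4),
                              meslike_beta = c(2, 5),
                              baseline_hazard = 0.03,
                              hazard_coef = 0.8,
                              censor_horizon = 60,
                              noise_sd = 0.5,
                              seed = 1L) {
  n_cells <- unlist(n_cells)
  stopifnot(n_tumors >= 3, all(n_cells >= 1),
            n_reference_genes >= 1, n_background_genes >= 1,
            baseline_hazard > 0, censor_horizon > 0, noise_sd > 0,
            effect_size >= 0)
  if (n_planted_genes < 1) stop("planted gene list must be non-empty")
  structure(
    list(n_tumors = n_tumors, n_cells = n_cells,
         n_reference_genes = n_reference_genes,
         n_planted_genes = n_planted_genes,
         n_background_genes = n_background_genes,
         effect_size = effect_size, stromal_beta = stromal_beta,
         meslike_beta = meslike_beta, baseline_hazard = baseline_hazard,
         hazard_coef = hazard_coef, censor_horizon = censor_horizon,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

#' Generate a synthetic cohort: single-cell compartments, bulk, survival
#'
#' @param config A [cohort_sim_config()].
#' @return A list with:
#'   \item{sc}{list of `values` (log-scale expression, genes x cells) and
#'     `cells` (data frame `cell_id`, `compartment`, `mes_latent`);}
#'   \item{bulk}{matrix genes x tumors of log-scale expression;}
#'   \item{survival}{data frame `sample_id`, `time` (months), `event`;}
#'   \item{tumors}{data frame with ground-truth `mes_score` and
#'     `stromal_fraction` per tumor;}
#'   \item{gene_sets}{list with `reference` (stroma-associated set) and
#'     `planted` (ground-truth tumor-cell-intrinsic set).}
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  genes <- list(
    reference = sprintf("REF%03d", seq_len(config$n_reference_genes)),
    planted = sprintf("SIG%03d", seq_len(config$n_planted_genes)),
    background = sprintf("BG%03d", seq_len(config$n_background_genes))
  )
  all_genes <- unlist(genes, use.names = FALSE)
  eff <- config$effect_size

  ## --- single-cell compartment matrix -------------------------------------
  nc <- config$n_cells
  comp <- rep(names(nc), times = nc)
  n_sc <- sum(nc)
  mes <- numeric(n_sc)
  is_et <- comp == "epithelial_tumor"
  mes[is_et] <- stats::rbeta(sum(is_et), config$meslike_beta[1], config$meslike_beta[2])
  mes[comp == "epithelial_normal"] <- stats::rbeta(sum(comp == "epithelial_normal"), 1, 12)
  mes[comp == "stromal"] <- 1
  sc_cells <- data.frame(
    cell_id = sprintf("sc%05d", seq_len(n_sc)),
    compartment = comp,
    mes_latent = mes
  )
  load_ref <- stats::runif(config$n_reference_genes, 1.5, 2.5) * eff
  load_sig <- stats::runif(config$n_planted_genes, 1.5, 2.5) * eff
  sc_vals <- matrix(stats::rnorm(length(all_genes) * n_sc, 0, config$noise_sd),
                    nrow = length(all_genes),
                    dimnames = list(all_genes, sc_cells$cell_id))
  # reference genes: driven by the latent score in epithelial cells, and
  # constitutively high in stroma (stromal contamination program)
  sc_vals[genes$reference, ] <- sc_vals[genes$reference, ] +
    outer(load_ref, mes) + outer(load_ref, as.numeric(comp == "stromal"))
  # planted genes: same latent score within the epithelial compartment,
  # but NOT stromal (tumor-cell intrinsic)
  sc_vals[genes$planted, ] <- sc_vals[genes$planted, ] +
    outer(load_sig, mes * as.numeric(comp != "stromal"))

  ## --- bulk cohort ---------------------------------------------------------
  n_t <- config$n_tumors
  stromal_frac <- stats::rbeta(n_t, config$stromal_beta[1], config$stromal_beta[2])
  mes_score <- stats::rbeta(n_t, config$meslike_beta[1], config$meslike_beta[2])
  tumors <- data.frame(
    sample_id = sprintf("T%03d", seq_len(n_t)),
    mes_score = mes_score,
    stromal_fraction = stromal_frac
  )
  bulk <- matrix(stats::rnorm(length(all_genes) * n_t, 0, config$noise_sd),
                 nrow = length(all_genes),
                 dimnames = list(all_genes, tumors$sample_id))
  bulk[genes$reference, ] <- bulk[genes$reference, ] + outer(load_ref, stromal_frac)
  bulk[genes$planted, ] <- bulk[genes$planted, ] + outer(load_sig, mes_score)

  ## --- survival ------------------------------------------------------------
  z <- if (stats::sd(mes_score) > 0) as.numeric(scale(mes_score)) else rep(0, n_t)
  rate <- config$baseline_hazard * exp(config$hazard_coef * z)
  t_event <- stats::rexp(n_t, rate)
  t_cens <- stats::runif(n_t, 0, config$censor_horizon)
  surv <- data.frame(
    sample_id = tumors$sample_id,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )

  list(
    sc = list(values = sc_vals, cells = sc_cells),
    bulk = bulk, survival = surv, tumors = tumors,
    gene_sets = list(reference = genes$reference, planted = genes$planted)
  )
}
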