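#' Meta-gene score of a gene set per sample
#'
#' Collapses a gene set into a single expression value per tumor, cell
#' line, or cell: the mean of the members' per-gene z-scores. Being
#' z-score based, the track is invariant to per-gene affine transforms of
#' the input expression.
#'
#' @param X Expression matrix, genes x samples.
#' @param members Gene identifiers (or a `list(name=, members=)`).
#' @param set_name Label used in messages.
#' @return Named numeric vector: one meta-gene value per sample.
#' @export
metagene <- function(X, members, set_name = "signature") {
  score_gene_set(X, members, method = "zscore", set_name = set_name)
}

#' Correlate two meta-gene tracks
#'
#' Pearson correlation between two per-sample score tracks over their
#' shared samples, with a two-sided t-approximation p-value — the
#' "relate two tracks" comparison of signature scores across a cohort.
#'
#' @param a,b Named numeric vectors (sample -> score).
#' @return A list with `r`, `p`, and `n` (shared samples).
#' @export
correlate_tracks <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b))) stop("tracks must carry sample names")
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) stop("need >= 3 shared samples to correlate tracks")
  x <- a[shared]; y <- b[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("a track has zero variance over the shared samples")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Derive a tumor-cell-intrinsic signature by compartment-restricted correlation
#'
#' Re-derives a stroma-associated reference signature inside the tumor
#' epithelial compartment: (1) the reference meta-gene is computed per
#' epithelial-tumor cell; (2) every gene in the matrix is Pearson-correlated
#' with that meta-gene across epithelial-tumor cells only; (3) genes with
#' correlation strictly greater than `r_threshold` form the derived set.
#' Because only epithelial-tumor cells enter the computation, the result is
#' invariant to adding or removing stromal cells, which is the point: the
#' derived signature captures the tumor-cell-intrinsic component of an
#' otherwise stroma-dominated program.
#'
#' @param values Expression matrix, genes x cells (normalized scale).
#' @param compartment Character vector, one label per cell; cells labeled
#'   `"epithelial_tumor"` drive the derivation. At least 10 such cells.
#' @param reference Gene identifiers of the reference signature.
#' @param r_threshold Strict inclusion threshold on Pearson r (default 0.3).
#' @return A list with `members` (selected genes, decreasing r), `r`
#'   (named vector of correlations for all testable genes), `n_cells`, and
#'   `threshold`.
#' @export
derive_epithelial_signature <- function(values, compartment, reference,
                                        r_threshold = 0.3) {
  if (length(compartment) != ncol(values)) {
    stop("compartment must label every cell (length mismatch)")
  }
  idx <- which(compartment == "epithelial_tumor")
  if (length(idx) == 0L) stop("no cells labeled 'epithelial_tumor'")
  if (length(idx) < 10L) stop("need >= 10 epithelial_tumor cells")
  Xe <- values[, idx, drop = FALSE]
  track <- metagene(Xe, reference, set_name = "reference")
  keep <- apply(Xe, 1, stats::sd) > 0
  r <- as.numeric(stats::cor(t(Xe[keep, , drop = FALSE]), track))
  names(r) <- rownames(Xe)[keep]
  members <- names(r)[r > r_threshold]
  members <- members[order(r[members], decreasing = TRUE)]
  list(members = members, r = r, n_cells = length(idx), threshold = r_threshold)
}

#' Annotate the most signature-associated cells as mesenchymal-like
#'
#' Labels the top fraction `q` of cells by meta-gene score as `"mes-like"`,
#' the rule used to call quasi-mesenchymal tumor cells from their
#' association with a tumor-cell-intrinsic signature. The default
#' `q = 0.097` reproduces the reported 9.7% prevalence: on 1000 cells with
#' distinct scores exactly 97 are labeled. The threshold is the
#' `ceiling(q * n)`-th largest score, and ties at the cut are all included,
#' so the labeled count can exceed `ceiling(q * n)` under ties.
#'
#' @param track Named numeric vector of per-cell meta-gene scores.
#' @param q Fraction to label, in (0, 1).
#' @return Character vector (`"mes-like"` / `"other"`), named by cell.
#' @export
annotate_mes_like <- function(track, q = 0.097) {
  if (!(q > 0 && q < 1)) stop("q must lie strictly in (0, 1)")
  thr <- .top_fraction_threshold(track, q)
  out <- ifelse(track >= thr, "mes-like", "other")
  names(out) <- names(track)
  out
}

#' Group samples by meta-gene score with 1-d k-means
#'
#' Clusters a per-sample score track into `k` groups by k-means (fixed
#' seed, 25 restarts) and names the groups by ascending cluster center:
#' `"low"`, `"intermediate"`, `"high"` for the default `k = 3`.
#'
#' @param track Named numeric vector of scores.
#' @param k Number of groups (default 3).
#' @param seed Integer seed.
#' @return Factor of group labels, named by sample, levels low < ... < high.
#' @export
expression_groups_kmeans <- function(track, k = 3, seed = 1L) {
  if (length(track) < k) stop("need at least k samples")
  if (stats::sd(track) == 0) stop("all scores identical; groups are undefined")
  set.seed(seed)
  km <- stats::kmeans(matrix(track, ncol = 1), centers = k, nstart = 25)
  lab <- if (k == 3) c("low", "intermediate", "high") else paste0("group", seq_len(k))
  relabel <- integer(k); relabel[order(km$centers[, 1])] <- seq_len(k)
  out <- factor(lab[relabel[km$cluster]], levels = lab)
  names(out) <- names(track)
  out
}

#' Group samples into equal tertiles of a meta-gene score
#'
#' Splits samples into three equal-size groups by ascending score
#' (`low`, `intermediate`, `high`). When the sample count is not divisible
#' by 3, the remainder is assigned from the low group upward (n = 10 gives
#' 4/3/3). Ties are broken by sample order, so the split is deterministic.
#'
#' @param track Named numeric vector of scores (>= 3 samples).
#' @return Factor of group labels, named by sample.
#' @export
expression_groups_tertiles <- function(track) {
  n <- length(track)
  if (n < 3L) stop("need >= 3 samples for tertiles")
  base <- n %/% 3L; rem <- n %% 3L
  sizes <- c(low = base, intermediate = base, high = base)
  if (rem >= 1L) sizes["low"] <- sizes["low"] + 1L
  if (rem == 2L) sizes["intermediate"] <- sizes["intermediate"] + 1L
  lab <- rep(c("low", "intermediate", "high"), times = sizes)
  out <- factor(character(n), levels = c("low", "intermediate", "high"))
  out[order(track)] <- lab
  names(out) <- names(track)
  out
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Product-limit survival estimate per group plus the k-sample log-rank
#' chi-square test (k - 1 degrees of freedom, asymptotic p), used to ask
#' whether signature-defined patient groups differ in relapse-free or
#' overall survival.
#'
#' @param surv Data frame with `time` (>= 0), `event` (0 = censored,
#'   1 = event), and `group`.
#' @return A list with `curves` (data frame `group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `chisq`, `df`, `p`, and the underlying
#'   [survival::survfit] object as `fit`.
#' @export
km_logrank <- function(surv) {
  need <- c("time", "event", "group")
  if (!all(need %in% names(surv))) stop("surv needs columns: ", paste(need, collapse = ", "))
  if (any(surv$time < 0)) stop("survival times must be non-negative")
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)")
  surv$group <- droplevels(factor(surv$group))
  if (nlevels(surv$group) < 2L) stop("need >= 2 non-empty groups")
  if (sum(surv$event) < 1L) stop("need at least one event overall")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = surv)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(
    group = sub("^group=", "", strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv
  )
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = surv)
  df <- nlevels(surv$group) - 1L
  list(curves = curves, chisq = lr$chisq, df = df,
       p = stats::pchisq(lr$chisq, df, lower.tail = FALSE), fit = fit)
}
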