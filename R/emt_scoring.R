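#' Library-size normalization and log transform
#'
#' Scales each cell's counts to the median library size across cells and
#' applies `log(1 + x)`, the standard pre-processing before gene-set
#' scoring.
#'
#' @param X Non-negative count matrix, genes x cells, with dimnames.
#' @return Normalized numeric matrix of the same shape.
#' @export
normalize_counts <- function(X) {
  if (any(X < 0)) stop("counts must be non-negative")
  totals <- colSums(X)
  zero <- which(totals == 0)
  if (length(zero)) {
    stop("cells with zero total counts cannot be normalized: ",
         paste(utils::head(colnames(X)[zero], 10), collapse = ", "))
  }
  med <- stats::median(totals)
  log1p(sweep(X, 2, totals, "/") * med)
}

# per-gene z-score across cells; zero-variance genes map to 0
.zscore_rows <- function(X) {
  mu <- rowMeans(X)
  sd <- apply(X, 1, stats::sd)
  Z <- (X - mu) / ifelse(sd > 0, sd, 1)
  Z[sd == 0, ] <- 0
  Z
}

#' Score cells (or samples) against a gene set
#'
#' Default scorer: z-score every gene across cells, then average the
#' z-scores of the set members present in the matrix. An alternative
#' rank-based scorer averages the within-cell normalized expression ranks
#' of the members. Both are scale-free summaries of the set's coordinate
#' activity per cell; the z-score form is the package default and is what
#' the E/M/meta-gene operations use.
#'
#' @param X Normalized expression matrix, genes x cells, rownames = genes.
#' @param members Character vector of gene identifiers (or a list with a
#'   `members` element, as returned by [read_gmt()]).
#' @param method `"zscore"` (default) or `"rank"`.
#' @param set_name Name used in messages.
#' @return Named numeric vector of per-cell scores, with attribute
#'   `"coverage"` = fraction of members found in the matrix. A warning is
#'   emitted when coverage falls below 50%.
#' @export
score_gene_set <- function(X, members, method = c("zscore", "rank"),
                           set_name = "gene set") {
  method <- match.arg(method)
  if (is.list(members) && !is.null(members$members)) {
    if (!is.null(members$name)) set_name <- members$name
    members <- members$members
  }
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("empty gene set: ", set_name)
  present <- intersect(members, rownames(X))
  if (length(present) == 0L) {
    stop(sprintf("no genes of set '%s' are present in the matrix", set_name))
  }
  coverage <- length(present) / length(members)
  if (coverage < 0.5) {
    warning(sprintf("low coverage for set '%s': %d/%d genes present (%.0f%%)",
                    set_name, length(present), length(members), 100 * coverage))
  }
  score <- if (method == "zscore") {
    colMeans(.zscore_rows(X)[present, , drop = FALSE])
  } else {
    R <- apply(X, 2, rank, ties.method = "average") / nrow(X)
    colMeans(R[present, , drop = FALSE])
  }
  names(score) <- colnames(X)
  attr(score, "coverage") <- coverage
  score
}

#' EMT and partial-EMT scores from E and M program scores
#'
#' Combines per-cell epithelial (E) and mesenchymal (M) program scores into
#' the EMT score `EMT = M - E` (position along the epithelial-mesenchymal
#' axis) and the partial-EMT score `pEMT = min(E, M)` (co-activation of
#' both programs, high for hybrid E/M cells). Cells are ranked by ascending
#' EMT score with ties broken by cell identifier, giving a deterministic
#' ordering of the EMT axis.
#'
#' @param E,M Named numeric vectors of per-cell scores over the same cells.
#' @return A `cell_scores` data frame: `cell_id`, `E`, `M`, `EMT`, `pEMT`,
#'   `rank` (a permutation of `1..n`).
#' @export
emt_pemt <- function(E, M) {
  if (length(E) != length(M)) stop("E and M must score the same cells (length mismatch)")
  if (!is.null(names(E)) && !is.null(names(M))) {
    if (!identical(names(E), names(M))) {
      if (!setequal(names(E), names(M))) stop("E and M cell identifiers differ")
      M <- M[names(E)]
    }
    ids <- names(E)
  } else {
    ids <- sprintf("cell%d", seq_along(E))
  }
  emt <- M - E
  pemt <- pmin(E, M)
  ord <- order(emt, ids, method = "radix")
  rk <- integer(length(emt)); rk[ord] <- seq_along(emt)
  out <- data.frame(cell_id = ids, E = unname(E), M = unname(M),
                    EMT = unname(emt), pEMT = unname(pemt), rank = rk)
  stopifnot(all(out$EMT == out$M - out$E), all(out$pEMT == pmin(out$E, out$M)))
  class(out) <- c("cell_scores", "data.frame")
  out
}

#' Smoothed expression trend along the EMT axis
#'
#' Orders cells by their EMT-axis rank and returns a centered moving
#' average of a gene's z-scored expression, the read-out used to inspect
#' how individual genes (e.g. SPARC-like partial-EMT markers) behave along
#' the epithelial-to-mesenchymal continuum. Windows are truncated at the
#' ends of the axis.
#'
#' @param X Normalized expression matrix, genes x cells.
#' @param gene Gene identifier (must be a rowname of `X`).
#' @param ranks Integer EMT-axis ranks, one per cell of `X` (a permutation
#'   of `1..ncol(X)`), e.g. the `rank` column of [emt_pemt()].
#' @param window Odd window size in cells, between 3 and `ncol(X)`.
#' @return A data frame `position` (1..n along the axis), `cell_id`,
#'   `smoothed` (windowed mean of the gene's z-score).
#' @export
smooth_trend <- function(X, gene, ranks, window = 51) {
  if (!gene %in% rownames(X)) stop("unknown gene: ", gene)
  n <- ncol(X)
  if (length(ranks) != n || !setequal(ranks, seq_len(n))) {
    stop("ranks must be a permutation of 1..n_cells")
  }
  if (window %% 2 != 1 || window < 3 || window > n) {
    stop("window must be odd and between 3 and the number of cells")
  }
  x <- as.numeric(.zscore_rows(X[gene, , drop = FALSE]))
  ord <- order(ranks)
  x <- x[ord]
  half <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  data.frame(position = seq_len(n), cell_id = colnames(X)[ord], smoothed = sm)
}

# threshold selecting the top ceiling(q * n) values (ties at the cut included)
.top_fraction_threshold <- function(x, q) {
  k <- ceiling(q * length(x))
  sort(x, decreasing = TRUE)[k]
}

#' Flag hybrid (partial-EMT) cells
#'
#' Flags the cells in the top `q` fraction of the pEMT score, i.e. cells
#' co-expressing the epithelial and mesenchymal programs most strongly.
#' The threshold is the `ceiling(q * n)`-th largest pEMT value (a
#' nearest-rank quantile); all cells tied at the threshold are flagged, so
#' the flagged fraction can exceed `q` under ties.
#'
#' @param scores A [emt_pemt()] result (or any data frame with `pEMT`).
#' @param q Top fraction to flag, in (0, 1); default 0.1.
#' @return Logical vector, one flag per cell.
#' @export
hybrid_cells <- function(scores, q = 0.1) {
  if (!(q > 0 && q < 1)) stop("q must lie strictly in (0, 1)")
  p <- scores$pEMT
  p >= .top_fraction_threshold(p, q)
}

#' Cluster genes into expression programs
#'
#' k-means grouping of genes by their average expression across cell
#' clusters, the procedure used to resolve coordinated epithelial and
#' mesenchymal sub-programs (epi1/epi2, mes1/mes2 and the like). Rows are
#' standardized before clustering so only the profile shape matters;
#' clustering runs with 25 random restarts under a fixed seed and programs
#' are reported in a deterministic order (by the cluster-center profile).
#'
#' @param M Numeric matrix genes x cell-clusters of mean expression.
#' @param k Number of programs, `2 <= k <= nrow(M)`.
#' @param seed Integer seed for the restarts.
#' @return A list with `assignment` (named integer vector gene -> program)
#'   and `programs` (list of gene-identifier vectors, `program1..programk`).
#' @export
gene_program_clusters <- function(M, k, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(M)) stop("k exceeds the number of genes")
  Z <- .zscore_rows(M)
  set.seed(seed)
  km <- stats::kmeans(Z, centers = k, nstart = 25, iter.max = 100)
  # relabel programs deterministically by their center profiles
  ord <- do.call(order, as.data.frame(km$centers))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assignment <- relabel[km$cluster]
  names(assignment) <- rownames(M)
  programs <- split(names(assignment), paste0("program", assignment))
  programs <- programs[paste0("program", seq_len(k))]
  list(assignment = assignment, programs = programs,
       withinss = km$tot.withinss)
}
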