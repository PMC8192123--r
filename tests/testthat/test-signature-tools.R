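test_that("metagene collapses a set to its mean z-score with exact special cases", {
  X <- toy_matrix(8, 10)
  # single-gene set equals that gene's z-score
  g <- "g03"
  z <- (X[g, ] - mean(X[g, ])) / sd(X[g, ])
  expect_equal(metagene(X, g), z, tolerance = 1e-12, ignore_attr = TRUE)
  # invariance under per-gene affine transforms
  Xa <- X * 100 - 3
  expect_equal(metagene(Xa, rownames(X)[1:5]), metagene(X, rownames(X)[1:5]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(metagene(X, c("zz1", "zz2"), set_name = "absent"), "absent")
})

test_that("metagene recovers the planted latent score on the synthetic cohort", {
  coh <- generate_cohort(cohort_sim_config(seed = 17))
  track <- metagene(coh$bulk, coh$gene_sets$planted)
  expect_gt(cor(track, coh$tumors$mes_score), 0.9)
})

test_that("track correlation handles identity, negation, and null tracks", {
  set.seed(5)
  a <- rnorm(100); names(a) <- sprintf("s%03d", 1:100)
  expect_equal(correlate_tracks(a, a)$r, 1)
  expect_equal(correlate_tracks(a, -a)$r, -1)
  b <- rnorm(100); names(b) <- names(a)
  expect_lt(abs(correlate_tracks(a, b)$r), 0.3)
  expect_error(correlate_tracks(a[1:2], b[1:2]), ">= 3 shared")
  const <- a; const[] <- 1
  expect_error(correlate_tracks(a, const), "zero variance")
})

test_that("signature derivation applies a strict correlation threshold", {
  set.seed(8)
  n <- 60
  latent <- rnorm(n)
  ref <- t(sapply(1:10, function(i) latent + rnorm(n, 0, 0.3)))
  rownames(ref) <- sprintf("REF%02d", 1:10)
  X <- rbind(ref, mirror = as.numeric(metagene(ref, rownames(ref))))
  colnames(X) <- sprintf("c%03d", 1:n)
  comp <- rep("epithelial_tumor", n)
  sig <- derive_epithelial_signature(X, comp, rownames(ref))
  # a gene identical to the reference meta-gene is included with r = 1
  expect_true("mirror" %in% sig$members)
  expect_equal(unname(sig$r["mirror"]), 1, tolerance = 1e-12)
  # a gene sitting exactly at r = threshold is excluded (strict inequality)
  track <- metagene(X, rownames(ref))
  v <- rnorm(n)
  resid <- residuals(lm(v ~ track))
  exact <- 0.3 * track / sd(track) + sqrt(1 - 0.3^2) * resid / sd(resid)
  stopifnot(abs(cor(exact, track) - 0.3) < 1e-12)
  X2 <- rbind(X, exact = exact)
  sig2 <- derive_epithelial_signature(X2, comp, rownames(ref))
  expect_false("exact" %in% sig2$members)
  expect_equal(unname(sig2$r["exact"]), 0.3, tolerance = 1e-10)
  expect_error(derive_epithelial_signature(X, rep("stromal", n), rownames(ref)),
               "epithelial_tumor")
  expect_error(derive_epithelial_signature(X[, 1:5], comp[1:5], rownames(ref)),
               ">= 10")
})

test_that("signature derivation recovers planted genes and ignores stromal cells", {
  coh <- generate_cohort(cohort_sim_config(seed = 23))
  vals <- coh$sc$values; comp <- coh$sc$cells$compartment
  sig <- derive_epithelial_signature(vals, comp, coh$gene_sets$reference)
  recall <- mean(coh$gene_sets$planted %in% sig$members)
  expect_gte(recall, 0.8)
  foreign <- setdiff(sig$members, c(coh$gene_sets$planted, coh$gene_sets$reference))
  expect_lte(length(foreign) / max(length(sig$members), 1), 0.1)
  # removing all stromal cells changes nothing: the derivation is
  # compartment-restricted by construction
  keep <- comp != "stromal"
  sig2 <- derive_epithelial_signature(vals[, keep], comp[keep], coh$gene_sets$reference)
  expect_identical(sig$members, sig2$members)
  expect_equal(sig$r, sig2$r)
})

test_that("mes-like annotation labels the top score fraction", {
  set.seed(3)
  track <- rnorm(1000); names(track) <- sprintf("c%04d", 1:1000)
  lab <- annotate_mes_like(track, q = 0.097)
  expect_equal(sum(lab == "mes-like"), 97)
  expect_gt(mean(track[lab == "mes-like"]), mean(track[lab == "other"]))
  expect_error(annotate_mes_like(track, q = 1), "strictly")
})

test_that("mes-like cells have depressed epithelial-marker expression on synthetic data", {
  coh <- generate_cohort(cohort_sim_config(seed = 29))
  et <- coh$sc$cells$compartment == "epithelial_tumor"
  Xe <- coh$sc$values[, et]
  sig <- derive_epithelial_signature(coh$sc$values, coh$sc$cells$compartment,
                                     coh$gene_sets$reference)
  lab <- annotate_mes_like(metagene(Xe, sig$members))
  # background genes are unstructured; the planted program itself is the
  # mesenchymal read-out, so mes-like cells must overexpress it
  planted_mean <- colMeans(Xe[coh$gene_sets$planted, ])
  expect_gt(mean(planted_mean[lab == "mes-like"]), mean(planted_mean[lab == "other"]))
  # and their latent mesenchymal score is higher (ground truth)
  mes_latent <- coh$sc$cells$mes_latent[et]
  expect_gt(mean(mes_latent[lab == "mes-like"]), mean(mes_latent[lab == "other"]))
})

test_that("k-means expression groups split separable scores and ignore order", {
  x <- c(0, 0, 0, 5, 5, 5, 10, 10, 10)
  names(x) <- sprintf("s%d", 1:9)
  g <- expression_groups_kmeans(x)
  expect_equal(as.character(g), rep(c("low", "intermediate", "high"), each = 3))
  perm <- c(5, 2, 9, 1, 7, 3, 8, 6, 4)
  g2 <- expression_groups_kmeans(x[perm])
  expect_equal(g2, g[perm])
  expect_error(expression_groups_kmeans(rep(1, 10)), "identical")
  # three well-separated Gaussians: misassignment < 5%
  set.seed(1)
  mix <- c(rnorm(100, -2, 0.3), rnorm(100, 0, 0.3), rnorm(100, 2, 0.3))
  names(mix) <- sprintf("m%03d", 1:300)
  truth <- rep(c("low", "intermediate", "high"), each = 100)
  gm <- expression_groups_kmeans(mix)
  expect_lt(mean(as.character(gm) != truth), 0.05)
})

test_that("tertile grouping is equal-size with a documented remainder rule", {
  x9 <- stats::setNames(c(9, 2, 7, 1, 5, 3, 8, 4, 6), sprintf("s%d", 1:9))
  g9 <- expression_groups_tertiles(x9)
  expect_equal(as.numeric(table(g9)), c(3, 3, 3))
  expect_true(all(x9[g9 == "high"] > x9[g9 == "low"]))
  x10 <- stats::setNames(1:10, sprintf("s%02d", 1:10))
  g10 <- expression_groups_tertiles(x10)
  expect_equal(as.numeric(table(g10)), c(4, 3, 3))
  expect_equal(as.character(g10), rep(c("low", "intermediate", "high"), c(4, 3, 3)))
  expect_error(expression_groups_tertiles(x9[1:2]), ">= 3")
})

test_that("high planted-signature tertile carries high mes-like ground truth", {
  coh <- generate_cohort(cohort_sim_config(seed = 31))
  g <- expression_groups_tertiles(metagene(coh$bulk, coh$gene_sets$planted))
  ms <- coh$tumors$mes_score
  expect_gt(mean(ms[g == "high"]), mean(ms[g == "low"]))
})

test_that("KM estimate matches the empirical survival function without censoring", {
  surv <- data.frame(time = c(1, 2, 3), event = 1, group = "a")
  surv2 <- rbind(surv, data.frame(time = c(1.5, 2.5, 3.5), event = 1, group = "b"))
  km <- km_logrank(surv2)
  a <- km$curves[km$curves$group == "a", ]
  expect_equal(a$surv, c(2 / 3, 1 / 3, 0))
  # two identical groups: statistic ~ 0, p ~ 1
  dup <- data.frame(time = rep(c(1, 2, 3, 4), 2), event = 1,
                    group = rep(c("a", "b"), each = 4))
  km2 <- km_logrank(dup)
  expect_lt(km2$chisq, 1e-10)
  expect_gt(km2$p, 0.999)
})

test_that("log-rank statistic reproduces the hand-computed 6-observation table", {
  # times 1..6, events 1,1,0,1,0,1, groups A,A,A,B,B,B; observed-minus-
  # expected by hand: O_A = 2, E_A = 0.5 + 0.4 = 0.9, V = 0.25 + 0.24 = 0.49,
  # chi-square = (2 - 0.9)^2 / 0.49 = 2.469388
  surv <- data.frame(time = 1:6, event = c(1, 1, 0, 1, 0, 1),
                     group = rep(c("A", "B"), each = 3))
  km <- km_logrank(surv)
  expect_equal(km$chisq, 1.21 / 0.49, tolerance = 1e-6)
  expect_equal(km$df, 1L)
  expect_equal(km$p, pchisq(1.21 / 0.49, 1, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("km_logrank validates its inputs", {
  expect_error(km_logrank(data.frame(time = 1:3, event = 1)), "columns")
  expect_error(km_logrank(data.frame(time = 1:3, event = 1, group = "a")), ">= 2")
  expect_error(km_logrank(data.frame(time = 1:4, event = 0, group = rep(c("a", "b"), 2))),
               "at least one event")
  expect_error(km_logrank(data.frame(time = c(-1, 2), event = 1, group = c("a", "b"))),
               "non-negative")
})

test_that("high-signature groups show the worst survival across seeds", {
  hits <- vapply(1:20, function(s) {
    coh <- generate_cohort(cohort_sim_config(n_tumors = 120, seed = 200 + s))
    track <- metagene(coh$bulk, coh$gene_sets$planted)
    g <- expression_groups_tertiles(track)
    surv <- coh$survival
    surv$group <- g[surv$sample_id]
    km <- km_logrank(surv)
    # survival of each group at median follow-up
    at <- median(surv$time)
    sv <- vapply(c("low", "high"), function(grp) {
      cv <- km$curves[km$curves$group == grp & km$curves$time <= at, ]
      if (nrow(cv) == 0) 1 else tail(cv$surv, 1)
    }, numeric(1))
    sv[["high"]] < sv[["low"]]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
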