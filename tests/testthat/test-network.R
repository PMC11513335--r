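test_that("trapezoid weights match the worked examples and invariants", {
  expect_equal(time_weights(c(0, 1, 2, 3)), c(1, 2, 2, 1) / 6)
  expect_equal(time_weights(c(0, 10)), c(0.5, 0.5))
  # equal spacing: interior weights equal, exactly twice the end weights
  for (n in c(2, 5, 37, 200)) {
    w <- time_weights(seq(0, by = 7, length.out = n))
    expect_equal(sum(w), 1)
    if (n > 2) {
      expect_equal(diff(range(w[2:(n - 1)])), 0)
      expect_equal(w[2] / w[1], 2)
    }
  }
  expect_error(time_weights(5), "at least 2")
  expect_error(time_weights(c(3, 3)), "strictly increasing")
})

complete_fixture <- function(n_m = 6, seed = 2, n_s = 15) {
  cfg <- sim_config(n_metabolites = n_m, n_subjects = n_s,
                    modules = if (n_m >= 4)
                      list(list(members = 1:2, loading = 0.7)) else list(),
                    templates = kt_flat(), noise_sd = 0.5, seed = seed)
  sim <- simulate_dataset(cfg)
  log2_values(sim$dataset)
}

test_that("partial correlation matrices are well-formed", {
  ds <- complete_fixture()
  fit <- dyn_pcor(ds)
  expect_equal(fit$pcor, t(fit$pcor))
  expect_equal(diag(fit$pcor), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(abs(fit$pcor) <= 1))
  expect_equal(fit$R, t(fit$R))
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
  expect_equal(fit$n_eff, 15 * 56)
})

test_that("lambda = 0 reproduces the direct-inversion oracle", {
  ds <- complete_fixture()
  fit <- dyn_pcor(ds, lambda = 0)
  oracle <- pcor_det_oracle(fit$R)
  expect_lt(max(abs(fit$pcor - oracle)), 1e-10)
})

test_that("lambda = 1 zeroes all off-diagonal partial correlations", {
  ds <- complete_fixture()
  fit <- dyn_pcor(ds, lambda = 1)
  off <- fit$pcor[upper.tri(fit$pcor)]
  expect_equal(off, rep(0, length(off)))
})

test_that("shrinkage attenuates partial correlations toward zero", {
  # stronger lambda pulls the largest |pcor| down monotonically; individual
  # small entries may wiggle slightly because conditioning renormalizes, so
  # elementwise monotonicity is only required up to a small slack
  ds <- complete_fixture()
  lams <- c(0, 0.2, 0.5, 0.8, 1)
  prev <- NULL
  for (l in lams) {
    pc <- abs(dyn_pcor(ds, lambda = l)$pcor)
    if (!is.null(prev)) {
      expect_lte(max(pc[upper.tri(pc)]), max(prev[upper.tri(prev)]) + 1e-12)
      expect_true(all(pc <= prev + 0.02))
    }
    prev <- pc
  }
  expect_equal(max(abs(prev[upper.tri(prev)])), 0)  # lambda = 1 endpoint
})

test_that("independent metabolites have near-zero partial correlation", {
  cfg <- sim_config(n_metabolites = 2, n_subjects = 15,
                    templates = kt_flat(), noise_sd = 0.5,
                    subject_variability = 0, seed = 23)
  ds <- log2_values(simulate_dataset(cfg)$dataset)
  fit <- dyn_pcor(ds)
  expect_lt(abs(fit$pcor[1, 2]), 0.1)
})

test_that("one-subject equally spaced dynamical correlation is weighted Pearson", {
  set.seed(10)
  n_k <- 24
  v <- array(rnorm(2 * n_k * 3), c(2, n_k, 3))
  design <- build_schedule("uniform", spacing = 30, n_per_block = n_k,
                           subjects = 1:2)
  ds <- tiny_dataset(v, design = design, transform = "log2")
  fit <- dyn_pcor(ds, subjects = NULL)
  # oracle: pooled weighted Pearson with trapezoid weights, per subject
  w <- time_weights(design$timepoints$clock_min)
  covs <- array(0, c(3, 3))
  for (s in 1:2) {
    X <- v[s, , ]
    mu <- colSums(w * X)
    cx <- sweep(X, 2, mu)
    covs <- covs + crossprod(cx, w * cx) / 2
  }
  R_oracle <- cov2cor(covs)
  expect_equal(unname(fit$R), unname(R_oracle), tolerance = 1e-12)
})

test_that("dyn_pcor insists on complete data and sane shapes", {
  ds <- complete_fixture()
  ds$data <- ds$data[-5, ]
  expect_error(dyn_pcor(ds), "complete data")
  ds2 <- complete_fixture()
  expect_error(dyn_pcor(ds2, uids = ds2$catalog$uid[1]), "at least 2")
})

test_that("null model is analytic at kappa = 3 and recovers kappa by MLE", {
  # kappa = 3: density uniform on (-1, 1), p(r) = 1 - |r|
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_lt(max(abs(pcor_pvalue(r, 3) - (1 - abs(r)))), 1e-10)
  expect_equal(pcor_pvalue(0, 42), 1)
  # MLE recovery from f0(kappa = 100) draws
  set.seed(77)
  k <- 100
  draws <- sqrt(rbeta(5000, 0.5, (k - 1) / 2)) * sample(c(-1, 1), 5000, TRUE)
  khat <- fit_null_kappa(draws)$kappa
  expect_gt(khat, 80); expect_lt(khat, 125)
  khat0 <- fit_null_kappa(draws, trim = 0)$kappa
  expect_gt(khat0, 80); expect_lt(khat0, 125)
  expect_error(fit_null_kappa(c(0.5, 1.5, rep(0.1, 60))), "lie in")
  expect_error(fit_null_kappa(rep(0.1, 10)), "at least 50")
})

test_that("cutoff-mode networks threshold the signed partial correlation", {
  ds <- complete_fixture()
  fit <- dyn_pcor(ds)
  # craft a fit with known off-diagonals
  fit$pcor <- diag(4)
  fit$pcor[1, 2] <- fit$pcor[2, 1] <- 0.15
  fit$pcor[1, 3] <- fit$pcor[3, 1] <- 0.10
  fit$pcor[1, 4] <- fit$pcor[4, 1] <- 0.05
  fit$pcor[2, 3] <- fit$pcor[3, 2] <- -0.30
  fit$uids <- fit$uids[1:4]
  net <- build_ggm(fit, mode = "cutoff", cutoff = 0.12)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$pcor, 0.15)
  # absolute option also catches the negative edge
  net2 <- build_ggm(fit, mode = "cutoff", cutoff = 0.12, absolute = TRUE)
  expect_equal(nrow(net2$edges), 2)
  expect_error(build_ggm(fit, mode = "cutoff", cutoff = 1.01), "cutoff")
})

test_that("significance-mode edges honor the Pearson gate", {
  cfg <- module_sim_config(seed = 41, n_metabolites = 20, module_size = 4)
  sim <- simulate_dataset(cfg)
  ds <- impute_knn(impute_linear(filter_missingness(
    log2_values(sim$dataset))))
  fit <- dyn_pcor(ds)
  Rp <- pooled_pearson(ds)
  net <- build_ggm(fit, mode = "significance", correction = "bonferroni",
                   R_plain = Rp, catalog = ds$catalog)
  expect_true(all(net$edges$p_pearson < 0.05))
  expect_true(all(net$edges$p_pcor < 0.05 / choose(20, 2)))
  expect_error(build_ggm(fit, mode = "significance", R_plain = NULL),
               "R_plain")
  # nodes carry catalog attributes
  expect_equal(net$nodes$fluid, rep("P", 20))
})

test_that("multi-fluid merge links matching metabolites across fluids", {
  mknet <- function(names, fluid, kegg = NA) {
    nodes <- data.frame(uid = make_uid(names, fluid, "nt-ms"),
                        fluid = fluid, platform = "nt-ms",
                        display_name = names, kegg = kegg,
                        hmdb = NA_character_, log2fc = NA_real_,
                        neg_log10_p = NA_real_, stringsAsFactors = FALSE)
    structure(list(nodes = nodes,
                   edges = data.frame(uid_a = character(),
                                      uid_b = character(), pcor = numeric(),
                                      pearson_r = numeric(),
                                      p_pcor = numeric(),
                                      p_pearson = numeric(),
                                      edge_type = character()),
                   provenance = list(mode = "cutoff")),
              class = "ggm_network")
  }
  a <- mknet(c("Ala", "B"), "P")
  b <- mknet(c("ala", "C"), "U")
  m <- merge_multifluid(a, b, match_on = "display_name")
  expect_equal(nrow(m$nodes), 4)
  cross <- m$edges[m$edges$edge_type == "same_metabolite", ]
  expect_equal(nrow(cross), 1)  # case-insensitive Ala-ala
  # no shared names: union with no cross edges
  m0 <- merge_multifluid(mknet("X", "P"), mknet("Y", "U"))
  expect_equal(sum(m0$edges$edge_type == "same_metabolite"), 0)
  # two urine isomers sharing one KEGG id vs one plasma node: 2 cross edges
  a2 <- mknet("glucose", "P", kegg = "C00031")
  b2 <- mknet(c("alpha-glucose", "beta-glucose"), "U",
              kegg = c("C00031", "C00031"))
  m2 <- merge_multifluid(a2, b2, match_on = "kegg")
  expect_equal(sum(m2$edges$edge_type == "same_metabolite"), 2)
  expect_error(merge_multifluid(a, a), "disjoint")
  expect_error(merge_multifluid(a, b, match_on = "hmdb"), "absent")
})

test_that("annotation and exports round-trip node and edge counts", {
  cfg <- module_sim_config(seed = 43, n_metabolites = 12, module_size = 4)
  sim <- simulate_dataset(cfg)
  ds <- impute_knn(impute_linear(filter_missingness(
    log2_values(sim$dataset))))
  fit <- dyn_pcor(ds)
  net <- build_ggm(fit, mode = "cutoff", cutoff = 0.1,
                   R_plain = pooled_pearson(ds), catalog = ds$catalog)
  scan <- paired_t_scan(ds, "OGTT")
  tp <- scan$tp[1]
  net <- annotate_ggm(net, scan, tp)
  i <- which(!is.na(net$nodes$log2fc))[1]
  row <- scan[scan$uid == net$nodes$uid[i] & scan$tp == tp, ]
  expect_equal(net$nodes$log2fc[i], row$log2fc)
  expect_equal(net$nodes$neg_log10_p[i], -log10(row$p))
  # a tiny p maps to its exact -log10
  net$nodes$neg_log10_p[1] <- NA
  scan2 <- scan; scan2$p[scan2$uid == net$nodes$uid[1] & scan2$tp == tp] <- 1e-14
  net2 <- annotate_ggm(net, scan2, tp)
  expect_equal(net2$nodes$neg_log10_p[1], 14)

  f <- withr::local_tempfile(fileext = ".graphml")
  export_ggm(net, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_ggm(net, f2, "edge_tsv")
  tsv <- read.delim(f2)
  expect_equal(nrow(tsv), nrow(net$edges))
  expect_named(tsv, c("uid_a", "uid_b", "pcor", "pearson_r", "p_pcor",
                      "p_pearson", "edge_type"))
  f3 <- withr::local_tempfile(fileext = ".json")
  export_ggm(net, f3, "json")
  j <- jsonlite::read_json(f3, simplifyVector = TRUE)
  expect_equal(nrow(j$nodes), nrow(net$nodes))
})
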