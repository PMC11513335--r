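test_that("log2 transform maps values and rejects non-positives", {
  v <- array(c(8, 1, 4, 2), c(1, 4, 1))
  ds <- tiny_dataset(v)
  lg <- log2_values(ds)
  expect_equal(lg$data$value, c(3, 0, 2, 1))
  expect_equal(lg$transform, "log2")
  expect_error(log2_values(lg), "raw-scale")
  v[1, 2, 1] <- 0
  expect_error(tiny_dataset(v), "strictly positive")
})

test_that("outlier rule matches the hand-computed single-tp oracle", {
  # 15 subjects at one tp: 14 zeros and one 10; mean 0.667, sd 2.582
  # (pooled and per-tp SD coincide on a single-tp fixture)
  v <- array(c(rep(0, 14), 10), c(15, 1, 1))
  design <- tiny_design(n_tp = 1, subjects = 1:15)
  # need >= 2 tps for a design; use 2 tps, second fully missing
  v2 <- array(NA_real_, c(15, 2, 1)); v2[, 1, 1] <- c(rep(0, 14), 10)
  ds <- tiny_dataset(v2, design = tiny_design(n_tp = 2, subjects = 1:15),
                     transform = "log2")
  vals <- ds$data$value
  m <- mean(vals); s <- sd(vals)
  expect_equal(m, 10 / 15)
  expect_equal(s, sqrt((14 * m^2 + (10 - m)^2) / 14))
  # |10 - 0.667| = 9.33 < 4 * 2.582 = 10.33: not flagged
  rep <- flag_outliers(ds)
  expect_equal(nrow(rep$flagged), 0)
  rep2 <- flag_outliers(ds, sd_method = "per_tp")
  expect_equal(nrow(rep2$flagged), 0)
})

test_that("multi-timepoint outliers are flagged by the pooled rule", {
  set.seed(5)
  v <- array(rnorm(15 * 8 * 2), c(15, 8, 2))
  v[3, 4, 1] <- v[3, 4, 1] + 8  # gross outlier, ~8 pooled SDs
  ds <- tiny_dataset(v, design = tiny_design(n_tp = 8, subjects = 1:15),
                     transform = "log2")
  rep <- flag_outliers(ds)
  expect_equal(nrow(rep$flagged), 1)
  expect_equal(rep$flagged$subject, 3)
  expect_equal(rep$flagged$tp, 4)
  # flagged entries honor the 4-SD inequality by construction
  expect_true(all(abs(rep$flagged$value - rep$flagged$tp_mean) >
                    4 * rep$flagged$tp_sd))
  # drop_flagged removes exactly the flagged key
  ds2 <- drop_flagged(ds, rep)
  expect_equal(nrow(ds2$data), nrow(ds$data) - 1)
})

test_that("deviant points just after a challenge onset are exempted", {
  # uniform design: challenge onset at the first tp (clock 0); tp 2 is 15 min
  # later, inside the closed 30-min exemption window
  design <- build_schedule("uniform", spacing = 15, n_per_block = 8,
                           subjects = 1:15)
  set.seed(6)
  v <- array(rnorm(15 * 8 * 1), c(15, 8, 1))
  v[5, 2, 1] <- v[5, 2, 1] + 10
  v[5, 6, 1] <- v[5, 6, 1] + 10  # 75 min: outside the window
  ds <- tiny_dataset(v, design = design, transform = "log2")
  rep <- flag_outliers(ds)
  expect_equal(nrow(rep$exempted), 1)
  expect_equal(rep$exempted$tp, 2)
  expect_equal(rep$flagged$tp, 6)
})

test_that("degenerate outlier groups are skipped", {
  # 2 subjects only: every group has n < 3
  v <- array(c(0, 100, 0, 100), c(2, 2, 1))
  ds <- tiny_dataset(v, design = tiny_design(n_tp = 2, subjects = 1:2),
                     transform = "log2")
  rep <- flag_outliers(ds)
  expect_equal(nrow(rep$flagged), 0)
  expect_gt(rep$n_groups_skipped, 0)
})

test_that("missingness filter applies a strict less-than rule", {
  design <- tiny_design(n_tp = 10, subjects = 1:100)
  cat <- metabolite_catalog(c("keep", "edge", "drop", "full"))
  grid <- expand.grid(subject = 1:100, tp = 1:10, stringsAsFactors = FALSE)
  mk <- function(uid, n_missing) {
    g <- grid; g$uid <- uid; g$value <- 1 + g$subject / 1000
    g[seq_len(nrow(g)) > n_missing, ]
  }
  # 1000 scheduled samples each: 299 (29.9%), 300 (30.0%), 301, 0 missing
  data <- rbind(mk(cat$uid[1], 299), mk(cat$uid[2], 300),
                mk(cat$uid[3], 301), mk(cat$uid[4], 0))
  ds <- profile_dataset(cat, design, data)
  kept <- filter_missingness(ds, 0.30)$catalog$display_name
  expect_setequal(kept, c("keep", "full"))
})

test_that("z-scoring standardizes every metabolite exactly", {
  set.seed(2)
  v <- array(rnorm(3 * 6 * 4, mean = 8, sd = 2), c(3, 6, 4))
  v[2, 3, 2] <- NA
  ds <- tiny_dataset(v, transform = "log2")
  zs <- transform_values(ds, "zscore")
  expect_equal(zs$transform, "zscore")
  for (u in zs$catalog$uid) {
    x <- zs$data$value[zs$data$uid == u]
    expect_lt(abs(mean(x)), 1e-8)
    expect_lt(abs(sd(x) - 1), 1e-8)
  }
  # constant metabolite cannot be standardized: all-missing with a warning
  v[, , 1] <- 5
  ds2 <- tiny_dataset(v, transform = "log2")
  expect_warning(z2 <- transform_values(ds2, "zscore"), "zero-variance")
  expect_false(ds2$catalog$uid[1] %in% z2$data$uid)
})

test_that("fold changes subtract the block and challenge references", {
  design <- build_schedule("uniform", spacing = 60, n_per_block = 4,
                           n_blocks = 2, subjects = 1)
  v <- array(NA_real_, c(1, 8, 1))
  v[1, , 1] <- c(3, 5, 4, 6, 10, 11, 9, 12)
  ds <- tiny_dataset(v, design = design, transform = "log2")
  fb <- transform_values(ds, "log2fc_block")
  expect_equal(fb$data$value, c(0, 2, 1, 3, 0, 1, -1, 2))
  fc <- transform_values(ds, "log2fc_challenge")
  # one challenge per block, baseline = first tp: same references here
  expect_equal(fc$data$value[fc$data$tp == 1], 0)  # baseline maps to 0
  expect_equal(fc$data$value[fc$data$tp == 2], 2)
  # missing reference propagates: drop baseline of block 2
  ds2 <- ds; ds2$data <- ds$data[ds$data$tp != 5, ]
  fb2 <- transform_values(ds2, "log2fc_block")
  expect_false(any(fb2$data$tp %in% 6:8))
})

test_that("linear imputation interpolates interior gaps only", {
  design <- build_schedule("uniform", spacing = 30, n_per_block = 4,
                           subjects = 1)
  # observed at t=0 (1) and t=90 (4); missing at 30 and 60
  v <- array(c(1, NA, NA, 4), c(1, 4, 1))
  ds <- tiny_dataset(v, design = design, transform = "log2")
  li <- impute_linear(ds)
  expect_equal(li$data$value[li$data$tp == 2], 2)  # 1 + 3 * 30/90
  expect_equal(li$data$value[li$data$tp == 3], 3)
  # trailing gap stays missing
  v2 <- array(c(1, 2, NA, NA), c(1, 4, 1))
  li2 <- impute_linear(tiny_dataset(v2, design = design, transform = "log2"))
  expect_equal(nrow(li2$data), 2)
  # observed values never touched
  expect_equal(li$data$value[li$data$tp %in% c(1, 4)], c(1, 4))
})

test_that("linear imputation is exact on piecewise-linear signals", {
  design <- build_schedule("uniform", spacing = 10, n_per_block = 12,
                           subjects = 1:3)
  t <- design$timepoints$clock_min
  v <- array(NA_real_, c(3, 12, 2))
  for (s in 1:3) {
    v[s, , 1] <- 2 + 0.05 * t + s          # linear
    v[s, , 2] <- pmax(1, 0.1 * (t - 40))   # piecewise linear, kink at t=40
  }
  full <- tiny_dataset(v, design = design, transform = "log2")
  holey <- full
  set.seed(9)
  # drop interior points away from the kink so segments stay linear
  drop <- holey$data$tp %in% c(3, 4, 8, 10) & holey$data$subject == 2
  holey$data <- holey$data[!drop, ]
  li <- impute_linear(holey)
  o1 <- full$data[order(full$data$uid, full$data$subject, full$data$tp), ]
  o2 <- li$data[order(li$data$uid, li$data$subject, li$data$tp), ]
  expect_equal(o2$value, o1$value, tolerance = 1e-12)
})

test_that("KNN imputation uses nearest samples and sensible fallbacks", {
  # target missing in one sample; 11 other samples identical in the
  # preselected metabolites, target value 4 everywhere
  set.seed(11)
  n_s <- 12
  v <- array(NA_real_, c(n_s, 2, 6))
  for (m in 2:6) v[, , m] <- matrix(rnorm(n_s * 2), n_s, 2)
  v[, , 1] <- v[, , 2] + rnorm(n_s * 2, sd = 0.01)  # correlated with m2
  v[1, 1, 1] <- NA
  ds <- tiny_dataset(v, design = tiny_design(n_tp = 2, subjects = 1:n_s),
                     transform = "log2")
  kn <- impute_knn(ds, k = 3, n_preselect = 1, min_complete_pairs = 5)
  imp <- kn$data$value[kn$data$subject == 1 & kn$data$tp == 1 &
                         kn$data$uid == ds$catalog$uid[1]]
  expect_length(imp, 1)
  # the imputed value should be close to the correlated partner's value
  expect_lt(abs(imp - v[1, 1, 2]), 0.6)
  # observed values untouched
  shared <- merge(ds$data, kn$data, by = c("subject", "tp", "uid"))
  expect_equal(shared$value.x, shared$value.y)

  # k = 1 picks the nearest sample exactly: candidate at anchor-distance 0
  # carries target value 2, the distant ones carry 8
  v2 <- array(NA_real_, c(2, 2, 2))
  v2[, 1, 2] <- c(0, 0); v2[, 2, 2] <- c(99, 99)   # distance anchor
  v2[, 1, 1] <- c(NA, 2); v2[, 2, 1] <- c(8, 8)
  ds2 <- tiny_dataset(v2, design = tiny_design(n_tp = 2, subjects = 1:2),
                      transform = "log2")
  kn2 <- impute_knn(ds2, k = 1, n_preselect = 1, min_complete_pairs = 3)
  imp2 <- kn2$data$value[kn2$data$subject == 1 & kn2$data$tp == 1 &
                           kn2$data$uid == ds2$catalog$uid[1]]
  expect_equal(imp2, 2)

  # entirely missing metabolite stays missing, with a warning
  v3 <- array(rnorm(12), c(3, 2, 2)); v3[, , 1] <- NA
  ds3 <- tiny_dataset(v3, design = tiny_design(n_tp = 2, subjects = 1:3),
                      transform = "log2")
  expect_warning(kn3 <- impute_knn(ds3), "entirely missing")
  expect_false(ds3$catalog$uid[1] %in% kn3$data$uid)
})

test_that("injected gross outliers are recovered with full recall", {
  cfg <- module_sim_config(seed = 31, n_metabolites = 15)
  sim <- simulate_dataset(cfg)
  # inject outside all exemption windows (challenge onsets +30 min)
  d <- sim$dataset$design
  exempt_tps <- unlist(lapply(d$challenges, function(ch) {
    blk <- d$timepoints$block[match(ch$baseline_tp, d$timepoints$index)]
    d$timepoints$index[d$timepoints$block == blk &
      d$timepoints$clock_min >= ch$onset_clock_min &
      d$timepoints$clock_min <= ch$onset_clock_min + 30]
  }))
  free_tps <- setdiff(d$timepoints$index[d$timepoints$plasma], exempt_tps)
  inj <- inject_outliers(sim$dataset, rate = 0.003,
                         magnitude_sd_multiples = 6, seed = 17,
                         tps = free_tps)
  expect_gt(nrow(inj$injected), 3)
  rep <- flag_outliers(log2_values(inj$dataset))
  fkey <- with(rep$flagged, paste(subject, tp, uid))
  ikey <- with(inj$injected, paste(subject, tp, uid))
  expect_true(all(ikey %in% fkey))  # recall 1.0
})

test_that("null-data false-flag rate stays within the Gaussian bound", {
  # 1e5 Gaussian points, no outliers: expected flags <= 1.5 * P(|Z|>4) * n
  set.seed(123)
  n_s <- 15; n_tp <- 30; n_m <- 223  # 100,350 points
  v <- array(rnorm(n_s * n_tp * n_m), c(n_s, n_tp, n_m))
  ds <- tiny_dataset(v, design = tiny_design(n_tp = n_tp, subjects = 1:n_s),
                     transform = "log2")
  rep <- flag_outliers(ds)
  bound <- 1.5 * 2 * pnorm(-4) * (n_s * n_tp * n_m)
  expect_lte(nrow(rep$flagged), bound)
})
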