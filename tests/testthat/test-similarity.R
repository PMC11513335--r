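test_that("banded Frechet distance matches hand-enumerable cases", {
  P <- curve_df(c(0, 30), c(0, 1))
  Q <- curve_df(c(0, 30), c(0.5, 0.9))
  # identity
  expect_equal(banded_frechet(P, P), 0)
  # all monotone couplings enumerated by hand give 0.5
  expect_equal(banded_frechet(P, Q, window = 30), 0.5)
  expect_equal(frechet_oracle(P, Q, 30), 0.5)
  # empty curve is an error
  expect_error(banded_frechet(P[0, ], Q), "non-empty")
  # no finite coupling: times too far apart for the band
  R <- curve_df(c(500, 530), c(0, 1))
  expect_equal(banded_frechet(P, R, window = 30), Inf)
})

test_that("W = 0 on identical grids reduces to the Chebyshev distance", {
  set.seed(4)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    t <- cumsum(runif(n, 1, 30))
    x <- curve_df(t, rnorm(n)); y <- curve_df(t, rnorm(n))
    expect_equal(banded_frechet(x, y, window = 0),
                 max(abs(x$value - y$value)))
  }
})

test_that("Frechet distance is symmetric and monotone in the window", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    P <- curve_df(sort(sample(0:20, n)) * 10, rnorm(n))
    Q <- curve_df(sort(sample(0:20, m)) * 10, rnorm(m))
    prev <- Inf
    for (w in c(0, 20, 50, 200, Inf)) {
      d <- banded_frechet(P, Q, window = w)
      dT <- banded_frechet(Q, P, window = w)
      expect_identical(d, dT)
      expect_lte(d, prev)
      expect_gte(d, 0)
      prev <- d
    }
    # with an unbounded window the distance never exceeds Chebyshev on
    # identical grids
    if (n == m && all(P$time == Q$time))
      expect_lte(banded_frechet(P, Q, window = Inf),
                 max(abs(P$value - Q$value)))
  }
})

test_that("the fasting span widens the matching window", {
  # points 60 min apart: unmatchable at the 30-min band, matchable at 120
  P <- curve_df(c(0, 100), c(0, 1))
  Q <- curve_df(c(60, 160), c(0, 1))
  expect_equal(banded_frechet(P, Q, window = 30, fasting_window = 120,
                              fasting_span = NULL), Inf)
  expect_lt(banded_frechet(P, Q, window = 30, fasting_window = 120,
                           fasting_span = c(0, 200)), Inf)
})

test_that("pointwise measures match their definitions", {
  expect_equal(pointwise_distance(1:3, 1:3, "euclidean"), 0)
  expect_equal(pointwise_distance(1:3, 1:3, "manhattan"), 0)
  expect_equal(pointwise_distance(1:3, 1:3, "pearson"), 1)
  expect_equal(pointwise_distance(c(0, 1), c(1, 0), "euclidean"), sqrt(2))
  expect_equal(pointwise_distance(c(0, 1), c(1, 0), "manhattan"), 2)
  expect_equal(pointwise_distance(c(1, 2, 3), c(2, 4, 6), "pearson"), 1)
  expect_error(pointwise_distance(1:3, 1:4, "euclidean"), "length")
  expect_error(pointwise_distance(c(1, 2), c(2, 1), "pearson"), "at least 3")
})

zscored_fixture <- function(v, design = NULL) {
  ds <- tiny_dataset(v, design = design, transform = "log2")
  suppressWarnings(transform_values(ds, "zscore"))
}

test_that("per-subject aggregation averages per-subject scores", {
  # 3 subjects, 5 tps, 2 metabolites; hand-checkable Pearson per subject
  set.seed(14)
  v <- array(NA_real_, c(3, 5, 2))
  v[1, , 1] <- c(1, 2, 3, 4, 5);  v[1, , 2] <- c(2, 4, 6, 8, 10)    # r = 1
  v[2, , 1] <- c(1, 2, 3, 4, 5);  v[2, , 2] <- c(5, 4, 3, 2, 1)     # r = -1
  v[3, , 1] <- c(1, 2, 1, 2, 1);  v[3, , 2] <- c(1, 2, 1, 2, 30)    # r = ?
  r3 <- cor(v[3, , 1], v[3, , 2])
  ds <- zscored_fixture(v, design = tiny_design(n_tp = 5, subjects = 1:3))
  res <- trajectory_similarity(ds, ds$catalog$uid[1], ds$catalog$uid[2],
                               measure = "pearson",
                               mode = "per_subject_mean")
  expect_equal(res$n_subjects_used, 3)
  expect_equal(res$score, mean(c(1, -1, r3)))
})

test_that("subjects with too few shared points are excluded", {
  v <- array(NA_real_, c(2, 5, 2))
  v[1, , 1] <- c(1, 2, 3, 4, 5); v[1, , 2] <- c(1, 3, 2, 5, 4)
  v[2, 1:2, 1] <- c(1, 2); v[2, 1:2, 2] <- c(2, 1)  # only 2 shared points
  ds <- zscored_fixture(v, design = tiny_design(n_tp = 5, subjects = 1:2))
  res <- trajectory_similarity(ds, ds$catalog$uid[1], ds$catalog$uid[2],
                               measure = "euclidean",
                               mode = "per_subject_mean")
  expect_equal(res$n_subjects_used, 1)
  # no subject retained -> insufficient overlap
  v2 <- v; v2[1, 3:5, 2] <- NA
  ds2 <- zscored_fixture(v2, design = tiny_design(n_tp = 5, subjects = 1:2))
  expect_error(trajectory_similarity(ds2, ds2$catalog$uid[1],
                                     ds2$catalog$uid[2],
                                     measure = "euclidean",
                                     mode = "per_subject_mean"),
               "insufficient overlap")
})

test_that("two per-subject distances average to their mean", {
  # euclidean distances 1 and 3 across two subjects -> 2
  v <- array(NA_real_, c(2, 4, 2))
  v[1, , 1] <- c(0, 0, 0, 0); v[1, , 2] <- c(1, 0, 0, 0)
  v[2, , 1] <- c(0, 0, 0, 0); v[2, , 2] <- c(3, 0, 0, 0)
  ds <- tiny_dataset(v, design = tiny_design(n_tp = 4, subjects = 1:2),
                     transform = "zscore")  # treat as already scaled
  res <- trajectory_similarity(ds, ds$catalog$uid[1], ds$catalog$uid[2],
                               measure = "euclidean",
                               mode = "per_subject_mean")
  expect_equal(res$score, 2)
})

test_that("ranking orders scores with lexicographic tie-breaks", {
  # candidates: identical copy (score 0), two equidistant, one far
  v <- array(NA_real_, c(2, 4, 5))
  base <- c(0, 1, 0, -1)
  v[1, , 1] <- base; v[2, , 1] <- base
  v[1, , 2] <- base; v[2, , 2] <- base                    # identical
  v[1, , 3] <- base + 0.5; v[2, , 3] <- base + 0.5        # tie a
  v[1, , 4] <- base - 0.5; v[2, , 4] <- base - 0.5        # tie b
  v[1, , 5] <- base + 3;   v[2, , 5] <- base + 3          # far
  ds <- tiny_dataset(v, design = tiny_design(n_tp = 4, subjects = 1:2),
                     transform = "zscore")
  uids <- ds$catalog$uid
  rk <- rank_similar(ds, uids[1], candidates = uids,
                     measure = "frechet", mode = "mean_trajectory")
  # self and its identical copy tie at 0, broken lexicographically
  expect_equal(rk$uid[1:2], sort(uids[1:2]))
  expect_equal(rk$score[1:2], c(0, 0))
  expect_equal(rk$uid[3:4], sort(uids[3:4]))  # tie broken by uid
  expect_equal(rk$score[3:4], c(0.5, 0.5))
  expect_equal(rk$uid[5], uids[5])
  expect_equal(rk$rank, 1:5)
  expect_error(rank_similar(ds, "nope"), "unknown uid")
})

test_that("candidates without computable scores are listed last as NA", {
  v <- array(NA_real_, c(2, 4, 3))
  v[1, , 1] <- c(0, 1, 0, 1); v[2, , 1] <- c(0, 1, 0, 1)
  v[1, , 2] <- c(1, 0, 1, 0); v[2, , 2] <- c(1, 0, 1, 0)
  v[1, 1, 3] <- 1  # single shared point: insufficient for pearson
  ds <- tiny_dataset(v, design = tiny_design(n_tp = 4, subjects = 1:2),
                     transform = "zscore")
  uids <- ds$catalog$uid
  rk <- rank_similar(ds, uids[1], candidates = uids[2:3],
                     measure = "pearson", mode = "mean_trajectory")
  expect_equal(rk$uid, c(uids[2], uids[3]))
  expect_true(is.na(rk$score[2]))
  expect_true(is.na(rk$rank[2]))
})
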