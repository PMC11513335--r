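#' Time-banded discrete Frechet distance
#'
#' Discrete Frechet distance between two time-stamped curves, computed by
#' dynamic programming over monotone couplings,
#' \deqn{c(i,j) = \max(d(i,j), \min(c(i-1,j), c(i,j-1), c(i-1,j-1)))}
#' with point cost \eqn{d(i,j) = |v_i - u_j|} when the two time stamps differ
#' by at most the window, and infinite otherwise. The window is
#' \code{fasting_window} when either stamp lies inside the extended-fasting
#' span and \code{window} everywhere else, so points may only be matched
#' within +/- 30 min in general and +/- 120 min during extended fasting (the
#' defaults). Time enters only through the band; the cost itself compares
#' values (z-score units upstream). Returns \code{Inf} when no finite
#' monotone coupling exists (e.g. curves from different study blocks).
#'
#' @param P,Q data.frames (or matrices) with columns \code{time} and
#'   \code{value} (a \code{t}/\code{v} pair of columns also works), times
#'   strictly increasing on the common study axis.
#' @param window default matching window (min).
#' @param fasting_window widened window during extended fasting (min).
#' @param fasting_span optional numeric length-2 study-time interval of the
#'   fasting challenge (see [fasting_span()]); \code{NULL} disables widening.
#' @return The banded discrete Frechet distance (non-negative, possibly
#'   \code{Inf}).
#' @export
banded_frechet <- function(P, Q, window = 30, fasting_window = 120,
                           fasting_span = NULL) {
  P <- curve_tv(P); Q <- curve_tv(Q)
  n <- nrow(P); m <- nrow(Q)
  if (n == 0 || m == 0) stop("curves must be non-empty")
  ## per-pair window
  W <- matrix(window, n, m)
  if (!is.null(fasting_span)) {
    inP <- P$t >= fasting_span[1] & P$t <= fasting_span[2]
    inQ <- Q$t >= fasting_span[1] & Q$t <= fasting_span[2]
    W[outer(inP, inQ, "|")] <- fasting_window
  }
  dt <- abs(outer(P$t, Q$t, "-"))
  cost <- abs(outer(P$v, Q$v, "-"))
  cost[dt > W] <- Inf
  ## dynamic programme
  C <- matrix(Inf, n, m)
  C[1, 1] <- cost[1, 1]
  if (m > 1) C[1, ] <- cummax(cost[1, ])
  if (n > 1) C[, 1] <- cummax(cost[, 1])
  if (n > 1 && m > 1) {
    for (i in 2:n) for (j in 2:m)
      C[i, j] <- max(cost[i, j], min(C[i - 1, j], C[i, j - 1],
                                     C[i - 1, j - 1]))
  }
  C[n, m]
}

curve_tv <- function(x) {
  x <- as.data.frame(x)
  tcol <- intersect(c("time", "t"), names(x))[1]
  vcol <- intersect(c("value", "v"), names(x))[1]
  if (is.na(tcol) || is.na(vcol)) {
    if (ncol(x) >= 2) { tcol <- names(x)[1]; vcol <- names(x)[2] }
    else stop("a curve needs time and value columns")
  }
  out <- data.frame(t = as.numeric(x[[tcol]]), v = as.numeric(x[[vcol]]))
  if (nrow(out) > 1 && any(diff(out$t) <= 0))
    stop("curve times must be strictly increasing")
  out
}

#' Pointwise distance / correlation between aligned value vectors
#'
#' @param x,y numeric vectors of equal length, aligned on shared observed time
#'   points (length >= 2; >= 3 for Pearson).
#' @param metric \code{euclidean}, \code{manhattan} or \code{pearson}.
#' @export
pointwise_distance <- function(x, y, metric = c("euclidean", "manhattan",
                                                "pearson")) {
  metric <- match.arg(metric)
  if (length(x) != length(y)) stop("x and y must have the same length")
  min_n <- if (metric == "pearson") 3 else 2
  if (length(x) < min_n)
    stop("need at least ", min_n, " aligned points for ", metric)
  switch(metric,
         euclidean = sqrt(sum((x - y)^2)),
         manhattan = sum(abs(x - y)),
         pearson = stats::cor(x, y))
}

#' Similarity of two metabolite trajectories
#'
#' Two aggregation modes follow the two ways per-subject time courses can be
#' reduced to one score: \code{per_subject_mean} computes the measure within
#' each chosen subject on the time points where both metabolites are observed
#' (subjects with fewer than \code{min_shared} shared points are skipped) and
#' averages across retained subjects; \code{mean_trajectory} first averages
#' the z-scores across subjects at each time point and applies the measure
#' once to the two mean curves. The Frechet measure uses the full (possibly
#' different) time grids with the time band of [banded_frechet()]; the
#' pointwise measures align on shared time points.
#'
#' @param ds a z-scored [profile_dataset()].
#' @param ref,cand metabolite uids.
#' @param measure \code{frechet}, \code{euclidean}, \code{manhattan} or
#'   \code{pearson}.
#' @param mode \code{mean_trajectory} (default) or \code{per_subject_mean}.
#' @param subjects subjects used (default: all in the data).
#' @param tps optional time-point restriction.
#' @param window,fasting_window Frechet band (min).
#' @param min_shared minimum shared observed points per subject.
#' @return list with \code{score} and \code{n_subjects_used}.
#' @export
trajectory_similarity <- function(ds, ref, cand,
                                  measure = c("frechet", "euclidean",
                                              "manhattan", "pearson"),
                                  mode = c("mean_trajectory",
                                           "per_subject_mean"),
                                  subjects = NULL, tps = NULL, window = 30,
                                  fasting_window = 120, min_shared = 3) {
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  if (ds$transform != "zscore")
    stop("trajectory similarity operates on z-scored data; run ",
         "transform_values(ds, 'zscore') first")
  for (u in c(ref, cand)) if (!u %in% ds$catalog$uid) stop("unknown uid: ", u)
  if (is.null(subjects)) subjects <- sort(unique(ds$data$subject))
  span <- fasting_span(ds$design)
  score_pair <- function(a, b) {
    if (measure == "frechet")
      return(banded_frechet(a, b, window, fasting_window, span))
    shared <- merge(a, b, by = "time")
    min_n <- max(min_shared, if (measure == "pearson") 3 else 2)
    if (nrow(shared) < min_n) return(NA_real_)
    pointwise_distance(shared$value.x, shared$value.y, measure)
  }
  if (mode == "mean_trajectory") {
    sds <- subset(ds, subjects = subjects)
    a <- trajectory(sds, ref, "mean", tps = tps)
    b <- trajectory(sds, cand, "mean", tps = tps)
    if (nrow(a) == 0 || nrow(b) == 0)
      stop("insufficient overlap: empty mean trajectory")
    s <- score_pair(a, b)
    if (is.na(s)) stop("insufficient overlap between mean trajectories")
    return(list(score = s, n_subjects_used = length(subjects)))
  }
  scores <- numeric(0)
  for (s in subjects) {
    a <- trajectory(ds, ref, s, tps = tps)
    b <- trajectory(ds, cand, s, tps = tps)
    shared_n <- length(intersect(a$tp, b$tp))
    if (shared_n < min_shared) next
    if (measure == "frechet") {
      keep <- intersect(a$tp, b$tp)
      a <- a[a$tp %in% keep, ]; b <- b[b$tp %in% keep, ]
    }
    v <- score_pair(a, b)
    if (!is.na(v)) scores <- c(scores, v)
  }
  if (length(scores) == 0)
    stop("insufficient overlap: no subject retained")
  list(score = mean(scores), n_subjects_used = length(scores))
}

#' Rank candidate metabolites by trajectory similarity
#'
#' Scores every candidate against the reference and returns them ranked:
#' ascending for distances, descending for Pearson correlation; ties broken by
#' uid; candidates failing the overlap rules are listed last with \code{NA}
#' score.
#'
#' @inheritParams trajectory_similarity
#' @param candidates candidate uids (may include the reference).
#' @return data.frame of class \code{similarity_result} with columns
#'   \code{uid}, \code{score}, \code{rank}, \code{n_subjects_used}, plus
#'   attributes \code{reference}, \code{measure}, \code{mode}.
#' @export
rank_similar <- function(ds, ref, candidates = setdiff(ds$catalog$uid, ref),
                         measure = c("frechet", "euclidean", "manhattan",
                                     "pearson"),
                         mode = c("mean_trajectory", "per_subject_mean"),
                         subjects = NULL, tps = NULL, window = 30,
                         fasting_window = 120, min_shared = 3) {
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  if (!ref %in% ds$catalog$uid) stop("unknown uid: ", ref)
  rows <- lapply(candidates, function(u) {
    r <- tryCatch(
      trajectory_similarity(ds, ref, u, measure, mode, subjects, tps,
                            window, fasting_window, min_shared),
      error = function(e) list(score = NA_real_, n_subjects_used = 0L))
    data.frame(uid = u, score = r$score,
               n_subjects_used = r$n_subjects_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  decreasing <- measure == "pearson"
  o <- order(is.na(out$score),
             if (decreasing) -out$score else out$score, out$uid)
  out <- out[o, , drop = FALSE]
  out$rank <- ifelse(is.na(out$score), NA_integer_, seq_len(nrow(out)))
  rownames(out) <- NULL
  structure(out[, c("uid", "score", "rank", "n_subjects_used")],
            reference = ref, measure = measure, mode = mode,
            class = c("similarity_result", "data.frame"))
}

#' @export
print.similarity_result <- function(x, n = 10, ...) {
  cat("Similarity ranking (", attr(x, "measure"), ", ", attr(x, "mode"),
      ") against ", attr(x, "reference"), "\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}
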