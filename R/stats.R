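#' Reactive Bonferroni threshold
#'
#' The Bonferroni-corrected significance level for a challenge scan is
#' \code{alpha / (n_metabolites * n_timepoints)}, computed from the number of
#' metabolites and time points actually submitted to the scan.
#'
#' @param n_metabolites,n_timepoints counts of the submitted scan.
#' @param alpha family-wise error rate (default 0.05).
#' @examples
#' bonferroni_threshold(2656, 1)  # 1.88e-05
#' @export
bonferroni_threshold <- function(n_metabolites, n_timepoints = 1,
                                 alpha = 0.05) {
  stopifnot(n_metabolites >= 1, n_timepoints >= 1)
  alpha / (n_metabolites * n_timepoints)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement (delegates to \code{stats::p.adjust}).
#'
#' @param p p-values in [0, 1].
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Paired t-test scan of a challenge window
#'
#' For every metabolite and tested time point of a challenge, tests the paired
#' difference of log2 values at the time point versus the challenge baseline,
#' over the subjects with both values observed. Results with fewer than 3
#' pairs, or with zero-variance differences, carry null statistics (NA).
#' The Bonferroni threshold is reactive: 0.05 divided by the scan's actual
#' metabolite x time point count. Benjamini-Hochberg q-values are computed
#' over all non-null p-values of the scan.
#'
#' @param ds a log2-scale (imputed or not) [profile_dataset()].
#' @param challenge challenge name.
#' @param tps \code{"all"} (every tested time point of the window) or a subset
#'   of tested time-point indices.
#' @param design defaults to the dataset's design.
#' @return data.frame of class \code{challenge_scan}: one row per (uid, tp)
#'   with \code{n_pairs}, \code{log2fc}, \code{t_stat}, \code{p}, \code{q_bh},
#'   \code{significant_bonf}, \code{significant_fdr}; the reactive threshold
#'   is in \code{attr(, "p_bonf_threshold")}.
#' @export
paired_t_scan <- function(ds, challenge, tps = "all", design = ds$design) {
  if (!ds$transform %in% c("log2"))
    stop("paired_t_scan expects log2-scale data")
  ch <- find_challenge(design, challenge)
  tested <- if (identical(tps, "all")) ch$tested_tps else as.integer(tps)
  bad <- setdiff(tested, ch$tested_tps)
  if (length(bad) > 0)
    stop("time point ", bad[1], " is not in the tested period of ", ch$name)
  d <- ds$data
  base <- d[d$tp == ch$baseline_tp, c("subject", "uid", "value")]
  names(base)[3] <- "base"
  uids <- ds$catalog$uid
  rows <- vector("list", length(uids) * length(tested))
  r <- 0
  for (tp in tested) {
    cur <- d[d$tp == tp, c("subject", "uid", "value")]
    mg <- merge(cur, base, by = c("subject", "uid"))
    dl <- split(mg$value - mg$base, factor(mg$uid, levels = uids))
    for (u in uids) {
      diffs <- dl[[u]]
      r <- r + 1
      n <- length(diffs)
      if (n < 3 || stats::sd(diffs) == 0) {
        if (n >= 3 && stats::sd(diffs) == 0)
          warning("zero-variance differences for ", u, " at tp ", tp,
                  "; null result")
        rows[[r]] <- data.frame(uid = u, challenge = ch$name, tp = tp,
                                n_pairs = n, log2fc = if (n > 0) mean(diffs)
                                else NA_real_,
                                t_stat = NA_real_, p = NA_real_,
                                stringsAsFactors = FALSE)
      } else {
        tt <- mean(diffs) / (stats::sd(diffs) / sqrt(n))
        p <- 2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE)
        rows[[r]] <- data.frame(uid = u, challenge = ch$name, tp = tp,
                                n_pairs = n, log2fc = mean(diffs),
                                t_stat = tt, p = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  thr <- bonferroni_threshold(length(uids), length(tested))
  out$q_bh <- NA_real_
  nn <- !is.na(out$p)
  out$q_bh[nn] <- adjust_bh(out$p[nn])
  out$significant_bonf <- !is.na(out$p) & out$p < thr
  out$significant_fdr <- !is.na(out$q_bh) & out$q_bh < 0.05
  rownames(out) <- NULL
  structure(out, p_bonf_threshold = thr,
            class = c("challenge_scan", "data.frame"))
}

#' Volcano-plot export of a scan
#'
#' @param scan a [paired_t_scan()] result.
#' @return data.frame (uid, challenge, tp, log2fc, neg_log10_p) with exactly
#'   the non-null scan rows.
#' @export
volcano_table <- function(scan) {
  s <- scan[!is.na(scan$p), , drop = FALSE]
  data.frame(uid = s$uid, challenge = s$challenge, tp = s$tp,
             log2fc = s$log2fc, neg_log10_p = -log10(s$p),
             stringsAsFactors = FALSE)
}

#' Hedges-corrected paired effect size
#'
#' Cohen's d for paired differences, \code{d = mean(diff) / sd(diff)}, with
#' the small-sample Hedges correction
#' \code{d_corrected = d * (n - 2) / (n - 1.25)}.
#'
#' @param diffs per-subject paired differences (length >= 3, positive SD).
#' @return list with \code{d}, \code{d_corrected}, \code{n_subjects}.
#' @export
hedges_d <- function(diffs) {
  n <- length(diffs)
  if (n < 3) stop("need at least 3 paired differences")
  s <- stats::sd(diffs)
  if (s == 0) stop("zero-variance differences: effect size undefined")
  d <- mean(diffs) / s
  list(d = d, d_corrected = d * (n - 2) / (n - 1.25), n_subjects = n)
}

#' Power of a two-sided paired t-test
#'
#' Exact power under the noncentral t distribution, with both rejection tails
#' included: \eqn{P(|T'| > t_{1-\alpha/2, n-1})} with noncentrality
#' \eqn{d\sqrt{n}}.
#'
#' @param n number of pairs (may be fractional; df = n - 1).
#' @param d standardized paired effect size.
#' @param alpha two-sided significance level.
#' @export
power_paired_t <- function(n, d, alpha = 0.05) {
  stopifnot(n > 1, alpha > 0, alpha < 1)
  tq <- stats::qt(1 - alpha / 2, df = n - 1)
  ncp <- d * sqrt(n)
  stats::pt(tq, df = n - 1, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tq, df = n - 1, ncp = ncp)
}

#' Sample size for a paired t-test
#'
#' Smallest (continuous) n >= 2 whose two-sided noncentral-t power reaches the
#' target, found by bracketing and bisection to a tolerance of 1e-4 on n;
#' returns the fractional solution and its ceiling.
#'
#' @param d_corrected standardized (bias-corrected) paired effect size, != 0.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return list with \code{n_fractional} and \code{n_ceiling}.
#' @examples
#' solve_n_for_power(0.94545, alpha = 0.05)  # ~ 11 subjects
#' @export
solve_n_for_power <- function(d_corrected, alpha = 0.05, power = 0.8) {
  stopifnot(d_corrected != 0, alpha > 0, alpha < 1, power > 0, power < 1)
  d <- abs(d_corrected)
  f <- function(n) power_paired_t(n, d, alpha) - power
  lo <- 2
  if (f(lo) >= 0) return(list(n_fractional = 2, n_ceiling = 2L))
  hi <- 4
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e7) stop("no solution below n = 1e7")
  }
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  list(n_fractional = hi, n_ceiling = as.integer(ceiling(hi)))
}
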