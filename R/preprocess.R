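#' Log2-transform a raw dataset
#'
#' @param ds a raw-scale [profile_dataset()].
#' @return The dataset with \code{value <- log2(value)} and transform tag
#'   \code{log2}.
#' @export
log2_values <- function(ds) {
  if (ds$transform != "raw")
    stop("log2_values expects a raw-scale dataset (got '", ds$transform, "')")
  bad <- which(ds$data$value <= 0)
  if (length(bad) > 0)
    stop("non-positive value at (subject ", ds$data$subject[bad[1]], ", tp ",
         ds$data$tp[bad[1]], ", ", ds$data$uid[bad[1]], ")")
  out <- ds
  out$data$value <- log2(ds$data$value)
  out$transform <- "log2"
  out
}

## pooled residual SD per uid: residuals around (uid, tp) means, SS pooled
## over that uid's time points, denominator sum(n_tp - 1); returned aligned
## with the input rows
pooled_residual_sd <- function(values, uid, grp) {
  mean_g <- stats::ave(values, grp, FUN = mean)
  n_g <- stats::ave(values, grp, FUN = length)
  res2 <- (values - mean_g)^2
  ss <- tapply(res2, uid, sum)
  ## df: one (n_tp - 1) contribution per group; count each group once
  first <- !duplicated(grp)
  df <- tapply((n_g - 1)[first], uid[first], sum)
  sd_u <- sqrt(ss / pmax(df, 1))
  sd_u[df < 1] <- NA_real_
  as.vector(sd_u[uid])
}

#' Flag outlier data points
#'
#' Systematic curation rule for challenge time courses: a subject's log2 value
#' is flagged when it lies outside the mean +/- 4 SD window for that
#' metabolite and time point, unless the time point falls within the first 30
#' minutes after a challenge onset (closed interval), in which case the point
#' is exempted (challenge-induced peaks are biologically meaningful). The mean
#' is always taken across subjects at the time point. Two SD estimators are
#' offered: \code{"pooled"} (default) uses the metabolite's residual SD around
#' time-point means, pooled over its time points — with small cohorts a
#' per-time-point SD that includes the tested value can never be exceeded
#' 4-fold (the maximum standardized deviation among n values is
#' (n-1)/sqrt(n), i.e. 3.61 at n = 15), so the pooled estimator is what makes
#' the rule operative; \code{"per_tp"} applies the literal per-time-point SD.
#' Groups with fewer than 3 non-missing subjects or zero SD are skipped.
#'
#' Flagged points are reported, not removed; see [drop_flagged()].
#'
#' @param ds a log2-scale [profile_dataset()].
#' @param design defaults to the dataset's design.
#' @param sd_multiples flag threshold in SD units (default 4).
#' @param exempt_min width of the post-onset exemption window (min).
#' @param sd_method \code{"pooled"} or \code{"per_tp"}.
#' @return An object of class \code{outlier_report}: \code{flagged} and
#'   \code{exempted} data.frames plus skip counters.
#' @export
flag_outliers <- function(ds, design = ds$design, sd_multiples = 4,
                          exempt_min = 30,
                          sd_method = c("pooled", "per_tp")) {
  sd_method <- match.arg(sd_method)
  if (ds$transform != "log2")
    stop("flag_outliers expects a log2-scale dataset")
  d <- ds$data
  grp <- paste(d$uid, d$tp, sep = "\r")
  n_g <- stats::ave(d$value, grp, FUN = length)
  mean_g <- stats::ave(d$value, grp, FUN = mean)
  sd_tp <- stats::ave(d$value, grp, FUN = stats::sd)
  sd_use <- if (sd_method == "pooled")
    pooled_residual_sd(d$value, d$uid, grp) else sd_tp
  ok <- n_g >= 3 & !is.na(sd_use) & sd_use > 0
  n_skipped <- length(unique(grp[!ok]))
  out <- abs(d$value - mean_g) > sd_multiples * sd_use & ok

  ## exemption: tp clock within [onset, onset + exempt_min] of any challenge
  ## onset in the same block
  blk <- tp_block(design, d$tp)
  clk <- tp_clock(design, d$tp)
  exempt <- rep(FALSE, nrow(d))
  for (ch in design$challenges) {
    chb <- tp_block(design, ch$baseline_tp)
    exempt <- exempt | (blk == chb & clk >= ch$onset_clock_min &
                          clk <= ch$onset_clock_min + exempt_min)
  }

  fl <- which(out & !exempt)
  ex <- which(out & exempt)
  structure(list(
    flagged = data.frame(subject = d$subject[fl], tp = d$tp[fl],
                         uid = d$uid[fl], value = d$value[fl],
                         tp_mean = mean_g[fl], tp_sd = sd_use[fl],
                         stringsAsFactors = FALSE),
    exempted = data.frame(subject = d$subject[ex], tp = d$tp[ex],
                          uid = d$uid[ex], stringsAsFactors = FALSE),
    n_groups_skipped = n_skipped, sd_method = sd_method,
    sd_multiples = sd_multiples),
    class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Outlier report (", x$sd_multiples, " SD, ", x$sd_method, " SD): ",
      nrow(x$flagged), " flagged, ", nrow(x$exempted),
      " exempted (challenge onset), ", x$n_groups_skipped,
      " group(s) skipped\n", sep = "")
  invisible(x)
}

#' Remove flagged observations
#'
#' The flag step only reports; curation decisions in practice involve manual
#' review. This helper removes all flagged points wholesale.
#'
#' @param ds the dataset the report was computed on.
#' @param report an [flag_outliers()] report.
#' @export
drop_flagged <- function(ds, report) {
  if (nrow(report$flagged) == 0) return(ds)
  key <- paste(ds$data$subject, ds$data$tp, ds$data$uid, sep = "\r")
  bad <- paste(report$flagged$subject, report$flagged$tp, report$flagged$uid,
               sep = "\r")
  out <- ds
  out$data <- ds$data[!key %in% bad, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Filter metabolites by missingness
#'
#' Drops every metabolite whose missing fraction — computed over all scheduled
#' (subject, time point) samples of its own fluid — is at or above
#' \code{max_missing_frac}; metabolites with missingness strictly below the
#' threshold are retained.
#'
#' @param ds a [profile_dataset()].
#' @param max_missing_frac threshold (default 0.30).
#' @export
filter_missingness <- function(ds, max_missing_frac = 0.30) {
  sc <- scheduled_counts(ds)
  frac <- 1 - sc$observed / sc$scheduled
  keep <- sc$uid[frac < max_missing_frac]
  subset(ds, uids = keep)
}

#' Scale transformations of a log2 dataset
#'
#' \describe{
#'   \item{zscore}{per metabolite, center and scale by the SD over all
#'     non-missing observations; zero-variance metabolites cannot be
#'     standardized and are emitted all-missing with a warning.}
#'   \item{log2fc_block}{per (subject, metabolite, block), subtract the
#'     subject's value at the block's first sampled time point for the
#'     metabolite's fluid; entries whose reference is missing become missing.}
#'   \item{log2fc_challenge}{per (subject, metabolite, challenge), subtract
#'     the subject's value at the challenge baseline; each time point is
#'     attributed to the first challenge (in design order) containing it,
#'     baselines included (so a baseline maps to 0); time points in no
#'     challenge window become missing.}
#' }
#'
#' @param ds a log2-scale [profile_dataset()].
#' @param mode one of \code{zscore}, \code{log2fc_block},
#'   \code{log2fc_challenge}.
#' @param design defaults to the dataset's design.
#' @export
transform_values <- function(ds, mode = c("zscore", "log2fc_block",
                                          "log2fc_challenge"),
                             design = ds$design) {
  mode <- match.arg(mode)
  if (ds$transform != "log2")
    stop("transform_values expects a log2-scale dataset")
  d <- ds$data
  if (mode == "zscore") {
    mu <- stats::ave(d$value, d$uid, FUN = mean)
    sg <- stats::ave(d$value, d$uid, FUN = stats::sd)
    const <- unique(d$uid[is.na(sg) | sg == 0])
    if (length(const) > 0)
      warning("zero-variance metabolite(s) cannot be z-scored, emitted ",
              "all-missing: ", paste(const, collapse = ", "))
    d$value <- ifelse(is.na(sg) | sg == 0, NA_real_, (d$value - mu) / sg)
  } else if (mode == "log2fc_block") {
    blk <- tp_block(design, d$tp)
    fluid <- ds$catalog$fluid[match(d$uid, ds$catalog$uid)]
    ## first sampled tp per (fluid, block)
    first_tp <- new.env()
    for (f in unique(fluid)) {
      tps <- fluid_tps(design, f)
      fb <- tp_block(design, tps)
      for (b in unique(fb))
        assign(paste(f, b), tps[fb == b][1], envir = first_tp)
    }
    ref_tp <- vapply(paste(fluid, blk), get, 0L, envir = first_tp,
                     USE.NAMES = FALSE)
    key <- paste(d$subject, ref_tp, d$uid, sep = "\r")
    dkey <- paste(d$subject, d$tp, d$uid, sep = "\r")
    d$value <- d$value - d$value[match(key, dkey)]
  } else {
    ## map tp -> challenge (first challenge in design order containing it)
    chal_of <- rep(NA_integer_, nrow(design$timepoints))
    base_of <- rep(NA_integer_, nrow(design$timepoints))
    for (i in seq_along(design$challenges)) {
      ch <- design$challenges[[i]]
      members <- c(ch$baseline_tp, ch$tested_tps)
      j <- match(members, design$timepoints$index)
      new <- is.na(chal_of[j])
      chal_of[j[new]] <- i
      base_of[j[new]] <- ch$baseline_tp
    }
    ref_tp <- base_of[match(d$tp, design$timepoints$index)]
    key <- paste(d$subject, ref_tp, d$uid, sep = "\r")
    dkey <- paste(d$subject, d$tp, d$uid, sep = "\r")
    d$value <- ifelse(is.na(ref_tp), NA_real_,
                      d$value - d$value[match(key, dkey)])
  }
  d <- d[!is.na(d$value), , drop = FALSE]
  rownames(d) <- NULL
  out <- ds
  out$data <- d
  out$transform <- if (mode == "zscore") "zscore" else mode
  out
}

#' Block-wise linear imputation
#'
#' Per (subject, metabolite, block): missing scheduled samples with at least
#' one observed value before and after within the same block are filled by
#' linear interpolation against clock time (stats::approx); leading and
#' trailing gaps remain missing (no extrapolation). Observed values are never
#' touched.
#'
#' @param ds a [profile_dataset()] (applied on the stored scale).
#' @param design defaults to the dataset's design.
#' @export
impute_linear <- function(ds, design = ds$design) {
  cat <- ds$catalog
  d <- ds$data
  dkey <- paste(d$subject, d$tp, d$uid, sep = "\r")
  add <- list()
  for (i in seq_len(nrow(cat))) {
    tps <- fluid_tps(design, cat$fluid[i])
    blocks <- tp_block(design, tps)
    clocks <- tp_clock(design, tps)
    du <- d[d$uid == cat$uid[i], , drop = FALSE]
    if (nrow(du) == 0) next
    for (s in unique(du$subject)) {
      dsub <- du[du$subject == s, , drop = FALSE]
      for (b in unique(blocks)) {
        btps <- tps[blocks == b]
        bclk <- clocks[blocks == b]
        obs <- match(dsub$tp, btps)
        here <- !is.na(obs)
        if (sum(here) < 2) next
        x_obs <- bclk[obs[here]]
        y_obs <- dsub$value[here]
        miss <- setdiff(btps, dsub$tp)
        if (length(miss) == 0) next
        x_mis <- bclk[match(miss, btps)]
        inside <- x_mis > min(x_obs) & x_mis < max(x_obs)
        if (!any(inside)) next
        yi <- stats::approx(x_obs, y_obs, xout = x_mis[inside])$y
        add[[length(add) + 1]] <-
          data.frame(subject = s, tp = miss[inside], uid = cat$uid[i],
                     value = yi, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(add) > 0) d <- rbind(d, do.call(rbind, add))
  out <- ds
  out$data <- d[order(d$uid, d$subject, d$tp), , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Correlation-preselected KNN imputation
#'
#' For each missing (sample, metabolite) entry — a sample being one (subject,
#' time point) — the other metabolites of the same fluid and platform are
#' ranked by absolute Pearson correlation with the target over complete pairs;
#' the top \code{n_preselect} with at least \code{min_complete_pairs} complete
#' pairs are retained and z-scored. Distances between the query sample and all
#' samples where the target is observed are Euclidean over the coordinates
#' non-missing in both, divided by the square root of the number of shared
#' coordinates (to compare across unequal overlaps). The imputed value is the
#' unweighted mean of the target's values in the \code{k} nearest samples
#' (all, if fewer than \code{k} are available; the target's overall mean if
#' none). Observed values are never touched.
#'
#' @param ds a log2-scale [profile_dataset()], normally after
#'   [filter_missingness()].
#' @param k neighbors (default 10).
#' @param n_preselect correlated metabolites retained (default 20).
#' @param min_complete_pairs minimum complete pairs for a correlation.
#' @export
impute_knn <- function(ds, k = 10, n_preselect = 20, min_complete_pairs = 10) {
  cat <- ds$catalog
  out <- ds
  for (g in unique(paste(cat$fluid, cat$platform, sep = "\r"))) {
    uids <- cat$uid[paste(cat$fluid, cat$platform, sep = "\r") == g]
    fluid <- cat$fluid[match(uids[1], cat$uid)]
    tps <- fluid_tps(ds$design, fluid)
    subs <- sort(unique(ds$data$subject))
    X <- pd_matrix(ds, uids = uids, subjects = subs, tps = tps)
    grid <- attr(X, "grid")
    if (!anyNA(X)) next
    cors <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
    npairs <- crossprod(!is.na(X))
    Z <- scale(X)  # per-column z-score over non-missing
    for (j in which(colSums(is.na(X)) > 0)) {
      cj <- abs(cors[, j]); cj[j] <- NA
      cj[npairs[, j] < min_complete_pairs] <- NA
      sel <- order(cj, decreasing = TRUE, na.last = NA)
      sel <- utils::head(sel, n_preselect)
      obs_rows <- which(!is.na(X[, j]))
      mis_rows <- which(is.na(X[, j]))
      if (length(obs_rows) == 0) {
        warning("metabolite entirely missing, left unimputed: ", uids[j])
        next
      }
      for (i in mis_rows) {
        if (length(sel) > 0) {
          q <- Z[i, sel]
          cand <- Z[obs_rows, sel, drop = FALSE]
          shared <- sweep(!is.na(cand), 2, !is.na(q), "&")
          nsh <- rowSums(shared)
          diff2 <- sweep(cand, 2, q, "-")^2
          diff2[!shared] <- 0
          dist <- sqrt(rowSums(diff2)) / sqrt(pmax(nsh, 1))
          dist[nsh == 0] <- NA
        } else dist <- rep(NA_real_, length(obs_rows))
        usable <- which(!is.na(dist))
        if (length(usable) == 0) {
          X[i, j] <- mean(X[obs_rows, j])  # overall-mean fallback
        } else {
          nn <- usable[order(dist[usable])][seq_len(min(k, length(usable)))]
          X[i, j] <- mean(X[obs_rows[nn], j])
        }
      }
    }
    idx <- which(!is.na(X), arr.ind = TRUE)
    newd <- data.frame(subject = grid$subject[idx[, 1]],
                       tp = grid$tp[idx[, 1]],
                       uid = uids[idx[, 2]], value = X[idx],
                       stringsAsFactors = FALSE)
    keep <- !(out$data$uid %in% uids)
    out$data <- rbind(out$data[keep, , drop = FALSE], newd)
  }
  out$data <- out$data[order(out$data$uid, out$data$subject, out$data$tp), ,
                       drop = FALSE]
  rownames(out$data) <- NULL
  out
}
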