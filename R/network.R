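#' Trapezoid time weights
#'
#' Observation weights for irregularly spaced longitudinal grids:
#' \eqn{w_1 = (t_2 - t_1)/2}, \eqn{w_k = (t_{k+1} - t_{k-1})/2} for interior
#' points, \eqn{w_T = (t_T - t_{T-1})/2}, normalized to sum to one. On an
#' equally spaced grid the interior weights are equal and exactly twice the
#' end weights.
#'
#' @param times strictly increasing clock times (length >= 2).
#' @return numeric weight vector summing to 1.
#' @export
time_weights <- function(times) {
  n <- length(times)
  if (n < 2) stop("need at least 2 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  w <- c(diff(times)[1] / 2,
         if (n > 2) (times[3:n] - times[1:(n - 2)]) / 2,
         diff(times)[n - 1] / 2)
  w / sum(w)
}

#' Dynamical shrinkage partial correlations
#'
#' The estimator behind longitudinal Gaussian graphical models: per-subject
#' time-weighted ("dynamical") covariances pooled across subjects, a
#' data-driven shrinkage of the resulting correlation matrix toward the
#' identity, and partial correlations from the inverse of the shrunken
#' matrix.
#'
#' For subject s with observations \eqn{x_{s,k,g}} on a grid with trapezoid
#' weights \eqn{w_k} ([time_weights()]):
#' \deqn{\mu_{s,g} = \sum_k w_k x_{s,k,g}, \quad
#'       c_s(g,h) = \sum_k w_k (x_{s,k,g}-\mu_{s,g})(x_{s,k,h}-\mu_{s,h})}
#' pooled \eqn{C = \mathrm{mean}_s\, c_s}, correlation \eqn{R} from \eqn{C}.
#' The shrinkage intensity is the Schaefer-Strimmer-type ratio
#' \eqn{\lambda^* = \mathrm{clip}_{[0,1]}\big(\sum_{i<j}\widehat{Var}(r_{ij})
#' / \sum_{i<j} r_{ij}^2\big)} with \eqn{\widehat{Var}(r_{ij})} the weighted
#' empirical variance of the per-(subject, time point) products of
#' standardized residuals, using normalized observation weights
#' \eqn{\omega_{s,k} = w_k/S} and the weighted-variance factor
#' \eqn{h/(1-h)}, \eqn{h = \sum \omega^2}. Partial correlations are
#' \eqn{-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}} with \eqn{\Omega} the
#' inverse of \eqn{\lambda^* I + (1-\lambda^*) R}.
#'
#' @param ds a complete (imputed) log2-scale [profile_dataset()].
#' @param uids metabolites to include (default: all; >= 2).
#' @param subjects subjects to pool (default: all observed).
#' @param tps time-point grid (default: all points sampled for every included
#'   metabolite's fluid).
#' @param lambda \code{NULL} for the data-driven intensity, or a forced value
#'   in [0, 1].
#' @param design defaults to the dataset's design.
#' @return Object of class \code{dyn_pcor}: \code{R} (dynamical correlation),
#'   \code{pcor}, \code{lambda}, \code{n_eff} (pooled subject x time point
#'   count), \code{uids}, \code{weights}.
#' @export
dyn_pcor <- function(ds, uids = NULL, subjects = NULL, tps = NULL,
                     lambda = NULL, design = ds$design) {
  if (!ds$transform %in% c("log2"))
    stop("dyn_pcor expects log2-scale (imputed) data")
  if (is.null(uids)) uids <- ds$catalog$uid
  if (length(uids) < 2) stop("need at least 2 metabolites")
  if (is.null(subjects)) subjects <- sort(unique(ds$data$subject))
  if (length(subjects) < 2) stop("need at least 2 subjects")
  if (is.null(tps)) {
    fluids <- unique(ds$catalog$fluid[match(uids, ds$catalog$uid)])
    tps <- Reduce(intersect, lapply(fluids, fluid_tps, design = design))
  }
  tps <- sort(tps)
  if (length(tps) < 3) stop("need at least 3 time points")
  X <- pd_matrix(ds, uids = uids, subjects = subjects, tps = tps)
  if (anyNA(X))
    stop("dyn_pcor requires complete data for the chosen grid; impute first (",
         sum(is.na(X)), " missing)")
  S <- length(subjects); K <- length(tps); G <- length(uids)
  w <- time_weights(study_time(design, tps))
  grid <- attr(X, "grid")

  C <- matrix(0, G, G, dimnames = list(uids, uids))
  Zres <- matrix(NA_real_, S * K, G)  # weighted-centered residuals, stacked
  for (si in seq_len(S)) {
    rows <- which(grid$subject == subjects[si])
    rows <- rows[match(tps, grid$tp[rows])]  # study order
    Xs <- X[rows, , drop = FALSE]
    mu <- colSums(w * Xs)
    cx <- sweep(Xs, 2, mu)
    C <- C + crossprod(cx, w * cx)
    Zres[(si - 1) * K + seq_len(K), ] <- cx
  }
  C <- C / S
  sds <- sqrt(diag(C))
  if (any(sds == 0)) stop("zero dynamical variance for: ",
                          uids[which(sds == 0)[1]])
  R <- C / tcrossprod(sds)

  if (is.null(lambda)) {
    Z <- sweep(Zres, 2, sds, "/")
    omega <- rep(w / S, times = S)          # sums to 1 over (subject, tp)
    h <- sum(omega^2)
    M1 <- crossprod(Z, omega * Z)           # weighted mean of z_g z_h  (= R)
    M2 <- crossprod(Z^2, omega * Z^2)       # weighted mean of (z_g z_h)^2
    Vhat <- h / (1 - h) * (M2 - M1^2)
    off <- upper.tri(R)
    denom <- sum(R[off]^2)
    lambda <- if (denom <= 0) 1 else min(1, max(0, sum(Vhat[off]) / denom))
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  }

  Rs <- lambda * diag(G) + (1 - lambda) * R
  Om <- tryCatch(solve(Rs), error = function(e)
    stop("shrunken correlation matrix is singular at lambda = ", lambda,
         "; force a floor lambda >= 1e-6"))
  pc <- -Om / sqrt(tcrossprod(diag(Om)))
  diag(pc) <- 1
  dimnames(pc) <- dimnames(R)
  structure(list(R = R, pcor = pc, lambda = lambda, n_eff = S * K,
                 uids = uids, subjects = subjects, tps = tps, weights = w),
            class = "dyn_pcor")
}

#' @export
print.dyn_pcor <- function(x, ...) {
  cat("Dynamical shrinkage partial correlations:", length(x$uids),
      "metabolites,", length(x$subjects), "subjects x", length(x$tps),
      "time points\n")
  cat(sprintf("  shrinkage intensity lambda* = %.4f, n_eff = %d\n",
              x$lambda, x$n_eff))
  op <- abs(x$pcor[upper.tri(x$pcor)])
  cat(sprintf("  |pcor| off-diagonal: median %.3f, max %.3f\n",
              stats::median(op), max(op)))
  invisible(x)
}

#' Pooled Pearson correlations
#'
#' Plain Pearson correlation over the pooled (subject, time point)
#' observations of a complete dataset; the companion statistic gating GGM
#' edges.
#'
#' @inheritParams dyn_pcor
#' @export
pooled_pearson <- function(ds, uids = NULL, subjects = NULL, tps = NULL,
                           design = ds$design) {
  if (is.null(uids)) uids <- ds$catalog$uid
  if (is.null(subjects)) subjects <- sort(unique(ds$data$subject))
  if (is.null(tps)) {
    fluids <- unique(ds$catalog$fluid[match(uids, ds$catalog$uid)])
    tps <- Reduce(intersect, lapply(fluids, fluid_tps, design = design))
  }
  X <- pd_matrix(ds, uids = uids, subjects = subjects, tps = sort(tps))
  if (anyNA(X)) stop("pooled_pearson requires complete data; impute first")
  stats::cor(X)
}

#' Null model for partial correlations
#'
#' Fits the null density \eqn{f_0(r;\kappa) \propto (1-r^2)^{(\kappa-3)/2}}
#' on (-1, 1) by maximum likelihood over the effective degrees of freedom
#' \eqn{\kappa}; at \eqn{\kappa = 3} the density is uniform. Two-sided
#' p-values use \eqn{R^2 \sim \mathrm{Beta}(1/2, (\kappa-1)/2)}.
#'
#' Because the observed partial correlations are a mixture of a large null
#' bulk and a minority of genuine associations in the tails, a plain maximum
#' likelihood fit over all values would be dragged toward small \eqn{\kappa}
#' by the signal. The default therefore fits a truncated likelihood on the
#' central bulk: values with \eqn{|r|} above the \code{1 - trim} quantile are
#' discarded and the density is renormalized to the retained region,
#' \eqn{\sum_i \log f_0(r_i;\kappa) - n \log P(|R| \le c;\kappa)}. With
#' \code{trim = 0} this is the ordinary MLE over all values.
#'
#' @param r observed off-diagonal partial correlations in (-1, 1); at least
#'   50 values for a stable fit.
#' @param trim fraction of the largest \eqn{|r|} excluded from the fit
#'   (default 0.2).
#' @return object of class \code{pcor_null} with element \code{kappa}.
#' @export
fit_null_kappa <- function(r, trim = 0.2) {
  if (any(abs(r) >= 1)) stop("partial correlations must lie in (-1, 1)")
  if (length(r) < 50) stop("need at least 50 values to fit the null model")
  if (trim < 0 || trim >= 1) stop("trim must lie in [0, 1)")
  if (trim > 0) {
    cut <- stats::quantile(abs(r), 1 - trim, names = FALSE)
    keep <- r[abs(r) <= cut]
  } else {
    cut <- NA_real_
    keep <- r
  }
  slog <- sum(log1p(-keep^2))
  n <- length(keep)
  nll <- function(logk) {
    k <- exp(logk)
    ll <- (k - 3) / 2 * slog +
      n * (lgamma(k / 2) - 0.5 * log(pi) - lgamma((k - 1) / 2))
    if (trim > 0)
      ll <- ll - n * stats::pbeta(cut^2, 0.5, (k - 1) / 2, log.p = TRUE)
    -ll
  }
  opt <- stats::optimize(nll, interval = c(log(1 + 1e-8), log(1e7)))
  structure(list(kappa = exp(opt$minimum), trim = trim),
            class = "pcor_null")
}

#' @export
print.pcor_null <- function(x, ...) {
  cat(sprintf("Partial-correlation null model: kappa = %.2f\n", x$kappa))
  invisible(x)
}

#' Two-sided null p-value for a partial correlation
#'
#' @param r partial correlation(s).
#' @param null a [fit_null_kappa()] model, or a kappa value.
#' @export
pcor_pvalue <- function(r, null) {
  kappa <- if (inherits(null, "pcor_null")) null$kappa else null
  stats::pbeta(r^2, 1 / 2, (kappa - 1) / 2, lower.tail = FALSE)
}

## two-sided p of a Pearson correlation on n pooled observations
pearson_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
}

#' Build a Gaussian graphical model network
#'
#' Draws an edge between two metabolites either when the dynamical partial
#' correlation exceeds a fixed cutoff (signed by default, matching the
#' convention "partial correlations >= c"; absolute optionally) or when it is
#' significant under the fitted null model after multiple-testing correction
#' over all p(p-1)/2 pairs — in significance mode the edge additionally
#' requires (by default) a Pearson correlation significant at 5\% on the
#' pooled observations. Edges carry all four statistics.
#'
#' @param fit a [dyn_pcor()] estimate.
#' @param mode \code{"cutoff"} or \code{"significance"}.
#' @param cutoff partial-correlation cutoff in [-1, 1] (cutoff mode).
#' @param absolute compare |pcor| instead of signed pcor to the cutoff.
#' @param correction \code{bonferroni}, \code{fdr} or \code{raw5}
#'   (significance mode).
#' @param require_pearson gate edges on Pearson significance (significance
#'   mode).
#' @param R_plain pooled Pearson matrix ([pooled_pearson()]); required when
#'   \code{require_pearson} and recommended always so edges carry Pearson
#'   statistics.
#' @param catalog optional [metabolite_catalog()] supplying node fluid,
#'   platform and match keys.
#' @return Object of class \code{ggm_network}: \code{nodes}, \code{edges},
#'   \code{provenance}.
#' @export
build_ggm <- function(fit, mode = c("cutoff", "significance"), cutoff = 0.12,
                      absolute = FALSE,
                      correction = c("bonferroni", "fdr", "raw5"),
                      require_pearson = TRUE, R_plain = NULL,
                      catalog = NULL) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  G <- length(fit$uids)
  pairs <- which(upper.tri(fit$pcor), arr.ind = TRUE)
  pc <- fit$pcor[pairs]
  pr <- if (!is.null(R_plain)) R_plain[fit$uids, fit$uids][pairs] else
    rep(NA_real_, nrow(pairs))
  p_pear <- if (!is.null(R_plain)) pearson_pvalue(pr, fit$n_eff) else
    rep(NA_real_, nrow(pairs))
  kappa <- NA_real_
  p_pc <- rep(NA_real_, nrow(pairs))
  if (mode == "cutoff") {
    if (cutoff < -1 || cutoff > 1) stop("cutoff must lie in [-1, 1]")
    keep <- if (absolute) abs(pc) >= cutoff else pc >= cutoff
  } else {
    null <- fit_null_kappa(pc)
    kappa <- null$kappa
    p_pc <- pcor_pvalue(pc, null)
    p_adj <- switch(correction,
                    bonferroni = pmin(1, p_pc * length(p_pc)),
                    fdr = adjust_bh(p_pc),
                    raw5 = p_pc)
    keep <- p_adj < 0.05
    if (require_pearson) {
      if (is.null(R_plain))
        stop("require_pearson needs R_plain (see pooled_pearson)")
      keep <- keep & p_pear < 0.05
    }
  }
  edges <- data.frame(uid_a = fit$uids[pairs[keep, 1]],
                      uid_b = fit$uids[pairs[keep, 2]],
                      pcor = pc[keep], pearson_r = pr[keep],
                      p_pcor = p_pc[keep], p_pearson = p_pear[keep],
                      edge_type = rep("pcor", sum(keep)),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(uid = fit$uids, fluid = NA_character_,
                      platform = NA_character_,
                      display_name = NA_character_, kegg = NA_character_,
                      hmdb = NA_character_, log2fc = NA_real_,
                      neg_log10_p = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(catalog)) {
    i <- match(nodes$uid, catalog$uid)
    nodes$fluid <- catalog$fluid[i]
    nodes$platform <- catalog$platform[i]
    nodes$display_name <- catalog$display_name[i]
    nodes$kegg <- catalog$kegg[i]
    nodes$hmdb <- catalog$hmdb[i]
  }
  structure(list(nodes = nodes, edges = edges,
                 provenance = list(mode = mode,
                                   cutoff = if (mode == "cutoff") cutoff,
                                   absolute = absolute,
                                   correction = if (mode == "significance")
                                     correction,
                                   require_pearson = require_pearson,
                                   lambda = fit$lambda, kappa = kappa,
                                   n_eff = fit$n_eff)),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  pe <- sum(x$edges$edge_type == "pcor")
  se <- sum(x$edges$edge_type == "same_metabolite")
  cat("GGM network:", nrow(x$nodes), "nodes,", pe, "partial-correlation",
      "edge(s)", if (se > 0) paste0("+ ", se, " same-metabolite edge(s)"),
      "\n")
  pv <- x$provenance
  if (identical(pv$mode, "cutoff"))
    cat("  cutoff:", pv$cutoff, if (isTRUE(pv$absolute)) "(absolute)", "\n")
  else if (identical(pv$mode, "significance"))
    cat("  significance:", pv$correction,
        if (isTRUE(pv$require_pearson)) "+ Pearson gate", "\n")
  invisible(x)
}

#' @export
summary.ggm_network <- function(object, ...) {
  print(object)
  if (nrow(object$edges) > 0) {
    pc <- object$edges$pcor[object$edges$edge_type == "pcor"]
    cat(sprintf("  pcor on edges: min %.3f, median %.3f, max %.3f\n",
                min(pc), stats::median(pc), max(pc)))
  }
  invisible(object)
}

#' Convert a GGM network to an igraph graph
#'
#' @param net a [build_ggm()] network.
#' @export
as_igraph <- function(net) {
  nodes <- net$nodes
  for (cl in names(nodes))
    if (is.character(nodes[[cl]])) nodes[[cl]][is.na(nodes[[cl]])] <- ""
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = nodes)
}

#' @export
plot.ggm_network <- function(x, ...) {
  g <- as_igraph(x)
  igraph::plot.igraph(g, vertex.size = 6, vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Merge two single-fluid networks into a multi-fluid network
#'
#' Takes the union of nodes and edges of two networks over disjoint uid sets
#' (different fluids) and adds one \code{same_metabolite} edge for every
#' cross-network node pair matching on the chosen key (case-insensitive);
#' nodes matching several partners get one edge per partner.
#'
#' @param net_a,net_b [build_ggm()] networks with disjoint uids.
#' @param match_on \code{display_name}, \code{kegg} or \code{hmdb}.
#' @export
merge_multifluid <- function(net_a, net_b,
                             match_on = c("display_name", "kegg", "hmdb")) {
  match_on <- match.arg(match_on)
  if (length(intersect(net_a$nodes$uid, net_b$nodes$uid)) > 0)
    stop("networks must cover disjoint uid sets")
  ka <- tolower(net_a$nodes[[match_on]])
  kb <- tolower(net_b$nodes[[match_on]])
  if (all(is.na(ka) | ka == "") || all(is.na(kb) | kb == ""))
    stop("match key '", match_on, "' is absent for all nodes of one network")
  cross <- which(outer(ka, kb, function(x, y)
    !is.na(x) & !is.na(y) & nzchar(x) & nzchar(y) & x == y), arr.ind = TRUE)
  nx <- nrow(cross)
  xedges <- data.frame(uid_a = net_a$nodes$uid[cross[, 1]],
                       uid_b = net_b$nodes$uid[cross[, 2]],
                       pcor = rep(NA_real_, nx),
                       pearson_r = rep(NA_real_, nx),
                       p_pcor = rep(NA_real_, nx),
                       p_pearson = rep(NA_real_, nx),
                       edge_type = rep("same_metabolite", nx),
                       stringsAsFactors = FALSE)
  structure(list(nodes = rbind(net_a$nodes, net_b$nodes),
                 edges = rbind(net_a$edges, net_b$edges, xedges),
                 provenance = list(mode = "multi_fluid", match_on = match_on,
                                   a = net_a$provenance,
                                   b = net_b$provenance)),
            class = "ggm_network")
}

#' Annotate network nodes with challenge statistics
#'
#' Sets the node attributes \code{log2fc} and \code{neg_log10_p} from a
#' challenge scan at one time point (nodes absent from the scan keep NA
#' attributes); in exports, node size conventionally depicts -log10 p and
#' color the log2 fold change.
#'
#' @param net a [build_ggm()] network.
#' @param scan a [paired_t_scan()] result.
#' @param tp the scanned time point to map.
#' @export
annotate_ggm <- function(net, scan, tp) {
  s <- scan[scan$tp == tp & !is.na(scan$p), , drop = FALSE]
  i <- match(net$nodes$uid, s$uid)
  net$nodes$log2fc <- s$log2fc[i]
  net$nodes$neg_log10_p <- -log10(s$p[i])
  net
}

#' Export a network
#'
#' @param net a [build_ggm()] network.
#' @param path output file.
#' @param format \code{graphml} (typed attributes, via igraph),
#'   \code{edge_tsv} (uid_a, uid_b, pcor, pearson_r, p_pcor, p_pearson,
#'   edge_type) or \code{json} (nodes + edges + provenance bundle).
#' @export
export_ggm <- function(net, path, format = c("graphml", "edge_tsv", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "edge_tsv") {
    utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(list(nodes = net$nodes, edges = net$edges,
                              provenance = net$provenance),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
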