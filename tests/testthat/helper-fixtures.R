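# shared fixture builders; everything is generated in code

# tiny regular design: n_tp points per block, spacing minutes apart
tiny_design <- function(n_tp = 6, spacing = 30, n_blocks = 1, subjects = 1:3) {
  build_schedule("uniform", spacing = spacing, n_per_block = n_tp,
                 n_blocks = n_blocks, subjects = subjects)
}

# small raw dataset with explicit values; values[s, k, m] on the log2 scale
tiny_dataset <- function(values, design = NULL, fluid = "P",
                         platform = "nt-ms", transform = "raw") {
  stopifnot(length(dim(values)) == 3)
  n_s <- dim(values)[1]; n_k <- dim(values)[2]; n_m <- dim(values)[3]
  if (is.null(design)) design <- tiny_design(n_tp = n_k, subjects = seq_len(n_s))
  cat <- metabolite_catalog(sprintf("M%02d", seq_len(n_m)), fluid = fluid,
                            platform = platform)
  tps <- fluid_tps_vis(design, fluid)[seq_len(n_k)]
  grid <- expand.grid(subject = seq_len(n_s), tp = tps, m = seq_len(n_m))
  data <- data.frame(subject = grid$subject, tp = grid$tp,
                     uid = cat$uid[grid$m],
                     value = values[cbind(grid$subject,
                                          match(grid$tp, tps), grid$m)])
  profile_dataset(cat, design, data[!is.na(data$value), , drop = FALSE],
                  transform = transform)
}

fluid_tps_vis <- function(design, fluid) {
  col <- c(P = "plasma", U = "urine", BA = "breath", BC = "breath")[fluid]
  design$timepoints$index[design$timepoints[[col]]]
}

# deterministic z-scored curve as a data.frame(time, value)
curve_df <- function(t, v) data.frame(time = t, value = v)

# the ground-truth module configuration used for network recovery checks:
# 40 metabolites in 8 modules of 5, loading 0.8, AR 0.6, noise SD 0.5
module_sim_config <- function(seed, n_metabolites = 40, module_size = 5,
                              loading = 0.8) {
  n_mod <- n_metabolites %/% module_size
  sim_config(n_metabolites = n_metabolites,
             modules = lapply(seq_len(n_mod) - 1, function(i)
               list(members = i * module_size + seq_len(module_size),
                    loading = loading)),
             noise_sd = 0.5, ar_coefficient = 0.6,
             missing_mcar = 0.02, missing_lod_quantile = 0.05, seed = seed)
}

# unordered edge keys for precision/recall computations
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# exhaustive monotone-coupling oracle for the discrete Frechet distance:
# enumerates every coupling path explicitly (independent of the DP)
coupling_paths_memo <- new.env()
coupling_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(coupling_paths_memo[[key]])) return(coupling_paths_memo[[key]])
  res <- list()
  walk <- function(i, j, acc) {
    acc <- c(acc, i + (j - 1) * n)
    if (i == n && j == m) { res[[length(res) + 1]] <<- acc; return() }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, integer(0))
  coupling_paths_memo[[key]] <- res
  res
}

frechet_oracle <- function(P, Q, window) {
  n <- nrow(P); m <- nrow(Q)
  cost <- abs(outer(P$value, Q$value, "-"))
  cost[abs(outer(P$time, Q$time, "-")) > window] <- Inf
  best <- Inf
  for (p in coupling_paths(n, m)) best <- min(best, max(cost[p]))
  best
}

# partial correlations from a correlation matrix via the cofactor/determinant
# formula -- an inversion-free oracle
pcor_det_oracle <- function(R) {
  p <- nrow(R)
  out <- diag(p)
  minor <- function(i, j) det(R[-i, -j, drop = FALSE])
  # pcor_ij = -C_ij / sqrt(C_ii C_jj), C the cofactor matrix of R
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    cij <- (-1)^(i + j) * minor(i, j)
    out[i, j] <- out[j, i] <- -cij / sqrt(minor(i, i) * minor(j, j))
  }
  out
}
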