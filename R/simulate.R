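#' Kinetic response templates
#'
#' Deterministic log2-scale response shapes used by the synthetic study
#' generator, emulating the phenomenology of challenge studies:
#' \describe{
#'   \item{washout}{exponential decay \eqn{A e^{-\Delta t/\tau}} of a compound
#'     acquired from pre-study exposure, resetting at each block start
#'     (\eqn{\Delta t} = minutes since block start).}
#'   \item{postprandial}{gamma-shaped impulse response
#'     \eqn{A (u/\theta)^a e^{-u/\theta} / (a^a e^{-a})} (peak-normalized, so
#'     \code{A} is the peak log2 excursion), summed over all preceding
#'     meal-type challenges (SLDr, SLD1, SLD2, OGTT, OLTT) of the same block.}
#'   \item{fasting_ramp}{saturating rise \eqn{A u/(u+h)} during the fast
#'     (\eqn{u} = minutes since fasting onset), decaying exponentially with
#'     time constant \eqn{\tau} after refeeding; zero in blocks without a
#'     fasting challenge.}
#'   \item{circadian}{\eqn{A \sin(2\pi \cdot tod/1440 + \phi)} with
#'     \eqn{tod} the time of day (blocks start at 08:00).}
#'   \item{flat}{identically zero.}
#' }
#'
#' @param A amplitude (log2 units).
#' @param tau decay time constant (min).
#' @param a,theta gamma shape (> 0) and scale (min).
#' @param h half-rise time (min).
#' @param phi phase (radians).
#' @rdname kinetic_template
#' @export
kt_washout <- function(A = 2, tau = 1440)
  structure(list(kind = "washout", A = A, tau = check_pos(tau, "tau")),
            class = "kinetic_template")

#' @rdname kinetic_template
#' @export
kt_postprandial <- function(A = 1.5, a = 2, theta = 45)
  structure(list(kind = "postprandial", A = A, a = check_pos(a, "a"),
                 theta = check_pos(theta, "theta")),
            class = "kinetic_template")

#' @rdname kinetic_template
#' @export
kt_fasting_ramp <- function(A = 2, h = 600, tau = 240)
  structure(list(kind = "fasting_ramp", A = A, h = check_pos(h, "h"),
                 tau = check_pos(tau, "tau")),
            class = "kinetic_template")

#' @rdname kinetic_template
#' @export
kt_circadian <- function(A = 0.5, phi = 0)
  structure(list(kind = "circadian", A = A, phi = phi),
            class = "kinetic_template")

#' @rdname kinetic_template
#' @export
kt_flat <- function()
  structure(list(kind = "flat"), class = "kinetic_template")

check_pos <- function(x, name) {
  if (!is.finite(x) || x <= 0) stop(name, " must be a positive finite number")
  x
}

MEAL_CHALLENGES <- c("SLDR", "SLD1", "SLD2", "OGTT", "OLTT")

#' Evaluate a kinetic template on a design's time grid
#'
#' @param tpl a kinetic template.
#' @param design a [study_design()].
#' @param tps time-point indices (default: all).
#' @return numeric vector of deterministic log2 responses.
#' @export
template_value <- function(tpl, design, tps = design$timepoints$index) {
  block <- tp_block(design, tps)
  clock <- tp_clock(design, tps)
  out <- numeric(length(tps))
  if (tpl$kind == "flat") return(out)
  if (tpl$kind == "washout") {
    tpd <- design$timepoints
    start <- vapply(block, function(b) min(tpd$clock_min[tpd$block == b]), 0)
    return(tpl$A * exp(-(clock - start) / tpl$tau))
  }
  if (tpl$kind == "circadian") {
    tod <- (480 + clock) %% 1440  # blocks start at 08:00
    return(tpl$A * sin(2 * pi * tod / 1440 + tpl$phi))
  }
  if (tpl$kind == "postprandial") {
    peak <- tpl$a^tpl$a * exp(-tpl$a)
    for (ch in design$challenges) {
      if (!ch$name %in% MEAL_CHALLENGES) next
      chb <- tp_block(design, ch$baseline_tp)
      u <- clock - ch$onset_clock_min
      on <- block == chb & u > 0
      out[on] <- out[on] +
        tpl$A * (u[on] / tpl$theta)^tpl$a * exp(-u[on] / tpl$theta) / peak
    }
    return(out)
  }
  if (tpl$kind == "fasting_ramp") {
    for (ch in design$challenges) {
      if (ch$name != "FASTING") next
      chb <- tp_block(design, ch$baseline_tp)
      ## refeeding = first meal onset in the fasting block after fasting onset
      meal_on <- vapply(design$challenges, function(m)
        if (m$name %in% MEAL_CHALLENGES &&
            tp_block(design, m$baseline_tp) == chb)
          m$onset_clock_min else Inf, 0)
      t_refeed <- min(meal_on)
      in_b <- block == chb
      u <- clock - ch$onset_clock_min
      rising <- in_b & clock <= t_refeed
      out[rising] <- tpl$A * u[rising] / (u[rising] + tpl$h)
      if (is.finite(t_refeed)) {
        lvl <- tpl$A * (t_refeed - ch$onset_clock_min) /
          (t_refeed - ch$onset_clock_min + tpl$h)
        falling <- in_b & clock > t_refeed
        out[falling] <- lvl * exp(-(clock[falling] - t_refeed) / tpl$tau)
      }
    }
    return(out)
  }
  stop("unknown template kind: ", tpl$kind)
}

#' Configuration of a synthetic challenge study
#'
#' Defines the generative model of the synthetic cohort: per-metabolite log2
#' signal = baseline + subject scale x kinetic template + module loading x
#' latent AR(1) module process + Gaussian noise; abundance = 2^signal.
#' Missingness arises by left-censoring below a per-metabolite detection
#' quantile plus an MCAR drop. Defaults mirror the emulated study class: 15
#' subjects, the built-in 56-time-point two-block design, latent-module AR
#' coefficient 0.6, log2 noise SD 0.5, 5\% detection-limit censoring.
#'
#' @param design a [study_design()].
#' @param n_subjects number of subjects (uses the first ids of the design).
#' @param n_metabolites number of simulated metabolites.
#' @param modules list of \code{list(members = <indices>, loading = <rho>)};
#'   each metabolite may belong to at most one module.
#' @param templates a single [kinetic_template] (recycled) or a list of length
#'   \code{n_metabolites}.
#' @param baseline_log2 per-metabolite baselines; \code{NULL} draws N(10, 1).
#' @param subject_variability SD of the per-subject random amplitude scale.
#' @param noise_sd additive log2 noise SD.
#' @param ar_coefficient AR(1) coefficient of the latent module processes.
#' @param missing_mcar MCAR missingness probability.
#' @param missing_lod_quantile left-censoring quantile in [0, 1).
#' @param outlier_rate probability of injected gross outliers (see
#'   [inject_outliers()]).
#' @param cross_platform_pairs list of
#'   \code{list(member = <index>, attenuation = <r>, platform = <tag>)}
#'   entries; each emits a duplicate measurement of the member metabolite on a
#'   second platform whose expected Pearson correlation with the original log2
#'   values is \code{attenuation}.
#' @param fluid,platform tags of the primary simulated dataset.
#' @param seed RNG seed; identical configs give bit-identical output.
#' @export
sim_config <- function(design = build_schedule("challenge56"),
                       n_subjects = 15, n_metabolites = 40,
                       modules = list(), templates = kt_flat(),
                       baseline_log2 = NULL,
                       subject_variability = 0.2, noise_sd = 0.5,
                       ar_coefficient = 0.6, missing_mcar = 0,
                       missing_lod_quantile = 0, outlier_rate = 0,
                       cross_platform_pairs = list(),
                       fluid = "P", platform = "nt-ms", seed = 1) {
  stopifnot(inherits(design, "study_design"),
            n_subjects >= 1, n_subjects <= length(design$subjects),
            n_metabolites >= 1,
            missing_mcar >= 0, missing_mcar <= 1,
            missing_lod_quantile >= 0, missing_lod_quantile < 1,
            outlier_rate >= 0, outlier_rate <= 1,
            abs(ar_coefficient) < 1)
  if (inherits(templates, "kinetic_template"))
    templates <- rep(list(templates), n_metabolites)
  if (length(templates) != n_metabolites)
    stop("templates must have length 1 or n_metabolites")
  seen <- integer(0)
  for (mod in modules) {
    if (!all(mod$members %in% seq_len(n_metabolites)))
      stop("module member not in metabolite list: ",
           setdiff(mod$members, seq_len(n_metabolites))[1])
    if (any(mod$members %in% seen))
      stop("metabolite assigned to more than one module")
    if (mod$loading <= 0 || mod$loading >= 1)
      stop("module loading must be in (0, 1)")
    seen <- c(seen, mod$members)
  }
  structure(list(design = design, n_subjects = as.integer(n_subjects),
                 n_metabolites = as.integer(n_metabolites), modules = modules,
                 templates = templates, baseline_log2 = baseline_log2,
                 subject_variability = subject_variability,
                 noise_sd = noise_sd, ar_coefficient = ar_coefficient,
                 missing_mcar = missing_mcar,
                 missing_lod_quantile = missing_lod_quantile,
                 outlier_rate = outlier_rate,
                 cross_platform_pairs = cross_platform_pairs,
                 fluid = fluid, platform = platform, seed = as.integer(seed)),
            class = "sim_config")
}

## stationary unit-variance AR(1) path of length n
ar1_path <- function(n, phi) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  if (n > 1) {
    innov <- stats::rnorm(n - 1) * sqrt(1 - phi^2)
    for (k in 2:n) x[k] <- phi * x[k - 1] + innov[k - 1]
  }
  x
}

#' Simulate a synthetic challenge study
#'
#' @param cfg a [sim_config()].
#' @return list with elements \code{dataset} (a raw-scale [profile_dataset()])
#'   and \code{truth} (module edges, per-challenge responders, template
#'   assignment).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  design <- cfg$design
  subjects <- design$subjects[seq_len(cfg$n_subjects)]
  tps <- fluid_tps(design, cfg$fluid)
  K <- length(tps)
  M <- cfg$n_metabolites
  names <- sprintf("SYN%03d", seq_len(M))
  cat <- metabolite_catalog(names, fluid = cfg$fluid, platform = cfg$platform)

  base <- cfg$baseline_log2
  if (is.null(base)) base <- stats::rnorm(M, mean = 10, sd = 1)
  stopifnot(length(base) == M)

  module_of <- rep(NA_integer_, M)
  loading <- rep(0, M)
  for (i in seq_along(cfg$modules)) {
    module_of[cfg$modules[[i]]$members] <- i
    loading[cfg$modules[[i]]$members] <- cfg$modules[[i]]$loading
  }

  tmpl_vals <- vapply(cfg$templates, template_value, numeric(K),
                      design = design, tps = tps)        # K x M
  s_scale <- 1 + stats::rnorm(cfg$n_subjects, sd = cfg$subject_variability)

  ## latent AR(1) module processes, one per (module, subject), over the tp grid
  latent <- array(0, dim = c(K, cfg$n_subjects, max(1, length(cfg$modules))))
  for (i in seq_along(cfg$modules))
    for (s in seq_len(cfg$n_subjects))
      latent[, s, i] <- ar1_path(K, cfg$ar_coefficient)

  log2v <- array(NA_real_, dim = c(K, cfg$n_subjects, M))
  for (m in seq_len(M)) {
    lat <- if (is.na(module_of[m])) 0 else
      loading[m] * latent[, , module_of[m]]
    eps <- matrix(stats::rnorm(K * cfg$n_subjects, sd = cfg$noise_sd),
                  K, cfg$n_subjects)
    log2v[, , m] <- base[m] +
      outer(tmpl_vals[, m], s_scale) + lat + eps
  }

  ## cross-platform duplicates: same signal plus noise calibrated so the
  ## expected Pearson correlation with the original equals the attenuation
  xp_uids <- character(0)
  xp_vals <- list()
  for (p in cfg$cross_platform_pairs) {
    m <- p$member
    r <- p$attenuation
    stopifnot(m %in% seq_len(M), r > 0, r <= 1)
    plat <- if (is.null(p$platform)) "t-ms" else p$platform
    v <- log2v[, , m]
    sig2 <- stats::var(as.vector(v)) * (1 / r^2 - 1)
    dup <- v + matrix(stats::rnorm(length(v), sd = sqrt(sig2)),
                      nrow(v), ncol(v))
    uid_b <- make_uid(names[m], cfg$fluid, plat)
    xp_uids <- c(xp_uids, uid_b)
    xp_vals[[uid_b]] <- dup
    cat <- rbind(cat, metabolite_catalog(names[m], fluid = cfg$fluid,
                                         platform = plat))
  }
  cat <- validate_catalog(cat)

  flatten <- function(v, uid) {
    grid <- expand.grid(tp = tps, subject = subjects, KEEP.OUT.ATTRS = FALSE)
    data.frame(subject = grid$subject, tp = grid$tp, uid = uid,
               value = as.vector(v), stringsAsFactors = FALSE)
  }
  rows <- vector("list", M + length(xp_uids))
  for (m in seq_len(M)) rows[[m]] <- flatten(log2v[, , m], cat$uid[m])
  for (i in seq_along(xp_uids))
    rows[[M + i]] <- flatten(xp_vals[[i]], xp_uids[i])
  data <- do.call(rbind, rows)

  ## missingness: left-censoring below the per-metabolite detection quantile,
  ## then MCAR
  drop <- rep(FALSE, nrow(data))
  if (cfg$missing_lod_quantile > 0) {
    for (u in unique(data$uid)) {
      i <- which(data$uid == u)
      thr <- stats::quantile(data$value[i], cfg$missing_lod_quantile,
                             names = FALSE)
      drop[i] <- data$value[i] < thr
    }
  }
  if (cfg$missing_mcar > 0)
    drop <- drop | (stats::runif(nrow(data)) < cfg$missing_mcar)
  data <- data[!drop, , drop = FALSE]
  data$value <- 2^data$value

  ds <- profile_dataset(cat, design, data, transform = "raw")

  edges <- do.call(rbind, lapply(cfg$modules, function(mod) {
    if (length(mod$members) < 2) return(NULL)
    cmb <- utils::combn(sort(mod$members), 2)
    data.frame(uid_a = cat$uid[cmb[1, ]], uid_b = cat$uid[cmb[2, ]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(uid_a = character(), uid_b = character())

  responders <- list()
  for (ch in design$challenges) {
    resp <- vapply(seq_len(M), function(m) {
      tv <- template_value(cfg$templates[[m]], design,
                           c(ch$baseline_tp, ch$tested_tps))
      any(abs(tv - tv[1]) > 1e-12)
    }, TRUE)
    responders[[ch$name]] <- cat$uid[seq_len(M)][resp]
  }

  truth <- list(true_edges = edges, true_responders = responders,
                template_assignment = stats::setNames(
                  vapply(cfg$templates, function(t) t$kind, ""),
                  cat$uid[seq_len(M)]),
                module_of = stats::setNames(module_of, cat$uid[seq_len(M)]),
                injected_outliers = data.frame(subject = integer(),
                                               tp = integer(),
                                               uid = character()))
  list(dataset = ds, truth = truth)
}

#' Inject gross outliers into a dataset
#'
#' Shifts randomly chosen observations by at least
#' \code{magnitude_sd_multiples} per-(metabolite, time point) standard
#' deviations on the log2 scale (multiplicatively on the raw scale), and
#' returns the list of injected points for recovery tests. The shift size is
#' \code{magnitude_sd_multiples} times the larger of the per-time-point SD and
#' the metabolite's pooled residual SD, directed away from the time-point
#' mean, so that an injected point is guaranteed to exceed the 4-SD curation
#' rule of [flag_outliers()] even after the injection itself inflates the SD
#' estimate. Only (metabolite, time
#' point) groups with at least 3 subjects and positive SD are eligible.
#'
#' @param ds a raw- or log2-scale [profile_dataset()].
#' @param rate per-observation injection probability.
#' @param magnitude_sd_multiples shift size in within-time-point SDs.
#' @param seed RNG seed.
#' @param tps optional restriction of injection to these time points.
#' @return list with \code{dataset} and \code{injected} (subject, tp, uid).
#' @export
inject_outliers <- function(ds, rate, magnitude_sd_multiples = 6, seed = 1,
                            tps = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!ds$transform %in% c("raw", "log2"))
    stop("outlier injection expects a raw or log2 scale dataset")
  set.seed(seed)
  d <- ds$data
  lv <- if (ds$transform == "raw") log2(d$value) else d$value
  grp <- paste(d$uid, d$tp, sep = "\r")
  n_g <- stats::ave(lv, grp, FUN = length)
  sd_g <- stats::ave(lv, grp, FUN = stats::sd)
  sd_pool <- pooled_residual_sd(lv, d$uid, grp)
  eligible <- n_g >= 3 & sd_g > 0
  if (!is.null(tps)) eligible <- eligible & d$tp %in% tps
  hit <- eligible & stats::runif(nrow(d)) < rate
  ## shift away from the time-point mean so the resulting deviation is at
  ## least the full shift size (a random direction could move a low point
  ## back toward the mean and void the exceed-the-rule guarantee)
  mean_g <- stats::ave(lv, grp, FUN = mean)
  sign <- ifelse(lv >= mean_g, 1, -1)
  shift <- sign * magnitude_sd_multiples * pmax(sd_g, sd_pool, na.rm = TRUE)
  lv[hit] <- lv[hit] + shift[hit]
  d$value <- if (ds$transform == "raw") 2^lv else lv
  out <- ds
  out$data <- d
  list(dataset = out,
       injected = data.frame(subject = d$subject[hit], tp = d$tp[hit],
                             uid = d$uid[hit], stringsAsFactors = FALSE))
}
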