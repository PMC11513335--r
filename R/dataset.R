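#' Long-format profile dataset
#'
#' The central container: abundances keyed by (subject, time point, metabolite
#' uid). Missing values are absent keys, never sentinel numbers. A
#' \code{transform} tag records the scale of the stored values (\code{raw},
#' \code{log2}, \code{zscore}, \code{log2fc_block}, \code{log2fc_challenge}).
#'
#' @param catalog a [metabolite_catalog()].
#' @param design a [study_design()].
#' @param data data.frame with columns \code{subject}, \code{tp}, \code{uid},
#'   \code{value}; one row per observed value.
#' @param transform scale tag of the stored values.
#' @return An object of class \code{profile_dataset}.
#' @export
profile_dataset <- function(catalog, design, data,
                            transform = c("raw", "log2", "zscore",
                                          "log2fc_block", "log2fc_challenge")) {
  transform <- match.arg(transform)
  catalog <- validate_catalog(catalog)
  stopifnot(inherits(design, "study_design"),
            all(c("subject", "tp", "uid", "value") %in% names(data)))
  data <- data[, c("subject", "tp", "uid", "value")]
  data$subject <- as.integer(data$subject)
  data$tp <- as.integer(data$tp)
  data <- data[!is.na(data$value), , drop = FALSE]
  bad_uid <- setdiff(data$uid, catalog$uid)
  if (length(bad_uid) > 0)
    stop("observation references unknown uid: ", bad_uid[1])
  bad_tp <- setdiff(data$tp, design$timepoints$index)
  if (length(bad_tp) > 0)
    stop("observation references unknown time point: ", bad_tp[1])
  bad_s <- setdiff(data$subject, design$subjects)
  if (length(bad_s) > 0)
    stop("observation references unknown subject: ", bad_s[1])
  key <- paste(data$subject, data$tp, data$uid, sep = "\r")
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1]
    stop("duplicate (subject, tp, uid) observation: ",
         gsub("\r", " / ", k, fixed = TRUE))
  }
  if (transform == "raw" && any(data$value <= 0))
    stop("raw abundances must be strictly positive")
  rownames(data) <- NULL
  structure(list(catalog = catalog, design = design, data = data,
                 transform = transform),
            class = "profile_dataset")
}

#' @export
print.profile_dataset <- function(x, ...) {
  cat("Profile dataset (", x$transform, " scale): ",
      nrow(x$catalog), " metabolites, ",
      length(unique(x$data$subject)), " subjects, ",
      nrow(x$data), " observations\n", sep = "")
  invisible(x)
}

#' @export
summary.profile_dataset <- function(object, ...) {
  sched <- scheduled_counts(object)
  cat("Profile dataset on the ", object$transform, " scale\n", sep = "")
  cat("  metabolites:", nrow(object$catalog), "\n")
  cat("  subjects:   ", length(object$design$subjects), "\n")
  cat("  observations:", nrow(object$data), "of", sum(sched$scheduled),
      sprintf("scheduled (%.1f%% missing)\n",
              100 * (1 - nrow(object$data) / sum(sched$scheduled))))
  invisible(sched)
}

## scheduled sample count per uid (its fluid's time points x subjects)
scheduled_counts <- function(ds) {
  tp <- ds$design$timepoints
  n_tp_fluid <- c(P = sum(tp$plasma), U = sum(tp$urine),
                  BA = sum(tp$breath), BC = sum(tp$breath))
  n_sub <- length(ds$design$subjects)
  obs <- table(factor(ds$data$uid, levels = ds$catalog$uid))
  data.frame(uid = ds$catalog$uid,
             scheduled = n_sub * as.vector(n_tp_fluid[ds$catalog$fluid]),
             observed = as.vector(obs))
}

## time points at which a fluid is sampled
fluid_tps <- function(design, fluid) {
  tp <- design$timepoints
  col <- c(P = "plasma", U = "urine", BA = "breath", BC = "breath")[fluid]
  tp$index[tp[[col]]]
}

#' Read a long-format observation table
#'
#' Expects a tab- or comma-separated file with header columns \code{subject},
#' \code{time_point}, \code{metabolite_uid}, \code{value}. Empty value cells
#' are missing observations (absent keys). Rows referencing uids or time
#' points that are not in the catalog/design are dropped with a warning.
#'
#' @param path file path.
#' @param catalog a [metabolite_catalog()].
#' @param design a [study_design()].
#' @return A [profile_dataset()] on the raw scale.
#' @export
read_long_table <- function(path, catalog, design) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = c(value = "character"), fill = TRUE)
  need <- c("subject", "time_point", "metabolite_uid", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
  value <- suppressWarnings(as.numeric(df$value))
  bad_num <- !is.na(df$value) & nzchar(trimws(df$value)) & is.na(value)
  if (any(bad_num))
    stop("non-numeric value in row ", which(bad_num)[1] + 1L)
  keep <- df$metabolite_uid %in% catalog$uid &
    df$time_point %in% design$timepoints$index
  if (any(!keep))
    warning(sum(!keep), " row(s) referencing unknown uids or time points dropped")
  data <- data.frame(subject = df$subject[keep],
                     tp = df$time_point[keep],
                     uid = df$metabolite_uid[keep],
                     value = value[keep], stringsAsFactors = FALSE)
  ## duplicate keys are an error even when one of the copies is missing
  key <- paste(data$subject, data$tp, data$uid, sep = "\r")
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1]
    stop("duplicate (subject, tp, uid) observation: ",
         gsub("\r", " / ", k, fixed = TRUE))
  }
  profile_dataset(catalog, design, data, transform = "raw")
}

#' Write a long-format observation table
#'
#' Writes one row per scheduled (subject, time point) sample of every
#' cataloged metabolite; missing observations get an empty value cell. Values
#' are printed with 17 significant digits so that a read/write round trip is
#' bit-identical.
#'
#' @param ds a [profile_dataset()].
#' @param path output path (TSV).
#' @export
write_long_table <- function(ds, path) {
  cat <- ds$catalog
  rows <- lapply(seq_len(nrow(cat)), function(i) {
    tps <- fluid_tps(ds$design, cat$fluid[i])
    if (length(tps) == 0) return(NULL)
    expand.grid(subject = ds$design$subjects, time_point = tps,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[
      , c("subject", "time_point")] |>
      cbind(metabolite_uid = cat$uid[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject = integer(), time_point = integer(),
                      metabolite_uid = character())
  key <- paste(out$subject, out$time_point, out$metabolite_uid, sep = "\r")
  dkey <- paste(ds$data$subject, ds$data$tp, ds$data$uid, sep = "\r")
  v <- ds$data$value[match(key, dkey)]
  out$value <- ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- out[order(out$metabolite_uid, out$subject, out$time_point), ]
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a profile dataset
#'
#' Restricts observations (and the catalog) to the intersection of the given
#' filters; \code{NULL} means "keep all". The transform tag is preserved and
#' the study design is kept whole, so challenge windows remain addressable.
#'
#' @param x a [profile_dataset()].
#' @param subjects,tps,uids,fluids,platforms filter sets.
#' @param ... unused.
#' @export
subset.profile_dataset <- function(x, subjects = NULL, tps = NULL, uids = NULL,
                                   fluids = NULL, platforms = NULL, ...) {
  check_known <- function(req, universe, what) {
    bad <- setdiff(req, universe)
    if (length(bad) > 0) stop("unknown ", what, ": ", bad[1])
    req
  }
  cat <- x$catalog
  data <- x$data
  if (!is.null(subjects)) {
    subjects <- check_known(subjects, x$design$subjects, "subject")
    data <- data[data$subject %in% subjects, , drop = FALSE]
  }
  if (!is.null(tps)) {
    tps <- check_known(tps, x$design$timepoints$index, "time point")
    data <- data[data$tp %in% tps, , drop = FALSE]
  }
  keep_uid <- cat$uid
  if (!is.null(uids)) keep_uid <- intersect(keep_uid,
                                            check_known(uids, cat$uid, "uid"))
  if (!is.null(fluids)) {
    check_known(fluids, FLUIDS, "fluid")
    keep_uid <- intersect(keep_uid, cat$uid[cat$fluid %in% fluids])
  }
  if (!is.null(platforms)) {
    check_known(platforms, PLATFORMS, "platform")
    keep_uid <- intersect(keep_uid, cat$uid[cat$platform %in% platforms])
  }
  cat <- cat[cat$uid %in% keep_uid, , drop = FALSE]
  data <- data[data$uid %in% keep_uid, , drop = FALSE]
  rownames(cat) <- rownames(data) <- NULL
  out <- x
  out$catalog <- cat
  out$data <- data
  out
}

#' Extract a metabolite trajectory
#'
#' Returns the ordered (study time, value) sequence for one metabolite, either
#' for a single subject or as the mean over subjects (the mean is taken over
#' non-missing values at each time point; time points at which the metabolite
#' is entirely missing are omitted).
#'
#' @param ds a [profile_dataset()].
#' @param uid metabolite uid.
#' @param subject a subject id, or \code{"mean"}.
#' @param tps optional restriction to a set of time-point indices.
#' @return data.frame with columns \code{tp}, \code{time} (concatenated study
#'   axis, min) and \code{value}, ordered by study time.
#' @export
trajectory <- function(ds, uid, subject = "mean", tps = NULL) {
  if (!uid %in% ds$catalog$uid) stop("unknown uid: ", uid)
  d <- ds$data[ds$data$uid == uid, , drop = FALSE]
  if (!is.null(tps)) d <- d[d$tp %in% tps, , drop = FALSE]
  if (identical(subject, "mean")) {
    v <- tapply(d$value, d$tp, mean)
    tp <- as.integer(names(v))
    out <- data.frame(tp = tp, time = study_time(ds$design, tp),
                      value = as.vector(v))
  } else {
    d <- d[d$subject == subject, , drop = FALSE]
    out <- data.frame(tp = d$tp, time = study_time(ds$design, d$tp),
                      value = d$value)
  }
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## dense matrix view: rows = (subject, tp) samples, columns = uids, NA = missing
pd_matrix <- function(ds, uids = ds$catalog$uid, subjects = ds$design$subjects,
                      tps = NULL) {
  if (is.null(tps)) tps <- sort(unique(ds$data$tp))
  d <- ds$data[ds$data$uid %in% uids & ds$data$subject %in% subjects &
                 ds$data$tp %in% tps, , drop = FALSE]
  grid <- expand.grid(tp = tps, subject = subjects, KEEP.OUT.ATTRS = FALSE)
  rkey <- paste(grid$subject, grid$tp, sep = "\r")
  m <- matrix(NA_real_, nrow = nrow(grid), ncol = length(uids),
              dimnames = list(rkey, uids))
  m[cbind(match(paste(d$subject, d$tp, sep = "\r"), rkey),
          match(d$uid, uids))] <- d$value
  attr(m, "grid") <- grid
  m
}

## rebuild a dataset from a matrix view (NA entries dropped)
pd_from_matrix <- function(ds, m, transform = ds$transform) {
  grid <- attr(m, "grid")
  idx <- which(!is.na(m), arr.ind = TRUE)
  data <- data.frame(subject = grid$subject[idx[, 1]],
                     tp = grid$tp[idx[, 1]],
                     uid = colnames(m)[idx[, 2]],
                     value = m[idx], stringsAsFactors = FALSE)
  profile_dataset(ds$catalog[ds$catalog$uid %in% colnames(m), , drop = FALSE],
                  ds$design, data, transform = transform)
}
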