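#' Study designs for time-resolved challenge metabolomics
#'
#' A study design holds the time-point grid (per-block clock times, the fluids
#' sampled at each point) and the challenge windows (baseline time point,
#' tested time points, onset clock time). Two study blocks separated by a long
#' break are never represented as contiguous elapsed time: for any analysis
#' that needs a single monotone time axis the blocks are concatenated with a
#' fixed spacer (default 720 min), which keeps time-banded matching from ever
#' pairing points across blocks.
#'
#' @param timepoints data.frame with columns \code{index}, \code{block},
#'   \code{day}, \code{clock_min} (minutes since the first scheduled sample of
#'   the block), and logical columns \code{plasma}, \code{urine},
#'   \code{breath}.
#' @param challenges list of challenge windows as returned by
#'   [challenge_window()].
#' @param subjects integer vector of subject ids.
#' @param block_spacer_min spacer inserted between blocks on the concatenated
#'   study time axis (minutes).
#' @return An object of class \code{study_design}.
#' @seealso [build_schedule()] for the built-in designs.
#' @export
study_design <- function(timepoints, challenges = list(), subjects = 1:15,
                         block_spacer_min = 720) {
  stopifnot(is.data.frame(timepoints))
  need <- c("index", "block", "day", "clock_min", "plasma", "urine", "breath")
  miss <- setdiff(need, names(timepoints))
  if (length(miss) > 0)
    stop("timepoints is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(timepoints$index))
    stop("time point indices must be unique")
  tp <- timepoints[order(timepoints$index), , drop = FALSE]
  for (b in unique(tp$block)) {
    ct <- tp$clock_min[tp$block == b]
    if (any(diff(ct) <= 0))
      stop("clock_min must be strictly increasing with index within block ", b)
    if (any(ct < 0)) stop("clock_min must be non-negative")
  }
  if (is.unsorted(tp$block))
    stop("block 2 indices must follow all block 1 indices")
  design <- structure(
    list(timepoints = tp, challenges = challenges,
         subjects = as.integer(subjects),
         block_spacer_min = block_spacer_min),
    class = "study_design")
  for (ch in challenges) {
    bad <- setdiff(c(ch$baseline_tp, ch$tested_tps), tp$index)
    if (length(bad) > 0)
      stop("challenge ", ch$name, " references unknown time point(s): ",
           paste(bad, collapse = ", "))
    if (any(study_time(design, ch$tested_tps) <=
            study_time(design, ch$baseline_tp)))
      stop("challenge ", ch$name, ": baseline must precede all tested points")
  }
  design
}

#' Define a challenge window
#'
#' @param name challenge label, one of \code{FASTING, SLDR, SLD1, OGTT, SLD2,
#'   OLTT, PAT, STRESS}.
#' @param baseline_tp index of the challenge-specific baseline time point.
#' @param tested_tps ordered indices of the time points in the tested period.
#' @param onset_clock_min challenge start, on the block clock (may be negative
#'   when the challenge began before the first sample, as for overnight
#'   fasting).
#' @param period_label free-text description of the tested period.
#' @export
challenge_window <- function(name, baseline_tp, tested_tps, onset_clock_min,
                             period_label = "") {
  name <- toupper(name)
  known <- c("FASTING", "SLDR", "SLD1", "OGTT", "SLD2", "OLTT", "PAT", "STRESS")
  if (!name %in% known)
    stop("unknown challenge name '", name, "'")
  list(name = name, baseline_tp = as.integer(baseline_tp),
       tested_tps = as.integer(tested_tps),
       onset_clock_min = onset_clock_min, period_label = period_label)
}

#' @export
print.study_design <- function(x, ...) {
  tp <- x$timepoints
  cat("Study design:", nrow(tp), "time points in", length(unique(tp$block)),
      "block(s),", length(x$subjects), "subjects\n")
  cat("  plasma:", sum(tp$plasma), " urine:", sum(tp$urine),
      " breath:", sum(tp$breath), "\n")
  if (length(x$challenges) > 0) {
    cat("  challenges:\n")
    for (ch in x$challenges)
      cat(sprintf("    %-8s baseline tp %d, %d tested tp(s) %s\n", ch$name,
                  ch$baseline_tp, length(ch$tested_tps),
                  if (nzchar(ch$period_label)) paste0("(", ch$period_label, ")") else ""))
  }
  invisible(x)
}

#' Concatenated study time axis
#'
#' Maps time-point indices to a single monotone time coordinate: block-internal
#' clock time plus, for later blocks, the end of the previous block and the
#' inter-block spacer. The real between-block break is deliberately not
#' represented as elapsed time.
#'
#' @param design a [study_design()].
#' @param tps time-point indices (default: all).
#' @return numeric vector of study times (min), in the order of \code{tps}.
#' @export
study_time <- function(design, tps = design$timepoints$index) {
  tp <- design$timepoints
  blocks <- sort(unique(tp$block))
  offset <- stats::setNames(numeric(length(blocks)), blocks)
  run <- 0
  for (b in blocks) {
    offset[as.character(b)] <- run
    run <- run + max(tp$clock_min[tp$block == b]) + design$block_spacer_min
  }
  i <- match(tps, tp$index)
  if (anyNA(i)) stop("unknown time point index: ",
                     paste(tps[is.na(i)], collapse = ", "))
  unname(tp$clock_min[i] + offset[as.character(tp$block[i])])
}

#' Study-axis span of the extended fasting challenge
#'
#' Returns the interval (in concatenated study time) from the fasting baseline
#' to the last tested fasting time point, used to widen the time band of the
#' windowed Frechet distance during extended fasting. \code{NULL} when the
#' design has no FASTING challenge.
#'
#' @param design a [study_design()].
#' @export
fasting_span <- function(design) {
  for (ch in design$challenges) {
    if (ch$name == "FASTING") {
      tt <- study_time(design, c(ch$baseline_tp, ch$tested_tps))
      return(range(tt))
    }
  }
  NULL
}

find_challenge <- function(design, name) {
  name <- toupper(name)
  for (ch in design$challenges) if (ch$name == name) return(ch)
  stop("challenge '", name, "' not found in the study design")
}

tp_block <- function(design, tps) {
  i <- match(tps, design$timepoints$index)
  design$timepoints$block[i]
}

tp_clock <- function(design, tps) {
  i <- match(tps, design$timepoints$index)
  design$timepoints$clock_min[i]
}

#' Built-in study schedules
#'
#' \code{"challenge56"} is the built-in two-block, four-day challenge design:
#' 56 plasma time points (28 per block) and 16 urine time points, with eight
#' challenge windows (extended fasting tested 12--36 h into the fast; mixed
#' meal drinks SLDr/SLD1/SLD2; oral glucose and lipid tolerance tests; a 30-min
#' exercise bout; a cold stress test). The exact clock times are an
#' approximation of that class of protocol: dense 15--120 min postprandial
#' sampling after each drink, sparser sampling during fasting and overnight.
#' Analyses in this package are schedule-agnostic, so a user-supplied design
#' (see [read_design()]) replaces it transparently.
#'
#' \code{"uniform"} is a regular grid with one synthetic meal-type challenge
#' per block, for simulation studies.
#'
#' @param name \code{"challenge56"} or \code{"uniform"}.
#' @param spacing,n_per_block grid spacing (min) and points per block for the
#'   uniform design.
#' @param n_blocks number of blocks for the uniform design.
#' @param subjects subject ids.
#' @return A [study_design()].
#' @examples
#' d <- build_schedule("challenge56")
#' sum(d$timepoints$plasma)   # 56
#' @export
build_schedule <- function(name = c("challenge56", "uniform"), spacing = 60,
                           n_per_block = 8, n_blocks = 1, subjects = 1:15) {
  name <- match.arg(name)
  if (name == "challenge56") return(schedule_challenge56(subjects))
  ## uniform grid, one synthetic meal challenge per block (onset at the
  ## block's second time point)
  tps <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    data.frame(block = b, clock_min = spacing * (seq_len(n_per_block) - 1))
  }))
  tps$index <- seq_len(nrow(tps))
  tps$day <- 2L * (tps$block - 1L) + 1L + (tps$clock_min + 480) %/% 1440
  tps$plasma <- TRUE; tps$urine <- TRUE; tps$breath <- FALSE
  challenges <- lapply(seq_len(n_blocks), function(b) {
    idx <- tps$index[tps$block == b]
    challenge_window(if (b == 1) "OGTT" else "SLD2", baseline_tp = idx[1],
                     tested_tps = idx[-1],
                     onset_clock_min = tps$clock_min[tps$index == idx[1]],
                     period_label = "synthetic")
  })
  study_design(tps[, c("index", "block", "day", "clock_min",
                       "plasma", "urine", "breath")],
               challenges, subjects = subjects)
}

schedule_challenge56 <- function(subjects = 1:15) {
  ## Block 1 (days 1-2): clock 0 = 08:00 day 1, 12 h into the fast.
  b1 <- c(0, 120, 240, 360, 480, 600, 780, 960, 1200, 1440,   # fasting 12-36 h
          1440 + c(15, 30, 45, 60, 90, 120, 180, 240),        # SLDr breakfast
          1680 + c(15, 30, 45, 60, 90, 120, 180, 240),        # SLD1 lunch
          2040, 2160)                                         # day-2 evening
  ## Block 2 (days 3-4): clock 0 = 08:00 day 3.
  b2 <- c(0,                                                  # OGTT baseline
          15, 30, 45, 60, 90, 120,                            # OGTT 0-2 h
          230,                                                # pre-lunch
          240 + c(15, 30, 45, 60, 90, 180),                   # SLD2 0-3 h
          530, 555, 570,                                      # PAT base + 0-30'
          720,                                                # day-3 evening
          1440, 1465, 1480,                                   # stress base + 0-30'
          1550,                                               # OLTT baseline
          1560 + c(15, 30, 60, 120, 180, 240))                # OLTT 0-4 h
  stopifnot(length(b1) == 28, length(b2) == 28)
  tps <- data.frame(index = 1:56,
                    block = rep(1:2, each = 28),
                    clock_min = c(b1, b2))
  tps$day <- 2L * (tps$block - 1L) + 1L + (tps$clock_min + 480) %/% 1440
  tps$plasma <- TRUE
  tps$urine <- tps$index %in% c(1, 4, 7, 10, 14, 18, 22, 26,
                                28, 29, 35, 42, 45, 46, 49, 56)
  tps$breath <- FALSE
  challenges <- list(
    challenge_window("FASTING", 1, 2:10, onset_clock_min = -720,
                     period_label = "12-36 h"),
    challenge_window("SLDR", 10, 11:18, onset_clock_min = 1440,
                     period_label = "0-4 h"),
    challenge_window("SLD1", 18, 19:26, onset_clock_min = 1680,
                     period_label = "0-4 h"),
    challenge_window("OGTT", 29, 30:35, onset_clock_min = 0,
                     period_label = "0-2 h"),
    challenge_window("SLD2", 36, 37:42, onset_clock_min = 240,
                     period_label = "0-3 h"),
    challenge_window("PAT", 43, 44:45, onset_clock_min = 540,
                     period_label = "0-30 min"),
    challenge_window("STRESS", 47, 48:49, onset_clock_min = 1450,
                     period_label = "0-30 min"),
    challenge_window("OLTT", 50, 51:56, onset_clock_min = 1560,
                     period_label = "0-4 h"))
  study_design(tps, challenges, subjects = subjects)
}

#' Read / write a study design as JSON
#'
#' @param path file path.
#' @param design a [study_design()].
#' @rdname design_io
#' @export
read_design <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- list()
  if (!is.null(j$challenges) && length(j$challenges) > 0) {
    raw <- j$challenges
    if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
    ch <- lapply(raw, function(r)
      challenge_window(r$name, r$baseline_tp, unlist(r$tested_tps),
                       r$onset_clock_min,
                       if (is.null(r$period_label)) "" else r$period_label))
    names(ch) <- NULL
  }
  study_design(as.data.frame(j$timepoints), ch, subjects = j$subjects,
               block_spacer_min = j$block_spacer_min)
}

#' @rdname design_io
#' @export
write_design <- function(design, path) {
  j <- list(timepoints = design$timepoints,
            challenges = lapply(design$challenges, function(ch)
              list(name = ch$name, baseline_tp = ch$baseline_tp,
                   tested_tps = ch$tested_tps,
                   onset_clock_min = ch$onset_clock_min,
                   period_label = ch$period_label)),
            subjects = design$subjects,
            block_spacer_min = design$block_spacer_min)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
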