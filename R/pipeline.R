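CONFIG_KEYS <- list(
  top = c("input", "preprocess", "analysis", "output_dir", "seed",
          "log_level"),
  input = c("data", "catalog", "design"),
  preprocess = c("flag_outliers", "drop_flagged", "filter_missing", "impute",
                 "transform"),
  analysis = c("simulate", "similarity", "stats", "network", "validate"))

#' Load and validate a run configuration
#'
#' A run configuration (YAML or JSON) names the input files, preprocessing
#' choices, and exactly one analysis block (\code{simulate},
#' \code{similarity}, \code{stats}, \code{network} or \code{validate}) with
#' that block's parameters. Unknown keys are rejected.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return object of class \code{run_config} with defaults filled in.
#' @export
load_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(cfg), CONFIG_KEYS$top)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$input)) {
    bad <- setdiff(names(cfg$input), CONFIG_KEYS$input)
    if (length(bad) > 0)
      stop("unknown input key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$preprocess)) {
    bad <- setdiff(names(cfg$preprocess), CONFIG_KEYS$preprocess)
    if (length(bad) > 0)
      stop("unknown preprocess key(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$analysis) || length(cfg$analysis) == 0)
    stop("configuration needs exactly one analysis block")
  bad <- setdiff(names(cfg$analysis), CONFIG_KEYS$analysis)
  if (length(bad) > 0)
    stop("unknown analysis block(s): ", paste(bad, collapse = ", "))
  if (length(cfg$analysis) != 1)
    stop("configuration needs exactly one analysis block, got ",
         length(cfg$analysis), ": ", paste(names(cfg$analysis),
                                           collapse = ", "))
  defaults <- list(output_dir = ".", seed = 1L, log_level = "info",
                   preprocess = list())
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  pp_defaults <- list(flag_outliers = FALSE, drop_flagged = FALSE,
                      filter_missing = NA_real_, impute = "none",
                      transform = "none")
  for (k in names(pp_defaults))
    if (is.null(cfg$preprocess[[k]])) cfg$preprocess[[k]] <- pp_defaults[[k]]
  if (!cfg$preprocess$impute %in% c("none", "linear", "knn"))
    stop("impute must be one of none, linear, knn")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

log_msg <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warning = 3, error = 4)
  if (levels[level] >= levels[cfg$log_level])
    message("[", level, "] ", ...)
}

#' Execute a configured run
#'
#' Runs the configured analysis block and writes its artifacts plus a
#' provenance JSON (settings, seed, package version, input checksums) into
#' the output directory. Errors from any stage propagate.
#'
#' @param cfg a [load_config()] configuration (or path to one).
#' @return (invisibly) named character vector of artifact paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  block <- names(cfg$analysis)[1]
  params <- cfg$analysis[[1]]
  if (is.null(params)) params <- list()
  artifacts <- character(0)
  out <- function(f) file.path(cfg$output_dir, f)

  if (block == "simulate") {
    n_met <- if (is.null(params$n_metabolites)) 40 else params$n_metabolites
    scfg <- sim_config(n_metabolites = n_met,
                       n_subjects = if (is.null(params$n_subjects)) 15 else
                         params$n_subjects,
                       missing_mcar = if (is.null(params$missing_mcar)) 0.02
                       else params$missing_mcar,
                       missing_lod_quantile =
                         if (is.null(params$missing_lod_quantile)) 0.05 else
                           params$missing_lod_quantile,
                       seed = cfg$seed)
    sim <- simulate_dataset(scfg)
    write_long_table(sim$dataset, out("dataset.tsv"))
    write_catalog(sim$dataset$catalog, out("catalog.tsv"))
    write_design(sim$dataset$design, out("design.json"))
    jsonlite::write_json(sim$truth, out("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    artifacts <- c(dataset = out("dataset.tsv"), catalog = out("catalog.tsv"),
                   design = out("design.json"),
                   truth = out("ground_truth.json"))
  } else {
    ds <- load_input(cfg)
    ds <- apply_preprocess(ds, cfg)
    if (block == "stats") {
      scan <- paired_t_scan(ds, challenge = params$challenge,
                            tps = if (is.null(params$tps)) "all" else
                              params$tps)
      v <- volcano_table(scan)
      res <- merge(as.data.frame(scan), v[, c("uid", "tp", "neg_log10_p")],
                   by = c("uid", "tp"), all.x = TRUE)
      utils::write.table(res, out("stats.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      artifacts <- c(stats = out("stats.tsv"))
    } else if (block == "similarity") {
      zs <- transform_values(ds, "zscore")
      rk <- rank_similar(zs, ref = params$ref,
                         measure = if (is.null(params$measure)) "frechet"
                         else params$measure,
                         mode = if (is.null(params$mode)) "mean_trajectory"
                         else params$mode,
                         window = if (is.null(params$window)) 30 else
                           params$window,
                         fasting_window =
                           if (is.null(params$fasting_window)) 120 else
                             params$fasting_window)
      utils::write.table(as.data.frame(rk), out("similarity.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      artifacts <- c(similarity = out("similarity.tsv"))
    } else if (block == "network") {
      fit <- dyn_pcor(ds, uids = params$uids)
      Rp <- pooled_pearson(ds, uids = params$uids)
      net <- build_ggm(fit,
                       mode = if (is.null(params$mode)) "cutoff" else
                         params$mode,
                       cutoff = if (is.null(params$cutoff)) 0.12 else
                         params$cutoff,
                       correction = if (is.null(params$correction))
                         "bonferroni" else params$correction,
                       R_plain = Rp, catalog = ds$catalog)
      export_ggm(net, out("network.graphml"), "graphml")
      export_ggm(net, out("network_edges.tsv"), "edge_tsv")
      artifacts <- c(graphml = out("network.graphml"),
                     edges = out("network_edges.tsv"))
    } else if (block == "validate") {
      fit <- dyn_pcor(ds, uids = params$uids)
      Rp <- pooled_pearson(ds, uids = params$uids)
      net <- build_ggm(fit, mode = "significance", correction = "bonferroni",
                       R_plain = Rp, catalog = ds$catalog)
      graph <- read_compound_graph(params$graph)
      map_df <- utils::read.delim(params$map, header = TRUE,
                                  stringsAsFactors = FALSE)
      id_map <- stats::setNames(map_df[[2]], map_df[[1]])
      prof <- pathway_distance_profile(net, graph, id_map)
      boot <- bootstrap_relabel(net, graph, id_map,
                                n_iter = if (is.null(params$iters)) 1000 else
                                  params$iters, seed = cfg$seed)
      jsonlite::write_json(list(distance_counts = as.list(prof$counts),
                                n_mappable = prof$n_mappable,
                                observed_d1 = boot$observed_count,
                                max_null = boot$max_null,
                                empirical_p = boot$empirical_p),
                           out("validation.json"), auto_unbox = TRUE,
                           digits = NA)
      artifacts <- c(validation = out("validation.json"))
    }
  }
  prov <- list(package = "metabodyn",
               version = as.character(utils::packageVersion("metabodyn")),
               seed = cfg$seed, block = block, settings = cfg$analysis,
               preprocess = cfg$preprocess,
               input_checksums = input_checksums(cfg))
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  artifacts <- c(artifacts, provenance = out("provenance.json"))
  log_msg(cfg, "info", "block '", block, "' complete: ",
          length(artifacts), " artifact(s)")
  invisible(artifacts)
}

load_input <- function(cfg) {
  inp <- cfg$input
  if (is.null(inp$data) || is.null(inp$catalog) || is.null(inp$design))
    stop("analysis blocks need input: data, catalog and design paths")
  for (p in unlist(inp)) if (!file.exists(p)) stop("input file not found: ", p)
  design <- read_design(inp$design)
  catalog <- read_catalog(inp$catalog)
  read_long_table(inp$data, catalog, design)
}

apply_preprocess <- function(ds, cfg) {
  pp <- cfg$preprocess
  ds <- log2_values(ds)
  if (isTRUE(pp$flag_outliers) || isTRUE(pp$drop_flagged)) {
    rep <- flag_outliers(ds)
    utils::write.table(rep$flagged,
                       file.path(cfg$output_dir, "outliers.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (isTRUE(pp$drop_flagged)) ds <- drop_flagged(ds, rep)
  }
  if (!is.na(pp$filter_missing))
    ds <- filter_missingness(ds, pp$filter_missing)
  if (pp$impute == "linear") ds <- impute_linear(ds)
  if (pp$impute == "knn") ds <- impute_knn(ds)
  if (!identical(pp$transform, "none") && !is.null(pp$transform) &&
      !is.na(pp$transform))
    ds <- transform_values(ds, pp$transform)
  ds
}

input_checksums <- function(cfg) {
  files <- unlist(cfg$input)
  if (is.null(files)) return(NULL)
  files <- files[file.exists(files)]
  if (length(files) == 0) return(NULL)
  as.list(tools::md5sum(files))
}
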