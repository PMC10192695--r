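#' Default pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Defaults follow the
#' reference analysis conventions: 10 s segments at 256 Hz over 23 channels,
#' 0.5-40 Hz zero-phase band-pass, STE threshold 0.02 bits, Kuramoto
#' coupling constant K = 3.5 with intrinsic frequencies evenly spaced over
#' \[0, 1\].
#'
#' @param n_per_class Synthetic segments per class (default 10).
#' @param stages Character vector of stages to run, in order, from
#'   `c("preprocess", "hht", "classify", "ste", "metrics", "kuramoto")`.
#' @param master_seed Master seed for data generation and training.
#' @param out_dir Output directory (created if missing).
#' @param ictal_spec,interictal_spec Regime specs for the generator.
#' @param filter_lo,filter_hi Band-pass edges in Hz.
#' @param ste_threshold Network threshold in bits (default 0.02).
#' @param classifier Optional [classifier_config()]; epochs default 20.
#' @param kuramoto Optional [kuramoto_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_class = 10L,
                            stages = c("preprocess", "hht", "ste",
                                       "metrics", "kuramoto"),
                            master_seed = 1L,
                            out_dir = tempfile("ictalnet-run-"),
                            ictal_spec = regime_spec("ictal"),
                            interictal_spec = regime_spec("interictal"),
                            filter_lo = 0.5, filter_hi = 40,
                            ste_threshold = 0.02,
                            classifier = classifier_config(),
                            kuramoto = kuramoto_config()) {
  known <- c("preprocess", "hht", "classify", "ste", "metrics", "kuramoto")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("unknown stages: %s", paste(bad, collapse = ", "))
  if ("metrics" %in% stages && !("ste" %in% stages))
    stopf("the metrics stage requires the ste stage")
  if ("kuramoto" %in% stages && !("ste" %in% stages))
    stopf("the kuramoto stage requires the ste stage")
  if ("classify" %in% stages && !("hht" %in% stages))
    stopf("the classify stage requires the hht stage")
  structure(list(n_per_class = as.integer(n_per_class), stages = stages,
                 master_seed = as.integer(master_seed), out_dir = out_dir,
                 ictal_spec = ictal_spec, interictal_spec = interictal_spec,
                 filter_lo = filter_lo, filter_hi = filter_hi,
                 ste_threshold = ste_threshold, classifier = classifier,
                 kuramoto = kuramoto),
            class = "pipeline_config")
}

#' Run the analysis pipeline on synthetic data
#'
#' Executes the requested stages in order on a generated balanced dataset:
#' band-pass preprocessing, HHT band energies (and spectrogram stacks +
#' classifier when requested), STE matrices and thresholded networks,
#' network metrics with a group summary, and a Kuramoto synchronization
#' comparison on one matched-weight network pair. All artifacts are written
#' under `cfg$out_dir` along with a JSON run manifest (config hash, seed,
#' per-stage record counts).
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) stopf("`cfg` must be a pipeline_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  log_stage <- function(stage, n_in, n_out, t0)
    message(sprintf("[%s] in=%d out=%d elapsed=%.1fs", stage, n_in, n_out,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ictalnet")),
    master_seed = cfg$master_seed,
    config_hash = config_hash(paste(utils::capture.output(utils::str(
      cfg[setdiff(names(cfg), "out_dir")])), collapse = "\n")),
    stages = cfg$stages, counts = list())

  t0 <- Sys.time()
  ds <- generate_dataset(cfg$n_per_class, cfg$ictal_spec, cfg$interictal_spec,
                         master_seed = cfg$master_seed)
  segs <- ds$segments
  manifest$counts$segments <- length(segs)
  log_stage("synthesize", 0L, length(segs), t0)

  if ("preprocess" %in% cfg$stages) {
    t0 <- Sys.time()
    segs <- lapply(segs, bandpass_filter, lo = cfg$filter_lo, hi = cfg$filter_hi)
    segs <- lapply(segs, remove_artifacts)
    manifest$counts$preprocessed <- length(segs)
    log_stage("preprocess", length(segs), length(segs), t0)
  }

  if ("hht" %in% cfg$stages) {
    t0 <- Sys.time()
    want_stacks <- "classify" %in% cfg$stages
    stacks <- if (want_stacks) vector("list", length(segs))
    bands <- matrix(0, length(segs), 4L,
                    dimnames = list(NULL, names(eeg_bands())))
    for (k in seq_along(segs)) {
      spectra <- segment_spectra(segs[[k]])
      pooled <- Reduce(`+`, lapply(spectra, function(h) colSums(h$grid)))
      ms <- structure(list(energy = pooled,
                           freq_edges = spectra[[1L]]$freq_edges),
                      class = "marginal_spectrum")
      bands[k, ] <- band_energy_fractions(ms)$fractions
      if (want_stacks) stacks[[k]] <- render_stack(spectra, label = ds$labels[k])
    }
    band_df <- data.frame(label = ds$labels, bands)
    write.csv(band_df, file.path(cfg$out_dir, "band_energies.csv"),
              row.names = FALSE)
    manifest$counts$band_energy_rows <- nrow(band_df)
    log_stage("hht", length(segs), nrow(band_df), t0)

    if (want_stacks) {
      t0 <- Sys.time()
      model <- train_classifier(stacks, labels = ds$labels,
                                cfg = cfg$classifier)
      jsonlite::write_json(unclass(model$holdout),
                           file.path(cfg$out_dir, "classifier_metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$counts$classified_holdout <- length(model$test_idx)
      log_stage("classify", length(stacks), length(model$test_idx), t0)
    }
  }

  if ("ste" %in% cfg$stages) {
    t0 <- Sys.time()
    nets <- vector("list", length(segs))
    for (k in seq_along(segs)) {
      M <- ste_matrix(segs[[k]])
      nets[[k]] <- threshold_network(M, cfg$ste_threshold)
    }
    net_dir <- file.path(cfg$out_dir, "networks")
    dir.create(net_dir, showWarnings = FALSE)
    for (k in seq_along(nets))
      write_network(nets[[k]],
                    file.path(net_dir, sprintf("net_%03d_%s.graphml",
                                               k, ds$labels[k])))
    manifest$counts$networks <- length(nets)
    log_stage("ste", length(segs), length(nets), t0)

    if ("metrics" %in% cfg$stages) {
      t0 <- Sys.time()
      reports <- do.call(rbind, lapply(seq_along(nets), function(k)
        network_metrics(nets[[k]], label = ds$labels[k])))
      write.csv(reports, file.path(cfg$out_dir, "network_metrics.csv"),
                row.names = FALSE)
      gs <- group_summary(reports)
      jsonlite::write_json(list(summary = gs$summary,
                                difference = as.list(gs$difference)),
                           file.path(cfg$out_dir, "group_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$counts$metric_rows <- nrow(reports)
      log_stage("metrics", length(nets), nrow(reports), t0)
    }

    if ("kuramoto" %in% cfg$stages) {
      t0 <- Sys.time()
      i_ict <- which(ds$labels == "ictal")[1L]
      i_int <- which(ds$labels == "interictal")[1L]
      res <- lapply(list(ictal = nets[[i_ict]], interictal = nets[[i_int]]),
                    function(net) {
        G <- as_coupling(net) * sync_coupling_scale()
        traj <- simulate_kuramoto(G, cfg$kuramoto)
        sync <- order_parameter(traj)
        list(sync = sync, tts = time_to_sync(sync),
             snap = snapshot(traj, times = c(0, min(150, cfg$kuramoto$T),
                                             min(1000, cfg$kuramoto$T))))
      })
      for (lbl in names(res)) {
        write.csv(data.frame(time = res[[lbl]]$sync$times, r = res[[lbl]]$sync$r),
                  file.path(cfg$out_dir, sprintf("order_parameter_%s.csv", lbl)),
                  row.names = FALSE)
        write.csv(res[[lbl]]$snap,
                  file.path(cfg$out_dir, sprintf("snapshots_%s.csv", lbl)),
                  row.names = FALSE)
      }
      jsonlite::write_json(list(ictal = res$ictal$tts,
                                interictal = res$interictal$tts),
                           file.path(cfg$out_dir, "time_to_sync.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      manifest$counts$kuramoto_runs <- 2L
      log_stage("kuramoto", 2L, 2L, t0)
    }
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a brain network as GraphML (and optionally edge-list CSV)
#'
#' GraphML carries the `weight` edge attribute; re-reading with
#' [read_network()] reproduces the edge set and weights.
#'
#' @param net A `brain_network`.
#' @param path GraphML output path.
#' @param csv_path Optional edge-list CSV path (columns source, target,
#'   weight).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, csv_path = NULL) {
  if (!inherits(net, "brain_network")) stopf("`net` must be a brain_network")
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  igraph::write_graph(g, path, format = "graphml")
  if (!is.null(csv_path))
    write.csv(data.frame(source = net$edges$from, target = net$edges$to,
                         weight = net$edges$weight),
              csv_path, row.names = FALSE)
  invisible(path)
}

#' Read a GraphML brain network written by [write_network()]
#'
#' @param path GraphML file path.
#' @param threshold Threshold recorded on the returned object (default NA).
#' @return A `brain_network`.
#' @export
read_network <- function(path, threshold = NA_real_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  el <- igraph::as_data_frame(g, what = "edges")
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(el) > 0)
    A[cbind(match(el$from, nodes), match(el$to, nodes))] <- el$weight
  edges <- data.frame(from = el$from, to = el$to, weight = el$weight,
                      stringsAsFactors = FALSE)
  ord <- order(match(edges$from, nodes), match(edges$to, nodes))
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, adjacency = A,
                 threshold = threshold, n_nodes = n,
                 density = nrow(edges) / (n * (n - 1))),
            class = "brain_network")
}
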