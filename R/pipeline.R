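#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a plain list, injects documented defaults
#' (significance levels 0.0005 / 0.02 / 0.05 for scalp-edge, scalp-network
#' and nodal inference; proportional threshold fraction 0.2; the standard
#' six-band scheme), and validates every field with actionable messages.
#' Unknown keys are an error.
#'
#' @param config file path to a YAML document, a list, or `NULL` (pure
#'   defaults).
#' @return object of class `pipeline_config` (a named list).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  defaults <- list(
    track = "scalp",
    alphas = list(scalp_edge = 5e-4, scalp_network = 0.02, nodal = 0.05),
    threshold_fraction = 0.2,
    mvar_order = "auto",
    measures = measure_registry()$measure,
    cluster_measure = "coherence",
    score = list(measure = "pdc", band = NULL, statistic = "clustering"),
    bands = NULL,
    preprocess = list(enabled = TRUE, low_pass_hz = 100, high_pass_hz = 0.5,
                      notch_hz = 50, z_thresh = 3, abs_amp_uv = 150),
    cohort = list(n_patients = 18, n_controls = 17, n_channels = 16,
                  epochs_per_subject = 60, epoch_len_s = 2, fs = 512,
                  noise_sd = 1, effect_strength = 0.35, effect_band = "theta"),
    montage_file = NULL,
    seed = 1)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$track %in% c("scalp", "nodal")) {
    stop("track must be \"scalp\" or \"nodal\"", call. = FALSE)
  }
  for (a in names(cfg$alphas)) {
    if (!(cfg$alphas[[a]] > 0 && cfg$alphas[[a]] < 1)) {
      stop("alpha ", a, " must be in (0,1)", call. = FALSE)
    }
  }
  if (!(cfg$threshold_fraction > 0 && cfg$threshold_fraction <= 1)) {
    stop("threshold_fraction must be in (0,1]", call. = FALSE)
  }
  bad <- setdiff(cfg$measures, measure_registry()$measure)
  if (length(bad) > 0) stop("unknown measures in config: ",
                            paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$bands)) {
    scheme <- tibble::tibble(band = names(cfg$bands),
                             lo = vapply(cfg$bands, `[`, numeric(1), 1),
                             hi = vapply(cfg$bands, `[`, numeric(1), 2))
    .validate_scheme(scheme)
    cfg$bands <- scheme
  } else {
    cfg$bands <- if (cfg$track == "nodal") band_scheme_nodal() else band_scheme()
  }
  if (is.null(cfg$score$band)) {
    cfg$score$band <- if ("beta" %in% cfg$bands$band) "beta" else "low_beta"
  }
  if (!is.null(cfg$montage_file) && !file.exists(cfg$montage_file)) {
    stop("montage file not found: ", cfg$montage_file, call. = FALSE)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the two-track analysis pipeline end to end
#'
#' Simulation (or supplied recordings) -> preprocessing -> spectral
#' decomposition -> connectivity -> band aggregation -> proportional
#' thresholding and network metrics -> group statistics (edge-wise at the
#' track's alpha, network metrics, per-frequency clusters, band
#' assortativity) -> ROC discriminability of the configured subject score.
#' Everything is a deterministic function of the config (and its seed).
#'
#' @param config a [validate_config()] object, list, or YAML path.
#' @param cohort optional pre-generated [generate_cohort()] result; when
#'   `NULL` a cohort is simulated from `config$cohort`.
#' @param out_dir optional directory; when given, tidy result tables and a
#'   JSON run manifest (with per-file checksums) are written there.
#' @return list with elements `edge_stats`, `network_stats`, `clusters`,
#'   `assortativity_bands`, `scores`, `roc`, `group_summary`, `manifest`,
#'   and `config`.
#' @export
run_pipeline <- function(config = NULL, cohort = NULL, out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  stage_times <- c()
  tick <- function(name) {
    stage_times[[name]] <<- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
  }

  ## ---- cohort ----------------------------------------------------------
  if (is.null(cohort)) {
    if (cfg$track == "nodal") {
      m <- make_roi_montage()
      spec <- cohort_spec(
        n_patients = cfg$cohort$n_patients, n_controls = cfg$cohort$n_controls,
        montage = m,
        effect = default_sn_effect_spec(m, strength = cfg$cohort$effect_strength),
        epochs_per_subject = cfg$cohort$epochs_per_subject,
        epoch_len_s = cfg$cohort$epoch_len_s, fs = cfg$cohort$fs,
        noise_sd = cfg$cohort$noise_sd, seed = cfg$seed)
      cohort <- generate_roi_cohort(spec)
    } else {
      m <- if (!is.null(cfg$montage_file)) read_montage(cfg$montage_file)
           else make_montage(cfg$cohort$n_channels)
      spec <- cohort_spec(
        n_patients = cfg$cohort$n_patients, n_controls = cfg$cohort$n_controls,
        montage = m,
        effect = default_effect_spec(m, strength = cfg$cohort$effect_strength,
                                     band = cfg$cohort$effect_band),
        epochs_per_subject = cfg$cohort$epochs_per_subject,
        epoch_len_s = cfg$cohort$epoch_len_s, fs = cfg$cohort$fs,
        noise_sd = cfg$cohort$noise_sd, seed = cfg$seed)
      cohort <- generate_cohort(spec)
    }
  }
  montage <- cohort$recordings[[1]]$montage
  groups <- vapply(cohort$recordings, function(r) r$group, "")
  is_pat <- groups == "patient"
  tick("simulate")

  ## ---- preprocess ------------------------------------------------------
  recs <- cohort$recordings
  if (isTRUE(cfg$preprocess$enabled)) {
    recs <- lapply(recs, function(r) {
      preprocess_recording(r, montage = montage,
                           low_pass_hz = cfg$preprocess$low_pass_hz,
                           high_pass_hz = cfg$preprocess$high_pass_hz,
                           notch_hz = cfg$preprocess$notch_hz,
                           z_thresh = cfg$preprocess$z_thresh,
                           abs_amp_uv = cfg$preprocess$abs_amp_uv)
    })
  }
  tick("preprocess")

  ## ---- connectivity + band aggregation ---------------------------------
  conn <- lapply(recs, function(r) {
    compute_all_measures(r, measures = cfg$measures, order = cfg$mvar_order)
  })
  names(conn) <- vapply(recs, function(r) r$subject_id, "")
  banded <- lapply(conn, function(ms) {
    lapply(ms, aggregate_bands, scheme = cfg$bands)
  })
  tick("connectivity")

  ## ---- edge-wise stats (scalp/nodal connectivity level) ----------------
  alpha_edge <- if (cfg$track == "nodal") cfg$alphas$nodal else cfg$alphas$scalp_edge
  edge_stats <- purrr::map_dfr(cfg$measures, function(ms) {
    res1 <- banded[[1]][[ms]]
    if (is.null(res1)) return(NULL)
    directed <- res1$directed
    k <- length(res1$labels)
    sel <- if (directed) which(row(diag(k)) != col(diag(k)))
           else which(upper.tri(diag(k)))
    purrr::map_dfr(seq_len(nrow(cfg$bands)), function(b) {
      vals <- t(vapply(banded, function(sr) sr[[ms]]$values[, , b][sel],
                       numeric(length(sel))))
      gc <- edgewise_ttest(vals[is_pat, , drop = FALSE],
                           vals[!is_pat, , drop = FALSE], alpha = alpha_edge)
      tibble::tibble(measure = ms, band = cfg$bands$band[b],
                     target = res1$labels[row(diag(k))[sel]],
                     source = res1$labels[col(diag(k))[sel]],
                     t = gc$t, p = gc$p, significant = gc$significant)
    })
  })
  tick("edge_stats")

  ## ---- network metrics + stats -----------------------------------------
  alpha_net <- if (cfg$track == "nodal") cfg$alphas$nodal else cfg$alphas$scalp_network
  network_stats <- purrr::map_dfr(cfg$measures, function(ms) {
    if (is.null(banded[[1]][[ms]])) return(NULL)
    purrr::map_dfr(cfg$bands$band, function(b) {
      met <- t(vapply(banded, function(sr) {
        g <- threshold_top_fraction(sr[[ms]], band = b,
                                    fraction = cfg$threshold_fraction)
        c(mean_degree = mean(graph_degree(g)),
          mean_clustering = mean(clustering_coefficient(g)),
          assortativity = suppressWarnings(assortativity_degree(g)))
      }, numeric(3)))
      purrr::map_dfr(colnames(met), function(metric) {
        v <- met[, metric]
        ok <- is.finite(v)
        if (sum(ok & is_pat) < 2 || sum(ok & !is_pat) < 2) return(NULL)
        gc <- edgewise_ttest(matrix(v[ok & is_pat]), matrix(v[ok & !is_pat]),
                             alpha = alpha_net)
        tibble::tibble(measure = ms, band = b, metric = metric,
                       t = gc$t, p = gc$p, significant = gc$significant,
                       mean_patient = gc$mean_patient,
                       mean_control = gc$mean_control)
      })
    })
  })
  tick("network_stats")

  ## ---- per-frequency cluster analysis (one configured measure) ---------
  clusters <- NULL
  assort_bands <- NULL
  cm <- cfg$cluster_measure
  if (cm %in% names(conn[[1]])) {
    k <- length(conn[[1]][[cm]]$labels)
    nf <- length(conn[[1]][[cm]]$freqs)
    # per-frequency node strength-degree proxy: clustering of thresholded graph
    met <- array(NA_real_, c(length(conn), k, nf))
    assort <- matrix(NA_real_, length(conn), nf)
    for (s in seq_along(conn)) {
      for (fi in seq_len(nf)) {
        g <- threshold_top_fraction(conn[[s]][[cm]], band = fi,
                                    fraction = cfg$threshold_fraction)
        met[s, , fi] <- clustering_coefficient(g)
        assort[s, fi] <- suppressWarnings(assortativity_degree(g))
      }
    }
    mc <- metric_comparison_per_frequency(
      met[is_pat, , , drop = FALSE], met[!is_pat, , , drop = FALSE],
      alpha = alpha_net, channel_labels = conn[[1]][[cm]]$labels,
      freqs = conn[[1]][[cm]]$freqs)
    clusters <- find_clusters(attr(mc, "mask"), montage,
                              t_matrix = attr(mc, "t_matrix"))
    ab <- apply(assort, 1, function(v) {
      aggregate_assortativity_bands(v, scheme = cfg$bands,
                                    freqs = conn[[1]][[cm]]$freqs)$value
    })
    ok <- apply(ab, 1, function(v) sum(is.finite(v[is_pat])) >= 2 &&
                  sum(is.finite(v[!is_pat])) >= 2)
    assort_bands <- purrr::map_dfr(which(ok), function(b) {
      v <- ab[b, ]
      fin <- is.finite(v)
      gc <- edgewise_ttest(matrix(v[fin & is_pat]), matrix(v[fin & !is_pat]),
                           alpha = alpha_net)
      tibble::tibble(band = cfg$bands$band[b], t = gc$t, p = gc$p,
                     significant = gc$significant)
    })
  }
  tick("clusters")

  ## ---- ROC discriminability --------------------------------------------
  sc_spec <- score_spec(measure = cfg$score$measure, band = cfg$score$band,
                        statistic = cfg$score$statistic,
                        fraction = cfg$threshold_fraction)
  scores <- subject_score(banded, spec = sc_spec)
  scores$group <- groups
  roc <- roc_curve(scores$score, is_pat)
  group_summary <- summarize_groups(scores$score, is_pat)
  tick("roc")

  ## ---- outputs + manifest ----------------------------------------------
  manifest <- tibble::tibble(stage = names(stage_times),
                             seconds = round(unlist(stage_times), 3))
  out <- list(edge_stats = edge_stats, network_stats = network_stats,
              clusters = clusters, assortativity_bands = assort_bands,
              scores = scores, roc = roc, group_summary = group_summary,
              manifest = manifest, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      f <- file.path(out_dir, name)
      utils::write.csv(df, f, row.names = FALSE)
      f
    }
    files <- c(wr(edge_stats, "edge_stats.csv"),
               wr(network_stats, "network_stats.csv"),
               if (!is.null(clusters)) wr(clusters, "clusters.csv"),
               if (!is.null(assort_bands)) wr(assort_bands,
                                              "assortativity_bands.csv"),
               wr(scores, "subject_scores.csv"),
               wr(roc$curve, "roc_curve.csv"))
    checks <- tools::md5sum(files)
    run_manifest <- list(
      package_version = as.character(utils::packageVersion("spectconn")),
      seed = cfg$seed, track = cfg$track,
      stages = as.list(stage_times),
      outputs = lapply(seq_along(files), function(i) {
        list(file = basename(files[i]), md5 = unname(checks[i]))
      }))
    jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out$output_files <- files
  }
  out
}
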