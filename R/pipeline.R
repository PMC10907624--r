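# End-to-end orchestration: screen -> complete submatrix -> normalization ->
# bipartite projection -> median filter -> Louvain communities ->
# target/chemistry corroboration -> efficacy/toxicity selection ->
# combination evaluation (synergy models, CR) -> proportion tests.

#' Pipeline configuration
#'
#' Collects every stage's parameters with defaults matching the canonical
#' analysis: five-dose ladder 1-10000 nM, PPT thresholds log(2)/log(0.5),
#' top 5% selection with a per-cluster cap of 4, and null proportion 0.33.
#'
#' @param screen a [screen_spec()] for synthetic input, or a path to a
#'   screen CSV ([read_screen_csv()]).
#' @param target_map NULL to skip, a list of arguments for
#'   [simulate_target_map()] (`n_proteins`, `bias`, `n_targets_per_drug`),
#'   or a path to a drug-target TSV.
#' @param fingerprints NULL to skip, a list of arguments for
#'   [simulate_fingerprints()] (`n_bits`, `within_similarity`, `density`),
#'   or a path to a fingerprint TSV.
#' @param normalization_scope `"global"` or `"per_drug"`.
#' @param submatrix_priority `"max_area"` or `"rows_first"`.
#' @param resolution,louvain_seed Louvain parameters.
#' @param ppt_threshold PPT log-ratio threshold (default `log(2)`).
#' @param fraction,per_cluster selection parameters.
#' @param dose_grid dose ladder for combination surfaces (nM).
#' @param combo_shift response-fraction interaction offset used when
#'   simulating combination surfaces for selected pairs (default 0: the
#'   surfaces follow the Bliss null).
#' @param combo_noise_sd replicate noise for simulated surfaces.
#' @param p0 null success probability of the proportion test.
#' @param seed master seed for the corroboration simulators and per-pair
#'   surface seeds.
#' @param out_dir optional directory; when set, every stage artifact is
#'   written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(screen = screen_spec(),
                            target_map = list(n_proteins = 100, bias = 0.9,
                                              n_targets_per_drug = 5),
                            fingerprints = list(n_bits = 1024,
                                                within_similarity = 0.8,
                                                density = 0.5),
                            normalization_scope = "global",
                            submatrix_priority = "max_area",
                            resolution = 1.0, louvain_seed = 0,
                            ppt_threshold = log(2),
                            fraction = 0.05, per_cluster = 4L,
                            dose_grid = c(1, 10, 100, 1000, 10000),
                            combo_shift = 0, combo_noise_sd = 0,
                            p0 = 0.33, seed = 1, out_dir = NULL) {
  if (!inherits(screen, "screen_spec") &&
      !(is.character(screen) && length(screen) == 1L)) {
    stop_field("screen", "must be a screen_spec or a CSV path")
  }
  structure(
    list(screen = screen, target_map = target_map, fingerprints = fingerprints,
         normalization_scope = match.arg(normalization_scope,
                                         c("global", "per_drug")),
         submatrix_priority = match.arg(submatrix_priority,
                                        c("max_area", "rows_first")),
         resolution = resolution, louvain_seed = louvain_seed,
         ppt_threshold = ppt_threshold, fraction = fraction,
         per_cluster = per_cluster, dose_grid = as.numeric(dose_grid),
         combo_shift = combo_shift, combo_noise_sd = combo_noise_sd,
         p0 = p0, seed = check_count(seed, "seed", min = 0L),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

# Bliss composite of two drugs' per-sample responses, averaged over a
# sample class: a screen-level proxy for the combination's mean inhibition.
.combo_screen_response <- function(m, drug1, drug2, cls) {
  idx <- m$sample_class == cls
  a <- m$a[idx, drug1]
  b <- m$a[idx, drug2]
  mean(a + b - a * b)
}

# Simulate and score a combination surface for one drug pair on one side
# (patient or healthy), with the drug's mean response as the Hill maximum.
.score_pair_side <- function(emax_a, emax_b, config, pair_seed) {
  spec <- surface_spec(
    hill_a = hill_params(e_min = 0, e_max = max(emax_a, 1e-3), ec50 = 100,
                         slope = 1),
    hill_b = hill_params(e_min = 0, e_max = max(emax_b, 1e-3), ec50 = 100,
                         slope = 1),
    dose_grid = config$dose_grid, interaction = "bliss_independent",
    shift_delta = config$combo_shift,
    replicate_noise_sd = config$combo_noise_sd, seed = pair_seed
  )
  surf <- simulate_surface(spec)
  scores <- vapply(c("hsa", "bliss", "loewe", "zip"),
                   function(mod) synergy_score(surf, mod)$score, numeric(1))
  c(scores, cr = combination_ratio(surf)$summary)
}

#' Run the full combination-design pipeline
#'
#' Executes every stage on synthetic or file-based inputs and returns a run
#' report whose manifest (parameter echo, seeds, package version) suffices
#' to re-run the analysis bit-identically. Corroboration stages (target
#' scoring, chemical similarity) are read-only with respect to the
#' clustering: they validate it but cannot alter the selection. Their
#' failure degrades gracefully to a warning.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_report` list with elements `screen`, `complete`,
#'   `response`, `network`, `filtered`, `clusters`, `targets`, `chem`,
#'   `profiles`, `selected`, `combinations`, `tests`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  screen <- if (inherits(config$screen, "screen_spec")) {
    simulate_screen(config$screen)
  } else {
    read_screen_csv(config$screen)
  }
  complete <- extract_complete_submatrix(screen, config$submatrix_priority)
  m <- normalize_inhibition(complete, config$normalization_scope)

  g <- build_bipartite(m)
  net <- project_onto_drugs(g)
  filtered <- filter_edges_median(net)
  clusters <- detect_communities(filtered, resolution = config$resolution,
                                 seed = config$louvain_seed)

  # corroboration inputs keyed to the planted labels when the screen is
  # synthetic (ground-truth chemistry/targets follow the true clusters)
  corro_labels <- if (!is.null(complete$drug_cluster)) {
    complete$drug_cluster
  } else {
    clusters$membership
  }

  targets <- tryCatch({
    map <- if (is.null(config$target_map)) NULL
    else if (is.character(config$target_map)) {
      read_target_map_tsv(config$target_map)
    } else {
      do.call(simulate_target_map,
              c(list(cluster_labels = corro_labels, seed = config$seed + 1L),
                config$target_map))
    }
    if (is.null(map)) NULL else {
      scores <- score_proteins(map, clusters)
      list(map = map, scores = scores,
           ppt = preferential_sets(scores, threshold = config$ppt_threshold),
           exclusive = exclusive_sets(map, clusters))
    }
  }, error = function(e) {
    warning(sprintf("target-scoring stage skipped: %s", conditionMessage(e)))
    NULL
  })

  chem <- tryCatch({
    fps <- if (is.null(config$fingerprints)) NULL
    else if (is.character(config$fingerprints)) {
      read_fingerprints_tsv(config$fingerprints)
    } else {
      do.call(simulate_fingerprints,
              c(list(cluster_labels = corro_labels, seed = config$seed + 2L),
                config$fingerprints))
    }
    if (is.null(fps)) NULL else {
      list(fingerprints = fps,
           homogeneity = homogeneity_test(fps, clusters))
    }
  }, error = function(e) {
    warning(sprintf("chem-similarity stage skipped: %s", conditionMessage(e)))
    NULL
  })

  profiles <- profile_drugs(m, clusters)
  selected <- select_candidates(profiles, fraction = config$fraction,
                                per_cluster = config$per_cluster)

  combinations <- NULL
  tests <- NULL
  if (nrow(selected) >= 2L) {
    combos <- label_combinations(selected$drug, clusters)
    combos$efficacy <- mapply(.combo_screen_response,
                              combos$drug1, combos$drug2,
                              MoreArgs = list(m = m, cls = "patient"))
    combos$toxicity <- mapply(.combo_screen_response,
                              combos$drug1, combos$drug2,
                              MoreArgs = list(m = m, cls = "healthy"))
    prof <- stats::setNames(profiles$efficacy, profiles$drug)
    tox <- stats::setNames(profiles$toxicity, profiles$drug)
    for (side in c("patient", "healthy")) {
      emax <- if (side == "patient") prof else tox
      suffix <- if (side == "patient") "patient" else "healthy"
      sc <- t(mapply(function(d1, d2, i) {
        .score_pair_side(emax[[d1]], emax[[d2]], config,
                         pair_seed = config$seed + 100L + i)
      }, combos$drug1, combos$drug2, seq_len(nrow(combos))))
      colnames(sc) <- paste(c("hsa", "bliss", "loewe", "zip", "cr"),
                            suffix, sep = "_")
      combos <- cbind(combos, sc)
    }
    rownames(combos) <- NULL
    combinations <- combos

    if (any(combos$group == "inter")) {
      tests <- list(
        efficacy_toxicity = proportion_test(
          combos, c("efficacy", "toxicity"), p0 = config$p0)
      )
      for (metric in c("hsa", "bliss", "loewe", "zip", "cr")) {
        tests[[metric]] <- proportion_test(
          combos, paste(metric, c("patient", "healthy"), sep = "_"),
          p0 = config$p0)
      }
    } else {
      warning("no inter-cluster combination among the selected drugs; proportion tests skipped")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("combnet")),
    config = config[setdiff(names(config), "out_dir")],
    n_samples_complete = nrow(m$a),
    n_drugs_complete = ncol(m$a),
    n_communities = length(unique(clusters$membership)),
    modularity = clusters$modularity,
    n_selected = nrow(selected),
    n_combinations = if (is.null(combinations)) 0L else nrow(combinations)
  )

  report <- structure(
    list(screen = screen, complete = complete, response = m, network = net,
         filtered = filtered, clusters = clusters, targets = targets,
         chem = chem, profiles = profiles, selected = selected,
         combinations = combinations, tests = tests, manifest = manifest),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    paste0("pipeline_report: %d x %d complete matrix, %d communities ",
           "(modularity %.3f), %d drugs selected, %d combinations\n"),
    m$n_samples_complete, m$n_drugs_complete, m$n_communities, m$modularity,
    m$n_selected, m$n_combinations))
  if (!is.null(x$tests)) {
    t0 <- x$tests$efficacy_toxicity
    cat(sprintf("  efficacy/toxicity proportion test: k = %d, n = %d, p = %.4g\n",
                t0$k, t0$n, t0$p_value))
  }
  invisible(x)
}

#' Write every stage artifact of a pipeline report to a directory
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed); one file per stage plus
#'   a JSON manifest.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_screen_csv(report$screen, p("screen_raw.csv"))
  write_screen_csv(report$complete, p("screen_complete.csv"))
  utils::write.csv(
    data.frame(sample = report$response$sample_ids,
               class = unname(report$response$sample_class),
               report$response$a, check.names = FALSE),
    p("response_matrix.csv"), row.names = FALSE)
  write_edge_list_tsv(report$network, p("drug_network_full.tsv"))
  write_edge_list_tsv(report$filtered, p("drug_network_filtered.tsv"))
  write_clusters_tsv(report$clusters, p("clusters.tsv"))
  if (!is.null(report$targets)) {
    write_target_map_tsv(report$targets$map, p("drug_targets.tsv"))
    utils::write.table(report$targets$scores, p("protein_scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$chem)) {
    write_fingerprints_tsv(report$chem$fingerprints, p("fingerprints.tsv"))
    utils::write.table(report$chem$homogeneity$tests, p("homogeneity_tests.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(report$profiles, p("drug_profiles.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report$selected, p("selected_drugs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(report$combinations)) {
    utils::write.table(report$combinations, p("combinations.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$tests)) {
    tests_json <- lapply(report$tests, function(t) {
      t[c("k", "n", "p0", "p_value", "q3", "q1", "metric_pair", "mode")]
    })
    jsonlite::write_json(tests_json, p("proportion_tests.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
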