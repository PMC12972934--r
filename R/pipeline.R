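#' Default pipeline configuration
#'
#' Returns the all-synthetic configuration the pipeline runs with when no
#' real database exports are supplied: target lists with a planted
#' 181-drug / 126-shared structure, a 126-node PPI network over the shared
#' targets with three planted clique hubs, a 50-term gene-set collection
#' with one term enriched at odds 8, and a docking table over the top-10
#' MCC hubs.
#'
#' @param seed Integer master seed.
#' @param output_dir Where artifacts are written.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1, output_dir = tempfile("netpharm_run_")) {
  list(
    seed = seed,
    output_dir = output_dir,
    targets = list(simulate = list(n_universe = 500, n_drug = 181,
                                   n_disease = 300, overlap = 126)),
    ppi = list(simulate = list(attach_m = 2, hub_nodes = 3,
                               hub_clique_size = 6),
               score_threshold = 0.4, hub_k = 10),
    enrichment = list(simulate = list(n_terms = 50, size_range = c(10, 40),
                                      enriched = 1, odds = 8),
                      alpha = 0.05, top_n = 10),
    ml = list(ratio = 0.7, percentile = 70,
              label_basis = c("degree_centrality", "betweenness",
                              "closeness"),
              holdout_label_features = FALSE),
    docking = list(simulate = list(energy_range = c(-7, -4))),
    aggregation = list(method = "borda")
  )
}

.known_config_keys <- c("seed", "output_dir", "targets", "ppi", "enrichment",
                        "ml", "docking", "aggregation")

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full target-prioritization pipeline
#'
#' Executes the chain targets -> PPI topology -> enrichment -> machine
#' learning -> evidence integration from one configuration (a list or a
#' YAML file path). Each input is either a file path (`file:`) or a
#' `simulate:` block handed to the corresponding generator. All artifacts
#' (Venn summary, node attributes, hub ranking, enrichment table, model
#' report, priority scores, evidence aggregate) are written under the
#' configured output directory together with a `report.json`; identical
#' config + seed reproduces an identical report.
#'
#' @param config Configuration list (see [default_config()]) or YAML path.
#' @return Invisibly, the pipeline report (nested list).
#' @export
run_pipeline <- function(config = default_config()) {
  config <- read_config(config)
  seed <- config$seed %||% 1L
  out <- config$output_dir %||% tempfile("netpharm_run_")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  ## stage 1: targets
  venn <- stage("targets", {
    tc <- config$targets
    if (!is.null(tc$simulate)) {
      man <- do.call(gen_target_lists,
                     c(list(seed = seed, dir = file.path(out, "inputs")),
                       tc$simulate))
      drug <- read_target_list(man$files$drug, "drug")
      disease <- read_target_list(man$files$disease, "disease")
    } else {
      drug <- read_target_list(tc$drug, "drug", column = tc$drug_column)
      disease_lists <- lapply(tc$disease, read_target_list)
      disease <- if (length(disease_lists) > 1L) {
        union_targets(disease_lists)
      } else {
        disease_lists[[1]]
      }
    }
    res <- intersect_targets(drug, disease)
    write_venn_summary(res, file.path(out, "venn_summary.csv"))
    res
  })

  ## stage 2: PPI topology + hubs
  ppi <- stage("ppi_topology", {
    pc <- config$ppi %||% list()
    thr <- pc$score_threshold %||% 0.4
    if (!is.null(pc$simulate)) {
      man <- do.call(gen_ppi_network,
                     c(list(seed = seed + 1L, dir = file.path(out, "inputs"),
                            n_nodes = venn$shared_count,
                            node_names = venn$shared),
                       pc$simulate))
      edges_path <- man$files$edges
    } else {
      edges_path <- pc$edges
    }
    g <- read_edge_list(edges_path, score_threshold = thr)
    topo <- compute_topology(g)
    hubs <- top_hubs(g, k = pc$hub_k %||% 10)
    export_network(g, topo, out)
    utils::write.csv(hubs, file.path(out, "hub_ranking.csv"),
                     row.names = FALSE)
    list(graph = g, topology = topo, hubs = hubs)
  })

  ## stage 3: enrichment
  enr <- stage("enrichment", {
    ec <- config$enrichment %||% list()
    query <- intersect(venn$shared, igraph::V(ppi$graph)$name)
    if (!is.null(ec$simulate)) {
      man <- do.call(gen_gene_sets,
                     c(list(seed = seed + 2L, dir = file.path(out, "inputs"),
                            universe = venn$shared, query = query),
                       ec$simulate))
      gmt_path <- man$files$gmt
    } else {
      gmt_path <- ec$gmt
    }
    coll <- read_gmt(gmt_path, namespace = ec$namespace %||% "geneset")
    res <- suppressMessages(ora(query, coll, universe = ec$universe))
    top <- top_terms(res, n = ec$top_n %||% 10, alpha = ec$alpha %||% 0.05)
    utils::write.csv(res, file.path(out, "enrichment_full.csv"),
                     row.names = FALSE)
    utils::write.csv(top, file.path(out, "enrichment_top.csv"),
                     row.names = FALSE)
    list(full = res, top = top)
  })

  ## stage 4: machine-learning prioritization
  ml <- stage("ml_prioritizer", {
    mc <- config$ml %||% list()
    fit <- ml_prioritize(
      ppi$topology, seed = seed + 3L,
      ratio = mc$ratio %||% 0.7,
      percentile = mc$percentile %||% 70,
      label_basis = mc$label_basis %||% c("degree_centrality",
                                          "betweenness", "closeness"),
      holdout_label_features = isTRUE(mc$holdout_label_features)
    )
    utils::write.csv(fit$scores, file.path(out, "priority_scores.csv"),
                     row.names = FALSE)
    imp <- do.call(rbind, lapply(names(fit$report$models), function(k)
      data.frame(model = k,
                 feature = names(fit$report$models[[k]]$feature_importances),
                 importance = unname(
                   fit$report$models[[k]]$feature_importances),
                 stringsAsFactors = FALSE)))
    utils::write.csv(imp, file.path(out, "feature_importances.csv"),
                     row.names = FALSE)
    fit
  })

  ## stage 5: evidence integration
  agg <- stage("evidence_integration", {
    dc <- config$docking
    docking_ranks <- NULL
    if (!is.null(dc)) {
      if (!is.null(dc$simulate)) {
        man <- do.call(gen_docking_results,
                       c(list(seed = seed + 4L,
                              dir = file.path(out, "inputs"),
                              targets = ppi$hubs$node),
                         dc$simulate))
        dpath <- man$files$docking
      } else {
        dpath <- dc$file
      }
      docking_ranks <- rank_by_energy(read_docking_table(dpath))
    } else {
      message("no docking input configured; aggregating two channels")
    }
    mcc_ranks <- stats::setNames(ppi$hubs$rank, ppi$hubs$node)
    ml_ranks <- stats::setNames(ml$scores$rank, ml$scores$target)
    ml_ranks <- ml_ranks[names(mcc_ranks)]  # fuse over the hub set
    channels <- list(mcc = mcc_ranks,
                     ml = ml_ranks[!is.na(ml_ranks)])
    if (!is.null(docking_ranks)) channels$docking <- docking_ranks
    res <- aggregate_ranks(channels,
                           method = config$aggregation$method %||% "borda")
    utils::write.csv(res, file.path(out, "evidence_aggregate.csv"),
                     row.names = FALSE)
    res
  })

  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("netpharm")),
      seed = seed,
      config = config
    ),
    venn = list(drug_count = venn$drug_count,
                disease_count = venn$disease_count,
                shared_count = venn$shared_count),
    hubs = ppi$hubs,
    enrichment_top = enr$top,
    ml = list(
      report = lapply(ml$report$models, function(m)
        m[c("accuracy_train", "f1_train", "accuracy_test", "f1_test",
            "cv10_f1_mean", "cv10_f1_sd", "overfit_gap_accuracy",
            "overfit_gap_f1", "best_hyperparameters")]),
      top_scores = utils::head(ml$scores, 10)
    ),
    evidence = agg
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
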