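#' @title Seeded synthetic-data generators
#' @description Every input the pipeline consumes (target lists, STRING-style
#'   PPI edge lists, GMT gene-set collections, docking tables, assay sheets)
#'   can be generated synthetically with a planted ground truth recorded in a
#'   manifest, so every stage is testable offline. Symbols live in a
#'   synthetic "G000001"-style namespace to avoid implying real gene
#'   identities. All generators are pure functions of their parameters and
#'   seed: the same call reproduces identical files.
#' @name synthetic_data
NULL

synth_symbols <- function(n, prefix = "G") {
  sprintf("%s%06d", prefix, seq_len(n))
}

write_manifest <- function(manifest, dir, name) {
  path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Generate drug and disease target lists with a planted overlap
#'
#' Draws disjoint symbol pools from a synthetic universe so that the drug
#' and disease lists share exactly `overlap` symbols. Optional duplicate
#' noise appends lowercase copies of some symbols, which ingestion must
#' collapse.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created).
#' @param n_universe Universe size (default 500).
#' @param n_drug,n_disease List sizes (defaults 181 and 300).
#' @param overlap Planted shared-symbol count (default 126).
#' @param dup_noise Number of duplicated (lowercased) entries appended to
#'   each file (default 0).
#' @return Manifest list: seed, parameters, planted `shared` symbols and
#'   file paths (`drug`, `disease`).
#' @export
gen_target_lists <- function(seed, dir, n_universe = 500, n_drug = 181,
                             n_disease = 300, overlap = 126, dup_noise = 0) {
  if (overlap > min(n_drug, n_disease) ||
      n_drug + n_disease - overlap > n_universe) {
    stop("infeasible target-list parameters", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  universe <- synth_symbols(n_universe)
  withr::with_seed(seed, {
    picked <- sample(universe, n_drug + n_disease - overlap)
    shared <- picked[seq_len(overlap)]
    drug_only <- picked[overlap + seq_len(n_drug - overlap)]
    disease_only <- picked[overlap + (n_drug - overlap) +
                             seq_len(n_disease - overlap)]
    drug <- sample(c(shared, drug_only))
    disease <- sample(c(shared, disease_only))
    if (dup_noise > 0) {
      drug <- c(drug, tolower(sample(drug, min(dup_noise, length(drug)))))
      disease <- c(disease,
                   tolower(sample(disease, min(dup_noise, length(disease)))))
    }
  })
  drug_path <- file.path(dir, "drug_targets.txt")
  disease_path <- file.path(dir, "disease_targets.txt")
  writeLines(drug, drug_path)
  writeLines(disease, disease_path)
  manifest <- list(generator = "gen_target_lists", seed = seed,
                   n_universe = n_universe, n_drug = n_drug,
                   n_disease = n_disease, overlap = overlap,
                   dup_noise = dup_noise, shared = sort(shared),
                   files = list(drug = drug_path, disease = disease_path))
  manifest$manifest_path <- write_manifest(manifest, dir, "targets")
  invisible(manifest)
}

#' Generate a scale-free-like PPI network with planted clique hubs
#'
#' Background: preferential attachment — each new node attaches to
#' `attach_m` distinct existing nodes with probability proportional to
#' degree. Hub planting: `hub_nodes` designated nodes are each embedded in
#' their own clique of `hub_clique_size` members recruited from the
#' lowest-degree non-hub nodes, which rewards them factorially under
#' maximal clique centrality. Edge confidence scores are drawn uniformly
#' from [0.4, 1.0] so a 0.4 threshold never severs planted structure; an
#' optional fraction of extra sub-threshold edges (scores in [0.05, 0.4))
#' exercises thresholding.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created).
#' @param n_nodes Total node count (default 100).
#' @param attach_m Attachment degree of each new node (default 2).
#' @param hub_nodes Number of planted hubs (default 3).
#' @param hub_clique_size Clique size around each hub (default 6).
#' @param subthreshold_fraction Extra droppable edges, as a fraction of the
#'   above-threshold edge count (default 0).
#' @param node_names Optional character vector of node names (length
#'   `n_nodes`); default synthetic "G" symbols.
#' @return Manifest list with planted `hubs`, per-threshold edge counts,
#'   an audit flag `hubs_are_top_mcc`, and the TSV path.
#' @export
gen_ppi_network <- function(seed, dir, n_nodes = 100, attach_m = 2,
                            hub_nodes = 3, hub_clique_size = 6,
                            subthreshold_fraction = 0, node_names = NULL) {
  if (hub_clique_size < 3 && hub_nodes > 0) {
    stop("hub_clique_size must be >= 3", call. = FALSE)
  }
  if (n_nodes <= hub_nodes * hub_clique_size) {
    stop("n_nodes must exceed hub_nodes * hub_clique_size", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(node_names)) node_names <- synth_symbols(n_nodes)
  stopifnot(length(node_names) == n_nodes, !anyDuplicated(node_names))

  edges <- withr::with_seed(seed, {
    # preferential-attachment background; the last hub_nodes*(clique-1) ids
    # are held out as fresh clique recruits with no background edges
    n_fresh <- if (hub_nodes > 0) hub_nodes * (hub_clique_size - 1L) else 0L
    n_bg <- n_nodes - n_fresh
    m0 <- attach_m + 1L
    el <- utils::combn(seq_len(m0), 2)          # seed clique
    deg <- integer(n_nodes)
    deg[seq_len(m0)] <- m0 - 1L
    pairs <- list(t(el))
    for (v in (m0 + 1L):n_bg) {
      existing <- seq_len(v - 1L)
      w <- deg[existing] + 1e-9
      att <- sample(existing, min(attach_m, v - 1L), prob = w)
      pairs[[length(pairs) + 1L]] <- cbind(att, v)
      deg[att] <- deg[att] + 1L
      deg[v] <- deg[v] + length(att)
    }
    em <- do.call(rbind, pairs)
    # plant hubs: the highest-degree background nodes become clique centers,
    # each joined into a clique with (hub_clique_size - 1) fresh recruits.
    # Recruits then score exactly (clique size - 1)! under MCC while the hub
    # adds its background neighborhood on top, making recovery sharp.
    hubs <- integer(0)
    if (hub_nodes > 0) {
      hubs <- order(-deg[seq_len(n_bg)], seq_len(n_bg))[seq_len(hub_nodes)]
      fresh <- n_bg + seq_len(n_fresh)
      for (i in seq_along(hubs)) {
        members <- c(hubs[i],
                     fresh[(i - 1L) * (hub_clique_size - 1L) +
                             seq_len(hub_clique_size - 1L)])
        cl <- utils::combn(members, 2)
        em <- rbind(em, t(cl))
      }
    }
    # dedup unordered pairs
    a <- pmin(em[, 1], em[, 2]); b <- pmax(em[, 1], em[, 2])
    keep <- !duplicated(paste(a, b))
    a <- a[keep]; b <- b[keep]
    score <- round(stats::runif(length(a), 0.4, 1.0), 3)
    df <- data.frame(node1 = node_names[a], node2 = node_names[b],
                     combined_score = score, stringsAsFactors = FALSE)
    if (subthreshold_fraction > 0) {
      n_extra <- ceiling(subthreshold_fraction * nrow(df))
      seen <- paste(a, b)
      extra <- matrix(NA_integer_, 0, 2)
      while (nrow(extra) < n_extra) {
        cand <- matrix(sample(seq_len(n_nodes), 2 * n_extra, replace = TRUE),
                       ncol = 2)
        cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
        ca <- pmin(cand[, 1], cand[, 2]); cb <- pmax(cand[, 1], cand[, 2])
        ok <- !(paste(ca, cb) %in% seen) & !duplicated(paste(ca, cb))
        extra <- rbind(extra, cbind(ca[ok], cb[ok]))
      }
      extra <- extra[seq_len(n_extra), , drop = FALSE]
      df <- rbind(df, data.frame(
        node1 = node_names[extra[, 1]], node2 = node_names[extra[, 2]],
        combined_score = round(stats::runif(n_extra, 0.05, 0.399), 3),
        stringsAsFactors = FALSE))
    }
    attr(df, "hubs") <- node_names[hubs]
    df
  })
  path <- file.path(dir, "ppi_edges.tsv")
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hubs <- attr(edges, "hubs")
  # audit: do the planted hubs hold the largest MCC scores above threshold?
  g <- read_edge_list(path, score_threshold = 0.4)
  mcc <- sort(mcc_scores(g), decreasing = TRUE)
  audit <- length(hubs) == 0 ||
    all(hubs %in% names(mcc)[seq_len(max(length(hubs), 1L))])
  manifest <- list(generator = "gen_ppi_network", seed = seed,
                   n_nodes = n_nodes, attach_m = attach_m,
                   hub_nodes = hub_nodes, hub_clique_size = hub_clique_size,
                   subthreshold_fraction = subthreshold_fraction,
                   hubs = hubs,
                   n_edges_total = nrow(edges),
                   n_edges_above_threshold = sum(edges$combined_score >= 0.4),
                   hubs_are_top_mcc = audit,
                   files = list(edges = path))
  manifest$manifest_path <- write_manifest(manifest, dir, "ppi")
  invisible(manifest)
}

#' Generate a GMT gene-set collection with planted enriched terms
#'
#' Decoy terms sample members uniformly from the universe; enriched terms
#' sample with query members weighted `odds`-fold relative to non-query
#' members, so the planted terms over-represent the query at a controlled
#' odds factor.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created).
#' @param universe Character vector of symbols.
#' @param query Character vector, subset of `universe`.
#' @param n_terms Total term count (default 50).
#' @param size_range Term-size range (default c(10, 40)).
#' @param enriched Number of planted enriched terms (default 1).
#' @param odds Sampling odds factor for query members (default 8).
#' @return Manifest with `enriched_terms`, per-term sizes, and the GMT path.
#' @export
gen_gene_sets <- function(seed, dir, universe, query, n_terms = 50,
                          size_range = c(10, 40), enriched = 1, odds = 8) {
  stopifnot(odds >= 1, all(query %in% universe),
            enriched <= n_terms, size_range[1] >= 3,
            size_range[2] <= length(universe))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("T%04d", seq_len(n_terms))
  is_enriched <- seq_len(n_terms) <= enriched
  lines <- character(n_terms)
  sizes <- integer(n_terms)
  withr::with_seed(seed, {
    w <- ifelse(universe %in% query, odds, 1)
    for (i in seq_len(n_terms)) {
      s <- sample(size_range[1]:size_range[2], 1)
      members <- if (is_enriched[i]) {
        sample(universe, s, prob = w)
      } else {
        sample(universe, s)
      }
      sizes[i] <- s
      desc <- if (is_enriched[i]) "planted_enriched" else "decoy"
      lines[i] <- paste(c(ids[i], desc, members), collapse = "\t")
    }
  })
  path <- file.path(dir, "gene_sets.gmt")
  writeLines(lines, path)
  manifest <- list(generator = "gen_gene_sets", seed = seed,
                   n_terms = n_terms, size_range = size_range,
                   odds = odds, enriched_terms = ids[is_enriched],
                   term_sizes = stats::setNames(as.list(sizes), ids),
                   files = list(gmt = path))
  manifest$manifest_path <- write_manifest(manifest, dir, "genesets")
  invisible(manifest)
}

#' Generate a synthetic docking-result table
#'
#' One uniform binding energy per target inside a negative energy window;
#' the true energy ordering is stored in the manifest.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created).
#' @param targets Character vector of target symbols.
#' @param energy_range Negative interval, default c(-7, -4) kcal/mol.
#' @return Manifest with `true_order` (targets sorted by ascending energy)
#'   and the CSV path.
#' @export
gen_docking_results <- function(seed, dir, targets,
                                energy_range = c(-7, -4)) {
  stopifnot(length(targets) >= 1, all(energy_range < 0))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  energies <- withr::with_seed(seed,
    round(stats::runif(length(targets), min(energy_range),
                       max(energy_range)), 2))
  df <- data.frame(target = targets, binding_energy = energies,
                   stringsAsFactors = FALSE)
  path <- file.path(dir, "docking_results.csv")
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- list(generator = "gen_docking_results", seed = seed,
                   energy_range = energy_range,
                   true_order = df$target[order(df$binding_energy,
                                                df$target)],
                   energies = stats::setNames(as.list(energies), targets),
                   files = list(docking = path))
  manifest$manifest_path <- write_manifest(manifest, dir, "docking")
  invisible(manifest)
}

#' Generate Gaussian assay measurement sheets
#'
#' Long-format CSV with `group`, `replicate`, `value` columns: `n_per_group`
#' Gaussian draws around each group mean. Ground-truth means are kept in the
#' manifest, so calculator outputs can be checked against closed-form values
#' at the means (exactly, when `group_sd = 0`).
#'
#' @param seed Integer seed.
#' @param dir Output directory (created).
#' @param group_means Named numeric vector of group means.
#' @param group_sd Common standard deviation (>= 0).
#' @param n_per_group Replicates per group (>= 1).
#' @param sheet_name File stem (default "assay").
#' @return Manifest with the true means and the CSV path.
#' @export
gen_assay_sheets <- function(seed, dir, group_means, group_sd = 0,
                             n_per_group = 3, sheet_name = "assay") {
  stopifnot(group_sd >= 0, n_per_group >= 1, !is.null(names(group_means)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- withr::with_seed(seed, {
    do.call(rbind, lapply(names(group_means), function(gname) {
      data.frame(group = gname, replicate = seq_len(n_per_group),
                 value = stats::rnorm(n_per_group, group_means[[gname]],
                                      group_sd),
                 stringsAsFactors = FALSE)
    }))
  })
  path <- file.path(dir, paste0(sheet_name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- list(generator = "gen_assay_sheets", seed = seed,
                   group_means = as.list(group_means), group_sd = group_sd,
                   n_per_group = n_per_group,
                   files = stats::setNames(list(path), sheet_name))
  manifest$manifest_path <- write_manifest(manifest, dir, sheet_name)
  invisible(manifest)
}
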