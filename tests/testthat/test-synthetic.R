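test_that("target-list generation plants the exact overlap and is byte-stable", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  man1 <- gen_target_lists(seed = 3, dir = d1, n_universe = 500,
                           n_drug = 181, n_disease = 300, overlap = 126)
  man2 <- gen_target_lists(seed = 3, dir = d2, n_universe = 500,
                           n_drug = 181, n_disease = 300, overlap = 126)
  expect_identical(readLines(man1$files$drug), readLines(man2$files$drug))
  expect_identical(readLines(man1$files$disease),
                   readLines(man2$files$disease))
  res <- intersect_targets(read_target_list(man1$files$drug),
                           read_target_list(man1$files$disease))
  expect_equal(res$drug_count, 181)
  expect_equal(res$shared_count, 126)
  expect_identical(res$shared, man1$shared)
  expect_error(gen_target_lists(seed = 1, dir = d1, n_universe = 50,
                                n_drug = 40, n_disease = 40, overlap = 45),
               "infeasible")
})

test_that("duplicate/case noise is collapsed by ingestion", {
  d <- withr::local_tempdir()
  man <- gen_target_lists(seed = 4, dir = d, n_universe = 100, n_drug = 50,
                          n_disease = 60, overlap = 20, dup_noise = 10)
  tl <- read_target_list(man$files$drug)
  expect_equal(tl$n_raw, 60)
  expect_equal(tl$n_unique, 50)
})

test_that("disjoint lists come out when overlap is zero", {
  d <- withr::local_tempdir()
  man <- gen_target_lists(seed = 5, dir = d, n_universe = 200, n_drug = 40,
                          n_disease = 40, overlap = 0)
  res <- intersect_targets(read_target_list(man$files$drug),
                           read_target_list(man$files$disease))
  expect_equal(res$shared_count, 0)
})

test_that("PPI generation is seeded, obeys the handshake lemma, audits hubs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  man1 <- gen_ppi_network(seed = 7, dir = d1, n_nodes = 100)
  man2 <- gen_ppi_network(seed = 7, dir = d2, n_nodes = 100)
  expect_identical(readLines(man1$files$edges), readLines(man2$files$edges))
  expect_true(man1$hubs_are_top_mcc)
  g <- read_edge_list(man1$files$edges, 0)
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
  expect_equal(man1$n_edges_total, igraph::ecount(g))
  top3 <- top_hubs(read_edge_list(man1$files$edges, 0.4), k = 3)$node
  expect_setequal(top3, man1$hubs)
  expect_error(gen_ppi_network(seed = 1, dir = d1, n_nodes = 10,
                               hub_nodes = 3, hub_clique_size = 6),
               "exceed")
})

test_that("hub-free generation is a plain attachment graph", {
  d <- withr::local_tempdir()
  man <- gen_ppi_network(seed = 8, dir = d, n_nodes = 50, hub_nodes = 0)
  expect_length(man$hubs, 0)
  expect_true(man$hubs_are_top_mcc)  # vacuous audit
  g <- read_edge_list(man$files$edges, 0.4)
  expect_equal(igraph::vcount(g), 50)
})

test_that("sub-threshold edges exist only below the confidence cut", {
  d <- withr::local_tempdir()
  man <- gen_ppi_network(seed = 9, dir = d, n_nodes = 60,
                         subthreshold_fraction = 0.3)
  g_all <- read_edge_list(man$files$edges, 0)
  g_thr <- read_edge_list(man$files$edges, 0.4)
  expect_equal(igraph::ecount(g_thr), man$n_edges_above_threshold)
  expect_gt(igraph::ecount(g_all), igraph::ecount(g_thr))
})

test_that("gene-set generation matches its manifest on re-read", {
  universe <- sprintf("G%06d", 1:200)
  d <- withr::local_tempdir()
  man <- gen_gene_sets(seed = 10, dir = d, universe = universe,
                       query = universe[1:30], n_terms = 20, enriched = 2)
  coll <- read_gmt(man$files$gmt)
  expect_length(coll$terms, 20)
  expect_equal(lengths(coll$terms)[names(man$term_sizes)],
               unlist(man$term_sizes), ignore_attr = TRUE)
  expect_true(all(man$enriched_terms %in% names(coll$terms)))
})

test_that("null gene sets (odds 1) plant no enrichment", {
  universe <- sprintf("G%06d", 1:300)
  query <- universe[1:40]
  d <- withr::local_tempdir()
  man <- gen_gene_sets(seed = 11, dir = d, universe = universe,
                       query = query, n_terms = 40, enriched = 0)
  res <- suppressMessages(ora(query, read_gmt(man$files$gmt),
                              universe = universe))
  expect_gt(min(res$q_value), 0.05 / 2)  # no overwhelming decoy signal
})

test_that("docking generation stores the true energy order", {
  d <- withr::local_tempdir()
  targets <- sprintf("T%02d", 1:10)
  man <- gen_docking_results(seed = 12, dir = d, targets = targets)
  tab <- read_docking_table(man$files$docking)
  expect_equal(nrow(tab), 10)
  ranks <- rank_by_energy(tab)
  expect_equal(names(sort(ranks)), man$true_order)
  expect_true(all(tab$binding_energy >= -7 & tab$binding_energy <= -4))
  man1 <- gen_docking_results(seed = 13, dir = d, targets = "ONLY")
  expect_equal(unname(rank_by_energy(
    read_docking_table(man1$files$docking))), 1)
})

test_that("assay sheets reproduce closed-form values at zero noise", {
  d <- withr::local_tempdir()
  man <- gen_assay_sheets(seed = 14, dir = d,
                          group_means = c(initial = 100, at_T = 40),
                          group_sd = 0, n_per_group = 3,
                          sheet_name = "scratch")
  df <- utils::read.csv(man$files$scratch)
  expect_equal(nrow(df), 6)
  init <- mean(df$value[df$group == "initial"])
  at_t <- mean(df$value[df$group == "at_T"])
  expect_equal(wound_healing_rate(init, at_t), 0.60)
})

test_that("noisy ddCt sheets recover the planted fold change within CLT bounds", {
  d <- withr::local_tempdir()
  # planted ddCt = -1 via group means (24, 20) treated, (25, 20) control
  n <- 40; sd <- 0.3
  man <- gen_assay_sheets(seed = 15, dir = d,
                          group_means = c(tt = 24, rt = 20, tc = 25,
                                          rc = 20),
                          group_sd = sd, n_per_group = n, sheet_name = "ct")
  df <- utils::read.csv(man$files$ct)
  m <- vapply(c("tt", "rt", "tc", "rc"),
              function(g) mean(df$value[df$group == g]), numeric(1))
  fold <- ddct_fold_change(m["tt"], m["rt"], m["tc"], m["rc"])
  expect_lt(abs(log2(fold) - 1), 3 * sd * 2 / sqrt(n))
})
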