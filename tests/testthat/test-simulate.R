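test_that("simulated pathways respect the configured sizes and seed", {
  cfg <- simulation_config(n_pathways = 5, seed = 3)
  pw <- simulate_pathways(cfg)
  expect_length(pw$sets, 5)
  expect_true(all(lengths(pw$sets) >= 15 & lengths(pw$sets) <= 40))
  expect_true(all(!vapply(pw$sets, anyDuplicated, integer(1))))
  expect_identical(simulate_pathways(cfg)$sets, pw$sets)
  expect_false(identical(simulate_pathways(cfg, seed = 4)$sets, pw$sets))
  expect_error(simulation_config(pathway_size_range = c(50, 700), n_genes = 600),
               "exceed")
})

test_that("multiplex generation plants enrichment and is seed-deterministic", {
  cfg <- simulation_config(seed = 5)
  pw <- simulate_pathways(cfg)
  net <- simulate_multiplex(cfg, pw)
  expect_s3_class(net$multiplex, "multiplex_network")
  expect_length(net$multiplex$layers, 3)
  expect_length(net$truth$planted_driver_genes, length(unique(net$truth$driver_table$gene)))
  expect_true(all(net$truth$planted_driver_genes %in% unlist(pw$sets)))

  net2 <- simulate_multiplex(cfg, pw)
  for (ln in names(net$multiplex$layers)) {
    expect_identical(net$multiplex$layers[[ln]]$edges,
                     net2$multiplex$layers[[ln]]$edges)
  }

  # no background and no planting -> empty layers
  cfg0 <- simulation_config(background_edge_prob = 0,
                            planted_within_pathway_prob = 0.5,
                            planted_drivers = 0, seed = 5)
  net0 <- simulate_multiplex(cfg0, pw)
  expect_true(all(vapply(net0$multiplex$layers,
                         function(l) nrow(l$edges) == 0, logical(1))))

  # planted drivers have larger mean within-pathway degree than background genes
  sens <- replicate(20, {
    s <- sample.int(1e5, 1)
    p <- simulate_pathways(cfg, seed = s)
    nt <- simulate_multiplex(cfg, p, seed = s + 1)
    rec <- build_centrality_records(nt$multiplex, p)
    planted <- rec$gene %in% nt$truth$planted_driver_genes
    mean(rec$di_P[planted]) - mean(rec$di_P[!planted])
  })
  expect_true(all(sens > 0))
})

test_that("layer edge density stays near the background probability", {
  cfg <- simulation_config(planted_drivers = 0, seed = 8)
  pw <- simulate_pathways(cfg)
  net <- simulate_multiplex(cfg, pw)
  n_pairs <- choose(cfg$n_genes, 2)
  se <- sqrt(cfg$background_edge_prob * (1 - cfg$background_edge_prob) / n_pairs)
  for (l in net$multiplex$layers) {
    dens <- nrow(l$edges) / n_pairs
    expect_lt(abs(dens - cfg$background_edge_prob), 3 * se)
  }
})

test_that("expression counts carry the planted fold changes and ground truth", {
  cfg <- simulation_config(seed = 9)
  pw <- simulate_pathways(cfg)
  net <- simulate_multiplex(cfg, pw)
  sim <- simulate_expression(cfg, net$truth)
  expect_equal(dim(sim$counts), c(600L, 80L))
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_setequal(sim$truth$planted_de_genes,
                  c(sim$truth$planted_driver_de_genes,
                    setdiff(sim$truth$planted_de_genes,
                            sim$truth$planted_driver_de_genes)))
  # drivers selected for DE are planted drivers; decoys sit outside pathways
  decoys <- setdiff(sim$truth$planted_de_genes, sim$truth$planted_driver_de_genes)
  expect_true(all(sim$truth$planted_driver_de_genes %in%
                    net$truth$planted_driver_genes))
  expect_false(any(decoys %in% net$truth$pathway_member_genes))
  expect_identical(simulate_expression(cfg, net$truth)$counts, sim$counts)

  # a null configuration records no truly DE gene
  cfg0 <- simulation_config(planted_log_fc = 0, seed = 9)
  sim0 <- simulate_expression(cfg0, net$truth)
  expect_length(sim0$truth$planted_de_genes, 0)
})

test_that("study bundles round-trip through the standard formats", {
  cfg <- simulation_config(n_genes = 150, n_pathways = 4,
                           pathway_size_range = c(8, 12),
                           planted_within_pathway_prob = 0.6,
                           n_samples_per_class = 6, n_decoy_de = 10, seed = 17)
  dir <- withr::local_tempdir()
  bundle <- generate_study(cfg, dir, overwrite = TRUE)
  expect_error(generate_study(cfg, dir), "non-empty")

  back <- read_study(dir)
  expect_equal(back$pathways$sets, bundle$pathways$sets)
  for (ln in names(bundle$multiplex$layers)) {
    expect_equal(back$multiplex$layers[[ln]]$edges,
                 bundle$multiplex$layers[[ln]]$edges, ignore_attr = TRUE)
    expect_equal(back$multiplex$layers[[ln]]$nodes,
                 bundle$multiplex$layers[[ln]]$nodes)
  }
  expect_equal(back$counts, bundle$counts)
  expect_equal(back$labels, bundle$labels)
  expect_equal(back$manifest$top_level_seed, 17)
  expect_equal(back$manifest$seed, cfg$seed)
})
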