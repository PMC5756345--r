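# Synthetic study bundles: pathways, multiplex layers with planted
# pathway-dense driver genes, and negative-binomial count matrices with
# planted fold changes, all with recorded ground truth.  Every generator
# output is a pure function of (config, seed).

#' Simulation settings for a synthetic study bundle
#'
#' Defaults describe the reference simulation regime used throughout the
#' package's evaluation: 600 genes, 12 pathways of 15-40 genes, three
#' interaction layers with Erdos-Renyi background density 0.02, three
#' planted driver genes per pathway whose within-pathway edges appear with
#' probability 0.5 in exactly two designated layers, and 40 samples per
#' class with negative-binomial counts (variance `mu + mu^2 * dispersion`)
#' in which a quarter of the planted drivers plus decoy genes carry a
#' 4-fold (log2 FC = 2) tumour shift.
#'
#' @param n_genes Gene-universe size.
#' @param n_pathways Number of pathways.
#' @param pathway_size_range Length-2 integer range of pathway sizes.
#' @param layer_names Character vector of layer (interaction-type) names.
#' @param background_edge_prob Erdos-Renyi edge probability per layer.
#' @param planted_drivers Planted driver genes per pathway.
#' @param planted_within_pathway_prob Edge probability from a planted driver
#'   to each pathway co-member in its planted layers; must exceed
#'   `background_edge_prob`.
#' @param n_layers_planted Number of layers carrying each driver's
#'   enrichment.
#' @param n_samples_per_class Samples per class in the count matrix.
#' @param nb_dispersion Negative-binomial dispersion.
#' @param planted_log_fc Absolute log2 fold change planted on DE genes; 0
#'   means no gene is truly differentially expressed.
#' @param fraction_drivers_de Fraction of planted drivers that also receive
#'   the expression shift (mirrors the minority of network drivers that are
#'   deregulated in any one condition).
#' @param n_decoy_de Number of non-pathway decoy genes receiving the shift.
#' @param baseline_mean_range Range of the log-uniform baseline means.
#' @param seed Top-level integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 600,
                              n_pathways = 12,
                              pathway_size_range = c(15, 40),
                              layer_names = c("co_localization",
                                              "physical_interaction",
                                              "shared_protein_domains"),
                              background_edge_prob = 0.02,
                              planted_drivers = 3,
                              planted_within_pathway_prob = 0.5,
                              n_layers_planted = 2,
                              n_samples_per_class = 40,
                              nb_dispersion = 0.1,
                              planted_log_fc = 2,
                              fraction_drivers_de = 0.25,
                              n_decoy_de = 40,
                              baseline_mean_range = c(20, 2000),
                              seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              layer_names = as.character(layer_names),
              background_edge_prob = background_edge_prob,
              planted_drivers = as.integer(planted_drivers),
              planted_within_pathway_prob = planted_within_pathway_prob,
              n_layers_planted = as.integer(n_layers_planted),
              n_samples_per_class = as.integer(n_samples_per_class),
              nb_dispersion = nb_dispersion,
              planted_log_fc = planted_log_fc,
              fraction_drivers_de = fraction_drivers_de,
              n_decoy_de = as.integer(n_decoy_de),
              baseline_mean_range = baseline_mean_range,
              seed = as.integer(seed))
  if (cfg$n_genes < 2 || cfg$n_pathways < 1) stopf("sizes must be positive")
  if (any(cfg$pathway_size_range < 1) ||
      cfg$pathway_size_range[2] < cfg$pathway_size_range[1]) {
    stopf("invalid pathway size range")
  }
  if (cfg$pathway_size_range[2] > cfg$n_genes) {
    stopf("pathway sizes exceed the gene universe")
  }
  probs <- c(cfg$background_edge_prob, cfg$planted_within_pathway_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$planted_within_pathway_prob <= cfg$background_edge_prob) {
    stopf("planted edge probability must exceed the background probability")
  }
  if (cfg$planted_drivers > cfg$pathway_size_range[1]) {
    stopf("more planted drivers than the smallest pathway can hold")
  }
  if (cfg$n_layers_planted > length(cfg$layer_names)) {
    stopf("cannot plant in more layers than exist")
  }
  if (cfg$n_layers_planted < 1) stopf("'n_layers_planted' must be >= 1")
  if (cfg$fraction_drivers_de < 0 || cfg$fraction_drivers_de > 1) {
    stopf("'fraction_drivers_de' must lie in [0, 1]")
  }
  structure(cfg, class = "simulation_config")
}

gene_universe <- function(config) sprintf("G%04d", seq_len(config$n_genes))

#' Simulate a pathway collection
#'
#' Samples `n_pathways` gene sets of sizes uniform in the configured range,
#' without within-pathway duplicates (genes may belong to several pathways).
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return A [gene_set_collection].
#' @export
simulate_pathways <- function(config, seed = config$seed) {
  genes <- gene_universe(config)
  with_seed(seed, {
    sizes <- sample(seq(config$pathway_size_range[1],
                        config$pathway_size_range[2]),
                    config$n_pathways, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(genes, s))
    names(sets) <- sprintf("PW%03d", seq_len(config$n_pathways))
    gene_set_collection(sets, source_name = "synthetic")
  })
}

# Sample Erdos-Renyi edges over n nodes; returns a two-column index matrix.
er_edges <- function(n, p) {
  if (p <= 0) return(matrix(integer(0), ncol = 2))
  ut <- which(upper.tri(matrix(FALSE, n, n)))
  chosen <- ut[stats::runif(length(ut)) < p]
  cbind(((chosen - 1L) %% n) + 1L, ((chosen - 1L) %/% n) + 1L)
}

#' Simulate a multiplex network with planted pathway-dense drivers
#'
#' Each layer is an Erdos-Renyi background graph at
#' `background_edge_prob`.  For every pathway, `planted_drivers` member
#' genes are designated drivers; each driver is assigned
#' `n_layers_planted` layers in which its edges to pathway co-members are
#' added independently with probability `planted_within_pathway_prob`.
#' This creates the regime the driver criterion is designed to detect:
#' genes whose within-pathway connectivity exceeds the equal-probability
#' expectation in at least two layers.
#'
#' @param config A [simulation_config()].
#' @param pathways A [gene_set_collection] over the config's gene universe.
#' @param seed Integer seed (defaults to the config seed).
#' @return List with elements `multiplex` (a [multiplex_network]) and
#'   `truth` (planted driver genes, per-driver planted layers, per-layer
#'   planted edges, pathway membership bookkeeping).
#' @export
simulate_multiplex <- function(config, pathways, seed = config$seed) {
  genes <- gene_universe(config)
  layer_names <- config$layer_names
  with_seed(seed, {
    empty_tab <- data.frame(gene = character(0), pathway = character(0),
                            layers = character(0), stringsAsFactors = FALSE)
    driver_tab <- do.call(rbind, lapply(names(pathways$sets), function(pid) {
      members <- pathways$sets[[pid]]
      if (config$planted_drivers > length(members)) {
        stopf("pathway '%s' smaller than the number of planted drivers", pid)
      }
      drv <- sample(members, config$planted_drivers)
      if (length(drv) == 0) return(empty_tab)
      do.call(rbind, lapply(drv, function(g) {
        data.frame(gene = g, pathway = pid,
                   layers = paste(sort(sample(layer_names,
                                              config$n_layers_planted)),
                                  collapse = ","),
                   stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(driver_tab)) driver_tab <- empty_tab

    planted_edges <- stats::setNames(
      lapply(layer_names, function(l) matrix(character(0), ncol = 2)),
      layer_names)
    layers <- list()
    for (ln in layer_names) {
      bg <- er_edges(config$n_genes, config$background_edge_prob)
      edges <- cbind(genes[bg[, 1]], genes[bg[, 2]])
      extra <- list()
      for (r in seq_len(nrow(driver_tab))) {
        if (!ln %in% strsplit(driver_tab$layers[r], ",", fixed = TRUE)[[1]]) next
        g <- driver_tab$gene[r]
        co <- setdiff(pathways$sets[[driver_tab$pathway[r]]], g)
        sel <- co[stats::runif(length(co)) < config$planted_within_pathway_prob]
        if (length(sel)) extra[[length(extra) + 1L]] <- cbind(rep(g, length(sel)), sel)
      }
      if (length(extra)) {
        pe <- do.call(rbind, extra)
        planted_edges[[ln]] <- pe
        edges <- rbind(edges, pe)
      }
      # node set = endpoint union, matching the convention used at ingest
      layers[[ln]] <- network_layer(ln, edges)
    }

    truth <- list(planted_driver_genes = sort(unique(driver_tab$gene)),
                  driver_table = driver_tab,
                  planted_edges = planted_edges,
                  pathway_member_genes = sort(unique(unlist(pathways$sets))))
    list(multiplex = multiplex_network(layers), truth = truth)
  })
}

#' Simulate negative-binomial expression counts with planted fold changes
#'
#' Baseline means are log-uniform in `baseline_mean_range`; counts are
#' negative binomial with variance `mu + mu^2 * dispersion`.  A fraction of
#' the planted driver genes and `n_decoy_de` decoy genes (drawn outside the
#' pathway membership, emulating deregulation unrelated to pathway-central
#' drivers) have their tumour-class mean multiplied by
#' `2^(+-planted_log_fc)` with random sign.  With `planted_log_fc = 0` no
#' gene is truly differentially expressed and the truth records empty DE
#' sets.
#'
#' @param config A [simulation_config()].
#' @param truth Truth list from [simulate_multiplex()].
#' @param seed Integer seed (defaults to the config seed).
#' @return List with `counts` (genes x samples integer matrix), `labels`
#'   (named factor), and `truth` (input truth extended with
#'   `planted_de_genes`, `planted_driver_de_genes`, `de_table`).
#' @export
simulate_expression <- function(config, truth, seed = config$seed) {
  if (config$n_samples_per_class < 2) stopf("need >= 2 samples per class")
  genes <- gene_universe(config)
  n <- config$n_samples_per_class
  samples <- c(sprintf("N%03d", seq_len(n)), sprintf("T%03d", seq_len(n)))
  labels <- sample_labels(stats::setNames(rep(c("normal", "tumour"), each = n),
                                          samples))
  with_seed(seed, {
    mu <- exp(stats::runif(config$n_genes,
                           log(config$baseline_mean_range[1]),
                           log(config$baseline_mean_range[2])))
    names(mu) <- genes

    if (config$planted_log_fc > 0) {
      drivers <- truth$planted_driver_genes
      n_dr_de <- round(config$fraction_drivers_de * length(drivers))
      dr_de <- if (n_dr_de > 0) sort(sample(drivers, n_dr_de)) else character(0)
      decoy_pool <- setdiff(genes, truth$pathway_member_genes)
      n_decoy <- min(config$n_decoy_de, length(decoy_pool))
      decoys <- if (n_decoy > 0) sort(sample(decoy_pool, n_decoy)) else character(0)
      de_genes <- c(dr_de, decoys)
      signs <- sample(c(-1, 1), length(de_genes), replace = TRUE)
    } else {
      dr_de <- character(0); decoys <- character(0)
      de_genes <- character(0); signs <- numeric(0)
    }
    mu_t <- mu
    mu_t[de_genes] <- mu[de_genes] * 2^(signs * config$planted_log_fc)

    draw <- function(means) {
      if (config$nb_dispersion > 0) {
        matrix(stats::rnbinom(length(means) * n, mu = rep(means, n),
                              size = 1 / config$nb_dispersion),
               nrow = length(means))
      } else {
        matrix(stats::rpois(length(means) * n, lambda = rep(means, n)),
               nrow = length(means))
      }
    }
    counts <- cbind(draw(mu), draw(mu_t))
    dimnames(counts) <- list(genes, samples)

    truth$planted_de_genes <- sort(de_genes)
    truth$planted_driver_de_genes <- dr_de
    truth$de_table <- data.frame(gene = de_genes,
                                 log_fc = signs * config$planted_log_fc,
                                 is_driver = de_genes %in% truth$planted_driver_genes,
                                 stringsAsFactors = FALSE)
    list(counts = counts, labels = labels, truth = truth)
  })
}

#' Generate and write a complete synthetic study bundle
#'
#' Runs the three generator stages with per-stage seeds derived from the
#' top-level seed (`seed`, `seed + 1`, `seed + 2`) and writes the bundle in
#' the package's standard formats: `pathways.gmt`, `layer_<name>.tsv`,
#' `counts.tsv`, `labels.tsv`, `truth.json`, `manifest.json`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory.
#' @param seed Top-level seed (defaults to the config seed).
#' @return Invisibly, the in-memory bundle: list with `pathways`,
#'   `multiplex`, `counts`, `labels`, `truth`, `config`, `dir`.
#' @export
generate_study <- function(config, out_dir, overwrite = FALSE,
                           seed = config$seed) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stopf("directory '%s' is non-empty; use overwrite = TRUE", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pathways <- simulate_pathways(config, seed = derive_seed(seed, 0L))
  net <- simulate_multiplex(config, pathways, seed = derive_seed(seed, 1L))
  expr <- simulate_expression(config, net$truth, seed = derive_seed(seed, 2L))

  write_gene_sets(pathways, file.path(out_dir, "pathways.gmt"))
  for (ln in names(net$multiplex$layers)) {
    write_network_layer(net$multiplex$layers[[ln]],
                        file.path(out_dir, sprintf("layer_%s.tsv", ln)))
  }
  write_expression(expr$counts, file.path(out_dir, "counts.tsv"))
  write_labels(expr$labels, file.path(out_dir, "labels.tsv"))

  truth_json <- expr$truth
  truth_json$planted_edges <- lapply(truth_json$planted_edges, function(m) {
    if (nrow(m) == 0) list() else apply(m, 1, paste, collapse = "-")
  })
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c(unclass(config), list(top_level_seed = seed))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(pathways = pathways, multiplex = net$multiplex,
                 counts = expr$counts, labels = expr$labels,
                 truth = expr$truth, config = config, dir = out_dir))
}

#' Read a study bundle written by [generate_study()]
#'
#' @param dir Bundle directory.
#' @return List with `pathways`, `multiplex`, `counts`, `labels`,
#'   `manifest`.
#' @export
read_study <- function(dir) {
  layer_files <- list.files(dir, pattern = "^layer_.*\\.tsv$", full.names = TRUE)
  layer_names <- sub("^layer_(.*)\\.tsv$", "\\1", basename(layer_files))
  layers <- Map(function(f, ln) read_network_layer(f, "edge_tsv", ln),
                layer_files, layer_names)
  names(layers) <- layer_names
  list(pathways = read_gene_sets(file.path(dir, "pathways.gmt")),
       multiplex = multiplex_network(layers),
       counts = read_expression(file.path(dir, "counts.tsv")),
       labels = read_labels(file.path(dir, "labels.tsv")),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE))
}
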