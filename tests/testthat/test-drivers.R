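make_record <- function(gene = "G", pathway = "P", layer = "L",
                        di_N = 0, di_P = 0, k = 1, m = 1) {
  data.frame(gene = gene, pathway = pathway, layer = layer,
             di_N = di_N, di_P = di_P, di_E = di_N * k / m, k = k, m = m,
             stringsAsFactors = FALSE)
}

test_that("criterion verdicts follow the strict inequality in both modes", {
  # zero within-pathway degree can never pass
  expect_false(evaluate_criterion(make_record(di_N = 5, di_P = 0, k = 5, m = 10)))
  # di_P=4, k=5, di_N=10, m=100: di_E=0.5, 0.8 > 0.5
  r <- make_record(di_N = 10, di_P = 4, k = 5, m = 100)
  expect_equal(r$di_E, 0.5)
  expect_true(evaluate_criterion(r, "literal"))
  # documented mode-divergence record: di_P=2, k=3, di_N=3, m=6 -> di_E=1.5
  d <- make_record(di_N = 3, di_P = 2, k = 3, m = 6)
  expect_equal(d$di_E, 1.5)
  expect_false(evaluate_criterion(d, "literal"))      # 2/3 is not > 1.5
  expect_true(evaluate_criterion(d, "unnormalized"))  # 2 > 1.5
  # ties are non-drivers
  t1 <- make_record(di_N = 4, di_P = 2, k = 5, m = 50)  # di_E = 0.4 = di_P/k
  expect_false(evaluate_criterion(t1, "literal"))
})

test_that("per-layer driver sets deduplicate genes across pathways", {
  calls <- driver_calls(rbind(
    make_record("G1", "P1", "A", di_N = 4, di_P = 3, k = 4, m = 100),
    make_record("G1", "P2", "A", di_N = 4, di_P = 3, k = 4, m = 100),
    make_record("G1", "P3", "A", di_N = 4, di_P = 3, k = 4, m = 100),
    make_record("G2", "P1", "A", di_N = 4, di_P = 0, k = 4, m = 100),
    make_record("G2", "P1", "B", di_N = 4, di_P = 0, k = 4, m = 100)
  ), "literal")
  expect_equal(layer_driver_set(calls, "A"), "G1")  # counted once
  expect_equal(layer_driver_set(calls, "B"), character(0))
  expect_error(layer_driver_set(calls, "Z"), "unknown layer")
})

test_that("multiplex aggregation distinguishes per-gene from per-pathway", {
  # G1 passes pathway P1 in layer A and pathway P2 in layer B
  calls <- driver_calls(rbind(
    make_record("G1", "P1", "A", di_N = 4, di_P = 3, k = 4, m = 100),
    make_record("G1", "P2", "B", di_N = 4, di_P = 3, k = 4, m = 100),
    make_record("G2", "P1", "A", di_N = 4, di_P = 3, k = 4, m = 100),
    make_record("G2", "P1", "B", di_N = 4, di_P = 3, k = 4, m = 100)
  ), "literal")
  per_gene <- multiplex_drivers(calls, min_layers = 2, aggregation = "per_gene")
  per_path <- multiplex_drivers(calls, min_layers = 2, aggregation = "per_pathway")
  expect_setequal(per_gene$driver_genes, c("G1", "G2"))
  expect_equal(per_path$driver_genes, "G2")
  expect_true(all(per_path$driver_genes %in% per_gene$driver_genes))

  # single layer with min_layers = 2 -> warning + empty set
  one <- calls[calls$layer == "A", ]
  expect_warning(r1 <- multiplex_drivers(one, min_layers = 2), "exceeds")
  expect_equal(r1$driver_genes, character(0))
})

test_that("driver sets shrink monotonically as min_layers grows", {
  set.seed(42)
  calls <- driver_calls(do.call(rbind, lapply(1:150, function(i) {
    make_record(sample(sprintf("G%02d", 1:15), 1),
                sample(c("P1", "P2", "P3"), 1),
                sample(c("A", "B", "C", "D"), 1),
                di_N = sample(0:10, 1), di_P = sample(0:6, 1),
                k = 8, m = 200)
  })), "unnormalized")
  prev <- NULL
  for (t in 1:4) {
    cur <- multiplex_drivers(calls, min_layers = t)$driver_genes
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  # min_layers = 1, per_gene: union of the per-layer sets
  r1 <- multiplex_drivers(calls, min_layers = 1)
  expect_setequal(r1$driver_genes,
                  unique(unlist(r1$per_layer_sets, use.names = FALSE)))
})

test_that("Venn regions partition the union and match brute force", {
  two <- list(A = c("g1", "g2", "g3"), B = c("h1", "h2", "h3", "h4"))
  v <- venn_region_counts(two)
  expect_equal(v$count[v$signature == "A"], 3L)
  expect_equal(v$count[v$signature == "B"], 4L)
  expect_equal(v$count[v$signature == "A&B"], 0L)

  same <- list(A = sprintf("x%d", 1:5), B = sprintf("x%d", 1:5))
  v2 <- venn_region_counts(same)
  expect_equal(v2$count[v2$signature == "A&B"], 5L)
  expect_equal(sum(v2$count[v2$signature != "A&B"]), 0L)

  # five random sets against an exhaustive membership-pattern tally
  set.seed(9)
  sets <- lapply(1:5, function(i) sample(sprintf("g%02d", 1:40), sample(5:25, 1)))
  names(sets) <- LETTERS[1:5]
  v5 <- venn_region_counts(sets)
  expect_equal(nrow(v5), 2^5 - 1)
  universe <- unique(unlist(sets))
  expect_equal(sum(v5$count), length(universe))
  pattern <- vapply(universe, function(g) {
    paste(LETTERS[1:5][vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  tally <- table(pattern)
  for (sig in names(tally)) {
    expect_equal(v5$count[v5$signature == sig], unname(as.integer(tally[sig])))
  }
})
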