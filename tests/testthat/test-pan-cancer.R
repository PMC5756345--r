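make_deg_table <- function(genes, lfc, p, condition_id = "cond") {
  select_degs(data.frame(gene = genes, log_fc = lfc, p_value = p,
                         stringsAsFactors = FALSE),
              condition_id = condition_id)
}

test_that("percentage arithmetic honours both rounding conventions", {
  expect_equal(percentage(319, 895, "round1"), 35.6)
  expect_equal(percentage(895, 1322, "truncate_int"), 67)
  expect_equal(percentage(90, 895, "truncate_int"), 10)
  expect_equal(percentage(0, 57, "round1"), 0)
  expect_equal(percentage(0, 57, "truncate_int"), 0)
  expect_error(percentage(1, 0), "denominator")
})

test_that("driver/DEG intersection is a plain set intersection", {
  dt <- make_deg_table(c("A", "B", "C", "D"),
                       c(2, -2, 2, 0.1), c(1e-9, 1e-9, 1e-9, 0.9))
  res <- intersect_driver_degs(c("B", "C", "Z"), dt)
  expect_setequal(res$driver_degs, c("B", "C"))
  expect_equal(res$pct_of_network_drivers, percentage(2, 3, "truncate_int"))

  empty_dt <- make_deg_table("A", 0.1, 0.9)
  expect_equal(intersect_driver_degs(c("A", "B"), empty_dt)$driver_degs,
               character(0))
  expect_warning(r0 <- intersect_driver_degs(character(0), dt), "empty driver")
  expect_equal(r0$pct_of_network_drivers, 0)
})

test_that("planted bundles recover the driver/DEG overlap exactly", {
  cfg <- operable_config(seed = 21)
  dir <- withr::local_tempdir()
  bundle <- suppressMessages(generate_study(cfg, dir, overwrite = TRUE))
  deg <- suppressMessages(run_dea(bundle$counts, bundle$labels))
  res <- intersect_driver_degs(bundle$truth$planted_driver_genes, deg)
  expect_setequal(res$driver_degs, bundle$truth$planted_driver_de_genes)
})

test_that("shared driver matrices are symmetric with set sizes on the diagonal", {
  mk <- function(id, genes) {
    structure(list(condition_id = id, degs = genes, driver_degs = genes,
                   pct_of_network_drivers = 0),
              class = "condition_driver_result")
  }
  a <- mk("A", c("g1", "g2", "g3", "g4"))
  b <- mk("B", c("g3", "g4", "g5"))
  m <- shared_driver_matrix(list(a, b))
  expect_equal(m["A", "B"], 2L)
  expect_equal(diag(m), c(A = 4L, B = 3L))
  expect_equal(m, t(m))
  expect_error(shared_driver_matrix(list(a, a)), "duplicate")

  set.seed(5)
  conds <- lapply(1:4, function(i) {
    mk(paste0("C", i), sample(sprintf("g%02d", 1:30), sample(5:20, 1)))
  })
  m4 <- shared_driver_matrix(conds)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(m4[i, j],
                 length(intersect(conds[[i]]$driver_degs,
                                  conds[[j]]$driver_degs)))
  }
})

test_that("FDR comparison summarises the two groups correctly", {
  dt <- make_deg_table(sprintf("G%02d", 1:20),
                       rep(c(2, -2), 10),
                       c(rep(1e-8, 5), seq(1e-4, 5e-3, length.out = 15)))
  all_degs <- dt$gene[dt$is_deg]
  same <- fdr_comparison(dt, all_degs)
  expect_equal(same$summary$median[1], same$summary$median[2])
  expect_equal(same$summary$mean[1], same$summary$mean[2])

  one <- fdr_comparison(dt, all_degs[1])
  expect_equal(one$summary$median[one$summary$group == "driver_degs"],
               dt$fdr[dt$gene == all_degs[1]])
  expect_error(fdr_comparison(dt, "NOT_A_GENE"), "absent")

  # stronger planted effects give the driver group a lower median FDR
  set.seed(33)
  n <- 25
  ids <- sprintf("S%02d", 1:(2 * n))
  lab <- sample_labels(setNames(rep(c("normal", "tumour"), each = n), ids))
  mu <- matrix(200, nrow = 120, ncol = 2 * n,
               dimnames = list(sprintf("G%03d", 1:120), ids))
  weak <- sprintf("G%03d", 1:100)   # 2.5-fold shift
  strong <- sprintf("G%03d", 101:120)  # 16-fold shift, the "driver" group
  mu[weak, lab == "tumour"] <- 200 * 2^1.3
  mu[strong, lab == "tumour"] <- 200 * 2^4
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 5), nrow = nrow(mu),
                   dimnames = dimnames(mu))
  deg <- suppressMessages(run_dea(counts, lab))
  drv_degs <- intersect(strong, deg$gene[deg$is_deg])
  cmp <- fdr_comparison(deg, drv_degs)
  med <- setNames(cmp$summary$median, cmp$summary$group)
  expect_lte(med[["driver_degs"]], med[["degs"]])
})

test_that("benchmark overlap counts catalogue membership", {
  tools <- list(t1 = c("A", "B"), t2 = c("B", "C"), t3 = c("C", "D"))
  expect_equal(benchmark_overlap(c("A", "B", "C", "E"), tools, 2), c("B", "C"))
  expect_equal(benchmark_overlap(c("A", "B"), tools, 4), character(0))
  expect_error(benchmark_overlap("A", list(), 1), "empty tool")

  set.seed(8)
  dd <- sprintf("g%02d", 1:25)
  sets <- lapply(1:6, function(i) sample(dd, sample(3:20, 1)))
  names(sets) <- paste0("tool", 1:6)
  prev <- NULL
  for (t in 1:6) {
    cur <- benchmark_overlap(dd, sets, t)
    hits <- vapply(dd, function(g) sum(vapply(sets, function(s) g %in% s,
                                              logical(1))), numeric(1))
    expect_setequal(cur, dd[hits >= t])
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})
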