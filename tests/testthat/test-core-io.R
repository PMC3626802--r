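test_that("probe panel round-trips through TSV and validates its schema", {
  m <- matrix(c(10, 20, 30, 40, 11, 21, 31, 41), 4, 2)
  rownames(m) <- paste0("p", 1:4)
  des <- array_design(c("a1", "a2"), c("A", "B"), c(1L, 1L))
  panel <- probe_panel(m, des)
  expect_equal(length(panel$probe_ids), 4L)

  ip <- tempfile(fileext = ".tsv"); dp <- tempfile(fileext = ".tsv")
  write_tsv(data.frame(probe_id = rownames(m), a1 = m[, 1], a2 = m[, 2]), ip)
  write_tsv(as.data.frame(des), dp)
  back <- read_probe_panel(ip, dp)
  expect_equal(back$intensities, panel$intensities)
  expect_equal(back$design$condition, c("A", "B"))
})

test_that("non-positive intensities are rejected naming the probe", {
  m <- matrix(c(1, 2, 0.0, 4, 5, 6), 3, 2)
  rownames(m) <- c("p1", "p2", "p3")
  m2 <- m[c(2, 3, 1), ]  # put the zero on row "p3"
  m2["p3", 1] <- 0
  err <- tryCatch(probe_panel(m2[c("p1", "p2", "p3"), ], tiny_design(2)),
                  error = identity)
  expect_s3_class(err, "uexpress_value_error")
  expect_match(conditionMessage(err), "p3")
})

test_that("design arrays must match the intensity header", {
  ip <- write_tsv(data.frame(probe_id = "p1", a1 = 2, a2 = 3))
  dp <- write_tsv(data.frame(array_id = c("a1", "a3"),
                             condition = c("A", "B"), replicate = c(1, 1)))
  expect_error(read_probe_panel(ip, dp), class = "uexpress_schema_error")
})

test_that("mapping table builds M(g, j) and rejects inconsistent gene links", {
  mt <- mapping_table(data.frame(
    probe_id = c("p1", "p1", "p2"),
    transcript_id = c("t1", "t2", "t2"),
    gene_id = "g1"))
  sets <- uexpress:::mapping_sets(mt, "g1")
  expect_setequal(sets$p1, c("t1", "t2"))
  expect_equal(sets$p2, "t2")

  expect_error(
    mapping_table(data.frame(probe_id = c("p1", "p2"),
                             transcript_id = c("t1", "t1"),
                             gene_id = c("g1", "g2"))),
    class = "uexpress_consistency_error")
})

test_that("empty mapping file reads as an empty mapping with a warning", {
  path <- tempfile(fileext = ".tsv")
  writeLines("probe_id\ttranscript_id\tgene_id", path)
  expect_warning(mt <- read_mapping_table(path), "empty")
  expect_equal(nrow(mt$links), 0L)
})

test_that("expression results round-trip losslessly with level and sd intact", {
  set.seed(1)
  er <- tiny_er(matrix(rnorm(6, 8), 3, 2),
                matrix(runif(6, 0.1, 1), 3, 2), level = "transcript")
  path <- tempfile(fileext = ".tsv")
  write_expression_result(er, path)
  back <- read_expression_result(path, er$design)
  expect_equal(back$mean, er$mean, tolerance = 1e-12)
  expect_equal(back$sd, er$sd, tolerance = 1e-12)
  expect_equal(back$level, "transcript")
})

test_that("malformed expression files are rejected", {
  # missing sd column
  path <- write_tsv(data.frame(target_id = "g1", a1_mean = 2))
  expect_error(read_expression_result(path, tiny_design(1)),
               class = "uexpress_schema_error")
  # negative sd
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("#level: gene", "target_id\ta1_mean\ta1_sd", "g1\t2\t-0.1"), path2)
  expect_error(read_expression_result(path2, tiny_design(1)),
               class = "uexpress_value_error")
})

test_that("global scaling equalises per-array statistics and is idempotent", {
  set.seed(7)
  m <- matrix(rexp(60, 1 / 20) + 1, 15, 4)
  rownames(m) <- paste0("p", 1:15)
  panel <- probe_panel(m, tiny_design(4))

  expect_identical(global_scaling_normalize(panel, "none"), panel)

  pm <- global_scaling_normalize(panel, "mean")
  mu <- colMeans(pm$intensities)
  expect_lt(max(abs(mu - mean(colMeans(m)))), 1e-9)
  expect_lt(diff(range(mu)), 1e-9)

  pmed <- global_scaling_normalize(panel, "median")
  expect_lt(diff(range(apply(pmed$intensities, 2, median))), 1e-9)

  pml <- global_scaling_normalize(panel, "meanlog")
  expect_lt(diff(range(colMeans(log(pml$intensities)))), 1e-9)

  # idempotence: applying twice equals applying once
  expect_equal(global_scaling_normalize(pm, "mean")$intensities,
               pm$intensities, tolerance = 1e-12)
  # fixed point: already centred input is unchanged
  expect_equal(global_scaling_normalize(pml, "meanlog")$intensities,
               pml$intensities, tolerance = 1e-12)

  expect_error(global_scaling_normalize(panel, "quantile"),
               class = "uexpress_usage_error")
})

test_that("two arrays with raw means 10 and 30 scale to a common mean of 20", {
  m <- cbind(a1 = c(5, 10, 15), a2 = c(15, 30, 45))
  rownames(m) <- paste0("p", 1:3)
  pm <- global_scaling_normalize(probe_panel(m, tiny_design(2)), "mean")
  expect_equal(unname(colMeans(pm$intensities)), c(20, 20), tolerance = 1e-12)
})

test_that("expression-result normalisation shifts means only, sds unchanged", {
  set.seed(2)
  er <- tiny_er(matrix(rnorm(20, 8, 2), 5, 4), design = tiny_design(4))
  for (mode in c("mean", "median", "meanlog")) {
    ern <- global_scaling_normalize(er, mode)
    expect_identical(ern$sd, er$sd)
    # per-array shift is constant across targets
    shift <- ern$mean - er$mean
    expect_lt(max(apply(shift, 2, function(col) diff(range(col)))), 1e-12)
  }
  erml <- global_scaling_normalize(er, "meanlog")
  expect_lt(diff(range(colMeans(erml$mean))), 1e-9)
})
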