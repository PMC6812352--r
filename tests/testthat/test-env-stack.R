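# Predictor stack construction, ASCII-grid I/O, correlation, pruning.

test_that("stack construction applies the union nodata mask and validates input", {
  a <- matrix(1:9, 3, 3)
  b <- matrix(9:1, 3, 3)
  a[1, 1] <- NA
  b[3, 3] <- NA
  st <- predictor_stack(list(a = a, b = b), origin = c(0, 3), cell_size = 1)
  expect_false(st$mask[1, 1])
  expect_false(st$mask[3, 3])
  expect_true(is.na(st$layers$b[1, 1])) # mask unioned into every layer
  expect_equal(sum(st$mask), 7)

  expect_error(
    predictor_stack(list(a = a, a = b), origin = c(0, 3), cell_size = 1),
    "unique"
  )
  expect_error(
    predictor_stack(list(a = a, b = matrix(1, 2, 2)), origin = c(0, 3), cell_size = 1),
    "dimensions"
  )
  expect_error(
    predictor_stack(list(a = a), origin = c(0, 3), cell_size = 0),
    "positive"
  )
})

test_that("ASCII grid round-trips and load_stack rejects misaligned rasters", {
  dir <- withr::local_tempdir()
  m <- matrix(rnorm(12), 3, 4)
  m[2, 2] <- NA
  p1 <- file.path(dir, "l1.asc")
  p2 <- file.path(dir, "l2.asc")
  p3 <- file.path(dir, "bad.asc")
  write_asc_grid(m, origin = c(10, 20), cell_size = 0.5, p1)
  write_asc_grid(m * 2, origin = c(10, 20), cell_size = 0.5, p2)
  write_asc_grid(m, origin = c(10, 20), cell_size = 0.25, p3)

  r <- read_asc_grid(p1)
  expect_equal(r$values, m, tolerance = 1e-8)
  expect_equal(r$origin, c(10, 20))
  expect_equal(r$cell_size, 0.5)

  st <- load_stack(c(p1, p2))
  expect_equal(st$layer_names, c("l1", "l2"))
  expect_equal(sum(st$mask), 11) # shared nodata cell
  expect_error(load_stack(c(p1, p3)), "not aligned")
  expect_error(load_stack(file.path(dir, "absent.asc")), "cannot read")

  # a file without nodata gives an all-valid mask
  write_asc_grid(matrix(1:4, 2, 2), c(0, 2), 1, file.path(dir, "full.asc"))
  expect_true(all(load_stack(file.path(dir, "full.asc"))$mask))
})

test_that("correlation_matrix matches exact and hand-computed coefficients", {
  st <- corr_stack()
  r <- correlation_matrix(st)
  expect_equal(r["a", "b"], 1.0) # b = 2a + 1
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_lt(max(abs(r - t(r))), 1e-12)

  neg <- predictor_stack(
    list(a = matrix(1:4, 2, 2), b = matrix(-(1:4), 2, 2)),
    origin = c(0, 2), cell_size = 1
  )
  expect_equal(correlation_matrix(neg)["a", "b"], -1.0)

  # frozen two-pass Pearson value for A=(1,2,3,4), B=(1,2,2,4)
  hand <- predictor_stack(
    list(A = matrix(c(1, 2, 3, 4), 1), B = matrix(c(1, 2, 2, 4), 1)),
    origin = c(0, 1), cell_size = 1
  )
  expect_equal(correlation_matrix(hand)["A", "B"], 0.92338052, tolerance = 1e-7)

  const <- predictor_stack(
    list(a = matrix(1:4, 2, 2), flat = matrix(5, 2, 2)),
    origin = c(0, 2), cell_size = 1
  )
  expect_error(correlation_matrix(const), "flat")
})

test_that("correlation over jointly valid cells agrees with a two-pass oracle", {
  set.seed(42)
  for (i in 1:5) {
    mats <- lapply(1:5, function(j) matrix(rnorm(100), 10, 10))
    mats[[2]][1:7] <- NA # force a nontrivial joint mask
    names(mats) <- paste0("v", 1:5)
    st <- predictor_stack(mats, origin = c(0, 10), cell_size = 1)
    x <- extract_values(st, valid_cells(st))
    oracle <- function(u, v) {
      du <- u - mean(u)
      dv <- v - mean(v)
      sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
    }
    r <- correlation_matrix(st)
    for (a in 1:4) {
      for (b in (a + 1):5) {
        expect_equal(r[a, b], oracle(x[, a], x[, b]), tolerance = 1e-10)
      }
    }
  }
})

test_that("prune_collinear follows the greedy drop rule and is idempotent", {
  set.seed(7)
  a <- rnorm(50)
  c_ <- rnorm(50)
  x <- cbind(A = a, B = a, C = c_)
  r <- cor(x)
  expect_equal(prune_collinear(r, 0.8), c("A", "C")) # duplicate B dropped by tie rule

  # nothing above cutoff: everything kept in original order
  expect_equal(prune_collinear(r, 1.0), c("A", "B", "C"))
  r2 <- cor(cbind(A = a, C = c_))
  expect_equal(prune_collinear(r2, 0.8), c("A", "C"))

  expect_error(prune_collinear(r, 0), "\\(0, 1\\]")
  expect_error(prune_collinear(r, 1.2), "\\(0, 1\\]")

  # random stacks: output has no offending pair and pruning is idempotent
  for (i in 1:10) {
    x <- matrix(rnorm(200), 20, 10)
    x[, 2] <- x[, 1] * 0.95 + rnorm(20, sd = 0.2)
    x[, 5] <- -x[, 4] + rnorm(20, sd = 0.1)
    colnames(x) <- letters[1:10]
    r <- cor(x)
    kept <- prune_collinear(r, 0.7)
    sub <- abs(r[kept, kept])
    diag(sub) <- 0
    expect_lte(max(sub), 0.7)
    expect_identical(prune_collinear(r[kept, kept], 0.7), kept)
  }
})
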