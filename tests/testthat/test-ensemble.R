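# Ensemble combination rules: max/mean (numeric) and OR / 2-of-3 (binary).

rand_grid_groups <- function(n_rep = 3, n_sub = 6, nr = 4, nc = 5, with_na = TRUE) {
  vals <- matrix(runif(nr * nc), nr, nc)
  lapply(seq_len(n_rep), function(r) {
    lapply(seq_len(n_sub), function(s) {
      m <- matrix(runif(nr * nc), nr, nc)
      if (with_na) m[1, 1] <- NA
      suitability_grid(m, origin = c(0, nr), cell_size = 1)
    })
  })
}

test_that("numeric ensemble takes the max over sub-models, the mean over replicates", {
  cellvals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.9)
  groups <- lapply(1:3, function(r) {
    lapply(cellvals, function(v) {
      suitability_grid(matrix(v, 1, 1), origin = c(0, 1), cell_size = 1)
    })
  })
  e <- numeric_ensemble(groups)
  expect_equal(e$complete[[1]]$values[1, 1], 0.9)
  expect_equal(e$final$values[1, 1], 0.9) # identical replicates: idempotent

  # complete values 0.9 / 0.6 / 0.3 across replicates average to 0.6
  groups2 <- lapply(c(0.9, 0.6, 0.3), function(v) {
    lapply(rep(v, 6), function(x) {
      suitability_grid(matrix(x, 1, 1), origin = c(0, 1), cell_size = 1)
    })
  })
  expect_equal(numeric_ensemble(groups2)$final$values[1, 1], 0.6)
})

test_that("numeric ensemble agrees with direct cellwise recomputation", {
  set.seed(6)
  for (rep in 1:5) {
    groups <- rand_grid_groups()
    e <- numeric_ensemble(groups)
    for (r in 1:3) {
      direct <- Reduce(pmax, lapply(groups[[r]], `[[`, "values"))
      expect_equal(e$complete[[r]]$values, direct)
    }
    direct_final <- (e$complete[[1]]$values + e$complete[[2]]$values +
      e$complete[[3]]$values) / 3
    expect_equal(e$final$values, direct_final)
    # max >= each element, so the final exceeds the mean of all 18 grids
    all18 <- Reduce(`+`, lapply(unlist(groups, recursive = FALSE), `[[`, "values")) / 18
    expect_true(all(e$final$values >= all18 - 1e-12, na.rm = TRUE))
    # nodata propagates
    expect_true(is.na(e$final$values[1, 1]))
  }
})

test_that("binary ensemble is any-of-submodels then majority-of-replicates", {
  bg <- function(v) {
    structure(list(values = matrix(v, 1, 1), origin = c(0, 1), cell_size = 1),
      class = "binary_grid")
  }
  one_hot <- lapply(c(0, 0, 0, 0, 0, 1), bg)
  zeros <- lapply(rep(0, 6), bg)
  e <- binary_ensemble(list(one_hot, one_hot, zeros))
  expect_equal(e$complete[[1]]$values[1, 1], 1) # at least one of six
  expect_equal(e$final$values[1, 1], 1) # present in 2 of 3
  e2 <- binary_ensemble(list(one_hot, zeros, zeros))
  expect_equal(e2$final$values[1, 1], 0) # 1 of 3 is not enough
  e3 <- binary_ensemble(list(zeros, zeros, zeros))
  expect_equal(e3$final$values[1, 1], 0)
})

test_that("binary ensemble matches recomputation and is monotone in its inputs", {
  set.seed(61)
  for (rep in 1:5) {
    groups <- lapply(1:3, function(r) {
      lapply(1:6, function(s) {
        structure(
          list(values = matrix(rbinom(20, 1, 0.3), 4, 5),
            origin = c(0, 4), cell_size = 1),
          class = "binary_grid"
        )
      })
    })
    e <- binary_ensemble(groups)
    votes <- Reduce(`+`, lapply(1:3, function(r) {
      Reduce(pmax, lapply(groups[[r]], `[[`, "values"))
    }))
    expect_equal(e$final$values, ifelse(votes >= 2, 1, 0))
    # final is a subset of the union of the complete maps
    union_ <- Reduce(pmax, lapply(e$complete, `[[`, "values"))
    expect_true(all(e$final$values <= union_))
    # flipping any 0 cell to 1 never turns the final off
    zero_at <- which(groups[[1]][[1]]$values == 0)
    if (length(zero_at)) {
      groups2 <- groups
      groups2[[1]][[1]]$values[zero_at[1]] <- 1
      e2 <- binary_ensemble(groups2)
      expect_true(all(e2$final$values >= e$final$values))
    }
  }
})

test_that("misaligned grids and wrong arities are rejected", {
  groups <- rand_grid_groups(with_na = FALSE)
  bad <- groups
  bad[[2]][[3]] <- suitability_grid(bad[[2]][[3]]$values, origin = c(5, 4), cell_size = 1)
  expect_error(numeric_ensemble(bad), "misaligned")
  expect_error(numeric_ensemble(groups[1:2]), "3 replicate")
  short <- groups
  short[[1]] <- short[[1]][1:4]
  expect_error(numeric_ensemble(short), "expected 6")
  # configurable arity passes when counts are declared
  expect_silent(numeric_ensemble(groups[1:2], n_submodels = 6, n_replicates = 2))
})
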