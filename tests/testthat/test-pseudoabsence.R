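# Pseudo-absence candidates (geographic / SRE), PA1 sampling, pairwise
# distance matching.

test_that("geographic exclusion keeps only cells far enough from presences", {
  st <- unit_stack()
  occ <- load_occurrences(data.frame(lon = 0, lat = 0), st, "sp") # center (0, 0)
  m <- geographic_candidates(st, occ, 2)
  expect_s3_class(m, "candidate_mask")
  # center (3, 0) at distance 3 is eligible; (1, 1) at sqrt(2) is not
  expect_true(m$eligible[points_to_cells(st, 3, 0)])
  expect_false(m$eligible[points_to_cells(st, 1, 1)])
  # presence cell itself never eligible
  expect_false(m$eligible[occ$cells])

  # vanishing exclusion distance: every non-presence valid cell is eligible
  m0 <- geographic_candidates(st, occ, 1e-6)
  expect_equal(sum(m0$eligible), sum(st$mask) - 1)

  # chebyshev reading: cell center (1, 0) is within 2 of the presence on both
  # axes, center (2, 0) is exactly 2 degrees away in longitude
  mc <- geographic_candidates(st, occ, 2, metric = "chebyshev")
  expect_false(mc$eligible[points_to_cells(st, 1, 0)])
  expect_true(mc$eligible[points_to_cells(st, 2, 0)])

  expect_error(geographic_candidates(st, occ, 50), "no eligible")
})

test_that("eligible geographic candidates all satisfy the distance bound", {
  fix <- std_fixture()
  m <- geographic_candidates(fix$stack, fix$occ, 2)
  cells <- which(m$eligible, arr.ind = TRUE)
  d <- rfsdm:::min_dist_to(cell_centers(fix$stack, cells), fix$occ$coords,
    distance = "degrees"
  )
  expect_gte(min(d), 2)
})

test_that("SRE envelope is closed: only strict exceedance makes a candidate", {
  a <- matrix(c(
    10, 15, 20, # presences will sit on 10 and 20
    25, 20, 12,
    14, 19, 11
  ), 3, 3, byrow = TRUE)
  st <- predictor_stack(list(a = a), origin = c(0, 3), cell_size = 1)
  occ <- occurrences_from_grid(
    matrix(c(1, 0, 1, rep(0, 6)), 3, 3, byrow = TRUE), st, "sp"
  )
  m <- sre_candidates(st, occ)
  expect_equal(m$method_tag, "sre")
  expect_true(m$eligible[2, 1]) # 25 > 20: outside
  expect_false(m$eligible[2, 2]) # exactly 20: on the closed boundary
  expect_false(m$eligible[3, 1]) # 14 inside [10, 20]
  expect_false(any(m$eligible[occ$cells])) # presences inside their own envelope
})

test_that("PA1 sampling is reproducible, exhaustive at the limit, and warns", {
  st <- unit_stack()
  occ <- load_occurrences(data.frame(lon = 0, lat = 4), st, "sp")
  m <- geographic_candidates(st, occ, 4) # few eligible cells
  n_el <- sum(m$eligible)
  expect_gte(n_el, 3)

  s1 <- sample_pa1(m, 3, seed = 9)
  s2 <- sample_pa1(m, 3, seed = 9)
  expect_equal(s1$cells, s2$cells)
  expect_equal(nrow(s1$cells), 3)
  expect_false(any(duplicated(s1$cells)))
  expect_true(all(m$eligible[s1$cells]))

  all_of_them <- sample_pa1(m, n_el, seed = 1)
  expect_equal(nrow(all_of_them$cells), n_el)
  expect_warning(big <- sample_pa1(m, n_el + 5, seed = 1), "taking all")
  expect_equal(nrow(big$cells), n_el)
  expect_error(sample_pa1(m, 0, seed = 1), ">= 1")
})

test_that("different seeds give different PA1 on a large mask", {
  fix <- std_fixture()
  m <- geographic_candidates(fix$stack, fix$occ, 2)
  a <- sample_pa1(m, 200, seed = 1)
  b <- sample_pa1(m, 200, seed = 2)
  expect_false(identical(a$cells, b$cells))
})

test_that("pairwise distance sampling matches by the tolerance rule in order", {
  ref <- cbind(lon = 0, lat = 0)
  fixed <- cbind(lon = 5, lat = 0) # d_f = 5
  cands <- cbind(lon = c(4.9, 10), lat = 0) # d_s = 4.9 and 10
  m <- pwd_sample(fixed, cands, ref, tolerance = 0.33, distance = "degrees")
  expect_equal(m, 1L) # |4.9-5| <= 1.65; 10 is ineligible

  # no eligible candidate: unmatched, reported
  expect_message(
    m2 <- pwd_sample(fixed, cbind(lon = 20, lat = 0), ref, distance = "degrees"),
    "unmatched"
  )
  expect_true(is.na(m2))

  # two presences competing for one candidate: first in input order wins
  fixed2 <- cbind(lon = c(5, 0), lat = c(0, 5))
  expect_message(
    m3 <- pwd_sample(fixed2, cbind(lon = 4.9, lat = 0), ref, distance = "degrees"),
    "1 of 2"
  )
  expect_equal(m3, c(1L, NA))

  expect_error(pwd_sample(fixed, cands, ref, tolerance = -1), "positive")
})

test_that("every pwd match satisfies the inequality and no candidate is reused", {
  set.seed(13)
  for (i in 1:5) {
    ref <- cbind(lon = runif(8, 0, 10), lat = runif(8, 0, 10))
    fixed <- cbind(lon = runif(15, 0, 10), lat = runif(15, 0, 10))
    cands <- cbind(lon = runif(40, 0, 10), lat = runif(40, 0, 10))
    m <- suppressMessages(
      pwd_sample(fixed, cands, ref, tolerance = 0.33, distance = "degrees")
    )
    ok <- !is.na(m)
    expect_false(any(duplicated(m[ok])))
    d_f <- rfsdm:::min_dist_to(fixed, ref, "degrees")
    d_s <- rfsdm:::min_dist_to(cands, ref, "degrees")
    expect_true(all(abs(d_s[m[ok]] - d_f[ok]) <= 0.33 * d_f[ok]))
  }
})
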