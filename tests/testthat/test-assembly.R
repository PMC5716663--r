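# Tetramer composition distributions, odds rendering and Monte Carlo.

test_that("composition distribution matches exhaustive draw enumeration", {
  # spot cases; the full denominator-<=8 sweep lives in the acceptance suite
  for (a in list(c(4), c(1, 1), c(1, 3), c(2, 3, 3), c(0, 1, 7))) {
    cd <- composition_distribution(pool_from_counts(a))
    orc <- oracle_composition(a)
    keys <- dist_keys(cd)
    expect_setequal(keys, orc$key)
    idx <- match(orc$key, keys)
    # exact cross-multiplied equality, no floating tolerance
    expect_identical(cd$num[idx] * orc$den, orc$num * cd$den[idx])
  }
})

test_that("composition probabilities sum exactly to one", {
  for (a in list(c(1, 7), c(1, 3), c(1, 1, 2), c(5, 2, 1))) {
    cd <- composition_distribution(pool_from_counts(a))
    k <- length(a)
    expect_equal(nrow(cd), choose(k + 3, k - 1))  # weak compositions of 4
    s <- Reduce(tetradose:::.rat_add,
                Map(function(n, d) c(n, d), cd$num, cd$den))
    expect_identical(unname(s), c(1, 1))
  }
  # floating pools still sum to 1 within 1e-12
  p <- subunit_pool(c(A = 1 / sqrt(2), B = 1 - 1 / sqrt(2)))
  expect_false(p$exact)
  expect_equal(sum(composition_distribution(p)$prob), 1, tolerance = 1e-12)
})

test_that("single-class and half-half pools give the textbook masses", {
  cd <- composition_distribution(subunit_pool(c(A = 1)))
  expect_identical(cd$prob, 1)
  cd <- composition_distribution(pool_from_counts(c(1, 1)))
  i <- which(dist_keys(cd) == "2,2")
  expect_identical(c(cd$num[i], cd$den[i]), c(3, 8))  # 6/16 reduced
})

test_that("homotetramer probability is f^4, bit-exact for the two dosages", {
  het <- homotetramer_probability(pool_from_fraction(1 / 8))
  expect_identical(c(attr(het, "num"), attr(het, "den")), c(1, 4096))
  hom <- homotetramer_probability(pool_from_fraction(1 / 4))
  expect_identical(c(attr(hom, "num"), attr(hom, "den")), c(1, 256))
  expect_identical(as.numeric(homotetramer_probability(pool_from_fraction(0))), 0)
  expect_identical(as.numeric(homotetramer_probability(pool_from_fraction(1))), 1)
  # strictly increasing in f
  f <- seq(0.05, 0.95, by = 0.1)
  v <- vapply(f, function(x)
    as.numeric(homotetramer_probability(pool_from_fraction(x))), 0)
  expect_true(all(diff(v) > 0))
  expect_error(homotetramer_probability(pool_from_fraction(1 / 4), "nope"),
               "not present")
})

test_that("leaky fraction follows the binomial tail and decreases in k", {
  pool <- pool_from_fraction(1 / 4)
  lf4 <- leaky_fraction(pool, activity_rule(4))
  expect_identical(c(attr(lf4, "num"), attr(lf4, "den")), c(1, 256))
  lf1 <- leaky_fraction(pool, activity_rule(1))
  expect_identical(c(attr(lf1, "num"), attr(lf1, "den")), c(175, 256))
  expect_equal(as.numeric(lf1), 1 - (3 / 4)^4)
  expect_identical(as.numeric(leaky_fraction(pool_from_fraction(1), 2)), 1)
  ks <- vapply(1:4, function(k) as.numeric(leaky_fraction(pool, k)), 0)
  expect_true(all(diff(ks) < 0))
  # independent route: summing composition masses with count >= k agrees
  cd <- composition_distribution(pool)
  for (k in 1:4) {
    expect_equal(sum(cd$prob[cd$brush >= k]),
                 as.numeric(leaky_fraction(pool, k)), tolerance = 1e-15)
  }
})

test_that("odds are rendered 1:N, exactly when the fraction allows", {
  expect_identical(odds_form(homotetramer_probability(pool_from_fraction(1 / 8))),
                   "1:4096")
  expect_identical(odds_form(homotetramer_probability(pool_from_fraction(1 / 4))),
                   "1:256")
  expect_identical(odds_form(homotetramer_probability(pool_from_fraction(1))),
                   "1:1")
  expect_identical(odds_form(0.3), "1:3.33")
  expect_identical(odds_form(0.3, digits = 4), "1:3.3333")
  expect_error(odds_form(0), class = "tetradose_infinite_odds")
})

test_that("per-cell hit probability has the closed form 1-(1-p)^n", {
  expect_equal(prob_at_least_one_leaky(pool_from_fraction(1 / 4), 64),
               1 - (255 / 256)^64)
  expect_equal(prob_at_least_one_leaky(pool_from_fraction(1 / 8), 64),
               1 - (4095 / 4096)^64)
  expect_identical(prob_at_least_one_leaky(pool_from_fraction(0), 64), 0)
  expect_identical(prob_at_least_one_leaky(pool_from_fraction(1), 64), 1)
})

test_that("closed-form hit probability agrees with Monte Carlo", {
  n_cells <- 2e5
  for (f in c(1 / 4, 1 / 8)) {
    counts <- simulate_cells(pool_from_fraction(f), n_cells, seed = 101)
    p_hat <- mean(counts >= 1)
    p <- prob_at_least_one_leaky(pool_from_fraction(f), 64)
    se <- sqrt(p * (1 - p) / n_cells)
    expect_lt(abs(p_hat - p), 3 * se)
  }
})

test_that("boundary pools assemble deterministically degenerate cells", {
  cell0 <- simulate_cell(pool_from_fraction(0), seed = 1)
  expect_identical(leaky_count(cell0), 0L)
  cell1 <- simulate_cell(pool_from_fraction(1), seed = 1)
  expect_identical(leaky_count(cell1), 64L)
  expect_identical(rowSums(cell1$composition), rep(4, 64))
})

test_that("infinite-pool composition frequencies pass a chi-square GOF", {
  n_draws <- 64 * 1e5  # tetramers across 1e5 cells of 64
  for (f in c(1 / 8, 1 / 4, 1 / 2)) {
    cd <- composition_distribution(pool_from_fraction(f))
    probs <- cd$prob[order(cd$brush)]
    set.seed(7)
    # oracle sampler: R's binomial, the mutant-count marginal of the model
    draws <- stats::rbinom(n_draws, 4, f)
    obs <- tabulate(draws + 1L, 5L)
    gof <- stats::chisq.test(obs, p = probs)
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("finite-pool mode conserves subunits and matches the target counts", {
  pool <- build_pool(hom_genotype())  # f = 1/4 over {WT, brush}
  cell <- simulate_cell(pool, n = 64, mode = "finite", seed = 5)
  totals <- colSums(cell$composition)
  expect_identical(sum(totals), 256)
  expect_identical(unname(totals), c(192, 64))  # 4n * (3/4, 1/4) exactly
  # largest-remainder rounding: non-integer targets still sum to 4n
  odd <- subunit_pool(c(A = 1 / 3, B = 1 / 3, C = 1 / 3), mutant_class = "C")
  cell3 <- simulate_cell(odd, n = 10, mode = "finite", seed = 5)
  expect_identical(sum(colSums(cell3$composition)), 40)
  expect_identical(unname(tetradose:::.finite_pool_counts(odd, 10)),
                   c(14L, 13L, 13L))  # tie after the first goes by class order
})

test_that("finite-pool composition frequencies approach the multinomial", {
  pool <- pool_from_fraction(1 / 4)
  cell <- simulate_cell(pool, n = 1e4, mode = "finite", seed = 11)
  emp <- tabulate(cell$composition[, "brush"] + 1L, 5L) / 1e4
  cd <- composition_distribution(pool)
  expect_equal(emp, cd$prob[order(cd$brush)], tolerance = 0.02)
})

test_that("simulations are reproducible under a fixed seed", {
  a <- simulate_cell(pool_from_fraction(1 / 4), seed = 9)
  b <- simulate_cell(pool_from_fraction(1 / 4), seed = 9)
  expect_identical(a$composition, b$composition)
  x <- simulate_cells(pool_from_fraction(1 / 8), 1000, seed = 9)
  y <- simulate_cells(pool_from_fraction(1 / 8), 1000, seed = 9)
  expect_identical(x, y)
})

test_that("grid rendering conserves one symbol per subunit", {
  cell <- simulate_cell(pool_from_fraction(1 / 4), n = 64, seed = 3)
  grid <- render_grid(cell)
  expect_length(grid, 8L)  # 8 x 8 layout
  symbols <- gsub(" ", "", paste(grid, collapse = ""))
  expect_identical(nchar(symbols), 256L)
  n_brush <- nchar(gsub("[^b]", "", symbols))
  expect_identical(n_brush, as.integer(sum(cell$composition[, "brush"])))
})
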