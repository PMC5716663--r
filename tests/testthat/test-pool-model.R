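# Genotype + interventions -> subunit pool frequencies.

test_that("allele dosage sets the mutant fraction (equal-weight cluster)", {
  het <- build_pool(het_genotype())
  expect_equal(unname(het$frequency[["brush"]]), 1 / 8)
  expect_true(het$exact)
  i <- match("brush", het$class)
  expect_identical(c(het$num[i], het$den[i]), c(1, 8))

  hom <- build_pool(hom_genotype())
  expect_equal(unname(hom$frequency[["brush"]]), 1 / 4)

  # null alleles contribute no subunits: 6 WT copies only, f(brush) = 0
  nul <- build_pool(genotype(BRUSH = c(null = 2)))
  expect_equal(unname(nul$frequency[["brush"]]), 0)
  expect_equal(sum(nul$frequency), 1)
})

test_that("overexpression dilutes and knockdown depletes, exactly", {
  # homozygote + WT transgene of weight 8: f = 2/16 = 1/8
  oe <- build_pool(hom_genotype(),
                   interventions = list(overexpression("WT", 8)))
  expect_equal(unname(oe$frequency[["brush"]]), 1 / 8)

  # homozygote + brush knocked down to 0.2 retained: f = 0.4/6.4 = 1/16
  kd <- build_pool(hom_genotype(),
                   interventions = list(knockdown("brush", 0.2)))
  i <- match("brush", kd$class)
  expect_identical(c(kd$num[i], kd$den[i]), c(1, 16))
})

test_that("pool frequencies are a probability vector, scale-invariant", {
  set.seed(42)
  for (rep in 1:20) {
    w <- sample(1:9, 5, replace = TRUE)
    loci <- default_loci(stats::setNames(w, names(default_loci())))
    g <- genotype(BRUSH = c(WT = 1, brush = 1))
    oe_w <- sample(0:8, 1)
    kd_f <- stats::runif(1)
    pool <- build_pool(g, loci, list(overexpression("WT", oe_w),
                                     knockdown("brush", kd_f)))
    expect_true(all(pool$frequency >= 0))
    expect_equal(sum(pool$frequency), 1, tolerance = 1e-12)
    # scaling every weight (native and transgene) by 3 changes nothing
    scaled <- build_pool(
      g, default_loci(stats::setNames(3 * w, names(default_loci()))),
      list(overexpression("WT", 3 * oe_w), knockdown("brush", kd_f)))
    expect_equal(scaled$frequency, pool$frequency, tolerance = 1e-12)
  }
})

test_that("knockdown fraction 1 is the identity; fraction 0 removes it", {
  base <- build_pool(hom_genotype())
  same <- build_pool(hom_genotype(),
                     interventions = list(knockdown("brush", 1)))
  expect_equal(same$frequency, base$frequency)
  gone <- build_pool(hom_genotype(),
                     interventions = list(knockdown("brush", 0)))
  expect_equal(unname(gone$frequency[["brush"]]), 0)
})

test_that("one diallelic mutant locus among L loci gives f = copies/(2L)", {
  for (L in 1:6) {
    loci <- lapply(seq_len(L), function(i) locus(paste0("L", i)))
    names(loci) <- vapply(loci, `[[`, "", "id")
    for (copies in 1:2) {
      counts <- c(WT = 2 - copies, brush = copies)
      g <- do.call(genotype, stats::setNames(list(counts), "L1"))
      pool <- build_pool(g, loci)
      expect_equal(unname(pool$frequency[["brush"]]), copies / (2 * L))
    }
  }
})

test_that("WT classes can be kept distinct per locus", {
  pool <- build_pool(het_genotype(), collapse_wt = FALSE)
  wt_classes <- grep("^WT:", pool$class, value = TRUE)
  expect_length(wt_classes, 4L)  # BRUSH WT copy + three cluster paralogs
  expect_equal(sum(pool$frequency[wt_classes]), 7 / 8)
  expect_equal(unname(pool$frequency[["brush"]]), 1 / 8)
})

test_that("degenerate inputs raise the documented errors", {
  # no expressed locus with positive weight -> empty pool
  silent <- list(B = locus("B", expressed = FALSE))
  expect_error(
    build_pool(do.call(genotype, list(B = c(brush = 2))), silent),
    class = "tetradose_empty_pool"
  )
  all_null <- lapply(names(default_loci()), function(id) c(null = 2))
  names(all_null) <- names(default_loci())
  expect_error(build_pool(do.call(genotype, all_null)),
               class = "tetradose_empty_pool")
  expect_error(locus("X", baseline_weight = -1), "non-negative")
  expect_error(knockdown("brush", 1.5), "\\[0, 1\\]")
  expect_error(overexpression("WT", -2), "non-negative")
  expect_error(genotype(BRUSH = c(WT = 1)), "sum to 2")
  expect_error(genotype(BRUSH = c(WT = 1, brush = 2)), "sum to 2")
})

test_that("pool_from_fraction builds the two-class pool", {
  expect_equal(unname(pool_from_fraction(0)$frequency),
               c(1, 0))
  expect_equal(unname(pool_from_fraction(1)$frequency),
               c(0, 1))
  p <- pool_from_fraction(1 / 8)
  expect_equal(unname(p$frequency[["brush"]]), 1 / 8)
  expect_equal(unname(p$frequency[["WT"]]), 7 / 8)
  expect_error(pool_from_fraction(-0.1), "\\[0, 1\\]")
  expect_error(pool_from_fraction(1.2), "\\[0, 1\\]")
})

test_that("subunit_pool validates and preserves exactness", {
  p <- subunit_pool(c(A = 1 / 3, B = 1 / 3, C = 1 / 3))
  expect_true(p$exact)
  expect_identical(p$num, rep(1, 3))
  expect_identical(p$den, rep(3, 3))
  expect_error(subunit_pool(c(A = 0.5, B = 0.4)), "sum to")
  expect_error(subunit_pool(c(A = -0.5, B = 1.5)), "non-negative")
})

test_that("pools round-trip through TSV", {
  p <- build_pool(het_genotype())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pool(p, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(stats::setNames(back$frequency, back$class),
               p$frequency)
})
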