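# Series/parallel composition algebra and recipe evaluation.

el <- function(r, c) lumped_element(r, c)

test_that("series and parallel rules reproduce published combinations", {
  # series resistance: M4 end-branches plus the M4 trunk
  s <- combine_series(list(el(1.40e8, 1.67e-14), el(1.87e9, 3.80e-15)))
  expect_equal(s$resistance, 2.01e9, tolerance = 0.01)
  expect_equal(s$compliance, 3.10e-15, tolerance = 0.01)
  # parallel: 9 lenticulostriate copies
  p <- combine_parallel(list(el(6.40e10, 6.60e-16)), factors = 9)
  expect_equal(p$resistance, 7.11e9, tolerance = 0.01)
  expect_equal(p$compliance, 5.94e-15, tolerance = 0.01)
  # fractional multiplicity: 7.6 perforators
  p2 <- combine_parallel(list(el(2.79e10, 1.10e-16)), factors = 7.6)
  expect_equal(p2$resistance, 3.67e9, tolerance = 0.01)
})

test_that("k identical elements obey the closed forms R/k and k*C", {
  set.seed(3)
  for (k in c(2, 5, 7.6, 16)) {
    e <- rand_elements(1)[[1]]
    p <- combine_parallel(list(e), factors = k)
    expect_equal(p$resistance, e$resistance / k)
    expect_equal(p$compliance, k * e$compliance)
  }
  # single element is the identity in both modes
  e <- rand_elements(1)[[1]]
  expect_equal(combine_series(list(e)), e)
  expect_equal(combine_parallel(list(e)), e)
})

test_that("combination is associative and order-invariant", {
  set.seed(21)
  for (i in 1:10) {
    es <- rand_elements(3)
    flat_s <- combine_series(es)
    nest_s <- combine_series(list(combine_series(es[1:2]), es[[3]]))
    expect_equal(flat_s$resistance, nest_s$resistance, tolerance = 1e-12)
    expect_equal(flat_s$compliance, nest_s$compliance, tolerance = 1e-12)
    flat_p <- combine_parallel(es)
    nest_p <- combine_parallel(list(combine_parallel(es[1:2]), es[[3]]))
    expect_equal(flat_p$resistance, nest_p$resistance, tolerance = 1e-12)
    expect_equal(flat_p$compliance, nest_p$compliance, tolerance = 1e-12)
    perm <- combine_series(es[c(3, 1, 2)])
    expect_equal(flat_s$resistance, perm$resistance, tolerance = 1e-12)
  }
})

test_that("parallel lowers resistance, series raises it; dual for compliance", {
  set.seed(5)
  for (i in 1:10) {
    es <- rand_elements(sample(2:5, 1))
    r <- vapply(es, `[[`, numeric(1), "resistance")
    c_ <- vapply(es, `[[`, numeric(1), "compliance")
    expect_lte(combine_parallel(es)$resistance, min(r))
    expect_gte(combine_series(es)$resistance, max(r))
    expect_gte(combine_parallel(es)$compliance, max(c_))
    expect_lte(combine_series(es)$compliance, min(c_))
  }
})

test_that("the compliance rules are the resistance rules under x -> 1/x", {
  set.seed(9)
  es <- rand_elements(4)
  # capacitors in series behave like resistors whose value is 1/C
  swapped <- lapply(es, function(e) el(1 / e$compliance, 1 / e$resistance))
  expect_equal(combine_series(es)$compliance,
               1 / combine_series(swapped)$resistance, tolerance = 1e-12)
  expect_equal(combine_parallel(es)$compliance,
               1 / combine_parallel(swapped)$resistance, tolerance = 1e-12)
})

test_that("degenerate combinations are rejected", {
  expect_error(combine_series(list()), "non-empty")
  expect_error(combine_series(list(el(1, 0), el(1, 1))), "zero compliance")
  expect_error(combine_parallel(list(el(0, 1))), "zero resistance")
  expect_error(combine_parallel(list(el(1, 1)), factors = -1), "factors")
  expect_error(combine_parallel(list(el(1, 1), el(2, 2)), factors = 1),
               "one multiplicity per element")
})

test_that("recipe evaluation resolves references in order at full precision", {
  base <- list(B1 = el(2e8, 1e-14), B2 = el(6e8, 4e-15))
  recipes <- recipe_table(
    reduction_recipe("X1", "parallel", c("B1", "B2"), c(2, 1)),
    reduction_recipe("X2", "series", c("X1", "B2")))
  ev <- evaluate_recipes(recipes, base)
  expect_named(ev, c("X1", "X2"))
  expect_equal(ev$X1$resistance, 1 / (2 / 2e8 + 1 / 6e8))
  expect_equal(ev$X2$resistance, ev$X1$resistance + 6e8)
  # single leaf with factor 1 is the base element
  one <- evaluate_recipes(
    recipe_table(reduction_recipe("Y", "parallel", "B1")), base)
  expect_equal(one$Y, base$B1)
})

test_that("dangling or forward references are rejected by name", {
  base <- list(B1 = el(1e8, 1e-14))
  expect_error(
    evaluate_recipes(recipe_table(
      reduction_recipe("X1", "series", c("B1", "NOPE"))), base),
    "X1.*NOPE")
  expect_error(
    evaluate_recipes(recipe_table(
      reduction_recipe("X1", "series", c("B1", "X2")),
      reduction_recipe("X2", "parallel", "B1")), base),
    "X1.*X2")
})

test_that("comparison report flags mismatches and sorts deterministically", {
  comp <- c(R16 = 6.236e7, R19 = 7.89e7, EXTRA = 1)
  prnt <- c(R16 = 6.24e7, R19 = 5.89e7, MISSING = 2)
  rep <- compare_to_printed(comp, prnt, rel_tol = 0.01)
  expect_equal(rep$name, sort(rep$name))
  expect_true(rep$pass[rep$name == "R16"])
  expect_false(rep$pass[rep$name == "R19"])
  expect_true(is.na(rep$rel_err[rep$name == "EXTRA"]))
  expect_true(is.na(rep$rel_err[rep$name == "MISSING"]))
  # identical mappings pass with zero error
  same <- compare_to_printed(prnt[1:2], prnt[1:2])
  expect_true(all(same$pass))
  expect_true(all(same$rel_err == 0))
})
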