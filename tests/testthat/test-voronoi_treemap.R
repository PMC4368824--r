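test_that("power diagram degenerate and symmetric cases", {
  sq <- unit_square()
  cells <- power_diagram(matrix(c(0.3, 0.4), 1), 0, sq)
  expect_equal(poly_area_test(cells[[1]]), 1)
  # two equal-weight sites placed symmetrically: two half squares
  s2 <- matrix(c(0.25, 0.5, 0.75, 0.5), 2, byrow = TRUE)
  cells2 <- power_diagram(s2, c(0, 0), sq)
  a <- vapply(cells2, poly_area_test, 0)
  expect_equal(a, c(0.5, 0.5))
  expect_equal(sum(a), 1, tolerance = 1e-9)
  # coincident equal sites are jittered, not fatal
  expect_message(
    cells3 <- power_diagram(matrix(0.5, 2, 2), c(0, 0), sq), "jitter")
  expect_equal(sum(vapply(cells3, poly_area_test, 0)), 1, tolerance = 1e-6)
})

test_that("zero-weight power diagram agrees with a Monte-Carlo Voronoi oracle", {
  set.seed(19)
  for (rep in 1:3) {
    sites <- matrix(runif(6), 3, 2)
    cells <- power_diagram(sites, c(0, 0, 0), unit_square())
    a <- vapply(cells, poly_area_test, 0)
    mc <- mc_voronoi_areas(sites, c(0, 0, 0))
    expect_equal(a, mc, tolerance = 0.015)   # MC sampling noise
    expect_equal(sum(a), 1, tolerance = 1e-9)
  }
})

test_that("area totals always equal the container area", {
  set.seed(23)
  for (n in c(2, 7, 25)) {
    sites <- matrix(runif(2 * n), n, 2)
    w <- runif(n, 0, 0.01)
    cells <- power_diagram(sites, w, unit_square())
    expect_equal(sum(vapply(cells, poly_area_test, 0)), 1, tolerance = 1e-9)
  }
})

test_that("solve_areas reaches weight-proportional cells", {
  lay1 <- solve_areas(5)
  expect_equal(lay1$areas, 1)
  expect_true(lay1$converged)
  lay2 <- solve_areas(c(1, 1), layout_config(seed = 3))
  expect_true(lay2$converged)
  expect_equal(lay2$areas, c(0.5, 0.5), tolerance = 0.01)
  lay4 <- solve_areas(c(1, 2, 3, 4), layout_config(seed = 5))
  expect_true(lay4$converged)
  expect_equal(lay4$areas, c(0.1, 0.2, 0.3, 0.4), tolerance = 0.01)
  expect_error(solve_areas(c(1, -1)), "positive")
  expect_error(layout_config(max_area_error = 0.5), "max_area_error")
})

test_that("hierarchical layout nests and conserves area at every level", {
  terms <- data.frame(term = c("A", "B", "A1", "A2", "B1", "B2"),
                      parent = c(NA, NA, "A", "A", "B", "B"),
                      weight = c(2, 2, 1, 1, 1, 1))
  cells <- layout_hierarchy(terms, layout_config(seed = 11))
  expect_true(all(cells$converged))
  leaves <- cells[cells$level == 2, ]
  expect_equal(leaves$area, rep(0.25, 4), tolerance = 0.01 * 0.25 + 0.01)
  # level-wise conservation within 0.5%
  for (p in c("A", "B")) {
    parent_area <- cells$area[cells$term == p]
    child_area <- sum(leaves$area[leaves$parent == p])
    expect_equal(child_area, parent_area, tolerance = 0.005)
  }
  # residual cell appears when the parent outweighs its children
  terms2 <- data.frame(term = c("A", "A1"), parent = c(NA, "A"),
                       weight = c(2, 1))
  cells2 <- layout_hierarchy(terms2, layout_config(seed = 2))
  expect_true("A::residual" %in% cells2$term)
  # single chain: only child's cell is its parent's cell
  terms3 <- data.frame(term = c("A", "A1"), parent = c(NA, "A"),
                       weight = c(1, 1))
  cells3 <- layout_hierarchy(terms3, layout_config(seed = 2))
  polys <- attr(cells3, "polygons")
  expect_equal(poly_area_test(polys[["A1"]]), poly_area_test(polys[["A"]]),
               tolerance = 1e-9)
  expect_error(layout_hierarchy(data.frame(term = "A", parent = "A",
                                           weight = 1)), "cyclic")
  terms_bad <- data.frame(term = c("A", "A1"), parent = c(NA, "A"),
                          weight = c(1, 2))
  expect_error(layout_hierarchy(terms_bad), "outweigh")
})

test_that("significance colouring is banded at alpha and monotone below", {
  terms <- data.frame(term = c("t1", "t2", "t3", "t4", "t5"),
                      parent = NA_character_, weight = rep(1, 5))
  cells <- layout_hierarchy(terms, layout_config(seed = 4))
  res <- data.frame(term = c("t1", "t2", "t3", "t4"),
                    p_adj = c(1.0, 0.05, 0.04, 0.0004))
  colored <- color_by_significance(cells, res, alpha = 0.05)
  col <- setNames(colored$color, colored$term)
  expect_equal(col[["t1"]], col[["t2"]])       # p = alpha: non-significant band
  expect_false(col[["t3"]] == col[["t2"]])
  expect_false(col[["t3"]] == col[["t4"]])     # distinct ramp colours
  # darker (smaller RGB sum) for smaller p
  lum <- function(h) sum(grDevices::col2rgb(h))
  expect_lt(lum(col[["t4"]]), lum(col[["t3"]]))
  expect_equal(col[["t5"]], "#BBBBBB")         # no result row: neutral grey
})

test_that("identical seed and inputs give byte-identical SVG", {
  terms <- data.frame(term = paste0("t", 1:8), parent = NA_character_,
                      weight = c(1, 2, 3, 4, 1, 2, 3, 4))
  res <- data.frame(term = terms$term, p_adj = seq(0.001, 0.8, length.out = 8))
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  treemap_svg(color_by_significance(
    layout_hierarchy(terms, layout_config(seed = 9)), res), f1)
  treemap_svg(color_by_significance(
    layout_hierarchy(terms, layout_config(seed = 9)), res), f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  # different seed, different bytes (placement differs)
  f3 <- withr::local_tempfile(fileext = ".svg")
  treemap_svg(color_by_significance(
    layout_hierarchy(terms, layout_config(seed = 10)), res), f3)
  expect_false(identical(readBin(f1, "raw", 1e6), readBin(f3, "raw", 1e6)))
})
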