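test_that("toy trees enumerate the expected vessels", {
  expect_equal(nrow(make_toy_tree(0, 0.05)), 1)

  toy <- make_toy_tree(2, 0.05, alpha = 0.8, beta = 0.8)
  expect_equal(nrow(toy), 7) # complete binary tree of depth 2
  leaves <- setdiff(toy$id, toy$parent)
  expect_length(leaves, 4)
  expect_equal(sort(unique(toy$depth)), 0:2)
  expect_equal(toy$length, 25 * toy$radius)

  # pruning below r_min
  toy2 <- make_toy_tree(6, 0.05, r_min = 0.031)
  expect_true(all(toy2$radius >= 0.031 * (1 - 1e-9)))
  expect_error(make_toy_tree(7, 0.05), "generations")
})

test_that("seeded radius perturbations are reproducible", {
  a <- make_toy_tree(3, 0.05, jitter = 0.05, seed = 11)
  b <- make_toy_tree(3, 0.05, jitter = 0.05, seed = 11)
  c <- make_toy_tree(3, 0.05, jitter = 0.05, seed = 12)
  expect_identical(a$radius, b$radius)
  expect_false(identical(a$radius, c$radius))
})

test_that("toy trees round-trip through the geometry file dialect", {
  toy <- make_toy_tree(2, 0.08, alpha = 0.85, beta = 0.65)
  path <- tempfile(fileext = ".csv")
  write_toy_tree(toy, path)
  tree <- load_vessel_table(path)
  expect_equal(nrow(tree$segments), nrow(toy))
  expect_equal(sort(tree$segments$r_prox), sort(toy$radius))
  expect_equal(tree$roots, "V1")
})
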