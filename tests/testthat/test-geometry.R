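test_that("the measured vessel table loads with unit conversion and topology", {
  tree <- load_vessel_table(coronary_table1())
  seg <- tree$segments
  expect_equal(nrow(seg), 17)
  expect_setequal(tree$roots, c("RCA", "LMCA"))

  rca <- seg[seg$name == "RCA", ]
  expect_equal(rca$length, 10.9)
  expect_equal(rca$r_prox, 0.151)
  expect_equal(rca$r_dist, 0.148)
  expect_equal(seg$r_dist[seg$name == "LMCA"], 0.179)

  expect_true(all(seg$r_dist <= seg$r_prox))
  expect_setequal(seg$name[seg$terminal],
                  names(coronary_supply_map()))
  # every non-root has exactly one parent, and parents exist
  nonroot <- seg[!seg$name %in% tree$roots, ]
  expect_true(all(nonroot$parent %in% seg$name))
})

test_that("malformed geometry files are rejected", {
  writeLines("name,length_mm,r_prox_mm,r_dist_mm,parent", tmp <- tempfile())
  expect_error(load_vessel_table(tmp), "no segments")

  writeLines(c("name,length_mm,r_prox_mm,parent", "A,10,1,"),
             tmp2 <- tempfile())
  expect_error(suppressWarnings(load_vessel_table(tmp2)), "missing column")

  writeLines(c("name,length_mm,r_prox_mm,r_dist_mm,parent",
               "A,10,1,0.9,", "B,5,0.8,0.7,NOPE"), tmp3 <- tempfile())
  expect_error(load_vessel_table(tmp3), "orphan")

  writeLines(c("name,length_mm,r_prox_mm,r_dist_mm,parent",
               "A,-10,1,0.9,"), tmp4 <- tempfile())
  expect_error(load_vessel_table(tmp4), "length")

  writeLines(c("name,length_mm,r_prox_mm,r_dist_mm,parent",
               "A,10,1,1.2,"), tmp5 <- tempfile())
  expect_error(load_vessel_table(tmp5), "taper")
})

test_that("splitting the trifurcation yields a binary tree with the stated intermediate segment", {
  tree <- load_vessel_table(coronary_table1())
  lm <- tree$segments[tree$segments$name == "LMCA", ]
  expect_length(lm$daughters[[1]], 3)

  out <- split_trifurcation(tree)
  seg <- out$segments
  d2 <- seg[seg$name == "D2", ]
  expect_equal(d2$r_prox, 0.185)
  expect_equal(d2$r_dist, 0.185)
  expect_equal(d2$length, 0.25)
  expect_setequal(seg$daughters[[which(seg$name == "LMCA")]], c("DIAG", "D2"))
  expect_setequal(seg$daughters[[which(seg$name == "D2")]], c("LAD", "LCX"))

  # all internal nodes binary; terminal set conserved
  internal <- seg[!seg$terminal, ]
  expect_true(all(lengths(internal$daughters) == 2))
  expect_setequal(seg$name[seg$terminal],
                  tree$segments$name[tree$segments$terminal])

  expect_error(split_trifurcation(out), "not a trifurcation")
  expect_error(split_trifurcation(tree, lmca = "NOPE"), "not found")
})

test_that("branching-relation residuals match direct evaluation", {
  p <- structured_tree_params()
  rep <- check_branching_relations(p)
  expect_equal(rep$value[rep$relation == "alpha^xi + beta^xi"],
               0.9^2.76 + 0.6^2.76, tolerance = 1e-12)
  expect_equal(0.9^2.76 + 0.6^2.76, 0.992, tolerance = 1e-3)
  expect_equal(rep$value[rep$relation == "asymmetry gamma"], (0.6 / 0.9)^2,
               tolerance = 1e-12)
  expect_equal((0.6 / 0.9)^2, 0.444, tolerance = 2e-3)
  # residual reported, not enforced
  expect_gt(rep$residual[rep$relation == "asymmetry gamma"], 0.03)

  # exact closure at xi = 2 with 3-4-5 radius ratios
  expect_equal(0.8^2 + 0.6^2, 1)
})

test_that("alpha and beta re-derived from (gamma, xi) reproduce the printed values", {
  p <- structured_tree_params(xi = 2.76, gamma = 0.41, derive_from_xi = TRUE)
  expect_equal(p$alpha, 0.9, tolerance = 0.02)
  expect_equal(p$beta, 0.6, tolerance = 0.04)
  p2 <- structured_tree_params(xi = 2.4, gamma = 0.41, derive_from_xi = TRUE)
  expect_lt(p2$alpha, p$alpha)
  expect_lt(p2$beta, p$beta)
})

test_that("the structured-tree radius lattice enumerates and truncates correctly", {
  p <- structured_tree_params(r_min = 0.03)
  lat <- structured_tree_radii(0.05, p)
  expect_equal(sort(lat$radius, decreasing = TRUE),
               c(0.05, 0.045, 0.0405, 0.03645, 0.032805, 0.03),
               tolerance = 1e-12)
  expect_equal(lat$length, p$l_rr * lat$radius)

  # boundary: root exactly at the minimum radius survives alone
  lat1 <- structured_tree_radii(0.03, p)
  expect_equal(nrow(lat1), 1)
  expect_equal(lat1$radius, 0.03)
  expect_warning(structured_tree_radii(0.029, p), "empty")

  # closed-form depth of the alpha chain
  pdeep <- structured_tree_params()
  latd <- structured_tree_radii(0.1, pdeep)
  expect_equal(max(latd$i), floor(log(0.1 / 1e-3) / log(1 / 0.9)))
  expect_equal(max(latd$i), 43)
})

test_that("the radius lattice is downward closed", {
  for (r_root in c(0.05, 0.1, 0.148)) {
    p <- structured_tree_params(r_min = 0.008)
    lat <- structured_tree_radii(r_root, p)
    key <- paste(lat$i, lat$j)
    for (k in seq_len(nrow(lat))) {
      if (lat$i[k] > 0) expect_true(paste(lat$i[k] - 1, lat$j[k]) %in% key)
      if (lat$j[k] > 0) expect_true(paste(lat$i[k], lat$j[k] - 1) %in% key)
    }
  }
})
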