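test_that("cylindrical areas reproduce the tabulated nodal capacitances", {
  ctrl <- surface_area(1.3, 0.8)
  expect_equal(ctrl$area_um2, pi * 0.8 * 1.3)
  # at 1 uF/cm2 the control node is 0.0327 pF, the AOE node 0.247 pF
  expect_equal(round(ctrl$area_cm2 * 1 * 1e6, 4), 0.0327)
  aoe <- surface_area(6.15, 1.28)
  expect_equal(round(aoe$area_cm2 * 1 * 1e6, 3), 0.247)
  expect_equal(surface_area(0, 1)$area_um2, 0)
})

test_that("length constant follows sqrt(rad * Rm / (2 Ra))", {
  base <- length_constant(1e-4, 5000, 70)
  expect_equal(length_constant(4e-4, 5000, 70), 2 * base)     # 4x radius -> 2x
  expect_equal(length_constant(1e-4, 5000 / 4, 70 / 4), base) # ratio invariance
  # control internodal axon: rad 0.625 um, Rm = 1/g_leak, Ra = 70 (frozen)
  expect_equal(length_constant(0.625e-4, 1 / 10.89e-6, 70),
               0.2024706378, tolerance = 1e-8)
  expect_error(length_constant(-1, 5000, 70), "positive")
})

test_that("axon geometry matches the published dimensions per condition", {
  ctrl <- axon_spec("control")
  nd <- ctrl[ctrl$kind == "node", ]
  expect_equal(unique(nd$length), 1.3)
  expect_equal(unique(nd$diameter), 0.8)
  expect_equal(unique(ctrl$length[ctrl$kind == "PN"]), 2.34)
  expect_equal(unique(ctrl$diameter[ctrl$kind == "PN"]), 0.75)
  expect_equal(unique(ctrl$length[ctrl$kind == "JP"]), 5.14)
  expect_equal(unique(ctrl$diameter[ctrl$kind == "JP"]), 2.13)
  expect_equal(unique(ctrl$diameter[ctrl$kind == "axon"]), 1.25)
  # 7 nodes, 6 internodes by default
  expect_equal(sum(ctrl$kind == "node"), 7)
  expect_equal(length(unique(stats::na.omit(ctrl$inr))), 6)

  a2 <- axon_spec("AOE2")
  expect_equal(unique(a2$length[a2$kind == "n1"]), 2.425)
  # two n1 inserts plus the node span the AOE1 node length
  expect_equal(1.3 + 2 * 2.425, 6.15)
  expect_true(all(a2[a2$kind %in% c("n1", "j1"),
                     c("g_na", "g_ht", "g_lt")] == 0))

  # node-centre spacing equals internode length + node length
  cab <- discretize(ctrl)
  nc <- attr(cab, "node_comp")
  expect_equal(diff(cab$position[nc]), rep(100 + 1.3, 6))
})

test_that("an AOE condition with no affected internodes is the control cable", {
  a <- axon_spec("AOE1", affected_inrs = integer(0))
  b <- axon_spec("control")
  expect_equal(a, b, ignore_attr = TRUE)
  da <- discretize(a); db <- discretize(b)
  expect_equal(da, db, ignore_attr = TRUE)
  expect_identical(attr(da, "node_comp"), attr(db, "node_comp"))
})

test_that("AOE1 rescaling conserves total channel conductance to machine precision", {
  f <- density_rescale_factor(list(kind = "node", length = 1.3, diameter = 0.8),
                              list(kind = "node", length = 6.15, diameter = 1.28))
  expect_equal(f, (0.8 * 1.3) / (1.28 * 6.15))
  expect_equal(f, 0.132, tolerance = 0.001)
  expect_equal(density_rescale_factor(list(kind = "JP", length = 5, diameter = 2),
                                      list(kind = "JP", length = 5, diameter = 2)), 1)
  expect_error(density_rescale_factor(list(kind = "node", length = 1, diameter = 1),
                                      list(kind = "PN", length = 1, diameter = 1)),
               "kind")

  ctrl <- discretize(axon_spec("control"))
  aoe1 <- discretize(axon_spec("AOE1"))
  n_ctrl <- ctrl[ctrl$kind == "node", ]
  n_aoe <- aoe1[aoe1$kind == "node", ]
  expect_equal(sum(n_aoe$g_na_uS), sum(n_ctrl$g_na_uS), tolerance = 1e-12)
  expect_equal(sum(n_aoe$g_ht_uS), sum(n_ctrl$g_ht_uS), tolerance = 1e-12)
  expect_equal(sum(aoe1$g_lt_uS), sum(ctrl$g_lt_uS), tolerance = 1e-12)
})

test_that("region length bookkeeping matches across conditions", {
  # AOE1 and AOE2 node-region total lengths agree (6.15 um), and the AOE1 JP
  # equals the AOE2 JP + j1 span
  g <- region_geometry()
  len <- function(cond, kind) g$length[g$condition == cond & g$kind == kind]
  expect_equal(len("AOE2", "node") + 2 * len("AOE2", "n1"), len("AOE1", "node"))
  expect_equal(len("AOE1", "JP"), len("AOE2", "JP") + len("AOE2", "j1"),
               tolerance = 0.002)
})

test_that("discretization obeys the lambda rule and conserves geometry", {
  spec <- long_passive_spec(6000)  # lambda ~472 um, so 0.1 lambda binds
  cab1 <- discretize(spec, max_lambda_fraction = 0.1)
  cab2 <- discretize(spec, max_lambda_fraction = 0.05)
  lam_um <- length_constant(0.625e-4, 1 / 0.2e-3, 70) * 1e4
  expect_true(all(cab1$length <= 0.1 * lam_um))
  expect_true(all(cab2$length <= 0.05 * lam_um))
  expect_gte(nrow(cab2), 2 * nrow(cab1))
  expect_equal(sum(cab1$length), 6000)
  expect_equal(sum(cab2$length), 6000)

  # a region shorter than 0.1 lambda stays one compartment
  short <- discretize(passive_single_spec())
  expect_equal(nrow(short), 1)

  # per-compartment area and the half-resistance formula (frozen value for
  # a uniform 10 um x 1.25 um pair at Ra = 70 Ohm cm)
  expect_equal(cab1$area_cm2, pi * cab1$diameter * cab1$length * 1e-8)
  pair <- axonwave:::new_axon_spec(
    tibble::tibble(kind = "axon", node = NA_integer_, inr = NA_integer_,
                   aoe = FALSE, length = c(10, 10), diameter = 1.25,
                   cm_specific = 1, g_leak = 0.2, g_na = 0, g_ht = 0, g_lt = 0),
    condition = "pair")
  pc <- discretize(pair)
  expect_equal(pc$r_axial_MOhm[1], 5.70411316, tolerance = 1e-8)
  expect_true(all(pc$r_axial_MOhm[-nrow(pc)] > 0))
})

test_that("nodal capacitance sums match the tabulated values after discretization", {
  ctrl <- discretize(axon_spec("control"))
  aoe <- discretize(axon_spec("AOE1"))
  c_node <- sum(ctrl$c_nF[ctrl$node == 0], na.rm = TRUE) * 1e3  # pF
  expect_equal(round(c_node, 4), 0.0327)
  c_node_aoe <- sum(aoe$c_nF[aoe$node == 0], na.rm = TRUE) * 1e3
  expect_equal(round(c_node_aoe, 3), 0.247)
})

test_that("rebuilding a cable from the same inputs is deterministic", {
  a <- discretize(axon_spec("AOE2", internode_length = 120))
  b <- discretize(axon_spec("AOE2", internode_length = 120))
  expect_equal(a, b, ignore_attr = TRUE)
  expect_identical(attr(a, "node_comp"), attr(b, "node_comp"))
})

test_that("impossible internode lengths are rejected", {
  expect_error(axon_spec("control", internode_length = 10), "cannot fit")
  expect_error(axon_spec("control", n_nodes = 1), "n_nodes")
})
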