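test_that("the 2D panel has the frozen manifest and formula-level values", {
  d <- compute_2d(c("CC", "c1ccccc1", "CCCCCC"))
  expect_equal(dim(d), c(3L, 242L))
  expect_identical(colnames(d), manifest_2d())
  # molecular weight of ethane from atomic masses: 2*12.011 + 6*1.008
  expect_equal(unname(d[1, "PHYS_MW"]), 2 * 12.011 + 6 * 1.008, tolerance = 1e-3)
  # bond-enumeration oracle: n-hexane has 3 rotatable C-C bonds
  expect_equal(unname(d[3, "PHYS_ROTORS"]), 3)
  expect_equal(unname(d[1, "PHYS_ROTORS"]), 0)
  # benzene: one six-ring, no H-bond donors
  expect_equal(unname(d[2, "MQN_36"]), 1)
  expect_equal(unname(d[2, "PHYS_HBD"]), 0)
  expect_gte(unname(d[2, "PHYS_ABONDS"]), 6)
  # names stable across calls
  expect_identical(colnames(compute_2d("CCO")), manifest_2d())
})

test_that("3D families are rigid-motion invariant with the stated sizes", {
  cf <- fx_conformers()$paracetamol
  v <- compute_3d(cf)
  expect_length(v, 628L)
  expect_identical(names(v), manifest_3d())
  expect_true(all(is.finite(v)))
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- conformer(cf$id, cf$elem, cf$xyz %*% rot + 7.5, cf$bonds,
                     formal_charge = cf$formal_charge)
  expect_equal(compute_3d(moved), v, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(compute_3d(cf), v)
})

test_that("the RDF of a diatomic peaks at the interatomic distance", {
  bond <- data.frame(a1 = 1L, a2 = 2L, order = 1L)
  for (d in c(3, 4.5)) {
    cf <- conformer("di", c("C", "C"),
                    matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE), bond)
    v <- compute_3d(cf)
    rdf_u <- v[sprintf("RDF_%03d", 1:30)]  # unweighted block, r = 0.5..15
    peak_r <- 0.5 * unname(which.max(rdf_u))
    expect_equal(peak_r, d)
    # closed form at the peak: single pair, unit weights, exp(0) = 1
    expect_equal(unname(max(rdf_u)), 1, tolerance = 1e-10)
  }
})

test_that("degenerate single-atom geometry is zero-filled and flagged", {
  cf <- conformer("one", "C", matrix(0, 1, 3),
                  data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)))
  v <- compute_3d(cf)
  expect_true(all(v == 0))
  expect_true(attr(v, "flagged"))
})

test_that("voxel grids conserve the deposited property weight", {
  # single carbon at the grid centre deposits its full atomic number
  c1 <- conformer("c1", "C", matrix(0, 1, 3),
                  data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)))
  v <- compute_voxel_grid(c1, grid_spec(property = "atomic_number"))
  expect_length(v, 11^3)
  expect_lt(abs(sum(v) - 6) / 6, 0.01)
  # conservation across embedded molecules that fit the grid
  for (cf in fx_conformers()) {
    g <- compute_voxel_grid(cf, grid_spec(edge_length = 24,
                                          property = "atomic_number"))
    w_tot <- sum(atomic_number(cf$elem))
    expect_lt(abs(sum(g) - w_tot) / w_tot, 0.02)
  }
  # neutral molecule, partial-charge weighting sums to ~0
  vq <- compute_voxel_grid(fx_conformers()$ethanol,
                           grid_spec(property = "gasteiger"))
  expect_lt(abs(sum(vq)), 0.02)
})

test_that("symmetric conformers produce mirror-symmetric grids", {
  cf <- conformer("mir", c("N", "N"),
                  matrix(c(-2.5, 0, 0, 2.5, 0, 0), 2, 3, byrow = TRUE),
                  data.frame(a1 = 1L, a2 = 2L, order = 1L))
  g <- array(compute_voxel_grid(cf, grid_spec()), dim = c(11, 11, 11))
  expect_equal(g, g[11:1, , ], tolerance = 1e-12)
})

test_that("molecules larger than the grid warn and report clipping", {
  chain <- embed_conformers(c(long = strrep("C", 30)))$long
  expect_warning(
    v <- compute_voxel_grid(chain, grid_spec(edge_length = 8)),
    "beyond the voxel grid")
  expect_gt(attr(v, "clipped_fraction"), 0.02)
})

test_that("docked-pose adoption reconciles permuted atoms", {
  cf <- fx_conformers()$biphenylamide
  # identity mapping
  same <- adopt_docked_pose(cf, cf)
  expect_equal(same$xyz, cf$xyz)
  expect_equal(same$pose_source, "docked")
  # permuted atom order round-trips exactly
  set.seed(9)
  perm <- sample(seq_along(cf$elem))
  inv <- order(perm)
  permuted <- conformer(cf$id, cf$elem[perm], cf$xyz[perm, , drop = FALSE],
                        data.frame(a1 = inv[cf$bonds$a1], a2 = inv[cf$bonds$a2],
                                   order = cf$bonds$order),
                        formal_charge = cf$formal_charge[perm])
  adopted <- adopt_docked_pose(cf, permuted)
  expect_equal(adopted$xyz, cf$xyz)
  expect_identical(adopted$elem, cf$elem)
  # different molecules are rejected
  eth <- fx_conformers()$ethanol
  meoh <- embed_conformers(c(m = "CO"))$m
  expect_error(adopt_docked_pose(eth, meoh), "mismatch")
})

test_that("descriptor assembly produces tagged, deterministic matrices", {
  ds <- fx_dataset_clean()
  recs <- ds$records[1:10, ]
  m <- assemble_descriptor_matrix(recs, families = "morgan")
  expect_equal(dim(m), c(10L, 1024L))
  expect_identical(rownames(m), recs$id)
  cfs <- embed_conformers(recs$smiles, ids = recs$id)
  m2 <- assemble_descriptor_matrix(
    recs, families = c("morgan", "autocorr3d", "morse", "rdf", "whim", "voxel"),
    conformers = cfs, grid_specs = grid_spec(edge_length = 24, property = "mr"))
  expect_equal(ncol(m2), 1024L + 628L + 1331L)  # 2983-column combined block
  tags <- attr(m2, "family_tags")
  expect_length(tags, ncol(m2))
  expect_setequal(unique(tags), c("morgan", "autocorr3d", "morse", "rdf",
                                  "whim", "voxel"))
  expect_error(assemble_descriptor_matrix(recs[0, ], families = "morgan"),
               "no records")
  expect_error(assemble_descriptor_matrix(recs, families = "morse"),
               "conformer")
})
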