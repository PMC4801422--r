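test_that("ground truth records the requested topology", {
  s <- generate_nmj(synth_spec(seed = 3, k_islands = 2, k_branches = 4,
                               spot_count = 10L))
  expect_equal(s$truth$n_islands, 2L)
  expect_equal(s$truth$n_branches, 4L)
  expect_equal(nrow(s$truth$spot_coordinates), 10L)
  expect_s3_class(s$pair, "nmj_stack_pair")
  expect_equal(dim(s$pair$marker_stack)[3], 42L)  # acquisition geometry
  expect_equal(s$pair$calibration$px_per_um_xy, 6.932)
  expect_equal(s$pair$calibration$z_step_um, 0.3)
})

test_that("equal seeds give bit-identical stacks, different seeds differ", {
  a <- generate_nmj(synth_spec(seed = 9, spot_count = 10L, noise_sd = 30))
  b <- generate_nmj(synth_spec(seed = 9, spot_count = 10L, noise_sd = 30))
  expect_identical(a$pair$marker_stack, b$pair$marker_stack)
  expect_identical(a$pair$spot_stack, b$pair$spot_stack)
  expect_identical(a$truth, b$truth)
  c_ <- generate_nmj(synth_spec(seed = 10, spot_count = 10L, noise_sd = 30))
  expect_false(identical(a$pair$marker_stack, c_$pair$marker_stack))
})

test_that("infeasible requests fail loudly", {
  # 2 branches on one island is topologically impossible
  expect_error(generate_nmj(synth_spec(seed = 1, k_islands = 1, k_branches = 2)),
               "infeasible")
  # far more spots than the footprint can hold at the separation floor
  expect_error(generate_nmj(synth_spec(seed = 1, spot_count = 5000L)),
               "packing")
})

test_that("planted spots respect the separation floor and stay in the footprint", {
  s <- generate_nmj(synth_spec(seed = 5, spot_count = 20L))
  sp <- s$truth$spot_coordinates
  d <- as.matrix(dist(sp)); diag(d) <- Inf
  expect_gte(min(d), 8)
  roi <- rasterize_polygon(s$roi, dim(s$pair$marker_stack)[1:2])
  for (i in seq_len(nrow(sp)))
    expect_true(roi[round(sp[i, "y"]), round(sp[i, "x"])])
})

test_that("fixture directories follow the pipeline file dialect and round-trip", {
  dir <- withr::local_tempdir()
  syn <- lapply(c(11, 12), function(sd)
    generate_nmj(synth_spec(seed = sd, img_size = c(128L, 128L), k_islands = 1L,
                            k_branches = 1L, spot_count = 4L,
                            cal = calibration(n_planes = 6L))))
  manifest <- write_fixture_directory(syn, dir)
  expect_equal(nrow(manifest), 2L)
  # 2 ids x 6 planes x 2 channels + 2 ROI files + manifest
  expect_length(list.files(dir, pattern = "_z[0-9]+_ch[12]\\.tif$"), 24L)
  expect_length(list.files(dir, pattern = "\\.roi\\.txt$"), 2L)
  pairs <- assemble_stacks(dir, cal = calibration(n_planes = 6L))
  expect_setequal(names(pairs), manifest$nmj_id)
  id1 <- syn[[1]]$pair$nmj_id
  expect_identical(pairs[[id1]]$marker_stack + 0, syn[[1]]$pair$marker_stack + 0)
  expect_identical(pairs[[id1]]$spot_stack + 0, syn[[1]]$pair$spot_stack + 0)
  # empty collection -> empty manifest
  empty <- write_fixture_directory(list(), file.path(dir, "sub"))
  expect_equal(nrow(empty), 0L)
})
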