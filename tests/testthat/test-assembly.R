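ca_only_domain <- function(ca, id = "ca", chain = "A") {
  n <- nrow(ca)
  as_domain(data.frame(
    elety = "CA", resid = "ALA", chain = chain, resno = seq_len(n), ins = "",
    x = ca[, 1], y = ca[, 2], z = ca[, 3], element = "C"), id = id)
}

test_that("window enumeration follows the (N_I-8)(N_J-8) formula", {
  set.seed(2)
  I <- ca_only_domain(random_cloud(50))
  J <- ca_only_domain(random_cloud(40))
  g <- enumerate_window_pairs(I, J)
  expect_equal(nrow(g), 42L * 32L)
  expect_equal(nrow(enumerate_window_pairs(ca_only_domain(random_cloud(9)),
                                           ca_only_domain(random_cloud(9)))),
               1L)
  expect_error(enumerate_window_pairs(ca_only_domain(random_cloud(8)), J),
               "at least")
})

test_that("the surface mask is strict at 10 A^2", {
  d <- ca_only_domain(random_cloud(3))
  d$sasa <- c(9.9, 10.1, 10.0)
  expect_equal(surface_mask(d), c(FALSE, TRUE, FALSE))
  expect_error(surface_mask(ca_only_domain(random_cloud(3))), "SASA")
  # an isolated 9-mer peptide is surface throughout
  pep <- prepare_domain(ideal_strand(9))
  expect_true(all(surface_mask(pep)))
})

test_that("match_and_build recovers the native pose from its own entry", {
  td <- make_toy_dimer(toy_dimer_spec("HH", seed = 12))
  I <- prepare_domain(td$I)
  J <- prepare_domain(td$J)
  recs <- interface_fragment_pairs(I, J)
  p <- recs[[1]]
  entry <- list(id = 1L, pair = p, member_count = 1L, motif = "HH")
  models <- match_and_build(I, J, p$center_i - 4L, p$center_j - 4L, entry)
  expect_gte(length(models), 1L)
  m <- models[[1]]
  expect_equal(m$orientation, 1L)
  expect_lt(m$rmsd_a, 1e-9)
  expect_lt(m$rmsd_b, 1e-9)
  expect_lt(complex_rmsd(model_coords(m, I, J), td$native), 1e-9)

  # an entry whose blocks cannot be aligned by any window yields nothing
  # (the per-block fit is translation invariant, so distort the shape)
  far <- p
  far$coords_a <- far$coords_a * 3
  far$coords_b <- far$coords_b * 3
  expect_length(match_and_build(I, J, p$center_i - 4L, p$center_j - 4L,
                                list(id = 2L, pair = far)), 0L)
})

test_that("a block-symmetric entry matches in both orientations", {
  h <- prepare_domain(ideal_helix(17))
  w <- h$ca[5:13, , drop = FALSE]
  axis_point <- colMeans(w) + c(4, 0, 0)
  R <- fraglib:::rotation_about(c(0, 0, 1), 180)
  w2 <- sweep(sweep(w, 2, axis_point) %*% t(R), 2, axis_point, "+")
  entry <- list(id = 1L, pair = fraglib:::new_fragment_pair(w, w2, "H", "H"))
  models <- match_and_build(h, h, 5L, 5L, entry)
  expect_equal(length(models), 2L)
  expect_setequal(vapply(models, `[[`, 0L, "orientation"), 1:2)
  # the two models are related by exchanging the domains
  mc1 <- model_coords(models[[1]], h, h)
  mc2 <- model_coords(models[[2]], h, h)
  expect_lt(kabsch_fit(rbind(mc1$ca_i, mc1$ca_j),
                       rbind(mc2$ca_j, mc2$ca_i))$rmsd, 1e-6)
})

test_that("the clash test is strict at the C-alpha cutoff", {
  set.seed(9)
  base <- random_cloud(10, scale = 3)
  mk_model <- function() structure(list(
    transform_i = identity_transform(), transform_j = identity_transform()),
    class = "complex_model")
  I <- ca_only_domain(base)
  # coincident domains clash; domains 50 A apart do not
  expect_true(clash_filter(mk_model(), I,
                           ca_only_domain(base, chain = "B"),
                           ca_cutoff = 3.5))
  expect_false(clash_filter(mk_model(), I,
                            ca_only_domain(base + 50, chain = "B"),
                            ca_cutoff = 3.5))
  # exact boundary: two single points at controlled distance
  a <- ca_only_domain(matrix(c(0, 0, 0), 1))
  b34 <- ca_only_domain(matrix(c(3.4, 0, 0), 1), chain = "B")
  b36 <- ca_only_domain(matrix(c(3.6, 0, 0), 1), chain = "B")
  expect_true(clash_filter(mk_model(), a, b34, ca_cutoff = 3.5))
  expect_false(clash_filter(mk_model(), a, b36, ca_cutoff = 3.5))
})

test_that("complex_rmsd matches the oracle and honours both modes", {
  set.seed(13)
  nat <- list(ca_i = random_cloud(20), ca_j = random_cloud(15) + 20)
  expect_equal(complex_rmsd(nat, nat), 0, tolerance = 1e-12)

  R <- random_rotation()
  moved <- list(ca_i = sweep(nat$ca_i %*% t(R), 2, c(5, 6, 7), "+"),
                ca_j = sweep(nat$ca_j %*% t(R), 2, c(5, 6, 7), "+"))
  expect_lt(complex_rmsd(moved, nat), 1e-9)

  shifted <- list(ca_i = nat$ca_i, ca_j = nat$ca_j +
                    matrix(rep(c(3, 0, 0), each = 15), 15, 3))
  expect_equal(complex_rmsd(shifted, nat),
               quat_rmsd_oracle(rbind(shifted$ca_i, shifted$ca_j),
                                rbind(nat$ca_i, nat$ca_j)),
               tolerance = 1e-9)
  # ligand mode with the receptor already aligned: exactly the shift length
  expect_equal(complex_rmsd(shifted, nat, mode = "ligand"), 3,
               tolerance = 1e-9)
  bad <- list(ca_i = nat$ca_i[1:10, ], ca_j = nat$ca_j)
  expect_error(complex_rmsd(bad, nat), "counts differ")
})

test_that("assembly with a domain's own library recovers the native complex", {
  td <- make_toy_dimer(toy_dimer_spec("HS", seed = 14))
  I <- prepare_domain(td$I)
  J <- prepare_domain(td$J)
  recs <- interface_fragment_pairs(I, J)
  lib <- cluster_and_build(recs, min_members = 0)
  ens <- assemble(I, J, lib)
  ev <- evaluate_ensemble(ens, I, J, td$native)
  expect_gt(ev$n_models, 0L)
  expect_lt(ev$lowest, 1e-6)
  expect_false(any(vapply(ens$models, `[[`, TRUE, "clash")))
  # a library with no entry near any window yields a valid empty ensemble
  far <- lib
  far$entries[[1]]$pair$coords_a <- far$entries[[1]]$pair$coords_a * 3
  far$entries <- far$entries[1]
  ens0 <- assemble(I, J, far)
  expect_length(ens0$models, 0L)
  ev0 <- evaluate_ensemble(ens0, I, J, td$native)
  expect_true(is.na(ev0$lowest))
  expect_equal(ev0$n_models, 0L)
})

test_that("model counts respond monotonically to every filter", {
  td <- make_toy_dimer(toy_dimer_spec("HH", seed = 15))
  I <- prepare_domain(td$I)
  J <- prepare_domain(td$J)
  lib <- cluster_and_build(interface_fragment_pairs(I, J), min_members = 0)
  n_models <- function(...) length(assemble(I, J, lib,
                                            default_params(...))$models)
  n0 <- n_models()
  expect_lte(n_models(align_cutoff = 1.0), n0)          # tighter alignment
  expect_lte(n0, n_models(clash_cutoff = 2.0))          # looser clash
  expect_lte(n_models(clash_cutoff = 5.0), n0)          # stricter clash
  expect_lte(n_models(surface_threshold = 40), n0)      # stricter surface
  expect_lte(n_models(dedup = TRUE), n0)                # dedup only removes
})

test_that("assembly is symmetric under exchanging the two domains", {
  td <- make_toy_dimer(toy_dimer_spec("HL", seed = 16))
  I <- prepare_domain(td$I)
  J <- prepare_domain(td$J)
  lib <- cluster_and_build(interface_fragment_pairs(I, J), min_members = 0)
  e1 <- assemble(I, J, lib)
  e2 <- assemble(J, I, lib)
  expect_equal(length(e1$models), length(e2$models))
  cas2 <- lapply(e2$models, function(m) {
    mc <- model_coords(m, J, I)
    rbind(mc$ca_j, mc$ca_i)          # reorder to (I, J)
  })
  for (m in e1$models) {
    mc <- model_coords(m, I, J)
    ca1 <- rbind(mc$ca_i, mc$ca_j)
    best <- min(vapply(cas2, function(c2) kabsch_fit(ca1, c2)$rmsd,
                       numeric(1)))
    expect_lt(best, 1e-6)
  }
})

test_that("ensemble PDB output is deterministic and readable", {
  td <- make_toy_dimer(toy_dimer_spec("SL", seed = 17))
  I <- prepare_domain(td$I)
  J <- prepare_domain(td$J)
  lib <- cluster_and_build(interface_fragment_pairs(I, J), min_members = 0)
  ens <- assemble(I, J, lib)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, I, J, p1)
  write_ensemble_pdb(ens, I, J, p2)
  expect_identical(readLines(p1), readLines(p2))
  txt <- readLines(p1)
  expect_equal(sum(grepl("^MODEL", txt)), length(ens$models))
  expect_true(any(grepl("^REMARK 100 ENTRY", txt)))
  pdb <- bio3d::read.pdb(p1, multi = TRUE, verbose = FALSE)
  expect_equal(dim(pdb$xyz)[1], length(ens$models))
})
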