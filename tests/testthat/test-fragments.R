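test_that("contact detection is strict at the 5 A side-chain boundary", {
  I <- point_residue_domain(c(0, 0, 0), id = "I", dir = -1)
  near <- point_residue_domain(c(4.9, 0, 0), id = "J", chain = "B", dir = 1)
  far <- point_residue_domain(c(5.1, 0, 0), id = "J", chain = "B", dir = 1)
  expect_equal(nrow(interface_residue_pairs(I, near, cutoff = 5.0)), 1L)
  expect_equal(nrow(interface_residue_pairs(I, far, cutoff = 5.0)), 0L)
})

test_that("glycine uses its C-alpha as side-chain surrogate", {
  gly <- point_residue_domain(c(0, 0, 0), id = "G", gly = TRUE, dir = -1)
  partner <- point_residue_domain(c(4.0, 0, 0), id = "J", chain = "B", dir = 1)
  hits <- interface_residue_pairs(gly, partner, cutoff = 5.0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$min_dist, 4.0, tolerance = 1e-6)
})

test_that("contact list matches brute force over all side-chain atom pairs", {
  td <- make_toy_dimer(toy_dimer_spec("HH", seed = 5))
  got <- interface_residue_pairs(td$I, td$J, cutoff = 5.0)

  sc_xyz <- function(dom) {
    at <- dom$atoms
    sc <- !(at$elety %in% c("N", "CA", "C", "O", "OXT"))
    # every residue here carries a CB, so no glycine fallback needed
    list(xyz = as.matrix(at[sc, c("x", "y", "z")]), res = at$res_index[sc])
  }
  a <- sc_xyz(td$I)
  b <- sc_xyz(td$J)
  brute <- expand.grid(i = seq_len(td$I$nres), j = seq_len(td$J$nres))
  brute$hit <- mapply(function(i, j) {
    ai <- a$xyz[a$res == i, , drop = FALSE]
    bj <- b$xyz[b$res == j, , drop = FALSE]
    any(fraglib:::cross_dist(ai, bj) < 5.0)
  }, brute$i, brute$j)
  expect_equal(nrow(got), sum(brute$hit))
  expect_setequal(paste(got$i, got$j), paste(brute$i, brute$j)[brute$hit])
})

test_that("a center contacting two partner residues yields two shifted records", {
  # two parallel ideal strands packed closely produce multi-contact centers
  s1 <- ideal_strand(15, chain = "A", id = "s1")
  s2 <- fraglib:::transform_domain(s1, structure(
    list(rotation = diag(3), translation = c(0, 4.4, 1.9), rmsd = NA_real_),
    class = "rigid_transform"))
  s2$id <- "s2"
  contacts <- interface_residue_pairs(s1, s2)
  multi <- names(which(table(contacts$i) >= 2))
  multi <- as.integer(multi)
  multi <- multi[multi >= 5 & multi <= 11]
  expect_gt(length(multi), 0)
  recs <- extract_fragment_pairs(s1, s2, contacts)
  i0 <- multi[1]
  js <- sort(contacts$j[contacts$i == i0])
  js <- js[js >= 5 & js <= 11]
  mine <- Filter(function(p) p$center_i == i0 && p$center_j %in% js, recs)
  expect_equal(length(mine), length(js))
  # partner windows are centered one residue apart: block coordinates of
  # consecutive records overlap in 8 of 9 rows
  if (length(mine) >= 2) {
    b1 <- mine[[1]]$coords_b
    b2 <- mine[[2]]$coords_b
    expect_equal(b1[2:9, ], b2[1:8, ], tolerance = 1e-9)
  }
})

test_that("incomplete windows are skipped and counts are conserved", {
  td <- make_toy_dimer(toy_dimer_spec("SL", seed = 9))
  contacts <- interface_residue_pairs(td$I, td$J)
  # force a contact record near the terminus to exercise the skip path
  contacts <- rbind(contacts, data.frame(i = 4L, j = 4L, min_dist = 4.0))
  recs <- extract_fragment_pairs(td$I, td$J, contacts)
  sk <- attr(recs, "skipped")
  expect_equal(length(recs) + nrow(sk), nrow(contacts))
  expect_true(any(sk$i == 4L & grepl("terminus", sk$reason)))
  # every record's centers appear in the contact list
  for (p in recs)
    expect_true(any(contacts$i == p$center_i & contacts$j == p$center_j))
})

test_that("windows spanning a numbering gap are skipped", {
  sheet <- fraglib:::two_strand_domain(13)   # resno gap between strands
  helix <- ideal_helix(23, chain = "B", id = "hx")
  # synthetic contact centered right at the gap (center 13 needs 10:17)
  fake <- data.frame(i = 13L, j = 12L, min_dist = 4.0)
  recs <- extract_fragment_pairs(sheet, helix, fake)
  expect_equal(length(recs), 0L)
  expect_match(attr(recs, "skipped")$reason, "numbering_gap")
})

test_that("swapping the two domains yields the same fragment pairs", {
  td <- make_toy_dimer(toy_dimer_spec("HL", seed = 4))
  I <- td$I; J <- td$J
  r1 <- extract_fragment_pairs(I, J, interface_residue_pairs(I, J))
  r2 <- extract_fragment_pairs(J, I, interface_residue_pairs(J, I))
  expect_equal(length(r1), length(r2))
  for (p in r1) {
    match_rmsd <- min(vapply(r2, function(q) pair_rmsd(p, q), numeric(1)))
    expect_lt(match_rmsd, 1e-9)
  }
})

test_that("fragment-pair tables round-trip through TSV", {
  ds <- make_planted_pair_dataset(K = 3, members_per = 2, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_pairs(ds$pairs, path)
  back <- read_fragment_pairs(path)
  expect_equal(length(back), length(ds$pairs))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$coords_a, ds$pairs[[k]]$coords_a, tolerance = 1e-5)
    expect_identical(back[[k]]$ss_a, ds$pairs[[k]]$ss_a)
    expect_identical(back[[k]]$source, ds$pairs[[k]]$source)
  }
})
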