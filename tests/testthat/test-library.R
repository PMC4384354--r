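planted_small <- make_planted_pair_dataset(K = 4, members_per = 6,
                                           noise_sigma = 0.3, seed = 21)

test_that("pair_rmsd is symmetric, order-insensitive and matches the oracle", {
  p <- planted_small$pairs[[1]]
  q <- planted_small$pairs[[8]]
  expect_equal(pair_rmsd(p, p), 0, tolerance = 1e-12)

  swapped <- p
  swapped$coords_a <- p$coords_b
  swapped$coords_b <- p$coords_a
  expect_equal(pair_rmsd(p, swapped), 0, tolerance = 1e-9)

  expect_equal(pair_rmsd(p, q), pair_rmsd(q, p), tolerance = 1e-12)
  expect_equal(pair_rmsd(p, q), oracle_pair_rmsd(p, q), tolerance = 1e-9)

  noisy <- p
  set.seed(1)
  noisy$coords_a <- p$coords_a + matrix(rnorm(27, 0, 0.3), 9, 3)
  noisy$coords_b <- p$coords_b + matrix(rnorm(27, 0, 0.3), 9, 3)
  expect_equal(pair_rmsd(p, noisy), oracle_pair_rmsd(p, noisy),
               tolerance = 1e-9)
})

test_that("pair_rmsd_matrix equals elementwise pair_rmsd", {
  pairs <- planted_small$pairs[1:8]
  M <- pair_rmsd_matrix(pairs)
  expect_equal(M, t(M))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(M[i, j], pair_rmsd(pairs[[i]], pairs[[j]]),
                 tolerance = 1e-9)
})

test_that("greedy clustering partitions the input for any seed and cutoff", {
  pairs <- planted_small$pairs
  M <- pair_rmsd_matrix(pairs)
  for (seed in c(0, 1, 99)) {
    for (cutoff in c(0.05, 4, 1000)) {
      cl <- greedy_cluster(pairs, cutoff = cutoff, order_seed = seed,
                           rmsd_matrix = M, representatives = FALSE)
      sizes <- vapply(cl, `[[`, 0L, "size")
      expect_equal(sum(sizes), length(pairs))
      expect_setequal(unlist(lapply(cl, `[[`, "member_ids")),
                      seq_along(pairs))
    }
  }
  # degenerate regimes: everything separate / everything together
  expect_equal(length(greedy_cluster(pairs, cutoff = 0.05, order_seed = 1,
                                     rmsd_matrix = M,
                                     representatives = FALSE)),
               length(pairs))
  expect_equal(length(greedy_cluster(pairs, cutoff = 1000, order_seed = 1,
                                     rmsd_matrix = M,
                                     representatives = FALSE)), 1L)
})

test_that("planted clusters are recovered exactly with any visiting order", {
  pairs <- planted_small$pairs
  M <- pair_rmsd_matrix(pairs)
  for (seed in 0:2) {
    cl <- greedy_cluster(pairs, cutoff = 4, order_seed = seed,
                         rmsd_matrix = M, representatives = FALSE)
    expect_equal(length(cl), 4L)
    asn <- attr(cl, "assignment")
    tab <- table(asn, planted_small$labels)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("representative selection follows neighbor count, then ties", {
  # chain A - B - C along a translation axis: B is within the cutoff of
  # both ends, the ends only of B
  base <- planted_small$pairs[[1]]
  shift <- function(p, d) {
    q <- p
    q$coords_b <- p$coords_b + matrix(rep(c(d, 0, 0), each = 9), 9, 3)
    q
  }
  A <- base
  B <- shift(base, 5)
  C <- shift(base, 10)
  trio <- list(A, B, C)
  M <- pair_rmsd_matrix(trio)
  # verify the construction gives the intended chain topology
  cutoff <- mean(c(M[1, 2], M[1, 3]))
  expect_lt(M[1, 2], cutoff)
  expect_lt(M[2, 3], cutoff)
  expect_gt(M[1, 3], cutoff)
  cl <- list(member_ids = 1:3, size = 3L)
  expect_equal(select_representative(cl, trio, cutoff, rmsd_matrix = M), 2L)

  # exact ties fall back to the lowest member id
  same <- list(base, base, base)
  M0 <- pair_rmsd_matrix(same)
  expect_equal(select_representative(list(member_ids = 1:3, size = 3L),
                                     same, 4, rmsd_matrix = M0), 1L)
  expect_equal(select_representative(list(member_ids = 7L, size = 1L),
                                     planted_small$pairs, 4), 7L)
})

test_that("the abundance filter is strictly greater-than", {
  geoms <- make_planted_pair_dataset(K = 4, members_per = c(25, 21, 20, 5),
                                     noise_sigma = 0.2, seed = 31)
  M <- pair_rmsd_matrix(geoms$pairs)
  cl <- greedy_cluster(geoms$pairs, cutoff = 4, order_seed = 0,
                       rmsd_matrix = M)
  expect_equal(sort(vapply(cl, `[[`, 0L, "size")), c(5L, 20L, 21L, 25L))
  lib20 <- build_library(cl, geoms$pairs, min_members = 20)
  expect_equal(length(lib20$entries), 2L)
  expect_equal(vapply(lib20$entries, `[[`, 0L, "member_count"), c(25L, 21L))
  lib0 <- build_library(cl, geoms$pairs, min_members = 0)
  expect_equal(length(lib0$entries), 4L)
  expect_warning(build_library(cl, geoms$pairs, min_members = 1000),
                 "empty library")
})

test_that("coverage behaves at its extremes and for planted half/half sets", {
  ds <- make_planted_pair_dataset(K = 2, members_per = 8, noise_sigma = 0.2,
                                  seed = 41, n_singletons = 16)
  M <- pair_rmsd_matrix(ds$pairs)
  cl <- greedy_cluster(ds$pairs, cutoff = 4, order_seed = 0, rmsd_matrix = M)
  lib <- build_library(cl, ds$pairs, min_members = 2)
  expect_equal(length(lib$entries), 2L)

  entries_as_queries <- lapply(lib$entries, `[[`, "pair")
  expect_equal(coverage(entries_as_queries, lib)$fraction, 1)

  singles <- ds$pairs[ds$labels > 2]          # all planted > 8 A away
  expect_equal(coverage(singles, lib)$fraction, 0)

  half <- c(ds$pairs[ds$labels == 1][1:8], singles[1:8])
  cov <- coverage(half, lib)
  expect_equal(cov$fraction, 0.5)
  expect_length(cov$min_rmsd, 16L)
  expect_error(coverage(list(), lib), "empty")
})

test_that("cutoff scans bracket the planted structure and are monotone", {
  pairs <- planted_small$pairs
  M <- pair_rmsd_matrix(pairs)
  scan <- cutoff_scan(pairs, c(0.05, 4, 500), order_seed = 3, rmsd_matrix = M)
  expect_equal(scan$n_clusters, c(length(pairs), 4L, 1L))
  dense <- cutoff_scan(pairs, c(0.05, 0.5, 2, 4, 8, 500), order_seed = 3,
                       rmsd_matrix = M)
  expect_true(all(diff(dense$n_clusters) <= 0))
  expect_error(cutoff_scan(pairs, 4), "cutoffs")
})

test_that("stability runs agree across visiting orders on separated data", {
  pairs <- planted_small$pairs
  M <- pair_rmsd_matrix(pairs)
  st <- stability_runs(pairs, cutoff = 4, n_runs = 3, seeds = 0:2,
                       min_members = 3, rmsd_matrix = M)
  expect_equal(st$summary$n_clusters, rep(4L, 3))
  expect_equal(st$summary$n_abundant, rep(4L, 3))
  for (p in st$size_profiles) expect_equal(sort(p), sort(st$size_profiles[[1]]))

  copies <- rep(pairs[1], 10)
  st1 <- stability_runs(copies, cutoff = 4, n_runs = 2, seeds = 0:1)
  expect_equal(st1$summary$n_clusters, c(1L, 1L))
  expect_error(stability_runs(pairs, 4, n_runs = 5, seeds = 0:2), "seeds")
})

test_that("library JSON round-trips and is byte-stable", {
  ds <- make_planted_pair_dataset(K = 3, members_per = 4, seed = 51)
  lib <- cluster_and_build(ds$pairs, min_members = 0, order_seed = 2)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_library(lib, p1)
  write_library(lib, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_library(p1)
  expect_equal(length(back$entries), length(lib$entries))
  expect_equal(back$params$min_members, lib$params$min_members)
  for (k in seq_along(back$entries)) {
    expect_lt(pair_rmsd(back$entries[[k]]$pair, lib$entries[[k]]$pair), 1e-5)
    expect_equal(back$entries[[k]]$member_count,
                 lib$entries[[k]]$member_count)
  }
  expect_error(read_library(withr::local_tempfile(lines = "{}",
                                                  fileext = ".json")),
               "library")
})
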