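## Deterministic generators of synthetic peptides, dimers and planted
## fragment-pair datasets. Everything is a pure function of its arguments
## (plus an explicit seed), so fixtures can be regenerated exactly.

# Run code with a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

unit <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

rotation_about <- function(axis, angle_deg) {
  a <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Natural-extension-reference-frame placement: position D given the three
# preceding atoms A-B-C, bond length r(C-D), angle theta(B-C-D) and
# torsion chi(A-B-C-D), angles in degrees.
nerf_place <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- unit(C - B)
  n <- unit(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(th), r * cos(ch) * sin(th), r * sin(ch) * sin(th))
  C + d[1L] * bc + d[2L] * m + d[3L] * n
}

# Pseudo-C-beta at ideal tetrahedral geometry from backbone N, CA, C.
pseudo_cb <- function(N, CA, C) {
  b <- CA - N
  c <- C - CA
  a <- cross3(b, c)
  CA - 0.58273431 * a + 0.56802827 * b - 0.54067466 * c
}

# Build an n-residue backbone (N, CA, C, O + pseudo-CB) from per-residue
# torsions using standard bond lengths/angles. phi[1] and the omega of the
# first residue are ignored.
backbone_from_torsions <- function(phi, psi, omega = NULL,
                                   resid = "ALA", chain = "A",
                                   resno = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  if (is.null(omega)) omega <- rep(180, n)
  if (is.null(resno)) resno <- seq_len(n)
  resid <- rep_len(resid, n)

  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1L, ] <- CA[1L, ] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in 2L:n) {
    N[i, ] <- nerf_place(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                         1.329, 116.2, psi[i - 1L])
    CA[i, ] <- nerf_place(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          1.458, 121.7, omega[i])
    C[i, ] <- nerf_place(C[i - 1L, ], N[i, ], CA[i, ],
                         1.525, 111.2, phi[i])
  }
  for (i in seq_len(n)) {
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi[i] + 180)
    CB[i, ] <- pseudo_cb(N[i, ], CA[i, ], C[i, ])
  }

  per_res <- function(i) {
    gly <- resid[i] == "GLY"
    nm <- c("N", "CA", "C", "O", if (!gly) "CB")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ], if (!gly) CB[i, ])
    data.frame(elety = nm, resid = resid[i], chain = chain,
               resno = resno[i], ins = "",
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               element = substr(nm, 1L, 1L),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(n), per_res))
}

#' Ideal alpha-helix fixture
#'
#' Canonical alpha-helical backbone (phi = -57, psi = -47; 1.5 A rise and
#' 100 degrees of twist per residue, C-alpha radius about 2.3 A) with
#' backbone N, CA, C, O and a pseudo-C-beta at tetrahedral geometry so
#' contact, secondary-structure and surface-area operations all work.
#'
#' @param n number of residues (>= 4).
#' @param chain,id chain identifier and domain id.
#' @return A \code{domain}.
#' @export
ideal_helix <- function(n, chain = "A", id = "helix") {
  stopifnot(n >= 4L)
  as_domain(backbone_from_torsions(rep(-57, n), rep(-47, n), chain = chain),
            id = id)
}

#' Ideal extended-strand fixture
#'
#' Extended beta geometry; the default torsions give a straight,
#' beta-sheet-compatible strand.
#'
#' @param n number of residues (>= 3).
#' @param phi,psi backbone torsions in degrees.
#' @param chain,id chain identifier and domain id.
#' @return A \code{domain}.
#' @export
ideal_strand <- function(n, phi = -120, psi = 120, chain = "A", id = "strand") {
  stopifnot(n >= 3L)
  as_domain(backbone_from_torsions(rep(phi, n), rep(psi, n), chain = chain),
            id = id)
}

#' Self-avoiding random-coil fixture
#'
#' Coil backbone with torsions drawn from a broad non-helical region and a
#' 4 A C-alpha self-avoidance constraint (resampled bounded number of
#' times). Deterministic given the seed.
#'
#' @param n number of residues (>= 3).
#' @param seed integer seed fixing all randomness.
#' @param chain,id chain identifier and domain id.
#' @return A \code{domain}.
#' @export
random_loop <- function(n, seed = 1L, chain = "A", id = "loop") {
  stopifnot(n >= 3L)
  for (attempt in 0:49) {
    dom <- with_seed(seed * 101L + attempt, {
      phi <- runif(n, -150, -60)
      psi <- runif(n, 60, 180)
      as_domain(backbone_from_torsions(phi, psi, chain = chain), id = id)
    })
    ca <- dom$ca
    d <- as.matrix(stats::dist(ca))
    far <- row(d) - col(d) > 2L
    if (all(d[far] > 4)) return(dom)
  }
  stop("could not generate a self-avoiding loop of length ", n)
}

transform_domain <- function(domain, transform) {
  at <- domain$atoms
  xyz <- apply_transform(transform, as.matrix(at[, c("x", "y", "z")]))
  at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  d <- as_domain(at, id = domain$id)
  d$ss3 <- domain$ss3
  d$sasa <- domain$sasa
  d
}

## ---- beta-sheet construction --------------------------------------------

strand_bb <- function(dom) {
  list(N = backbone_matrix(dom, "N"), CA = dom$ca,
       C = backbone_matrix(dom, "C"), O = backbone_matrix(dom, "O"))
}

# Count Kabsch-Sander inter-strand H-bonds between two separate strands
# given their backbone coordinate sets (no chain continuity between them).
inter_strand_hbonds <- function(bb1, bb2) {
  hcoord <- function(bb) {
    n <- nrow(bb$N)
    H <- matrix(NA_real_, n, 3L)
    for (i in 2L:n) {
      co <- bb$O[i - 1L, ] - bb$C[i - 1L, ]
      H[i, ] <- bb$N[i, ] - 1.01 * unit(co)
    }
    H
  }
  energy <- function(don, acc, Hdon) {
    ok <- which(rowSums(is.na(Hdon)) == 0L)
    if (!length(ok)) return(matrix(numeric(0), 0, 0))
    r_on <- cross_dist(don$N[ok, , drop = FALSE], acc$O)
    r_ch <- cross_dist(Hdon[ok, , drop = FALSE], acc$C)
    r_oh <- cross_dist(Hdon[ok, , drop = FALSE], acc$O)
    r_cn <- cross_dist(don$N[ok, , drop = FALSE], acc$C)
    27.888 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  }
  H1 <- hcoord(bb1); H2 <- hcoord(bb2)
  sum(energy(bb1, bb2, H1) < -0.5) + sum(energy(bb2, bb1, H2) < -0.5)
}

apply_to_bb <- function(bb, R, t) {
  lapply(bb, function(m) sweep(m %*% t(R), 2L, t, "+"))
}

# Place a geometrically identical partner strand next to `strand` so the
# two form a hydrogen-bonded (anti)parallel sheet. The partner placement
# (rigid transform of the input strand) is found by a deterministic grid
# search over the sheet offsets that maximizes the number of inter-strand
# Kabsch-Sander H-bonds, keeping all inter-strand C-alpha pairs above
# `ca_floor`. If `away_from` (a coordinate matrix, e.g. an existing
# neighbouring strand) is given, placements that collide with it are
# rejected, which selects the free side of an edge strand.
sheet_partner_transform <- function(strand, type = c("antiparallel", "parallel"),
                                    away_from = NULL, ca_floor = 4.3) {
  type <- match.arg(type)
  bb <- strand_bb(strand)
  n <- nrow(bb$CA)

  # canonical frame: strand axis -> x, average carbonyl direction of the
  # even residues (the inter-strand hydrogen-bond direction) -> +/- y
  axis <- unit(bb$CA[n, ] - bb$CA[1L, ])
  co <- bb$O - bb$C
  ev <- seq(2L, n, by = 2L)
  ydir <- colMeans(co[ev, , drop = FALSE])
  ydir <- ydir - sum(ydir * axis) * axis
  cen <- colMeans(bb$CA)
  base_R <- if (type == "antiparallel") rotation_about(c(0, 1, 0), 180) else diag(3L)

  best <- NULL
  for (ysign in c(1, -1)) {
    y0 <- unit(ysign * ydir)
    z0 <- cross3(axis, y0)
    Rw <- rbind(axis, y0, z0)        # world -> canonical
    canon <- apply_to_bb(bb, Rw, as.numeric(-Rw %*% cen))
    away <- if (is.null(away_from)) NULL
            else sweep(away_from %*% t(Rw), 2L, as.numeric(-Rw %*% cen), "+")
    score_at <- function(dx, dy, dz, phase_deg) {
      R <- rotation_about(c(1, 0, 0), phase_deg) %*% base_R
      partner <- apply_to_bb(canon, R, c(dx, dy, dz))
      if (min(cross_dist(canon$CA, partner$CA)) < ca_floor) return(-1L)
      if (!is.null(away) && min(cross_dist(away, partner$CA)) < ca_floor)
        return(-1L)
      inter_strand_hbonds(canon, partner)
    }
    for (phase in c(0, 180)) {
      for (dy in seq(4.0, 5.8, by = 0.2)) {
        for (dx in seq(-3.5, 3.5, by = 0.25)) {
          for (dz in c(-0.8, 0, 0.8)) {
            s <- score_at(dx, dy, dz, phase)
            if (is.null(best) || s > best$s)
              best <- list(s = s, dx = dx, dy = dy, dz = dz, phase = phase,
                           ysign = ysign, Rw = Rw, score_at = score_at)
          }
        }
      }
    }
  }
  sc <- best$score_at
  for (dy in seq(best$dy - 0.25, best$dy + 0.25, by = 0.05)) {
    for (dx in seq(best$dx - 0.3, best$dx + 0.3, by = 0.05)) {
      for (dz in seq(best$dz - 0.8, best$dz + 0.8, by = 0.2)) {
        s <- sc(dx, dy, dz, best$phase)
        if (s > best$s) {
          best$s <- s; best$dx <- dx; best$dy <- dy; best$dz <- dz
        }
      }
    }
  }
  if (best$s < 2L)
    stop("failed to find a hydrogen-bonded sheet registration")

  # compose: world -> canonical -> partner -> world
  # y = Rw' R1 Rw x + (cen - Rw' R1 Rw cen + Rw' t1)
  Rw <- best$Rw
  R1 <- rotation_about(c(1, 0, 0), best$phase) %*% base_R
  t1 <- c(best$dx, best$dy, best$dz)
  R <- t(Rw) %*% R1 %*% Rw
  tr <- as.numeric(cen - R %*% cen + t(Rw) %*% t1)
  structure(list(rotation = R, translation = tr, rmsd = NA_real_),
            class = "rigid_transform")
}

.sheet_cache <- new.env(parent = emptyenv())

sheet_partner_cached <- function(strand, type) {
  key <- paste(type, strand$nres, sep = "_")
  if (is.null(.sheet_cache[[key]]))
    .sheet_cache[[key]] <- sheet_partner_transform(strand, type)
  .sheet_cache[[key]]
}

# Two-strand antiparallel beta-sheet domain (strands joined by a numbering
# gap, not a built loop); edge strand 2 is the designated packing element.
two_strand_domain <- function(strand_len = 13L, chain = "A", id = "sheet") {
  s1 <- ideal_strand(strand_len, phi = -139, psi = 135, chain = chain)
  tf <- sheet_partner_cached(s1, "antiparallel")
  at1 <- s1$atoms
  s2 <- transform_domain(s1, tf)
  at2 <- s2$atoms
  at2$resno <- at2$resno + 100L
  as_domain(rbind(at1, at2), id = id)
}

## ---- toy dimers ----------------------------------------------------------

TOY_MOTIFS <- c("HH", "SS-parallel", "SS-antiparallel", "LL", "HL", "HS", "SL")

#' Specification of a synthetic two-domain complex
#'
#' @param motif one of "HH", "SS-parallel", "SS-antiparallel", "LL", "HL",
#'   "HS", "SL": the secondary-structure classes of the two packed
#'   elements (SS variants control the strand directions across the
#'   interface).
#' @param lengths residues per domain (length-2; >= 9 each). Sheet domains
#'   use two strands of about half this length.
#' @param separation center-to-center C-alpha distance of the packed
#'   elements in Angstrom (ignored for hydrogen-bonded SS interfaces,
#'   where sheet geometry fixes the spacing).
#' @param angle inter-element packing angle in degrees (rotation of domain
#'   J's element about the packing axis).
#' @param noise_sigma Gaussian coordinate noise, Angstrom.
#' @param seed integer; fixes all randomness.
#' @return A \code{toy_dimer_spec} list.
#' @export
toy_dimer_spec <- function(motif = "HH", lengths = c(23L, 23L),
                           separation = 6.5, angle = NULL,
                           noise_sigma = 0, seed = 1L) {
  motif <- match.arg(motif, TOY_MOTIFS)
  # helix-on-sheet packs near-perpendicular; the other elements cross at
  # the oblique angle typical of helix pairs
  if (is.null(angle)) angle <- if (motif == "HS") 90 else 150
  stopifnot(length(lengths) == 2L, all(lengths >= 9L),
            separation > 0, noise_sigma >= 0)
  structure(list(motif = motif, lengths = as.integer(lengths),
                 separation = separation, angle = angle,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "toy_dimer_spec")
}

toy_element <- function(kind, len, chain, seed, edge = c("second", "first")) {
  edge <- match.arg(edge)
  switch(kind,
    H = list(domain = ideal_helix(len, chain = chain,
                                  id = paste0("helix", chain)),
             center = (len + 1L) %/% 2L),
    S = {
      sl <- max(11L, len %/% 2L)
      dom <- two_strand_domain(sl, chain = chain, id = paste0("sheet", chain))
      center <- if (edge == "second") sl + (sl + 1L) %/% 2L else (sl + 1L) %/% 2L
      list(domain = dom, center = center)
    },
    L = list(domain = random_loop(max(len, 15L), seed = seed, chain = chain,
                                  id = paste0("loop", chain)),
             center = (max(len, 15L) + 1L) %/% 2L)
  )
}

# Rotate/translate a domain so that residue `center`'s CB->CA axis points
# along -x (CB toward +x), with the local chain direction along +z.
orient_by_center <- function(domain, center) {
  at <- domain$atoms
  ca <- domain$ca[center, ]
  cb_row <- which(at$res_index == center & at$elety == "CB")
  if (!length(cb_row)) cb_row <- which(at$res_index == center & at$elety == "CA")
  cb <- as.numeric(at[cb_row[1L], c("x", "y", "z")])
  x <- unit(cb - ca)
  # element axis from the end-to-end vector of the contiguous segment
  # around the center (local i-1/i+1 chords wobble badly on a helix)
  lo <- center
  while (lo > 1L && domain$resno[lo] - domain$resno[lo - 1L] == 1L) lo <- lo - 1L
  hi <- center
  while (hi < domain$nres && domain$resno[hi + 1L] - domain$resno[hi] == 1L)
    hi <- hi + 1L
  chain_dir <- unit(domain$ca[hi, ] - domain$ca[lo, ])
  z <- chain_dir - sum(chain_dir * x) * x
  if (sqrt(sum(z^2)) < 1e-6) z <- cross3(x, c(0, 1, 0))
  z <- unit(z)
  y <- cross3(z, x)
  R <- rbind(x, y, z)                 # maps world dirs onto axes
  tf <- structure(list(rotation = R, translation = as.numeric(-R %*% ca),
                       rmsd = NA_real_), class = "rigid_transform")
  transform_domain(domain, tf)
}

add_coordinate_noise <- function(domain, sigma, seed) {
  if (sigma <= 0) return(domain)
  at <- domain$atoms
  noise <- with_seed(seed, matrix(rnorm(3L * nrow(at), 0, sigma), ncol = 3L))
  at$x <- at$x + noise[, 1L]
  at$y <- at$y + noise[, 2L]
  at$z <- at$z + noise[, 3L]
  as_domain(at, id = domain$id)
}

#' Generate a synthetic two-domain complex with a planted interface
#'
#' Builds two small domains (ideal helices, two-strand beta-sheets or
#' self-avoiding coils per the spec's motif), packs their designated
#' central elements at the requested separation and packing angle (or, for
#' hydrogen-bonded SS interfaces, at ideal sheet geometry), optionally
#' adds Gaussian coordinate noise, and verifies that at least one
#' side-chain contact exists under the 5 A interface rule.
#'
#' @param spec A \code{\link{toy_dimer_spec}}.
#' @return List with elements \code{I}, \code{J} (the two \code{domain}s,
#'   in the native complex frame), \code{native} (list of the native
#'   C-alpha matrices \code{ca_i}, \code{ca_j}) and \code{spec}.
#' @export
make_toy_dimer <- function(spec) {
  stopifnot(inherits(spec, "toy_dimer_spec"))
  kinds <- switch(spec$motif,
    "HH" = c("H", "H"), "LL" = c("L", "L"), "HL" = c("H", "L"),
    "HS" = c("H", "S"), "SL" = c("S", "L"),
    "SS-parallel" = c("S", "S"), "SS-antiparallel" = c("S", "S"))

  is_sheet_interface <- spec$motif %in% c("SS-parallel", "SS-antiparallel")
  lenJ <- if (is_sheet_interface) spec$lengths[1L] else spec$lengths[2L]
  eI <- toy_element(kinds[1L], spec$lengths[1L], "A", spec$seed, edge = "second")
  eJ <- toy_element(kinds[2L], lenJ, "B", spec$seed + 7L, edge = "first")
  I <- eI$domain
  J <- eJ$domain

  if (is_sheet_interface) {
    # continue domain I's sheet with domain J, built strand by strand:
    # J's first strand is the interface partner of I's edge strand, J's
    # inner strand extends the sheet away from I
    sl <- max(11L, spec$lengths[1L] %/% 2L)
    proto <- ideal_strand(sl, phi = -139, psi = 135, chain = "B")
    type <- if (spec$motif == "SS-parallel") "parallel" else "antiparallel"
    edge <- transform_domain(proto, sheet_partner_cached(proto, "antiparallel"))
    j1 <- transform_domain(edge,
                           sheet_partner_transform(edge, type,
                                                   away_from = proto$ca))
    j2 <- transform_domain(j1,
                           sheet_partner_transform(j1, "antiparallel",
                                                   away_from = I$ca))
    at1 <- j1$atoms
    at2 <- j2$atoms
    at2$resno <- at2$resno + 100L
    J <- as_domain(rbind(at1, at2), id = J$id)
  } else {
    I <- orient_by_center(I, eI$center)
    J0 <- orient_by_center(J, eJ$center)
    flip <- rotation_about(c(0, 0, 1), 180)   # turn J's CB toward -x
    spin <- rotation_about(c(1, 0, 0), spec$angle)
    R <- spin %*% flip
    # back the domains off along the packing axis until no C-alpha pair
    # comes closer than 4 A (irregular elements can graze at the nominal
    # separation), keeping the center contact
    sep <- spec$separation
    repeat {
      tf <- structure(list(rotation = R, translation = c(sep, 0, 0),
                           rmsd = NA_real_), class = "rigid_transform")
      J <- transform_domain(J0, tf)
      if (min(cross_dist(I$ca, J$ca)) >= 4.0 || sep > spec$separation + 4)
        break
      sep <- sep + 0.5
    }
  }

  if (spec$noise_sigma > 0) {
    I <- add_coordinate_noise(I, spec$noise_sigma, spec$seed * 13L + 1L)
    J <- add_coordinate_noise(J, spec$noise_sigma, spec$seed * 13L + 2L)
  }

  contacts <- interface_residue_pairs(I, J, cutoff = 5.0)
  if (nrow(contacts) == 0L)
    stop("toy dimer spec produced no interface contact (motif ", spec$motif,
         ", separation ", spec$separation, ")")

  list(I = I, J = J,
       native = list(ca_i = I$ca, ca_j = J$ca),
       spec = spec)
}

#' Deterministic toy benchmark of dimer specifications
#'
#' A fixed roster of \code{\link{toy_dimer_spec}}s cycling through all
#' seven interface motifs with varying domain lengths and seeds, used to
#' exercise assembly end-to-end.
#'
#' @param n number of specs.
#' @return List of \code{toy_dimer_spec}.
#' @export
toy_benchmark_specs <- function(n = 20L) {
  lens <- c(21L, 23L, 25L)
  lapply(seq_len(n), function(i) {
    toy_dimer_spec(motif = TOY_MOTIFS[(i - 1L) %% length(TOY_MOTIFS) + 1L],
                   lengths = rep(lens[(i - 1L) %% 3L + 1L], 2L),
                   seed = 100L + i)
  })
}

## ---- planted fragment-pair datasets --------------------------------------

random_ca_fragment <- function(n = 9L, step = 3.8, wobble = 0.45) {
  v <- unit(rnorm(3L))
  pts <- matrix(0, n, 3L)
  for (k in 2L:n) {
    v <- unit(v + wobble * rnorm(3L))
    pts[k, ] <- pts[k - 1L, ] + step * v
  }
  pts
}

random_pair_geometry <- function(max_sep = 34) {
  # chain stiffness and block separation are drawn broadly so that
  # distinct geometries are far apart in superposition RMSD
  a <- random_ca_fragment(wobble = runif(1L, 0.1, 0.9))
  b <- random_ca_fragment(wobble = runif(1L, 0.1, 0.9))
  R <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  offset <- unit(rnorm(3L)) * runif(1L, 6, max_sep)
  b <- sweep(b %*% t(R), 2L, offset + colMeans(a) - colMeans(b %*% t(R)), "+")
  list(a = a, b = b)
}

new_fragment_pair <- function(coords_a, coords_b, ss_a, ss_b,
                              center_i = 5L, center_j = 5L,
                              source = "synthetic", id = NA_integer_) {
  structure(list(id = id, source = source,
                 center_i = center_i, center_j = center_j,
                 coords_a = coords_a, coords_b = coords_b,
                 ss_a = ss_a, ss_b = ss_b),
            class = "fragment_pair")
}

#' Planted fragment-pair dataset with known cluster structure
#'
#' Draws K random, well-separated fragment-pair geometries (rejection
#' sampling enforces an inter-geometry RMSD larger than twice the intended
#' clustering cutoff) and emits noisy copies of each, carrying the true
#' cluster labels. Secondary-structure types of the fragments are sampled
#' from fixed frequencies so motif statistics can be exercised.
#'
#' @param K number of planted geometries.
#' @param members_per copies per geometry (scalar or length-K).
#' @param noise_sigma Gaussian noise per coordinate, Angstrom.
#' @param seed integer seed.
#' @param cluster_cutoff intended clustering cutoff (separation is
#'   enforced at twice this value).
#' @param n_singletons additional well-separated single-member geometries.
#' @param type_probs sampling frequencies for fragment types H/S/L.
#' @return List with \code{pairs} (list of \code{fragment_pair}),
#'   \code{labels} (integer vector of true cluster ids) and \code{geoms}
#'   (the seed geometries).
#' @export
make_planted_pair_dataset <- function(K, members_per, noise_sigma = 0.3,
                                      seed = 1L, cluster_cutoff = 4,
                                      n_singletons = 0L,
                                      type_probs = c(H = 0.432, S = 0.286, L = 0.282)) {
  stopifnot(K >= 1L, all(members_per >= 1L))
  n_geom <- K + n_singletons
  members <- c(rep_len(members_per, K), rep(1L, n_singletons))

  with_seed(seed, {
    geoms <- list()
    for (g in seq_len(n_geom)) {
      placed <- FALSE
      for (try in 1:2000) {
        # later geometries draw from a wider separation range so that a
        # crowded set can still satisfy the mutual-distance constraint
        cand <- random_pair_geometry(max_sep = 30 + 2 * g)
        cand_pair <- new_fragment_pair(cand$a, cand$b, "L", "L")
        ok <- all(vapply(geoms, function(gg)
          pair_rmsd(cand_pair, new_fragment_pair(gg$a, gg$b, "L", "L")) >
            2 * cluster_cutoff, logical(1L)))
        if (ok) { geoms[[g]] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place ", n_geom, " geometries at separation > ",
             2 * cluster_cutoff, " A")
    }

    pairs <- list()
    labels <- integer(0)
    types <- names(type_probs)
    idx <- 0L
    for (g in seq_len(n_geom)) {
      for (m in seq_len(members[g])) {
        idx <- idx + 1L
        a <- geoms[[g]]$a + matrix(rnorm(27L, 0, noise_sigma), 9L, 3L)
        b <- geoms[[g]]$b + matrix(rnorm(27L, 0, noise_sigma), 9L, 3L)
        pairs[[idx]] <- new_fragment_pair(
          a, b,
          sample(types, 1L, prob = type_probs),
          sample(types, 1L, prob = type_probs),
          source = sprintf("planted_g%02d_m%03d", g, m), id = idx)
        labels[idx] <- g
      }
    }
    list(pairs = pairs, labels = labels, geoms = geoms)
  })
}

#' Noisy copies of fragment-pair records
#'
#' @param pairs list of \code{fragment_pair}.
#' @param sigma Gaussian noise per coordinate, Angstrom.
#' @param seed integer seed.
#' @param copies noisy copies per input record.
#' @return List of perturbed \code{fragment_pair} records.
#' @export
perturb_fragment_pairs <- function(pairs, sigma, seed = 1L, copies = 1L) {
  with_seed(seed, {
    out <- list()
    idx <- 0L
    for (p in pairs) {
      for (k in seq_len(copies)) {
        idx <- idx + 1L
        q <- p
        q$id <- idx
        q$source <- paste0(p$source, "_pert", k)
        q$coords_a <- p$coords_a + matrix(rnorm(27L, 0, sigma), 9L, 3L)
        q$coords_b <- p$coords_b + matrix(rnorm(27L, 0, sigma), 9L, 3L)
        out[[idx]] <- q
      }
    }
    out
  })
}
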