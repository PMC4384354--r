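#' @importFrom stats rnorm runif setNames
#' @importFrom utils head read.table write.table
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Van der Waals radii used for surface-area calculations
#'
#' A single fixed table of heavy-atom radii, keyed by element symbol.
#' Unknown elements fall back to the carbon radius.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, H = 1.20)
}

element_from_name <- function(elety) {
  # strip digits/primes, take the leading alphabetic part; two-letter
  # elements occurring in proteins (SE of selenomethionine) handled first
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  el <- substr(nm, 1L, 1L)
  el[substr(nm, 1L, 2L) == "SE"] <- "SE"
  el
}

#' Build a domain structure from an atom table
#'
#' The in-memory container used throughout the package: an ordered list of
#' residues with heavy-atom coordinates, a C-alpha trace, and slots for
#' 3-state secondary structure and per-residue solvent accessibility.
#' Residues are indexed sequentially from 1 in the order (chain, author
#' number, insertion code); author numbering is retained for reporting.
#'
#' @param atoms data.frame with columns \code{elety} (atom name),
#'   \code{resid} (3-letter residue name), \code{chain}, \code{resno}
#'   (author residue number), \code{ins} (insertion code, "" if none),
#'   \code{x}, \code{y}, \code{z}, and optionally \code{element}.
#' @param id character tag identifying the source (structure id, chain,
#'   residue range).
#' @return An object of class \code{domain}.
#' @export
as_domain <- function(atoms, id = "domain") {
  stopifnot(is.data.frame(atoms),
            all(c("elety", "resid", "chain", "resno", "x", "y", "z")
                %in% names(atoms)))
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$element)) atoms$element <- element_from_name(atoms$elety)
  if (nrow(atoms) == 0L) stop("domain has no atoms")

  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
  ukey <- unique(key)
  ord <- order(atoms$chain[match(ukey, key)],
               atoms$resno[match(ukey, key)],
               atoms$ins[match(ukey, key)])
  ukey <- ukey[ord]
  atoms$res_index <- match(key, ukey)
  atoms <- atoms[order(atoms$res_index), , drop = FALSE]
  rownames(atoms) <- NULL

  first <- match(seq_along(ukey), atoms$res_index)
  nres <- length(ukey)
  ca <- matrix(NA_real_, nres, 3L)
  is_ca <- atoms$elety == "CA"
  ca_rows <- which(is_ca)[match(seq_len(nres), atoms$res_index[is_ca])]
  ok <- !is.na(ca_rows)
  ca[ok, ] <- as.matrix(atoms[ca_rows[ok], c("x", "y", "z")])

  structure(list(
    id = id,
    atoms = atoms,
    nres = nres,
    resno = atoms$resno[first],
    ins = atoms$ins[first],
    resid = atoms$resid[first],
    chain = atoms$chain[first],
    ca = ca,
    ss3 = NULL,
    sasa = NULL
  ), class = "domain")
}

#' @export
print.domain <- function(x, ...) {
  cat("domain", x$id, "-", x$nres, "residues,", nrow(x$atoms), "heavy atoms\n")
  if (!is.null(x$ss3))
    cat("ss3:", paste(table(factor(x$ss3, c("H", "S", "L"))), collapse = "/"),
        "(H/S/L)\n")
  if (!is.null(x$sasa))
    cat("sasa: total", round(sum(x$sasa), 1), "A^2\n")
  invisible(x)
}

#' Read one protein domain from a PDB or mmCIF file
#'
#' Reads the first model, keeps heavy atoms of ATOM records only (ligands,
#' waters and hydrogens are dropped), resolves alternate locations by
#' keeping the highest-occupancy conformer (ties broken by altloc 'A',
#' then alphabetically), and optionally restricts to an author-numbering
#' residue range.
#'
#' @param path PDB (.pdb/.ent) or mmCIF (.cif) file.
#' @param chain chain identifier; must exist in the file.
#' @param range optional length-2 integer vector \code{c(first, last)} of
#'   author residue numbers (inclusive).
#' @param format "auto" (by extension), "pdb" or "cif".
#' @return A \code{domain} object.
#' @export
read_domain <- function(path, chain, range = NULL, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  # keep all altlocs at read time; occupancy-based resolution is ours
  pdb <- if (format == "cif") bio3d::read.cif(path, verbose = FALSE,
                                              rm.alt = FALSE)
         else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at$chain[is.na(at$chain)] <- ""
  if (!chain %in% at$chain)
    stop("chain '", chain, "' not found in ", path)
  at <- at[at$chain == chain, , drop = FALSE]

  # hydrogens out
  el <- at$elesy
  el[is.na(el) | el == ""] <- element_from_name(at$elety[is.na(el) | el == ""])
  el <- toupper(el)
  at <- at[!(el %in% c("H", "D")), , drop = FALSE]
  el <- el[!(el %in% c("H", "D"))]

  # altloc resolution: highest occupancy, ties -> 'A' then alphabetical
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  pref <- order(key, -occ, alt != "A", alt)
  keep <- pref[!duplicated(key[pref])]
  at <- at[sort(keep), , drop = FALSE]

  ins <- at$insert
  ins[is.na(ins)] <- ""
  if (!is.null(range)) {
    stopifnot(length(range) == 2L)
    sel <- at$resno >= range[1L] & at$resno <= range[2L]
    at <- at[sel, , drop = FALSE]
    ins <- ins[sel]
    if (nrow(at) == 0L)
      stop("no residues of chain '", chain, "' in range ",
           range[1L], "-", range[2L])
  }

  atoms <- data.frame(
    elety = at$elety, resid = at$resid, chain = at$chain,
    resno = at$resno, ins = ins,
    x = at$x, y = at$y, z = at$z,
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             element_from_name(at$elety), at$elesy)),
    stringsAsFactors = FALSE
  )
  id <- paste0(sub("\\.(pdb|ent|cif)$", "", basename(path), ignore.case = TRUE),
               "_", chain,
               if (!is.null(range)) paste0("_", range[1L], "-", range[2L]) else "")
  as_domain(atoms, id = id)
}

pdb_atom_line <- function(serial, elety, resid, chain, resno, ins, xyz, element) {
  # PDB v3 fixed columns; atom names of < 4 chars start in column 14
  name <- if (nchar(elety) >= 4L) substr(elety, 1L, 4L)
          else sprintf(" %-3s", elety)
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name, resid, substr(chain, 1L, 1L),
          resno %% 10000L, ifelse(ins == "", " ", ins),
          xyz[1L], xyz[2L], xyz[3L], 1, 0, element)
}

domain_pdb_lines <- function(domain, chain = NULL, serial0 = 0L) {
  at <- domain$atoms
  ch <- if (is.null(chain)) at$chain else rep(chain, nrow(at))
  vapply(seq_len(nrow(at)), function(k) {
    pdb_atom_line(serial0 + k, at$elety[k], at$resid[k], ch[k],
                  at$resno[k], at$ins[k],
                  c(at$x[k], at$y[k], at$z[k]), at$element[k])
  }, character(1L))
}

#' Write a domain to a PDB file
#'
#' Minimal single-chain PDB writer used for fixtures and model output;
#' coordinates are written at standard PDB precision (3 decimals).
#'
#' @param domain A \code{domain}.
#' @param path output file.
#' @param chain optional chain id override.
#' @return Invisibly, \code{path}.
#' @export
write_domain_pdb <- function(domain, path, chain = NULL) {
  lines <- c(domain_pdb_lines(domain, chain = chain), "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

## ---- secondary structure -------------------------------------------------

backbone_matrix <- function(domain, name) {
  at <- domain$atoms
  m <- matrix(NA_real_, domain$nres, 3L)
  sel <- at$elety == name
  rows <- which(sel)[match(seq_len(domain$nres), at$res_index[sel])]
  ok <- !is.na(rows)
  m[ok, ] <- as.matrix(at[rows[ok], c("x", "y", "z")])
  m
}

cross_dist <- function(a, b) {
  # euclidean distances between rows of a (n x 3) and rows of b (m x 3)
  aa <- rowSums(a * a)
  bb <- rowSums(b * b)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Backbone amide hydrogen-bond energies after Kabsch & Sander:
# E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol, with the
# amide H placed 1.01 A from N, anti-parallel to the preceding C=O bond.
# Returns a logical donor x acceptor matrix of bonds with E < -0.5 kcal/mol.
ks_hbond_matrix <- function(domain) {
  n <- domain$nres
  N <- backbone_matrix(domain, "N")
  CA <- domain$ca
  C <- backbone_matrix(domain, "C")
  O <- backbone_matrix(domain, "O")

  # chain continuity between i-1 and i (peptide bond present)
  cont <- rep(FALSE, n)
  if (n > 1L) {
    d <- sqrt(rowSums((N[-1L, , drop = FALSE] - C[-n, , drop = FALSE])^2))
    cont[-1L] <- !is.na(d) & d < 2.5
  }

  H <- matrix(NA_real_, n, 3L)
  prev <- which(cont)
  if (length(prev)) {
    co <- O[prev - 1L, , drop = FALSE] - C[prev - 1L, , drop = FALSE]
    co <- co / sqrt(rowSums(co^2))
    H[prev, ] <- N[prev, , drop = FALSE] - 1.01 * co
  }

  donor_ok <- rowSums(is.na(H)) == 0L & domain$resid != "PRO" &
    rowSums(is.na(N)) == 0L
  acc_ok <- rowSums(is.na(C)) == 0L & rowSums(is.na(O)) == 0L

  hb <- matrix(FALSE, n, n)
  if (!any(donor_ok) || !any(acc_ok)) return(hb)

  di <- which(donor_ok)
  ai <- which(acc_ok)
  r_on <- cross_dist(N[di, , drop = FALSE], O[ai, , drop = FALSE])
  r_ch <- cross_dist(H[di, , drop = FALSE], C[ai, , drop = FALSE])
  r_oh <- cross_dist(H[di, , drop = FALSE], O[ai, , drop = FALSE])
  r_cn <- cross_dist(N[di, , drop = FALSE], C[ai, , drop = FALSE])
  E <- 27.888 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  E[r_on < 0.5 | r_ch < 0.5 | r_oh < 0.5 | r_cn < 0.5] <- -9.9

  # proximity gate (as in DSSP) and self-exclusion
  ca_ok <- rowSums(is.na(CA)) == 0L
  near <- matrix(TRUE, length(di), length(ai))
  if (all(ca_ok[di]) && all(ca_ok[ai]))
    near <- cross_dist(CA[di, , drop = FALSE], CA[ai, , drop = FALSE]) < 9
  bond <- E < -0.5 & near
  hb[di, ai] <- bond
  diag(hb) <- FALSE
  hb
}

ss3_from_geometry <- function(domain) {
  n <- domain$nres
  hb <- ks_hbond_matrix(domain)
  ss <- rep("L", n)

  turn_at <- function(k) {
    # n-turn at i: H-bond from the NH of residue i+k to the CO of residue i
    i <- seq_len(max(n - k, 0L))
    vapply(i, function(ii) hb[ii + k, ii], logical(1L))
  }

  helix <- rep(FALSE, n)
  for (k in c(4L, 3L, 5L)) {
    t_k <- turn_at(k)
    if (length(t_k) < 2L) next
    starts <- which(t_k[-1L] & t_k[-length(t_k)]) + 1L  # turns at i-1 and i
    for (i in starts) helix[i:(i + k - 1L)] <- TRUE
  }

  strand <- rep(FALSE, n)
  hbond <- function(a, b) {
    a >= 1L && a <= n && b >= 1L && b <= n && hb[a, b]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 3L) next
      par <- (hbond(i - 1L, j) && hbond(j, i + 1L)) ||
             (hbond(j - 1L, i) && hbond(i, j + 1L))
      anti <- (hbond(i, j) && hbond(j, i)) ||
              (hbond(i - 1L, j + 1L) && hbond(j - 1L, i + 1L))
      if (par || anti) { strand[i] <- TRUE; strand[j] <- TRUE }
    }
  }

  ss[strand] <- "S"
  ss[helix] <- "H"   # helix takes precedence, as in DSSP
  ss
}

map_ss8_to_ss3 <- function(ss8) {
  out <- rep("L", length(ss8))
  out[ss8 %in% c("H", "G", "I")] <- "H"
  out[ss8 %in% c("E", "B")] <- "S"
  out
}

#' Read a classic-format DSSP output file
#'
#' Parses the fixed-column residue table of a classic (non-mmCIF) DSSP
#' output file into chain, author residue number, insertion code and
#' 8-state secondary-structure code.
#'
#' @param path DSSP output file.
#' @return data.frame with columns chain, resno, ins, ss8.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a classic-format DSSP file: ", path)
  body <- lines[(hdr[1L] + 1L):length(lines)]
  body <- body[nchar(body) >= 17 & substr(body, 14L, 14L) != "!"]
  data.frame(
    chain = trimws(substr(body, 12L, 12L)),
    resno = as.integer(substr(body, 6L, 10L)),
    ins = trimws(substr(body, 11L, 11L)),
    ss8 = substr(body, 17L, 17L),
    stringsAsFactors = FALSE
  )
}

#' Assign 3-state secondary structure
#'
#' Labels each residue H (helix), S (strand) or L (everything else).
#' By default an internal assigner applies the Kabsch-Sander backbone
#' hydrogen-bond energy (cutoff -0.5 kcal/mol) and the standard turn and
#' bridge patterns; helices (4-, 3- and 5-turn) map to H, beta bridges and
#' ladders to S. When an external DSSP output file is supplied it takes
#' precedence, with the usual 8-to-3-state collapse (H,G,I to H; E,B to S;
#' rest to L).
#'
#' @param domain A \code{domain} with backbone N, CA, C, O atoms.
#' @param dssp_file optional path to a classic-format DSSP output covering
#'   the domain's chain; a residue of the domain missing from the file is
#'   an error.
#' @return Character vector of labels in \{H, S, L\}, one per residue.
#' @export
assign_ss3 <- function(domain, dssp_file = NULL) {
  stopifnot(inherits(domain, "domain"))
  if (is.null(dssp_file)) return(ss3_from_geometry(domain))
  tab <- read_dssp(dssp_file)
  key <- paste(tab$chain, tab$resno, tab$ins, sep = "|")
  want <- paste(domain$chain, domain$resno, domain$ins, sep = "|")
  hit <- match(want, key)
  if (anyNA(hit))
    stop("DSSP file does not cover residue(s) ",
         paste(head(which(is.na(hit))), collapse = ", "),
         " of domain ", domain$id, " (chain mismatch?)")
  map_ss8_to_ss3(tab$ss8[hit])
}

## ---- solvent accessibility ----------------------------------------------

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA of the isolated domain: each heavy atom is covered with
#' an approximately uniform (Fibonacci) point lattice on its solvent-
#' extended sphere, points inside any neighbouring extended sphere are
#' buried, and the exposed fraction is converted to area. The per-residue
#' value is the sum over the residue's atoms.
#'
#' @param domain A \code{domain}.
#' @param probe probe radius in Angstrom (water = 1.4).
#' @param n_points lattice points per atom.
#' @return Numeric vector of areas (Angstrom^2), one per residue.
#' @export
compute_sasa <- function(domain, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(domain, "domain"), probe >= 0, n_points >= 12L)
  at <- domain$atoms
  m <- nrow(at)
  radii <- vdw_radii()
  r <- unname(radii[at$element])
  r[is.na(r)] <- radii[["C"]]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rext <- r + probe
  sphere <- fibonacci_sphere(n_points)

  area <- numeric(m)
  for (i in seq_len(m)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < rext[i] + rext & seq_len(m) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * rext[i]^2
      next
    }
    pts <- sphere * rext[i]
    pts <- sweep(pts, 2L, xyz[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (pts[, 1L] - xyz[j, 1L])^2 + (pts[, 2L] - xyz[j, 2L])^2 +
             (pts[, 3L] - xyz[j, 3L])^2
      buried <- buried | dj2 < rext[j]^2
      if (all(buried)) break
    }
    area[i] <- 4 * pi * rext[i]^2 * sum(!buried) / n_points
  }

  res_area <- vapply(seq_len(domain$nres), function(k) {
    rows <- which(at$res_index == k)
    if (!length(rows)) {
      warning("residue ", k, " of ", domain$id, " has no atoms; SASA = 0")
      return(0)
    }
    sum(area[rows])
  }, numeric(1L))
  res_area
}

#' Fill in secondary structure and solvent accessibility
#'
#' Convenience wrapper: returns the domain with \code{ss3} and \code{sasa}
#' computed (if not already present or if \code{force}).
#'
#' @param domain A \code{domain}.
#' @param probe,n_points passed to \code{\link{compute_sasa}}.
#' @param dssp_file passed to \code{\link{assign_ss3}}.
#' @param force recompute even if already present.
#' @return The domain with \code{ss3} and \code{sasa} slots filled.
#' @export
prepare_domain <- function(domain, probe = 1.4, n_points = 960L,
                           dssp_file = NULL, force = FALSE) {
  if (is.null(domain$ss3) || force)
    domain$ss3 <- assign_ss3(domain, dssp_file = dssp_file)
  if (is.null(domain$sasa) || force)
    domain$sasa <- compute_sasa(domain, probe = probe, n_points = n_points)
  domain
}
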