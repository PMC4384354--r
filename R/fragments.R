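## Interface residue detection and 9-residue fragment-pair extraction.

side_chain_rows <- function(domain) {
  # "side chain" = C-beta and beyond; glycine (or any residue without
  # side-chain atoms) falls back to its C-alpha as surrogate
  at <- domain$atoms
  sc <- !(at$elety %in% BACKBONE_ATOMS)
  has_sc <- tapply(sc, at$res_index, any)
  need_ca <- which(!has_sc[as.character(seq_len(domain$nres))] |
                     is.na(has_sc[as.character(seq_len(domain$nres))]))
  rows <- which(sc)
  ca_rows <- which(at$elety == "CA" & at$res_index %in% need_ca)
  sort(c(rows, ca_rows))
}

#' Interface residue pairs between two domains
#'
#' A residue of domain I and a residue of domain J form an interface pair
#' when the minimum distance over their side-chain heavy-atom pairs is
#' below the cutoff (strict). Side-chain atoms are C-beta and beyond; for
#' glycine the C-alpha serves as side-chain surrogate.
#'
#' @param I,J \code{domain} objects.
#' @param cutoff contact distance cutoff in Angstrom.
#' @return data.frame with columns \code{i}, \code{j} (1-based residue
#'   indices in I and J) and \code{min_dist}.
#' @export
interface_residue_pairs <- function(I, J, cutoff = 5.0) {
  stopifnot(inherits(I, "domain"), inherits(J, "domain"))
  empty <- data.frame(i = integer(0), j = integer(0), min_dist = numeric(0))
  if (nrow(I$atoms) == 0L || nrow(J$atoms) == 0L) {
    warning("empty atom set; no interface pairs")
    return(empty)
  }
  ri <- side_chain_rows(I)
  rj <- side_chain_rows(J)
  if (!length(ri) || !length(rj)) {
    warning("no side-chain atoms; no interface pairs")
    return(empty)
  }
  ai <- I$atoms[ri, , drop = FALSE]
  aj <- J$atoms[rj, , drop = FALSE]
  d <- cross_dist(as.matrix(ai[, c("x", "y", "z")]),
                  as.matrix(aj[, c("x", "y", "z")]))
  hit <- which(d < cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  key <- paste(ai$res_index[hit[, 1L]], aj$res_index[hit[, 2L]], sep = "|")
  md <- tapply(d[hit], key, min)
  parts <- strsplit(names(md), "|", fixed = TRUE)
  out <- data.frame(
    i = as.integer(vapply(parts, `[[`, "", 1L)),
    j = as.integer(vapply(parts, `[[`, "", 2L)),
    min_dist = as.numeric(md)
  )
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# A window of `window` residues centered at `center` is usable when it
# stays inside the chain, author numbering is consecutive without
# insertion codes, every position has a C-alpha, and consecutive C-alpha
# distances stay below 4.5 A (chain-break guard).
window_ok <- function(domain, center, window = 9L) {
  half <- (window - 1L) %/% 2L
  lo <- center - half
  hi <- center + half
  if (lo < 1L || hi > domain$nres) return("terminus")
  idx <- lo:hi
  if (any(diff(domain$resno[idx]) != 1L) || any(domain$ins[idx] != ""))
    return("numbering_gap")
  ca <- domain$ca[idx, , drop = FALSE]
  if (anyNA(ca)) return("missing_ca")
  if (any(sqrt(rowSums(diff(ca)^2)) >= 4.5)) return("chain_break")
  "ok"
}

#' Extract interface fragment pairs
#'
#' Converts each interface residue pair into a record of two 9-residue
#' C-alpha windows centered at the contacting residues. A center that
#' contacts two partner residues yields two records (one per contacting
#' center combination). Records whose window would run past a terminus or
#' span a numbering gap, missing C-alpha or chain break are skipped; the
#' skips are reported in the \code{"skipped"} attribute so that records
#' plus skips always account for every input pair.
#'
#' @param I,J \code{domain} objects (with \code{ss3} assigned if motif
#'   labels are wanted).
#' @param pairs data.frame from \code{\link{interface_residue_pairs}}.
#' @param window odd window length (default 9).
#' @return List of \code{fragment_pair} records; attribute
#'   \code{"skipped"} is a data.frame (i, j, reason).
#' @export
extract_fragment_pairs <- function(I, J, pairs, window = 9L) {
  stopifnot(window %% 2L == 1L, window >= 3L)
  half <- (window - 1L) %/% 2L
  out <- list()
  skipped <- data.frame(i = integer(0), j = integer(0),
                        reason = character(0))
  idx <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]
    j <- pairs$j[k]
    oki <- window_ok(I, i, window)
    okj <- window_ok(J, j, window)
    if (oki != "ok" || okj != "ok") {
      skipped <- rbind(skipped, data.frame(
        i = i, j = j,
        reason = paste0(if (oki != "ok") paste0("I:", oki) else "",
                        if (oki != "ok" && okj != "ok") "," else "",
                        if (okj != "ok") paste0("J:", okj) else "")))
      next
    }
    idx <- idx + 1L
    out[[idx]] <- new_fragment_pair(
      coords_a = I$ca[(i - half):(i + half), , drop = FALSE],
      coords_b = J$ca[(j - half):(j + half), , drop = FALSE],
      ss_a = if (!is.null(I$ss3)) I$ss3[i] else NA_character_,
      ss_b = if (!is.null(J$ss3)) J$ss3[j] else NA_character_,
      center_i = i, center_j = j,
      source = paste0(I$id, "|", J$id), id = idx)
  }
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.fragment_pair <- function(x, ...) {
  cat("fragment_pair", if (!is.na(x$id)) paste0("#", x$id) else "",
      "centers", x$center_i, "/", x$center_j,
      "ss", paste0(x$ss_a, "/", x$ss_b),
      "source", x$source, "\n")
  invisible(x)
}

## ---- fragment-pair table I/O ---------------------------------------------

#' Write fragment pairs to a TSV table
#'
#' Provenance columns plus JSON-encoded 9x3 coordinate payloads, one
#' record per row.
#'
#' @param pairs list of \code{fragment_pair}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_fragment_pairs <- function(pairs, path) {
  enc <- function(m) as.character(jsonlite::toJSON(round(unname(m), 6), digits = NA))
  df <- data.frame(
    id = vapply(pairs, function(p) as.integer(p$id), integer(1L)),
    source = vapply(pairs, `[[`, "", "source"),
    center_i = vapply(pairs, function(p) as.integer(p$center_i), integer(1L)),
    center_j = vapply(pairs, function(p) as.integer(p$center_j), integer(1L)),
    ss_a = vapply(pairs, function(p) as.character(p$ss_a), character(1L)),
    ss_b = vapply(pairs, function(p) as.character(p$ss_b), character(1L)),
    coords_a = vapply(pairs, function(p) enc(p$coords_a), character(1L)),
    coords_b = vapply(pairs, function(p) enc(p$coords_b), character(1L)),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fragment pairs from a TSV table
#'
#' @param path file written by \code{\link{write_fragment_pairs}}.
#' @return List of \code{fragment_pair} records.
#' @export
read_fragment_pairs <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  dec <- function(s) {
    m <- jsonlite::fromJSON(s)
    storage.mode(m) <- "double"
    m
  }
  lapply(seq_len(nrow(df)), function(k) {
    new_fragment_pair(
      coords_a = dec(df$coords_a[k]), coords_b = dec(df$coords_b[k]),
      ss_a = if (is.na(df$ss_a[k])) NA_character_ else df$ss_a[k],
      ss_b = if (is.na(df$ss_b[k])) NA_character_ else df$ss_b[k],
      center_i = df$center_i[k], center_j = df$center_j[k],
      source = df$source[k], id = df$id[k])
  })
}
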