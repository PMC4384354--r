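## End-to-end conveniences tying the modules together.

#' Extract all interface fragment pairs of a two-domain complex
#'
#' Runs contact detection and window extraction in one step. Secondary
#' structure and SASA are computed on the monomers if absent so that the
#' records carry center types.
#'
#' @param I,J \code{domain} objects.
#' @param contact_cutoff side-chain contact cutoff in Angstrom.
#' @param window window length.
#' @param prepare compute ss3/SASA on the domains if missing.
#' @return List of \code{fragment_pair} (with a \code{"skipped"}
#'   attribute); see \code{\link{extract_fragment_pairs}}.
#' @export
interface_fragment_pairs <- function(I, J, contact_cutoff = 5.0, window = 9L,
                                     prepare = TRUE) {
  if (prepare) {
    if (is.null(I$ss3)) I$ss3 <- assign_ss3(I)
    if (is.null(J$ss3)) J$ss3 <- assign_ss3(J)
  }
  contacts <- interface_residue_pairs(I, J, cutoff = contact_cutoff)
  extract_fragment_pairs(I, J, contacts, window = window)
}

#' Cluster fragment pairs and build the library
#'
#' @param pairs list of \code{fragment_pair}.
#' @param cluster_cutoff clustering RMSD cutoff in Angstrom.
#' @param min_members abundance threshold (strict ">").
#' @param order_seed visiting-order seed.
#' @param rmsd_matrix optional precomputed RMSD matrix.
#' @return A \code{fragment_pair_library}.
#' @export
cluster_and_build <- function(pairs, cluster_cutoff = 4.0, min_members = 20L,
                              order_seed = 1L, rmsd_matrix = NULL) {
  cl <- greedy_cluster(pairs, cutoff = cluster_cutoff,
                       order_seed = order_seed, rmsd_matrix = rmsd_matrix)
  build_library(cl, pairs, min_members = min_members)
}
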