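## Library-guided enumeration of rigid-body complex models.

#' Default pipeline parameters
#'
#' All tunables of the pipeline with their standard values: 5.0 A
#' side-chain contact cutoff, window of 9 residues, 4.0 A clustering
#' cutoff, abundance threshold of 20 members (strict), 2.0 A window
#' alignment cutoff, 10 A^2 surface threshold (strict), 1.4 A probe,
#' 3.5 A C-alpha clash distance, deduplication off.
#'
#' @param ... name = value overrides of any default.
#' @return Named list of parameters.
#' @export
default_params <- function(...) {
  p <- list(
    contact_cutoff = 5.0,
    window = 9L,
    cluster_cutoff = 4.0,
    min_members = 20L,
    align_cutoff = 2.0,
    surface_threshold = 10.0,
    probe = 1.4,
    sasa_points = 960L,
    clash_cutoff = 3.5,
    clash_mode = "ca",          # or "heavy"
    heavy_clash_cutoff = 2.5,
    dedup = FALSE,
    dedup_cutoff = 1.0,
    order_seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

#' Enumerate sliding-window start pairs
#'
#' All \code{(N_I - window + 1) x (N_J - window + 1)} combinations of
#' window start indices on the two domains, before any filtering (for the
#' default 9-residue window: \code{(N_I - 8) (N_J - 8)} combinations).
#'
#' @param I,J \code{domain} objects with at least \code{window} residues.
#' @param window window length.
#' @return data.frame with columns \code{start_i}, \code{start_j}.
#' @export
enumerate_window_pairs <- function(I, J, window = 9L) {
  if (I$nres < window || J$nres < window)
    stop("both domains must have at least ", window, " residues")
  g <- expand.grid(start_i = seq_len(I$nres - window + 1L),
                   start_j = seq_len(J$nres - window + 1L))
  g[order(g$start_i, g$start_j), , drop = FALSE]
}

#' Surface-residue mask
#'
#' TRUE for residues whose solvent-accessible surface area is strictly
#' greater than the threshold.
#'
#' @param domain \code{domain} with \code{sasa} computed.
#' @param threshold area threshold in Angstrom^2.
#' @return Logical vector, one entry per residue.
#' @export
surface_mask <- function(domain, threshold = 10.0) {
  if (is.null(domain$sasa))
    stop("domain ", domain$id, " has no SASA; run prepare_domain() first")
  domain$sasa > threshold
}

#' Match one window pair against a library entry and build models
#'
#' Aligns the 9 C-alpha atoms of domain I's window onto entry block A and
#' domain J's window onto block B (orientation 1), and the converse
#' pairing (orientation 2). For each orientation where both alignment
#' RMSDs fall below the cutoff, the whole domains are carried by their
#' window transforms into the entry frame and a candidate model is
#' emitted. Surface filtering of the window centers is the caller's
#' responsibility (see \code{\link{assemble}}).
#'
#' @param I,J \code{domain} objects.
#' @param start_i,start_j window start indices.
#' @param entry a library entry (element of
#'   \code{fragment_pair_library$entries}).
#' @param align_cutoff alignment RMSD cutoff in Angstrom.
#' @param window window length.
#' @return List of 0, 1 or 2 \code{complex_model} objects.
#' @export
match_and_build <- function(I, J, start_i, start_j, entry,
                            align_cutoff = 2.0, window = 9L) {
  wi <- I$ca[start_i:(start_i + window - 1L), , drop = FALSE]
  wj <- J$ca[start_j:(start_j + window - 1L), , drop = FALSE]
  if (anyNA(wi) || anyNA(wj)) return(list())
  out <- list()
  blocks <- list(list(a = entry$pair$coords_a, b = entry$pair$coords_b),
                 list(a = entry$pair$coords_b, b = entry$pair$coords_a))
  for (orient in 1:2) {
    fit_i <- kabsch_fit(wi, blocks[[orient]]$a)
    if (fit_i$rmsd >= align_cutoff) next
    fit_j <- kabsch_fit(wj, blocks[[orient]]$b)
    if (fit_j$rmsd >= align_cutoff) next
    out[[length(out) + 1L]] <- structure(list(
      transform_i = fit_i, transform_j = fit_j,
      entry_id = entry$id, window_i = start_i, window_j = start_j,
      orientation = orient,
      rmsd_a = fit_i$rmsd, rmsd_b = fit_j$rmsd,
      clash = NA), class = "complex_model")
  }
  out
}

#' Placed C-alpha coordinates of a model
#'
#' @param model a \code{complex_model}.
#' @param I,J the source \code{domain}s.
#' @return List with \code{ca_i} and \code{ca_j} matrices.
#' @export
model_coords <- function(model, I, J) {
  list(ca_i = apply_transform(model$transform_i, I$ca),
       ca_j = apply_transform(model$transform_j, J$ca))
}

#' Inter-domain clash test
#'
#' A model clashes when any inter-domain C-alpha pair comes closer than
#' the cutoff after placement (mode "ca"), or any heavy-atom pair closer
#' than the heavy cutoff (mode "heavy").
#'
#' @param model a \code{complex_model}.
#' @param I,J the source \code{domain}s.
#' @param ca_cutoff C-alpha clash distance in Angstrom.
#' @param mode "ca" or "heavy".
#' @param heavy_cutoff heavy-atom clash distance in Angstrom.
#' @return TRUE if the model clashes.
#' @export
clash_filter <- function(model, I, J, ca_cutoff = 3.5,
                         mode = c("ca", "heavy"), heavy_cutoff = 2.5) {
  mode <- match.arg(mode)
  if (mode == "ca") {
    mc <- model_coords(model, I, J)
    d <- cross_dist(mc$ca_i[stats::complete.cases(mc$ca_i), , drop = FALSE],
                    mc$ca_j[stats::complete.cases(mc$ca_j), , drop = FALSE])
    return(any(d < ca_cutoff))
  }
  xi <- apply_transform(model$transform_i,
                        as.matrix(I$atoms[, c("x", "y", "z")]))
  xj <- apply_transform(model$transform_j,
                        as.matrix(J$atoms[, c("x", "y", "z")]))
  any(cross_dist(xi, xj) < heavy_cutoff)
}

#' Assemble candidate complex models of two domains
#'
#' Iterates every window pair of the two domains against every library
#' entry in both block orientations, keeping models whose window centers
#' are surface residues, whose two 9-atom alignments both beat the
#' alignment cutoff, and which survive the clash filter. Counts at every
#' filter stage are recorded. Assembly is fully deterministic.
#'
#' @param I,J \code{domain} objects (SASA is computed on the isolated
#'   monomers if absent).
#' @param lib a non-empty \code{fragment_pair_library}.
#' @param params parameter list from \code{\link{default_params}}.
#' @return Object of class \code{ensemble}: list with \code{models} (no
#'   clashing model retained), \code{provenance} and \code{stats}
#'   (per-stage counts and models-per-entry table).
#' @export
assemble <- function(I, J, lib, params = default_params()) {
  stopifnot(inherits(lib, "fragment_pair_library"))
  if (!length(lib$entries)) stop("empty library")
  if (is.null(I$sasa)) I$sasa <- compute_sasa(I, probe = params$probe,
                                              n_points = params$sasa_points)
  if (is.null(J$sasa)) J$sasa <- compute_sasa(J, probe = params$probe,
                                              n_points = params$sasa_points)
  w <- params$window
  half <- (w - 1L) %/% 2L
  surf_i <- surface_mask(I, params$surface_threshold)
  surf_j <- surface_mask(J, params$surface_threshold)
  win <- enumerate_window_pairs(I, J, window = w)
  ok_i <- vapply(seq_len(I$nres - w + 1L),
                 function(s) window_ok(I, s + half, w) == "ok", logical(1L))
  ok_j <- vapply(seq_len(J$nres - w + 1L),
                 function(s) window_ok(J, s + half, w) == "ok", logical(1L))

  stats <- list(n_window_pairs = nrow(win), n_windows_skipped = 0L,
                n_surface_ok = 0L, n_candidates = 0L, n_clashed = 0L,
                n_deduped = 0L, n_kept = 0L)
  models <- list()
  per_entry <- setNames(integer(length(lib$entries)),
                        vapply(lib$entries, function(e) as.character(e$id), ""))

  for (k in seq_len(nrow(win))) {
    si <- win$start_i[k]
    sj <- win$start_j[k]
    if (!ok_i[si] || !ok_j[sj]) {
      stats$n_windows_skipped <- stats$n_windows_skipped + 1L
      next
    }
    if (!surf_i[si + half] || !surf_j[sj + half]) next
    stats$n_surface_ok <- stats$n_surface_ok + 1L
    for (e in lib$entries) {
      cand <- match_and_build(I, J, si, sj, e,
                              align_cutoff = params$align_cutoff, window = w)
      for (m in cand) {
        stats$n_candidates <- stats$n_candidates + 1L
        m$clash <- clash_filter(m, I, J, ca_cutoff = params$clash_cutoff,
                                mode = params$clash_mode,
                                heavy_cutoff = params$heavy_clash_cutoff)
        if (m$clash) {
          stats$n_clashed <- stats$n_clashed + 1L
          next
        }
        models[[length(models) + 1L]] <- m
        per_entry[as.character(e$id)] <- per_entry[as.character(e$id)] + 1L
      }
    }
  }

  if (isTRUE(params$dedup) && length(models) > 1L) {
    kept <- list()
    kept_ca <- list()
    for (m in models) {
      mc <- model_coords(m, I, J)
      ca <- rbind(mc$ca_i, mc$ca_j)
      dup <- FALSE
      for (kc in kept_ca) {
        if (kabsch_fit(ca, kc)$rmsd < params$dedup_cutoff) {
          dup <- TRUE
          break
        }
      }
      if (dup) {
        stats$n_deduped <- stats$n_deduped + 1L
      } else {
        kept[[length(kept) + 1L]] <- m
        kept_ca[[length(kept_ca) + 1L]] <- ca
      }
    }
    models <- kept
  }
  stats$n_kept <- length(models)
  stats$models_per_entry <- per_entry

  structure(list(
    models = models,
    provenance = list(domain_i = I$id, domain_j = J$id,
                      n_entries = length(lib$entries),
                      lib_params = lib$params, params = params),
    stats = stats
  ), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  s <- x$stats
  cat("ensemble:", length(x$models), "models",
      "(", x$provenance$domain_i, "x", x$provenance$domain_j, ",",
      x$provenance$n_entries, "library entries )\n")
  cat(sprintf(
    "window pairs %d | skipped %d | surface-ok %d | aligned %d | clashed %d | deduped %d\n",
    s$n_window_pairs, s$n_windows_skipped, s$n_surface_ok,
    s$n_candidates, s$n_clashed, s$n_deduped))
  invisible(x)
}

#' RMSD between a modeled and a native complex
#'
#' Default mode "complex": C-alpha RMSD over all residues of both domains
#' after a single optimal superposition of the whole model onto the whole
#' native complex. Mode "ligand": the receptor (domain I) C-alphas are
#' superposed and the RMSD is evaluated over the ligand (domain J)
#' C-alphas without refitting.
#'
#' @param model_ca list with \code{ca_i}, \code{ca_j}
#'   (see \code{\link{model_coords}}).
#' @param native_ca list with \code{ca_i}, \code{ca_j} of the native
#'   complex; residue correspondence must be identical.
#' @param mode "complex" or "ligand".
#' @return RMSD in Angstrom.
#' @export
complex_rmsd <- function(model_ca, native_ca, mode = c("complex", "ligand")) {
  mode <- match.arg(mode)
  if (nrow(model_ca$ca_i) != nrow(native_ca$ca_i) ||
      nrow(model_ca$ca_j) != nrow(native_ca$ca_j))
    stop("model and native residue counts differ")
  if (mode == "complex") {
    return(kabsch_fit(rbind(model_ca$ca_i, model_ca$ca_j),
                      rbind(native_ca$ca_i, native_ca$ca_j))$rmsd)
  }
  fit <- kabsch_fit(model_ca$ca_i, native_ca$ca_i)
  moved <- apply_transform(fit, model_ca$ca_j)
  sqrt(mean(rowSums((moved - native_ca$ca_j)^2)))
}

#' Evaluate an ensemble against the native complex
#'
#' @param ens an \code{ensemble}.
#' @param I,J the source \code{domain}s.
#' @param native_ca native C-alpha list (\code{ca_i}, \code{ca_j}).
#' @param mode passed to \code{\link{complex_rmsd}}.
#' @return List with \code{lowest} (NA for an empty ensemble),
#'   \code{n_models} and \code{rmsds} (per-model values).
#' @export
evaluate_ensemble <- function(ens, I, J, native_ca,
                              mode = c("complex", "ligand")) {
  stopifnot(inherits(ens, "ensemble"))
  mode <- match.arg(mode)
  if (!length(ens$models))
    return(list(lowest = NA_real_, n_models = 0L, rmsds = numeric(0)))
  rmsds <- vapply(ens$models, function(m)
    complex_rmsd(model_coords(m, I, J), native_ca, mode = mode), numeric(1L))
  list(lowest = min(rmsds), n_models = length(rmsds), rmsds = rmsds)
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per retained model, domains written as chains A
#' and B, with REMARK lines carrying the library entry, window starts,
#' orientation and alignment RMSDs.
#'
#' @param ens an \code{ensemble}.
#' @param I,J the source \code{domain}s.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_ensemble_pdb <- function(ens, I, J, path) {
  stopifnot(inherits(ens, "ensemble"))
  lines <- c(
    sprintf("REMARK   3 ENSEMBLE OF %d MODELS", length(ens$models)),
    sprintf("REMARK   3 DOMAINS %s %s", I$id, J$id))
  for (k in seq_along(ens$models)) {
    m <- ens$models[[k]]
    ti <- transform_domain(I, m$transform_i)
    tj <- transform_domain(J, m$transform_j)
    lines <- c(lines,
      sprintf("MODEL %8d", k),
      sprintf("REMARK 100 ENTRY %s WINDOWS %d %d ORIENT %d RMSD_A %.4f RMSD_B %.4f",
              m$entry_id, m$window_i, m$window_j, m$orientation,
              m$rmsd_a, m$rmsd_b),
      domain_pdb_lines(ti, chain = "A"),
      "TER",
      domain_pdb_lines(tj, chain = "B", serial0 = nrow(ti$atoms)),
      "TER",
      "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
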