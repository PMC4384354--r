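## Fragment-pair RMSD, greedy nearest-neighbor clustering, and the
## abundance-filtered fragment pair library.

#' Order-insensitive RMSD between two fragment pairs
#'
#' Joint 18-point Kabsch superposition of the concatenated C-alpha blocks
#' of \code{p} onto those of \code{q}, computed for both block pairings
#' (a-to-a/b-to-b and a-to-b/b-to-a); the smaller RMSD is returned, so
#' relabeling the two sides of either record cannot change the value.
#' Fragment N-to-C direction is never reversed.
#'
#' @param p,q \code{fragment_pair} records.
#' @return RMSD in Angstrom.
#' @export
pair_rmsd <- function(p, q) {
  P <- rbind(p$coords_a, p$coords_b)
  min(kabsch_fit(P, rbind(q$coords_a, q$coords_b))$rmsd,
      kabsch_fit(P, rbind(q$coords_b, q$coords_a))$rmsd)
}

#' All-against-all fragment-pair RMSD matrix
#'
#' @param pairs list of \code{fragment_pair}.
#' @return Symmetric N x N matrix of \code{\link{pair_rmsd}} values.
#' @export
pair_rmsd_matrix <- function(pairs) {
  n <- length(pairs)
  m <- matrix(0, n, n)
  if (n < 2L) return(m)
  # precentered stacked blocks (a||b and b||a share the joint centroid)
  cen <- lapply(pairs, function(p) {
    na <- nrow(p$coords_a)
    P <- rbind(p$coords_a, p$coords_b)
    P <- sweep(P, 2L, colMeans(P))
    swp <- c((na + 1L):nrow(P), seq_len(na))
    list(ab = P, ba = P[swp, , drop = FALSE], e = sum(P * P))
  })
  npt <- nrow(cen[[1L]]$ab)
  for (i in seq_len(n - 1L)) {
    Pi <- cen[[i]]$ab
    for (j in (i + 1L):n) {
      e0 <- cen[[i]]$e + cen[[j]]$e
      best <- Inf
      for (Q in list(cen[[j]]$ab, cen[[j]]$ba)) {
        H <- crossprod(Pi, Q)
        d <- svd(H, nu = 0L, nv = 0L)$d
        s <- if (det(H) < 0) d[1L] + d[2L] - d[3L] else sum(d)
        best <- min(best, (e0 - 2 * s) / npt)
      }
      # the closed form is eps-limited near zero; refine tiny values with
      # the residual-based fit
      m[i, j] <- m[j, i] <- if (best < 1e-8)
        pair_rmsd(pairs[[i]], pairs[[j]]) else sqrt(best)
    }
  }
  m
}

#' Greedy nearest-neighbor clustering of fragment pairs
#'
#' Entries are visited in a seed-shuffled order. Each entry joins the
#' cluster of its nearest previously-visited entry if that RMSD is below
#' the cutoff, and founds a new cluster otherwise. Deterministic given the
#' seed; the clusters partition the input.
#'
#' @param pairs list of \code{fragment_pair}.
#' @param cutoff clustering RMSD cutoff in Angstrom.
#' @param order_seed integer seed for the visiting order.
#' @param rmsd_matrix optional precomputed \code{\link{pair_rmsd_matrix}}
#'   (recommended when clustering the same set repeatedly).
#' @param representatives compute cluster representatives (see
#'   \code{\link{select_representative}}).
#' @return List of clusters, each a list with \code{member_ids} (indices
#'   into \code{pairs}), \code{representative_id} and \code{size}.
#' @export
greedy_cluster <- function(pairs, cutoff = 4.0, order_seed = 1L,
                           rmsd_matrix = NULL, representatives = TRUE) {
  n <- length(pairs)
  stopifnot(n >= 1L)
  ord <- with_seed(order_seed, sample.int(n))
  lookup <- function(i, js) {
    if (!is.null(rmsd_matrix)) rmsd_matrix[i, js]
    else vapply(js, function(j) pair_rmsd(pairs[[i]], pairs[[j]]), numeric(1L))
  }
  assign <- integer(n)
  visited <- integer(0)
  n_clusters <- 0L
  for (k in seq_len(n)) {
    i <- ord[k]
    if (k == 1L) {
      n_clusters <- 1L
      assign[i] <- 1L
    } else {
      d <- lookup(i, visited)
      b <- which.min(d)
      if (d[b] < cutoff) {
        assign[i] <- assign[visited[b]]
      } else {
        n_clusters <- n_clusters + 1L
        assign[i] <- n_clusters
      }
    }
    visited <- c(visited, i)
  }
  clusters <- lapply(seq_len(n_clusters), function(c) {
    members <- which(assign == c)
    list(member_ids = members, representative_id = NA_integer_,
         size = length(members))
  })
  if (representatives) {
    clusters <- lapply(clusters, function(cl) {
      cl$representative_id <- select_representative(cl, pairs, cutoff,
                                                    rmsd_matrix = rmsd_matrix)
      cl
    })
  }
  attr(clusters, "assignment") <- assign
  attr(clusters, "order_seed") <- order_seed
  attr(clusters, "cutoff") <- cutoff
  clusters
}

#' Select the representative member of a cluster
#'
#' The representative maximizes the number of co-members within the
#' cutoff RMSD; ties are broken by lowest mean RMSD to co-members, then by
#' lowest member id.
#'
#' @param cluster one cluster from \code{\link{greedy_cluster}}.
#' @param pairs the full list of \code{fragment_pair}.
#' @param cutoff neighbor RMSD cutoff in Angstrom.
#' @param rmsd_matrix optional precomputed RMSD matrix.
#' @return The representative member id (index into \code{pairs}).
#' @export
select_representative <- function(cluster, pairs, cutoff = 4.0,
                                  rmsd_matrix = NULL) {
  ids <- cluster$member_ids
  stopifnot(length(ids) >= 1L)
  if (length(ids) == 1L) return(ids)
  sub <- if (!is.null(rmsd_matrix)) rmsd_matrix[ids, ids, drop = FALSE]
         else pair_rmsd_matrix(pairs[ids])
  nb <- rowSums(sub < cutoff) - 1L   # exclude self
  mean_r <- rowSums(sub) / (length(ids) - 1L)
  best <- order(-nb, mean_r, ids)[1L]
  ids[best]
}

#' Build the fragment pair library from clusters
#'
#' Keeps clusters whose size is strictly greater than \code{min_members}
#' and stores each one's representative coordinates, member count and
#' secondary-structure motif label, sorted by descending member count.
#'
#' @param clusters output of \code{\link{greedy_cluster}}.
#' @param pairs the clustered \code{fragment_pair} list.
#' @param min_members abundance threshold (strict ">").
#' @return Object of class \code{fragment_pair_library}: list with
#'   \code{entries} (each: id, pair, member_count, motif, source) and
#'   \code{params}.
#' @export
build_library <- function(clusters, pairs, min_members = 20L) {
  keep <- Filter(function(cl) cl$size > min_members, clusters)
  if (!length(keep))
    warning("no cluster exceeds ", min_members, " members; empty library")
  keep <- keep[order(-vapply(keep, `[[`, 0L, "size"))]
  entries <- lapply(seq_along(keep), function(k) {
    cl <- keep[[k]]
    rep_id <- if (is.na(cl$representative_id))
      select_representative(cl, pairs, attr(clusters, "cutoff") %||% 4.0)
    else cl$representative_id
    p <- pairs[[rep_id]]
    motif <- if (!is.na(p$ss_a) && !is.na(p$ss_b)) motif_label(p$ss_a, p$ss_b)
             else NA_character_
    list(id = k, pair = p, member_count = cl$size, motif = motif,
         source = p$source)
  })
  structure(list(
    entries = entries,
    params = list(cutoff_A = attr(clusters, "cutoff") %||% NA_real_,
                  min_members = min_members,
                  seed = attr(clusters, "order_seed") %||% NA_integer_)
  ), class = "fragment_pair_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fragment_pair_library <- function(x, ...) {
  cat("fragment_pair_library:", length(x$entries), "entries",
      "(cutoff", x$params$cutoff_A, "A, min members >",
      x$params$min_members, ")\n")
  if (length(x$entries)) {
    counts <- vapply(x$entries, `[[`, 0L, "member_count")
    motifs <- vapply(x$entries, function(e) e$motif %||% NA_character_,
                     NA_character_)
    cat("member counts:", paste(head(counts, 10L), collapse = " "),
        if (length(counts) > 10L) "..." else "", "\n")
    cat("motifs:", paste(names(table(motifs)), table(motifs),
                         sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Library coverage of a query set
#'
#' Fraction of query fragment pairs whose closest library entry lies
#' within the RMSD cutoff, plus the per-query minimum RMSD (the histogram
#' input for coverage plots).
#'
#' @param queries list of \code{fragment_pair} (must be non-empty).
#' @param lib a \code{fragment_pair_library}.
#' @param cutoff RMSD cutoff in Angstrom.
#' @return List with \code{fraction} and \code{min_rmsd} (numeric vector,
#'   one value per query).
#' @export
coverage <- function(queries, lib, cutoff = 4.0) {
  stopifnot(inherits(lib, "fragment_pair_library"))
  if (!length(queries)) stop("empty query list")
  if (!length(lib$entries)) stop("empty library")
  min_rmsd <- vapply(queries, function(q) {
    min(vapply(lib$entries, function(e) pair_rmsd(q, e$pair), numeric(1L)))
  }, numeric(1L))
  list(fraction = mean(min_rmsd < cutoff), min_rmsd = min_rmsd)
}

#' Cluster-count scan over RMSD cutoffs
#'
#' Runs an independent greedy clustering per cutoff with the same visiting
#' order and reports the number of clusters obtained.
#'
#' @param pairs list of \code{fragment_pair}.
#' @param cutoffs numeric vector of at least two cutoffs (Angstrom).
#' @param order_seed integer seed (shared across cutoffs).
#' @param rmsd_matrix optional precomputed RMSD matrix.
#' @return data.frame with columns \code{cutoff} and \code{n_clusters}.
#' @export
cutoff_scan <- function(pairs, cutoffs, order_seed = 1L, rmsd_matrix = NULL) {
  stopifnot(length(cutoffs) >= 2L)
  if (is.null(rmsd_matrix)) rmsd_matrix <- pair_rmsd_matrix(pairs)
  n_clusters <- vapply(cutoffs, function(co) {
    length(greedy_cluster(pairs, cutoff = co, order_seed = order_seed,
                          rmsd_matrix = rmsd_matrix,
                          representatives = FALSE))
  }, integer(1L))
  data.frame(cutoff = cutoffs, n_clusters = n_clusters)
}

#' Clustering stability across shuffled visiting orders
#'
#' Repeats the greedy clustering under different visiting orders and
#' reports, per run, the total cluster count, the number of abundant
#' clusters (size > \code{min_members}) and the rank-size profile.
#'
#' @param pairs list of \code{fragment_pair}.
#' @param cutoff clustering cutoff in Angstrom.
#' @param n_runs number of runs (>= 2).
#' @param seeds integer vector of visiting-order seeds, at least
#'   \code{n_runs} long.
#' @param min_members abundance threshold (strict ">").
#' @param rmsd_matrix optional precomputed RMSD matrix.
#' @return List with \code{summary} (data.frame: seed, n_clusters,
#'   n_abundant) and \code{size_profiles} (list of decreasing size
#'   vectors).
#' @export
stability_runs <- function(pairs, cutoff = 4.0, n_runs = 5L, seeds = 0:4,
                           min_members = 20L, rmsd_matrix = NULL) {
  stopifnot(n_runs >= 2L)
  if (length(seeds) < n_runs)
    stop("need at least ", n_runs, " seeds, got ", length(seeds))
  seeds <- seeds[seq_len(n_runs)]
  if (is.null(rmsd_matrix)) rmsd_matrix <- pair_rmsd_matrix(pairs)
  profiles <- list()
  summary <- data.frame(seed = integer(0), n_clusters = integer(0),
                        n_abundant = integer(0))
  for (k in seq_len(n_runs)) {
    cl <- greedy_cluster(pairs, cutoff = cutoff, order_seed = seeds[k],
                         rmsd_matrix = rmsd_matrix, representatives = FALSE)
    sizes <- sort(vapply(cl, `[[`, 0L, "size"), decreasing = TRUE)
    profiles[[k]] <- sizes
    summary <- rbind(summary, data.frame(
      seed = seeds[k], n_clusters = length(cl),
      n_abundant = sum(sizes > min_members)))
  }
  list(summary = summary, size_profiles = profiles)
}

## ---- library JSON I/O ----------------------------------------------------

#' Write a fragment pair library to JSON
#'
#' Schema: \code{\{params: \{cutoff_A, min_members, seed\},
#' entries: [\{id, motif, member_count, coords_a, coords_b, source\}]\}}.
#' Output is deterministic for identical input.
#'
#' @param lib a \code{fragment_pair_library}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "fragment_pair_library"))
  obj <- list(
    params = lib$params,
    entries = lapply(lib$entries, function(e) list(
      id = e$id,
      motif = if (is.na(e$motif %||% NA_character_)) NULL else e$motif,
      member_count = e$member_count,
      coords_a = round(unname(e$pair$coords_a), 6),
      coords_b = round(unname(e$pair$coords_b), 6),
      source = e$source
    ))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a fragment pair library from JSON
#'
#' @param path file written by \code{\link{write_library}}.
#' @return A \code{fragment_pair_library}.
#' @export
read_library <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (is.null(obj$params) || is.null(obj$entries))
    stop("not a fragment pair library file: ", path)
  entries <- lapply(obj$entries, function(e) {
    ca <- matrix(unlist(e$coords_a), ncol = 3L, byrow = is.list(e$coords_a))
    cb <- matrix(unlist(e$coords_b), ncol = 3L, byrow = is.list(e$coords_b))
    motif <- e$motif %||% NA_character_
    ss <- if (!is.na(motif)) strsplit(motif, "")[[1L]] else c(NA, NA)
    list(id = e$id,
         pair = new_fragment_pair(ca, cb, ss[1L], ss[2L],
                                  source = e$source %||% "library",
                                  id = e$id),
         member_count = e$member_count,
         motif = motif,
         source = e$source %||% "library")
  })
  structure(list(entries = entries, params = obj$params),
            class = "fragment_pair_library")
}
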