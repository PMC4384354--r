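#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimize the root mean
#' square deviation between two point sets with positional correspondence
#' (the i-th row of \code{mobile} maps to the i-th row of \code{target}).
#' Reflections are never returned: the sign of the smallest singular value
#' of the cross-covariance matrix is corrected so that \code{det(R) = +1},
#' preserving protein chirality even for degenerate (collinear or
#' coincident) point sets.
#'
#' @param mobile n x 3 numeric matrix of coordinates to be moved (Angstrom).
#' @param target n x 3 numeric matrix of reference coordinates.
#' @return An object of class \code{rigid_transform}: a list with
#'   \code{rotation} (3 x 3 orthonormal matrix, det +1), \code{translation}
#'   (length-3 vector) and \code{rmsd} (Angstrom). The transform maps a
#'   coordinate row \code{x} to \code{R \%*\% x + t}.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch_fit(a, a)
#' fit$rmsd  # 0
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  n <- nrow(mobile)
  if (!is.numeric(mobile) || !is.numeric(target) ||
      ncol(mobile) != 3L || ncol(target) != 3L)
    stop("coordinates must be numeric n x 3 matrices")
  if (nrow(target) != n)
    stop("mobile and target must have the same number of points")
  if (n < 3L)
    stop("at least 3 points are required for a rigid fit")
  if (!all(is.finite(mobile)) || !all(is.finite(target)))
    stop("coordinates must be finite")

  mc <- colMeans(mobile)
  tc <- colMeans(target)
  M <- sweep(mobile, 2L, mc)
  Q <- sweep(target, 2L, tc)
  H <- crossprod(M, Q)             # Sum_i m_i q_i^T
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1               # rank-deficient: keep the proper branch
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # rmsd from explicit residuals: the singular-value closed form cancels
  # catastrophically for near-identical point sets
  res <- M %*% t(R) - Q
  tr <- as.numeric(tc - R %*% mc)
  structure(
    list(rotation = R, translation = tr, rmsd = sqrt(sum(res * res) / n)),
    class = "rigid_transform"
  )
}

#' Apply a rigid-body transform to coordinates
#'
#' @param transform A \code{rigid_transform} (see \code{\link{kabsch_fit}}).
#' @param coords n x 3 coordinate matrix.
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, coords) {
  stopifnot(inherits(transform, "rigid_transform"))
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' Invert a rigid-body transform
#'
#' @param transform A \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  structure(
    list(rotation = Rt,
         translation = as.numeric(-Rt %*% transform$translation),
         rmsd = NA_real_),
    class = "rigid_transform"
  )
}

#' Identity rigid transform
#' @return A \code{rigid_transform} that leaves coordinates unchanged.
#' @export
identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0), rmsd = 0),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform (y = R x + t)\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 4), collapse = " "), "\n")
  if (!is.na(x$rmsd)) cat("fit rmsd:", format(x$rmsd), "Angstrom\n")
  invisible(x)
}

# RMSD of an optimal superposition without keeping the transform.
kabsch_rmsd <- function(a, b) kabsch_fit(a, b)$rmsd
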