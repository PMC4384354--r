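# Independent superposition oracle: Horn's quaternion method. The optimal
# proper rotation corresponds to the largest eigenvalue of the 4x4
# Davenport matrix built from the cross-covariance; entirely separate
# from the SVD-based implementation under test.
quat_rmsd_oracle <- function(a, b) {
  A <- sweep(a, 2, colMeans(a))
  B <- sweep(b, 2, colMeans(b))
  S <- crossprod(A, B)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(A * A) + sum(B * B) - 2 * lam) / nrow(a))
}

oracle_pair_rmsd <- function(p, q) {
  P <- rbind(p$coords_a, p$coords_b)
  min(quat_rmsd_oracle(P, rbind(q$coords_a, q$coords_b)),
      quat_rmsd_oracle(P, rbind(q$coords_b, q$coords_a)))
}

random_cloud <- function(n, scale = 10) matrix(rnorm(3 * n, 0, scale), n, 3)

random_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# minimal single-residue domain with its side-chain-eligible atom (CB, or
# CA for glycine) at a chosen position and the backbone tucked `dir`
# units behind it along x; for contact boundary fixtures
point_residue_domain <- function(sc_at, id = "pt", chain = "A", resno = 1L,
                                 gly = FALSE, dir = -1) {
  off <- function(dx, dy, dz) sc_at + c(dir * dx, dy, dz)
  pos <- list(N = off(2.4, 0.8, 0),
              CA = if (gly) sc_at else off(1.5, 0, 0),
              C = off(2.6, -0.6, 1.0),
              O = off(3.4, 0.2, 1.4))
  if (!gly) pos$CB <- sc_at
  atoms <- data.frame(
    elety = names(pos),
    resid = if (gly) "GLY" else "ALA",
    chain = chain, resno = resno, ins = "",
    x = vapply(pos, `[`, 0, 1), y = vapply(pos, `[`, 0, 2),
    z = vapply(pos, `[`, 0, 3),
    element = substr(names(pos), 1, 1),
    stringsAsFactors = FALSE
  )
  as_domain(atoms, id = id)
}
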