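# Independent oracles and fixture builders used across the suite.
# Each oracle is a separate code path from the implementation it checks.

# --- random sequence / record generation -------------------------------

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_record <- function(id, n) {
  protein_record(id, paste(sample(AA20, n, replace = TRUE), collapse = ""))
}

# --- pI oracle: composition-based charge on a fine pH grid -------------
# Recomputes the Henderson-Hasselbalch sum from residue counts (not via
# net_charge) and scans a 1e-3 pH grid for the sign change.

grid_pi_oracle <- function(sequence, pkas) {
  chars <- strsplit(sequence, "")[[1]]
  cnt <- function(a) sum(chars == a)
  nt <- if (chars[1] %in% names(pkas$nterm)) pkas$nterm[[chars[1]]] else
    pkas$nterm[["default"]]
  pH <- seq(0, 14, by = 1e-3)
  pos <- 1 / (1 + 10^(pH - nt))
  for (a in c("K", "R", "H")) pos <- pos + cnt(a) / (1 + 10^(pH - pkas$side[[a]]))
  neg <- 1 / (1 + 10^(pkas$cterm - pH))
  for (a in c("D", "E", "C", "Y")) neg <- neg + cnt(a) / (1 + 10^(pkas$side[[a]] - pH))
  q <- pos - neg
  i <- which(q <= 0)[1]  # charge strictly decreasing; first non-positive point
  if (is.na(i)) return(14)
  if (i == 1) return(0)
  # linear interpolation across the sign change
  pH[i - 1] + (pH[i] - pH[i - 1]) * q[i - 1] / (q[i - 1] - q[i])
}

# --- Kabsch oracle: Horn's quaternion eigenvector method ---------------

quaternion_superpose_oracle <- function(reference, mobile) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(P, Q)  # sum over points of p_i q_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  lam <- e$values[1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  n <- nrow(P)
  rmsd <- sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * lam) / n))
  list(rotation = R, rmsd = rmsd)
}

# --- rigid motions ------------------------------------------------------

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(X, R, t) X %*% t(R) + matrix(t, nrow(X), 3, byrow = TRUE)

# --- tiny handcrafted PDB text -----------------------------------------

pdb_line <- function(serial, name, resn, chain, resi, x, y, z,
                     occ = 1, b = 0, altloc = " ", elem = NULL) {
  if (is.null(elem)) elem <- substr(name, 1, 1)
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), altloc,
          resn, chain, resi, x, y, z, occ, b, elem)
}

# path of a bundled extdata file
extdata_path <- function(...) system.file("extdata", ..., package = "qtykit")
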