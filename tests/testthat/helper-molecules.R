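# Small molecules built in code for unit tests.

no_bonds <- data.frame(i = integer(), j = integer(), order = integer())

mk_water <- function() {
  list(mol = molecule(c("O", "H", "H"),
                      data.frame(i = c(1, 1), j = c(2, 3), order = 1L)),
       conf = conformer(rbind(c(0, 0, 0),
                              c(0.757, 0.586, 0),
                              c(-0.757, 0.586, 0))))
}

mk_methane <- function() {
  t <- 1.09 / sqrt(3)
  list(mol = molecule(c("C", "H", "H", "H", "H"),
                      data.frame(i = rep(1, 4), j = 2:5, order = 1L)),
       conf = conformer(rbind(c(0, 0, 0), c(t, t, t), c(t, -t, -t),
                              c(-t, t, -t), c(-t, -t, t))))
}

mk_methanol <- function() {
  t <- 1.09 / sqrt(3)
  list(mol = molecule(c("C", "O", "H", "H", "H", "H"),
                      data.frame(i = c(1, 2, 1, 1, 1),
                                 j = c(2, 3, 4, 5, 6), order = 1L)),
       conf = conformer(rbind(c(0, 0, 0), c(1.43, 0, 0), c(1.78, 0.9, 0),
                              c(-t, t, t), c(-t, -t, -t), c(t, -t, t))))
}

mk_methanethiol <- function() {
  molecule(c("C", "S", "H", "H", "H", "H"),
           data.frame(i = c(1, 2, 1, 1, 1), j = c(2, 3, 4, 5, 6),
                      order = 1L))
}

mk_tetramethylammonium <- function() {
  el <- c("N", rep("C", 4), rep("H", 12))
  b <- data.frame(i = rep(1, 4), j = 2:5, order = 1L)
  h <- 6L
  for (c_idx in 2:5) {
    b <- rbind(b, data.frame(i = c_idx, j = h:(h + 2), order = 1L))
    h <- h + 3L
  }
  molecule(el, b, charges = c(1L, rep(0L, 16)))
}

mk_benzene <- function() {
  ang <- (0:5) * pi / 3
  cc <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  hh <- cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)
  b <- data.frame(i = 1:6, j = c(2:6, 1), order = rep(c(2L, 1L), 3))
  b <- rbind(b, data.frame(i = 1:6, j = 7:12, order = 1L))
  list(mol = molecule(rep(c("C", "H"), each = 6), b),
       conf = conformer(rbind(cc, hh)))
}

mk_naphthalene <- function() {
  # Kekule: doubles 1-2, 3-4, 4a(5)-8a(10), 6-7, 8-9
  b <- data.frame(
    i =     c(1, 2, 3, 4, 5, 5, 6, 7, 8, 9, 10),
    j =     c(2, 3, 4, 5, 10, 6, 7, 8, 9, 10, 1),
    order = c(2, 1, 2, 1, 2, 1, 2, 1, 2, 1, 1))
  el <- c(rep("C", 10), rep("H", 8))
  hb <- data.frame(i = c(1, 2, 3, 4, 6, 7, 8, 9), j = 11:18, order = 1L)
  molecule(el, rbind(b, hb))
}

mk_thiazole <- function() {
  # S1-C2=N3-C4=C5-S1 with H on C2, C4, C5
  b <- data.frame(i = c(1, 2, 3, 4, 5, 2, 4, 5),
                  j = c(2, 3, 4, 5, 1, 6, 7, 8),
                  order = c(1, 2, 1, 2, 1, 1, 1, 1))
  molecule(c("S", "C", "N", "C", "C", "H", "H", "H"), b)
}

# Donor-acceptor probe: HO-CH2-CH2-CH=O with the donor H placed at an
# exact H...acceptor distance d (Angstrom) and D-H...A angle (degrees).
# Donor heavy atom (O1) and acceptor (O5) are 3 bonds apart.
mk_probe <- function(d, angle_deg) {
  el <- c("O", "C", "C", "C", "O", "H")
  b <- data.frame(i = c(1, 2, 3, 4, 1),
                  j = c(2, 3, 4, 5, 6),
                  order = c(1, 1, 1, 2, 1))
  mol <- molecule(el, b)
  o1 <- c(0, 0, 0)
  h <- c(0.96, 0, 0)
  th <- angle_deg * pi / 180
  a <- h + d * c(-cos(th), sin(th), 0)
  # chain carbons parked away from the contact; irrelevant to detection
  coords <- rbind(o1, c(0, -3, 0), c(1.5, -3.5, 0), c(3, -3, 0), a, h)
  list(mol = mol, conf = conformer(coords),
       roles = assign_hbond_roles(mol))
}

# Horn's closed-form quaternion solution for optimal superposition RMSD:
# an independent oracle for the Kabsch-based implementation.
horn_rmsd <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  M <- t(A) %*% B
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ga <- sum(A^2); gb <- sum(B^2)
  sqrt(max(0, (ga + gb - 2 * lam) / nrow(A)))
}

rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}
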