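# Small geometry helpers shared across modules. Coordinates are plain
# numeric matrices (n x 3) in Angstrom throughout.

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

# All pairwise Euclidean distances between rows of a (n x 3) and b (m x 3).
cross_dist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) abort("cannot normalise a zero vector")
  v / n
}

# Angle at vertex `b` spanned by points a-b-c, in degrees.
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Angle between two direction vectors, in degrees.
vector_angle_deg <- function(u, v) {
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Rotation matrix about a unit axis by `theta` degrees (Rodrigues).
rotation_about_axis <- function(axis, theta) {
  axis <- unit_vec(axis)
  th <- theta * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

residue_key <- function(chain, resno, insert) {
  paste(chain, resno, ifelse(is.na(insert) | insert == "", ".", insert),
        sep = "|")
}

`%||%` <- rlang::`%||%`
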