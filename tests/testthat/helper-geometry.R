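## shared geometric helpers for the test suite

## proper rotation matrix from an axis-angle pair (Rodrigues)
rotation_matrix <- function(angle, axis) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

## apply a rigid transform to an N x 3 coordinate matrix
apply_rigid <- function(xyz, rot, shift) {
  xyz %*% t(rot) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
}

## apply a rigid transform to a clc_structure
transform_structure <- function(st, rot, shift) {
  xyz <- apply_rigid(coords(st), rot, shift)
  st$atoms$x <- xyz[, 1]
  st$atoms$y <- xyz[, 2]
  st$atoms$z <- xyz[, 3]
  st
}
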