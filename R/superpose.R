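## Rigid-body superposition (Kabsch) and dimer assembly from monomer copies.

#' Optimal rigid superposition of paired point sets
#'
#' Closed-form least-squares fit of `mobile` onto `target` (Kabsch): returns
#' the proper rotation (determinant +1) and translation minimising the sum of
#' squared deviations, and the RMSD after the fit.
#'
#' @param mobile,target N x 3 coordinate matrices with matched rows, N >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`.
#'   The fitted coordinates are `mobile %*% t(rotation) + translation` (row
#'   vectors).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (ncol(mobile) != 3 || ncol(target) != 3)
    stop("coordinate matrices must have 3 columns")
  if (nrow(mobile) != nrow(target))
    stop("point counts differ: ", nrow(mobile), " vs ", nrow(target))
  if (nrow(mobile) < 3) stop("at least 3 paired points required")
  cm <- colMeans(mobile); ct <- colMeans(target)
  mc <- sweep(mobile, 2, cm); tc <- sweep(target, 2, ct)
  sv_m <- svd(mc)$d
  if (sv_m[2] < 1e-9 * max(sv_m[1], 1))
    stop("points are collinear; rotation is not determined")
  h <- crossprod(mc, tc)                       # 3 x 3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # applied as x' = R x (col vec)
  trans <- as.numeric(ct - rot %*% cm)
  fitted <- mobile %*% t(rot) + matrix(trans, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

## apply a kabsch fit to a structure's coordinates
.transform_structure <- function(structure, fit) {
  xyz <- coords(structure) %*% t(fit$rotation) +
    matrix(fit$translation, nrow(structure$atoms), 3, byrow = TRUE)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

## CA coordinates of mapped residues; errors if a CA is absent
.mapped_ca <- function(structure, resnos, label) {
  a <- structure$atoms
  out <- matrix(NA_real_, length(resnos), 3)
  for (i in seq_along(resnos)) {
    sel <- a$resno == resnos[i] & a$elety == "CA"
    if (!any(sel))
      stop("no CA atom for mapped residue ", resnos[i], " in ", label)
    out[i, ] <- as.numeric(a[which(sel)[1], c("x", "y", "z")])
  }
  out
}

#' Assemble a two-chain dimer from a monomer and a dimeric template
#'
#' Two copies of the monomer are rigidly superposed onto the two chains of a
#' template dimer via CA atoms of mapped residues, mirroring the standard way
#' a dimeric channel model is built from a monomer model and a dimeric
#' crystal structure. Chains are relabelled "A" and "B".
#'
#' @param monomer single-chain [clc_structure()].
#' @param template_chain_a,template_chain_b single-chain structures giving
#'   the target placement of each subunit.
#' @param mapping data.frame with columns `mono` and `tmpl`: residue numbers
#'   paired between monomer and template (>= 3 rows).
#' @return two-chain [clc_structure()].
#' @export
assemble_dimer <- function(monomer, template_chain_a, template_chain_b, mapping) {
  if (!all(c("mono", "tmpl") %in% names(mapping)))
    stop("mapping needs columns 'mono' and 'tmpl'")
  if (nrow(mapping) < 3) stop("mapping must pair at least 3 residues")
  mono_ca <- .mapped_ca(monomer, mapping$mono, "monomer")
  place <- function(tmpl, chain_label) {
    tmpl_ca <- .mapped_ca(tmpl, mapping$tmpl, paste("template chain", chain_label))
    fit <- kabsch_superpose(mono_ca, tmpl_ca)
    copy <- .transform_structure(monomer, fit)
    copy$atoms$chain <- chain_label
    copy
  }
  a <- place(template_chain_a, "A")
  b <- place(template_chain_b, "B")
  atoms <- rbind(a$atoms, b$atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  clc_structure(atoms, title = paste0(monomer$title, " dimer"))
}
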