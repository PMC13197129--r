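#' Kabsch rigid-body superposition
#'
#' Least-squares superposition of two ordered point sets by the closed-form
#' SVD solution, with the determinant sign correction so that only proper
#' rotations are allowed. Nucleic acids are chiral: permitting reflections
#' would silently merge mirror-image conformers.
#'
#' @param x,y Numeric `n x 3` matrices with the same number of rows
#'   (`n >= 3`); row i of `x` corresponds to row i of `y`.
#' @return A list of class `kabsch_fit` with elements `rmsd` (Angstrom),
#'   `rotation` (3x3 proper orthogonal matrix), and `translation`
#'   (length-3 vector) such that `x %*% t(rotation) + translation`
#'   superposes `x` onto `y`.
#' @examples
#' x <- matrix(rnorm(27), ncol = 3)
#' kabsch(x, x)$rmsd  # 0
#' @export
kabsch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y)))
    stop("point sets differ in size: ", nrow(x), " vs ", nrow(y))
  if (ncol(x) != 3L) stop("points must be 3-dimensional")
  if (nrow(x) < 3L) stop("need at least 3 points for superposition")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  h <- crossprod(xc, yc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  # explicit residuals: the singular-value shortcut loses ~7 digits to
  # cancellation near zero, which matters for exact-copy detection
  msd <- mean(rowSums((xc %*% t(rot) - yc)^2))
  structure(
    list(rmsd = sqrt(msd), rotation = rot,
         translation = as.numeric(cy - rot %*% cx)),
    class = "kabsch_fit"
  )
}

#' Kabsch RMSD between two coordinate sets
#'
#' @inheritParams kabsch
#' @return Minimum RMSD (Angstrom) over proper rotations and translations.
#' @export
kabsch_rmsd <- function(x, y) kabsch(x, y)$rmsd

# internal fast path used by distance matrices: precentered coords
.rmsd_centered <- function(xc, yc, e0, n) {
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((xc %*% t(rot) - yc)^2)))
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention; the angle is reported in degrees in the interval
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 vectors.
#' @return Angle in degrees.
#' @examples
#' dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))  # 0 (cis)
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) < 1e-12 || sum(b2^2) < 1e-12 || sum(b3^2) < 1e-12)
    stop("degenerate dihedral: consecutive points coincide")
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("degenerate dihedral: three consecutive points are collinear")
  xcomp <- sum(n1 * n2)
  ycomp <- sum(.cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(ycomp, xcomp) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.atom_xyz <- function(nts, i, name) {
  atoms <- nts$atoms[[i]]
  if (!name %in% rownames(atoms)) return(NULL)
  atoms[name, ]
}

#' Pseudo-torsion angles eta and theta
#'
#' The RNA backbone can be summarised by two pseudo-torsions per residue,
#' defined over the alternating C4' and P atoms of consecutive nucleotides:
#' eta = C4'(i-1), P(i), C4'(i), P(i+1) and theta = P(i), C4'(i), P(i+1),
#' C4'(i+1). Both neighbours of position i must lie within the fragment, so
#' only interior positions (2..k-1) are defined; for a tri-nucleotide that
#' is the central nucleotide.
#'
#' @param fragments Fragment tibble (all fragments must have `k >= 3`).
#' @param position Optional integer: evaluate only this position of each
#'   fragment (must be interior). Default evaluates all interior positions.
#' @return A tibble with columns `fragment` (row index into `fragments`),
#'   `position`, `eta`, `theta` (degrees in (-180, 180]).
#' @export
pseudo_torsions <- function(fragments, position = NULL) {
  ks <- fragments$k
  if (any(ks < 3L)) stop("pseudo-torsions need fragments of length >= 3")
  res <- purrr::imap(fragments$nucleotides, function(nts, fi) {
    k <- nrow(nts)
    pos <- if (is.null(position)) seq(2L, k - 1L) else as.integer(position)
    if (any(pos < 2L | pos > k - 1L))
      stop("pseudo-torsions are undefined at terminal positions (fragment ",
           fi, ", position ", paste(pos[pos < 2L | pos > k - 1L], collapse = ","),
           ")")
    purrr::map(pos, function(i) {
      need <- list(c4p = .atom_xyz(nts, i - 1L, "C4'"),
                   p0  = .atom_xyz(nts, i, "P"),
                   c40 = .atom_xyz(nts, i, "C4'"),
                   p1  = .atom_xyz(nts, i + 1L, "P"),
                   c41 = .atom_xyz(nts, i + 1L, "C4'"))
      if (any(vapply(need, is.null, logical(1))))
        stop("missing C4'/P atom for pseudo-torsions in fragment ", fi)
      tibble::tibble(
        fragment = fi, position = i,
        eta = dihedral_angle(need$c4p, need$p0, need$c40, need$p1),
        theta = dihedral_angle(need$p0, need$c40, need$p1, need$c41))
    })
  })
  dplyr::bind_rows(purrr::flatten(res))
}

#' Backbone torsion angles alpha..zeta (and chi)
#'
#' Standard nucleic-acid mainchain torsions per nucleotide:
#' alpha O3'(i-1)-P-O5'-C5', beta P-O5'-C5'-C4', gamma O5'-C5'-C4'-C3',
#' delta C5'-C4'-C3'-O3', epsilon C4'-C3'-O3'-P(i+1),
#' zeta C3'-O3'-P(i+1)-O5'(i+1), plus the glycosidic chi
#' (O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines).
#' Angles whose defining atoms fall outside the fragment (e.g. alpha at the
#' 5' terminus) are `NA`, not an error.
#'
#' @param fragments Fragment tibble.
#' @return A tibble with columns `fragment`, `position`, `alpha`..`zeta`,
#'   `chi` in degrees.
#' @export
backbone_torsions <- function(fragments) {
  res <- purrr::imap(fragments$nucleotides, function(nts, fi) {
    k <- nrow(nts)
    purrr::map(seq_len(k), function(i) {
      g <- function(j, name) if (j < 1L || j > k) NULL else .atom_xyz(nts, j, name)
      dh <- function(a, b, c, d)
        if (is.null(a) || is.null(b) || is.null(c) || is.null(d)) NA_real_
        else dihedral_angle(a, b, c, d)
      bc <- nts$base_class[[i]]
      chi_atoms <- if (identical(bc, "purine")) c("N9", "C4") else c("N1", "C2")
      tibble::tibble(
        fragment = fi, position = i,
        alpha = dh(g(i - 1L, "O3'"), g(i, "P"), g(i, "O5'"), g(i, "C5'")),
        beta  = dh(g(i, "P"), g(i, "O5'"), g(i, "C5'"), g(i, "C4'")),
        gamma = dh(g(i, "O5'"), g(i, "C5'"), g(i, "C4'"), g(i, "C3'")),
        delta = dh(g(i, "C5'"), g(i, "C4'"), g(i, "C3'"), g(i, "O3'")),
        epsilon = dh(g(i, "C4'"), g(i, "C3'"), g(i, "O3'"), g(i + 1L, "P")),
        zeta  = dh(g(i, "C3'"), g(i, "O3'"), g(i + 1L, "P"), g(i + 1L, "O5'")),
        chi   = dh(g(i, "O4'"), g(i, "C1'"), g(i, chi_atoms[1]), g(i, chi_atoms[2])))
    })
  })
  dplyr::bind_rows(purrr::flatten(res))
}

#' Angle distance between pseudo-torsion pairs
#'
#' The root-mean-square of the two wrapped angle differences:
#' `sqrt((d_eta^2 + d_theta^2) / 2)` where each difference is wrapped onto
#' \[0, 180\] degrees, i.e. `d = min(|a - b|, 360 - |a - b|)`. Vectorised.
#'
#' @param eta1,theta1,eta2,theta2 Angles in degrees.
#' @return Angle distance in degrees, in \[0, 180\].
#' @examples
#' angle_distance(10, 0, 0, 0)      # sqrt(100/2) ~ 7.07
#' angle_distance(179, 0, -179, 0)  # wraps: d_eta = 2
#' @export
angle_distance <- function(eta1, theta1, eta2, theta2) {
  wrap <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  sqrt((wrap(eta1, eta2)^2 + wrap(theta1, theta2)^2) / 2)
}
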