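# World-space affine transforms (mm), parameterized as T . Rz . Ry . Rx .
# Shear . Scale about the world origin (bregma).  Rotations are Euler angles
# in degrees; scales are dimensionless; shears (xy, xz, yz) default to 0.

rot3 <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Construct a world-space affine transform from decomposed parameters
#'
#' The matrix is `T %*% R %*% Sh %*% S` with rotation order `Rz Ry Rx`,
#' applied about the world origin (bregma).  Use [affine_params()] to
#' decompose a matrix back.
#'
#' @param tx,ty,tz translations in mm.
#' @param rx,ry,rz rotations in degrees about the x, y, z world axes.
#' @param sx,sy,sz scale factors.
#' @param kxy,kxz,kyz shear terms (default 0).
#' @return object of class `affine_transform` holding the 4x4 `matrix` and
#'   the parameter vector `params`.
#' @examples
#' t <- make_affine(tx = 1, rz = 10)
#' affine_params(t)
#' @export
make_affine <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0,
                        sx = 1, sy = 1, sz = 1,
                        kxy = 0, kxz = 0, kyz = 0) {
  Sh <- diag(3); Sh[1, 2] <- kxy; Sh[1, 3] <- kxz; Sh[2, 3] <- kyz
  M3 <- rot3(rx, ry, rz) %*% Sh %*% diag(c(sx, sy, sz))
  M <- rbind(cbind(M3, c(tx, ty, tz)), c(0, 0, 0, 1))
  p <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz,
         sx = sx, sy = sy, sz = sz, kxy = kxy, kxz = kxz, kyz = kyz)
  structure(list(matrix = M, params = p), class = "affine_transform")
}

#' Wrap a 4x4 matrix as an affine transform
#'
#' @param M invertible 4x4 homogeneous matrix (world mm).
#' @return an `affine_transform`; parameters are recovered by decomposition.
#' @export
affine_transform <- function(M) {
  M <- as.matrix(M)
  stopifnot(all(dim(M) == c(4, 4)))
  if (abs(det(M[1:3, 1:3])) < 1e-12) stop("singular affine matrix")
  structure(list(matrix = M, params = decompose_matrix(M)),
            class = "affine_transform")
}

#' Identity transform
#' @return an `affine_transform`.
#' @export
identity_affine <- function() make_affine()

#' Pure translation transform
#' @param tx,ty,tz translations in mm (or a length-3 vector as `tx`).
#' @export
translation_affine <- function(tx, ty = NULL, tz = NULL) {
  if (is.null(ty)) { ty <- tx[2]; tz <- tx[3]; tx <- tx[1] }
  make_affine(tx = tx, ty = ty, tz = tz)
}

# Decompose M = T . R . Sh . S via a Gram-Schmidt (QR-like) factorization of
# the 3x3 block into rotation x upper-triangular.  Assumes positive scales
# and det > 0; Euler angles follow the Rz Ry Rx order.
decompose_matrix <- function(M) {
  A <- M[1:3, 1:3]
  qrd <- qr(A)
  Q <- qr.Q(qrd); U <- qr.R(qrd)
  sgn <- sign(diag(U)); sgn[sgn == 0] <- 1
  Q <- Q %*% diag(sgn); U <- diag(sgn) %*% U
  if (det(Q) < 0) stop("affine has negative determinant; not T.R.Sh.S")
  s <- diag(U)
  # U = Sh %*% diag(s) with Sh unit upper triangular: Sh[i,j] = U[i,j]/s[j]
  kxy <- U[1, 2] / s[2]; kxz <- U[1, 3] / s[3]; kyz <- U[2, 3] / s[3]
  ry <- asin(max(-1, min(1, -Q[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(Q[3, 2], Q[3, 3])
    rz <- atan2(Q[2, 1], Q[1, 1])
  } else {               # gimbal lock: fold rx into rz
    rx <- atan2(-Q[2, 3], Q[2, 2])
    rz <- 0
  }
  c(tx = M[1, 4], ty = M[2, 4], tz = M[3, 4],
    rx = rx * 180 / pi, ry = ry * 180 / pi, rz = rz * 180 / pi,
    sx = s[1], sy = s[2], sz = s[3], kxy = kxy, kxz = kxz, kyz = kyz)
}

#' Decomposed parameters of an affine transform
#'
#' @param t an `affine_transform`.
#' @return named numeric vector: translations (mm), Euler rotations
#'   (degrees, order Rz Ry Rx), scales, shears.
#' @export
affine_params <- function(t) t$params

#' Compose two affine transforms
#'
#' `compose_affine(a, b)` applies `b` first, then `a` (matrix product
#' `a$matrix %*% b$matrix`).
#' @param a,b `affine_transform` objects.
#' @export
compose_affine <- function(a, b) affine_transform(a$matrix %*% b$matrix)

#' Invert an affine transform
#' @param a an `affine_transform`.
#' @export
invert_affine <- function(a) affine_transform(solve(a$matrix))

#' @export
print.affine_transform <- function(x, ...) {
  p <- signif(x$params, 4)
  cat("affine_transform\n  t (mm):   ", p[1], p[2], p[3],
      "\n  r (deg):  ", p[4], p[5], p[6],
      "\n  scale:    ", p[7], p[8], p[9],
      "\n  shear:    ", p[10], p[11], p[12], "\n")
  invisible(x)
}

#' Serialize / deserialize a transform
#'
#' The 4x4 matrix is written row-major as plain text; a JSON sidecar
#' (`<path>.json`) records the decomposed parameters.
#' @param t an `affine_transform`.
#' @param path output text file.
#' @export
write_transform <- function(t, path) {
  utils::write.table(t$matrix, path, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(as.list(t$params), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  M <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(M) <- NULL
  affine_transform(M)
}
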