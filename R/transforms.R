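#' Rigid transform
#'
#' Proper rotation plus translation, mapping coordinates as `x' = R x + t`.
#'
#' @param rotation 3x3 proper orthogonal matrix (det +1)
#' @param translation length-3 numeric, Angstrom
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be proper orthogonal (det +1)")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation matrix is not orthogonal")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_axis_angle(x$rotation)
  cat(sprintf("rigid_transform: %.3f deg about (%.3f, %.3f, %.3f), t = (%.3f, %.3f, %.3f) A\n",
              aa$angle_deg, aa$axis[1], aa$axis[2], aa$axis[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform
#' @param t rigid_transform
#' @param x n x 3 coordinate matrix or a structure_model
#' @return transformed coordinates / model
#' @export
apply_transform <- function(t, x) {
  if (inherits(x, "structure_model")) {
    coords(x) <- apply_transform(t, coords(x))
    return(x)
  }
  sweep(x %*% t(t$rotation), 2, t$translation, "+")
}

#' Invert a rigid transform
#' @param t rigid_transform
#' @return rigid_transform undoing `t`
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.numeric(t(t$rotation) %*% t$translation))
}

#' Compose rigid transforms (apply `b` first, then `a`)
#' @param a,b rigid_transform
#' @return rigid_transform equal to a o b
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 direction (normalised internally)
#' @param angle_deg rotation angle, degrees (right-handed about the axis)
#' @return 3x3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  n <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Axis and angle of a rotation matrix
#'
#' Angle is in (0, 180]; the axis sign is chosen so the angle is positive
#' (right-handed). For the identity the angle is 0 and axis is (0,0,1).
#'
#' @param R 3x3 proper rotation matrix
#' @return list(axis = unit 3-vector, angle_deg)
#' @export
rotation_axis_angle <- function(R) {
  q <- rotation_to_quaternion(R)
  v <- q[2:4]
  s <- sqrt(sum(v^2))
  angle <- 2 * atan2(s, q[1]) * 180 / pi
  if (s < 1e-12) return(list(axis = c(0, 0, 1), angle_deg = 0))
  list(axis = v / s, angle_deg = angle)
}

# Unit quaternion (w, x, y, z) with w >= 0 from a rotation matrix.
rotation_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired atoms of a mobile and a target model. Pairing is by atom identity
#' `(chain, resno, name)` when `pairing = "auto"`, by row order when
#' `pairing = "order"`, or explicit via a two-column index matrix.
#'
#' @param mobile,target structure_model or n x 3 coordinate matrices
#' @param pairing "auto", "order", or a 2-column matrix of (mobile, target)
#'   atom row indices
#' @return list(transform = rigid_transform, rmsd = Angstrom)
#' @export
superpose <- function(mobile, target, pairing = "auto") {
  getxyz <- function(m) if (inherits(m, "structure_model")) coords(m) else as.matrix(m)
  X <- getxyz(mobile)
  Y <- getxyz(target)
  if (is.matrix(pairing)) {
    X <- X[pairing[, 1], , drop = FALSE]
    Y <- Y[pairing[, 2], , drop = FALSE]
  } else if (identical(pairing, "auto") && inherits(mobile, "structure_model") &&
             inherits(target, "structure_model")) {
    key <- function(m) paste(m$atoms$chain, m$atoms$resno, m$atoms$name)
    km <- key(mobile); kt <- key(target)
    common <- intersect(km, kt)
    if (length(common) < 3) {
      stop("pairing mismatch: ", length(setdiff(km, kt)),
           " mobile atoms unmatched (first: ",
           paste(utils::head(setdiff(km, kt), 3), collapse = "; "), ")")
    }
    X <- X[match(common, km), , drop = FALSE]
    Y <- Y[match(common, kt), , drop = FALSE]
  } else {
    if (nrow(X) != nrow(Y)) {
      stop("pairing mismatch: ", nrow(X), " mobile vs ", nrow(Y), " target atoms")
    }
  }
  if (nrow(X) < 3) stop("need at least 3 paired atoms")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Xc, Yc))          # X^T Y
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-30)) {
    stop("degenerate (collinear) atom pairing; superposition is ill-posed")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cy - as.numeric(R %*% cx)
  tr <- rigid_transform(R, t)
  diff <- apply_transform(tr, X) - Y
  list(transform = tr, rmsd = sqrt(mean(rowSums(diff^2))))
}
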