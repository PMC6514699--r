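#' Projective transformation parameters
#'
#' The eight-parameter planar homography used for distortion calibration,
#' written as the 3x3 matrix `[[A,B,C],[D,E,F],[G,H,1]]` with the scale
#' normalized so the bottom-right entry is 1.  A point `(x, y)` on the
#' distorted image maps to `u = (Ax+By+C)/(Gx+Hy+1)`,
#' `v = (Dx+Ey+F)/(Gx+Hy+1)` on the virtual (rectified) plate.
#'
#' @param A,B,C,D,E,F,G,H Real matrix entries.
#' @return A `homography` object.
#' @export
homography <- function(A, B, C, D, E, F, G, H) {
  p <- c(A = A, B = B, C = C, D = D, E = E, F = F, G = G, H = H)
  if (any(!is.finite(p))) stop_invalid_param("homography entries must be finite")
  M <- matrix(c(A, B, C, D, E, F, G, H, 1), 3, 3, byrow = TRUE)
  if (abs(det(M)) <= 1e-12)
    stop_singular_system("homography matrix is singular (|det| <= 1e-12)")
  structure(list(A = A, B = B, C = C, D = D, E = E, F = F, G = G, H = H,
                 lambda = 1), class = "homography")
}

#' @export
print.homography <- function(x, ...) {
  cat("<homography> u = (Ax+By+C)/(Gx+Hy+1), v = (Dx+Ey+F)/(Gx+Hy+1)\n")
  print(round(homography_matrix(x), 6))
  invisible(x)
}

#' Homography as a 3x3 matrix
#' @param H A [homography].
#' @return Numeric 3x3 matrix with bottom-right entry 1.
#' @export
homography_matrix <- function(H) {
  matrix(c(H$A, H$B, H$C, H$D, H$E, H$F, H$G, H$H, 1), 3, 3, byrow = TRUE)
}

#' Build a homography from any 3x3 matrix
#'
#' The matrix is normalized by its bottom-right entry (the scale convention
#' `lambda = 1`).
#'
#' @param M Invertible numeric 3x3 matrix with non-zero `M[3,3]`.
#' @return A [homography].
#' @export
homography_from_matrix <- function(M) {
  if (!is.matrix(M) || any(dim(M) != c(3, 3)))
    stop_invalid_param("expected a 3x3 matrix")
  if (abs(M[3, 3]) <= 1e-12)
    stop_singular_system("matrix cannot be normalized: bottom-right entry is ~0")
  M <- M / M[3, 3]
  homography(M[1, 1], M[1, 2], M[1, 3], M[2, 1], M[2, 2], M[2, 3],
             M[3, 1], M[3, 2])
}

#' Apply a homography to points
#'
#' @param H A [homography] or a 3x3 matrix.
#' @param pts N x 2 matrix of (x, y) points.
#' @return N x 2 matrix of transformed points.
#' @export
apply_homography <- function(H, pts) {
  M <- if (inherits(H, "homography")) homography_matrix(H) else H
  pts <- matrix(as.numeric(pts), ncol = 2)
  q <- M %*% rbind(t(pts), 1)
  if (any(abs(q[3, ]) < 1e-12))
    stop_singular_system("point maps to the line at infinity")
  cbind(q[1, ] / q[3, ], q[2, ] / q[3, ])
}

#' Invert a homography
#' @param H A [homography].
#' @return The inverse [homography].
#' @export
invert_homography <- function(H) {
  homography_from_matrix(solve(homography_matrix(H)))
}

#' Estimate the homography from four point correspondences
#'
#' Solves the exact 8 x 8 linear system pairing each detected plate corner
#' `(x, y)` with its virtual calibration point `(u, v)`:
#' `u = (Ax+By+C)/(Gx+Hy+1)` and `v = (Dx+Ey+F)/(Gx+Hy+1)`.
#'
#' @param quad A [plate_quad] of detected corners (image pixels).
#' @param virtual A [virtual_plate]; its four corner points are the targets.
#' @return A [homography] mapping image coordinates to rectified coordinates.
#' @export
estimate_homography <- function(quad, virtual) {
  src <- quad$corners
  dst <- virtual$corners
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i,     ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i]     <- v
  }
  h <- tryCatch(solve(A, b), error = function(e)
    stop_singular_system(paste("degenerate corner configuration:",
                               conditionMessage(e))))
  homography(h[1], h[2], h[3], h[4], h[5], h[6], h[7], h[8])
}

#' Serialize a homography to JSON
#' @param H A [homography].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
homography_to_json <- function(H, path = NULL) {
  s <- jsonlite::toJSON(unclass(H), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Read a homography back from JSON
#' @param x JSON string or path to a JSON file written by [homography_to_json].
#' @return A [homography].
#' @export
homography_from_json <- function(x) {
  p <- jsonlite::fromJSON(x)
  homography(p$A, p$B, p$C, p$D, p$E, p$F, p$G, p$H)
}
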