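## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

DEG2RAD <- pi / 180

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Assign values to non-overlapping tolerance bins around a set of centers.
#'
#' Returns an integer vector: index into `centers` for values falling within
#' `tol` of a center, NA otherwise.  Bins must not overlap (centers at least
#' 2*tol apart); a value exactly on an edge shared by two touching bins goes
#' to the upper bin.
#' @noRd
bin_assign <- function(x, centers, tol) {
  ord <- order(centers)
  cs <- centers[ord]
  if (length(cs) > 1L && any(diff(cs) < 2 * tol - 1e-12)) {
    ## overlapping bins: fall back to a per-bin scan (first match wins)
    out <- rep(NA_integer_, length(x))
    for (j in seq_along(cs)) {
      hit <- is.na(out) & abs(x - cs[j]) <= tol
      out[hit] <- ord[j]
    }
    return(out)
  }
  edges <- as.vector(rbind(cs - tol, cs + tol))
  idx <- findInterval(x, edges, left.open = FALSE)
  inbin <- idx >= 1L & idx %% 2L == 1L
  out <- rep(NA_integer_, length(x))
  out[inbin] <- ord[(idx[inbin] + 1L) %/% 2L]
  out
}

#' Normalize a 3-vector to unit length.
#' @noRd
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stopf("cannot normalize a zero vector")
  v / n
}

#' Two unit vectors completing `w` to an orthonormal frame.
#' @noRd
frame3 <- function(w) {
  w <- unit3(w)
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(pracma_cross(ref, w))
  v <- pracma_cross(w, u)
  list(u = u, v = v, w = w)
}

## tiny cross product (avoids importing pracma just for this)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
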