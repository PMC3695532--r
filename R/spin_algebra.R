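# Angular-momentum algebra on the coupled 13C (spin 1/2) x 14N (spin 1) space.
#
# Conventions used throughout the package:
#   * Zeeman basis ordered m = +I ... -I for both spins.
#   * Coupled basis |mS, mN>, 13C outer, 14N inner: index = 3*(iS-1) + iN.
#   * 14N coherence order of the element |i><j| is p = mN(i) - mN(j); an
#     order-p component transforms as exp(-i p phi) under a 14N z-rotation
#     by phi (p = +1 for raising, I+ -like, terms).

.halfint <- function(x, target) isTRUE(all.equal(x, target))

.ladder_ops <- function(I) {
  # generic spin-I matrices in the m = +I..-I basis (internal; any I)
  m <- seq(I, -I)
  d <- length(m)
  Ip <- matrix(0, d, d)
  # I+ |m> = sqrt(I(I+1) - m(m+1)) |m+1>; with descending basis this fills
  # the first superdiagonal
  if (d > 1) {
    mm <- m[-1]
    Ip[cbind(seq_len(d - 1), seq(2, d))] <- sqrt(I * (I + 1) - mm * (mm + 1))
  }
  Im <- t(Ip)
  list(
    Ix = (Ip + Im) / 2,
    Iy = (Ip - Im) / (2i),
    Iz = diag(m, d, d),
    Ip = Ip,
    Im = Im,
    E  = diag(d)
  )
}

#' Angular-momentum operator matrices
#'
#' Cartesian and ladder operators for a single spin in the Zeeman basis
#' ordered `m = +I, ..., -I`.
#'
#' @param quantum_number Spin quantum number; `1/2` (13C) or `1` (14N).
#' @return A named list with complex matrices `Ix`, `Iy`, `Iz`, `Ip`, `Im`
#'   and the identity `E`.
#' @examples
#' spin_matrices(1)$Iz       # diag(1, 0, -1)
#' spin_matrices(1/2)$Ix
#' @export
spin_matrices <- function(quantum_number) {
  if (!(.halfint(quantum_number, 0.5) || .halfint(quantum_number, 1))) {
    abort("`quantum_number` must be 1/2 or 1.")
  }
  ops <- .ladder_ops(quantum_number)
  lapply(ops, function(x) x + 0i)
}

#' Irreducible spherical tensor operators
#'
#' Single-spin irreducible spherical tensor operator `T_{l,m}`, normalised to
#' unit Frobenius norm, `Tr(T^H T) = 1`, so that coherence-amplitude ratios
#' are basis independent. The family satisfies
#' `T_{l,m}^H = (-1)^m T_{l,-m}`.
#'
#' @inheritParams spin_matrices
#' @param l Tensor rank, `0 <= l <= 2 * quantum_number`.
#' @param m Component, `|m| <= l`.
#' @return A complex matrix of dimension `2 * quantum_number + 1`.
#' @examples
#' spherical_tensor(1, 1, 0)    # proportional to Iz
#' spherical_tensor(1, 2, 2)    # pure double-quantum |+1><-1|
#' @export
spherical_tensor <- function(quantum_number, l, m) {
  if (!(.halfint(quantum_number, 0.5) || .halfint(quantum_number, 1))) {
    abort("`quantum_number` must be 1/2 or 1.")
  }
  if (l < 0 || l > 2 * quantum_number || l != round(l)) {
    abort(sprintf("rank `l` must be an integer in 0..%d.", 2 * quantum_number))
  }
  if (abs(m) > l || m != round(m)) {
    abort("component `m` must satisfy |m| <= l.")
  }
  ops <- .ladder_ops(quantum_number)
  d <- nrow(ops$Iz)
  if (l == 0) return(diag(d) / sqrt(d) + 0i)
  # top component from (I+)^l, unit Frobenius norm; standard phase (-1)^l
  Tm <- (-1)^l * .matpow(ops$Ip + 0i, l)
  Tm <- Tm / sqrt(sum(Mod(Tm)^2))
  mm <- l
  while (mm > m) {
    # [I-, T_{l,m}] = sqrt(l(l+1) - m(m-1)) T_{l,m-1}: norm preserving
    Tm <- (ops$Im %*% Tm - Tm %*% ops$Im) / sqrt(l * (l + 1) - mm * (mm - 1))
    mm <- mm - 1
  }
  Tm
}

#' Embed a single-spin operator in the coupled two-spin space
#'
#' Kronecker extension of a 13C (2x2) or 14N (3x3) operator to the
#' 6-dimensional coupled space `|mS, mN>` (13C outer, 14N inner).
#'
#' @param op Complex single-spin matrix (2x2 for `"C13"`, 3x3 for `"N14"`).
#' @param spin `"C13"` or `"N14"`.
#' @return A 6x6 complex matrix.
#' @examples
#' Sz6 <- embed_operator(spin_matrices(1/2)$Iz, "C13")
#' Iz6 <- embed_operator(spin_matrices(1)$Iz, "N14")
#' max(Mod(Sz6 %*% Iz6 - Iz6 %*% Sz6))   # embedded operators commute
#' @export
embed_operator <- function(op, spin = c("C13", "N14")) {
  spin <- match.arg(spin)
  need <- if (spin == "C13") 2L else 3L
  if (!is.matrix(op) || nrow(op) != need || ncol(op) != need) {
    abort(sprintf("`op` must be a %dx%d matrix for spin %s.", need, need, spin))
  }
  if (spin == "C13") kronecker(op, diag(3)) else kronecker(diag(2), op)
}

# 6x6 matrix of 14N coherence orders p(i, j) = mN(i) - mN(j)
.pmask <- function() {
  mN <- rep(c(1, 0, -1), times = 2)
  outer(mN, mN, "-")
}

# frequently used embedded operators
.op6 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- spin_matrices(1 / 2)
      n <- spin_matrices(1)
      cache <<- list(
        Sx = embed_operator(s$Ix, "C13"),
        Sy = embed_operator(s$Iy, "C13"),
        Sz = embed_operator(s$Iz, "C13"),
        Iz = embed_operator(n$Iz, "N14"),
        # ideal pi pulse on 13C about +x: exp(-i pi Sx) = -2i Sx
        Upi = kronecker(matrix(c(0, -1i, -1i, 0), 2, 2), diag(3)),
        p = .pmask()
      )
    }
    cache
  }
})

#' Decompose a density operator into 14N coherence orders
#'
#' Splits a 6x6 operator on the coupled space into its 14N coherence-order
#' components `p = -2 ... +2`. The components sum to the input exactly, and
#' the order-p component picks up a phase `exp(-i p phi)` under a 14N
#' z-rotation by `phi`.
#'
#' @param rho 6x6 complex matrix.
#' @return Named list of 6x6 matrices, names `"-2"` to `"2"`.
#' @examples
#' rho <- embed_operator(spin_matrices(1)$Ip, "N14")
#' names(Filter(function(m) any(Mod(m) > 0), coherence_decompose(rho)))
#' @export
coherence_decompose <- function(rho) {
  stopifnot(is.matrix(rho), all(dim(rho) == 6))
  p <- .pmask()
  setNames(
    lapply(-2:2, function(k) rho * (p == k)),
    as.character(-2:2)
  )
}

#' 14N coherence orders present in an operator
#'
#' @param mat 6x6 complex matrix.
#' @param tol Magnitude below which an element counts as zero.
#' @return Integer vector of orders in `-2:2` with nonzero components.
#' @export
coherence_orders <- function(mat, tol = 1e-12) {
  comp <- coherence_decompose(mat)
  which_p <- vapply(comp, function(m) any(Mod(m) > tol), logical(1))
  as.integer(names(comp)[which_p])
}

# matrix power by repeated multiplication (small integer n)
.matpow <- function(M, n) {
  stopifnot(n >= 0, n == round(n))
  out <- diag(nrow(M)) + 0i
  P <- M
  n <- as.integer(n)
  while (n > 0) {
    if (n %% 2L == 1L) out <- P %*% out
    P <- P %*% P
    n <- n %/% 2L
  }
  out
}
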