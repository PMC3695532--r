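test_that("angular-momentum matrices satisfy the Zeeman-basis definitions", {
  for (I in c(1 / 2, 1)) {
    ops <- spin_matrices(I)
    expect_equal(diag(Re(ops$Iz)), seq(I, -I))
    # commutation [Ix, Iy] = i Iz
    comm <- ops$Ix %*% ops$Iy - ops$Iy %*% ops$Ix
    expect_lt(frob(comm - 1i * ops$Iz), 1e-12)
    # ladder consistency
    expect_lt(frob(ops$Ip - (ops$Ix + 1i * ops$Iy)), 1e-12)
  }
  expect_error(spin_matrices(3 / 2), "1/2 or 1")
})

test_that("spherical tensors are orthonormal with the documented phase", {
  for (I in c(1 / 2, 1)) {
    lm <- do.call(rbind, lapply(0:(2 * I), function(l)
      cbind(l, seq(-l, l))))
    Ts <- lapply(seq_len(nrow(lm)), function(k)
      spherical_tensor(I, lm[k, 1], lm[k, 2]))
    for (a in seq_along(Ts)) for (b in seq_along(Ts)) {
      ip <- sum(diag(Conj(t(Ts[[a]])) %*% Ts[[b]]))
      expect_equal(Mod(ip), as.numeric(a == b), tolerance = 1e-10)
    }
    # T_{l,m}^H = (-1)^m T_{l,-m}
    for (k in seq_len(nrow(lm))) {
      l <- lm[k, 1]; m <- lm[k, 2]
      expect_lt(frob(Conj(t(Ts[[k]])) -
                       (-1)^m * spherical_tensor(I, l, -m)), 1e-10)
    }
  }
  # rank-1 zero component is proportional to Iz
  T10 <- spherical_tensor(1, 1, 0)
  Iz <- spin_matrices(1)$Iz
  expect_lt(frob(T10 - Iz / frob(Iz)), 1e-12)
  # double-quantum tensor has a single nonzero entry |+1><-1|
  T22 <- spherical_tensor(1, 2, 2)
  expect_equal(sum(Mod(T22) > 1e-12), 1)
  expect_gt(Mod(T22[1, 3]), 0.99)
  expect_error(spherical_tensor(1, 3, 0), "rank")
  expect_error(spherical_tensor(1, 2, 3), "\\|m\\|")
})

test_that("embedding extends operators to the coupled space correctly", {
  s <- spin_matrices(1 / 2)
  n <- spin_matrices(1)
  expect_equal(embed_operator(s$E, "C13"), diag(6) + 0i)
  expect_equal(embed_operator(n$E, "N14"), diag(6) + 0i)
  Sz6 <- embed_operator(s$Iz, "C13")
  Iz6 <- embed_operator(n$Iz, "N14")
  expect_lt(frob(Sz6 %*% Iz6 - Iz6 %*% Sz6), 1e-14)
  ev <- sort(Re(eigen(Sz6 %*% Iz6, only.values = TRUE)$values))
  expect_equal(ev, sort(as.vector(outer(c(0.5, -0.5), c(1, 0, -1)))),
               tolerance = 1e-12)
  expect_error(embed_operator(s$Iz, "N14"), "3x3")
})

test_that("the 36 tensor products span the operator space", {
  basis <- list()
  for (lc in 0:1) for (mc in seq(-lc, lc))
    for (ln in 0:2) for (mn in seq(-ln, ln)) {
      TC <- embed_operator(spherical_tensor(1 / 2, lc, mc), "C13")
      TN <- embed_operator(spherical_tensor(1, ln, mn), "N14")
      basis[[length(basis) + 1]] <- TC %*% TN / frob(TC %*% TN)
    }
  expect_length(basis, 36)
  M <- random_hermitian6(7)
  coeff <- vapply(basis, function(B) sum(diag(Conj(t(B)) %*% M)), complex(1))
  M2 <- Reduce(`+`, Map(function(c, B) c * B, coeff, basis))
  expect_lt(frob(M - M2) / frob(M), 1e-12)
})

test_that("coherence decomposition resolves identity and tracks z-rotations", {
  n <- spin_matrices(1)
  expect_equal(coherence_orders(embed_operator(n$Iz, "N14")), 0L)
  expect_equal(coherence_orders(embed_operator(n$Ip, "N14")), 1L)
  rho <- random_hermitian6(3)
  comp <- coherence_decompose(rho)
  expect_lt(frob(rho - Reduce(`+`, comp)), 1e-14)
  # order p transforms as exp(-i p phi) under 14N z-rotation, phi = pi/2
  phi <- pi / 2
  Rz <- embed_operator(diag(exp(-1i * phi * c(1, 0, -1))), "N14")
  rot <- Rz %*% rho %*% Conj(t(Rz))
  for (p in -2:2) {
    expected <- comp[[as.character(p)]] * exp(-1i * p * phi)
    expect_lt(frob(coherence_decompose(rot)[[as.character(p)]] - expected),
              1e-12)
  }
})
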