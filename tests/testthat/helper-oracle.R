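# Independent brute-force oracle for the coherency construction and the
# purity indices.  Coded from the definitions, without reusing any package
# internals: the Kronecker products are expanded by explicit index
# arithmetic, one scalar entry at a time.

oracle_pauli <- function(a) {
  switch(a,
    `1` = matrix(c(1 + 0i, 0, 0, 1), 2, 2),
    `2` = matrix(c(1 + 0i, 0, 0, -1), 2, 2),
    `3` = matrix(c(0, 1 + 0i, 1, 0), 2, 2),
    `4` = matrix(c(0, 1i, -1i, 0), 2, 2)
  )
}

oracle_coherency <- function(M) {
  H <- matrix(0 + 0i, 4, 4)
  for (a in 1:4) {
    for (b in 1:4) {
      sa <- oracle_pauli(as.character(a))
      sb <- Conj(oracle_pauli(as.character(b)))
      # kron(sa, sb)[2*(i-1)+k, 2*(j-1)+l] = sa[i,j] * sb[k,l]
      for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
        r <- 2L * (i - 1L) + k
        c <- 2L * (j - 1L) + l
        H[r, c] <- H[r, c] + M[a, b] * sa[i, j] * sb[k, l] / 4
      }
    }
  }
  H
}

oracle_spectrum <- function(M) {
  lam <- sort(Re(eigen(oracle_coherency(M))$values), decreasing = TRUE)
  lam[lam < 0 & lam > -1e-12] <- 0
  lam / sum(lam)
}

oracle_ipps <- function(M) {
  l <- oracle_spectrum(M)
  c(l[1] - l[2], l[1] + l[2] - 2 * l[3], l[1] + l[2] + l[3] - 3 * l[4])
}

# constant image of a single Mueller matrix
constant_image <- function(M, h = 2L, w = 2L) {
  el <- array(0, c(h, w, 4L, 4L))
  for (a in 1:4) for (b in 1:4) el[, , a, b] <- M[a, b]
  mueller_image(el)
}

rect <- function(x0, y0, x1, y1) list(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
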