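# Trilinear 8-node hexahedron quadrature machinery shared by the mesh
# (volumes) and the finite-element assembly.  Local node order follows the
# VTK_HEXAHEDRON convention.

hex8_local_nodes <- matrix(c(
  -1, -1, -1,
   1, -1, -1,
   1,  1, -1,
  -1,  1, -1,
  -1, -1,  1,
   1, -1,  1,
   1,  1,  1,
  -1,  1,  1), ncol = 3, byrow = TRUE)

# Shape-function derivatives w.r.t. local coords at a local point (xi,eta,ze):
# returns 8 x 3 matrix dN/dxi.
hex8_dN <- function(xi, eta, ze) {
  s <- hex8_local_nodes
  cbind(
    s[, 1] * (1 + s[, 2] * eta) * (1 + s[, 3] * ze),
    (1 + s[, 1] * xi) * s[, 2] * (1 + s[, 3] * ze),
    (1 + s[, 1] * xi) * (1 + s[, 2] * eta) * s[, 3]
  ) / 8
}

hex8_shape <- function(xi, eta, ze) {
  s <- hex8_local_nodes
  (1 + s[, 1] * xi) * (1 + s[, 2] * eta) * (1 + s[, 3] * ze) / 8
}

# 2x2x2 Gauss points (weight 1 each).
hex8_gauss <- local({
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), ze = c(-g, g)))
})

# Volumes of hexahedral elements by 2x2x2 quadrature of det(J).
hex8_volumes <- function(nodes, elems) {
  nel <- nrow(elems)
  vol <- numeric(nel)
  dN_list <- lapply(seq_len(8), function(g) {
    hex8_dN(hex8_gauss[g, 1], hex8_gauss[g, 2], hex8_gauss[g, 3])
  })
  for (e in seq_len(nel)) {
    xe <- nodes[elems[e, ], , drop = FALSE]
    v <- 0
    for (g in seq_len(8)) {
      J <- crossprod(dN_list[[g]], xe)  # 3x3: dN' %*% xe
      v <- v + det(J)
    }
    vol[e] <- v
  }
  vol
}
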