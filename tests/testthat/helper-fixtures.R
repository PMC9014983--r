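# Shared fixtures: small skeleton spaces, random stacks, and an independent
# TFCE oracle built on igraph component labeling.

tinySpace <- function(dim = c(5, 5, 5), ...) {
  syntheticSkeletonSpace(dim, ...)
}

randomStack <- function(n, space, metric = "MD", seed = 1) {
  set.seed(seed)
  metricStack(metric, matrix(rnorm(n * nVoxels(space)), n), space)
}

# Brute-force TFCE: per threshold, label connected components among
# suprathreshold voxels with igraph and accumulate extent^E * h^H * dh.
# Independent of the package's C++ implementation.
tfceOracle <- function(values, space, H, E, steps, connectivity = 26) {
  values <- pmax(values, 0)
  vmax <- max(values)
  out <- numeric(length(values))
  if (vmax <= 0) return(out)
  co <- voxelCoords(space)
  v <- nrow(co)
  # all neighbor pairs under the connectivity, restricted to the skeleton
  pairs <- which(outer(seq_len(v), seq_len(v), Vectorize(function(i, j) {
    if (i >= j) return(FALSE)
    d <- abs(co[i, ] - co[j, ])
    m <- sum(d)
    all(d <= 1) && m > 0 &&
      (connectivity == 26 || (connectivity == 18 && m <= 2) ||
         (connectivity == 6 && m <= 1))
  })), arr.ind = TRUE)
  dh <- vmax / steps
  for (k in seq_len(steps)) {
    h <- vmax * k / steps
    supra <- which(values >= h)
    if (!length(supra)) next
    keep <- pairs[, 1] %in% supra & pairs[, 2] %in% supra
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(pairs[keep, 1]),
                 to = as.character(pairs[keep, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(supra)))
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership]
    out[supra] <- out[supra] + sizes^E * h^H * dh
  }
  out
}
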