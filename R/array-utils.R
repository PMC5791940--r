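# Internal 3D array helpers shared by segmentation and texture code.

# The 13 unique 3D direction vectors (one orientation each); together with
# their negatives they span the full 26-neighborhood.
unique_directions_3d <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE]
  # keep one of each {v, -v} pair: first nonzero component positive
  keep <- apply(d, 1L, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  unname(d[keep, , drop = FALSE])
}

# result[v] = a[v + d], with `fill` where v + d falls outside the grid
shift_array <- function(a, d, fill = 0) {
  dm <- dim(a)
  src <- mapply(function(n, k) {
    i <- seq_len(n) + k
    i[i < 1L | i > n] <- NA_integer_
    i
  }, dm, d, SIMPLIFY = FALSE)
  out <- a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out[is.na(out)] <- fill
  dim(out) <- dm
  out
}

# linear-index offset of direction d on a grid of dim dm (valid only where
# the shifted voxel is known to stay in range)
linear_offset <- function(d, dm) {
  d[1] + d[2] * dm[1] + d[3] * dm[1] * dm[2]
}

# Connected components of the voxels where `include` is TRUE, under
# 26-connectivity, optionally requiring equal `labels` across an edge.
# Returns an integer array: component id (1..k) inside, 0 outside.
connected_components_3d <- function(include, labels = NULL) {
  dm <- dim(include)
  idx <- which(include)
  if (length(idx) == 0L)
    return(array(0L, dim = dm))
  vid <- array(0L, dim = dm)
  vid[idx] <- seq_along(idx)
  dirs <- unique_directions_3d()
  edges <- vector("list", nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    nb <- shift_array(vid, d, fill = 0L)
    both <- include & nb > 0L
    if (!is.null(labels)) {
      lab_nb <- shift_array(labels, d, fill = NA)
      both <- both & !is.na(lab_nb) & lab_nb == labels
    }
    from <- vid[both]
    if (length(from))
      edges[[k]] <- cbind(from, nb[both])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  out <- array(0L, dim = dm)
  out[idx] <- as.integer(comp)
  out
}
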