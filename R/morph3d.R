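## 3-D binary morphology helpers. Connected components are computed by 2-D
## labelling per axial slice (EBImage) followed by a union of components that
## overlap between adjacent slices (igraph), i.e. 6-connectivity along the
## slice axis.

#' Label 3-D connected components
#'
#' @param mask logical 3-D array
#' @return integer array of component labels (0 = background)
#' @export
labelComponents3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  for (z in seq_len(d[3]))
    lab[, , z] <- EBImage::bwlabel(mask[, , z] * 1)
  maxPer <- apply(lab, 3, max)
  if (sum(maxPer) == 0) return(lab)
  off <- cumsum(c(0L, maxPer[-d[3]]))
  lab <- lab + array(rep(off, each = d[1] * d[2]), d) * (lab > 0L)
  edges <- NULL
  for (z in seq_len(d[3] - 1)) {
    a <- lab[, , z]; b <- lab[, , z + 1]
    sel <- a > 0L & b > 0L
    if (any(sel)) edges <- rbind(edges, unique(cbind(a[sel], b[sel])))
  }
  nTot <- sum(maxPer)
  g <- igraph::make_empty_graph(n = nTot, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  out <- array(0L, d)
  out[lab > 0L] <- memb[lab[lab > 0L]]
  out
}

#' Keep the largest connected component of a mask
#' @param mask logical 3-D array
#' @return logical array
#' @export
largestComponent <- function(mask) {
  lab <- labelComponents3d(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

## shift a 3-D logical array by (dx, dy, dz), padding with `pad`
.shift3d <- function(mask, s, pad = FALSE) {
  d <- dim(mask)
  out <- array(pad, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (s[k] >= 0) {
      src[[k]] <- seq_len(d[k] - s[k])
      dst[[k]] <- src[[k]] + s[k]
    } else {
      src[[k]] <- seq(1 - s[k], d[k])
      dst[[k]] <- src[[k]] + s[k]
    }
    if (length(src[[k]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

.dilate3d <- function(mask, r = 1) {
  for (i in seq_len(r)) {
    acc <- mask
    for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1)))
      acc <- acc | .shift3d(mask, s)
    mask <- acc
  }
  mask
}

## erosion treats outside-of-array as background
.erode3d <- function(mask, r = 1) {
  for (i in seq_len(r)) {
    acc <- mask
    for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1)))
      acc <- acc & .shift3d(mask, s, pad = FALSE)
    mask <- acc
  }
  mask
}

#' Morphological closing (dilation then erosion, 6-neighborhood)
#' @param mask logical 3-D array
#' @param r radius in voxels
#' @return logical array
#' @export
binaryClose3d <- function(mask, r = 1) .erode3d(.dilate3d(mask, r), r)

#' Fill interior holes of a 3-D mask
#'
#' Background components not connected to the array border are treated as
#' holes and filled.
#'
#' @param mask logical 3-D array
#' @return logical array
#' @export
fillHoles3d <- function(mask) {
  bg <- labelComponents3d(!mask)
  if (max(bg) == 0L) return(mask)
  d <- dim(mask)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                     bg[, , c(1, d[3])]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}
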