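#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

# Evaluate expr under a private Mersenne-Twister stream; the caller's RNG
# state is untouched.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

abort <- function(msg, class) {
  stop(structure(class = c(class, "gliadyn_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Euclidean disc structuring element
#'
#' Square 0/1 matrix of side 2*radius+1 whose ones are the integer offsets
#' (dy, dx) with dy^2 + dx^2 <= radius^2.
#'
#' @param radius_px non-negative integer radius in pixels.
#' @return numeric matrix usable as an `EBImage` morphological kernel.
#' @export
disc_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  stopifnot(r >= 0)
  off <- seq.int(-r, r)
  outer(off, off, function(a, b) as.numeric(a * a + b * b <= r * r))
}

# Binary dilation/erosion with a Euclidean disc, via EBImage.
dilate_mask <- function(mask, radius_px) {
  if (radius_px == 0) return(mask)
  out <- EBImage::dilate(EBImage::Image(mask * 1), disc_kernel(radius_px))
  EBImage::imageData(out) > 0.5
}

erode_mask <- function(mask, radius_px) {
  if (radius_px == 0) return(mask)
  out <- EBImage::erode(EBImage::Image(mask * 1), disc_kernel(radius_px))
  EBImage::imageData(out) > 0.5
}

#' Label connected components of a binary mask
#'
#' 8-connectivity in 2D and 26-connectivity in 3D (the conventions used by
#' the segmentation chain). Implemented over an igraph components call on the
#' foreground adjacency.
#'
#' @param mask logical matrix (2D) or 3D logical array.
#' @return integer array of the same shape; 0 is background, components are
#'   numbered from 1 in decreasing size order.
#' @export
label_components <- function(mask) {
  dims <- dim(mask)
  nd <- length(dims)
  stopifnot(nd %in% c(2L, 3L), is.logical(mask))
  lab <- array(0L, dims)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  id <- integer(prod(dims))
  id[fg] <- seq_along(fg)
  co <- arrayInd(fg, dims)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  # half the neighborhood suffices for an undirected graph: keep offsets whose
  # first non-zero coordinate is positive
  keep <- apply(offs, 1L, function(o) {
    nz <- which(o != 0L)
    length(nz) > 0L && o[nz[1L]] > 0L
  })
  offs <- offs[keep, , drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, offs[i, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (d in seq_len(nd)) ok <- ok & nb[, d] >= 1L & nb[, d] <= dims[d]
    if (!any(ok)) next
    lin <- nb[ok, 1L]
    if (nd == 2L) lin <- lin + (nb[ok, 2L] - 1L) * dims[1L]
    if (nd == 3L) {
      lin <- nb[ok, 1L] + (nb[ok, 2L] - 1L) * dims[1L] +
        (nb[ok, 3L] - 1L) * dims[1L] * dims[2L]
    }
    hit <- id[lin] > 0L
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <- cbind(id[fg[ok]][hit], id[lin][hit])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(integer(), 0, 2),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_along(fg)]
  sizes <- table(memb)
  rank <- integer(length(sizes))
  rank[order(as.integer(sizes), decreasing = TRUE)] <- seq_along(sizes)
  lab[fg] <- rank[memb]
  lab
}

#' Remove small connected components
#'
#' Counterpart of MATLAB's bwareaopen: drops 8-connected (2D) or 26-connected
#' (3D) components smaller than `min_area_px`.
#'
#' @param mask logical mask.
#' @param min_area_px components with fewer pixels than this are removed.
#' @return logical mask of the same shape.
#' @export
remove_small_components <- function(mask, min_area_px) {
  if (min_area_px <= 1) return(mask)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_px)
  array(lab %in% keep, dim(mask))
}

# population standard deviation
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# deterministic JSON writer used by all provenance/truth sidecars
write_json_file <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(txt, path)
  invisible(path)
}
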