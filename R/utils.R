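# Internal helpers: scoped RNG, binary morphology on logical matrices,
# boundary extraction and perimeter estimation.  All masks are logical
# matrices in row-major pixel convention (row = y, column = x), 0-based
# coordinates at the API surface where coordinates are exposed.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Shift a matrix by (di, dj) pixels, filling exposed cells with `fill`.
shift_mat <- function(m, di, dj, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- max(1, 1 + di):min(nr, nr + di)
  rj <- max(1, 1 + dj):min(nc, nc + dj)
  if (length(ri) == 0 || length(rj) == 0) return(out)
  out[ri, rj] <- m[ri - di, rj - dj, drop = FALSE]
  out
}

NEIGH4 <- cbind(di = c(-1L, 1L, 0L, 0L), dj = c(0L, 0L, -1L, 1L))
NEIGH8 <- cbind(di = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                dj = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))

dilate_mask <- function(mask, connectivity = 8L, iterations = 1L) {
  nb <- if (connectivity == 8L) NEIGH8 else NEIGH4
  for (it in seq_len(iterations)) {
    out <- mask
    for (k in seq_len(nrow(nb)))
      out <- out | shift_mat(mask, nb[k, 1], nb[k, 2], FALSE)
    mask <- out
  }
  mask
}

erode_mask <- function(mask, connectivity = 8L, iterations = 1L) {
  nb <- if (connectivity == 8L) NEIGH8 else NEIGH4
  for (it in seq_len(iterations)) {
    out <- mask
    for (k in seq_len(nrow(nb)))
      out <- out & shift_mat(mask, nb[k, 1], nb[k, 2], FALSE)
    mask <- out
  }
  mask
}

# Boundary pixels of `mask`: mask pixels with at least one 4-neighbour that
# lies inside `roi` but outside `mask`.  Neighbours outside `roi` (or outside
# the image) do not create surface, so a mask cut by the ROI edge is "open"
# there -- ROI cut edges are not biological surfaces.
boundary_mask <- function(mask, roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(mask), ncol(mask))
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(NEIGH4))) {
    nb_bg <- shift_mat(roi & !mask, NEIGH4[k, 1], NEIGH4[k, 2], FALSE)
    out <- out | (mask & nb_bg)
  }
  out
}

# Perimeter length in pixel units with diagonal correction, following the
# weighted border-pixel scheme of Benkrid et al. as popularised by
# scikit-image: each border pixel is classified by its border-neighbour
# configuration (2x isothetic + 10x diagonal neighbour counts + 1) and
# weighted 1, sqrt(2) or (1+sqrt(2))/2.  Exact for isothetic edges;
# approximate for oblique ones.  ROI cut edges contribute nothing.
perimeter_length <- function(mask, roi = NULL) {
  border <- boundary_mask(mask, roi)
  if (!any(border)) return(0)
  iso <- matrix(0L, nrow(mask), ncol(mask))
  dia <- matrix(0L, nrow(mask), ncol(mask))
  for (k in 1:4) iso <- iso + shift_mat(border, NEIGH4[k, 1], NEIGH4[k, 2], FALSE)
  for (k in 5:8) dia <- dia + shift_mat(border, NEIGH8[k, 1], NEIGH8[k, 2], FALSE)
  code <- 1L + 2L * iso + 10L * dia
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1L] <- 1
  w[c(21, 33) + 1L] <- sqrt(2)
  w[c(13, 23) + 1L] <- (1 + sqrt(2)) / 2
  sum(w[code[border] + 1L])
}

# Connected-component labelling (thin wrapper over the compiled routine).
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4L, 8L))
  .cc_label(mask, as.integer(connectivity))
}

# Euclidean distance (pixels) from every TRUE pixel to the nearest FALSE
# pixel; 0 on FALSE pixels.  Pixels outside the image count as background.
distance_transform <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  .edt(mask)
}

# argument checking -----------------------------------------------------

stop_if_not_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

as_mask <- function(x, dims = NULL) {
  if (is.logical(x) && is.matrix(x)) m <- x
  else if (is.numeric(x) && is.matrix(x)) m <- x != 0
  else stop("mask must be a logical (or 0/1 numeric) matrix", call. = FALSE)
  if (!is.null(dims) && !identical(dim(m), as.integer(dims)))
    stop("mask dimensions do not match the image", call. = FALSE)
  m
}
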