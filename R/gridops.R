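# Internal grid operations: connected-component labelling and a chamfer
# distance transform. Pure-matrix implementations (vectorized sweeps).

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# label connected components of a logical mask (8-connectivity) by iterated
# min-label propagation; returns an integer matrix (0 = background)
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  }
  repeat {
    new <- lab
    for (o in offs) new <- pmin(new, shift_mat(lab, o[1], o[2]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  ids <- sort(unique(lab[is.finite(lab)]))
  out[mask] <- match(lab[mask], ids)
  out
}

# chamfer (quasi-Euclidean) distance transform: distance in meters from each
# cell center to the nearest TRUE cell, via sweeps to a fixpoint
chamfer_distance <- function(mask, cell_size) {
  a <- cell_size; b <- cell_size * sqrt(2)
  d <- matrix(Inf, nrow(mask), ncol(mask))
  d[mask] <- 0
  w <- list(list(c(-1, -1), b), list(c(-1, 0), a), list(c(-1, 1), b),
            list(c(0, -1), a), list(c(0, 1), a),
            list(c(1, -1), b), list(c(1, 0), a), list(c(1, 1), b))
  nc <- ncol(d)
  repeat {
    new <- d
    # row sweeps
    for (o in w) new <- pmin(new, shift_mat(new, o[[1]][1], o[[1]][2]) + o[[2]])
    # in-row left/right propagation
    for (cc in 2:nc) new[, cc] <- pmin(new[, cc], new[, cc - 1] + a)
    for (cc in (nc - 1):1) new[, cc] <- pmin(new[, cc], new[, cc + 1] + a)
    if (max(abs(new - d)[is.finite(d) | is.finite(new)], 0) < 1e-9) break
    d <- new
  }
  d
}

# boundary cells of a labelled patch: cells with at least one non-patch
# 4-neighbor (or on the grid edge)
boundary_cells <- function(lab, id) {
  mask <- lab == id
  inner <- shift_mat(mask, 1, 0, FALSE) & shift_mat(mask, -1, 0, FALSE) &
           shift_mat(mask, 0, 1, FALSE) & shift_mat(mask, 0, -1, FALSE)
  which(mask & !inner, arr.ind = TRUE)
}
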