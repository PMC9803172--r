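#' Trace the outer boundary of a mask
#'
#' Moore neighbour tracing. The traversal starts at the top-most, then
#' left-most foreground pixel, terminates when the (start, next) pixel pair
#' recurs (so spurs that legitimately revisit the start are handled), and is
#' returned with consistent counter-clockwise orientation (positive shoelace
#' area in `(x = col, y = -row)` coordinates). Alongside the ordered boundary
#' points the Freeman 8-direction chain code of the traversal is produced;
#' the traversal length `T` counts 1 per axial step and `sqrt(2)` per
#' diagonal step.
#'
#' @param mask `glia_mask` with a single 8-connected component of area >= 8.
#' @return A list of class `glia_contour`: `points` (n x 2 matrix of 1-based
#'   (row, col)), `chain_code` (n integers in 0..7, closing step included) and
#'   `T` (total traversal length).
#' @export
trace_contour <- function(mask) {
  area <- sum(mask == 1L)
  if (area < 8L) abort_glia("degenerate shape: area < 8", "glia_degenerate_shape")
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)   # guard ring: lookups never leave the matrix
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask == 1L
  fg <- which(pad == 1L)
  ord <- order((fg - 1L) %% (nr + 2L), (fg - 1L) %/% (nr + 2L))
  s <- fg[ord][1L]
  start <- c((s - 1L) %% (nr + 2L) + 1L, (s - 1L) %/% (nr + 2L) + 1L)
  # clockwise Moore neighbourhood starting at W
  nbr <- cbind(c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
               c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))
  rel2idx <- matrix(NA_integer_, 3L, 3L)
  for (j in 1:8) rel2idx[nbr[j, 1L] + 2L, nbr[j, 2L] + 2L] <- j
  # advance from (p, backtrack index): first foreground neighbour clockwise
  advance <- function(p, brel) {
    for (k in 0:7) {
      j <- (brel - 1L + k) %% 8L + 1L
      q <- p + nbr[j, ]
      if (pad[q[1L], q[2L]] == 1L) {
        bpix <- p + nbr[(j - 2L) %% 8L + 1L, ]   # neighbour examined just before q
        return(list(q = q, brel = rel2idx[bpix[1L] - q[1L] + 2L, bpix[2L] - q[2L] + 2L]))
      }
    }
    NULL
  }
  st <- advance(start, 1L)   # backtrack of start is its W neighbour (background)
  if (is.null(st)) abort_glia("degenerate shape: isolated pixel", "glia_degenerate_shape")
  second <- st$q
  pts <- matrix(0L, 8L * area + 16L, 2L)
  pts[1L, ] <- start; pts[2L, ] <- second
  np <- 2L
  p <- second; brel <- st$brel
  repeat {
    st <- advance(p, brel)
    q <- st$q; brel <- st$brel
    if (q[1L] == start[1L] && q[2L] == start[2L]) {
      nxt <- advance(q, brel)
      if (nxt$q[1L] == second[1L] && nxt$q[2L] == second[2L]) break
    }
    np <- np + 1L
    if (np > nrow(pts)) abort_glia("contour tracing did not terminate", "glia_contour_error")
    pts[np, ] <- q
    p <- q
  }
  pts <- pts[seq_len(np), , drop = FALSE] - 1L   # undo padding
  if (np < 8L) abort_glia("degenerate shape: contour too short", "glia_degenerate_shape")
  pts <- orient_ccw(pts)
  key <- (pts[, 1L] - 1) * (nc + 1) + pts[, 2L]
  i0 <- which.min(key)                            # restart at top-most/left-most
  if (i0 > 1L) pts <- pts[c(i0:np, 1L:(i0 - 1L)), , drop = FALSE]
  steps <- rbind(diff(pts), pts[1L, , drop = FALSE] - pts[np, , drop = FALSE])
  code <- chain_code_of(steps)
  structure(list(points = pts, chain_code = code,
                 T = sum(ifelse(code %% 2L == 0L, 1, sqrt(2)))),
            class = "glia_contour")
}

# counter-clockwise in (x = col, y = -row): positive shoelace area
orient_ccw <- function(pts) {
  x <- pts[, 2L]; y <- -pts[, 1L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  if (sum(x * y2 - x2 * y) < 0) pts[rev(seq_len(nrow(pts))), , drop = FALSE] else pts
}

# Freeman code in (x = col, y = -row): 0=E, 1=NE, ..., 7=SE
chain_code_of <- function(steps) {
  dr <- steps[, 1L]; dc <- steps[, 2L]
  if (any(abs(dr) > 1L | abs(dc) > 1L | (dr == 0L & dc == 0L))) {
    abort_glia("contour steps are not unit Moore moves", "glia_contour_error")
  }
  lut <- matrix(NA_integer_, 3L, 3L)  # [dr+2, dc+2]
  lut[2L, 3L] <- 0L; lut[1L, 3L] <- 1L; lut[1L, 2L] <- 2L; lut[1L, 1L] <- 3L
  lut[2L, 1L] <- 4L; lut[3L, 1L] <- 5L; lut[3L, 2L] <- 6L; lut[3L, 3L] <- 7L
  lut[cbind(dr + 2L, dc + 2L)]
}
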