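#' Segmentation parameters
#'
#' Settings for the Chan-Vese active contour and the downstream cleanup.
#' `mu` weights the contour-length penalty (higher = smoother, fewer small
#' regions); the data terms `lambda_in`/`lambda_out` weight intensity
#' variance inside/outside the contour. Iteration stops when the maximum
#' per-pixel level-set change in one step falls below `tol` (checked every
#' `check_every` iterations) or at `max_iter`.
#'
#' @param mu Contour-length weight, >= 0. Default 0.2.
#' @param max_iter Iteration cap, >= 1. Default 1000.
#' @param lambda_in,lambda_out Region data-term weights. Default 1.
#' @param tol Convergence tolerance on max |delta phi| per pixel. Default 1e-3.
#' @param epsilon Width (pixels) of the smoothed Heaviside/delta pair.
#'   Default 1.
#' @param dt Gradient-descent step size. Default 1 (stable for the
#'   regularized flow; halving it roughly doubles iterations to
#'   convergence without changing the mask).
#' @param check_every Iterations between convergence checks. Default 10.
#' @param min_area Small-object removal threshold in pixels. Default 64.
#' @param crop_margin Padding around each cell crop, pixels. Default 2.
#' @return A `seg_params` list.
#' @export
seg_params <- function(mu = 0.2, max_iter = 1000L, lambda_in = 1,
                       lambda_out = 1, tol = 1e-3, epsilon = 1, dt = 1,
                       check_every = 10L, min_area = 64L, crop_margin = 2L) {
  stopifnot(mu >= 0, max_iter >= 1, tol > 0, epsilon > 0, dt > 0,
            min_area >= 0, crop_margin >= 0)
  structure(
    list(mu = mu, max_iter = as.integer(max_iter), lambda_in = lambda_in,
         lambda_out = lambda_out, tol = tol, epsilon = epsilon, dt = dt,
         check_every = as.integer(check_every),
         min_area = as.integer(min_area),
         crop_margin = as.integer(crop_margin)),
    class = "seg_params"
  )
}

# Neighbor shifts with replicated (Neumann) borders.
sh_up <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
sh_down <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
sh_left <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
sh_right <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

heaviside_eps <- function(phi, eps) 0.5 * (1 + 2 / pi * atan(phi / eps))
delta_eps <- function(phi, eps) eps / (pi * (eps^2 + phi^2))

cv_curvature <- function(phi) {
  n <- sh_up(phi); s <- sh_down(phi); w <- sh_left(phi); e <- sh_right(phi)
  px <- (e - w) / 2
  py <- (s - n) / 2
  pxx <- e - 2 * phi + w
  pyy <- s - 2 * phi + n
  pxy <- (sh_down(sh_right(phi)) - sh_up(sh_right(phi)) -
            sh_down(sh_left(phi)) + sh_up(sh_left(phi))) / 4
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
    ((px^2 + py^2)^1.5 + 1e-8)
}

cv_energy <- function(u, phi, c_in, c_out, p) {
  h <- heaviside_eps(phi, p$epsilon)
  hx <- (sh_right(h) - sh_left(h)) / 2
  hy <- (sh_down(h) - sh_up(h)) / 2
  perimeter <- sum(sqrt(hx^2 + hy^2))
  p$mu * perimeter +
    p$lambda_in * sum((u - c_in)^2 * h) +
    p$lambda_out * sum((u - c_out)^2 * (1 - h))
}

#' Chan-Vese active-contour segmentation
#'
#' Region-based two-phase segmentation minimizing the piecewise-constant
#' Mumford-Shah energy
#' \deqn{\mu\,\mathrm{length}(C) +
#'   \lambda_{in}\int_{in}(u - c_{in})^2 +
#'   \lambda_{out}\int_{out}(u - c_{out})^2}
#' by explicit gradient descent on a level-set function `phi`, with a
#' smoothed Heaviside of width `epsilon` and central-difference curvature.
#' The method needs no edges and handles topology changes, so scattered
#' cells on a smear are captured as separate components from a single
#' initial contour.
#'
#' The image is rescaled to \[0, 1\] internally (no other preprocessing),
#' which also makes the result invariant to constant intensity shifts. The
#' level set starts as a checkerboard pattern, a standard initialization
#' that converges regardless of where objects lie. After convergence the
#' region whose mean intensity differs most from the image-border mean is
#' declared foreground, so dark cells on a light background (or the
#' reverse) come out as the mask.
#'
#' @param image 2-D numeric matrix of grayscale intensities (any range;
#'   rescaled internally). Constant images are rejected: the two-region
#'   partition is undefined.
#' @param params A [seg_params()] object.
#' @return Object of class `cell_segmentation`: list with `mask` (logical
#'   matrix, foreground = cells), `phi` (final level set), `c_in`, `c_out`
#'   (region means on the rescaled image), `energy` (final energy),
#'   `energy_trace` (energy at each convergence checkpoint), `iterations`,
#'   and `converged`.
#' @export
chan_vese_segment <- function(image, params = seg_params()) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2-D numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image))) stop("image has non-finite values", call. = FALSE)
  rng <- range(image)
  if (rng[1] == rng[2]) {
    stop("constant image: two-region segmentation is undefined",
         call. = FALSE)
  }
  p <- params
  u <- (image - rng[1]) / (rng[2] - rng[1])

  nr <- nrow(u); nc <- ncol(u)
  # checkerboard initialization: sign alternates on a ~10-pixel period
  phi <- outer(
    sin(pi / 5 * (seq_len(nr) - 1)),
    sin(pi / 5 * (seq_len(nc) - 1))
  )

  region_means <- function(phi) {
    inside <- phi > 0
    c_in <- if (any(inside)) mean(u[inside]) else mean(u)
    c_out <- if (any(!inside)) mean(u[!inside]) else mean(u)
    c(c_in, c_out)
  }

  converged <- FALSE
  iter <- 0L
  energy_trace <- numeric(0)
  clamp <- 5  # bound |phi| so the regularized delta keeps the flow stable
  phi_prev <- phi
  while (iter < p$max_iter) {
    iter <- iter + 1L
    cm <- region_means(phi)
    force_term <- p$mu * cv_curvature(phi) -
      p$lambda_in * (u - cm[1])^2 + p$lambda_out * (u - cm[2])^2
    phi <- phi + p$dt * delta_eps(phi, p$epsilon) * force_term
    phi <- pmin(pmax(phi, -clamp), clamp)
    if (iter %% p$check_every == 0L || iter == p$max_iter) {
      cm <- region_means(phi)
      energy_trace <- c(energy_trace, cv_energy(u, phi, cm[1], cm[2], p))
      # mean per-iteration change over the window: robust to interface
      # flicker at the clamp while still catching systematic drift
      if (max(abs(phi - phi_prev)) / p$check_every < p$tol) {
        converged <- TRUE
        break
      }
      phi_prev <- phi
    }
  }

  mask <- phi > 0
  cm <- region_means(phi)
  # foreground = region most unlike the border (background) intensity
  border <- c(u[1, ], u[nr, ], u[, 1], u[, nc])
  if (abs(cm[2] - mean(border)) > abs(cm[1] - mean(border))) {
    mask <- !mask
    phi <- -phi
    cm <- rev(cm)
  }
  cm_orig <- cm * (rng[2] - rng[1]) + rng[1]  # back to input intensity units
  structure(
    list(mask = mask, phi = phi, c_in = cm_orig[1], c_out = cm_orig[2],
         energy = energy_trace[length(energy_trace)],
         energy_trace = energy_trace, iterations = iter,
         converged = converged),
    class = "cell_segmentation"
  )
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat("Chan-Vese segmentation:", sum(x$mask), "foreground pixels of",
      length(x$mask), "\n  region means:", round(x$c_in, 4), "(in) /",
      round(x$c_out, 4), "(out);", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}

# 8-connected component labels. EBImage::bwlabel is 4-connected; merge
# labels that touch diagonally with a union-find pass over label pairs.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  diag_pairs <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    cbind(a[keep], b[keep])
  }
  pairs <- rbind(
    diag_pairs(lab[-nr, -nc], lab[-1, -1]),   # NW-SE
    diag_pairs(lab[-nr, -1], lab[-1, -nc])    # NE-SW
  )
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

#' Remove small connected components from a mask
#'
#' Drops every 8-connected foreground component smaller than `min_area`
#' pixels — specks of noise or debris that would otherwise become spurious
#' cell crops. Never adds pixels, and applying it twice changes nothing.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param min_area Minimum surviving component area in pixels.
#' @return Logical matrix.
#' @export
remove_small_objects <- function(mask, min_area) {
  mask <- mask > 0
  if (min_area <= 0) return(mask)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  lab %in% keep & mask
}

#' Extract per-cell crops from a segmentation mask
#'
#' One crop per 8-connected component of the (cleaned) mask. Bounding
#' boxes are padded by `crop_margin` pixels and clipped to the image;
#' coordinates are 1-based inclusive (row/column indices into the image
#' matrix). Crops get stable ids `cell_001`, `cell_002`, ... ordered by
#' (top, left) of their boxes.
#'
#' @param mask Logical matrix, typically after [remove_small_objects()].
#' @param image Grayscale matrix of the same dimensions (optional; when
#'   given, each crop carries its intensity patch).
#' @param params A [seg_params()] (for `crop_margin`).
#' @return Tibble with one row per cell: `cell_id`, `top`, `left`,
#'   `bottom`, `right`, `area`, and list-columns `mask` (component mask
#'   within the box) and `patch` (image values, `NULL` if no image given).
#'   Empty mask gives an empty tibble.
#' @export
extract_cells <- function(mask, image = NULL, params = seg_params()) {
  mask <- mask > 0
  if (!is.null(image)) stopifnot(all(dim(image) == dim(mask)))
  lab <- label_components(mask)
  n <- max(lab)
  empty <- tibble::tibble(
    cell_id = character(), top = integer(), left = integer(),
    bottom = integer(), right = integer(), area = integer(),
    mask = list(), patch = list()
  )
  if (n == 0L) return(empty)
  margin <- params$crop_margin
  rows <- row(lab); cols <- col(lab)
  boxes <- purrr::map(seq_len(n), function(i) {
    sel <- lab == i
    top <- max(1L, min(rows[sel]) - margin)
    bottom <- min(nrow(lab), max(rows[sel]) + margin)
    left <- max(1L, min(cols[sel]) - margin)
    right <- min(ncol(lab), max(cols[sel]) + margin)
    list(top = top, left = left, bottom = bottom, right = right,
         area = sum(sel),
         mask = sel[top:bottom, left:right, drop = FALSE],
         patch = if (is.null(image)) NULL
                 else image[top:bottom, left:right, drop = FALSE])
  })
  ord <- order(purrr::map_int(boxes, "top"), purrr::map_int(boxes, "left"))
  boxes <- boxes[ord]
  tibble::tibble(
    cell_id = sprintf("cell_%03d", seq_len(n)),
    top = purrr::map_int(boxes, "top"),
    left = purrr::map_int(boxes, "left"),
    bottom = purrr::map_int(boxes, "bottom"),
    right = purrr::map_int(boxes, "right"),
    area = purrr::map_int(boxes, "area"),
    mask = purrr::map(boxes, "mask"),
    patch = purrr::map(boxes, "patch")
  )
}

#' Dice overlap between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b Logical matrices of equal dimensions.
#' @return Fraction in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  a <- a > 0; b <- b > 0
  stopifnot(all(dim(a) == dim(b)))
  tot <- sum(a) + sum(b)
  if (tot == 0) return(1)
  2 * sum(a & b) / tot
}

#' Read a grayscale smear image
#'
#' Reads PNG or TIFF via EBImage; color images are averaged to grayscale.
#'
#' @param path Image file path.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_smear_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- if (length(d) == 2L) EBImage::imageData(img)
       else apply(EBImage::imageData(img), c(1, 2), mean)
  # EBImage stores x-by-y; transpose to row = image row
  t(m)
}

#' Write a binary mask as a PNG
#'
#' @param mask Logical matrix.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path, type = "png")
  invisible(path)
}
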