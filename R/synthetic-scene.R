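# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shape rasterizers: logical mask on the full pixel grid. Coordinates are
# (row, col) centers; all shapes are simply connected and fit in a bounding
# radius used for overlap rejection.

raster_disc <- function(nr, nc, cy, cx, r) {
  outer(seq_len(nr), seq_len(nc), function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

# Capsule (segment dilated by half-width w): elongated/sickle stand-in with
# aspect ratio length/width >= 3.
raster_capsule <- function(nr, nc, cy, cx, half_len, w, theta) {
  dy <- sin(theta) * half_len
  dx <- cos(theta) * half_len
  y1 <- cy - dy; x1 <- cx - dx
  y2 <- cy + dy; x2 <- cx + dx
  outer(seq_len(nr), seq_len(nc), function(y, x) {
    # distance from pixel to the segment (p1, p2)
    vx <- x2 - x1; vy <- y2 - y1
    tt <- pmin(pmax(((x - x1) * vx + (y - y1) * vy) / (vx^2 + vy^2), 0), 1)
    (x - (x1 + tt * vx))^2 + (y - (y1 + tt * vy))^2 <= w^2
  })
}

# Star-shaped irregular blob: radius modulated around the angle.
raster_blob <- function(nr, nc, cy, cx, r, m, amp, phase) {
  outer(seq_len(nr), seq_len(nc), function(y, x) {
    ang <- atan2(y - cy, x - cx)
    rho <- r * (1 + amp * sin(m * ang + phase))
    (y - cy)^2 + (x - cx)^2 <= rho^2
  })
}

#' Generate a synthetic smear-like scene with known ground truth
#'
#' Renders dark cells on a lighter background with additive Gaussian noise,
#' emulating a grayscale blood-smear crop: circular cells are discs,
#' elongated (sickle) cells are thin capsules with aspect ratio at least
#' 3:1, and "other" deformations are irregular star/blob shapes. Cells are
#' placed by rejection sampling so that masks never touch (a 2-pixel
#' clearance is enforced), giving every planted cell its own connected
#' component. All randomness flows through `seed`; identical seeds give
#' identical scenes.
#'
#' @param n_cells Number of cells to place (>= 0).
#' @param class_mix Probabilities for (circular, elongated, other). Default
#'   `c(0.7, 0.2, 0.1)`, the imbalance typical of smears from sickle-cell
#'   patients where normal cells dominate.
#' @param image_size `c(rows, cols)` of the image. Default 128 x 128.
#' @param noise_sd Additive Gaussian noise sd on the \[0, 1\] intensity
#'   scale. Default 0.02.
#' @param seed Integer seed (mandatory).
#' @param background,cell_intensity Background / cell gray levels. Defaults
#'   0.9 and 0.25 (dark cells, light field).
#' @param radius_range Base cell radius range in pixels. Default `c(5, 9)`.
#' @param max_tries Placement attempts per cell before giving up. Default 200.
#' @return Object of class `smear_scene`: list with `image` (matrix in
#'   \[0, 1\]), `labels` (integer matrix, 0 = background, i = cell i),
#'   `cells` (tibble `cell_id`, `label`, `area`), `noise_sd`, `seed`.
#' @export
generate_scene <- function(n_cells, class_mix = c(0.7, 0.2, 0.1),
                           image_size = c(128L, 128L), noise_sd = 0.02,
                           seed, background = 0.9, cell_intensity = 0.25,
                           radius_range = c(5, 9), max_tries = 200L) {
  stopifnot(n_cells >= 0, length(class_mix) == 3L, all(class_mix >= 0),
            sum(class_mix) > 0, length(image_size) == 2L)
  class_mix <- class_mix / sum(class_mix)
  nr <- as.integer(image_size[1]); nc <- as.integer(image_size[2])
  lv <- cell_levels()

  with_seed(seed, {
    labels_m <- matrix(0L, nr, nc)
    occupied <- matrix(FALSE, nr, nc)  # masks dilated by clearance
    cells <- list()
    placed <- 0L
    if (n_cells > 0) {
      draw_class <- sample(3L, n_cells, replace = TRUE, prob = class_mix)
      for (i in seq_len(n_cells)) {
        cls <- draw_class[i]
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          r <- stats::runif(1, radius_range[1], radius_range[2])
          # bounding radius of the widest shape variant
          bound <- r * 1.6
          cy <- stats::runif(1, bound + 2, nr - bound - 1)
          cx <- stats::runif(1, bound + 2, nc - bound - 1)
          m <- switch(cls,
            raster_disc(nr, nc, cy, cx, r),
            {
              w <- max(1.6, r / 2.2)
              raster_capsule(nr, nc, cy, cx, half_len = 3 * w, w = w,
                             theta = stats::runif(1, 0, pi))
            },
            raster_blob(nr, nc, cy, cx, r * 0.9,
                        m = sample(3:6, 1), amp = stats::runif(1, 0.25, 0.4),
                        phase = stats::runif(1, 0, 2 * pi))
          )
          if (!any(m & occupied)) {
            placed <- placed + 1L
            labels_m[m] <- placed
            # 2-pixel clearance so neighboring cells never form one component
            occupied <- occupied | dilate_mask(m, 2L)
            cells[[placed]] <- tibble::tibble(
              cell_id = sprintf("cell_%03d", placed),
              label = lv[cls], area = sum(m)
            )
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop("could not place cell ", i, " of ", n_cells,
               " without overlap (placed ", placed, "); ",
               "reduce n_cells or enlarge the image", call. = FALSE)
        }
      }
    }
    img <- matrix(background, nr, nc)
    img[labels_m > 0L] <- cell_intensity
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    }
    img <- pmin(pmax(img, 0), 1)
    structure(
      list(image = img, labels = labels_m,
           cells = if (placed > 0) dplyr::bind_rows(cells)
                   else tibble::tibble(cell_id = character(),
                                       label = character(),
                                       area = integer()),
           noise_sd = noise_sd, seed = as.integer(seed)),
      class = "smear_scene"
    )
  })
}

# Chebyshev dilation by `by` pixels via shifted ORs.
dilate_mask <- function(mask, by) {
  out <- mask
  for (i in seq_len(by)) {
    out <- out | sh_up(out) | sh_down(out) | sh_left(out) | sh_right(out)
    out <- out | sh_up(sh_left(out)) | sh_down(sh_right(out))
  }
  out
}

#' @export
print.smear_scene <- function(x, ...) {
  cat("Synthetic smear scene:", nrow(x$cells), "cells on a",
      paste(dim(x$image), collapse = " x "), "field (seed", x$seed, ")\n")
  if (nrow(x$cells) > 0) print(dplyr::count(x$cells, .data$label))
  invisible(x)
}
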