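#' Specification of a synthetic histology section
#'
#' Parameters for [generate_histology_phantom()], which builds a
#' trichrome-like colour section with exactly known ground truth: stained
#' tissue on a white slide, near-circular bright fat vacuoles, and bright
#' vessel/tear structures that a correct morphometric filter must reject.
#'
#' The default pixel size of 0.5 um/pixel makes the standard 100-10000 px
#' particle-size window correspond to vacuole diameters of about 5.6-56 um.
#' The default vacuole diameter range (8-40 um) sits inside that window so
#' that rasterised vacuole areas stay within the filter bounds.
#'
#' @param width,height Image size in pixels.
#' @param pixel_size Pixel size in um/pixel.
#' @param target_fat_fraction Desired areal fat fraction (fat / tissue area),
#'   in `[0, 0.5]`. The generator places vacuoles until the achieved fraction
#'   is within 10 percent (relative) of this target.
#' @param vacuole_diameter_range Length-2 vector, vacuole diameters in um.
#' @param n_vessels Number of large roundish bright structures (area above
#'   the 10000 px filter bound, so rejected by size).
#' @param n_tears Number of elongated bright structures (circularity below
#'   0.5, so rejected by shape).
#' @param tissue_color_mean,tissue_color_sd Mean RGB (length 3) and texture
#'   sd of the stained tissue, 8-bit scale. The green channel is kept below
#'   220 so thresholding separates tissue from bright structures exactly.
#' @param background_value Slide background intensity (near-white).
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec including this seed.
#' @return An object of class `histology_phantom_spec`.
#' @export
histology_phantom_spec <- function(width = 768, height = 768,
                                   pixel_size = 0.5,
                                   target_fat_fraction = 0.1,
                                   vacuole_diameter_range = c(8, 40),
                                   n_vessels = 2, n_tears = 1,
                                   tissue_color_mean = c(175, 110, 150),
                                   tissue_color_sd = 8,
                                   background_value = 255,
                                   seed = 1) {
  .check_num(width, "width", lo = 64)
  .check_num(height, "height", lo = 64)
  .check_num(pixel_size, "pixel_size", lo = 1e-6)
  .check_num(target_fat_fraction, "target_fat_fraction", lo = 0, hi = 0.5)
  .check_num(vacuole_diameter_range, "vacuole_diameter_range",
             lo = 1e-6, len = 2L)
  if (vacuole_diameter_range[1] > vacuole_diameter_range[2]) {
    stop("vacuole_diameter_range must be increasing", call. = FALSE)
  }
  .check_num(n_vessels, "n_vessels", lo = 0)
  .check_num(n_tears, "n_tears", lo = 0)
  .check_num(tissue_color_mean, "tissue_color_mean", lo = 0, hi = 255, len = 3L)
  .check_num(tissue_color_sd, "tissue_color_sd", lo = 0)
  .check_num(background_value, "background_value", lo = 220, hi = 255)
  .check_num(seed, "seed")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size,
                 target_fat_fraction = target_fat_fraction,
                 vacuole_diameter_range = vacuole_diameter_range,
                 n_vessels = as.integer(n_vessels),
                 n_tears = as.integer(n_tears),
                 tissue_color_mean = tissue_color_mean,
                 tissue_color_sd = tissue_color_sd,
                 background_value = background_value,
                 seed = as.integer(seed)),
            class = "histology_phantom_spec")
}

# internal: linear indices of a rotated ellipse with semi-axes a, b (pixels)
# centred at (cy, cx), orientation phi; returns NULL if it leaves the image
.ellipse_idx <- function(cy, cx, a, b, phi, h, w) {
  half <- ceiling(max(a, b)) + 1
  r0 <- floor(cy - half); r1 <- ceiling(cy + half)
  c0 <- floor(cx - half); c1 <- ceiling(cx + half)
  if (r0 < 1 || c0 < 1 || r1 > h || c1 > w) return(NULL)
  rr <- rep(r0:r1, times = c1 - c0 + 1)
  cc <- rep(c0:c1, each = r1 - r0 + 1)
  dx <- cc - cx; dy <- rr - cy
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  keep <- u^2 + v^2 <= 1
  (cc[keep] - 1) * h + rr[keep]
}

# internal: place one shape whose pixels (plus a `gap` margin) must lie in
# `allowed` and off `occupied`; returns its linear indices or NULL
.try_place <- function(centers, gen_idx, allowed, occupied, gap, h, w,
                       attempts) {
  for (i in seq_len(attempts)) {
    ctr <- centers[sample.int(length(centers), 1)]
    cy <- (ctr - 1) %% h + 1
    cx <- (ctr - 1) %/% h + 1
    core <- gen_idx(cy, cx, 0)
    if (is.null(core)) next
    grown <- gen_idx(cy, cx, gap)
    if (is.null(grown)) next
    if (all(allowed[grown]) && !any(occupied[grown])) return(core)
  }
  NULL
}

#' Generate a synthetic histology section with known fat content
#'
#' Builds a colour image in which an irregular blob of stained tissue sits on
#' a white slide; near-circular bright vacuoles (the ground-truth fat),
#' large bright vessel-like blobs and elongated tear-like streaks are
#' composited inside the tissue. Vacuoles never overlap each other or the
#' vessel/tear structures, so the ground-truth masks are exact by
#' construction. Vacuole placement continues until the achieved areal fat
#' fraction is within 10 percent (relative) of the target; if the target
#' cannot be reached within the available tissue area the generator fails
#' explicitly rather than under-filling silently.
#'
#' @param spec A [histology_phantom_spec()].
#' @return An object of class `histology_phantom`: `image` (RGB array,
#'   8-bit), `fat_mask`, `vessel_mask`, `tissue_mask` (logical matrices),
#'   `true_areal_fat_fraction` (= fat pixels / tissue pixels, exact) and the
#'   `spec`.
#' @examples
#' ph <- generate_histology_phantom(histology_phantom_spec(
#'   width = 256, height = 256, target_fat_fraction = 0.05,
#'   n_vessels = 0, n_tears = 0, seed = 7))
#' ph$true_areal_fat_fraction
#' @export
generate_histology_phantom <- function(spec = histology_phantom_spec()) {
  stopifnot(inherits(spec, "histology_phantom_spec"))
  .with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    cy <- h / 2; cx <- w / 2
    ry <- 0.42 * h; rx <- 0.44 * w

    # wavy-ellipse tissue blob
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    dy <- (rows - cy) / ry; dx <- (cols - cx) / rx
    rad <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    amp <- runif(3, 0.3, 1); ph_ <- runif(3, 0, 2 * pi)
    wob <- 0.07 * (amp[1] * sin(2 * th + ph_[1]) +
                   amp[2] * sin(3 * th + ph_[2]) +
                   amp[3] * sin(5 * th + ph_[3])) / sum(amp) * 3
    tissue <- rad <= 1 + wob

    # placement domain: tissue eroded so no structure touches its boundary
    eroded <- EBImage::erode(tissue, EBImage::makeBrush(9, "disc"))
    eroded <- matrix(eroded != 0, h, w)
    centers <- which(eroded)
    if (length(centers) == 0) stop("tissue region is empty", call. = FALSE)

    occupied <- matrix(FALSE, h, w)
    vessel_mask <- matrix(FALSE, h, w)
    gap <- 2

    # large roundish vessels (size-rejected downstream)
    for (i in seq_len(spec$n_vessels)) {
      ab <- runif(2, 59, 72)
      phi <- runif(1, 0, pi)
      idx <- .try_place(centers,
                        function(y, x, g) .ellipse_idx(y, x, ab[1] + g, ab[2] + g, phi, h, w),
                        eroded, occupied, gap, h, w, 400)
      if (is.null(idx)) {
        stop("could not place a vessel inside the tissue; enlarge the image",
             call. = FALSE)
      }
      vessel_mask[idx] <- TRUE; occupied[idx] <- TRUE
    }

    # elongated tears (circularity-rejected downstream)
    for (i in seq_len(spec$n_tears)) {
      a <- runif(1, 120, 180); b <- runif(1, 3, 5)
      phi <- runif(1, 0, pi)
      idx <- .try_place(centers,
                        function(y, x, g) .ellipse_idx(y, x, a + g, b + g, phi, h, w),
                        eroded, occupied, gap, h, w, 400)
      if (is.null(idx)) {
        stop("could not place a tear inside the tissue; enlarge the image",
             call. = FALSE)
      }
      vessel_mask[idx] <- TRUE; occupied[idx] <- TRUE
    }

    # fat vacuoles: resample until the achieved fraction is on target
    fat_mask <- matrix(FALSE, h, w)
    tissue_px <- sum(tissue)
    target_area <- spec$target_fat_fraction * tissue_px
    d_lo <- spec$vacuole_diameter_range[1]
    d_hi <- spec$vacuole_diameter_range[2]
    cur <- 0
    if (target_area > 0) {
      repeat {
        if (cur >= target_area) break
        d_cap <- 2 * spec$pixel_size * sqrt((1.08 * target_area - cur) / pi)
        hi <- min(d_hi, d_cap)
        if (hi < d_lo) break
        d <- runif(1, d_lo, hi)
        r_px <- d / (2 * spec$pixel_size)
        idx <- .try_place(centers,
                          function(y, x, g) .ellipse_idx(y, x, r_px + g, r_px + g, 0, h, w),
                          eroded, occupied, gap, h, w, 300)
        if (is.null(idx)) {
          # crowded: retry with the smallest admissible vacuole before giving up
          r_px <- d_lo / (2 * spec$pixel_size)
          idx <- .try_place(centers,
                            function(y, x, g) .ellipse_idx(y, x, r_px + g, r_px + g, 0, h, w),
                            eroded, occupied, gap, h, w, 300)
          if (is.null(idx)) break
        }
        fat_mask[idx] <- TRUE; occupied[idx] <- TRUE
        cur <- cur + length(idx)
      }
      if (abs(cur / target_area - 1) > 0.10) {
        stop(sprintf(paste0("target fat fraction %.3f unreachable: achieved %.3f; ",
                            "reduce the target or enlarge the image"),
                     spec$target_fat_fraction, cur / tissue_px),
             call. = FALSE)
      }
    }

    # composite the colour image
    img <- array(spec$background_value, dim = c(h, w, 3))
    n_t <- sum(tissue)
    for (ch in 1:3) {
      plane <- img[, , ch]
      vals <- spec$tissue_color_mean[ch] + rnorm(n_t, sd = spec$tissue_color_sd)
      if (ch == 2) vals <- pmin(vals, 219)  # keep tissue below the threshold
      plane[tissue] <- pmin(pmax(vals, 0), 255)
      img[, , ch] <- plane
    }
    bright <- fat_mask | vessel_mask
    n_b <- sum(bright)
    if (n_b > 0) {
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[bright] <- pmin(pmax(250 + rnorm(n_b, sd = 1.5), 240), 255)
        img[, , ch] <- plane
      }
    }
    img <- round(img)

    structure(list(image = img,
                   fat_mask = fat_mask,
                   vessel_mask = vessel_mask,
                   tissue_mask = tissue,
                   true_areal_fat_fraction = sum(fat_mask) / tissue_px,
                   spec = spec),
              class = "histology_phantom")
  })
}

#' @export
print.histology_phantom <- function(x, ...) {
  cat(sprintf("histology phantom %dx%d px: true areal fat fraction %.4f (%d fat / %d tissue px)\n",
              x$spec$width, x$spec$height, x$true_areal_fat_fraction,
              sum(x$fat_mask), sum(x$tissue_mask)))
  invisible(x)
}
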