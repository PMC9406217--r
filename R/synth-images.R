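#' Configuration for synthetic 3-channel fluorescence images
#'
#' Emulates 3D-culture live/dead imaging: a nuclear-stain channel with one
#' blurred disk per nucleus, a live-cell channel with one blob per colony,
#' and a dead-cell channel marking dead colonies. Fragmented nuclei are
#' drawn as a connected chain of 2-4 small disks (each well under 30% of
#' the parent's area) inside the parent footprint; anuclear colonies carry
#' live-channel signal but no nuclear signal. Images receive a Gaussian
#' blur followed by Poisson noise, a minimal realistic fluorescence model.
#'
#' @param size Image side length in pixels (square images).
#' @param n_colonies Number of colonies per image.
#' @param nuclei_rate Mean nuclei per colony (1 + Poisson(`nuclei_rate` -
#'   1)).
#' @param nucleus_area_mean,nucleus_area_sd Lognormal nucleus area moments
#'   in pixels squared.
#' @param frac_fragmented Fraction of nuclei drawn fragmented.
#' @param frac_anuclear Fraction of colonies drawn without nuclei.
#' @param frac_dead Fraction of colonies marked in the dead channel.
#' @param blur_sigma Gaussian blur SD in pixels.
#' @param photon_scale Poisson photon count at intensity 1 (higher = less
#'   noise).
#' @param background Background intensity level.
#' @param seed Integer seed.
#' @return A `synth_image_config` list.
#' @export
synth_image_config <- function(size = 512, n_colonies = 25, nuclei_rate = 5,
                               nucleus_area_mean = 120,
                               nucleus_area_sd = 40,
                               frac_fragmented = 0, frac_anuclear = 0,
                               frac_dead = 0, blur_sigma = 1.2,
                               photon_scale = 300, background = 0.03,
                               seed = 1L) {
  assert_count(size, "size", min = 32)
  assert_count(n_colonies, "n_colonies", min = 0)
  assert_positive(nuclei_rate, "nuclei_rate")
  assert_positive(nucleus_area_mean, "nucleus_area_mean")
  assert_positive(nucleus_area_sd, "nucleus_area_sd")
  assert_fraction(frac_fragmented, "frac_fragmented")
  assert_fraction(frac_anuclear, "frac_anuclear")
  assert_fraction(frac_dead, "frac_dead")
  structure(list(size = as.integer(size), n_colonies = as.integer(n_colonies),
                 nuclei_rate = nuclei_rate,
                 nucleus_area_mean = nucleus_area_mean,
                 nucleus_area_sd = nucleus_area_sd,
                 frac_fragmented = frac_fragmented,
                 frac_anuclear = frac_anuclear, frac_dead = frac_dead,
                 blur_sigma = blur_sigma, photon_scale = photon_scale,
                 background = background, seed = as.integer(seed)),
            class = "synth_image_config")
}

# add a filled disk to a matrix (x = column, y = row coordinates)
draw_disk <- function(mat, cx, cy, r, value) {
  n <- nrow(mat)
  rows <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(ncol(mat), ceiling(cx + r))
  if (!length(rows) || !length(cols)) return(mat)
  dy <- (rows - cy)^2
  dx <- (cols - cx)^2
  hit <- outer(dy, dx, "+") <= r^2
  sub <- mat[rows, cols, drop = FALSE]
  sub[hit] <- pmax(sub[hit], value)
  mat[rows, cols] <- sub
  mat
}

finish_channel <- function(mat, blur_sigma, photon_scale, background) {
  img <- mat + background
  if (blur_sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  }
  noisy <- rpois(length(img), pmax(img, 0) * photon_scale) / photon_scale
  matrix(pmin(noisy, 1), nrow = nrow(mat))
}

#' Generate a synthetic 3-channel image with ground truth
#'
#' @param cfg A [synth_image_config()].
#' @return List with `channels` (matrices `hoechst`, `calcein`, `ethd1` in
#'   \[0, 1\]), `colonies` (truth tibble: position, radius, `n_nuclei`,
#'   `anuclear`, `dead`), and `nuclei` (one row per drawn disk:
#'   `object_id`, `parent_id`, `colony_id`, position, `area`,
#'   `fragmented`).
#' @export
#' @examples
#' img <- generate_images(synth_image_config(size = 128, n_colonies = 3,
#'                                           seed = 1))
#' nrow(img$colonies)
generate_images <- function(cfg) {
  stopifnot(inherits(cfg, "synth_image_config"))
  n <- cfg$size
  with_seed(cfg$seed, {
    hoechst <- calcein <- ethd1 <- matrix(0, n, n)
    sdlog <- sqrt(log(1 + (cfg$nucleus_area_sd / cfg$nucleus_area_mean)^2))
    meanlog <- log(cfg$nucleus_area_mean) - sdlog^2 / 2
    colonies <- list(); nuclei <- list()
    placed <- matrix(numeric(0), ncol = 3)  # x, y, r
    parent_id <- 0L; object_id <- 0L
    for (ci in seq_len(cfg$n_colonies)) {
      n_nuc <- 1L + rpois(1, max(cfg$nuclei_rate - 1, 0))
      anuclear <- runif(1) < cfg$frac_anuclear
      dead <- runif(1) < cfg$frac_dead
      r_col <- max(sqrt(4 * n_nuc * cfg$nucleus_area_mean / pi), 8)
      ok <- FALSE
      for (try in 1:300) {
        cx <- runif(1, r_col + 2, n - r_col - 2)
        cy <- runif(1, r_col + 2, n - r_col - 2)
        if (!nrow(placed) ||
            all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                placed[, 3] + r_col + 4)) { ok <- TRUE; break }
      }
      placed <- rbind(placed, c(cx, cy, r_col))
      calcein <- draw_disk(calcein, cx, cy, r_col, 0.6)
      if (dead) ethd1 <- draw_disk(ethd1, cx, cy, r_col, 0.75)
      n_drawn <- if (anuclear) 0L else n_nuc
      in_col <- matrix(numeric(0), ncol = 3)
      for (ni in seq_len(n_drawn)) {
        area <- rlnorm(1, meanlog, sdlog)
        r_nuc <- sqrt(area / pi)
        for (try in 1:50) {
          ang <- runif(1, 0, 2 * pi)
          rad <- sqrt(runif(1)) * max(r_col - r_nuc - 1, 1)
          nx <- cx + rad * cos(ang); ny <- cy + rad * sin(ang)
          if (!nrow(in_col) ||
              all(sqrt((in_col[, 1] - nx)^2 + (in_col[, 2] - ny)^2) >
                  in_col[, 3] + r_nuc + 1)) break
        }
        in_col <- rbind(in_col, c(nx, ny, r_nuc))
        parent_id <- parent_id + 1L
        fragmented <- runif(1) < cfg$frac_fragmented
        if (!fragmented) {
          object_id <- object_id + 1L
          hoechst <- draw_disk(hoechst, nx, ny, r_nuc, 0.85)
          nuclei[[length(nuclei) + 1L]] <-
            tibble(object_id = object_id, parent_id = parent_id,
                   colony_id = ci, x = nx, y = ny, area = pi * r_nuc^2,
                   fragmented = FALSE)
        } else {
          k <- sample(2:4, 1)
          # fragment disks each ~10% of the parent, total capped below the
          # 30% fragmentation-call threshold so planted truth is recoverable
          fas <- runif(k, 0.08, 0.12) * area
          fas <- fas * min(1, 0.28 * area / sum(fas))
          fx <- nx; fy <- ny; r_prev <- 0
          for (fi in seq_len(k)) {
            fa <- fas[fi]
            fr <- sqrt(fa / pi)
            if (fi > 1) {
              ang <- runif(1, 0, 2 * pi)
              fx <- fx + (r_prev + fr) * 0.6 * cos(ang)
              fy <- fy + (r_prev + fr) * 0.6 * sin(ang)
            }
            object_id <- object_id + 1L
            hoechst <- draw_disk(hoechst, fx, fy, fr, 0.85)
            nuclei[[length(nuclei) + 1L]] <-
              tibble(object_id = object_id, parent_id = parent_id,
                     colony_id = ci, x = fx, y = fy, area = pi * fr^2,
                     fragmented = TRUE)
            r_prev <- fr
          }
        }
      }
      colonies[[ci]] <- tibble(colony_id = ci, x = cx, y = cy,
                               radius = r_col, area = pi * r_col^2,
                               n_nuclei = n_drawn, anuclear = anuclear,
                               dead = dead)
    }
    list(
      channels = list(
        hoechst = finish_channel(hoechst, cfg$blur_sigma, cfg$photon_scale,
                                 cfg$background),
        calcein = finish_channel(calcein, cfg$blur_sigma, cfg$photon_scale,
                                 cfg$background),
        ethd1 = finish_channel(ethd1, cfg$blur_sigma, cfg$photon_scale,
                               cfg$background)
      ),
      colonies = if (length(colonies)) bind_rows(colonies) else
        tibble(colony_id = integer(), x = numeric(), y = numeric(),
               radius = numeric(), area = numeric(), n_nuclei = integer(),
               anuclear = logical(), dead = logical()),
      nuclei = if (length(nuclei)) bind_rows(nuclei) else
        tibble(object_id = integer(), parent_id = integer(),
               colony_id = integer(), x = numeric(), y = numeric(),
               area = numeric(), fragmented = logical())
    )
  })
}

#' Write a 3-channel image stack as 16-bit TIFF
#'
#' Channel order: nuclear stain, live stain, dead stain. Requires the
#' `tiff` package.
#'
#' @param channels Named list of matrices in \[0, 1\] (as produced by
#'   [generate_images()]).
#' @param path Output TIFF path.
#' @export
write_image_stack <- function(channels, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the `tiff` package is required to write TIFF stacks")
  }
  tiff::writeTIFF(channels[c("hoechst", "calcein", "ethd1")], path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Generate the default two-condition 3D-culture morphometry study
#'
#' A vehicle arm and a treated arm of `n_images` images each. The treated
#' arm plants a `fold` increase in mean nuclear area (SD scaled
#' proportionally, so the shape of the lognormal is preserved) and uses
#' slightly fewer colonies per image, emulating a growth-inhibited culture.
#' The defaults give well over 500 nuclei per condition, the scale at which
#' large-sample nuclear-size comparisons are made.
#'
#' @param n_images Images per condition (default 6).
#' @param fold Planted fold change in mean nuclear area (default 2.6).
#' @param vehicle_area_mean,vehicle_area_sd Vehicle nucleus-area lognormal
#'   moments in pixels squared.
#' @param size,n_colonies,nuclei_rate Shared image geometry (defaults 512,
#'   25 colonies, 5 nuclei per colony).
#' @param seed Integer seed; image `i` of condition `c` uses
#'   `seed + 100 * c + i`.
#' @return List with `vehicle` and `treated`, each a list of
#'   [generate_images()] results.
#' @export
generate_morphometry_study <- function(n_images = 6, fold = 2.6,
                                       vehicle_area_mean = 100,
                                       vehicle_area_sd = 30, size = 512,
                                       n_colonies = 25, nuclei_rate = 5,
                                       seed = 1L) {
  arm <- function(area_mean, area_sd, n_col, offset) {
    lapply(seq_len(n_images), function(i) {
      generate_images(synth_image_config(
        size = size, n_colonies = n_col, nuclei_rate = nuclei_rate,
        nucleus_area_mean = area_mean, nucleus_area_sd = area_sd,
        seed = seed + offset + i))
    })
  }
  list(
    vehicle = arm(vehicle_area_mean, vehicle_area_sd, n_colonies, 100L),
    treated = arm(fold * vehicle_area_mean, fold * vehicle_area_sd,
                  max(round(0.75 * n_colonies), 1), 200L)
  )
}
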