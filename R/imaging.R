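label_features <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) {
    return(tibble(label = integer(), x = numeric(), y = numeric(),
                  area = integer()))
  }
  labs <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  tibble(
    label = as.integer(sort(unique(labs))),
    x = as.numeric(tapply(cols, labs, mean)),
    y = as.numeric(tapply(rows, labs, mean)),
    area = as.integer(tapply(labs, labs, length))
  )
}

otsu_mask <- function(img) {
  if (diff(range(img)) < 1e-6) return(NULL)
  x <- EBImage::Image(img)
  th <- EBImage::otsu(x, range = c(0, 1))
  matrix(img > th, nrow = nrow(img))
}

relabel <- function(lab, keep) {
  map <- integer(max(lab, 1))
  map[keep] <- seq_along(keep)
  out <- lab
  out[out > 0] <- map[out[out > 0]]
  out
}

#' Segment colonies from live/dead channels
#'
#' The live-cell channel covers the whole cell body and defines the regions
#' of interest: it is Otsu-binarized and connected components of at least
#' `min_area` pixels become colonies. A colony is called dead when the
#' fraction of its pixels positive in the Otsu-binarized dead-cell channel
#' reaches `dead_overlap` (default 0.5).
#'
#' @param calcein,ethd1 Grayscale matrices in \[0, 1\] of equal shape.
#' @param min_area Minimum colony area in pixels (default 50).
#' @param dead_overlap Dead-channel overlap fraction calling a colony dead
#'   (default 0.5).
#' @return Tibble with `colony_id`, `x`, `y`, `area`, `dead`, `live`; the
#'   colony label matrix is attached as attribute `"labels"`. A blank
#'   live channel yields zero colonies with a warning.
#' @export
segment_colonies <- function(calcein, ethd1, min_area = 50,
                             dead_overlap = 0.5) {
  if (!all(dim(calcein) == dim(ethd1))) {
    abort("channels must have identical dimensions",
          class = "foxscreen_input_error")
  }
  mask <- otsu_mask(calcein)
  if (is.null(mask) || !any(mask)) {
    warn("blank live channel: no colonies segmented")
    out <- tibble(colony_id = integer(), x = numeric(), y = numeric(),
                  area = integer(), dead = logical(), live = logical())
    attr(out, "labels") <- matrix(0L, nrow(calcein), ncol(calcein))
    return(out)
  }
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  feats <- label_features(lab)
  keep <- feats$label[feats$area >= min_area]
  lab <- relabel(lab, keep)
  feats <- filter(feats, .data$label %in% keep) |>
    mutate(colony_id = row_number())
  dmask <- otsu_mask(ethd1)
  dead_frac <- if (is.null(dmask)) rep(0, nrow(feats)) else
    vapply(feats$colony_id, function(i) mean(dmask[lab == i]), numeric(1))
  out <- feats |>
    mutate(dead = dead_frac >= dead_overlap, live = !.data$dead) |>
    select("colony_id", "x", "y", "area", "dead", "live")
  attr(out, "labels") <- lab
  out
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Otsu threshold, then a 3x3 median filter (despeckle), then a
#' distance-transform watershed to split touching nuclei; components of at
#' least `min_area` pixels are kept.
#'
#' @param hoechst Grayscale matrix in \[0, 1\].
#' @param min_area Minimum nucleus area in pixels (default 10).
#' @param despeckle Apply the 3x3 median filter (default TRUE).
#' @param tolerance Watershed intensity tolerance (default 1).
#' @return Tibble with `nucleus_id`, `x`, `y`, `area`; the label matrix is
#'   attached as attribute `"labels"`.
#' @export
#' @examples
#' img <- generate_images(synth_image_config(size = 128, n_colonies = 3,
#'                                           seed = 1))
#' segment_nuclei(img$channels$hoechst)
segment_nuclei <- function(hoechst, min_area = 10, despeckle = TRUE,
                           tolerance = 1) {
  mask <- otsu_mask(hoechst)
  if (is.null(mask) || !any(mask)) {
    out <- tibble(nucleus_id = integer(), x = numeric(), y = numeric(),
                  area = integer())
    attr(out, "labels") <- matrix(0L, nrow(hoechst), ncol(hoechst))
    return(out)
  }
  if (despeckle) {
    sm <- EBImage::medianFilter(EBImage::Image(mask * 1), size = 1)
    mask <- as.matrix(sm) > 0.5
  }
  dm <- EBImage::distmap(EBImage::Image(mask))
  lab <- as.matrix(EBImage::watershed(dm, tolerance = tolerance, ext = 1))
  feats <- label_features(lab)
  keep <- feats$label[feats$area >= min_area]
  lab <- relabel(lab, keep)
  out <- feats |>
    filter(.data$label %in% keep) |>
    mutate(nucleus_id = row_number()) |>
    select("nucleus_id", "x", "y", "area")
  attr(out, "labels") <- lab
  out
}

#' Flag anuclear colonies
#'
#' A colony has a nucleus when at least one nucleus centroid falls inside
#' its mask; the anuclear fraction is reported as a rounded whole percent
#' alongside the raw counts.
#'
#' @param colonies [segment_colonies()] output (with its `"labels"`
#'   attribute).
#' @param nuclei [segment_nuclei()] output.
#' @return List with `colonies` (input plus `has_nucleus`), `n_anuclear`,
#'   `n_colonies`, `percent_anuclear` (whole percent).
#' @export
detect_anuclear <- function(colonies, nuclei) {
  lab <- attr(colonies, "labels")
  if (is.null(lab)) abort("`colonies` lacks its label matrix; pass the segment_colonies() result",
                          class = "foxscreen_input_error")
  hit <- integer(0)
  if (nrow(nuclei)) {
    ri <- pmin(pmax(round(nuclei$y), 1), nrow(lab))
    ci <- pmin(pmax(round(nuclei$x), 1), ncol(lab))
    hit <- unique(lab[cbind(ri, ci)])
    hit <- hit[hit > 0]
  }
  out <- colonies |> mutate(has_nucleus = .data$colony_id %in% hit)
  n_anuc <- sum(!out$has_nucleus)
  list(colonies = out, n_anuclear = n_anuc, n_colonies = nrow(out),
       percent_anuclear = if (nrow(out)) count_percent(n_anuc, nrow(out))
       else NA_real_)
}

#' Flag fragmented nuclei by area against a vehicle reference
#'
#' A nucleus is called fragmented when its area falls below `frag_ratio`
#' (default 0.3) times the median vehicle nucleus area — an operational
#' rule for a call otherwise made by eye. The fraction is reported as a
#' rounded whole percent with the raw counts.
#'
#' @param nuclei Nucleus table (needs an `area` column).
#' @param vehicle_nuclei Vehicle-condition nucleus table (non-empty).
#' @param frag_ratio Area ratio below which a nucleus is fragmented
#'   (default 0.3).
#' @return List with `nuclei` (input plus `fragmented`), `n_fragmented`,
#'   `n_nuclei`, `percent_fragmented`, and the `threshold` used.
#' @export
classify_fragmented <- function(nuclei, vehicle_nuclei, frag_ratio = 0.3) {
  if (!nrow(vehicle_nuclei)) abort("vehicle nucleus set is empty",
                                   class = "foxscreen_input_error")
  thr <- frag_ratio * median(vehicle_nuclei$area)
  out <- nuclei |> mutate(fragmented = .data$area < thr)
  list(nuclei = out, n_fragmented = sum(out$fragmented),
       n_nuclei = nrow(out),
       percent_fragmented = if (nrow(out))
         count_percent(sum(out$fragmented), nrow(out)) else NA_real_,
       threshold = thr)
}

signed_fold <- function(ratio) ifelse(ratio >= 1, ratio, -1 / ratio)

#' Compare object size distributions between conditions
#'
#' Two-sample z-test on mean areas (large-sample normal approximation);
#' with fewer than `min_n` objects in either arm it falls back to a Welch
#' t-test with a warning. The fold change is reported signed: the ratio
#' when at least 1, else minus its reciprocal.
#'
#' @param treated,vehicle Numeric vectors of per-object areas, or tables
#'   with an `area` column.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum arm size for the z-test (default 30).
#' @return One-row tibble: arm sizes and means, `fold`, `signed_fold`,
#'   `statistic`, `p_value`, `test`, `significant`.
#' @export
compare_morphology <- function(treated, vehicle, alpha = 0.05, min_n = 30) {
  if (is.data.frame(treated)) treated <- treated$area
  if (is.data.frame(vehicle)) vehicle <- vehicle$area
  n1 <- length(treated); n2 <- length(vehicle)
  if (n1 < 2 || n2 < 2) abort("need at least 2 objects per arm",
                              class = "foxscreen_input_error")
  m1 <- mean(treated); m2 <- mean(vehicle)
  if (n1 >= min_n && n2 >= min_n) {
    se <- sqrt(sd(treated)^2 / n1 + sd(vehicle)^2 / n2)
    z <- (m1 - m2) / se
    p <- 2 * pnorm(-abs(z))
    test <- "z"; statistic <- z
  } else {
    warn(sprintf("fewer than %d objects in an arm: falling back to Welch t-test",
                 min_n))
    tt <- safe_t_test(treated, vehicle)
    p <- tt$p.value; test <- "t"; statistic <- unname(tt$statistic)
  }
  ratio <- m1 / m2
  tibble(n_treated = n1, n_vehicle = n2, mean_treated = m1,
         mean_vehicle = m2, fold = ratio, signed_fold = signed_fold(ratio),
         statistic = statistic, p_value = p, test = test,
         significant = p < alpha)
}

#' Compare colony counts between conditions
#'
#' Standardized-count z-test for two Poisson counts:
#' `z = (c1 - c2) / sqrt(c1 + c2)`.
#'
#' @param count_treated,count_vehicle Object counts.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble with the counts, `signed_fold`, `statistic`,
#'   `p_value`, `significant`.
#' @export
compare_counts <- function(count_treated, count_vehicle, alpha = 0.05) {
  if (count_treated < 0 || count_vehicle < 0 ||
      count_treated + count_vehicle == 0) {
    abort("counts must be non-negative and not both zero",
          class = "foxscreen_input_error")
  }
  z <- (count_treated - count_vehicle) / sqrt(count_treated + count_vehicle)
  p <- 2 * pnorm(-abs(z))
  tibble(count_treated = count_treated, count_vehicle = count_vehicle,
         signed_fold = signed_fold(count_treated / count_vehicle),
         statistic = z, p_value = p, significant = p < alpha)
}
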