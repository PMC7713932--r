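# Wing colour measurement: modal RGB values over masked wing regions,
# species-level aggregation, and the lightness-independent index.

WING_REGIONS <- c("wing", "cell1", "cell2", "cell3")
COLOR_CHANNELS <- c("total", "red", "green", "blue")

#' Modal value of a colour channel over a masked region
#'
#' The most frequent 8-bit value of the requested channel across the pixels
#' selected by the mask; `"total"` is the per-pixel sum R+G+B (0-765), so its
#' mode is the mode of a genuinely measured quantity rather than a sum of
#' per-channel modes. Ties are broken to the smallest value.
#'
#' @param pixels H x W x 3 integer array (0-255 per channel), or a fixture
#'   from [sim_wing_region()].
#' @param mask Logical H x W matrix; ignored when `pixels` is a fixture that
#'   carries its own mask.
#' @param channel One of `"red"`, `"green"`, `"blue"`, `"total"`.
#' @return Integer mode.
#' @export
mode_channel <- function(pixels, mask = NULL,
                         channel = c("red", "green", "blue", "total")) {
  channel <- match.arg(channel)
  if (is.list(pixels) && !is.null(pixels$pixels)) {
    if (is.null(mask)) mask <- pixels$mask
    pixels <- pixels$pixels
  }
  if (is.null(mask)) mask <- matrix(TRUE, dim(pixels)[1], dim(pixels)[2])
  if (!any(mask)) stop("mask selects no pixels")
  vals <- switch(channel,
    red = pixels[, , 1][mask],
    green = pixels[, , 2][mask],
    blue = pixels[, , 3][mask],
    total = pixels[, , 1][mask] + pixels[, , 2][mask] + pixels[, , 3][mask]
  )
  tab <- table(vals)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)
}

#' Measure one specimen over its wing regions
#'
#' @param pixels H x W x 3 integer array for the specimen photograph.
#' @param masks Named list of logical masks; names must be among
#'   `wing`, `cell1`, `cell2`, `cell3`.
#' @param species Species label the specimen belongs to.
#' @param specimen Optional specimen identifier.
#' @return data.frame with one row per region: species, specimen, region,
#'   mode_R, mode_G, mode_B, mode_total.
#' @export
measure_specimen <- function(pixels, masks, species, specimen = NA_character_) {
  if (!all(names(masks) %in% WING_REGIONS))
    stop("regions must be among: ", paste(WING_REGIONS, collapse = ", "))
  rows <- lapply(names(masks), function(r) {
    data.frame(
      species = species, specimen = specimen, region = r,
      mode_R = mode_channel(pixels, masks[[r]], "red"),
      mode_G = mode_channel(pixels, masks[[r]], "green"),
      mode_B = mode_channel(pixels, masks[[r]], "blue"),
      mode_total = mode_channel(pixels, masks[[r]], "total")
    )
  })
  do.call(rbind, rows)
}

#' Aggregate specimen measurements into a species trait table
#'
#' Species value = arithmetic mean of the specimen modes per trait, rounded
#' to two decimals. Every tree tip must be represented by at least one
#' specimen covering all four regions; the result has one row per tip and
#' the 16 colour traits (4 regions x total/red/green/blue) as columns.
#'
#' @param measurements data.frame as produced by [measure_specimen()]
#'   (rows from many specimens concatenated).
#' @param tips Character vector of tree tip labels the table must cover.
#' @return data.frame with a `species` column and 16 trait columns named
#'   `<region>_<channel>` (e.g. `wing_total`, `cell1_red`).
#' @export
aggregate_species <- function(measurements, tips) {
  keep <- measurements$species %in% tips
  m <- measurements[keep, , drop = FALSE]
  missing <- setdiff(tips, unique(m$species))
  if (length(missing))
    stop("tips with zero specimens: ", paste(missing, collapse = ", "))
  chan_col <- c(total = "mode_total", red = "mode_R", green = "mode_G",
                blue = "mode_B")
  out <- data.frame(species = tips)
  for (r in WING_REGIONS) {
    mr <- m[m$region == r, , drop = FALSE]
    if (!all(tips %in% mr$species))
      stop("region '", r, "' missing for some species")
    for (ch in COLOR_CHANNELS) {
      v <- tapply(mr[[chan_col[[ch]]]], mr$species, mean)
      out[[paste(r, ch, sep = "_")]] <- round(unname(v[tips]), 2)
    }
  }
  rownames(out) <- tips
  out
}

#' Lightness-independent colour index
#'
#' Rapid fluctuation between red and blue and rapid fluctuation in overall
#' lightness can leave the same signature in single-channel rates. To focus
#' on hue, each of the 12 single-channel traits (R, G, B per region) is
#' regressed by ordinary least squares against that region's lightness
#' (defined as `mode_total / 3`) across species, and the residuals are used
#' as lightness-independent traits. Residuals of each fitted trait sum to 0.
#'
#' @param table Species trait table from [aggregate_species()].
#' @return data.frame of 12 residual traits (columns `<region>_<channel>_resid`),
#'   rownames = species.
#' @export
lightness_index <- function(table) {
  if (nrow(table) < 3) stop("need at least 3 species")
  out <- data.frame(row.names = rownames(table))
  for (r in WING_REGIONS) {
    light <- table[[paste0(r, "_total")]] / 3
    if (stats::var(light) == 0)
      stop("constant lightness in region '", r, "'")
    for (ch in c("red", "green", "blue")) {
      y <- table[[paste(r, ch, sep = "_")]]
      out[[paste(r, ch, "resid", sep = "_")]] <-
        unname(stats::residuals(stats::lm(y ~ light)))
    }
  }
  out
}

#' Read a wing image (PNG) as an integer pixel array
#'
#' @param file PNG path.
#' @return H x W x 3 integer array, channels 0-255.
#' @export
read_wing_image <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  arr <- array(as.integer(round(img[, , 1:3] * 255)), dim = c(dim(img)[1:2], 3L))
  arr
}

#' Read a 0/1 PNG region mask
#' @param file PNG path; nonzero pixels are inside the region.
#' @return Logical matrix.
#' @export
read_region_mask <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Write a pixel array as PNG
#' @param pixels H x W x 3 integer array (0-255).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_wing_image <- function(pixels, file) {
  png::writePNG(pixels / 255, file)
  invisible(file)
}
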