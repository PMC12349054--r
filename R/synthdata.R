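#' VesselPhantom: synthetic vascular test image
#'
#' Container for one synthetic phantom: the image (dark branching vessels on
#' a bright, smoothly varying background with additive noise), the binary
#' ground-truth mask, and an echo of the generating configuration (including
#' the seed, so the phantom can be regenerated byte-identically).
#'
#' @slot image `H x W` matrix in `[0, 255]`.
#' @slot mask binary `H x W` matrix (1 = vessel).
#' @slot config list: the generation parameters.
#' @export
setClass("VesselPhantom",
         representation(image = "matrix", mask = "matrix", config = "list"))

setValidity("VesselPhantom", function(object) {
  if (!identical(dim(object@image), dim(object@mask)))
    return("image and mask must have identical dimensions")
  if (!all(object@mask %in% c(0, 1)))
    return("mask must be binary")
  if (!all(is.finite(object@image)))
    return("image must be finite")
  TRUE
})

setMethod("show", "VesselPhantom", function(object) {
  d <- dim(object@image)
  cat(sprintf("VesselPhantom %d x %d, vessel fraction %.3f, seed %d\n",
              d[1], d[2], mean(object@mask), object@config$seed))
})

#' @describeIn VesselPhantom-class image accessor
#' @param x a `VesselPhantom`.
#' @export
phantomImage <- function(x) x@image

#' @describeIn VesselPhantom-class mask accessor
#' @export
phantomMask <- function(x) x@mask

#' Phantom generation parameters
#'
#' Defaults emulate the challenges of fundus vasculature: vessel widths
#' spanning 1-8 px (capillaries to major vessels), low vessel-to-background
#' contrast, smooth illumination heterogeneity and sensor noise.
#'
#' @param size square image edge in pixels (multiple of 8, at least 32).
#' @param nTrees number of vascular trees.
#' @param branchDepth bifurcation levels per tree.
#' @param widthRange `(min, max)` vessel width in pixels at the finest and
#'   coarsest scale.
#' @param tortuosity standard deviation (radians) of the per-step direction
#'   change of the centerline random walk; 0 gives straight vessels.
#' @param vesselContrast fractional intensity drop of a vessel core relative
#'   to full scale, in (0, 1).
#' @param illumAmplitude amplitude (gray levels) of the smooth low-frequency
#'   illumination field added to the background.
#' @param noiseSd standard deviation (gray levels) of the additive Gaussian
#'   noise.
#' @param seed integer seed; equal configurations are byte-identical.
#' @return a named list of parameters.
#' @export
phantomConfig <- function(size = 128L, nTrees = 2L, branchDepth = 4L,
                          widthRange = c(1, 8), tortuosity = 0.15,
                          vesselContrast = 0.45, illumAmplitude = 20,
                          noiseSd = 8, seed = 1L) {
  if (size < 32L || size %% 8L != 0L)
    stop("size must be a multiple of 8 and at least 32")
  if (widthRange[1] < 1) stop("minimum vessel width must be at least 1 px")
  if (vesselContrast <= 0 || vesselContrast >= 1)
    stop("vesselContrast must be in (0, 1)")
  list(size = as.integer(size), nTrees = as.integer(nTrees),
       branchDepth = as.integer(branchDepth), widthRange = widthRange,
       tortuosity = tortuosity, vesselContrast = vesselContrast,
       illumAmplitude = illumAmplitude, noiseSd = noiseSd,
       seed = as.integer(seed))
}

# stamp a disk of diameter w at (r, c) into logical matrix m; the nearest
# pixel is always marked so that unit steps along a centerline produce an
# 8-connected chain even for 1-px vessels
stampDisk <- function(m, r, c, w) {
  rad <- max(w / 2, 0.5)
  ir <- max(1L, floor(r - rad)):min(nrow(m), ceiling(r + rad))
  ic <- max(1L, floor(c - rad)):min(ncol(m), ceiling(c + rad))
  for (j in ic) {
    dj2 <- (j - c)^2
    keep <- ir[(ir - r)^2 + dj2 <= rad^2]
    m[keep, j] <- TRUE
  }
  m[min(max(round(r), 1L), nrow(m)), min(max(round(c), 1L), ncol(m))] <- TRUE
  m
}

# one vascular tree: recursive bifurcating random walk; returns its own mask
# plus the centerline points with widths (used for width measurements)
growTree <- function(size, depth, w0, wmin, tortuosity) {
  mask <- matrix(FALSE, size, size)
  pts <- matrix(numeric(0), 0, 3)  # (row, col, width)
  # start on a border, heading inward
  side <- sample(4L, 1L)
  pos <- switch(side,
                c(1, runif(1, 0.2, 0.8) * size),
                c(size, runif(1, 0.2, 0.8) * size),
                c(runif(1, 0.2, 0.8) * size, 1),
                c(runif(1, 0.2, 0.8) * size, size))
  ang <- switch(side, pi / 2, -pi / 2, 0, pi) + rnorm(1, 0, 0.3)
  segLen <- max(8L, round(size / (depth + 2)))
  # iterative stack instead of recursion
  stack <- list(list(pos = pos, ang = ang, w = w0, level = depth))
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    pos <- nd$pos; ang <- nd$ang; w <- nd$w
    alive <- TRUE
    for (s in seq_len(segLen)) {
      ang <- ang + rnorm(1, 0, tortuosity)
      pos <- pos + c(sin(ang), cos(ang))
      if (any(pos < 1) || any(pos > size)) { alive <- FALSE; break }
      mask <- stampDisk(mask, pos[1], pos[2], w)
      pts <- rbind(pts, c(pos, w))
    }
    if (alive && nd$level > 0L) {
      split <- runif(1, 0.3, 0.7)
      for (sgn in c(-1, 1)) {
        # daughters carry 0.55-0.75 of the parent calibre; a branch may
        # terminate early (p = 0.15), keeping the tree sparse like real
        # vasculature (~10% vessel fraction at the default settings)
        wc <- w * runif(1, 0.55, 0.75)
        if (wc >= wmin && runif(1) < 0.85)
          stack[[length(stack) + 1L]] <-
            list(pos = pos, ang = ang + sgn * split, w = wc,
                 level = nd$level - 1L)
      }
    }
  }
  list(mask = mask, points = pts)
}

#' Generate one vessel phantom
#'
#' Builds recursive branching centerlines (a random walk whose curvature is
#' bounded by `tortuosity`; child branches carry 0.55-0.75 of the parent
#' width), strokes them into a binary tube mask, and renders the image as a
#' bright background plus a smooth low-frequency illumination field, minus a
#' distance-faded dark tube profile scaled by `vesselContrast`, plus
#' Gaussian noise. Deterministic per seed (byte-identical output for equal
#' configurations).
#'
#' @param config a [phantomConfig()] list.
#' @return a [VesselPhantom-class]; when `nTrees = 0` the empty mask is
#'   flagged with a warning and `config$empty = TRUE`.
#' @examples
#' ph <- generatePhantom(phantomConfig(size = 64, seed = 7))
#' mean(phantomMask(ph))
#' @export
generatePhantom <- function(config = phantomConfig()) {
  n <- config$size
  withSeed(config$seed, {
    mask <- matrix(FALSE, n, n)
    trees <- list()
    if (config$nTrees > 0L) {
      for (k in seq_len(config$nTrees)) {
        w0 <- runif(1, 0.6, 1) * config$widthRange[2]
        tr <- growTree(n, config$branchDepth, w0, config$widthRange[1],
                       config$tortuosity)
        trees[[k]] <- tr
        mask <- mask | tr$mask
      }
    } else {
      warning("nTrees = 0: phantom has an empty mask")
      config$empty <- TRUE
    }
    maskNum <- matrix(as.numeric(mask), n, n)
    # smooth illumination: a few broad Gaussian bumps, scaled to amplitude
    illum <- matrix(0, n, n)
    for (k in 1:3) {
      cx <- runif(1, 0.2, 0.8) * n; cy <- runif(1, 0.2, 0.8) * n
      sg <- runif(1, 0.3, 0.6) * n
      g <- outer(seq_len(n), seq_len(n),
                 function(i, j) exp(-((i - cy)^2 + (j - cx)^2) / (2 * sg^2)))
      illum <- illum + (if (k %% 2L) 1 else -1) * g
    }
    if (max(abs(illum)) > 0)
      illum <- illum / max(abs(illum)) * config$illumAmplitude
    profile <- maskNum
    if (any(mask)) {
      profile <- as.matrix(EBImage::gblur(maskNum, sigma = 0.8))
      profile <- profile / max(profile)
    }
    img <- 210 + illum - 255 * config$vesselContrast * profile +
      matrix(rnorm(n * n, 0, config$noiseSd), n, n)
    img <- pmin(pmax(img, 0), 255)
    ph <- methods::new("VesselPhantom", image = img, mask = maskNum,
                       config = config)
    ph@config$centerlines <- lapply(trees, `[[`, "points")
    ph@config$treeMasks <- lapply(trees, `[[`, "mask")
    ph
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom image/mask pairs as 8-bit grayscale PNGs plus a JSON
#' manifest (id, per-phantom seed, configuration). Phantom `i` uses seed
#' `config$seed + i - 1`, so regeneration from the manifest reproduces the
#' files byte for byte.
#'
#' @param n number of phantoms.
#' @param config base [phantomConfig()]; its seed is the base seed.
#' @param outDir output directory (created if missing).
#' @return the manifest, invisibly (a list with `records` and `config`).
#' @export
generateDataset <- function(n, config = phantomConfig(), outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    ph <- generatePhantom(cfg)
    id <- sprintf("phantom_%03d", i)
    png::writePNG(phantomImage(ph) / 255, file.path(outDir, paste0(id, "_image.png")))
    png::writePNG(phantomMask(ph), file.path(outDir, paste0(id, "_mask.png")))
    records[[i]] <- list(id = id, seed = cfg$seed,
                         image = paste0(id, "_image.png"),
                         mask = paste0(id, "_mask.png"))
  }
  manifest <- list(records = records,
                   config = config[setdiff(names(config),
                                           c("centerlines", "treeMasks"))])
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a phantom dataset written by [generateDataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return list of records, each with `id`, `image` (`H x W` matrix in
#'   `[0, 255]`) and binary `mask`.
#' @export
loadDataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(mf$records, function(r) {
    img <- png::readPNG(file.path(dir, r$image)) * 255
    msk <- round(png::readPNG(file.path(dir, r$mask)))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    list(id = r$id, image = img, mask = msk)
  })
}

#' Desk-scale phantom configuration
#'
#' A 64-pixel configuration with tree geometry scaled proportionally from
#' the 128-pixel defaults (half the linear scale: one less bifurcation
#' level, maximum width 5 px, two trees), keeping the vessel fraction near
#' the ~10% typical of fundus imagery. Used for fast end-to-end training
#' runs and examples.
#'
#' @param seed integer seed.
#' @return a [phantomConfig()] list.
#' @export
smallPhantomConfig <- function(seed = 1L) {
  phantomConfig(size = 64L, nTrees = 2L, branchDepth = 3L,
                widthRange = c(1, 5), seed = seed)
}
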