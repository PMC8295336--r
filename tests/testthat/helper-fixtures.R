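# shared small fixtures built in code

# a crop with a dark disk planted on a noiseless background
diskCrop <- function(size = 31, radius = 5, bg = 200, depth = 60) {
  img <- matrix(bg, size, size)
  ctr <- (size + 1) / 2
  for (r in seq_len(size)) for (c in seq_len(size))
    if ((r - ctr)^2 + (c - ctr)^2 <= radius^2) img[r, c] <- bg - depth
  img
}

# rasterized ellipse mask of given pixel area and axis ratio
ellipseMask <- function(area, ratio, size = 41, theta = 0) {
  b <- sqrt(area / (pi * ratio)); a <- ratio * b
  ctr <- (size + 1) / 2
  m <- matrix(FALSE, size, size)
  for (r in seq_len(size)) for (c in seq_len(size)) {
    dx <- c - ctr; dy <- r - ctr
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    if (u^2 + v^2 <= 1) m[r, c] <- TRUE
  }
  m
}

# small labeled crop set for filter/discrimination experiments: the two
# classes differ in the darkness of a planted disk
toyCropClasses <- function(nPerClass = 20, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(depth, id) {
      img <- matrix(rnorm(31 * 31, 200, 2), 31, 31)
      ctr <- 16
      for (r in 1:31) for (c in 1:31)
        if ((r - ctr)^2 + (c - ctr)^2 <= 25) img[r, c] <- img[r, c] - depth
      new("CellCrop", image = img, sourceField = "toy",
          box = c(0L, 0L, 31L, 31L), cellId = id)
    }
    list(wt = lapply(seq_len(nPerClass), function(i)
           mk(40, sprintf("wt_%03d", i))),
         mut = lapply(seq_len(nPerClass), function(i)
           mk(70, sprintf("mut_%03d", i))))
  })
}

# mean noncircularity of rasterized ellipses over random orientations and
# lognormal areas, one value per axis ratio 1..4
meanNcLadder <- function(cfg, n = 60, seed = 77) {
  withr::with_seed(seed, {
    vapply(c(1, 2, 3, 4), function(ratio) {
      mean(replicate(n, {
        a <- max(rlnorm(1, log(30), 0.45), 6)
        m <- ellipseMask(a, ratio, size = 41, theta = runif(1, 0, pi))
        cl <- labelClumps(m, cfg)
        mean(noncircularity(cl$area, cl$perimeter))
      }))
    }, numeric(1))
  })
}

# clump count at the threshold matched to the generator's planted
# darkness: the absolute mid-darkness cut, expressed as the equivalent
# relative tau of the crop. A crop whose intensity range lies entirely
# above the cut (a cell with no planted clumps) has count zero.
matchedClumpCount <- function(fp, params, cfg) {
  img <- bfImage(fp)
  thr <- params@backgroundMean - params@clumpDarkness / 2
  rng <- range(img)
  if (thr <= rng[1]) return(0L)
  tau <- min((thr - rng[1]) / (rng[2] - rng[1]), 1 - 1e-9)
  nrow(labelClumps(binarizeDark(img, tau), cfg))
}
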