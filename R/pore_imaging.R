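#' Micrograph container for pore-structure analysis
#'
#' @param data Numeric matrix of grayscale intensities (0--1 or 0--255;
#'   rescaled to 0--1) or a binary 0/1 matrix.
#' @param pixel_size Physical pixel size in nm/px, or `NA` when unknown
#'   (physical-unit outputs are then omitted).
#' @param source Optional provenance string.
#' @return An object of class `pore_image` (a matrix with attributes).
#' @export
pore_image <- function(data, pixel_size = NA_real_, source = NA_character_) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (max(data) > 1) data <- data / 255
  if (min(data) < 0 || max(data) > 1)
    stop("intensities must lie in [0, 1] or [0, 255]", call. = FALSE)
  structure(data, pixel_size = pixel_size, source = source,
            class = c("pore_image", "matrix", "array"))
}

#' @export
print.pore_image <- function(x, ...) {
  cat("pore_image:", nrow(x), "x", ncol(x), "px")
  ps <- attr(x, "pixel_size")
  if (!is.na(ps)) cat(",", ps, "nm/px")
  cat("; intensity range [", signif(min(x), 3), ",", signif(max(x), 3), "]\n")
  invisible(x)
}

# pad a matrix with a constant border
pad1 <- function(m, value = 0) {
  p <- matrix(value, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  p
}

#' Preprocess a micrograph: contrast stretch and frequency bandpass
#'
#' Mirrors the usual micrograph clean-up before binarization: a
#' histogram-based contrast stretch saturating 0.35\% of pixels at each
#' tail, followed by a radial Butterworth (order 4) bandpass in the
#' frequency domain that suppresses illumination inhomogeneities larger
#' than `band[2]` px and noise finer than `band[1]` px, then an intensity
#' renormalization to \[0, 1\].
#'
#' @param image A [pore_image()].
#' @param band Length-2 numeric: smallest and largest preserved structure
#'   size in px; `band[1]` must be at least 2 px (the Nyquist limit).
#' @param stretch Apply the saturating contrast stretch first.
#' @param renormalize Rescale the result to \[0, 1\]. With
#'   `renormalize = FALSE` the raw zero-mean filter response is returned
#'   as a plain matrix (useful for inspecting the filter itself).
#' @return A filtered [pore_image()]. A constant image is returned
#'   unchanged with a warning.
#' @export
preprocess <- function(image, band = c(3, 40), stretch = TRUE,
                       renormalize = TRUE) {
  if (min(image) == max(image)) {
    warning("constant image: returned unchanged")
    return(image)
  }
  if (band[1] < 2) stop("band[1] below the 2 px Nyquist limit", call. = FALSE)
  if (band[2] <= band[1] || band[2] > nrow(image))
    stop("band must satisfy 2 <= band[1] < band[2] <= image side",
         call. = FALSE)
  m <- unclass(image)
  if (stretch) {
    q <- stats::quantile(m, c(0.0035, 0.9965), names = FALSE)
    if (q[2] > q[1]) m <- pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1)
    dim(m) <- dim(image)
  }
  n <- nrow(m); nc <- ncol(m)
  kx <- c(0:(nc %/% 2), -((nc - (nc %/% 2 + 1)):1)) / nc
  ky <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) / n
  k <- sqrt(outer(ky^2, kx^2, "+"))          # cycles per px
  k_hi <- 1 / band[1]; k_lo <- 1 / band[2]
  H <- (1 / (1 + (k / k_hi)^8)) * ((k / k_lo)^8 / (1 + (k / k_lo)^8))
  filtered <- Re(stats::fft(stats::fft(m) * H, inverse = TRUE)) / (n * nc)
  if (!renormalize) return(filtered)   # raw (zero-mean) filter response
  rng <- range(filtered)
  filtered <- if (rng[2] > rng[1])
    (filtered - rng[1]) / (rng[2] - rng[1]) else filtered - rng[1]
  pore_image(pmin(pmax(filtered, 0), 1), attr(image, "pixel_size"),
             source = attr(image, "source"))
}

#' Maximum-entropy (Kapur) threshold of a grayscale image
#'
#' Binarizes a micrograph at the threshold maximizing the sum of Shannon
#' entropies of the foreground and background gray-level populations over
#' a 256-bin histogram (Kapur's criterion); ties break toward the lower
#' threshold. The returned binary image is 1 where the selected pore phase
#' lies: by default the dark phase, matching the contrast of cryo-SEM
#' micrographs where pores image darker than the polymer walls.
#'
#' @param image A [pore_image()] with at least 2 distinct gray levels.
#' @param pore One of `"dark"`, `"bright"`: which phase is the pore phase.
#' @return A binary [pore_image()] (0/1) with attributes `threshold`
#'   (gray-level bin, 0--255) and `pore`.
#' @export
threshold_maxentropy <- function(image, pore = c("dark", "bright")) {
  pore <- match.arg(pore)
  bins <- pmin(floor(unclass(image) * 256), 255)
  h <- tabulate(as.vector(bins) + 1L, nbins = 256)
  if (sum(h > 0) < 2) stop("image has fewer than 2 gray levels",
                           call. = FALSE)
  p <- h / sum(h)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p); S0 <- cumsum(plogp)
  P1 <- 1 - P0; S1 <- sum(plogp) - S0
  t_idx <- seq_len(255)                      # threshold after bin t (0-based t-1)
  valid <- P0[t_idx] > 0 & P1[t_idx] > 0
  psi <- rep(-Inf, 255)
  psi[valid] <- (log(P0[t_idx]) - S0[t_idx] / P0[t_idx])[valid] +
    (log(P1[t_idx]) - S1[t_idx] / P1[t_idx])[valid]
  thr <- which.max(psi) - 1L                 # gray level: background <= thr
  binary <- if (pore == "dark") (bins <= thr) * 1 else (bins > thr) * 1
  dim(binary) <- dim(image)
  out <- pore_image(binary, attr(image, "pixel_size"),
                    source = attr(image, "source"))
  attr(out, "threshold") <- thr
  attr(out, "pore") <- pore
  out
}

# 8-connected labeling of a binary matrix via pixel-adjacency graph
label_components <- function(binary) {
  n <- nrow(binary); nc <- ncol(binary)
  fg <- which(binary > 0)
  labels <- matrix(0L, n, nc)
  if (length(fg) == 0) return(labels)
  id <- integer(n * nc); id[fg] <- seq_along(fg)
  row_i <- ((fg - 1L) %% n) + 1L
  col_i <- ((fg - 1L) %/% n) + 1L
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    r2 <- row_i + s[1]; c2 <- col_i + s[2]
    ok <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * n + r2[ok]
    both <- id[nb] > 0L
    edges[[length(edges) + 1]] <-
      cbind(id[fg[ok]][both], id[nb][both])
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  labels[fg] <- comp[seq_along(fg)]
  labels
}

# crack-length perimeter with diagonal corner correction, per component crop
perimeter_crack <- function(mask) {
  m <- pad1(mask * 1)
  nr <- nrow(m); ncl <- ncol(m)
  inner_r <- 2:(nr - 1); inner_c <- 2:(ncl - 1)
  core <- m[inner_r, inner_c]
  e <- sum(core & !m[inner_r - 1, inner_c]) +
       sum(core & !m[inner_r + 1, inner_c]) +
       sum(core & !m[inner_r, inner_c - 1]) +
       sum(core & !m[inner_r, inner_c + 1])
  # 2x2 window census for corner configurations
  a <- m[1:(nr - 1), 1:(ncl - 1)]; b <- m[2:nr, 1:(ncl - 1)]
  cc <- m[1:(nr - 1), 2:ncl]; d <- m[2:nr, 2:ncl]
  s <- a + b + cc + d
  n1 <- sum(s == 1); n3 <- sum(s == 3)
  nd <- sum(s == 2 & ((a == 1 & d == 1) | (b == 1 & cc == 1)))
  e - (2 - sqrt(2)) * (n1 + n3 + 2 * nd)
}

#' Pore segmentation and per-pore statistics
#'
#' Labels 8-connected foreground (pore) components, optionally splitting
#' touching pores with a distance-transform watershed, discards components
#' below `min_area_px`, and reports per-pore area and perimeter in pixels
#' and (when the pixel size is known) physical units. The perimeter is a
#' crack-length estimator with a diagonal corner correction; perimeter
#' definitions differ across image-analysis tools, so absolute values
#' should only be compared within one tool.
#'
#' @param binary A binary [pore_image()] (1 = pore phase).
#' @param use_watershed Split touching pores along ridges of the distance
#'   transform before measuring.
#' @param min_area_px Discard components smaller than this (default 4 px,
#'   suppressing single-pixel noise).
#' @return An object of class `pore_stats`: a list with `table` (columns
#'   `id`, `area_px2`, `perimeter_px` and, with known pixel size,
#'   `area_nm2`, `perimeter_nm`), `count` and `summary` (five-number
#'   summary plus mean of the areas).
#' @export
analyze_pores <- function(binary, use_watershed = FALSE, min_area_px = 4) {
  if (!all(unclass(binary) %in% c(0, 1)))
    stop("`binary` must be a 0/1 image", call. = FALSE)
  ps <- attr(binary, "pixel_size")
  m <- unclass(binary)
  if (sum(m) == 0) {
    warning("empty foreground: no pores")
    tab <- data.frame(id = integer(0), area_px2 = numeric(0),
                      perimeter_px = numeric(0))
    return(structure(list(table = tab, count = 0L, summary = NULL),
                     class = "pore_stats"))
  }
  labels <- if (use_watershed) {
    dm <- EBImage::distmap(EBImage::Image(m))
    ws <- EBImage::watershed(dm)
    matrix(as.integer(EBImage::imageData(ws)), nrow(m), ncol(m))
  } else {
    label_components(m)
  }
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0) {
    warning("no components at or above min_area_px = ", min_area_px)
    tab <- data.frame(id = integer(0), area_px2 = numeric(0),
                      perimeter_px = numeric(0))
    return(structure(list(table = tab, count = 0L, summary = NULL),
                     class = "pore_stats"))
  }
  rows <- lapply(seq_along(keep), function(i) {
    l <- keep[i]
    idx <- which(labels == l)
    ri <- range(((idx - 1L) %% nrow(m)) + 1L)
    ci <- range(((idx - 1L) %/% nrow(m)) + 1L)
    crop <- (labels[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE] == l)
    data.frame(id = i, area_px2 = areas[l],
               perimeter_px = perimeter_crack(crop))
  })
  tab <- do.call(rbind, rows)
  if (!is.na(ps)) {
    tab$area_nm2 <- tab$area_px2 * ps^2
    tab$perimeter_nm <- tab$perimeter_px * ps
  }
  structure(list(table = tab, count = nrow(tab),
                 summary = summarize(tab$area_px2)),
            class = "pore_stats")
}

#' @export
print.pore_stats <- function(x, ...) {
  cat("Pore statistics:", x$count, "pores\n")
  if (x$count > 0) {
    cat("  area (px^2): ")
    print(unlist(x$summary))
  }
  invisible(x)
}

# Zhang-Suen topology-preserving thinning of a binary matrix
thin_zhang_suen <- function(m) {
  m <- m * 1
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad1(m)
      nr <- nrow(p); ncl <- ncol(p)
      ir <- 2:(nr - 1); ic <- 2:(ncl - 1)
      p2 <- p[ir - 1, ic];     p3 <- p[ir - 1, ic + 1]
      p4 <- p[ir, ic + 1];     p5 <- p[ir + 1, ic + 1]
      p6 <- p[ir + 1, ic];     p7 <- p[ir + 1, ic - 1]
      p8 <- p[ir, ic - 1];     p9 <- p[ir - 1, ic - 1]
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Skeletonize a binary image and measure its branches
#'
#' Thins the foreground to a one-pixel-wide, topology-preserving medial
#' axis (Zhang--Suen thinning), classifies skeleton pixels by their
#' 8-neighbor count (endpoint = 1, slab = 2, junction >= 3), groups
#' adjacent junction pixels into junctions, and traces branches between
#' endpoints/junctions. Branch length is the 8-connected path length with
#' \eqn{\sqrt 2} diagonal steps, reported in px and (when the pixel size
#' is known) nm.
#'
#' @param binary A binary [pore_image()] (1 = network phase to be
#'   skeletonized).
#' @return An object of class `skeleton_stats`: list with `branches`
#'   (columns `branch_id`, `length_px`, `type` and optionally
#'   `length_nm`), `branch_count`, `junction_count`, `endpoint_count`,
#'   `skeleton` (binary matrix) and `summary` of branch lengths.
#' @export
analyze_skeleton <- function(binary) {
  if (!all(unclass(binary) %in% c(0, 1)))
    stop("`binary` must be a 0/1 image", call. = FALSE)
  ps <- attr(binary, "pixel_size")
  m <- unclass(binary) * 1
  empty <- structure(list(
    branches = data.frame(branch_id = integer(0), length_px = numeric(0),
                          type = character(0)),
    branch_count = 0L, junction_count = 0L, endpoint_count = 0L,
    skeleton = m, summary = NULL), class = "skeleton_stats")
  if (sum(m) == 0) return(empty)
  skel <- thin_zhang_suen(m)
  if (all(skel == m)) {
    warning("foreground is everywhere thinner than 2 px: skeleton equals input")
  }
  p <- pad1(skel)
  nr <- nrow(p); ncl <- ncol(p)
  ir <- 2:(nr - 1); ic <- 2:(ncl - 1)
  nb <- p[ir - 1, ic] + p[ir - 1, ic + 1] + p[ir, ic + 1] +
    p[ir + 1, ic + 1] + p[ir + 1, ic] + p[ir + 1, ic - 1] +
    p[ir, ic - 1] + p[ir - 1, ic - 1]
  is_skel <- skel == 1
  endpoint <- is_skel & nb == 1
  junction <- is_skel & nb >= 3
  # junctions: clusters of adjacent junction pixels
  jlab <- label_components(junction * 1)
  junction_count <- max(jlab)
  endpoint_count <- sum(endpoint)
  # branches: components of the skeleton with junction pixels removed
  seg <- is_skel & !junction
  slab <- label_components(seg * 1)
  nseg <- max(slab)
  if (nseg == 0) return_branches <- NULL
  n <- nrow(skel)
  edge_weight <- function(i1, i2) {
    r1 <- ((i1 - 1) %% n) + 1; c1 <- ((i1 - 1) %/% n) + 1
    r2 <- ((i2 - 1) %% n) + 1; c2 <- ((i2 - 1) %/% n) + 1
    ifelse(abs(r1 - r2) + abs(c1 - c2) == 2, sqrt(2), 1)
  }
  neighbors8 <- function(idx) {
    r <- ((idx - 1) %% n) + 1; cl <- ((idx - 1) %/% n) + 1
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
    rr <- r + dr; cc <- cl + dc
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= ncol(skel)
    (cc[ok] - 1) * n + rr[ok]
  }
  branches <- vector("list", nseg)
  for (b in seq_len(nseg)) {
    idx <- which(slab == b)
    len <- 0
    if (length(idx) > 1) {
      # path length inside the segment: sum of adjacency weights along it
      for (i in idx) {
        nbs <- neighbors8(i)
        nbs <- nbs[slab[nbs] == b & nbs > i]
        if (length(nbs)) len <- len + sum(edge_weight(i, nbs))
      }
    }
    # connections from segment ends to adjacent junction clusters
    touching <- integer(0)
    for (i in idx) {
      nbs <- neighbors8(i)
      jn <- nbs[junction[nbs]]
      if (length(jn)) {
        len <- len + min(edge_weight(i, jn))
        touching <- c(touching, unique(jlab[jn]))
      }
    }
    n_j <- length(unique(touching))
    n_e <- sum(endpoint[idx])
    type <- if (n_j >= 2) "junction-junction"
      else if (n_j == 1 && n_e >= 1) "junction-endpoint"
      else if (n_e >= 2) "endpoint-endpoint"
      else if (n_j == 1) "junction-junction"   # short spur looping to one junction
      else "loop"
    branches[[b]] <- data.frame(branch_id = b, length_px = len, type = type)
  }
  btab <- if (nseg > 0) do.call(rbind, branches) else empty$branches
  if (!is.na(ps) && nrow(btab) > 0) btab$length_nm <- btab$length_px * ps
  structure(list(branches = btab, branch_count = nrow(btab),
                 junction_count = junction_count,
                 endpoint_count = endpoint_count, skeleton = skel,
                 summary = if (nrow(btab) > 0) summarize(btab$length_px)),
            class = "skeleton_stats")
}

#' @export
print.skeleton_stats <- function(x, ...) {
  cat("Skeleton:", x$branch_count, "branches,", x$junction_count,
      "junctions,", x$endpoint_count, "endpoints\n")
  if (x$branch_count > 0) {
    cat("  branch length (px): ")
    print(unlist(x$summary))
  }
  invisible(x)
}

#' Box-plot summary of a set of observations
#'
#' Five-number summary (min, lower quartile, median, upper quartile, max)
#' plus the mean; quartiles use linear interpolation between order
#' statistics.
#'
#' @param x Numeric vector with at least one observation.
#' @return Named list with `min`, `q1`, `median`, `q3`, `max`, `mean`.
#' @examples
#' summarize(1:5)
#' @export
summarize <- function(x) {
  if (length(x) < 1) stop("need at least one observation", call. = FALSE)
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
       mean = mean(x))
}
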