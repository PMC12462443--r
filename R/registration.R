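#' Rigid 2-D transform
#'
#' Rotation (degrees, counter-clockwise about `center`) followed by a
#' translation in pixels: `T(x) = R (x - c) + c + t`. Pixel centres sit at
#' integer coordinates (origin top-left, first pixel at (1,1)).
#'
#' @param rotation Rotation angle, degrees.
#' @param translation Numeric pair `(dx, dy)`, pixels.
#' @param center Rotation centre `(cx, cy)`, pixels.
#' @return An object of class `rigid2d`.
#' @export
rigid2d <- function(rotation = 0, translation = c(0, 0), center = c(0, 0)) {
  stop_if(!is_number(rotation) || length(translation) != 2 ||
            length(center) != 2, "invalid rigid transform")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 center = as.numeric(center)), class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("<rigid2d> rotation %.3f deg, translation (%.3f, %.3f) px\n",
              x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

## 3x3 homogeneous matrix of a rigid2d (x = column 1, y = column 2)
rigid2d_matrix <- function(tf) {
  a <- tf$rotation * pi / 180
  R <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
  t <- tf$center + tf$translation - R %*% tf$center
  rbind(cbind(R, t), c(0, 0, 1))
}

## rigid2d from a 3x3 homogeneous matrix (center folded into translation)
rigid2d_from_matrix <- function(M) {
  rot <- atan2(M[2, 1], M[1, 1]) * 180 / pi
  rigid2d(rotation = rot, translation = M[1:2, 3], center = c(0, 0))
}

#' Invert a rigid 2-D transform
#' @param tf A [rigid2d()].
#' @return The inverse [rigid2d()].
#' @export
rigid2d_invert <- function(tf) rigid2d_from_matrix(solve(rigid2d_matrix(tf)))

#' Compose a chain of rigid 2-D transforms
#'
#' Sequential application `T = T_n o ... o T_2 o T_1` (first element
#' applied first), collapsing a multi-step coregistration chain (e.g.
#' fluorescence -> angiography -> anatomical -> functional) into a single
#' transform.
#'
#' @param transforms Nonempty list of [rigid2d()] objects.
#' @return A single [rigid2d()].
#' @export
compose_chain <- function(transforms) {
  stop_if(length(transforms) == 0, "empty transform list")
  M <- diag(3)
  for (tf in transforms) M <- rigid2d_matrix(tf) %*% M
  rigid2d_from_matrix(M)
}

## bilinear sampling of matrix img at continuous (row, col) coordinates;
## outside -> fill
sample_bilinear <- function(img, ri, ci, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(ri))
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  r0 <- pmin(floor(ri[ok]), nr - 1L); c0 <- pmin(floor(ci[ok]), nc - 1L)
  if (nr == 1L) r0 <- rep(1, sum(ok))
  if (nc == 1L) c0 <- rep(1, sum(ok))
  fr <- ri[ok] - r0; fc <- ci[ok] - c0
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  out[ok] <- (1 - fr) * ((1 - fc) * img[cbind(r0, c0)] +
                           fc * img[cbind(r0, c1)]) +
    fr * ((1 - fc) * img[cbind(r1, c0)] + fc * img[cbind(r1, c1)])
  out
}

#' Apply a rigid 2-D transform to an image
#'
#' Moves the image content by the transform: `out(x) = in(T^{-1}(x))`,
#' bilinear interpolation, zero fill outside. Coordinates are (x, y) =
#' (column, row).
#'
#' @param img Numeric matrix.
#' @param tf A [rigid2d()].
#' @return Transformed matrix of the same size.
#' @export
apply_rigid2d <- function(img, tf) {
  Minv <- solve(rigid2d_matrix(tf))
  g <- expand.grid(r = seq_len(nrow(img)), c = seq_len(ncol(img)))
  src <- Minv %*% rbind(g$c, g$r, 1)
  matrix(sample_bilinear(img, src[2, ], src[1, ]), nrow(img), ncol(img))
}

#' Mutual information between two images
#'
#' Shannon mutual information (bits) of the joint intensity distribution,
#' estimated from a joint histogram with `bins` levels per image after
#' min-max scaling, using linear (partial-volume) bin assignment.
#' Symmetric and non-negative; a constant image carries no information and
#' returns 0 with a warning.
#'
#' @param a,b Numeric matrices of equal size.
#' @param bins Histogram bins per image (>= 2, default 32).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(a, b, bins = 32) {
  stop_if(!all(dim(a) == dim(b)), "image shapes differ")
  stop_if(!is_number(bins) || bins < 2, "`bins` must be >= 2")
  H <- joint_histogram(a, b, bins)
  if (is.null(H)) {
    warning("constant image: mutual information is 0", call. = FALSE)
    return(0)
  }
  mi_from_hist(H)
}

## joint partial-volume histogram; NULL if either image is constant
joint_histogram <- function(a, b, bins) {
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) return(NULL)
  va <- (a - ra[1]) / (ra[2] - ra[1]) * (bins - 1)
  vb <- (b - rb[1]) / (rb[2] - rb[1]) * (bins - 1)
  a0 <- pmin(floor(va), bins - 2); fa <- va - a0
  b0 <- pmin(floor(vb), bins - 2); fb <- vb - b0
  H <- numeric(bins * bins)
  acc <- function(i, j, w) {
    idx <- as.vector(i + 1 + j * bins)
    s <- rowsum(as.vector(w), idx)
    H[as.integer(rownames(s))] <<- H[as.integer(rownames(s))] + s
    invisible(NULL)
  }
  acc(a0,     b0,     (1 - fa) * (1 - fb))
  acc(a0 + 1, b0,     fa * (1 - fb))
  acc(a0,     b0 + 1, (1 - fa) * fb)
  acc(a0 + 1, b0 + 1, fa * fb)
  matrix(H, bins, bins)
}

mi_from_hist <- function(H) {
  P <- H / sum(H)
  px <- rowSums(P); py <- colSums(P)
  nz <- P > 0
  sum(P[nz] * log2(P[nz] / (px[row(P)[nz]] * py[col(P)[nz]])))
}

#' Rigid 2-D registration by mutual-information maximization
#'
#' Deterministic coarse-to-fine pattern search over rotation and
#' translation: starting from `init`, the (rotation, dx, dy) neighbourhood
#' is explored on a step grid, moving greedily to the best improvement and
#' halving the steps when none remains, down to a 0.05 px / 0.02 deg
#' resolution. The cost is the mutual information between `fixed` and the
#' transformed `moving` image.
#'
#' @param moving,fixed Numeric matrices of equal size.
#' @param init Starting [rigid2d()] (default identity about the image
#'   centre).
#' @param bins Histogram bins for the MI estimate.
#' @param step_px,step_deg Initial search steps.
#' @param min_step_px,min_step_deg Final resolution.
#' @return The estimated [rigid2d()] mapping `moving` onto `fixed`, with
#'   attributes `mi` (final value) and `improved` (FALSE if the search
#'   never left `init`).
#' @export
mi_register_2d <- function(moving, fixed, init = NULL, bins = 32,
                           step_px = 4, step_deg = 2,
                           min_step_px = 0.05, min_step_deg = 0.02) {
  stop_if(!all(dim(moving) == dim(fixed)), "image shapes differ")
  ctr <- c(ncol(moving), nrow(moving)) / 2
  if (is.null(init)) init <- rigid2d(center = ctr)
  par <- c(init$rotation, init$translation)
  score <- function(p)
    mutual_information(apply_rigid2d(moving, rigid2d(p[1], p[2:3], ctr)),
                       fixed, bins)
  best <- score(par)
  init_score <- best
  step <- c(step_deg, step_px, step_px)
  minstep <- c(min_step_deg, min_step_px, min_step_px)
  while (TRUE) {
    moved <- FALSE
    for (k in 1:3) for (s in c(-1, 1)) {
      cand <- par; cand[k] <- cand[k] + s * step[k]
      sc <- score(cand)
      if (sc > best + 1e-12) { par <- cand; best <- sc; moved <- TRUE }
    }
    if (!moved) {
      if (all(step <= minstep)) break
      step <- pmax(step / 2, minstep)
    }
  }
  out <- rigid2d(par[1], par[2:3], ctr)
  attr(out, "mi") <- best
  attr(out, "improved") <- best > init_score + 1e-12
  out
}

#' Shared-vasculature registration phantoms
#'
#' Renders one synthetic cortical vessel tree (random-walk branches plus a
#' brain outline and midline) into two contrasts: a fluorescence-like image
#' (bright vessels, mild vignetting) and an angiography-like image
#' (saturating vessel contrast, smooth background, stronger blur), related
#' by a known rigid transform. The true transform maps the fluorescence
#' frame into the angiography frame.
#'
#' @param seed Integer seed for the vessel tree.
#' @param rotation True rotation, degrees.
#' @param translation True translation `(dx, dy)`, pixels.
#' @param size Image side, pixels.
#' @param n_branches Number of vessel branches.
#' @return List: `fl` (matrix), `mra` (matrix), `true_transform`
#'   ([rigid2d()] about the image centre).
#' @export
make_registration_phantoms <- function(seed = 1, rotation = 0,
                                       translation = c(0, 0), size = 128,
                                       n_branches = 14) {
  with_seed(seed, {
    canvas <- matrix(0, size, size)
    ctr <- size / 2
    ## brain outline: soft ellipse ring + midline
    g <- expand.grid(r = seq_len(size), c = seq_len(size))
    el <- ((g$c - ctr) / (0.42 * size))^2 + ((g$r - ctr) / (0.46 * size))^2
    ring <- exp(-((el - 1) / 0.02)^2)
    canvas <- canvas + matrix(ring, size, size) * 0.5
    mid <- exp(-((g$c - ctr) / 1.5)^2) * (abs(g$r - ctr) < 0.4 * size)
    canvas <- canvas + matrix(mid, size, size) * 0.35
    ## vessel branches: correlated random walks from near the midline
    for (b in seq_len(n_branches)) {
      r <- ctr + stats::runif(1, -0.3, 0.3) * size
      c <- ctr + stats::runif(1, -0.1, 0.1) * size
      ang <- stats::runif(1, 0, 2 * pi)
      w <- stats::runif(1, 0.8, 1.6)
      for (s in seq_len(round(0.45 * size))) {
        ang <- ang + stats::rnorm(1, 0, 0.25)
        r <- r + sin(ang); c <- c + cos(ang)
        if (r < 2 || r > size - 1 || c < 2 || c > size - 1) break
        rr <- round(r); cc <- round(c)
        canvas[rr, cc] <- canvas[rr, cc] + w
      }
    }
    vessels <- blur2d(canvas, 0.8)
    vessels <- vessels / max(vessels)
    fl <- vessels + 0.05 * matrix(el, size, size)  # mild vignetting field
    tf <- rigid2d(rotation, translation, center = c(ctr, ctr))
    mra_src <- 0.2 + 0.8 * tanh(3 * vessels)       # saturating contrast
    mra <- apply_rigid2d(blur2d(mra_src, 1.2), tf)
    list(fl = fl, mra = mra, true_transform = tf)
  })
}

#' Project atlas labels through cortical layers
#'
#' Collapses a 3-D layered atlas to a 2-D surface template: each surface
#' pixel takes the majority region label among the voxels of its depth
#' column whose layer index is in `layers` (default 1-4, the superficial
#' layers visible to widefield fluorescence). Deep-layer voxels never
#' contribute; ties go to the lowest label id; columns with no voxel in the
#' requested layers get label 0.
#'
#' @param atlas An [make_mini_atlas()] object.
#' @param layers Integer set of cortical layers to project.
#' @return Object of class `atlas_template`: `labels` (matrix x, y) and
#'   `region_names`.
#' @export
project_atlas_layers <- function(atlas, layers = 1:4) {
  stopifnot(inherits(atlas, "atlas_volume"))
  d <- dim(atlas$labels)
  out <- matrix(0L, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    sel <- atlas$layer[i, j, ] %in% layers & atlas$labels[i, j, ] > 0
    if (!any(sel)) next
    tab <- table(atlas$labels[i, j, sel])
    top <- tab[tab == max(tab)]
    out[i, j] <- min(as.integer(names(top)))
  }
  structure(list(labels = out, region_names = atlas$region_names),
            class = "atlas_template")
}

#' Extract an ROI time course
#'
#' Spatial mean inside a cubic (volume) or square (stack) region of
#' interest per time point. Membership is computed in world coordinates
#' with half-open bounds `[center - size/2, center + size/2)`; voxel/pixel
#' centres sit at `(index - 0.5) * spacing`.
#'
#' @param data A [volume4d()] or [image_stack()].
#' @param center World centre: mm triple for volumes, mm pair (x, y) for
#'   stacks.
#' @param size_mm Side of the ROI cube/square, mm (default 0.6).
#' @return A [trace_set()] (`fs = 1/tr` or the frame rate); attribute
#'   `n_voxels` gives the ROI size.
#' @export
extract_roi_timecourse <- function(data, center, size_mm = 0.6) {
  half <- size_mm / 2
  if (inherits(data, "volume4d")) {
    d <- dim(data$data)
    sel <- lapply(1:3, function(k) {
      cc <- (seq_len(d[k]) - 0.5) * data$voxel[k]
      which(cc >= center[k] - half & cc < center[k] + half)
    })
    stop_if(any(vapply(sel, length, 0L) == 0) ||
              any(center < 0) || any(center > volume_extent(data)),
            "ROI outside the lattice")
    sub <- data$data[sel[[1]], sel[[2]], sel[[3]], , drop = FALSE]
    out <- trace_set(apply(sub, 4, mean), fs = 1 / data$tr, channel = "ROI",
                     t0 = data$t0 %||% 0)
    attr(out, "n_voxels") <- prod(dim(sub)[1:3])
    out
  } else if (inherits(data, "image_stack")) {
    d <- dim(data$frames)
    pitch_mm <- data$pixel_pitch / 1000
    cx <- (seq_len(d[2]) - 0.5) * pitch_mm   # x = columns
    cy <- (seq_len(d[1]) - 0.5) * pitch_mm   # y = rows
    jx <- which(cx >= center[1] - half & cx < center[1] + half)
    iy <- which(cy >= center[2] - half & cy < center[2] + half)
    stop_if(length(jx) == 0 || length(iy) == 0 ||
              any(center < 0) || center[1] > d[2] * pitch_mm ||
              center[2] > d[1] * pitch_mm,
            "ROI outside the image")
    sub <- data$frames[iy, jx, , drop = FALSE]
    out <- trace_set(apply(sub, 3, mean), fs = data$frame_rate,
                     channel = paste0(data$channel, "-ROI"))
    attr(out, "n_voxels") <- length(iy) * length(jx)
    out
  } else stop("unsupported data type", call. = FALSE)
}
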