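#' 9-parameter affine transform (translation, rotation, anisotropic scale)
#'
#' Maps world coordinates `x` (mm, template space) to
#' `y = center + R S (x - center) + t`, where `R = Rz Ry Rx` is built from
#' the rotation angles in degrees and `S = diag(scale)`. Exactly 9 free
#' parameters; the rotation centre is fixed metadata, not optimized.
#'
#' @param translation length-3 translation in mm.
#' @param rotation length-3 rotation in degrees (applied as `Rz Ry Rx`).
#' @param scale length-3 positive scale factors.
#' @param center rotation/scaling centre in world mm.
#' @return An object of class `ct_affine`.
#' @export
affine_transform <- function(translation = c(0, 0, 0),
                             rotation = c(0, 0, 0),
                             scale = c(1, 1, 1),
                             center = c(0, 0, 0)) {
  scale <- rep_len(as.numeric(scale), 3L)
  if (any(scale <= 0)) stop("scales must be positive")
  structure(list(translation = rep_len(as.numeric(translation), 3L),
                 rotation = rep_len(as.numeric(rotation), 3L),
                 scale = scale, center = rep_len(as.numeric(center), 3L)),
            class = "ct_affine")
}

#' @export
print.ct_affine <- function(x, ...) {
  cat(sprintf(paste0("<ct_affine> t = (%s) mm, rot = (%s) deg, ",
                     "scale = (%s)\n"),
              paste(format(x$translation, digits = 3), collapse = ", "),
              paste(format(x$rotation, digits = 3), collapse = ", "),
              paste(format(x$scale, digits = 4), collapse = ", ")))
  invisible(x)
}

#' 4x4 homogeneous matrix of an affine transform
#' @param tf a `ct_affine`.
#' @return 4x4 matrix acting on homogeneous world coordinates.
#' @export
affine_matrix <- function(tf) {
  R <- rotation_matrix(tf$rotation)
  A <- R %*% diag(tf$scale)
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- tf$center - A %*% tf$center + tf$translation
  M
}

# internal optimizer parameterization: scales on the log axis so the
# positivity constraint is built in
params_to_affine <- function(p, center) {
  affine_transform(p[1:3], p[4:6], exp(p[7:9]), center)
}

mask_centroid_world <- function(vol) {
  idx <- which(vol$data != 0)
  if (length(idx) == 0) stop("mask is empty")
  d <- dim(vol$data)
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  c(mean(i) * vol$spacing[1] + vol$origin[1],
    mean(j) * vol$spacing[2] + vol$origin[2],
    mean(k) * vol$spacing[3] + vol$origin[3])
}

resample_to_grid <- function(vol, dst_dim, dst_spacing, dst_origin, A,
                             disp = NULL, method = "linear", fill = 0) {
  dd <- if (is.null(disp)) numeric(0) else disp$field
  ds <- if (is.null(disp)) c(1, 1, 1) else disp$spacing
  do <- if (is.null(disp)) c(0, 0, 0) else disp$origin
  mcode <- switch(method, nearest = 0L, linear = 1L, cubic = 2L,
                  stop("unknown interpolation: ", method))
  out <- .cq_resample(vol$data * 1.0, vol$spacing, vol$origin,
                      as.integer(dst_dim), dst_spacing, dst_origin,
                      A, dd, ds, do, mcode, fill)
  ct_volume(out, dst_spacing, dst_origin)
}

# crop a volume to the bounding box of its support (values > eps), with a
# voxel margin; keeps world coordinates consistent via the origin
crop_to_support <- function(vol, eps = 1e-3, margin = 2) {
  idx <- which(vol$data > eps, arr.ind = TRUE)
  if (nrow(idx) == 0) return(vol)
  lo <- pmax(apply(idx, 2, min) - margin, 1)
  hi <- pmin(apply(idx, 2, max) + margin, dim(vol$data))
  ct_volume(vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
            vol$spacing, vol$origin + (lo - 1) * vol$spacing)
}

downsample_volume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  sm <- smooth_gaussian(vol, sigma_vox = factor / 2)
  dst_dim <- pmax(8L, as.integer(ceiling(dim(vol$data) / factor)))
  resample_to_grid(sm, dst_dim, vol$spacing * factor, vol$origin, diag(4))
}

#' Affine registration of binary skull masks
#'
#' Finds the 9-parameter affine transform (template world -> subject world)
#' minimizing the sum of squared differences between the Gaussian-smoothed
#' binary masks under gradient-based (BFGS) optimization with a coarse-to-
#' fine multiresolution schedule. Deterministic given its configuration.
#'
#' @param subject_mask binary [ct_volume()] skull mask of the subject.
#' @param template_mask binary [ct_volume()] skull mask of the template.
#' @param smooth_sigma_vox Gaussian smoothing of both masks, in voxels.
#' @param levels multiresolution downsampling factors, coarse to fine.
#' @param maxit BFGS iteration caps per level (the coarsest level is
#'   explored derivative-free; its entry is the Nelder-Mead budget per
#'   start).
#' @param rotation_starts rotation offsets (degrees) for the coarse-level
#'   multi-start grid (`expand.grid` over the three axes); the SSD of thin
#'   skull shells has rotation local minima, so large unknown rotations
#'   need a grid wider than the default when poses beyond ~10 degrees are
#'   expected. A single `0` disables the multi-start.
#' @param keep_candidates coarse-level candidates carried to the next
#'   level before committing to the best basin.
#' @return A `ct_affine` with attributes `ssd_trace` (per-level SSD) and
#'   `ssd_init` (SSD at the initial centroid alignment).
#' @export
affine_register_masks <- function(subject_mask, template_mask,
                                  smooth_sigma_vox = 1,
                                  levels = c(3, 1.5, 1),
                                  maxit = c(60, 40, 30),
                                  rotation_starts = c(-7, 0, 7),
                                  keep_candidates = 2) {
  if (sum(subject_mask$data != 0) == 0 || sum(template_mask$data != 0) == 0)
    stop("registration failure: empty skull mask")
  maxit <- rep_len(maxit, length(levels))
  sub_sm <- smooth_gaussian(with_data(subject_mask,
                                      (subject_mask$data != 0) * 1.0),
                            smooth_sigma_vox)
  tmp_sm <- smooth_gaussian(with_data(template_mask,
                                      (template_mask$data != 0) * 1.0),
                            smooth_sigma_vox)
  center <- mask_centroid_world(template_mask)
  t0 <- mask_centroid_world(subject_mask) - center
  par <- c(t0, 0, 0, 0, 0, 0, 0)
  # coarse levels evaluate the SSD over the full (cropped) grid; fine
  # levels restrict it to the fixed mask's support voxels, which carry
  # all the information once the poses are roughly aligned
  make_obj <- function(fix, support_only) {
    force(fix)
    if (!support_only) {
      return(function(p) {
        tf <- params_to_affine(p, center)
        .cq_ssd_affine(sub_sm$data, sub_sm$spacing, sub_sm$origin,
                       fix$data, dim(fix$data), fix$spacing, fix$origin,
                       affine_matrix(tf))
      })
    }
    sel <- which(fix$data > 1e-4)
    d <- dim(fix$data)
    i <- (sel - 1) %% d[1]
    j <- ((sel - 1) %/% d[1]) %% d[2]
    k <- (sel - 1) %/% (d[1] * d[2])
    pts <- cbind(i * fix$spacing[1] + fix$origin[1],
                 j * fix$spacing[2] + fix$origin[2],
                 k * fix$spacing[3] + fix$origin[3])
    fvals <- fix$data[sel]
    function(p) {
      tf <- params_to_affine(p, center)
      .cq_ssd_affine_pts(sub_sm$data, sub_sm$spacing, sub_sm$origin,
                         pts, fvals, affine_matrix(tf))
    }
  }
  objs <- lapply(seq_along(levels), function(li)
    make_obj(crop_to_support(downsample_volume(tmp_sm, levels[li]),
                             margin = 3), support_only = li > 1))
  ssd_init <- objs[[1]](par)
  bfgs_ctl <- function(mi) list(maxit = mi,
                                parscale = c(1, 1, 1, 2, 2, 2,
                                             0.01, 0.01, 0.01),
                                reltol = 1e-11)
  starts <- as.matrix(expand.grid(rotation_starts, rotation_starts,
                                  rotation_starts))
  cand <- lapply(seq_len(nrow(starts)), function(s) {
    p0 <- par
    p0[4:6] <- starts[s, ]
    optim(p0, objs[[1]], method = "Nelder-Mead",
          control = list(maxit = maxit[1],
                         parscale = c(2, 2, 2, 4, 4, 4,
                                      0.02, 0.02, 0.02)))
  })
  vals <- vapply(cand, `[[`, 0, "value")
  ssd_trace <- min(vals)
  keep <- order(vals)[seq_len(min(keep_candidates, length(vals)))]
  li2 <- min(2, length(objs))
  refined <- lapply(keep, function(s)
    optim(cand[[s]]$par, objs[[li2]], method = "BFGS",
          control = bfgs_ctl(maxit[li2])))
  best <- refined[[which.min(vapply(refined, `[[`, 0, "value"))]]
  par <- best$par
  ssd_trace <- c(ssd_trace, best$value)
  for (li in seq_along(levels)[-c(1, li2)]) {
    fit <- optim(par, objs[[li]], method = "BFGS",
                 control = bfgs_ctl(maxit[li]))
    par <- fit$par
    ssd_trace <- c(ssd_trace, fit$value)
  }
  # derivative-free polish: the voxelized-mask SSD has fine-scale ripple
  # that stalls quasi-Newton line searches short of the optimum
  fit <- optim(par, objs[[length(objs)]], method = "Nelder-Mead",
               control = list(maxit = 250,
                              parscale = c(0.5, 0.5, 0.5, 1, 1, 1,
                                           0.005, 0.005, 0.005)))
  par <- fit$par
  ssd_trace <- c(ssd_trace, fit$value)
  if (tail(ssd_trace, 1) > ssd_init * 1.5 + 1e-12)
    stop("registration diverged: SSD increased from ",
         format(ssd_init), " to ", format(tail(ssd_trace, 1)))
  tf <- params_to_affine(par, center)
  attr(tf, "ssd_trace") <- ssd_trace
  attr(tf, "ssd_init") <- ssd_init
  tf
}

#' Normalized mutual information of two intensity samples
#'
#' `(H(X) + H(Y)) / H(X, Y)` from a joint histogram with linear Parzen
#' binning (each sample spreads linearly over two adjacent bins per axis).
#'
#' @param x,y numeric vectors, arrays or [ct_volume()]s of equal length.
#' @param bins number of histogram bins per axis.
#' @param range_x,range_y optional fixed intensity ranges for binning.
#' @return Scalar NMI (>= 1; equals 2 for identical discrete signals).
#' @export
nmi <- function(x, y, bins = 32, range_x = NULL, range_y = NULL) {
  if (is_ct_volume(x)) x <- x$data
  if (is_ct_volume(y)) y <- y$data
  x <- as.vector(x); y <- as.vector(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (sd(x) == 0 || sd(y) == 0)
    stop("NMI undefined for constant images")
  h <- parzen_joint_hist(x, y, bins, range_x, range_y)$h
  p <- h / sum(h)
  px <- rowSums(p); py <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  (ent(px) + ent(py)) / ent(p)
}

parzen_bin_coords <- function(v, bins, rng = NULL) {
  if (is.null(rng)) rng <- range(v)
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
  b <- (v - rng[1]) / (rng[2] - rng[1]) * (bins - 1) + 1
  b <- pmin(pmax(b, 1), bins)
  i0 <- pmin(floor(b), bins - 1)
  list(i0 = as.integer(i0), w1 = b - i0, delta = (rng[2] - rng[1]) / (bins - 1),
       rng = rng)
}

parzen_joint_hist <- function(x, y, bins, range_x = NULL, range_y = NULL) {
  bx <- parzen_bin_coords(x, bins, range_x)
  by <- parzen_bin_coords(y, bins, range_y)
  h <- .cq_hist2d_w(bx$i0, by$i0, (1 - bx$w1) * (1 - by$w1), bins) +
    .cq_hist2d_w(bx$i0 + 1L, by$i0, bx$w1 * (1 - by$w1), bins) +
    .cq_hist2d_w(bx$i0, by$i0 + 1L, (1 - bx$w1) * by$w1, bins) +
    .cq_hist2d_w(bx$i0 + 1L, by$i0 + 1L, bx$w1 * by$w1, bins)
  list(h = h, bx = bx, by = by)
}

# dense displacement field (template grid) from a control grid
dense_displacement <- function(ctrl, ctrl_spacing, ctrl_origin, grid_dim,
                               grid_spacing, grid_origin) {
  out <- array(0, c(grid_dim, 3))
  for (c3 in 1:3) {
    comp <- ct_volume(array(ctrl[, , , c3], dim(ctrl)[1:3]),
                      ctrl_spacing, ctrl_origin)
    out[, , , c3] <- resample_to_grid(comp, grid_dim, grid_spacing,
                                      grid_origin, diag(4))$data
  }
  out
}

#' Nonrigid refinement by normalized-mutual-information maximization
#'
#' Estimates a parametric displacement field (first-order B-spline /
#' trilinear control grid, default 8-voxel knot spacing) such that the
#' moving image warped by `x + D(x)` maximizes NMI against the fixed
#' image, with a bending-energy (control-point Laplacian) penalty.
#' Gradient ascent with backtracking step control; the attained NMI is
#' nondecreasing over outer iterations by construction.
#'
#' Both images must live on the same grid; apply the affine first (see
#' [transport()]). In the pipeline the fixed image is the subject CT
#' resampled to template space and the moving image is the template, so
#' the resulting field composes directly with the inverse affine when
#' transporting template data to native space.
#'
#' @param fixed,moving [ct_volume()]s on a common grid.
#' @param nmi_bins histogram bins for NMI.
#' @param reg_weight bending-energy weight.
#' @param knot_spacing_vox control-point spacing in voxels.
#' @param max_iter outer gradient-ascent iterations.
#' @param step_mm initial maximum control-point step per iteration (mm).
#' @return A `deformation_field`: `field` (dense \[X,Y,Z,3\] mm), `ctrl`
#'   (control grid), `spacing`, `origin`, `nmi_trace`, `reg_weight`.
#' @export
nonrigid_refine <- function(fixed, moving, nmi_bins = 32, reg_weight = 0.05,
                            knot_spacing_vox = 8, max_iter = 30,
                            step_mm = 1) {
  stopifnot_same_grid(fixed, moving, "fixed and moving images")
  if (sd(fixed$data) == 0 || sd(moving$data) == 0)
    stop("NMI undefined for constant images")
  d <- dim(fixed$data)
  sp <- fixed$spacing
  cd <- pmax(2L, as.integer(ceiling((d - 1) / knot_spacing_vox)) + 1L)
  csp <- (d - 1) * sp / (cd - 1)
  ctrl <- array(0, c(cd, 3))
  rng_f <- range(fixed$data)
  rng_m <- range(moving$data)
  fvec <- as.vector(fixed$data)
  bx <- parzen_bin_coords(fvec, nmi_bins, rng_f)

  # moving-image spatial gradient (per mm), sampled later at warped points
  grad_m <- lapply(1:3, function(ax) {
    g <- array(0, d)
    arr <- moving$data
    n <- d[ax]
    perm_take <- function(a, take) {
      switch(ax, a[take, , , drop = FALSE], a[, take, , drop = FALSE],
             a[, , take, drop = FALSE])
    }
    assign_slice <- function(a, take, val) {
      switch(ax,
             { a[take, , ] <- val; a },
             { a[, take, ] <- val; a },
             { a[, , take] <- val; a })
    }
    g <- assign_slice(g, 2:(n - 1),
                      (perm_take(arr, 3:n) - perm_take(arr, 1:(n - 2))) /
                        (2 * sp[ax]))
    ct_volume(g, sp, fixed$origin)
  })

  warp_sample <- function(vol, field) {
    disp <- list(field = field, spacing = sp, origin = fixed$origin)
    resample_to_grid(vol, d, sp, fixed$origin, diag(4), disp = disp,
                     fill = rng_m[1])$data
  }
  bend_energy <- function(cg) {
    e <- 0
    for (ax in 1:3) {
      n <- dim(cg)[ax]
      if (n < 2) next
      d1 <- switch(ax, cg[2:n, , , , drop = FALSE] -
                     cg[1:(n - 1), , , , drop = FALSE],
                   cg[, 2:n, , , drop = FALSE] -
                     cg[, 1:(n - 1), , , drop = FALSE],
                   cg[, , 2:n, , drop = FALSE] -
                     cg[, , 1:(n - 1), , drop = FALSE])
      e <- e + sum(d1^2)
    }
    e / length(cg)
  }
  objective <- function(cg) {
    field <- dense_displacement(cg, csp, fixed$origin, d, sp, fixed$origin)
    mw <- warp_sample(moving, field)
    ph <- parzen_joint_hist(fvec, as.vector(mw), nmi_bins, rng_f, rng_m)
    p <- ph$h / sum(ph$h)
    px <- rowSums(p); py <- colSums(p)
    ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
    list(nmi = (ent(px) + ent(py)) / ent(p),
         value = (ent(px) + ent(py)) / ent(p) - reg_weight * bend_energy(cg),
         field = field, mw = mw, hist = ph)
  }

  # analytic NMI gradient w.r.t. control displacements
  gradient <- function(cur) {
    ph <- cur$hist
    h <- ph$h
    N <- sum(h)
    p <- h / N
    py <- colSums(p)
    Hxy <- { q <- p[p > 0]; -sum(q * log(q)) }
    Hy <- { q <- py[py > 0]; -sum(q * log(q)) }
    Hx <- { q <- rowSums(p); q <- q[q > 0]; -sum(q * log(q)) }
    logp <- matrix(0, nrow(h), ncol(h))
    logp[p > 0] <- log(p[p > 0])
    logq <- ifelse(py > 0, log(py), 0)
    dHxy <- -(logp + 1) / N
    dHy <- matrix(rep(-(logq + 1) / N, each = nrow(h)), nrow(h))
    G <- (dHy * Hxy - (Hx + Hy) * dHxy) / Hxy^2
    by <- parzen_bin_coords(as.vector(cur$mw), nmi_bins, rng_m)
    j0 <- by$i0
    # d h / d m(v) pushes weight from column j0 to j0+1 at rate 1/delta
    gmv <- ((1 - bx$w1) * (G[cbind(bx$i0, j0 + 1L)] -
                             G[cbind(bx$i0, j0)]) +
              bx$w1 * (G[cbind(bx$i0 + 1L, j0 + 1L)] -
                         G[cbind(bx$i0 + 1L, j0)])) / by$delta
    # chain through the moving-image spatial gradient at warped points
    force <- array(0, c(d, 3))
    for (ax in 1:3)
      force[, , , ax] <- array(gmv, d) * warp_sample(grad_m[[ax]],
                                                     cur$field)
    # splat voxel forces onto the control grid (trilinear adjoint)
    splat_axis_coord <- function(ax) {
      ((seq_len(d[ax]) - 1) * sp[ax]) / csp[ax] + 1
    }
    gx <- splat_axis_coord(1); gy <- splat_axis_coord(2)
    gz <- splat_axis_coord(3)
    i0 <- pmin(floor(gx), cd[1] - 1); wx <- gx - i0
    j0c <- pmin(floor(gy), cd[2] - 1); wy <- gy - j0c
    k0 <- pmin(floor(gz), cd[3] - 1); wz <- gz - k0
    grad_ctrl <- array(0, c(cd, 3))
    VX <- rep(seq_len(d[1]), times = d[2] * d[3])
    VY <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
    VZ <- rep(seq_len(d[3]), each = d[1] * d[2])
    ii0 <- i0[VX]; wwx <- wx[VX]
    jj0 <- j0c[VY]; wwy <- wy[VY]
    kk0 <- k0[VZ]; wwz <- wz[VZ]
    for (ax in 1:3) {
      fv <- as.vector(force[, , , ax])
      acc <- numeric(prod(cd))
      for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
        w <- (if (cx) wwx else 1 - wwx) * (if (cy) wwy else 1 - wwy) *
          (if (cz) wwz else 1 - wwz)
        idx <- (ii0 + cx) + (jj0 + cy - 1L) * cd[1] +
          (kk0 + cz - 1L) * cd[1] * cd[2]
        sums <- rowsum(fv * w, idx)
        acc[as.integer(rownames(sums))] <-
          acc[as.integer(rownames(sums))] + sums[, 1]
      }
      grad_ctrl[, , , ax] <- array(acc, cd)
    }
    # bending-energy gradient: graph Laplacian on the control grid
    bend_grad <- array(0, c(cd, 3))
    for (ax in 1:3) {
      n <- cd[ax]
      if (n < 2) next
      shift_hi <- function(a) {
        switch(ax,
               a[c(2:n, n), , , , drop = FALSE],
               a[, c(2:n, n), , , drop = FALSE],
               a[, , c(2:n, n), , drop = FALSE])
      }
      shift_lo <- function(a) {
        switch(ax,
               a[c(1, 1:(n - 1)), , , , drop = FALSE],
               a[, c(1, 1:(n - 1)), , , drop = FALSE],
               a[, , c(1, 1:(n - 1)), , drop = FALSE])
      }
      bend_grad <- bend_grad +
        (2 * ctrl - shift_hi(ctrl) - shift_lo(ctrl)) * 2 / length(ctrl)
    }
    grad_ctrl - reg_weight * bend_grad
  }

  cur <- objective(ctrl)
  trace <- cur$nmi
  step <- step_mm
  for (it in seq_len(max_iter)) {
    g <- gradient(cur)
    gmax <- max(abs(g))
    if (gmax < 1e-12) break
    accepted <- FALSE
    while (step > 1e-3) {
      cand <- ctrl + g * (step / gmax)
      res <- objective(cand)
      if (res$value > cur$value + 1e-7) {
        ctrl <- cand
        cur <- res
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    trace <- c(trace, cur$nmi)
    if (!accepted) break
  }
  structure(list(field = cur$field, ctrl = ctrl, ctrl_spacing = csp,
                 spacing = sp, origin = fixed$origin, nmi_trace = trace,
                 reg_weight = reg_weight),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf(paste0("<deformation_field> ctrl grid %s, max |d| %.2f mm, ",
                     "NMI %.4f -> %.4f (%d steps)\n"),
              paste(dim(x$ctrl)[1:3], collapse = "x"),
              max(abs(x$field)), x$nmi_trace[1],
              tail(x$nmi_trace, 1), length(x$nmi_trace) - 1))
  invisible(x)
}

#' Resample a volume through an affine (optionally + nonrigid) transform
#'
#' For each target voxel with world coordinate `w`, the source coordinate
#' is `p = M w` (forward) or `p = M^-1 w` (inverse), where `M` is the
#' affine matrix of `transform` (template world -> subject world as fitted
#' by [affine_register_masks()]). A `deformation` field, when given, is
#' evaluated at `p` and added (`p + D(p)`), matching the composition used
#' to carry template data to native space: template-space fields compose
#' with `direction = "inverse"`.
#'
#' With the subject-to-template fit, `direction = "forward"` pulls subject
#' data onto a template-space target grid, and `direction = "inverse"`
#' pulls template-space data (masks, percentile maps) onto the subject
#' grid.
#'
#' @param volume source [ct_volume()].
#' @param transform a `ct_affine` (or `NULL` for identity).
#' @param target [ct_volume()] defining the output grid.
#' @param direction `"forward"` or `"inverse"`.
#' @param interpolation `"linear"` for probabilities, `"cubic"`
#'   (Catmull-Rom) for intensities where small structures matter,
#'   `"nearest"` for masks and label volumes (preserves the label
#'   alphabet).
#' @param deformation optional `deformation_field` from
#'   [nonrigid_refine()].
#' @param fill value for voxels sampled outside the source volume.
#' @return Resampled [ct_volume()] on the target grid.
#' @export
transport <- function(volume, transform, target,
                      direction = c("forward", "inverse"),
                      interpolation = c("linear", "nearest", "cubic"),
                      deformation = NULL, fill = 0) {
  direction <- match.arg(direction)
  interpolation <- match.arg(interpolation)
  M <- if (is.null(transform)) diag(4) else affine_matrix(transform)
  if (direction == "inverse") M <- solve(M)
  disp <- if (is.null(deformation)) NULL else
    list(field = deformation$field, spacing = deformation$spacing,
         origin = deformation$origin)
  out <- resample_to_grid(volume, dim(target$data), target$spacing,
                          target$origin, M, disp = disp,
                          method = interpolation, fill = fill)
  if (interpolation == "nearest" && is.integer(volume$data))
    out$data <- array(as.integer(round(out$data)), dim(out$data))
  out
}

#' Z-score CT intensities over the brain mask
#'
#' @param ct a [ct_volume()].
#' @param brain_mask a `brain_mask` or binary [ct_volume()]/array.
#' @param fill value assigned outside the mask.
#' @param stat_erosion_vox radius (voxels) by which the mask is eroded
#'   before computing the normalization statistics. After resampling, a
#'   brain-mask boundary voxel can blend in bone intensity; even a small
#'   fraction of such voxels inflates the SD enough to crush the
#'   CSF/parenchyma contrast. 0 disables the erosion. The statistics use
#'   the eroded mask; the output is masked by the full mask.
#' @return `ct_volume` with (eroded-)mask mean 0 and SD 1.
#' @export
zscore_brain <- function(ct, brain_mask, fill = 0, stat_erosion_vox = 0) {
  m <- if (inherits(brain_mask, "brain_mask")) brain_mask$mask$data
  else if (is_ct_volume(brain_mask)) brain_mask$data
  else brain_mask
  sel <- as.vector(m != 0)
  if (sum(sel) < 2) stop("brain mask has fewer than 2 voxels")
  stat_sel <- sel
  if (stat_erosion_vox > 0) {
    er <- .cq_morph(array(as.integer(m != 0), dim(ct$data)),
                    stat_erosion_vox, 0L)
    if (sum(er) >= 2) stat_sel <- as.vector(er != 0)
  }
  v <- as.vector(ct$data)[stat_sel]
  s <- sd(v)
  if (s == 0) stop("zero intensity variance within the brain mask")
  out <- array(fill, dim(ct$data))
  out[sel] <- (as.vector(ct$data)[sel] - mean(v)) / s
  with_data(ct, out)
}
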