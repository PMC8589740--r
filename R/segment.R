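#' Configuration of the CSF/WML segmentation network
#'
#' A U-shaped residual convolutional network mapping a z-scored CT volume
#' to per-voxel class probabilities for background, CSF and white-matter
#' lesion. The "desk" preset is a small network (one down/up-sampling
#' stage, 4 residual elements, ~12 weight layers, ~10k parameters) sized
#' so that training on a synthetic cohort takes seconds to minutes on one
#' CPU; the "full" preset matches the scale of the uResNet family of
#' lesion-segmentation networks (3 deconvolutional stages, 8 residual
#' elements, on the order of a million parameters).
#'
#' @param preset `"desk"` (default) or `"full"`.
#' @param base_channels channels after the stem convolution; doubled at
#'   each down-sampling stage.
#' @param n_deconv_layers number of down/up-sampling stage pairs.
#' @param epochs training epochs (one optimizer step per subject-crop per
#'   epoch).
#' @param batch_size crops drawn per subject per epoch.
#' @param learning_rate Adam step size.
#' @param patch_size training crop edge length in voxels (must be
#'   divisible by `2^n_deconv_layers`).
#' @param class_weight_exponent loss weights per class are proportional to
#'   `count^-exponent`; 1 is plain inverse frequency, 0 unweighted.
#' @param dice_weight weight of the soft-Dice term added to the
#'   cross-entropy for the CSF and WML classes (scalar, or length 2 for
#'   separate CSF and WML weights); 0 disables it.
#' @param seed RNG seed for weight initialization and crop sampling.
#' @return A `segmenter_config` list; `n_residual_blocks` and `classes`
#'   are derived fields.
#' @export
segmenter_config <- function(preset = c("desk", "full"),
                             base_channels = NULL, n_deconv_layers = NULL,
                             epochs = NULL, batch_size = 1,
                             learning_rate = 1e-2, patch_size = 32,
                             class_weight_exponent = 0.3,
                             dice_weight = 2, seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "desk")
    list(base_channels = 4L, n_deconv_layers = 1L, epochs = 40L)
  else
    list(base_channels = 24L, n_deconv_layers = 3L, epochs = 100L)
  base_channels <- as.integer(base_channels %||% def$base_channels)
  n_deconv_layers <- as.integer(n_deconv_layers %||% def$n_deconv_layers)
  epochs <- as.integer(epochs %||% def$epochs)
  if (patch_size %% 2^n_deconv_layers != 0)
    stop("patch_size must be divisible by 2^n_deconv_layers")
  structure(list(preset = preset, base_channels = base_channels,
                 n_deconv_layers = n_deconv_layers,
                 n_residual_blocks = 2L * n_deconv_layers + 2L,
                 classes = c("background", "csf", "wml"),
                 epochs = epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patch_size = as.integer(patch_size),
                 class_weight_exponent = class_weight_exponent,
                 dice_weight = dice_weight,
                 seed = as.integer(seed)),
            class = "segmenter_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_conv <- function(k, ci, co, stride = 1L) {
  fan_in <- k^3 * ci
  list(W = array(rnorm(k^3 * ci * co, 0, sqrt(2 / fan_in)),
                 c(k, k, k, ci, co)),
       b = numeric(co), stride = as.integer(stride),
       pad = as.integer((k - 1) / 2))
}

# transposed conv: W has shape [k, k, k, C_high, C_low]; forward maps a
# C_low low-resolution tensor to a C_high tensor at double resolution
new_upconv <- function(k, c_high, c_low) {
  fan_in <- k^3 * c_low
  list(W = array(rnorm(k^3 * c_high * c_low, 0, sqrt(2 / fan_in)),
                 c(k, k, k, c_high, c_low)),
       b = numeric(c_high), stride = 2L, pad = 1L)
}

new_resblock <- function(ch) list(conv1 = new_conv(3, ch, ch),
                                  conv2 = new_conv(3, ch, ch))

build_segmenter <- function(config) {
  C <- config$base_channels
  Cin <- config$in_channels %||% 4L
  D <- config$n_deconv_layers
  enc <- vector("list", D)
  for (l in seq_len(D)) {
    ch <- C * 2^(l - 1)
    enc[[l]] <- list(res = new_resblock(ch),
                     down = new_conv(3, ch, ch * 2, stride = 2L))
  }
  bottom <- list(new_resblock(C * 2^D), new_resblock(C * 2^D))
  dec <- vector("list", D)
  for (l in seq_len(D)) {   # stored in decoding order (deepest first)
    ch <- C * 2^(D - l)
    dec[[l]] <- list(up = new_upconv(3, ch, ch * 2),
                     res = new_resblock(ch))
  }
  list(stem = new_conv(3, Cin, C), enc = enc, bottom = bottom, dec = dec,
       out = new_conv(1, C, length(config$classes)), config = config)
}

n_parameters <- function(model) {
  n <- 0
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$W)) n <<- n + length(x$W) + length(x$b)
      for (el in x) if (is.list(el)) walk(el)
    }
  }
  walk(model[c("stem", "enc", "bottom", "dec", "out")])
  n
}

# leaky rectifier: the small negative slope keeps units trainable (plain
# ReLU lets whole channels die under aggressive early Adam steps at this
# tiny network scale, which showed up as seed-dependent training collapse)
relu_alpha <- 0.05

relu_f <- function(a) {
  neg <- a < 0
  a[neg] <- relu_alpha * a[neg]
  a
}

relu_mask <- function(pre) {
  m <- array(1, dim(pre))
  m[pre < 0] <- relu_alpha
  m
}

conv_f <- function(l, x) .cq_conv3d_fwd(x, l$W, l$b, l$stride, l$pad)

# network input channels, all fixed functions of the z-scored CT:
#   1. the z map itself
#   2. tissue-anchored intensity: plain z statistics shift with the CSF
#      fraction (atrophy severity), moving the lesion intensity across
#      any fixed decision boundary; a two-class EM over the brain values
#      finds the CSF and parenchyma means and maps parenchyma -> 0,
#      CSF -> -1, which is stable across subjects
#   3. local contrast of the anchored map (minus a sigma 1.5 voxel
#      Gaussian blur) -- makes small blob-like hypodensities separable
#   4. CSF adjacency (sigma 2.5 voxel blur of anchored < -0.75) --
#      separates partial-volume rings hugging large CSF bodies from
#      isolated lesions, whose intensities overlap
seg_input <- function(ct) {
  z <- ct$data * 1.0
  v <- z[z != 0]
  v <- v[v > -5 & v < 5]
  anch <- z
  anchors <- tryCatch({
    em <- em_two_class(v, priors = c(0.3, 0.7), max_iter = 50)
    c(lo = em$class_means[1], hi = em$class_means[2])
  }, error = function(e) c(lo = -1, hi = 0))
  scale <- max(anchors["hi"] - anchors["lo"], 0.1)
  anch <- (z - anchors[["hi"]]) / scale
  anch[anch < -3] <- -3
  anch[anch > 3] <- 3
  lc <- anch - .cq_gauss3(anch, c(1.5, 1.5, 1.5))
  adj <- .cq_gauss3((anch < -0.75) * 1.0, c(2.5, 2.5, 2.5))
  array(c(z, anch, lc, adj), c(dim(z), 4L))
}

upconv_f <- function(l, x) {
  od <- dim(x)[1:3] * 2L
  y <- .cq_conv3d_bwd_input(x, l$W, od, l$stride, l$pad)
  sweep_bias(y, l$b)
}

sweep_bias <- function(y, b) {
  d <- dim(y)
  y + array(rep(b, each = prod(d[1:3])), d)
}

res_f <- function(blk, x) {
  r1 <- .cq_leaky(conv_f(blk$conv1, x), relu_alpha)
  h2 <- conv_f(blk$conv2, r1$y)
  ry <- .cq_leaky(x + h2, relu_alpha)
  list(y = ry$y,
       cache = list(x = x, a1 = r1$y, m1 = r1$m, my = ry$m))
}

res_b <- function(blk, cache, gy) {
  g <- gy * cache$my
  gw2 <- .cq_conv3d_bwd_weights(cache$a1, g, dim(blk$conv2$W)[1],
                                blk$conv2$stride, blk$conv2$pad)
  ga1 <- .cq_conv3d_bwd_input(g, blk$conv2$W, dim(cache$a1)[1:3],
                              blk$conv2$stride, blk$conv2$pad)
  gh1 <- ga1 * cache$m1
  gw1 <- .cq_conv3d_bwd_weights(cache$x, gh1, dim(blk$conv1$W)[1],
                                blk$conv1$stride, blk$conv1$pad)
  gx <- g + .cq_conv3d_bwd_input(gh1, blk$conv1$W, dim(cache$x)[1:3],
                                 blk$conv1$stride, blk$conv1$pad)
  list(gx = gx,
       grads = list(conv1 = list(W = gw1$gW, b = gw1$gb),
                    conv2 = list(W = gw2$gW, b = gw2$gb)))
}

seg_forward <- function(model, x, keep_cache = FALSE) {
  D <- length(model$enc)
  cache <- list()
  rs <- .cq_leaky(conv_f(model$stem, x), relu_alpha)
  a <- rs$y
  cache$stem <- list(x = x, m = rs$m)
  skips <- vector("list", D)
  cache$enc <- vector("list", D)
  for (l in seq_len(D)) {
    r <- res_f(model$enc[[l]]$res, a)
    skips[[l]] <- r$y
    rd <- .cq_leaky(conv_f(model$enc[[l]]$down, r$y), relu_alpha)
    cache$enc[[l]] <- list(res = r$cache, down_x = r$y, down_m = rd$m)
    a <- rd$y
  }
  cache$bottom <- vector("list", length(model$bottom))
  for (i in seq_along(model$bottom)) {
    r <- res_f(model$bottom[[i]], a)
    cache$bottom[[i]] <- r$cache
    a <- r$y
  }
  cache$dec <- vector("list", D)
  for (l in seq_len(D)) {
    up <- model$dec[[l]]$up
    ru <- .cq_leaky(upconv_f(up, a), relu_alpha)
    asum <- ru$y + skips[[D - l + 1]]
    r <- res_f(model$dec[[l]]$res, asum)
    cache$dec[[l]] <- list(up_x = a, up_m = ru$m, res = r$cache)
    a <- r$y
  }
  logits <- conv_f(model$out, a)
  cache$out_x <- a
  if (keep_cache) list(logits = logits, cache = cache, skips = skips)
  else list(logits = logits)
}

seg_backward <- function(model, cache, glogits) {
  D <- length(model$enc)
  grads <- list()
  gwo <- .cq_conv3d_bwd_weights(cache$out_x, glogits, dim(model$out$W)[1],
                                model$out$stride, model$out$pad)
  grads$out <- list(W = gwo$gW, b = gwo$gb)
  ga <- .cq_conv3d_bwd_input(glogits, model$out$W, dim(cache$out_x)[1:3],
                             model$out$stride, model$out$pad)
  gskips <- vector("list", D)
  grads$dec <- vector("list", D)
  for (l in rev(seq_len(D))) {
    cc <- cache$dec[[l]]
    rb <- res_b(model$dec[[l]]$res, cc$res, ga)
    gsum <- rb$gx
    gskips[[D - l + 1]] <- gsum
    ghu <- gsum * cc$up_m
    up <- model$dec[[l]]$up
    gb_up <- apply(ghu, 4, sum)
    gw_up <- .cq_conv3d_bwd_weights(ghu, cc$up_x, dim(up$W)[1],
                                    up$stride, up$pad)
    ga <- conv_f(list(W = up$W, b = numeric(dim(up$W)[5]),
                      stride = up$stride, pad = up$pad), ghu)
    grads$dec[[l]] <- list(up = list(W = gw_up$gW, b = gb_up),
                           res = rb$grads)
  }
  grads$bottom <- vector("list", length(model$bottom))
  for (i in rev(seq_along(model$bottom))) {
    rb <- res_b(model$bottom[[i]], cache$bottom[[i]], ga)
    grads$bottom[[i]] <- rb$grads
    ga <- rb$gx
  }
  grads$enc <- vector("list", D)
  for (l in rev(seq_len(D))) {
    cc <- cache$enc[[l]]
    gad <- ga * cc$down_m
    down <- model$enc[[l]]$down
    gw_d <- .cq_conv3d_bwd_weights(cc$down_x, gad, dim(down$W)[1],
                                   down$stride, down$pad)
    g_res_y <- .cq_conv3d_bwd_input(gad, down$W, dim(cc$down_x)[1:3],
                                    down$stride, down$pad) +
      gskips[[l]]
    rb <- res_b(model$enc[[l]]$res, cc$res, g_res_y)
    grads$enc[[l]] <- list(res = rb$grads,
                           down = list(W = gw_d$gW, b = gw_d$gb))
    ga <- rb$gx
  }
  gh <- ga * cache$stem$m
  gw_s <- .cq_conv3d_bwd_weights(cache$stem$x, gh, dim(model$stem$W)[1],
                                 model$stem$stride, model$stem$pad)
  grads$stem <- list(W = gw_s$gW, b = gw_s$gb)
  grads
}

softmax4 <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[4])
  mx <- m[, 1]
  for (j in 2:d[4]) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  array(p, d)
}

# weighted softmax cross-entropy plus soft-Dice on the foreground
# classes; returns loss and gradient w.r.t. logits. The Dice term
# optimizes overlap directly, which the voxel-count-dominated CE cannot
# do for classes occupying a fraction of a percent of the volume.
seg_loss <- function(logits, labels, class_weights, dice_weight = 1,
                     dice_classes = 2:3, vox_mask = NULL) {
  d <- dim(logits)
  nC <- d[4]
  p <- matrix(softmax4(logits), ncol = nC)
  y <- as.vector(labels) + 1L
  m <- if (is.null(vox_mask)) 1 else as.vector(vox_mask)
  w <- class_weights[y] * m
  wsum <- sum(w)
  if (wsum <= 0) wsum <- 1
  idx <- cbind(seq_along(y), y)
  loss <- -sum(w * log(pmax(p[idx], 1e-12))) / wsum
  # gradient of CE w.r.t. logits (standard closed form)
  g <- p * w
  g[idx] <- g[idx] - w
  g <- g / wsum
  dice_weight <- rep_len(dice_weight, length(dice_classes))
  if (any(dice_weight > 0)) {
    eps <- 1
    dLdp <- matrix(0, nrow(p), nC)
    for (ci in seq_along(dice_classes)) {
      cc <- dice_classes[ci]
      dw <- dice_weight[ci]
      yc <- as.numeric(y == cc) * m
      if (sum(yc) == 0 || dw <= 0) next
      pc <- p[, cc] * m
      Sp <- sum(pc); Sy <- sum(yc); I <- sum(pc * yc)
      dice_c <- (2 * I + eps) / (Sp + Sy + eps)
      loss <- loss + dw * (1 - dice_c)
      ddice_dp <- m * (2 * yc * (Sp + Sy + eps) - (2 * I + eps)) /
        (Sp + Sy + eps)^2
      dLdp[, cc] <- dLdp[, cc] - dw * ddice_dp
    }
    # chain through softmax: dL/dz_k = p_k (dL/dp_k - sum_c dL/dp_c p_c)
    dot <- rowSums(dLdp * p)
    g <- g + p * (dLdp - dot)
  }
  list(loss = loss, glogits = array(g, d))
}

# global-norm gradient clipping over the nested gradient lists
clip_grads <- function(grads, max_norm = 1) {
  total <- 0
  walk_sum <- function(g) {
    if (!is.null(g$W)) {
      total <<- total + sum(g$W^2) + sum(g$b^2)
      return(invisible())
    }
    for (el in g) if (is.list(el)) walk_sum(el)
  }
  for (pt in c("stem", "enc", "bottom", "dec", "out")) walk_sum(grads[[pt]])
  nrm <- sqrt(total)
  if (!is.finite(nrm) || nrm <= max_norm) return(grads)
  scale <- max_norm / nrm
  walk_scale <- function(g) {
    if (!is.null(g$W)) {
      g$W <- g$W * scale
      g$b <- g$b * scale
      return(g)
    }
    for (i in seq_along(g)) if (is.list(g[[i]])) g[[i]] <- walk_scale(g[[i]])
    g
  }
  for (pt in c("stem", "enc", "bottom", "dec", "out"))
    grads[[pt]] <- walk_scale(grads[[pt]])
  grads
}

# elementwise Adam over the nested parameter lists
adam_step <- function(model, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    if (is.null(s)) s <- list(m = p * 0, v = p * 0)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  walk <- function(m, g, s) {
    if (!is.null(m$W)) {
      rw <- upd(m$W, g$W, s$W)
      rb <- upd(m$b, g$b, s$b)
      m$W <- rw$p; m$b <- rb$p
      return(list(m = m, s = list(W = rw$s, b = rb$s)))
    }
    sn <- if (is.null(s)) vector("list", length(m)) else s
    for (i in seq_along(m)) {
      if (!is.list(m[[i]])) next
      r <- walk(m[[i]], g[[i]], sn[[i]])
      m[[i]] <- r$m
      sn[[i]] <- r$s
    }
    list(m = m, s = sn)
  }
  parts <- c("stem", "enc", "bottom", "dec", "out")
  for (pt in parts) {
    r <- walk(model[[pt]], grads[[pt]], state[[pt]])
    model[[pt]] <- r$m
    state[[pt]] <- r$s
  }
  list(model = model, state = state)
}

#' Map phantom tissue labels to segmentation classes
#'
#' Background 0, CSF 1, WML 2 (see [phantom_labels]).
#' @param labels integer label [ct_volume()] from a phantom.
#' @return Integer class [ct_volume()].
#' @export
segmentation_classes <- function(labels) {
  v <- labels$data
  out <- array(0L, dim(v))
  out[v == phantom_labels[["csf"]]] <- 1L
  out[v == phantom_labels[["wml"]]] <- 2L
  with_data(labels, out)
}

#' Train the CSF/WML segmentation network
#'
#' Optimizes a voxelwise softmax cross-entropy with inverse-frequency
#' class weights by Adam, one randomly cropped patch per subject per
#' epoch. Deterministic given `config$seed`.
#'
#' @param pairs list of training pairs, each a list with `ct` (z-scored
#'   template-space [ct_volume()]), `labels` (class [ct_volume()] with
#'   codes 0 background, 1 CSF, 2 WML) and optionally `weight` (binary
#'   [ct_volume()]; voxels with weight 0 — e.g. resampling-ambiguous
#'   label boundaries — are excluded from the loss).
#' @param config a [segmenter_config()].
#' @param verbose print per-epoch mean loss.
#' @return A `ct_segmenter`: the network with `loss_history`,
#'   `class_weights`, `config`.
#' @export
train_segmenter <- function(pairs, config = segmenter_config(),
                            verbose = FALSE) {
  if (length(pairs) < 2) stop("need at least 2 training pairs")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  nC <- length(config$classes)
  counts <- numeric(nC)
  for (p in pairs) {
    lab <- as.vector(p$labels$data)
    if (!is.null(p$weight)) lab <- lab[as.vector(p$weight$data) != 0]
    counts <- counts + tabulate(lab + 1L, nC)
  }
  if (any(counts == 0)) {
    warning("class(es) absent from all training labels: ",
            paste(config$classes[counts == 0], collapse = ", "),
            "; their loss weight is zero")
  }
  # tempered inverse-frequency weights (count^-exponent): plain inverse
  # frequency lets the rare lesion class dominate the loss and flood the
  # prediction with false positives at this class imbalance (~1e3 : 1),
  # while equal weights never learn the rare class at all
  cw <- ifelse(counts > 0, counts^(-config$class_weight_exponent), 0)
  cw <- cw / sum(cw)
  # foreground voxel lists for lesion/CSF-centred crop sampling
  csf_idx <- lapply(pairs, function(p)
    which(p$labels$data == 1L, arr.ind = TRUE))
  wml_idx <- lapply(pairs, function(p)
    which(p$labels$data == 2L, arr.ind = TRUE))
  # input channels are built on the full volume so the local-contrast
  # channel has no crop-border artifacts
  xs <- lapply(pairs, function(p) seg_input(p$ct))
  model <- build_segmenter(config)
  state <- list()
  t <- 0
  ps <- config$patch_size
  loss_hist <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(pairs))
    ep_loss <- 0
    n_steps <- 0
    for (s in ord) {
      for (bb in seq_len(config$batch_size)) {
        d <- dim(pairs[[s]]$ct$data)
        u <- runif(1)
        pool <- if (u < 0.35 && nrow(wml_idx[[s]]) > 0) wml_idx[[s]]
        else if (u < 0.6 && nrow(csf_idx[[s]]) > 0) csf_idx[[s]]
        else NULL
        if (!is.null(pool)) {
          # crop centred on a random CSF or lesion voxel so rare classes
          # appear in a constant fraction of training patches
          ctr <- pool[sample.int(nrow(pool), 1), ]
          lo <- pmin(pmax(ctr - ps %/% 2, 1L), d - ps + 1L) - 1L
        } else {
          lo <- pmin(d - ps, pmax(0L, c(
            sample.int(max(d[1] - ps, 1), 1),
            sample.int(max(d[2] - ps, 1), 1),
            sample.int(max(d[3] - ps, 1), 1)) - 1L))
        }
        ix <- (lo[1] + 1):(lo[1] + ps)
        iy <- (lo[2] + 1):(lo[2] + ps)
        iz <- (lo[3] + 1):(lo[3] + ps)
        x <- xs[[s]][ix, iy, iz, , drop = FALSE]
        yl <- pairs[[s]]$labels$data[ix, iy, iz]
        vm <- if (is.null(pairs[[s]]$weight)) NULL else
          pairs[[s]]$weight$data[ix, iy, iz]
        fw <- seg_forward(model, x, keep_cache = TRUE)
        ls <- seg_loss(fw$logits, yl, cw,
                       dice_weight = config$dice_weight, vox_mask = vm)
        grads <- seg_backward(model, fw$cache, ls$glogits)
        grads <- clip_grads(grads, max_norm = 1)
        t <- t + 1
        # linear warmup, then step decay toward the end of training
        total_steps <- config$epochs * length(pairs) * config$batch_size
        warm <- min(1, t / max(1, round(0.1 * total_steps)))
        decay <- if (ep > 0.85 * config$epochs) 0.1
        else if (ep > 0.6 * config$epochs) 0.3
        else 1
        st <- adam_step(model, grads, state,
                       config$learning_rate * warm * decay, t)
        model <- st$model
        state <- st$state
        ep_loss <- ep_loss + ls$loss
        n_steps <- n_steps + 1
      }
    }
    loss_hist <- c(loss_hist, ep_loss / n_steps)
    if (verbose) message(sprintf("epoch %d/%d  loss %.4f", ep,
                                 config$epochs, tail(loss_hist, 1)))
  }
  model$loss_history <- loss_hist
  model$class_weights <- cw
  class(model) <- "ct_segmenter"
  model
}

#' @export
print.ct_segmenter <- function(x, ...) {
  cat(sprintf(paste0("<ct_segmenter> %s preset, %d parameters, ",
                     "%d epochs, final loss %.4f\n"),
              x$config$preset, n_parameters(x),
              length(x$loss_history), tail(x$loss_history, 1)))
  invisible(x)
}

#' Per-voxel class probabilities from a trained segmenter
#'
#' Training with class-weighted cross-entropy estimates a posterior
#' tilted by the class weights; with `unbias = TRUE` the emitted
#' probabilities are re-normalized by `p_c / w_c`, which removes that
#' tilt exactly when the network has converged to the weighted Bayes
#' posterior. With the default mild weights and Dice-dominated loss the
#' raw posterior already places the 0.5 decision sensibly, so the
#' correction is off by default (an undertrained network under-shoots
#' its confidence and the correction then over-suppresses rare
#' classes).
#'
#' @param model a `ct_segmenter`.
#' @param ct z-scored template-space [ct_volume()]; each grid axis must be
#'   divisible by `2^n_deconv_layers`.
#' @param unbias divide the softmax posterior by the training class
#'   weights before re-normalizing.
#' @return Named list of probability [ct_volume()]s (one per class,
#'   summing to 1 voxelwise).
#' @export
predict_segmenter <- function(model, ct, unbias = FALSE) {
  d <- dim(ct$data)
  if (any(d %% 2^model$config$n_deconv_layers != 0))
    stop("grid axes must be divisible by 2^n_deconv_layers")
  x <- seg_input(ct)
  p <- softmax4(seg_forward(model, x)$logits)
  if (unbias && !is.null(model$class_weights)) {
    w <- pmax(model$class_weights, 1e-12)
    for (ci in seq_along(w)) p[, , , ci] <- p[, , , ci] / w[ci]
    tot <- p[, , , 1]
    for (ci in seq_along(w)[-1]) tot <- tot + p[, , , ci]
    for (ci in seq_along(w)) p[, , , ci] <- p[, , , ci] / tot
  }
  out <- lapply(seq_along(model$config$classes), function(ci)
    with_data(ct, array(p[, , , ci], d)))
  names(out) <- model$config$classes
  out
}

#' Train an ensemble of independently seeded segmenters
#'
#' Repeated CNN segmentation improves robustness: the ten-repetition
#' protocol fuses K separate segmentations of the same subject; here
#' each repetition is an independently seeded training run of the same
#' architecture.
#'
#' @param pairs training pairs (see [train_segmenter()]).
#' @param K number of repetitions (>= 2).
#' @param config base [segmenter_config()]; member `i` trains with seed
#'   `config$seed + i - 1`.
#' @param verbose print progress.
#' @return List of `ct_segmenter` objects of length `K`.
#' @export
train_ensemble <- function(pairs, K = 10, config = segmenter_config(),
                           verbose = FALSE) {
  if (K < 2) stop("K must be >= 2")
  lapply(seq_len(K), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    if (verbose) message("training ensemble member ", i, "/", K)
    train_segmenter(pairs, cfg, verbose = FALSE)
  })
}

#' Ensemble predictions for one subject
#'
#' @param models list of >= 2 trained `ct_segmenter`s.
#' @param ct z-scored template-space [ct_volume()].
#' @return List with `csf` and `wml`: each a list of K probability
#'   [ct_volume()]s (one per ensemble member).
#' @export
predict_ensemble <- function(models, ct) {
  if (length(models) < 2) stop("need >= 2 ensemble members")
  preds <- lapply(models, predict_segmenter, ct = ct)
  list(csf = lapply(preds, `[[`, "csf"),
       wml = lapply(preds, `[[`, "wml"))
}

#' Correlation-weighted fusion of repeated segmentations
#'
#' Implements the four-step combination rule: (1) Pearson correlation
#' `c_ij` between every pair of member probability maps over the analysis
#' domain; (2) for each member `i`, the count `n_i` of `c_ij` exceeding
#' `min(0.8, 0.9 * max_j(c_ij))` (maximum over the other members; the
#' self-pair `c_ii = 1` is included in the count); (3) weights
#' `w_i = n_i / sum(n_i)`; (4) the weighted sum of the member
#' probabilities thresholded at 0.5.
#'
#' A member with zero variance over the domain has undefined correlations;
#' it is excluded from counts and gets weight 0, with a warning.
#'
#' @param members list of K >= 2 probability [ct_volume()]s (or arrays) on
#'   one grid.
#' @param mask optional binary mask (array or [ct_volume()]) defining the
#'   correlation domain; default whole grid.
#' @param threshold fusion probability threshold.
#' @param include_self logical; count the self-pair in `n_i` (default, the
#'   plain reading of the rule) or not.
#' @return An `ensemble_fusion`: `members`, `corr` (KxK), `counts`,
#'   `weights` (sum to 1), `mean_prob` (weighted-mean probability
#'   [ct_volume()], the un-thresholded consensus), `fused` (binary
#'   [ct_volume()]), `threshold`.
#' @export
fuse_ensemble <- function(members, mask = NULL, threshold = 0.5,
                          include_self = TRUE) {
  K <- length(members)
  if (K < 2) stop("need >= 2 ensemble members")
  vols <- lapply(members, function(m)
    if (is_ct_volume(m)) m else ct_volume(m))
  ref <- vols[[1]]
  for (v in vols) stopifnot_same_grid(ref, v, "ensemble members")
  sel <- if (is.null(mask)) rep(TRUE, length(ref$data)) else {
    mm <- if (is_ct_volume(mask)) mask$data else mask
    as.vector(mm != 0)
  }
  mat <- vapply(vols, function(v) as.vector(v$data)[sel],
                numeric(sum(sel)))
  sds <- apply(mat, 2, sd)
  degenerate <- sds == 0
  if (any(degenerate))
    warning(sum(degenerate), " ensemble member(s) with zero variance ",
            "excluded from correlation weighting")
  corr <- matrix(NA_real_, K, K)
  ok <- which(!degenerate)
  if (length(ok) >= 2) corr[ok, ok] <- cor(mat[, ok, drop = FALSE])
  dg <- diag(corr)
  dg[!degenerate] <- 1
  diag(corr) <- dg
  counts <- numeric(K)
  for (i in seq_len(K)) {
    if (degenerate[i]) next
    others <- corr[i, -i]
    others <- others[!is.na(others)]
    if (length(others) == 0) next
    thr_i <- min(0.8, 0.9 * max(others))
    cand <- if (include_self) c(1, others) else others
    counts[i] <- sum(cand > thr_i)
  }
  if (sum(counts) == 0) stop("no valid ensemble members to fuse")
  weights <- counts / sum(counts)
  wsum <- array(0, dim(ref$data))
  for (i in seq_len(K)) if (weights[i] > 0)
    wsum <- wsum + weights[i] * vols[[i]]$data
  mean_prob <- with_data(ref, wsum)
  fused <- with_data(ref, array(as.integer(wsum >= threshold),
                                dim(ref$data)))
  structure(list(members = vols, corr = corr, counts = counts,
                 weights = weights, mean_prob = mean_prob, fused = fused,
                 threshold = threshold),
            class = "ensemble_fusion")
}

#' @export
print.ensemble_fusion <- function(x, ...) {
  cat(sprintf(paste0("<ensemble_fusion> %d members, weights [%s], ",
                     "%d fused voxels\n"),
              length(x$members),
              paste(format(x$weights, digits = 3), collapse = ", "),
              sum(x$fused$data)))
  invisible(x)
}

#' K-fold cross-validated training and out-of-fold prediction
#'
#' Deterministic fold assignment given `seed`; every sample is predicted
#' exactly once, by the model that did not train on it.
#'
#' @param pairs training pairs (see [train_segmenter()]).
#' @param folds number of folds (default 10; must be <= number of pairs).
#' @param config a [segmenter_config()].
#' @param seed fold-assignment seed.
#' @param verbose print progress.
#' @return List with `fold` (assignment per pair), `models` (one per
#'   fold), `predictions` (per pair, the out-of-fold class probability
#'   list).
#' @export
crossvalidate <- function(pairs, folds = 10, config = segmenter_config(),
                          seed = 1L, verbose = FALSE) {
  n <- length(pairs)
  if (folds > n) stop("folds must not exceed the number of pairs")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  models <- vector("list", folds)
  predictions <- vector("list", n)
  for (f in seq_len(folds)) {
    if (verbose) message("fold ", f, "/", folds)
    models[[f]] <- train_segmenter(pairs[fold != f], config)
    for (s in which(fold == f))
      predictions[[s]] <- predict_segmenter(models[[f]], pairs[[s]]$ct)
  }
  list(fold = fold, models = models, predictions = predictions)
}
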