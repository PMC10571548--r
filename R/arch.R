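# Structural definitions of the YOLOv8 detector family (n/s/m) and the
# efficient multi-scale attention (EMA) variant, with exact trainable
# parameter and FLOP accounting. There is no training and no weight
# loading here: the module exists so the architecture's size claims can be
# verified by arithmetic, layer by layer, on one CPU in milliseconds.
#
# Conventions (the family's customary reporting): parameters are the sum
# of convolution kernels, biases and batch-norm affine pairs; FLOPs are
# 2 x multiply-accumulates of all convolutions at the stated input size.

YOLO_VARIANTS <- list(
  n = list(depth = 0.33, width = 0.25, max_channels = 1024),
  s = list(depth = 0.33, width = 0.50, max_channels = 1024),
  m = list(depth = 0.67, width = 0.75, max_channels = 768)
)

#' Detector architecture configuration
#'
#' @param variant One of `"n"`, `"s"`, `"m"`; fixes the published
#'   depth/width multipliers (n: 0.33/0.25/1024, s: 0.33/0.50/1024,
#'   m: 0.67/0.75/768).
#' @param num_classes Number of detection classes. The default is 2
#'   (`pig`, `pig_fighting`): all totals in this package are for the
#'   two-class head, which is what makes the n-variant land at 3.01 M
#'   parameters rather than the 80-class 3.16 M.
#' @param attention `"none"` or `"ema"` (insert the multi-scale attention
#'   block).
#' @param input_size Square input resolution in pixels (default 640).
#' @param ema_groups Channel groups of the EMA block (default 8).
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(variant = c("n", "s", "m"), num_classes = 2L,
                        attention = c("none", "ema"), input_size = 640L,
                        ema_groups = 8L) {
  variant <- match.arg(variant)
  attention <- match.arg(attention)
  stopifnot_scalar_num(num_classes, "num_classes", lower = 1)
  stopifnot_scalar_num(input_size, "input_size", lower = 32)
  if (input_size %% 32 != 0)
    pt_config_error("input_size must be a multiple of the maximum stride 32")
  structure(c(YOLO_VARIANTS[[variant]],
              list(variant = variant, num_classes = as.integer(num_classes),
                   attention = attention, input_size = as.integer(input_size),
                   ema_groups = as.integer(ema_groups))),
            class = "arch_config")
}

make_divisible <- function(x, divisor = 8) ceiling(x / divisor) * divisor

# --- layer-table builder ---------------------------------------------------
# Each primitive appends one row: name, module, params, macs, output shape.

arch_builder <- function() {
  rows <- list()
  add <- function(name, module, params, macs, c, h, w) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, module = module, params = params, macs = macs,
      out_c = c, out_h = h, out_w = w, stringsAsFactors = FALSE)
  }
  conv <- function(name, c1, c2, k, h, w) {
    # k x k convolution (no bias) + batch-norm affine pair
    add(name, "Conv", c1 * c2 * k * k + 2 * c2, c1 * c2 * k * k * h * w,
        c2, h, w)
  }
  conv2d <- function(name, c1, c2, k, h, w, bias = TRUE) {
    add(name, "Conv2d", c1 * c2 * k * k + if (bias) c2 else 0,
        c1 * c2 * k * k * h * w, c2, h, w)
  }
  list(rows = function() do.call(rbind, rows), add = add,
       conv = conv, conv2d = conv2d)
}

build_bottleneck <- function(b, name, c1, c2, s) {
  b$conv(paste0(name, ".cv1"), c1, c2, 3, s, s)
  b$conv(paste0(name, ".cv2"), c2, c2, 3, s, s)
}

build_c2f <- function(b, name, c1, c2, n, s) {
  c <- c2 %/% 2L
  b$conv(paste0(name, ".cv1"), c1, 2 * c, 1, s, s)
  for (i in seq_len(n)) build_bottleneck(b, paste0(name, ".m", i), c, c, s)
  b$conv(paste0(name, ".cv2"), (2 + n) * c, c2, 1, s, s)
}

build_sppf <- function(b, name, c1, c2, s) {
  ch <- c1 %/% 2L
  b$conv(paste0(name, ".cv1"), c1, ch, 1, s, s)
  b$conv(paste0(name, ".cv2"), 4 * ch, c2, 1, s, s)
}

build_detect <- function(b, name, chs, nc, sizes) {
  reg_max <- 16L
  c2h <- max(16L, chs[1L] %/% 4L, reg_max * 4L)
  c3h <- max(chs[1L], min(nc, 100L))
  for (i in seq_along(chs)) {
    x <- chs[i]; s <- sizes[i]
    b$conv(sprintf("%s.cv2.%d.0", name, i), x, c2h, 3, s, s)
    b$conv(sprintf("%s.cv2.%d.1", name, i), c2h, c2h, 3, s, s)
    b$conv2d(sprintf("%s.cv2.%d.2", name, i), c2h, 4L * reg_max, 1, s, s)
    b$conv(sprintf("%s.cv3.%d.0", name, i), x, c3h, 3, s, s)
    b$conv(sprintf("%s.cv3.%d.1", name, i), c3h, c3h, 3, s, s)
    b$conv2d(sprintf("%s.cv3.%d.2", name, i), c3h, nc, 1, s, s)
  }
  b$add(paste0(name, ".dfl"), "DFL", reg_max, 0, 4L + nc, sizes[1L], sizes[1L])
}

ema_accounting <- function(channels, groups, h, w) {
  if (channels %% groups != 0)
    pt_config_error(sprintf("EMA groups (%d) must divide channels (%d)",
                            groups, channels))
  cg <- channels %/% groups
  list(
    conv1x1 = c(params = cg * cg + cg, macs = groups * cg * cg * (h + w)),
    conv3x3 = c(params = 9 * cg * cg + cg, macs = groups * 9 * cg * cg * h * w),
    group_norm = c(params = 2 * cg, macs = 0),
    cross_attn = c(params = 0, macs = 2 * groups * cg * h * w)
  )
}

#' Build a YOLOv8-family layer graph
#'
#' Constructs the CSPDarknet-style backbone (stem and four stages of C2f
#' blocks plus SPPF), the PAN feature-aggregation neck, and the decoupled
#' anchor-free head, scaled by the variant's depth/width multipliers, as a
#' per-layer accounting table. With `attention = "ema"` one EMA block is
#' inserted on the backbone output (after SPPF), the placement used for
#' the attention-augmented n-variant. A forward pass at `input_size`
#' produces three detection maps at strides 8, 16 and 32 (recorded in the
#' `detect_shapes` attribute).
#'
#' @param config An [arch_config()].
#' @return An object of class `layer_graph`: list with `config`, `layers`
#'   (the per-layer table) and `detect_shapes`.
#' @export
build_detector <- function(config) {
  if (!inherits(config, "arch_config"))
    pt_config_error("build_detector expects an arch_config")
  img <- config$input_size
  ch <- function(c) make_divisible(min(c, config$max_channels) * config$width)
  rep_ <- function(n) max(round(n * config$depth), 1L)
  c64 <- ch(64); c128 <- ch(128); c256 <- ch(256)
  c512 <- ch(512); c1024 <- ch(1024)
  b <- arch_builder()

  # backbone
  b$conv("0.stem", 3, c64, 3, img / 2, img / 2)
  b$conv("1.down_p2", c64, c128, 3, img / 4, img / 4)
  build_c2f(b, "2.c2f", c128, c128, rep_(3), img / 4)
  b$conv("3.down_p3", c128, c256, 3, img / 8, img / 8)
  build_c2f(b, "4.c2f", c256, c256, rep_(6), img / 8)
  b$conv("5.down_p4", c256, c512, 3, img / 16, img / 16)
  build_c2f(b, "6.c2f", c512, c512, rep_(6), img / 16)
  b$conv("7.down_p5", c512, c1024, 3, img / 32, img / 32)
  build_c2f(b, "8.c2f", c1024, c1024, rep_(3), img / 32)
  build_sppf(b, "9.sppf", c1024, c1024, img / 32)

  if (config$attention == "ema") {
    acc <- ema_accounting(c1024, config$ema_groups, img / 32, img / 32)
    for (nm in names(acc))
      b$add(paste0("9e.ema.", nm), "EMA", acc[[nm]][["params"]],
            acc[[nm]][["macs"]], c1024, img / 32, img / 32)
  }

  # PAN neck (upsample/concat layers hold no parameters)
  b$add("10.upsample", "Upsample", 0, 0, c1024, img / 16, img / 16)
  b$add("11.concat", "Concat", 0, 0, c1024 + c512, img / 16, img / 16)
  build_c2f(b, "12.c2f", c1024 + c512, c512, rep_(3), img / 16)
  b$add("13.upsample", "Upsample", 0, 0, c512, img / 8, img / 8)
  b$add("14.concat", "Concat", 0, 0, c512 + c256, img / 8, img / 8)
  build_c2f(b, "15.c2f", c512 + c256, c256, rep_(3), img / 8)
  b$conv("16.down", c256, c256, 3, img / 16, img / 16)
  b$add("17.concat", "Concat", 0, 0, c256 + c512, img / 16, img / 16)
  build_c2f(b, "18.c2f", c256 + c512, c512, rep_(3), img / 16)
  b$conv("19.down", c512, c512, 3, img / 32, img / 32)
  b$add("20.concat", "Concat", 0, 0, c512 + c1024, img / 32, img / 32)
  build_c2f(b, "21.c2f", c512 + c1024, c1024, rep_(3), img / 32)

  # decoupled anchor-free head at strides 8/16/32
  build_detect(b, "22.detect", c(c256, c512, c1024), config$num_classes,
               c(img / 8, img / 16, img / 32))

  layers <- b$rows()
  structure(list(config = config, layers = layers,
                 detect_shapes = data.frame(
                   stride = c(8L, 16L, 32L),
                   h = img / c(8L, 16L, 32L), w = img / c(8L, 16L, 32L))),
            class = "layer_graph")
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf("<layer_graph> YOLOv8%s nc=%d attention=%s @ %d px: %d rows\n",
              x$config$variant, x$config$num_classes, x$config$attention,
              x$config$input_size, nrow(x$layers)))
  invisible(x)
}

#' Parameter and FLOP totals of a layer graph
#'
#' Sums the per-layer accounting: exact trainable-parameter total (an
#' integer, identical across runs), parameters in millions rounded to two
#' decimals, and forward-pass FLOPs at the configured input size counting
#' each multiply-accumulate as two operations, in billions rounded to one
#' decimal.
#'
#' @param graph A [build_detector()] result.
#' @return An object of class `arch_summary`.
#' @export
summarize_arch <- function(graph) {
  if (!inherits(graph, "layer_graph"))
    pt_config_error("summarize_arch expects a layer_graph")
  total <- sum(graph$layers$params)
  macs <- sum(graph$layers$macs)
  structure(list(variant = graph$config$variant,
                 attention = graph$config$attention,
                 num_classes = graph$config$num_classes,
                 input_size = graph$config$input_size,
                 total_params = total,
                 params_millions = round(total / 1e6, 2),
                 flops_g = round(2 * macs / 1e9, 1),
                 layers = graph$layers),
            class = "arch_summary")
}

#' @export
print.arch_summary <- function(x, ...) {
  cat(sprintf(
    "<arch_summary> YOLOv8%s%s nc=%d @ %d px: %s params (%.2f M), %.1f GFLOPs\n",
    x$variant, if (x$attention == "ema") "+EMA" else "", x$num_classes,
    x$input_size, format(x$total_params, big.mark = ","),
    x$params_millions, x$flops_g))
  invisible(x)
}

# --- EMA block with a real (numeric) forward pass --------------------------

#' Efficient multi-scale attention block
#'
#' The attention block combines channel grouping, directional (per-row and
#' per-column) average pooling feeding a shared 1x1 convolution with
#' sigmoid gating, a parallel 3x3 convolution branch, and cross-branch
#' softmax-weighted spatial attention, closing with a sigmoid gate on the
#' grouped input. It reweights a `(C, H, W)` feature map without changing
#' its shape, and its parameter count (one 1x1 kernel, one 3x3 kernel and
#' one group-norm affine pair, each over `C / groups` channels) is
#' independent of H and W.
#'
#' Weights are randomly initialized (seeded by `init_seed`): the block is
#' a structural reference, not a trained module.
#'
#' @param channels Number of input channels; must be divisible by
#'   `groups`.
#' @param groups Number of channel groups (default 8).
#' @param init_seed Seed for the random weight initialization.
#' @return An object of class `ema_block` with a params table and weights.
#' @export
build_ema_block <- function(channels, groups = 8L, init_seed = 0L) {
  acc <- ema_accounting(channels, groups, 1, 1)  # spatial size irrelevant
  cg <- channels %/% groups
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(init_seed)
  weights <- list(
    w1 = matrix(stats::rnorm(cg * cg, 0, sqrt(2 / cg)), cg, cg),
    b1 = numeric(cg),
    w3 = array(stats::rnorm(cg * 9 * cg, 0, sqrt(2 / (9 * cg))),
               c(cg, 3, 3, cg)),
    b3 = numeric(cg),
    gn_gamma = rep(1, cg),
    gn_beta = numeric(cg)
  )
  params <- data.frame(
    layer = c("conv1x1", "conv3x3", "group_norm"),
    params = c(acc$conv1x1[["params"]], acc$conv3x3[["params"]],
               acc$group_norm[["params"]])
  )
  structure(list(channels = as.integer(channels), groups = as.integer(groups),
                 cg = cg, params = params,
                 total_params = sum(params$params), weights = weights),
            class = "ema_block")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

conv3x3_same <- function(x, w, bias) {
  # x: (cin, h, w); w: (cin, 3, 3, cout); zero padding 1
  cin <- dim(x)[1L]; h <- dim(x)[2L]; wd <- dim(x)[3L]
  cout <- dim(w)[4L]
  xp <- array(0, c(cin, h + 2L, wd + 2L))
  xp[, 2:(h + 1L), 2:(wd + 1L)] <- x
  out <- array(0, c(cout, h, wd))
  for (co in seq_len(cout)) {
    acc <- matrix(bias[co], h, wd)
    for (ci in seq_len(cin)) {
      for (dy in 0:2) for (dx in 0:2) {
        acc <- acc + w[ci, dy + 1L, dx + 1L, co] *
          xp[ci, (1L + dy):(h + dy), (1L + dx):(wd + dx)]
      }
    }
    out[co, , ] <- acc
  }
  out
}

#' Forward pass of an EMA block
#'
#' @param block An [build_ema_block()] result.
#' @param x A numeric array of shape `(channels, H, W)`.
#' @return A numeric array of the same shape.
#' @export
ema_forward <- function(block, x) {
  if (length(dim(x)) != 3L || dim(x)[1L] != block$channels)
    pt_validation_error(sprintf("expected input of shape (%d, H, W)",
                                block$channels))
  cg <- block$cg; g <- block$groups
  h <- dim(x)[2L]; wd <- dim(x)[3L]
  wts <- block$weights
  out <- array(0, dim(x))
  for (grp in seq_len(g)) {
    chs <- ((grp - 1L) * cg + 1L):(grp * cg)
    gx <- x[chs, , , drop = FALSE]
    dim(gx) <- c(cg, h, wd)
    # directional pooling + shared 1x1 conv
    x_h <- apply(gx, c(1L, 2L), mean)               # cg x h
    x_w <- apply(gx, c(1L, 3L), mean)               # cg x w
    y <- wts$w1 %*% cbind(x_h, x_w) + wts$b1
    gh <- sigmoid(y[, seq_len(h), drop = FALSE])
    gw <- sigmoid(y[, h + seq_len(wd), drop = FALSE])
    att <- gx * array(rep(gh, times = wd), c(cg, h, wd)) *
      aperm(array(rep(t(gw), times = h), c(wd, cg, h)), c(2L, 3L, 1L))
    # per-channel normalization (group norm with one channel per group)
    x1 <- att
    for (ci in seq_len(cg)) {
      v <- att[ci, , ]
      mu <- mean(v); sd2 <- mean((v - mu)^2)
      x1[ci, , ] <- (v - mu) / sqrt(sd2 + 1e-5) * wts$gn_gamma[ci] +
        wts$gn_beta[ci]
    }
    x2 <- conv3x3_same(gx, wts$w3, wts$b3)
    # cross-branch spatial attention
    a1 <- softmax_vec(apply(x1, 1L, mean))          # cg
    a2 <- softmax_vec(apply(x2, 1L, mean))
    m1 <- matrix(x2, cg, h * wd)
    m2 <- matrix(x1, cg, h * wd)
    wmap <- sigmoid(as.numeric(a1 %*% m1 + a2 %*% m2))
    out[chs, , ] <- gx * aperm(array(wmap, c(h, wd, cg)), c(3L, 1L, 2L))
  }
  out
}
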