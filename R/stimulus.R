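#' Convert an image pattern to a spike-train stimulus
#'
#' Each pixel is assigned to one input channel; grayscale values 0-255 map
#' linearly to firing rates 0-\code{f_max} (default 50 Hz). Channels emit
#' independent seeded Poisson spike trains during the active window
#' (default 0.5 s) and are silent afterwards (default 0.5 s), letting the
#' fading memory dissipate between stimuli. A regular-train mode is
#' provided for single-synapse protocols that need fixed frequencies.
#'
#' @param pattern numeric matrix with values in [0, 255]; channels are
#'   taken in column-major order
#' @param f_max rate for pixel value 255 (Hz)
#' @param active active-window length (s)
#' @param silence silent-interval length (s)
#' @param seed RNG seed of the stimulus stream
#' @param mode \code{"poisson"} or \code{"regular"}
#' @return object of class \code{stimulus}: per-channel spike-time lists
#' @export
encode_image <- function(pattern, f_max = 50, active = 0.5, silence = 0.5,
                         seed = 1L, mode = c("poisson", "regular")) {
  mode <- match.arg(mode)
  if (any(pattern < 0) || any(pattern > 255)) stop("pixel values must be in [0, 255]")
  rates <- as.vector(pattern) / 255 * f_max
  trains <- withr::with_seed(derive_seed(seed, "stimulus"), {
    lapply(rates, function(r) {
      if (r <= 0) return(numeric(0))
      if (mode == "poisson") {
        n <- stats::rpois(1, r * active)
        sort(stats::runif(n, 0, active))
      } else {
        seq(0, active - 1e-9, by = 1 / r)
      }
    })
  })
  structure(list(trains = trains, n_channels = length(rates),
                 active = active, silence = silence,
                 duration = active + silence, seed = seed,
                 dim = dim(pattern)),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("stimulus: %d channels, %.2g s active + %.2g s silent, %d spikes\n",
              x$n_channels, x$active, x$silence, sum(lengths(x$trains))))
  invisible(x)
}

# Flatten a stimulus (or list of stimuli with offsets) into sorted event
# arrays for the engine.
stimulus_events <- function(stimulus, offsets = NULL) {
  if (inherits(stimulus, "stimulus")) {
    stimulus <- list(stimulus)
    offsets <- 0
  }
  if (is.null(offsets)) offsets <- (seq_along(stimulus) - 1) *
      vapply(stimulus, function(s) s$duration, 0)
  n_ch <- stimulus[[1]]$n_channels
  tt <- list(); cc <- list()
  for (i in seq_along(stimulus)) {
    s <- stimulus[[i]]
    if (s$n_channels != n_ch) stop("stimuli have differing channel counts")
    times <- unlist(s$trains, use.names = FALSE)
    chans <- rep.int(seq_len(n_ch), lengths(s$trains))
    tt[[i]] <- times + offsets[i]
    cc[[i]] <- chans
  }
  time <- unlist(tt, use.names = FALSE)
  channel <- unlist(cc, use.names = FALSE)
  o <- order(time)
  list(time = time[o], channel = channel[o], n_channels = n_ch)
}

#' Preprocess a raw grayscale image
#'
#' Optionally converts the image to a line drawing with Sobel edge
#' detection (reducing noise from shading), then downsamples to the target
#' size by block averaging. Output values are scaled into [0, 255].
#'
#' @param img numeric matrix (any range; normalized internally)
#' @param target_size integer pair (rows, cols)
#' @param mode \code{"grayscale"} or \code{"edge"}
#' @param edge_threshold gradient magnitudes below this fraction of the
#'   maximum are zeroed in edge mode
#' @return matrix of the target size with values in [0, 255]
#' @export
preprocess_image <- function(img, target_size, mode = c("grayscale", "edge"),
                             edge_threshold = 0.1) {
  mode <- match.arg(mode)
  if (length(img) == 0) stop("empty image")
  img <- as.matrix(img)
  if (mode == "edge") img <- sobel_edges(img, edge_threshold)
  out <- downsample(img, target_size)
  rng <- range(out)
  if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng) * 255 else out[] <- 0
  out
}

# Sobel gradient magnitude with soft thresholding
sobel_edges <- function(img, threshold = 0.1) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv2d(img, kx)
  gy <- conv2d(img, t(kx))
  g <- sqrt(gx^2 + gy^2)
  if (max(g) > 0) g[g < threshold * max(g)] <- 0
  g
}

# small direct 2-D convolution with edge replication
conv2d <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- (nrow(k) - 1L) / 2L; kc <- (ncol(k) - 1L) / 2L
  pad <- img[pmin(pmax(seq_len(nr + 2 * kr) - kr, 1), nr),
             pmin(pmax(seq_len(nc + 2 * kc) - kc, 1), nc), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(k))) for (j in seq_len(ncol(k))) {
    if (k[i, j] != 0)
      out <- out + k[i, j] * pad[(i - 1) + seq_len(nr), (j - 1) + seq_len(nc)]
  }
  out
}

# separable gaussian blur
gauss_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2)); k <- k / sum(k)
  conv2d(conv2d(img, matrix(k, ncol = 1)), matrix(k, nrow = 1))
}

# block-average downsampling (pads to a multiple of the block size)
downsample <- function(img, target_size) {
  tr <- target_size[1]; tc <- target_size[2]
  if (nrow(img) == tr && ncol(img) == tc) return(img)
  fr <- ceiling(nrow(img) / tr); fc <- ceiling(ncol(img) / tc)
  rpad <- tr * fr; cpad <- tc * fc
  pad <- matrix(0, rpad, cpad)
  pad[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  ri <- rep(seq_len(tr), each = fr)[seq_len(rpad)]
  ci <- rep(seq_len(tc), each = fc)[seq_len(cpad)]
  out <- rowsum(pad, ri)
  out <- t(rowsum(t(out), ci))
  out / (fr * fc)
}

#' Upscale a 20x20 pattern to 50x50
#'
#' Each pixel is replicated once to form a 40x40 image whose pixel (i, j)
#' fills the 2x2 block at rows 2i-1..2i and columns 2j-1..2j; the remaining
#' rows and columns on the right and bottom are padded with void (zero)
#' pixels to reach 50x50.
#'
#' @param pattern 20x20 numeric matrix
#' @return 50x50 matrix
#' @export
upscale_pattern <- function(pattern) {
  if (!all(dim(pattern) == c(20, 20))) stop("pattern must be 20x20")
  rep2 <- pattern[rep(seq_len(20), each = 2), rep(seq_len(20), each = 2)]
  out <- matrix(0, 50, 50)
  out[1:40, 1:40] <- rep2
  out
}

#' Scramble an image by relocating all pixels
#'
#' Applies a seeded random permutation of the pixel positions; the
#' intensity multiset is preserved exactly.
#'
#' @param pattern numeric matrix
#' @param seed RNG seed
#' @return matrix of the same dimensions
#' @export
scramble_image <- function(pattern, seed = 1L) {
  v <- as.vector(pattern)
  perm <- withr::with_seed(derive_seed(seed, "scramble"),
                           sample.int(length(v)))
  matrix(v[perm], nrow(pattern), ncol(pattern))
}

#' Generate a synthetic set of face-like image classes
#'
#' Stands in for face/car/dog photograph sets: every class is a smoothed
#' random template with consistent within-class structure, and each item
#' adds a seeded item-specific perturbation. In \code{"line"} mode the
#' patterns are converted to sparse line drawings (edge maps), emulating
#' the preprocessing applied to photographs. A binary feature block (e.g.
#' a beard region covering the lower part of the image) can be added to
#' designated classes.
#'
#' @param n_classes number of classes
#' @param n_per_class items per class
#' @param size image side length (pixels)
#' @param feature_classes classes (indices) receiving the feature block,
#'   or \code{NULL}
#' @param item_sd relative strength of item-specific structure
#' @param mode \code{"line"} (sparse edge drawings) or \code{"smooth"}
#' @param seed RNG seed
#' @return list of image matrices with attributes \code{class} (class
#'   index) and \code{item}; values in [0, 255]
#' @export
generate_synthetic_faces <- function(n_classes = 3, n_per_class = 10,
                                     size = 20, feature_classes = NULL,
                                     item_sd = 0.5,
                                     mode = c("line", "smooth"), seed = 1L) {
  mode <- match.arg(mode)
  if (n_classes < 1 || n_per_class < 1 || size < 4) stop("degenerate size")
  sigma <- size / 10
  withr::with_seed(derive_seed(seed, "faces"), {
    images <- list()
    for (cl in seq_len(n_classes)) {
      template <- gauss_blur(matrix(stats::rnorm(size^2), size, size), sigma)
      for (it in seq_len(n_per_class)) {
        pert <- gauss_blur(matrix(stats::rnorm(size^2), size, size), sigma)
        field <- template + item_sd * pert
        img <- if (mode == "line") {
          # sparse line drawing: most pixels dark, distinct bright lines
          g <- sobel_edges(field, threshold = 0)
          q <- stats::quantile(g, 0.70)
          g[g < q] <- 0
          pmin(g / stats::quantile(g, 0.97) * 255, 255)
        } else {
          f <- field - min(field)
          f / max(f) * 255
        }
        if (cl %in% feature_classes) {
          rows <- seq(floor(0.7 * size), size)
          cols <- seq(floor(0.25 * size), ceiling(0.75 * size))
          img[rows, cols] <- pmin(255, img[rows, cols] + 180)
        }
        attr(img, "class_id") <- cl
        attr(img, "item") <- it
        images[[length(images) + 1L]] <- img
      }
    }
    images
  })
}

#' Equalize baseline network responses across an image set
#'
#' Recursively adjusts the mean pixel value of each image (clipping to
#' [0, 255]) until the baseline network responses they evoke lie within
#' \code{tolerance} of their common mean. Probe runs use fixed per-image
#' stimulus seeds and plasticity disabled, so the procedure is
#' deterministic for a given network.
#'
#' @param images list of image matrices
#' @param network \code{lsm_network} with an input projection
#' @param tolerance relative tolerance on the spread of baseline responses
#' @param max_iters iteration limit; non-convergence is reported via the
#'   \code{converged} flag
#' @param f_max peak encoding rate (Hz)
#' @param probe_seed base seed of the probe stimulus streams
#' @param dt timestep (s)
#' @param target_rate population response level (1/s) the images are
#'   equalized to; \code{NULL} equalizes to the running mean response.
#'   A moderate level keeps the reservoir in its sparse down-state regime
#'   during subsequent learning.
#' @param n_probes probe encodings averaged per response measurement; the
#'   reservoir operates at the edge of chaos, so averaging over a few
#'   probe spike-train realizations smooths the response readout
#' @return list: \code{images} (adjusted), \code{responses} (final probe
#'   responses, 1/s), \code{converged}, \code{iterations}, \code{log}
#' @export
normalize_image_set <- function(images, network, tolerance = 0.05,
                                max_iters = 20, f_max = 50,
                                probe_seed = 1000L, dt = 2e-4,
                                target_rate = NULL, n_probes = 3L) {
  stopifnot(length(images) >= 1)
  n <- length(images)
  probe <- function(imgs) {
    vapply(seq_len(n), function(i) {
      mean(vapply(seq_len(n_probes), function(k) {
        st <- encode_image(imgs[[i]], f_max = f_max, silence = 0,
                           seed = probe_seed + i + 1000L * (k - 1L))
        sim <- run_network(network, st, duration = st$active,
                           plasticity = "off", seed = probe_seed + i, dt = dt)
        firing_rate(sim$record, c(0, st$active))
      }, 0))
    }, 0)
  }
  if (n == 1) {
    r <- probe(images)
    return(list(images = images, responses = r, converged = TRUE,
                iterations = 0L, log = data.frame()))
  }
  shift_img <- function(img, d) {
    at <- attributes(img)
    out <- pmin(255, pmax(0, img + d))
    attributes(out) <- at
    out
  }
  # Each image is adjusted by a cumulative intensity shift; probes are
  # deterministic, so the response is a (stepped) monotone-ish function of
  # the shift and a bracketed secant/bisection search per image is robust.
  base <- images
  shift <- rep(0, n)
  r <- probe(images)
  lo_s <- rep(-300, n); hi_s <- rep(300, n)   # shift brackets
  lo_r <- rep(NA_real_, n); hi_r <- rep(NA_real_, n)
  prev_s <- shift; prev_r <- r
  log <- list()
  iter <- 0L; converged <- FALSE
  repeat {
    target <- if (is.null(target_rate)) mean(r) else target_rate
    spread <- max(abs(r - target))
    log[[iter + 1L]] <- data.frame(iter = iter, spread = spread,
                                   mean_response = mean(r))
    if (spread <= tolerance * max(target, 1e-9) || iter >= max_iters) {
      converged <- spread <= tolerance * max(target, 1e-9)
      break
    }
    iter <- iter + 1L
    new_shift <- shift
    for (i in seq_len(n)) {
      err <- r[i] - target
      if (abs(err) <= tolerance * max(target, 1e-9)) next
      # update brackets (response increases with shift)
      if (err > 0 && (is.na(hi_r[i]) || shift[i] < hi_s[i])) {
        hi_s[i] <- shift[i]; hi_r[i] <- r[i]
      }
      if (err < 0 && (is.na(lo_r[i]) || shift[i] > lo_s[i])) {
        lo_s[i] <- shift[i]; lo_r[i] <- r[i]
      }
      ds <- shift[i] - prev_s[i]; dr <- r[i] - prev_r[i]
      step <- if (abs(ds) > 1e-6 && dr * ds > 0) {
        -err * ds / dr * 0.8                       # damped secant
      } else -sign(err) * 40
      step <- max(-80, min(80, step))
      cand <- shift[i] + step
      # keep inside the current bracket; bisect when it would escape
      if (!is.na(lo_r[i]) && !is.na(hi_r[i]) &&
          (cand <= lo_s[i] || cand >= hi_s[i]))
        cand <- (lo_s[i] + hi_s[i]) / 2
      new_shift[i] <- max(-300, min(300, cand))
    }
    prev_s <- shift; prev_r <- r
    shift <- new_shift
    images <- lapply(seq_len(n), function(i) shift_img(base[[i]], shift[i]))
    r <- probe(images)
  }
  list(images = images, responses = r, converged = converged,
       iterations = iter, log = do.call(rbind, log))
}

#' Read a grayscale image file
#'
#' Reads PNG (via the png package) or TIFF (via the tiff package) files
#' into a 0-255 grayscale matrix; multichannel images are averaged.
#'
#' @param path image file
#' @return numeric matrix in [0, 255]
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = { requireNamespace("png"); png::readPNG(path) },
    tif = , tiff = { requireNamespace("tiff"); tiff::readTIFF(path) },
    pgm = read_pgm(path),
    stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:min(3, dim(arr)[3])], c(1, 2), mean)
  if (max(arr) <= 1) arr <- arr * 255
  arr
}

# minimal plain (P2) and binary (P5) PGM reader/writer for text fixtures
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("only plain (P2) PGM is supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / mx * 255
}

#' Write a pattern as a plain PGM file
#' @param pattern numeric matrix in [0, 255]
#' @param path output file
#' @return invisibly, the path
#' @export
write_pgm <- function(pattern, path) {
  v <- round(pmin(pmax(pattern, 0), 255))   # pmin/pmax keep the dims of x
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(v), nrow(v)), "255"), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
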