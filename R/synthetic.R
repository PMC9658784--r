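#' Synthetic image classification data
#'
#' Seeded stand-in for the label+pixel CSV image datasets: each class is a
#' fixed geometric prototype (bars, cross, blob, diagonal, border) on an
#' `H x W` grid, plus Gaussian pixel noise, clipped to the unit interval. Class counts
#' are balanced to within one. Images default to 8 x 8 so encrypted runs stay
#' desk-scale.
#'
#' @param n number of images.
#' @param shape `c(H, W)` image shape.
#' @param K number of classes (at most the number of prototypes, 6).
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param seed RNG seed; the generator is a pure function of it.
#' @return an `image_dataset`: list with `images` (an `n x H x W` array with
#'   values in the unit interval), `labels` (0-based integers), `K`, `shape`.
#' @export
gen_toy_images <- function(n, shape = c(8, 8), K = 2, noise_sd = 0.1,
                           seed = 42) {
  protos <- image_prototypes(shape)
  if (K > length(protos))
    stop(fhe_condition("fhe_value_error",
                       sprintf("K = %d exceeds the %d available prototypes",
                               K, length(protos))))
  set.seed(seed)
  labels <- sample(rep_len(0:(K - 1L), n))
  images <- array(0, dim = c(n, shape))
  for (i in seq_len(n)) {
    img <- protos[[labels[i] + 1L]] +
      matrix(stats::rnorm(prod(shape), 0, noise_sd), shape[1], shape[2])
    images[i, , ] <- pmin(pmax(img, 0), 1)
  }
  structure(list(images = images, labels = as.integer(labels),
                 K = as.integer(K), shape = as.integer(shape)),
            class = "image_dataset")
}

#' @rdname gen_toy_images
#' @export
image_prototypes <- function(shape = c(8, 8)) {
  H <- shape[1]; W <- shape[2]
  z <- function() matrix(0, H, W)
  hbar <- z(); hbar[ceiling(H / 2) + (-1:0), ] <- 1
  vbar <- z(); vbar[, ceiling(W / 2) + (-1:0)] <- 1
  cross <- pmax(hbar, vbar)
  blob <- outer(seq_len(H), seq_len(W), function(i, j)
    exp(-(((i - (H + 1) / 2)^2 + (j - (W + 1) / 2)^2) / (0.15 * H * W))))
  diagm <- z(); for (i in seq_len(min(H, W))) diagm[i, i] <- 1
  border <- z(); border[c(1, H), ] <- 1; border[, c(1, W)] <- 1
  list(hbar = hbar, vbar = vbar, cross = cross,
       blob = blob / max(blob), diag = diagm, border = border)
}

#' Read a label + pixel CSV image file
#'
#' Each row is a class label followed by `H * W` pixel values in 0-255;
#' values are normalised to the unit interval and reshaped back to `H x W`.
#'
#' @param path CSV file (no header by default; a non-numeric first row is
#'   treated as a header and skipped).
#' @param shape image shape; inferred as square when NULL.
#' @return an `image_dataset`.
#' @export
read_label_pixel_csv <- function(path, shape = NULL) {
  fields <- utils::count.fields(path, sep = ",")
  if (length(unique(fields)) != 1L)
    stop(fhe_condition("fhe_parse_error",
                       sprintf("malformed row %d: %d fields (expected %d)",
                               which(fields != fields[1])[1],
                               fields[which(fields != fields[1])[1]],
                               fields[1])))
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           colClasses = "character")
  header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  d <- utils::read.csv(path, header = header)
  m <- as.matrix(d)
  if (!is.numeric(m) || anyNA(m))
    stop(fhe_condition("fhe_parse_error",
                       sprintf("malformed row %d: non-numeric pixel values",
                               which(apply(is.na(m), 1, any))[1])))
  npix <- ncol(m) - 1L
  if (is.null(shape)) {
    side <- sqrt(npix)
    if (side != floor(side))
      stop(fhe_condition("fhe_parse_error",
                         "pixel count is not square; supply 'shape'"))
    shape <- c(side, side)
  }
  if (prod(shape) != npix)
    stop(fhe_condition("fhe_parse_error",
                       sprintf("expected %d pixel columns, found %d",
                               prod(shape), npix)))
  if (any(m[, -1L] < 0 | m[, -1L] > 255))
    stop(fhe_condition("fhe_parse_error", "pixel values outside 0-255"))
  n <- nrow(m)
  images <- array(0, dim = c(n, shape))
  for (i in seq_len(n))
    images[i, , ] <- matrix(m[i, -1L] / 255, shape[1], shape[2], byrow = TRUE)
  labels <- as.integer(m[, 1L])
  structure(list(images = images, labels = labels,
                 K = length(unique(labels)), shape = as.integer(shape)),
            class = "image_dataset")
}

#' Write an image dataset in the label + pixel CSV dialect
#'
#' @param ds an `image_dataset`.
#' @param path output file.
#' @export
write_label_pixel_csv <- function(ds, path) {
  n <- dim(ds$images)[1L]
  rows <- t(vapply(seq_len(n), function(i)
    c(ds$labels[i], round(as.numeric(t(ds$images[i, , ])) * 255)),
    numeric(1L + prod(ds$shape))))
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Synthetic environmental yield series

yield_feature_names <- c("temperature", "humidity", "light", "wind_speed",
                         "wind_dir_N", "wind_dir_E", "wind_dir_S",
                         "wind_dir_W", "precipitation", "soil_moisture",
                         "soil_temperature", "irrigation_status")

## fixed standardisation constants so the latent map is learnable (and the
## generator doubles as the parameter-recovery oracle)
yield_constants <- list(
  temp_mean = 16, temp_sd = 3.2,
  light_mean = 0.55, light_sd = 0.16,
  dd_mean = 1.0, dd_sd = 0.48,
  la_mean = 0.55, la_sd = 0.22,
  stress_mean = 0.04, stress_sd = 0.028,
  w_dd = 1.1, w_light = 0.8, w_stress = -0.7,
  link_gain = 0.8, y_lo = 0.4, y_span = 0.6
)

#' Synthetic environmental yield time-series
#'
#' Emulates polytunnel strawberry-yield forecasting data: smooth latent
#' weather processes (temperature, light, humidity, wind, precipitation,
#' irrigation and soil state) sampled daily, cut into non-overlapping
#' windows of `T_x` days, with a positive yield response at `horizon` days
#' after each window. The yield is a saturating (logistic) function of the
#' window's degree-day and light accumulations minus a moisture-stress term,
#' so it depends only on features at or before the prediction point;
#' multiplicative noise grows linearly with the horizon, making longer
#' horizons genuinely harder. Continuous features are standardised with
#' fixed constants; wind direction and irrigation are one-hot/binary.
#'
#' @param n number of windows.
#' @param T_x window length in days (>= 2).
#' @param horizon days-ahead of the prediction, one of 7, 14, 21.
#' @param noise_sd base relative noise at horizon 7.
#' @param seed RNG seed.
#' @return a `yield_series_dataset`: `windows` (`n x T_x x F`), `targets`
#'   (positive yields), `window_start` (day index), `horizon`,
#'   `feature_names`, and `latent` (the noiseless targets, retained so the
#'   generator can serve as its own recovery oracle).
#' @export
gen_yield_series <- function(n, T_x = 14, horizon = 7, noise_sd = 0.05,
                             seed = 42) {
  if (T_x < 2) stop(fhe_condition("fhe_value_error", "T_x must be >= 2"))
  if (!horizon %in% c(7L, 14L, 21L))
    stop(fhe_condition("fhe_value_error", "horizon must be 7, 14 or 21"))
  set.seed(seed)
  k <- yield_constants
  days <- n * T_x + horizon
  t <- seq_len(days)
  smooth <- function(sd, span = 5) {
    as.numeric(stats::filter(stats::rnorm(days + 2 * span, 0, sd),
                             rep(1 / span, span), sides = 2))[span + t]
  }
  temp <- 16 + 4 * sin(2 * pi * t / 365) + smooth(4)
  light <- pmin(pmax(0.55 + 0.3 * sin(2 * pi * t / 365) +
                       smooth(0.35), 0), 1)
  humidity <- pmin(pmax(0.65 - 0.2 * sin(2 * pi * t / 365) + smooth(0.3),
                        0.1), 1)
  wind_speed <- pmax(3 + smooth(2.5), 0)
  wind_dir <- sample.int(4, days, replace = TRUE,
                         prob = c(0.35, 0.25, 0.2, 0.2))
  precipitation <- pmax(smooth(1.5), 0)
  irrigation <- as.numeric((t %% 3) == 0)
  soil_moisture <- pmin(pmax(0.45 + 0.35 * as.numeric(
    stats::filter(precipitation + 0.5 * irrigation - 0.35,
                  0.6, method = "recursive")), 0.05), 1)
  soil_temp <- 0.8 * temp + 3 + smooth(1)

  F <- length(yield_feature_names)
  windows <- array(0, dim = c(n, T_x, F))
  targets <- numeric(n)
  latent <- numeric(n)
  starts <- integer(n)
  std <- function(x, m, s) (x - m) / s
  for (i in seq_len(n)) {
    ix <- ((i - 1L) * T_x + 1L):(i * T_x)
    starts[i] <- ix[1L]
    wd <- matrix(0, T_x, 4); wd[cbind(seq_len(T_x), wind_dir[ix])] <- 1
    windows[i, , ] <- cbind(
      std(temp[ix], k$temp_mean, k$temp_sd),
      std(humidity[ix], 0.65, 0.15),
      std(light[ix], k$light_mean, k$light_sd),
      std(wind_speed[ix], 3, 2),
      wd,
      std(precipitation[ix], 0.5, 0.6),
      std(soil_moisture[ix], 0.5, 0.2),
      std(soil_temp[ix], 16, 3),
      irrigation[ix])
    ## accumulations at or before the prediction point (window only)
    dd <- mean(pmax(temp[ix] - 10, 0)) / 6
    la <- mean(light[ix])
    stress <- mean(pmax(0.4 - soil_moisture[ix], 0) +
                     0.3 * pmax(temp[ix] - 24, 0) / 6)
    z <- k$w_dd * std(dd, k$dd_mean, k$dd_sd) +
      k$w_light * std(la, k$la_mean, k$la_sd) +
      k$w_stress * std(stress, k$stress_mean, k$stress_sd)
    latent[i] <- k$y_lo + k$y_span * sigmoid_exact(k$link_gain * z)
    eps <- stats::rnorm(1, 0, noise_sd * horizon / 7)
    targets[i] <- max(latent[i] * (1 + eps), 0.05)
  }
  dimnames(windows)[[3]] <- yield_feature_names
  structure(list(windows = windows, targets = targets, latent = latent,
                 window_start = starts, horizon = as.integer(horizon),
                 T_x = as.integer(T_x),
                 feature_names = yield_feature_names),
            class = "yield_series_dataset")
}

#' Invert the yield generator's link (recovery oracle helper)
#'
#' Maps observed yields back to the latent linear predictor through the
#' documented logistic link, so an ordinary linear regression on window
#' features recovers the generating map on noiseless data.
#'
#' @param y yields from [gen_yield_series()].
#' @export
yield_link_inverse <- function(y) {
  k <- yield_constants
  p <- pmin(pmax((y - k$y_lo) / k$y_span, 1e-6), 1 - 1e-6)
  log(p / (1 - p)) / k$link_gain
}

## ---------------------------------------------------------------------------

dataset_n <- function(ds) {
  if (inherits(ds, "image_dataset")) dim(ds$images)[1L]
  else if (inherits(ds, "yield_series_dataset")) dim(ds$windows)[1L]
  else stop(fhe_condition("fhe_value_error", "unknown dataset type"))
}

dataset_subset <- function(ds, ix) {
  if (inherits(ds, "image_dataset")) {
    out <- ds
    out$images <- ds$images[ix, , , drop = FALSE]
    out$labels <- ds$labels[ix]
    out
  } else {
    out <- ds
    out$windows <- ds$windows[ix, , , drop = FALSE]
    out$targets <- ds$targets[ix]
    out$latent <- ds$latent[ix]
    out$window_start <- ds$window_start[ix]
    out
  }
}

#' Random (or time-blocked) train/test split
#'
#' @param ds an `image_dataset` or `yield_series_dataset`.
#' @param fraction train fraction.
#' @param seed RNG seed for the random split.
#' @param time_blocked for series: put the chronologically first `fraction`
#'   of windows in train, so the test set is strictly later.
#' @return list with `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(ds, fraction = 0.8, seed = 42,
                             time_blocked = FALSE) {
  n <- dataset_n(ds)
  if (n < 2) stop(fhe_condition("fhe_value_error", "need at least 2 examples"))
  n_train <- floor(fraction * n)
  if (time_blocked && inherits(ds, "yield_series_dataset")) {
    ord <- order(ds$window_start)
    train_ix <- ord[seq_len(n_train)]
  } else {
    set.seed(seed)
    train_ix <- sample.int(n, n_train)
  }
  list(train = dataset_subset(ds, sort(train_ix)),
       test = dataset_subset(ds, sort(setdiff(seq_len(n), train_ix))))
}
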