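#' Synthetic femur phantom specification
#'
#' Parameters of one synthetic proximal-femur phantom: a bright bone region
#' (circular femoral head + oblique neck + vertical shaft) on a darker
#' background, with salt-and-pepper acquisition noise and a global
#' protocol-dependent intensity gain. The shapes are deliberately simple so
#' that every geometric parameter is recoverable from the ground-truth
#' mask.
#'
#' @param class_label 0 (healthy) or 1 (unhealthy); carried onto the image.
#' @param size Image side length in pixels (square image).
#' @param head_radius_px Femoral head radius.
#' @param neck_width_px Neck width; must be < 2 * head radius.
#' @param shaft_width_px Shaft width.
#' @param neck_shaft_angle_deg Anatomical neck-shaft angle (angle between
#'   the neck axis and the distal shaft direction), degrees.
#' @param bone_mean_intensity,bone_intensity_sd Gaussian intensity field
#'   inside the bone.
#' @param background_mean Constant background intensity.
#' @param salt_pepper_fraction Fraction of pixels replaced by salt (bright)
#'   or pepper (zero) noise, in `[0, 1]`.
#' @param protocol_gain Global multiplicative intensity scale (> 0),
#'   mimicking acquisition-protocol differences.
#' @param side `"left"` or `"right"`; right phantoms are exact mirrors of
#'   the equivalent left phantom.
#' @param t_score Optional DEXA T-score to carry onto the image.
#' @param rng_seed Integer seed; the same spec (including seed) always
#'   yields a bit-identical phantom.
#'
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(class_label = 0, size = 128,
                         head_radius_px = 20, neck_width_px = 14,
                         shaft_width_px = 18, neck_shaft_angle_deg = 130,
                         bone_mean_intensity = 180, bone_intensity_sd = 8,
                         background_mean = 30, salt_pepper_fraction = 0.02,
                         protocol_gain = 1, side = c("left", "right"),
                         t_score = NULL, rng_seed = 1) {
  side <- match.arg(side)
  geom <- c(head_radius_px = head_radius_px, neck_width_px = neck_width_px,
            shaft_width_px = shaft_width_px,
            neck_shaft_angle_deg = neck_shaft_angle_deg)
  if (any(geom <= 0)) {
    stop_pfb("all geometry parameters must be positive", "pfbmri_param_error")
  }
  if (head_radius_px <= neck_width_px / 2) {
    stop_pfb("head_radius_px must exceed neck_width_px / 2",
             "pfbmri_param_error")
  }
  if (salt_pepper_fraction < 0 || salt_pepper_fraction > 1) {
    stop_pfb("salt_pepper_fraction must lie in [0, 1]", "pfbmri_param_error")
  }
  if (protocol_gain <= 0) {
    stop_pfb("protocol_gain must be positive", "pfbmri_param_error")
  }
  if (size < 64) {
    stop_pfb("phantom size must be at least 64 px", "pfbmri_param_error")
  }
  structure(
    list(class_label = class_label, size = size,
         head_radius_px = head_radius_px, neck_width_px = neck_width_px,
         shaft_width_px = shaft_width_px,
         neck_shaft_angle_deg = neck_shaft_angle_deg,
         bone_mean_intensity = bone_mean_intensity,
         bone_intensity_sd = bone_intensity_sd,
         background_mean = background_mean,
         salt_pepper_fraction = salt_pepper_fraction,
         protocol_gain = protocol_gain, side = side, t_score = t_score,
         rng_seed = rng_seed),
    class = "phantom_spec")
}

# Ground-truth bone mask of the left-side phantom geometry: head disk +
# neck rectangle at the neck-shaft angle + vertical shaft rectangle, all
# overlapping (hence simply connected).
phantom_truth_mask <- function(spec) {
  n <- spec$size
  r <- spec$head_radius_px
  # junction of neck and shaft
  jr <- 0.52 * n
  jc <- 0.62 * n
  phi <- (spec$neck_shaft_angle_deg - 90) * pi / 180 # neck elevation
  dn <- c(-sin(phi), -cos(phi))                      # (drow, dcol), toward head
  neck_len <- 1.6 * r
  hc <- c(jr, jc) + neck_len * dn                    # head centre
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  # head disk
  head <- (g$r - hc[1])^2 + (g$c - hc[2])^2 <= r^2
  # neck: band of width neck_width along segment junction -> head centre
  vr <- g$r - jr
  vc <- g$c - jc
  t_along <- vr * dn[1] + vc * dn[2]
  t_perp <- abs(vr * dn[2] - vc * dn[1])
  neck <- t_along >= 0 & t_along <= neck_len & t_perp <= spec$neck_width_px / 2
  # shaft: vertical rectangle from the junction down to a bottom margin
  shaft_bottom <- n - max(6, round(0.06 * n))
  shaft <- g$r >= jr & g$r <= shaft_bottom &
    abs(g$c - jc) <= spec$shaft_width_px / 2
  m <- matrix(head | neck | shaft, n, n)
  attr(m, "head_center") <- hc
  attr(m, "junction") <- c(jr, jc)
  m
}

#' Generate a synthetic femur phantom
#'
#' Renders the phantom described by a [phantom_spec()]: the ground-truth
#' bone mask is filled with a Gaussian intensity field
#' (`bone_mean_intensity`, `bone_intensity_sd`), the background is the
#' constant `background_mean`, the whole image is scaled by
#' `protocol_gain`, and `salt_pepper_fraction` of the pixels are replaced
#' by extreme salt/pepper values. `side = "right"` phantoms are the exact
#' horizontal mirror of the equivalent left phantom with the same seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` ([pfb_image]) and `mask`
#'   ([pfb_mask], the exact ground truth, `method = "ground_truth"`).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(rng_seed = 7))
#' dim(ph$image)
#' sum(ph$mask$mask)
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  m <- phantom_truth_mask(spec)
  n <- spec$size
  img <- with_seed(spec$rng_seed, {
    im <- matrix(spec$background_mean, n, n)
    nb <- sum(m)
    im[m] <- spec$bone_mean_intensity +
      if (spec$bone_intensity_sd > 0) rnorm(nb, 0, spec$bone_intensity_sd) else 0
    im <- pmax(im, 0) * spec$protocol_gain
    if (spec$salt_pepper_fraction > 0) {
      n_noise <- round(spec$salt_pepper_fraction * n * n)
      if (n_noise > 0) {
        idx <- sample.int(n * n, n_noise)
        salt_val <- (spec$bone_mean_intensity + 4 * spec$bone_intensity_sd + 20) *
          spec$protocol_gain
        half <- seq_len(n_noise) <= n_noise / 2
        im[idx[half]] <- 0
        im[idx[!half]] <- salt_val
      }
    }
    im
  })
  head_center <- attr(m, "head_center")
  mm <- matrix(as.logical(m), n, n)
  if (spec$side == "right") {
    img <- img[, rev(seq_len(n))]
    mm <- mm[, rev(seq_len(n))]
    head_center[2] <- n + 1 - head_center[2]
  }
  image <- pfb_image(img, side = spec$side,
                     protocol = spec$protocol %||% NULL,
                     subject_id = sprintf("phantom_seed%d", spec$rng_seed),
                     t_score = spec$t_score, label = spec$class_label)
  mask <- pfb_mask(mm, method = "ground_truth")
  attr(mask, "head_center") <- head_center
  attr(mask, "spec") <- spec
  list(image = image, mask = mask)
}

#' The seven MRI acquisition protocols of the study cohort
#'
#' TR/TE/flip-angle settings and referred / healthy / unhealthy subject
#' counts for the seven acquisition protocols the cohort was scanned with.
#' [phantom_dataset()] samples protocols from this table (with a
#' protocol-specific intensity gain) to emulate multi-protocol acquisition.
#'
#' @return A tibble with columns `protocol`, `weighting`, `TR`, `TE`,
#'   `flip_angle`, `referred`, `healthy`, `unhealthy`, `gain`.
#' @export
mri_protocols <- function() {
  tibble::tibble(
    protocol = 1:7,
    weighting = c("T1", "T1", "T1", "T1", "T2", "T2", "T1"),
    TR = c(415, 536, 4070, 420, 3600, 7840, 389),
    TE = c(19, 11, 33, 22, 80, 109, 13.42),
    flip_angle = c(150, 180, 180, 180, 150, 150, 110),
    referred = c(44, 43, 42, 45, 45, 41, 24),
    healthy = c(33, 31, 29, 36, 19, 28, 9),
    unhealthy = c(11, 12, 13, 9, 26, 13, 15),
    gain = c(1.00, 1.10, 0.85, 1.05, 0.75, 0.70, 0.95)
  )
}

#' Generate a labeled phantom dataset with controllable class separation
#'
#' Draws `n_per_class` phantoms per class. Class differences (narrower,
#' lower-intensity, noisier bone for the unhealthy class, emulating
#' cortical thinning and marrow changes) are scaled by `separation`:
#' `separation = 0` makes the two class distributions identical (so any
#' classifier should sit at chance), `separation = 1` gives a clearly
#' separable cohort. Protocols are sampled from [mri_protocols()]
#' proportionally to the cohort's referred counts and set the intensity
#' gain; sides are random.
#'
#' @param n_per_class Phantoms per class.
#' @param separation Class-separation scale in `[0, 1]`.
#' @param size Image side length (px).
#' @param rng_seed Integer seed.
#' @return A [pfb_dataset] with ground-truth masks.
#' @export
phantom_dataset <- function(n_per_class = 30, separation = 1, size = 96,
                            rng_seed = 1) {
  stopifnot(separation >= 0, separation <= 1)
  protos <- mri_protocols()
  with_seed(rng_seed, {
    images <- list()
    masks <- list()
    k <- 0
    for (label in c(0, 1)) {
      s <- separation
      for (i in seq_len(n_per_class)) {
        k <- k + 1
        scale <- size / 128
        if (label == 0) {
          head_r <- runif(1, 18, 22) * scale
          neck_w <- rnorm(1, 15, 1.2) * scale
          bone_mu <- rnorm(1, 180, 6)
          bone_sd <- 8
          angle <- rnorm(1, 130, 3)
          t_sc <- runif(1, -0.8, 2.5)
        } else {
          head_r <- runif(1, 18 - 2 * s, 22 - 2 * s) * scale
          neck_w <- rnorm(1, 15 - 4.5 * s, 1.2) * scale
          bone_mu <- rnorm(1, 180 - 40 * s, 6)
          bone_sd <- 8 + 7 * s
          angle <- rnorm(1, 130 + 6 * s, 3)
          t_sc <- runif(1, -3.5, -0.9)
        }
        neck_w <- max(neck_w, 4)
        head_r <- max(head_r, neck_w / 2 + 2)
        p <- protos[sample.int(7, 1, prob = protos$referred), ]
        sp <- phantom_spec(
          class_label = label, size = size, head_radius_px = head_r,
          neck_width_px = neck_w,
          shaft_width_px = runif(1, 16, 20) * scale,
          neck_shaft_angle_deg = min(max(angle, 110), 160),
          bone_mean_intensity = max(bone_mu, 60),
          bone_intensity_sd = bone_sd,
          background_mean = 30, salt_pepper_fraction = 0.02,
          protocol_gain = p$gain,
          side = sample(c("left", "right"), 1),
          t_score = t_sc,
          rng_seed = sample.int(2^30, 1))
        ph <- generate_phantom(sp)
        ph$image$subject_id <- sprintf("phantom_%03d", k)
        ph$image$protocol <- list(TR = p$TR, TE = p$TE,
                                  flip_angle = p$flip_angle)
        images[[k]] <- ph$image
        masks[[k]] <- ph$mask
      }
    }
    pfb_dataset(images, masks)
  })
}

#' Add calibrated Gaussian white noise
#'
#' Adds zero-mean Gaussian noise whose variance is chosen so that
#' `10 * log10(signal_power / noise_variance) = snr_db`, where the signal
#' power is the mean squared intensity of the input image. By default the
#' result is clipped at zero (intensities stay non-negative); pass
#' `clip = FALSE` to keep the raw noisy field, e.g. when checking the
#' noise-variance calibration itself, which clipping would bias at low SNR.
#'
#' @param image A [pfb_image] (or matrix).
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param rng_seed Integer seed.
#' @param clip Clip negative intensities to zero (default `TRUE`).
#' @return A [pfb_image] with the same metadata; the target noise SD is
#'   attached as attribute `"noise_sd"`.
#' @export
add_gaussian_noise <- function(image, snr_db, rng_seed = 1, clip = TRUE) {
  px <- as_pixels(image)
  if (max(px) == min(px)) {
    stop_pfb("SNR is undefined for a constant image", "pfbmri_param_error")
  }
  p_sig <- mean(px^2)
  noise_var <- p_sig / 10^(snr_db / 10)
  noisy <- with_seed(rng_seed, px + rnorm(length(px), 0, sqrt(noise_var)))
  noisy <- matrix(noisy, nrow(px), ncol(px))
  if (clip) noisy <- pmax(noisy, 0)
  out <- if (inherits(image, "pfb_image")) {
    image$pixels <- noisy
    image
  } else {
    noisy
  }
  attr(out, "noise_sd") <- sqrt(noise_var)
  out
}

#' Balance classes by augmenting the minority class
#'
#' Appends synthetic copies of minority-class images (uniform random
#' rotation in `[-rotation_range_deg, +rotation_range_deg]` and uniform
#' random horizontal/vertical shifts of at most `shift_fraction` of the
#' image dimension) until both classes have equal counts. Ground-truth
#' masks, when present, are transformed identically (nearest-neighbour).
#' Original images are never modified.
#'
#' @param dataset A [pfb_dataset] containing both classes.
#' @param rotation_range_deg Rotation half-range in degrees (default 40).
#' @param shift_fraction Maximum shift as a fraction of each image
#'   dimension (default 0.2).
#' @param rng_seed Integer seed.
#' @return A [pfb_dataset] with equal class counts; augmented images carry
#'   subject ids suffixed `_augN`.
#' @export
augment_minority <- function(dataset, rotation_range_deg = 40,
                             shift_fraction = 0.2, rng_seed = 1) {
  labs <- dataset_labels(dataset)
  if (anyNA(labs)) {
    stop_pfb("all images must carry labels for augmentation",
             "pfbmri_balance_error")
  }
  n0 <- sum(labs == 0)
  n1 <- sum(labs == 1)
  if (n0 == 0 || n1 == 0) {
    stop_pfb("augmentation needs both classes present",
             "pfbmri_balance_error")
  }
  if (n0 == n1) return(dataset)
  minority <- if (n0 < n1) 0 else 1
  min_idx <- which(labs == minority)
  n_add <- abs(n0 - n1)
  with_seed(rng_seed, {
    src <- rep(min_idx, length.out = n_add)
    images <- dataset$images
    masks <- dataset$masks
    for (i in seq_len(n_add)) {
      im <- images[[src[i]]]
      ang <- runif(1, -rotation_range_deg, rotation_range_deg)
      dr <- runif(1, -shift_fraction, shift_fraction) * nrow(im$pixels)
      dc <- runif(1, -shift_fraction, shift_fraction) * ncol(im$pixels)
      bg <- median(im$pixels[c(1, nrow(im$pixels)),
                             c(1, ncol(im$pixels))])
      new_im <- im
      new_im$pixels <- pmax(affine_resample(im$pixels, ang, dr, dc,
                                            "bilinear", fill = bg), 0)
      new_im$subject_id <- sprintf("%s_aug%d", im$subject_id, i)
      images[[length(images) + 1]] <- new_im
      if (!is.null(masks)) {
        mk <- masks[[src[i]]]
        newm <- affine_resample(mk$mask * 1, ang, dr, dc, "nearest", fill = 0)
        masks[[length(masks) + 1]] <-
          tryCatch(pfb_mask(newm > 0.5, method = mk$method),
                   error = function(e) pfb_mask(newm > 0.5,
                                                method = mk$method,
                                                check = FALSE))
      }
    }
    pfb_dataset(images, masks)
  })
}
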