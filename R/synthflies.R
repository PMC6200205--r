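# Procedural generator of individual fly image chips.
#
# The goal is statistical structure, not photorealism: each individual owns a
# latent morphology vector (sizes, abdominal pigmentation stripes, wing
# opacity, leg thickness) that persists across recording days, while days add
# nuisance variation (small latent drift, illumination gain) and frames add
# pose jitter and pixel noise. That is exactly the structure an across-day
# re-identification experiment needs: identity signal that survives the day
# boundary, wrapped in within-day correlation and noise.

latent_names <- c("body_len", "thorax_w", "abd_w", "taper",
                  paste0("stripe", 1:5), "wing_op", "leg_th")

latent_base <- c(body_len = 112.5, thorax_w = 32, abd_w = 38, taper = 0.65,
                 stripe1 = 0.55, stripe2 = 0.55, stripe3 = 0.55,
                 stripe4 = 0.55, stripe5 = 0.55, wing_op = 0.25, leg_th = 2.2)

# female-minus-male mean difference at dimorphism = 1 (females larger; males
# darker posterior abdomen, i.e. lower stripe intensity near the tip)
latent_sexdiff <- c(body_len = 15, thorax_w = 4, abd_w = 8, taper = -0.1,
                    stripe1 = 0, stripe2 = 0, stripe3 = 0.1,
                    stripe4 = 0.3, stripe5 = 0.35, wing_op = 0, leg_th = 0)

# between-individual standard deviations (the identity signal); size and
# shape dominate, pigmentation varies more subtly, as in real conspecifics
latent_sd <- c(body_len = 9, thorax_w = 3, abd_w = 3.5, taper = 0.05,
               stripe1 = 0.05, stripe2 = 0.05, stripe3 = 0.05,
               stripe4 = 0.05, stripe5 = 0.05, wing_op = 0.04, leg_th = 0.3)

clamp_latent <- function(l) {
  l["body_len"] <- min(max(l["body_len"], 70), 160)
  l["thorax_w"] <- min(max(l["thorax_w"], 16), 52)
  l["abd_w"] <- min(max(l["abd_w"], 18), 60)
  l["taper"] <- min(max(l["taper"], 0.3), 0.9)
  s <- grep("^stripe", names(l))
  l[s] <- pmin(pmax(l[s], 0.05), 0.95)
  l["wing_op"] <- min(max(l["wing_op"], 0.05), 0.6)
  l["leg_th"] <- min(max(l["leg_th"], 1), 4)
  l
}

#' Generate a population of synthetic fly identities
#'
#' Sexes are balanced (first half male, second half female) and each
#' individual draws a latent morphology vector from Gaussians around
#' sex-specific means. The latent vector is fixed for the lifetime of the
#' individual — it is what makes the fly re-identifiable across days.
#'
#' @param n number of flies (even, at least 2; default 20 = 10 M + 10 F).
#' @param seed integer seed; the same seed reproduces the same population.
#' @param dimorphism scales the male/female mean separation: 1 = default
#'   sexual dimorphism, 0 = sexes differ only by label.
#' @return list of \code{fly_identity} objects (class \code{fly_population});
#'   the per-sex latent means used are stored in the \code{"sex_means"}
#'   attribute.
#' @export
make_population <- function(n = 20L, seed = 1L, dimorphism = 1) {
  if (n < 2) stop("need at least 2 flies")
  if (n %% 2 != 0) stop("n must be even for balanced sexes")
  mean_M <- latent_base - dimorphism * latent_sexdiff / 2
  mean_F <- latent_base + dimorphism * latent_sexdiff / 2
  sexes <- rep(c("M", "F"), each = n / 2)
  pop <- with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      mu <- if (sexes[i] == "M") mean_M else mean_F
      lat <- rnorm(length(mu), mu, latent_sd)
      names(lat) <- latent_names
      lat <- clamp_latent(lat)
      structure(list(id = i, sex = sexes[i], latent = lat,
                     seed = sub_seeds[i]),
                class = "fly_identity")
    })
  })
  structure(pop, class = "fly_population",
            sex_means = list(M = mean_M, F = mean_F))
}

#' @export
print.fly_population <- function(x, ...) {
  cat("<fly_population> ", length(x), " flies (",
      sum(vapply(x, function(f) f$sex, "") == "M"), " M, ",
      sum(vapply(x, function(f) f$sex, "") == "F"), " F)\n", sep = "")
  invisible(x)
}

clamp01 <- function(x) {
  y <- clamp01_cpp(x)
  attributes(y) <- attributes(x)
  y
}

# soft-edged ellipse coverage in [0,1]; ~2 px anti-aliased edge
soft_ellipse <- function(x, y, cx, cy, ax, ay, soft = 2) {
  q <- sqrt(((x - cx) / ax)^2 + ((y - cy) / ay)^2)
  clamp01((1 - q) * min(ax, ay) / soft + 0.5)
}

# coverage of a thick line segment (for legs)
soft_segment <- function(x, y, x0, y0, x1, y1, half_th) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- clamp01(((x - x0) * dx + (y - y0) * dy) / len2)
  d <- sqrt((x - (x0 + t * dx))^2 + (y - (y0 + t * dy))^2)
  clamp01(half_th + 1 - d)
}

# paint: alpha-blend a value over the canvas
blend <- function(img, cov, value, alpha = 1) {
  a <- cov * alpha
  img * (1 - a) + value * a
}

#' Render one synthetic fly chip
#'
#' Draws a stylized grayscale fly — head, thorax, tapered abdomen with five
#' pigmentation stripes, wings and legs depending on viewpoint — centred and
#' facing up on a 181x181 chip. The recording day perturbs the latent
#' morphology by a multiplicative Gaussian drift of sd \code{day_drift_sd}
#' and applies a day-specific illumination gain; both are derived
#' deterministically from the identity and the day, so every frame of one
#' fly-day shares them. Pose jitter (small rotation/translation) and additive
#' pixel noise are drawn from the current RNG stream (or from \code{seed}
#' when given, leaving the caller's stream untouched).
#'
#' @param identity a \code{fly_identity} from [make_population()].
#' @param viewpoint "dorsal", "ventral" or "lateral".
#' @param day recording day (>= 1).
#' @param day_drift_sd sd of the per-day multiplicative latent drift.
#' @param noise_sd sd of additive Gaussian pixel noise.
#' @param pose_rot_sd,pose_shift_sd pose jitter: rotation sd in degrees,
#'   translation sd in pixels. Set to 0 to disable.
#' @param seed optional integer for a fully reproducible chip.
#' @param size chip side length in pixels (default 181).
#' @return \code{size} x \code{size} matrix in [0,1].
#' @export
render_chip <- function(identity, viewpoint = "dorsal", day = 1L,
                        day_drift_sd = 0.02, noise_sd = 0.05,
                        pose_rot_sd = 6, pose_shift_sd = 3,
                        seed = NULL, size = 181L) {
  stopifnot(inherits(identity, "fly_identity"))
  if (!viewpoint %in% c("dorsal", "ventral", "lateral"))
    stop("viewpoint must be dorsal, ventral or lateral")
  if (!is.null(seed)) return(with_seed(seed, render_chip(
    identity, viewpoint, day, day_drift_sd, noise_sd,
    pose_rot_sd, pose_shift_sd, seed = NULL, size = size)))

  # deterministic per-(fly, day) state: latent drift + illumination gain
  day_state <- with_seed(identity$seed %% 100000000L + 1009L * as.integer(day), {
    list(drift = rnorm(length(identity$latent), 0, day_drift_sd),
         gain = 1 + rnorm(1, 0, day_drift_sd))
  })
  lat <- clamp_latent(identity$latent * (1 + day_state$drift))
  px_scale <- size / 181           # native geometry is defined on 181 px
  # pose jitter + noise come from the ambient stream
  ang <- rnorm(1, 0, pose_rot_sd) * pi / 180
  tx <- rnorm(1, 0, pose_shift_sd) * px_scale
  ty <- rnorm(1, 0, pose_shift_sd) * px_scale

  c0 <- (size + 1) / 2
  xg <- matrix(rep(seq_len(size) - c0, each = size), size, size)  # column offset
  yg <- matrix(rep(seq_len(size) - c0, times = size), size, size) # row offset
  # into the (jittered) body frame
  xb <- cos(ang) * (xg - tx) + sin(ang) * (yg - ty)
  yb <- -sin(ang) * (xg - tx) + cos(ang) * (yg - ty)

  Lb <- lat["body_len"] * px_scale
  wfac <- switch(viewpoint, dorsal = 1, ventral = 1, lateral = 0.55)
  thw <- lat["thorax_w"] * px_scale * wfac / 2
  abw <- lat["abd_w"] * px_scale * wfac / 2
  leg_half <- lat["leg_th"] * px_scale / 2

  img <- matrix(0.08, size, size)

  # wings first (translucent, under the body)
  if (viewpoint == "dorsal") {
    for (s in c(-1, 1)) {
      wa <- s * 25 * pi / 180
      xw <- cos(wa) * xb + sin(wa) * yb
      yw <- -sin(wa) * xb + cos(wa) * yb
      cov <- soft_ellipse(xw, yw, s * 0.10 * Lb, 0.18 * Lb,
                          0.14 * Lb, 0.38 * Lb)
      img <- blend(img, cov, 0.72, alpha = lat["wing_op"])
    }
  } else if (viewpoint == "lateral") {
    cov <- soft_ellipse(xb, yb, 0.10 * Lb, 0.12 * Lb, 0.10 * Lb, 0.34 * Lb)
    img <- blend(img, cov, 0.72, alpha = min(1, 1.6 * lat["wing_op"]))
  }

  # legs (ventral: both sides; lateral: one side)
  if (viewpoint != "dorsal") {
    sides <- if (viewpoint == "ventral") c(-1, 1) else 1
    for (s in sides) {
      for (k in 1:3) {
        y0 <- (-0.16 + 0.10 * k) * Lb
        cov <- soft_segment(xb, yb, s * thw * 0.6, y0,
                            s * (thw * 0.6 + 0.26 * Lb),
                            y0 + (k - 2) * 0.16 * Lb,
                            leg_half)
        img <- blend(img, cov, 0.30, alpha = 0.85)
      }
    }
  }

  base <- if (viewpoint == "ventral") 0.06 else 0
  # head (anterior, negative y), thorax, abdomen
  head_cov <- soft_ellipse(xb, yb, 0, -0.40 * Lb, 0.11 * Lb * max(wfac, 0.7),
                           0.10 * Lb)
  img <- blend(img, head_cov, 0.36 + base)
  thor_cov <- soft_ellipse(xb, yb, 0, -0.17 * Lb, thw, 0.17 * Lb)
  img <- blend(img, thor_cov, 0.46 + base)

  ab_cy <- 0.17 * Lb; ab_len <- 0.33 * Lb
  tfrac <- clamp01((yb - (ab_cy - ab_len)) / (2 * ab_len))
  halfw <- pmax(abw * (1 - (1 - lat["taper"]) * tfrac), 1)
  qa <- sqrt((xb / halfw)^2 + ((yb - ab_cy) / ab_len)^2)
  ab_cov <- clamp01((1 - qa) * min(abw, ab_len) / 2 + 0.5)
  stripe_scale <- switch(viewpoint, dorsal = 1, ventral = 0.5, lateral = 0.8)
  band <- pmin(floor(tfrac * 5) + 1, 5)
  stripes <- lat[paste0("stripe", 1:5)]
  ab_val <- 0.5 * (1 - stripe_scale) + stripe_scale * stripes[band] + base
  img <- img * (1 - ab_cov) + matrix(ab_val, size, size) * ab_cov

  img <- img * day_state$gain
  if (noise_sd > 0) img <- img + rnorm(size * size, 0, noise_sd)
  clamp01(img)
}

#' Specification of a synthetic recording session
#'
#' Defaults emulate the acquisition design of the study this package models:
#' 20 flies (10 per sex) filmed for 15 minutes at 16 frames/second on each of
#' 3 consecutive days, i.e. 14,400 frames per fly per day. For desk-scale
#' work pass \code{frames_per_day} directly; \code{minutes} is then derived
#' so that \code{frames_per_day == minutes * 60 * fps} always holds.
#'
#' @param n_flies number of individuals (even; default 20).
#' @param n_days number of recording days (default 3).
#' @param minutes recording length per day (default 15).
#' @param fps frames per second (default 16).
#' @param frames_per_day optional override; sets \code{minutes} accordingly.
#' @param viewpoint_mix named probabilities over dorsal/ventral/lateral
#'   (must sum to 1; default uniform thirds).
#' @param day_drift_sd per-day multiplicative latent drift sd (default 0.02).
#' @param noise_sd additive pixel noise sd (default 0.05).
#' @param dimorphism see [make_population()].
#' @param pose_rot_sd,pose_shift_sd pose jitter bounds (degrees, pixels).
#' @param chip_size native chip side (default 181).
#' @return object of class \code{session_spec}.
#' @export
session_spec <- function(n_flies = 20L, n_days = 3L, minutes = 15,
                         fps = 16L, frames_per_day = NULL,
                         viewpoint_mix = c(dorsal = 1/3, ventral = 1/3,
                                           lateral = 1/3),
                         day_drift_sd = 0.02, noise_sd = 0.05,
                         dimorphism = 1, pose_rot_sd = 6,
                         pose_shift_sd = 3, chip_size = 181L) {
  if (is.null(frames_per_day)) {
    frames_per_day <- minutes * 60 * fps
    if (frames_per_day != round(frames_per_day))
      stop("minutes * 60 * fps must be an integer frame count")
  } else {
    minutes <- frames_per_day / (60 * fps)
  }
  if (abs(sum(viewpoint_mix) - 1) > 1e-8)
    stop("viewpoint_mix must sum to 1")
  stopifnot(frames_per_day == minutes * 60 * fps)
  structure(list(n_flies = as.integer(n_flies), n_days = as.integer(n_days),
                 minutes = minutes, fps = as.integer(fps),
                 frames_per_day = as.integer(frames_per_day),
                 viewpoint_mix = viewpoint_mix,
                 day_drift_sd = day_drift_sd, noise_sd = noise_sd,
                 dimorphism = dimorphism, pose_rot_sd = pose_rot_sd,
                 pose_shift_sd = pose_shift_sd,
                 chip_size = as.integer(chip_size)),
            class = "session_spec")
}

#' Generate a full synthetic chip dataset
#'
#' Renders \code{n_flies * n_days * frames_per_day} chips. An optional
#' per-chip \code{transform} (e.g. [bottleneck_29()]) is applied at
#' generation time so only the transformed chips are ever held in memory —
#' the streamed mode that makes full-scale sessions tractable. With
#' \code{out} set, chips are written incrementally to an HDF5 stack instead
#' of being returned.
#'
#' @param spec a [session_spec()].
#' @param seed integer; drives the population and every frame.
#' @param transform optional function matrix -> matrix applied to each chip.
#' @param out optional HDF5 path for streamed output.
#' @param overwrite replace an existing \code{out} file.
#' @return a [chip_stack()] (in-memory mode) or \code{out} invisibly. The
#'   stack carries per-fly body sizes and sexes in attributes
#'   \code{fly_sizes} / \code{fly_sexes} for confusion-matrix ordering.
#' @export
make_dataset <- function(spec, seed = 1L, transform = NULL, out = NULL,
                         overwrite = FALSE) {
  stopifnot(inherits(spec, "session_spec"))
  pop <- make_population(spec$n_flies, seed = seed,
                         dimorphism = spec$dimorphism)
  probe <- render_chip(pop[[1]], "dorsal", day = 1L,
                       day_drift_sd = spec$day_drift_sd, noise_sd = 0,
                       pose_rot_sd = 0, pose_shift_sd = 0, seed = 1L,
                       size = spec$chip_size)
  if (!is.null(transform)) probe <- transform(probe)
  H <- nrow(probe); W <- ncol(probe)
  total <- spec$n_flies * spec$n_days * spec$frames_per_day

  if (is.null(out) && 8 * as.double(H) * W * total > 3e9)
    stop("in-memory dataset would exceed 3 GB; pass out = \"file.h5\" to ",
         "stream to disk, or reduce frames_per_day / use a transform")
  if (!is.null(out) && file.exists(out)) {
    if (!overwrite) stop("file exists (use overwrite = TRUE): ", out)
    unlink(out)
  }
  if (!is.null(out)) {
    rhdf5::h5createFile(out)
    rhdf5::h5createDataset(out, "images", dims = c(H, W, total),
                           storage.mode = "double",
                           chunk = c(H, W, min(64L, total)))
  }

  images <- if (is.null(out)) array(NA_real_, c(H, W, total)) else NULL
  meta <- data.frame(identity = integer(total), sex = character(total),
                     day = integer(total), viewpoint = character(total),
                     frame = integer(total), stringsAsFactors = FALSE)
  vps <- names(spec$viewpoint_mix)

  with_seed(seed + 1L, {
    pos <- 0L
    block <- array(NA_real_, c(H, W, spec$frames_per_day))
    for (fly in pop) {
      for (d in seq_len(spec$n_days)) {
        vp <- sample(vps, spec$frames_per_day, replace = TRUE,
                     prob = spec$viewpoint_mix)
        for (fr in seq_len(spec$frames_per_day)) {
          chip <- render_chip(fly, vp[fr], day = d,
                              day_drift_sd = spec$day_drift_sd,
                              noise_sd = spec$noise_sd,
                              pose_rot_sd = spec$pose_rot_sd,
                              pose_shift_sd = spec$pose_shift_sd,
                              size = spec$chip_size)
          if (!is.null(transform)) chip <- transform(chip)
          block[, , fr] <- chip
        }
        idx <- pos + seq_len(spec$frames_per_day)
        if (is.null(out)) images[, , idx] <- block
        else rhdf5::h5write(block, out, "images",
                            index = list(NULL, NULL, idx))
        meta$identity[idx] <- fly$id
        meta$sex[idx] <- fly$sex
        meta$day[idx] <- d
        meta$viewpoint[idx] <- vp
        meta$frame[idx] <- seq_len(spec$frames_per_day)
        pos <- pos + spec$frames_per_day
      }
    }
  })

  sizes <- vapply(pop, function(f) unname(f$latent["body_len"]), 0)
  names(sizes) <- vapply(pop, function(f) as.character(f$id), "")
  sexes <- vapply(pop, function(f) f$sex, "")
  names(sexes) <- names(sizes)

  if (!is.null(out)) {
    for (col in names(meta)) rhdf5::h5write(meta[[col]], out, col)
    rhdf5::h5write(as.integer(names(sizes)), out, "fly_id")
    rhdf5::h5write(as.numeric(sizes), out, "fly_size")
    rhdf5::h5write(sexes, out, "fly_sex")
    rhdf5::h5closeAll()
    return(invisible(out))
  }
  st <- chip_stack(images, meta$identity, meta$sex, meta$day, meta$viewpoint,
                   meta$frame)
  attr(st, "fly_sizes") <- sizes
  attr(st, "fly_sexes") <- sexes
  st
}
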