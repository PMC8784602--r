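# Synthetic H&E-like ROI generator. The images are a stylised proxy for
# stained myocardium — an eosin-pink textured background with
# hematoxylin-dark nuclear disks — not photorealistic histology. What
# matters for testing is controllable statistical structure: the failure
# class differs from non-failure only through (a) enlarged nuclei, (b)
# infiltration-like clusters of small dark cells, and (c) perinuclear
# vacuolation-like clearings, all scaled by a single effect size, with
# exact ground-truth masks over the planted class-specific pixels.
#
# RNG discipline: every random draw for a ROI happens in a fixed order that
# does not depend on the label, so rendering the same seeds under the
# opposite label changes planted-structure pixels only — the property the
# mask tests rely on.

#' Configuration for the synthetic EMB-like dataset
#'
#' Defaults emulate the structure of the real collection this package is
#' aimed at: 250 x 250 px ROIs (50 x 50 um^2 at 0.2 um/px), 11 ROIs per
#' case. Failure-class differences are all scaled by `effect_size`:
#' the failure nucleus radius distribution is
#' `nonfailure + effect_size * (failure - nonfailure)` and the
#' infiltration/vacuole probabilities are `min(1, prob * effect_size)`,
#' so `effect_size = 0` makes the two class-conditional image
#' distributions identical and larger values make the classes easier to
#' separate.
#'
#' @param img_size square ROI side in pixels (>= 64)
#' @param n_rois_per_case ROIs generated per case (default 11)
#' @param nucleus_density nuclei proposed per ROI (a minimum-separation
#'   thinning keeps planted structures disjoint, so the realised count can
#'   be lower)
#' @param nucleus_radius_nonfailure,nucleus_radius_failure `c(mean, sd)` of
#'   the nucleus radius in px for each class (failure applies at
#'   `effect_size = 1`)
#' @param infiltration_prob probability a failure ROI receives a dense
#'   small-cell cluster (before effect-size scaling)
#' @param vacuole_prob probability a failure ROI receives perinuclear
#'   clearings (before effect-size scaling)
#' @param effect_size nonnegative scalar scaling all class differences
#' @param background_rgb,nucleus_rgb stain base colors in \[0, 1\]
#' @param noise_sd additive Gaussian pixel noise sd
#' @param seed master seed; per-ROI seeds are derived from
#'   (seed, case_seed, roi_index) so any ROI is regenerable in isolation
#' @return a list of class `"synth_config"`
#' @export
synth_config <- function(img_size = 250L, n_rois_per_case = 11L,
                         nucleus_density = 40L,
                         nucleus_radius_nonfailure = c(4, 0.8),
                         nucleus_radius_failure = c(6, 1.2),
                         infiltration_prob = 0.5, vacuole_prob = 0.5,
                         effect_size = 1,
                         background_rgb = c(0.91, 0.77, 0.83),
                         nucleus_rgb = c(0.36, 0.25, 0.52),
                         noise_sd = 0.02, seed = 0L) {
  if (img_size < 64) stop("img_size must be >= 64")
  for (p in c(infiltration_prob, vacuole_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  structure(list(img_size = as.integer(img_size),
                 n_rois_per_case = as.integer(n_rois_per_case),
                 nucleus_density = as.integer(nucleus_density),
                 nucleus_radius_nonfailure = nucleus_radius_nonfailure,
                 nucleus_radius_failure = nucleus_radius_failure,
                 infiltration_prob = infiltration_prob,
                 vacuole_prob = vacuole_prob, effect_size = effect_size,
                 background_rgb = background_rgb, nucleus_rgb = nucleus_rgb,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# Effective failure radius distribution at the configured effect size.
failure_radius <- function(cfg) {
  cfg$nucleus_radius_nonfailure + cfg$effect_size *
    (cfg$nucleus_radius_failure - cfg$nucleus_radius_nonfailure)
}

# Paint an annulus (r0 < d <= r1; a full disk when r0 = 0) into `img` and
# optionally mark it in `mask`. With `color = NULL` only the mask is marked
# (used for attenuation annuli, where the planted change is the *absence*
# of stain). Returns modified copies.
paint_annulus <- function(img, mask, cx, cy, r0, r1, color, mark) {
  S <- dim(img)[1]
  xr <- max(1L, floor(cx - r1)):min(S, ceiling(cx + r1))
  yr <- max(1L, floor(cy - r1)):min(S, ceiling(cy + r1))
  if (!length(xr) || !length(yr)) return(list(img = img, mask = mask))
  d2 <- outer((yr - cy)^2, (xr - cx)^2, "+")
  sel <- d2 <= r1^2 & d2 > r0^2
  if (any(sel)) {
    if (!is.null(color)) {
      for (ch in 1:3) {
        plane <- img[yr, xr, ch]
        plane[sel] <- color[ch]
        img[yr, xr, ch] <- plane
      }
    }
    mp <- mask[yr, xr]
    mp[sel] <- mp[sel] | mark
    mask[yr, xr] <- mp
  }
  list(img = img, mask = mask)
}

# Generate one ROI (image + lesion mask) for a given label.
generate_roi <- function(label, cfg, roi_seed) {
  S <- cfg$img_size
  set.seed(roi_seed)
  # -- background: smooth eosin texture with faint fiber striations --------
  coarse <- matrix(stats::runif(64, -1, 1), 8, 8)
  tex <- 1 + 0.10 * bilinear_resize(coarse, S, S)
  ang <- stats::runif(1, 0, pi)
  phase <- stats::runif(1, 0, 2 * pi)
  freq <- stats::runif(1, 0.15, 0.35)
  xy <- outer(seq_len(S) * sin(ang), seq_len(S) * cos(ang), "+")
  tex <- tex * (1 + 0.04 * sin(freq * xy + phase))
  img <- array(0, c(S, S, 3))
  for (ch in 1:3) img[, , ch] <- cfg$background_rgb[ch] * tex
  mask <- matrix(FALSE, S, S)

  # -- label-independent structure proposals -------------------------------
  n <- cfg$nucleus_density
  px <- stats::runif(n, 2, S - 1)
  py <- stats::runif(n, 2, S - 1)
  z <- stats::rnorm(n)                        # radius quantiles, shared
  shade <- stats::runif(n, -0.05, 0.05)       # per-nucleus color jitter
  u_inf <- stats::runif(1)
  inf_cx <- stats::runif(1, 0.2 * S, 0.8 * S)
  inf_cy <- stats::runif(1, 0.2 * S, 0.8 * S)
  n_inf <- 10L + stats::rpois(1, 3)
  inf_dx <- stats::rnorm(40)                  # generous pools; first n_inf used
  inf_dy <- stats::rnorm(40)
  inf_r <- stats::runif(40, 0.6, 1.1)
  u_vac <- stats::runif(1)
  vac_pick <- stats::runif(n)
  hyper_pick <- stats::runif(n)
  noise <- array(stats::rnorm(S * S * 3, sd = cfg$noise_sd), c(S, S, 3))

  # -- thinning: keep nuclei far enough apart that planted structures
  #    (enlarged disks, vacuole rings) never overlap another nucleus -------
  rf <- failure_radius(cfg)
  rmax <- max(rf[1] + 3 * rf[2], cfg$nucleus_radius_nonfailure[1] +
                3 * cfg$nucleus_radius_nonfailure[2])
  minsep <- 2.8 * rmax
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    if (any(keep)) {
      ok <- all((px[i] - px[keep])^2 + (py[i] - py[keep])^2 >= minsep^2)
    }
    keep[i] <- ok
  }
  kx <- px[keep]; ky <- py[keep]; kz <- z[keep]
  kshade <- shade[keep]; kvac <- vac_pick[keep]
  khyper <- hyper_pick[keep]

  failing <- identical(label, "failure")
  e <- cfg$effect_size
  rn <- cfg$nucleus_radius_nonfailure
  r_nf <- pmax(1, rn[1] + rn[2] * kz)

  # Failure nucleus sizes: a subset of nuclei is hypertrophied to the
  # (effect-size-interpolated) failure radius distribution, and the
  # remaining nuclei are attenuated so that the total nuclear area matches
  # the non-failure rendering. The class signal is therefore morphological
  # (size dispersion, hypertrophic outliers), not total stain quantity —
  # which also mirrors the coexistence of hypertrophic and attenuated
  # fibers in failing myocardium.
  p_inf <- min(1, cfg$infiltration_prob * e)
  p_vac <- min(1, cfg$vacuole_prob * e)
  has_inf <- failing && u_inf < p_inf
  has_vac <- failing && u_vac < p_vac
  r_lab <- r_nf
  if (failing && e > 0) {
    hyper <- khyper < 0.3
    r_big <- pmax(1, rf[1] + rf[2] * kz)
    s_all <- sum(r_nf^2)
    s_big <- sum(r_big[hyper]^2)
    s_inf <- if (has_inf) sum(inf_r[seq_len(n_inf)]^2) else 0
    s_rest <- sum(r_nf[!hyper]^2)
    shrink <- if (s_rest > 0) {
      sqrt(clamp((s_all - s_big - s_inf) / s_rest, 0.25, 1))
    } else 1
    r_lab[hyper] <- r_big[hyper]
    r_lab[!hyper] <- pmax(1, shrink * r_nf[!hyper])
  }

  # -- nuclei: common core disk, plus hypertrophy / attenuation annuli -----
  for (i in seq_along(kx)) {
    color <- clamp(cfg$nucleus_rgb + kshade[i], 0, 1)
    core <- min(r_nf[i], r_lab[i])
    pa <- paint_annulus(img, mask, kx[i], ky[i], 0, core, color, mark = FALSE)
    img <- pa$img; mask <- pa$mask
    if (r_lab[i] > core) {          # hypertrophied: extra stained annulus
      pa <- paint_annulus(img, mask, kx[i], ky[i], core, r_lab[i], color,
                          mark = TRUE)
      img <- pa$img; mask <- pa$mask
    } else if (r_nf[i] > core) {    # attenuated: stain replaced by background
      pa <- paint_annulus(img, mask, kx[i], ky[i], core, r_nf[i], NULL,
                          mark = TRUE)
      img <- pa$img; mask <- pa$mask
    }
  }

  # -- infiltration-like cluster of small dark cells (failure only) --------
  if (has_inf) {
    spread <- rmax
    for (j in seq_len(n_inf)) {
      cx <- clamp(inf_cx + spread * inf_dx[j], 2, S - 1)
      cy <- clamp(inf_cy + spread * inf_dy[j], 2, S - 1)
      pa <- paint_annulus(img, mask, cx, cy, 0, inf_r[j],
                          clamp(cfg$nucleus_rgb - 0.08, 0, 1), mark = TRUE)
      img <- pa$img; mask <- pa$mask
    }
  }

  # -- perinuclear vacuolation-like clearing (failure only): a flat,
  #    faintly lightened halo — visible as loss of fiber texture around the
  #    nucleus rather than as a bright ring -------------------------------
  if (has_vac) {
    halo <- clamp(cfg$background_rgb * 1.06, 0, 1)
    sel <- kvac < 0.4
    for (i in which(sel)) {
      pa <- paint_annulus(img, mask, kx[i], ky[i], r_lab[i], 1.7 * r_lab[i],
                          halo, mark = TRUE)
      img <- pa$img; mask <- pa$mask
    }
  }

  img <- clamp(img + noise, 0, 1)
  list(image = img, mask = mask,
       stats = c(n_nuclei = length(kx), mean_radius = mean(r_lab)))
}

#' Generate one synthetic case (images plus ground-truth lesion masks)
#'
#' Produces `n_rois_per_case` ROI images for one case under the given label.
#' Per-ROI seeds are derived from `(config$seed, case_seed, roi_index)`, so
#' generation is bit-reproducible and any single ROI can be regenerated in
#' isolation. Lesion masks mark exactly the pixels of planted
#' failure-specific structure (nucleus-enlargement annuli, infiltration
#' clusters, vacuole clearings); they are empty for non-failure ROIs and,
#' when `effect_size > 0`, nonempty for failure ROIs.
#'
#' @param label `"failure"` or `"non_failure"`
#' @param config a [synth_config()]
#' @param case_seed integer seed component for this case
#' @return a list with `images` (list of img_size^2 x 3 arrays), `masks`
#'   (list of logical matrices), `stats` (per-ROI realised nucleus count and
#'   mean radius) and `label`
#' @export
generate_case <- function(label, config, case_seed) {
  check_labels(label)
  rois <- lapply(seq_len(config$n_rois_per_case), function(r) {
    generate_roi(label, config, mix_seed(config$seed, case_seed, r))
  })
  list(images = lapply(rois, `[[`, "image"),
       masks = lapply(rois, `[[`, "mask"),
       stats = do.call(rbind, lapply(rois, `[[`, "stats")),
       label = label)
}

#' Generate a synthetic dataset
#'
#' Generates `round(n_cases * failure_fraction)` failure cases and the rest
#' non-failure. With `out_dir` given, ROIs are written as 8-bit RGB PNGs
#' under `images/`, masks as single-channel PNGs under `masks/`, and a
#' `manifest.csv` (case_id, label, roi_path, subtype) is written alongside;
#' the returned manifest then references the files on disk. With
#' `out_dir = NULL` everything stays in memory and the returned object
#' carries the images and masks directly (keyed by their virtual roi paths).
#'
#' @param n_cases number of cases (>= 2)
#' @param failure_fraction fraction of failure cases
#' @param config a [synth_config()]
#' @param out_dir output directory, or NULL for in-memory generation
#' @return a list with `manifest` (an `"emb_manifest"`), and — in-memory
#'   mode — `images` and `masks` named by roi path
#' @export
generate_dataset <- function(n_cases, failure_fraction,
                             config = synth_config(), out_dir = NULL) {
  if (n_cases < 2) stop("n_cases must be >= 2")
  n_fail <- round(n_cases * failure_fraction)
  labels <- rep(c("failure", "non_failure"), c(n_fail, n_cases - n_fail))
  ids <- sprintf("case_%04d", seq_len(n_cases))
  on_disk <- !is.null(out_dir)
  if (on_disk) {
    for (d in file.path(out_dir, c("images", "masks"))) {
      if (!dir.exists(d) && !dir.create(d, recursive = TRUE)) {
        stop("cannot create output directory ", d)
      }
    }
  }
  cases <- list()
  images <- list()
  masks <- list()
  for (i in seq_len(n_cases)) {
    cs <- generate_case(labels[i], config, case_seed = i)
    paths <- sprintf("images/%s_roi%02d.png", ids[i], seq_along(cs$images))
    if (on_disk) {
      for (r in seq_along(paths)) {
        png::writePNG(cs$images[[r]], file.path(out_dir, paths[r]))
        png::writePNG(cs$masks[[r]] * 1.0,
                      file.path(out_dir, sub("^images/", "masks/", paths[r])))
      }
    } else {
      images[paths] <- cs$images
      masks[paths] <- cs$masks
    }
    cases[[ids[i]]] <- list(case_id = ids[i], label = labels[i],
                            roi_paths = paths, subtype = NA_character_)
  }
  manifest <- new_manifest(cases, dir = if (on_disk) out_dir else ".")
  if (on_disk) {
    utils::write.csv(as.data.frame(manifest),
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
    list(manifest = manifest)
  } else {
    list(manifest = manifest, images = images, masks = masks)
  }
}

# Assemble a roi_set for the given cases from a manifest, taking images from
# an in-memory store (as returned by generate_dataset(out_dir = NULL)) or
# loading PNGs from disk.
manifest_roi_set <- function(manifest, case_ids, images = NULL) {
  check_case_ids(manifest, case_ids)
  rel <- unlist(lapply(manifest$cases[case_ids], `[[`, "roi_paths"),
                use.names = FALSE)
  nroi <- vapply(manifest$cases[case_ids], function(cs) length(cs$roi_paths), 0L)
  labs <- rep(unname(manifest_labels(manifest, case_ids)), nroi)
  cids <- rep(case_ids, unname(nroi))
  imgs <- if (is.null(images)) {
    load_images(file.path(manifest$dir, rel))
  } else {
    images[rel]
  }
  rs <- roi_set(imgs, labs, cids)
  rs$roi_paths <- rel
  rs
}
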