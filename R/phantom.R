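#' Specification of a synthetic B-mode lesion phantom
#'
#' Describes one speckle-textured phantom image with a single star-convex
#' lesion: background parenchyma intensity, lesion/parenchyma echogenicity
#' ratio, boundary irregularity (radial harmonic perturbation), Gaussian
#' margin blur, anteroposterior stretch, bright calcification discs placed by
#' zone, a dark anechoic (cystic) fraction, and fully developed speckle
#' modelled as a low-pass-filtered Rayleigh envelope.
#'
#' @param image_shape integer c(rows, cols) in pixels.
#' @param spacing named numeric c(y =, x =) pixel spacing in mm.
#' @param parenchyma_mean target mean background intensity in (0, 1).
#' @param echogenicity_ratio target lesion/parenchyma mean-intensity ratio.
#' @param lesion_radius_mm base lesion radius before stretch/irregularity.
#' @param irregularity_amplitude max radial perturbation as a fraction of the
#'   radius (0 = smooth ellipse).
#' @param irregularity_harmonics number of random radial harmonics.
#' @param margin_blur_mm Gaussian scale of the lesion edge transition.
#' @param aspect_stretch anteroposterior/transverse axis ratio.
#' @param calcifications list of \code{list(max_dim_mm =, zone =)} entries,
#'   zone one of \code{"peripheral"}, \code{"central"}.
#' @param anechoic_fraction target cystic fraction of the lesion area.
#' @param speckle_model \code{"rayleigh"} or \code{"none"}.
#' @param speckle_corr_mm speckle correlation length (low-pass scale).
#' @param seed integer seed making the phantom deterministic.
#' @return list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(image_shape = c(128L, 128L),
                         spacing = c(y = 0.1, x = 0.1),
                         parenchyma_mean = 0.5,
                         echogenicity_ratio = 0.6,
                         lesion_radius_mm = 4,
                         irregularity_amplitude = 0.1,
                         irregularity_harmonics = 8L,
                         margin_blur_mm = 0.15,
                         aspect_stretch = 1.0,
                         calcifications = list(),
                         anechoic_fraction = 0,
                         speckle_model = c("rayleigh", "none"),
                         speckle_corr_mm = 0.3,
                         seed = 1L) {
  speckle_model <- match.arg(speckle_model)
  stopifnot(echogenicity_ratio > 0, parenchyma_mean > 0, parenchyma_mean < 1,
            lesion_radius_mm > 0, margin_blur_mm >= 0, aspect_stretch > 0,
            irregularity_amplitude >= 0, anechoic_fraction >= 0,
            anechoic_fraction < 1)
  half_y <- image_shape[1] * spacing[["y"]] / 2
  half_x <- image_shape[2] * spacing[["x"]] / 2
  max_r <- lesion_radius_mm * (1 + irregularity_amplitude) * max(1, aspect_stretch)
  if (max_r + 1 > min(half_y, half_x))
    stop("lesion does not fit in the frame with 1 mm clearance")
  structure(list(image_shape = as.integer(image_shape), spacing = spacing,
                 parenchyma_mean = parenchyma_mean,
                 echogenicity_ratio = echogenicity_ratio,
                 lesion_radius_mm = lesion_radius_mm,
                 irregularity_amplitude = irregularity_amplitude,
                 irregularity_harmonics = as.integer(irregularity_harmonics),
                 margin_blur_mm = margin_blur_mm,
                 aspect_stretch = aspect_stretch,
                 calcifications = calcifications,
                 anechoic_fraction = anechoic_fraction,
                 speckle_model = speckle_model,
                 speckle_corr_mm = speckle_corr_mm,
                 seed = seed),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Generate one phantom image with ground truth
#'
#' Renders the phantom described by a \code{\link{phantom_spec}}: the lesion
#' boundary is the star-convex curve \eqn{r(\theta) = R(1 + a\,h(\theta))}
#' with \eqn{h} a seeded random harmonic sum normalized to unit maximum,
#' stretched along the anteroposterior axis; the edge transition is blurred
#' at \code{margin_blur_mm}; speckle multiplies the piecewise-constant scene
#' with a unit-mean low-pass Rayleigh envelope; calcification discs
#' (intensity 0.95) and anechoic discs (intensity 0.05) are placed by
#' rejection sampling, with zone membership verified by the same
#' erosion-derived majority rule the structural detector applies, so recorded
#' counts are consistent with extraction by construction.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{frame} (\code{\link{us_frame}}), \code{mask}
#'   (\code{\link{lesion_mask}} — the true boundary), \code{reference}
#'   (logical matrix, parenchyma band 1-4 mm outside the lesion) and
#'   \code{truth}, a list of expected feature values: \code{aspect_ratio}
#'   (from the continuous boundary curve), \code{echogenicity_ratio},
#'   \code{n_micro}, \code{n_macro}, \code{peripheral_count},
#'   \code{central_count}, \code{anechoic_pct} (realized, pixel-exact) and
#'   \code{anechoic_target_pct}.
#' @export
generate_phantom <- function(spec) {
  with_seed(spec$seed, {
    sh <- spec$image_shape; sp <- spec$spacing
    r_mm <- seq_len(sh[1]) * sp[["y"]]
    c_mm <- seq_len(sh[2]) * sp[["x"]]
    cy <- mean(range(r_mm)); cx <- mean(range(c_mm))

    # boundary curve r(theta), harmonics k = 2..(m+1), unit-max perturbation
    m <- spec$irregularity_harmonics
    amp <- spec$irregularity_amplitude
    if (amp > 0 && m > 0) {
      ks <- 2:(m + 1)
      ca <- stats::rnorm(m); cb <- stats::rnorm(m)
      hfun <- function(th) {
        s <- rep(0, length(th))
        for (i in seq_along(ks)) s <- s + ca[i] * cos(ks[i] * th) + cb[i] * sin(ks[i] * th)
        s
      }
      th_dense <- seq(0, 2 * pi, length.out = 2048)
      norm <- max(abs(hfun(th_dense)))
      radius_fn <- function(th) spec$lesion_radius_mm * (1 + amp * hfun(th) / norm)
    } else {
      radius_fn <- function(th) rep(spec$lesion_radius_mm, length(th))
    }

    v <- matrix(r_mm - cy, sh[1], sh[2]) / spec$aspect_stretch  # AP, unstretched
    u <- matrix(c_mm - cx, sh[1], sh[2], byrow = TRUE)          # transverse
    rho <- sqrt(u^2 + v^2)
    th <- atan2(v, u)
    mask <- rho <= radius_fn(th)
    mask <- largest_component(mask)

    # analytic aspect ratio from the continuous curve
    th_d <- seq(0, 2 * pi, length.out = 4096)
    rd <- radius_fn(th_d)
    ap_ext <- diff(range(rd * sin(th_d))) * spec$aspect_stretch
    tr_ext <- diff(range(rd * cos(th_d)))
    true_ar <- ap_ext / tr_ext

    les_val <- spec$echogenicity_ratio * spec$parenchyma_mean
    bg_val <- spec$parenchyma_mean
    w <- if (spec$margin_blur_mm > 0)
      pmin(pmax(gauss_blur_mm(mask + 0, spec$margin_blur_mm, sp), 0), 1)
    else mask + 0
    base <- bg_val + (les_val - bg_val) * w

    if (spec$speckle_model == "rayleigh") {
      sigma <- sqrt(2 / pi)
      env <- matrix(sigma * sqrt(-2 * log(stats::runif(prod(sh)))), sh[1], sh[2])
      env <- gauss_blur_mm(env, spec$speckle_corr_mm, sp)
      env <- env / mean(env)
      base <- base * env
    }

    dist_in <- -signed_contour_distance(mask, sp)  # positive inside
    zones <- zone_partition(mask, sp)
    occupied <- matrix(FALSE, sh[1], sh[2])

    place_disc <- function(diam_mm, allowed_centre, label,
                           accept = function(disc) TRUE) {
      rad <- diam_mm / 2
      cand <- which(allowed_centre, arr.ind = TRUE)
      if (!nrow(cand)) stop("no feasible position for ", label)
      RR <- matrix(r_mm, sh[1], sh[2])
      CC <- matrix(c_mm, sh[1], sh[2], byrow = TRUE)
      for (try in 1:200) {
        pick <- cand[sample.int(nrow(cand), 1L), ]
        py <- pick[1] * sp[["y"]]; px <- pick[2] * sp[["x"]]
        dd <- sqrt((RR - py)^2 + (CC - px)^2)
        disc <- dd <= rad
        if (!any(disc)) next
        if (any(disc & !mask)) next
        # keep a 2-px moat so 8-connected components stay separate
        moat <- dd <= rad + 2 * max(sp)
        if (any(moat & occupied)) next
        if (!accept(disc)) next
        occupied <<- occupied | moat
        return(disc)
      }
      stop("could not place ", label, " after 200 attempts")
    }

    # anechoic inclusion first (single disc matching the target fraction)
    anechoic_px <- matrix(FALSE, sh[1], sh[2])
    if (spec$anechoic_fraction > 0) {
      A_les <- sum(mask) * sp[["y"]] * sp[["x"]]
      rad_an <- sqrt(spec$anechoic_fraction * A_les / pi)
      allowed <- mask & dist_in >= rad_an + 0.2
      disc <- place_disc(2 * rad_an, allowed, "anechoic inclusion")
      anechoic_px <- disc
      base[disc] <- 0.05
    }

    calc_truth <- data.frame(max_dim_mm = numeric(0), zone = character(0))
    for (cc in spec$calcifications) {
      rad <- cc$max_dim_mm / 2
      allowed <- if (cc$zone == "peripheral")
        mask & dist_in >= rad & dist_in <= zones$depth_mm + rad
      else
        zones$central & dist_in >= rad + zones$depth_mm
      allowed <- allowed & !occupied
      zone_ok <- function(disc) {
        frac <- mean(zones$peripheral[disc])
        zone_got <- if (frac >= 0.5) "peripheral" else "central"
        zone_got == cc$zone
      }
      disc <- place_disc(cc$max_dim_mm, allowed,
                         paste0(cc$zone, " calcification"), accept = zone_ok)
      base[disc] <- 0.95
      calc_truth <- rbind(calc_truth,
                          data.frame(max_dim_mm = cc$max_dim_mm, zone = cc$zone))
    }

    img <- pmin(pmax(base, 0), 1)
    frame <- us_frame(img, sp[["y"]], sp[["x"]], source_id = paste0("phantom-", spec$seed))
    reference <- !mask & dist_in <= -1 & dist_in >= -4

    truth <- list(
      aspect_ratio = true_ar,
      echogenicity_ratio = spec$echogenicity_ratio,
      n_micro = sum(calc_truth$max_dim_mm <= 1.5),
      n_macro = sum(calc_truth$max_dim_mm > 1.5),
      peripheral_count = sum(calc_truth$zone == "peripheral"),
      central_count = sum(calc_truth$zone == "central"),
      anechoic_pct = 100 * sum(anechoic_px) / sum(mask),
      anechoic_target_pct = 100 * spec$anechoic_fraction,
      calcifications = calc_truth,
      # directions the generator guarantees across its parameter ladders
      monotone_directions = list(
        perimeter_to_area = "increases with irregularity_amplitude",
        gradient_mean = "decreases with margin_blur_mm",
        profile_mean = "decreases with margin_blur_mm",
        kl_divergence = "increases with lesion/parenchyma contrast"))

    list(frame = frame, mask = lesion_mask(mask), reference = reference,
         truth = truth, spec = spec)
  })
}

#' Default subtype phantom templates
#'
#' Three parameter templates encoding the qualitative contrasts between the
#' carcinoma subtypes: PTC-like lesions are hypoechoic with strongly irregular,
#' blurred margins; FTC-like lesions are near-isoechoic with smooth sharp
#' margins and many peripheral calcifications; MTC-like lesions are the most
#' hypoechoic with fairly smooth margins and occasional central
#' macrocalcifications. Magnitudes are package choices — the source cohort
#' reports only effect directions and two medians — tuned once to give
#' well-separated classes.
#'
#' @return named list of template parameter lists (PTC, FTC, MTC).
#' @export
default_subtype_templates <- function() {
  list(
    PTC = list(echogenicity_ratio = 0.65, lesion_radius_mm = 3.2,
               irregularity_amplitude = 0.28, irregularity_harmonics = 9L,
               margin_blur_mm = 0.45, aspect_stretch = 1.0,
               n_peripheral = 2L, peripheral_dim_mm = 0.6,
               n_central = 2L, central_dim_mm = 0.6,
               anechoic_fraction = 0.01),
    FTC = list(echogenicity_ratio = 0.95, lesion_radius_mm = 3.4,
               irregularity_amplitude = 0.05, irregularity_harmonics = 6L,
               margin_blur_mm = 0.08, aspect_stretch = 0.95,
               n_peripheral = 8L, peripheral_dim_mm = 0.6,
               n_central = 1L, central_dim_mm = 1.0,
               anechoic_fraction = 0.03),
    MTC = list(echogenicity_ratio = 0.45, lesion_radius_mm = 3.3,
               irregularity_amplitude = 0.10, irregularity_harmonics = 6L,
               margin_blur_mm = 0.20, aspect_stretch = 0.85,
               n_peripheral = 2L, peripheral_dim_mm = 0.6,
               n_central = 1L, central_dim_mm = 1.8,
               anechoic_fraction = 0.01))
}

template_to_spec <- function(tpl, seed, jitter_frac = 0.15,
                             image_shape = c(128L, 128L),
                             spacing = c(y = 0.1, x = 0.1),
                             speckle_model = "rayleigh") {
  jit <- function(x) x * stats::runif(1, 1 - jitter_frac, 1 + jitter_frac)
  n_per <- max(0L, tpl$n_peripheral +
                 sample(c(-1L, 0L, 1L), 1L, prob = c(0.25, 0.5, 0.25)))
  n_cen <- max(0L, tpl$n_central +
                 sample(c(-1L, 0L, 1L), 1L, prob = c(0.25, 0.5, 0.25)))
  calcs <- c(
    lapply(seq_len(n_per), function(i)
      list(max_dim_mm = jit(tpl$peripheral_dim_mm), zone = "peripheral")),
    lapply(seq_len(n_cen), function(i)
      list(max_dim_mm = jit(tpl$central_dim_mm), zone = "central")))
  phantom_spec(image_shape = image_shape, spacing = spacing,
               parenchyma_mean = 0.5,
               echogenicity_ratio = jit(tpl$echogenicity_ratio),
               lesion_radius_mm = jit(tpl$lesion_radius_mm),
               irregularity_amplitude = jit(tpl$irregularity_amplitude),
               irregularity_harmonics = tpl$irregularity_harmonics,
               margin_blur_mm = jit(tpl$margin_blur_mm),
               aspect_stretch = jit(tpl$aspect_stretch),
               calcifications = calcs,
               anechoic_fraction = jit(tpl$anechoic_fraction),
               speckle_model = speckle_model,
               seed = sample.int(.Machine$integer.max, 1L))
}

#' Image/lesion/subtype design of a synthetic cohort
#'
#' The bookkeeping of \code{\link{generate_cohort}} without rendering any
#' images: one row per image with \code{image_id}, \code{lesion_id} (the two
#' orthogonal views of a lesion share it) and \code{subtype}.
#'
#' @param n_per_class named integer vector, default c(PTC = 90, FTC = 14,
#'   MTC = 18) mirroring the source cohort's class sizes.
#' @param views_per_lesion images per lesion (default 2, transverse +
#'   longitudinal).
#' @return data.frame with one row per image.
#' @export
cohort_design <- function(n_per_class = c(PTC = 90, FTC = 14, MTC = 18),
                          views_per_lesion = 2L) {
  rows <- list()
  for (cls in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cls]])) {
      lid <- sprintf("%s-%03d", cls, i)
      for (v in seq_len(views_per_lesion)) {
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = sprintf("%s-v%d", lid, v),
          lesion_id = lid, subtype = cls,
          plane = if (v == 1L) "transverse" else "longitudinal")
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a labelled cohort of phantoms
#'
#' Draws per-phantom parameters from the subtype templates with uniform
#' jitter (default +/-15 percent of each template value; calcification counts
#' move by at most one) and renders each image. With
#' \code{views_per_lesion = 2} the two views of a lesion share the template
#' draw but are rendered independently, mimicking orthogonal scan planes.
#'
#' @param n_per_class named integer vector of lesions per subtype.
#' @param templates template list as from
#'   \code{\link{default_subtype_templates}}.
#' @param seed cohort seed; all phantom seeds derive from it.
#' @param views_per_lesion images rendered per lesion.
#' @param jitter_frac uniform jitter half-width as a fraction.
#' @param speckle_model forwarded to \code{\link{phantom_spec}}.
#' @param image_shape,spacing forwarded to \code{\link{phantom_spec}}.
#' @return list of per-image records: \code{frame}, \code{mask},
#'   \code{reference}, \code{truth}, \code{image_id}, \code{lesion_id},
#'   \code{subtype}.
#' @export
generate_cohort <- function(n_per_class = c(PTC = 90, FTC = 14, MTC = 18),
                            templates = default_subtype_templates(),
                            seed = 1L, views_per_lesion = 1L,
                            jitter_frac = 0.15,
                            speckle_model = "rayleigh",
                            image_shape = c(128L, 128L),
                            spacing = c(y = 0.1, x = 0.1)) {
  stopifnot(all(n_per_class >= 1), all(names(n_per_class) %in% names(templates)))
  design <- cohort_design(n_per_class, views_per_lesion)
  with_seed(seed, {
    out <- vector("list", nrow(design))
    prev_lesion <- ""
    spec <- NULL
    for (i in seq_len(nrow(design))) {
      row <- design[i, ]
      if (row$lesion_id != prev_lesion) {
        spec <- template_to_spec(templates[[row$subtype]], seed,
                                 jitter_frac = jitter_frac,
                                 image_shape = image_shape, spacing = spacing,
                                 speckle_model = speckle_model)
        prev_lesion <- row$lesion_id
      }
      # a jittered draw can request geometrically infeasible inclusions
      # (e.g. two central macrocalcifications in a small core); reject the
      # draw and redraw the lesion parameters, still under the cohort seed
      ph <- NULL
      for (attempt in 1:10) {
        sp_i <- spec
        sp_i$seed <- sample.int(.Machine$integer.max, 1L)
        ph <- tryCatch(generate_phantom(sp_i), error = function(e) NULL)
        if (!is.null(ph)) break
        spec <- template_to_spec(templates[[row$subtype]], seed,
                                 jitter_frac = jitter_frac,
                                 image_shape = image_shape, spacing = spacing,
                                 speckle_model = speckle_model)
      }
      if (is.null(ph))
        stop("could not realize a feasible ", row$subtype,
             " phantom for ", row$lesion_id)
      ph$image_id <- row$image_id
      ph$lesion_id <- row$lesion_id
      ph$subtype <- row$subtype
      ph$frame$plane_label <- row$plane
      out[[i]] <- ph
    }
    out
  })
}
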