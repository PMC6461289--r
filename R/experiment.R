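#' Factorial experiment design
#'
#' Describes the full simulation study: `n_variants` random rigid-body
#' variations of the ground-truth ellipsoid, each reconstructed at every
#' combination of orientation, in-plane size and slice-thickness factor.
#' The study default (100 variants x 3 orientations x 5 in-plane sizes x 6
#' factors) totals 9000 volumes; subsets of any dimension give desk-scale
#' runs.
#'
#' @param n_variants number of random rigid-body variants per orientation.
#' @param orientations subset of `c("parallel", "diagonal", "orthogonal")`.
#' @param in_plane in-plane voxel sizes (mm).
#' @param thickness_factors slice-thickness factors (multiples of in-plane).
#' @param objects ground-truth [ellipsoid()] (or list); default is the
#'   164.9 mm^3 study ellipsoid.
#' @param bounds rigid-body sampling bounds, see [rigid_bounds()].
#' @param fov field of view (mm).
#' @param master_seed integer master seed; every stochastic component of a
#'   run derives its own sub-seed deterministically from it.
#' @param reference_in_plane isotropic voxel size (mm) of the
#'   high-resolution reference reconstruction used for Dice scoring
#'   (0.1 mm in the study design).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_variants = 100,
                              orientations = c("parallel", "diagonal",
                                               "orthogonal"),
                              in_plane = c(0.1, 0.2, 0.5, 1.0, 2.0),
                              thickness_factors = c(1.0, 1.2, 1.5, 1.8,
                                                    2.0, 3.0),
                              objects = ellipsoid(),
                              bounds = rigid_bounds(),
                              fov = c(36, 36, 36),
                              master_seed = 1L,
                              reference_in_plane = 0.1) {
  orientations <- match.arg(orientations, several.ok = TRUE)
  stopifnot(n_variants >= 1, n_variants <= 1024,
            length(in_plane) >= 1, all(in_plane > 0),
            length(thickness_factors) >= 1, all(thickness_factors > 0),
            reference_in_plane > 0, master_seed == round(master_seed))
  if (length(fov) == 1) fov <- rep(fov, 3)
  objects <- .as_object_list(objects)
  # validate every cell grid up front (integer matrix dims, no interpolation)
  for (ip in in_plane) for (tf in thickness_factors) grid_spec(ip, tf, fov)
  grid_spec(reference_in_plane, 1, fov)
  structure(list(n_variants = as.integer(n_variants),
                 orientations = orientations,
                 in_plane = as.numeric(in_plane),
                 thickness_factors = as.numeric(thickness_factors),
                 objects = objects, bounds = bounds, fov = as.numeric(fov),
                 master_seed = as.integer(master_seed),
                 reference_in_plane = as.numeric(reference_in_plane)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment design> %d variants x %d orientations x %d sizes x %d factors (seed %d)\n",
    x$n_variants, length(x$orientations), length(x$in_plane),
    length(x$thickness_factors), x$master_seed))
  invisible(x)
}

# Per-variant sub-seeds, derived once from the master seed. The table has a
# fixed width so the seed of variant v does not depend on n_variants: runs
# that share a master seed share poses (and hence reference masks) for
# common variants.
.design_seeds <- function(master_seed, n_variants) {
  withr::with_seed(as.integer(master_seed), {
    pose <- sample.int(.Machine$integer.max, 1024L)
    lab <- sample.int(.Machine$integer.max, 1024L)
  })
  list(pose = pose[seq_len(n_variants)], label = lab[seq_len(n_variants)])
}

.ref_key <- function(design, variant, orientation) {
  sprintf("seed%d_v%03d_%s_ref%g", design$master_seed, variant, orientation,
          design$reference_in_plane)
}

# Build (or fetch) the high-resolution optimal-rater reference mask for one
# variant x orientation. Cached bit-packed in `ref_cache` (an environment)
# when supplied.
.reference_mask <- function(design, pose, variant, orientation,
                            ref_cache = NULL, verbose = FALSE) {
  key <- .ref_key(design, variant, orientation)
  if (!is.null(ref_cache) && exists(key, envir = ref_cache, inherits = FALSE))
    return(.unpack_mask(get(key, envir = ref_cache)))
  if (verbose)
    message(sprintf("  reference %s at %g mm", key, design$reference_in_plane))
  grid <- grid_spec(design$reference_in_plane, 1, design$fov)
  img <- simulate_volume(design$objects, grid, pose)
  mask <- optimal_label(img, design$objects, design$fov)
  if (!is.null(ref_cache))
    assign(key, .pack_mask(mask$data), envir = ref_cache)
  mask$data
}

.apply_rater <- function(rater, img, objects, fov, seed) {
  if (rater$kind == "optimal") {
    optimal_label(img, objects, fov)
  } else {
    probabilistic_label(img, rater$curve, seed = seed, mode = rater$mode)
  }
}

#' Run a factorial simulation design
#'
#' For every variant: draws the rigid-body pose, builds the 0.1 mm (or
#' configured) isotropic optimal-rater reference per orientation, then for
#' every resolution cell reconstructs the volume, labels it with each
#' rater, upsamples the mask to the reference grid with nearest-neighbour
#' interpolation, and scores volume deviation and Dice overlap. Fully
#' deterministic for a fixed `master_seed`.
#'
#' @param design an [experiment_design()].
#' @param raters non-empty list of [rater_spec()]s.
#' @param ref_cache optional environment used to cache reference masks
#'   (bit-packed) across calls; runs sharing a master seed reuse them.
#' @param verbose print per-cell progress.
#' @return A data.frame of trial records with one row per
#'   variant x orientation x resolution x rater: design keys, volumes
#'   (mm^3), `pct_deviation`, `dcs`, and for the optimal rater the
#'   quantization-free `continuous_volume` and its deviation.
#' @export
run_design <- function(design, raters = list(rater_spec("optimal")),
                       ref_cache = NULL, verbose = FALSE) {
  stopifnot(inherits(design, "experiment_design"), length(raters) >= 1,
            all(vapply(raters, inherits, TRUE, "rater_spec")))
  rater_ids <- vapply(raters, `[[`, "", "kind")
  if (anyDuplicated(rater_ids))
    rater_ids <- make.unique(rater_ids, sep = "_")
  seeds <- .design_seeds(design$master_seed, design$n_variants)
  truth_vol <- sum(vapply(design$objects, ellipsoid_volume, 0))
  ref_grid <- grid_spec(design$reference_in_plane, 1, design$fov)
  rows <- vector("list",
                 design$n_variants * length(design$orientations) *
                   length(design$in_plane) *
                   length(design$thickness_factors) * length(raters))
  ri <- 0L
  for (v in seq_len(design$n_variants)) {
    pose_rand <- sample_rigid_transform(seed = seeds$pose[v],
                                        bounds = design$bounds)
    for (orient in design$orientations) {
      pose <- list(base_orientation(orient), pose_rand)
      ref <- tryCatch(
        .reference_mask(design, pose, v, orient, ref_cache, verbose),
        error = function(e) stop(sprintf(
          "reference for variant %d, orientation %s: %s", v, orient,
          conditionMessage(e)), call. = FALSE))
      cell <- 0L
      for (ip in design$in_plane) {
        for (tf in design$thickness_factors) {
          grid <- grid_spec(ip, tf, design$fov)
          if (verbose)
            message(sprintf("  variant %d %s: %g mm x%g", v, orient, ip, tf))
          img <- tryCatch(
            simulate_volume(design$objects, grid, pose),
            error = function(e) stop(sprintf(
              "cell (variant %d, %s, %g mm, factor %g): %s", v, orient, ip,
              tf, conditionMessage(e)), call. = FALSE))
          for (k in seq_along(raters)) {
            cell <- cell + 1L
            lab_seed <- (seeds$label[v] + 1000003 * cell) %% 2147483647
            mask <- .apply_rater(raters[[k]], img, design$objects,
                                 design$fov, lab_seed)
            up <- upsample_nearest(mask, ref_grid)
            vol <- mask_volume(mask)
            cont <- attr(mask, "continuous_volume")
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
              variant = v, orientation = orient, in_plane = ip,
              thickness_factor = tf, rater = rater_ids[k],
              voxel_volume = voxel_volume(grid),
              labeled_volume = vol,
              continuous_volume = if (is.null(cont)) NA_real_ else cont,
              truth_volume = truth_vol,
              pct_deviation = pct_deviation(vol, truth_vol),
              pct_deviation_continuous =
                if (is.null(cont)) NA_real_
                else pct_deviation(cont, truth_vol),
              dcs = .dice_raw(up$data, ref),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize trial records into design-cell aggregates
#'
#' Per cell (orientation x in-plane x factor x rater): mean, SD and normal
#' approximation 95% confidence interval of the percentage volume
#' deviation, mean and SD of the Dice score, and the voxel volume relative
#' to the ground truth.
#'
#' @param records trial records from [run_design()].
#' @return A data.frame of summary cells.
#' @export
summarize_trials <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  key <- interaction(records$orientation, records$in_plane,
                     records$thickness_factor, records$rater, drop = TRUE)
  parts <- split(records, key)
  out <- lapply(parts, function(d) {
    n <- nrow(d)
    m <- mean(d$pct_deviation)
    s <- if (n > 1) stats::sd(d$pct_deviation) else 0
    half <- if (n > 1) 1.96 * s / sqrt(n) else 0
    data.frame(
      orientation = d$orientation[1], in_plane = d$in_plane[1],
      thickness_factor = d$thickness_factor[1], rater = d$rater[1],
      n = n, mean_pct_deviation = m, sd_pct_deviation = s,
      ci95_low = m - half, ci95_high = m + half,
      mean_dcs = mean(d$dcs),
      sd_dcs = if (n > 1) stats::sd(d$dcs) else 0,
      mean_pct_deviation_continuous = mean(d$pct_deviation_continuous),
      relative_voxel_volume = 100 * d$voxel_volume[1] / d$truth_volume[1],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$rater, out$orientation, out$in_plane, out$thickness_factor), ]
}

#' Same voxel volume, different voxel shape
#'
#' Compares 8-fold anisotropic voxels with isotropic voxels of identical
#' volume: 0.1 x 0.1 x 0.8 mm vs 0.2 mm isotropic (both 0.008 mm^3) and
#' 0.5 x 0.5 x 4.0 mm vs 1.0 mm isotropic (both 1.0 mm^3). Isolates the
#' effect of voxel shape from voxel size.
#'
#' @param n_variants variants per orientation.
#' @param orientations orientations to include.
#' @param rater a [rater_spec()]; the study uses the joint rater here.
#' @param master_seed master seed shared by both members of each pair.
#' @param ref_cache optional reference cache environment.
#' @param ... passed to [experiment_design()] (e.g. `bounds`, `objects`).
#' @return A list with `records` (trial records plus `pair` and `member`
#'   columns) and `summary` (per pair x member x orientation mean/SD of
#'   deviation and Dice).
#' @export
same_volume_comparison <- function(n_variants = 10,
                                   orientations = c("parallel", "diagonal",
                                                    "orthogonal"),
                                   rater = rater_spec("joint"),
                                   master_seed = 1L, ref_cache = NULL, ...) {
  cells <- list(
    list(pair = "fine", member = "anisotropic", in_plane = 0.1, factor = 8),
    list(pair = "fine", member = "isotropic", in_plane = 0.2, factor = 1),
    list(pair = "coarse", member = "anisotropic", in_plane = 0.5, factor = 8),
    list(pair = "coarse", member = "isotropic", in_plane = 1.0, factor = 1))
  if (is.null(ref_cache)) ref_cache <- new.env(parent = emptyenv())
  recs <- lapply(cells, function(cl) {
    d <- experiment_design(n_variants = n_variants,
                           orientations = orientations,
                           in_plane = cl$in_plane,
                           thickness_factors = cl$factor,
                           master_seed = master_seed, ...)
    r <- run_design(d, raters = list(rater), ref_cache = ref_cache)
    r$pair <- cl$pair
    r$member <- cl$member
    r
  })
  records <- do.call(rbind, recs)
  key <- interaction(records$pair, records$member, records$orientation,
                     drop = TRUE)
  summary <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(pair = d$pair[1], member = d$member[1],
               orientation = d$orientation[1], n = nrow(d),
               voxel_volume = d$voxel_volume[1],
               mean_pct_deviation = mean(d$pct_deviation),
               sd_pct_deviation = stats::sd(d$pct_deviation),
               mean_dcs = mean(d$dcs), sd_dcs = stats::sd(d$dcs),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}

#' Fit the Dice-versus-deviation guideline curve
#'
#' Least-squares fit of a monotone decreasing exponential
#' `DCS = (1 - c) * exp(-k * |deviation|) + c` (anchored at DCS = 1 for
#' zero deviation) relating shape similarity to absolute percentage volume
#' deviation, and its analytic inverse. Used to translate DCS guideline
#' levels (0.90 ideal, 0.75 acceptable) into tolerable volume deviations.
#'
#' @param records trial records from [run_design()] (or any data.frame with
#'   `pct_deviation` and `dcs` columns).
#' @return An object of class `dcs_deviation_fit` with elements `k`, `c`,
#'   `sse`, `n`, `converged`.
#' @export
fit_dcs_deviation_curve <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("pct_deviation", "dcs") %in% names(records)))
  x <- abs(records$pct_deviation)
  y <- records$dcs
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || diff(range(x)) < 1e-9)
    stop("records must span a range of deviations")
  c0 <- max(0, min(y) - 0.05)
  pos <- y > c0 + 1e-6
  k0 <- tryCatch({
    sl <- stats::coef(stats::lm(log((y[pos] - c0) / (1 - c0)) ~ 0 + x[pos]))
    max(1e-6, -as.numeric(sl))
  }, error = function(e) 0.01)
  sse <- function(p) {
    r <- y - ((1 - p[2]) * exp(-p[1] * x) + p[2])
    sum(r * r)
  }
  opt <- stats::optim(c(k0, c0), sse, method = "L-BFGS-B",
                      lower = c(1e-8, 0), upper = c(10, 0.999))
  if (opt$convergence != 0) {
    # line-search failures near the bounds: polish with a bounded
    # Nelder-Mead restart from the best point found
    nm <- stats::optim(opt$par, function(p) {
      if (p[1] < 1e-8 || p[1] > 10 || p[2] < 0 || p[2] > 0.999) return(1e10)
      sse(p)
    }, method = "Nelder-Mead")
    if (nm$value <= opt$value) opt <- nm
  }
  if (opt$convergence != 0)
    warning(sprintf("guideline-curve fit did not fully converge (code %d): %s",
                    opt$convergence, opt$message))
  structure(list(k = opt$par[1], c = opt$par[2], sse = opt$value,
                 n = length(x), converged = opt$convergence == 0),
            class = "dcs_deviation_fit")
}

#' @export
print.dcs_deviation_fit <- function(x, ...) {
  cat(sprintf(
    "<DCS ~ deviation fit> DCS = (1 - %.4f) exp(-%.5f |dev|) + %.4f (n = %d)\n",
    x$c, x$k, x$c, x$n))
  cat(sprintf("  DCS 0.90 at %.1f%% deviation, DCS 0.75 at %.1f%%\n",
              deviation_at_dcs(x, 0.90), deviation_at_dcs(x, 0.75)))
  invisible(x)
}

#' @export
predict.dcs_deviation_fit <- function(object, deviation, ...) {
  (1 - object$c) * exp(-object$k * abs(deviation)) + object$c
}

#' Volume deviation at a given Dice level
#'
#' Analytic inverse of the fitted guideline curve:
#' `|dev| = -log((dcs - c) / (1 - c)) / k`.
#'
#' @param fit a `dcs_deviation_fit`.
#' @param dcs Dice level(s) in `(c, 1)`.
#' @return Absolute percentage deviation(s).
#' @export
deviation_at_dcs <- function(fit, dcs) {
  stopifnot(inherits(fit, "dcs_deviation_fit"))
  if (any(dcs <= fit$c) || any(dcs >= 1))
    stop(sprintf("DCS level must lie in (%.3f, 1): asymptote of the fit",
                 fit$c))
  -log((dcs - fit$c) / (1 - fit$c)) / fit$k
}

#' Guideline table: Dice versus anisotropy per relative-voxel-volume tier
#'
#' Tabulates mean DCS against the anisotropy factor for each in-plane size
#' tier (expressed as voxel volume relative to the ground-truth volume) and
#' flags cells meeting the acceptable (DCS > 0.75) and ideal (DCS > 0.90)
#' levels.
#'
#' @param summary summary cells from [summarize_trials()].
#' @param rater which rater's cells to tabulate (default `"joint"`, falling
#'   back to the only rater present).
#' @param acceptable,ideal DCS guideline levels.
#' @return A data.frame with one row per orientation x tier x factor.
#' @export
guideline_table <- function(summary, rater = NULL, acceptable = 0.75,
                            ideal = 0.90) {
  stopifnot(is.data.frame(summary), "mean_dcs" %in% names(summary))
  if (is.null(rater)) {
    rater <- if ("joint" %in% summary$rater) "joint" else summary$rater[1]
  }
  d <- summary[summary$rater == rater, ]
  if (!nrow(d)) stop(sprintf("no summary cells for rater '%s'", rater))
  out <- data.frame(
    rater = rater, orientation = d$orientation, in_plane = d$in_plane,
    anisotropy_factor = d$thickness_factor,
    relative_voxel_volume = d$relative_voxel_volume,
    mean_dcs = d$mean_dcs,
    meets_acceptable = d$mean_dcs > acceptable,
    meets_ideal = d$mean_dcs > ideal,
    stringsAsFactors = FALSE)
  out[order(out$orientation, out$relative_voxel_volume,
            out$anisotropy_factor), ]
}
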