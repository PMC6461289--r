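#' Logistic psychometric curve
#'
#' The labeling decision of a human rater is modeled as a logistic function
#' of scaled voxel intensity i: `P(labeled) = 1 / (1 + exp(-(b0 + b1 * i)))`.
#' `b0` is the logit intercept and `b1` the slope per unit intensity; the
#' midpoint (50% inclusion) sits at `-b0 / b1`.
#'
#' @param beta0 logit intercept.
#' @param beta1 logit slope per unit intensity.
#' @return An object of class `psychometric_curve`.
#' @export
psychometric_curve <- function(beta0, beta1) {
  stopifnot(length(beta0) == 1, is.finite(beta0),
            length(beta1) == 1, is.finite(beta1))
  structure(list(beta0 = as.numeric(beta0), beta1 = as.numeric(beta1)),
            class = "psychometric_curve")
}

#' @export
print.psychometric_curve <- function(x, ...) {
  mid <- if (x$beta1 != 0) -x$beta0 / x$beta1 else NA_real_
  cat(sprintf("<psychometric curve> beta0 = %.3f, beta1 = %.3f (midpoint %.3f)\n",
              x$beta0, x$beta1, mid))
  if (isTRUE(attr(x, "separation")))
    cat("  [flagged: complete separation, slope capped]\n")
  invisible(x)
}

#' Inclusion probability under a psychometric curve
#'
#' @param curve a [psychometric_curve()].
#' @param i voxel intensity (vectorized).
#' @return Probabilities in (0, 1).
#' @export
logistic_probability <- function(curve, i) {
  stopifnot(inherits(curve, "psychometric_curve"), all(is.finite(i)))
  stats::plogis(curve$beta0 + curve$beta1 * i)
}

#' Fit a psychometric curve to binary labeling data
#'
#' Maximum-likelihood logistic regression of the binary label on voxel
#' intensity (`stats::glm`, binomial family). Perfectly separated data (a
#' threshold rater) have no finite MLE; such fits are flagged via the
#' `separation` attribute and the slope is capped at `cap` (preserving the
#' fitted midpoint) rather than returning the unbounded estimate.
#'
#' @param intensity numeric intensities in `[0, 1]` (or a data.frame with
#'   columns `intensity` and `label`).
#' @param label binary labels (0/1 or logical).
#' @param cap absolute slope above which the fit is treated as separated.
#' @return A [psychometric_curve()] with attributes `separation` (logical),
#'   `se` (coefficient standard errors) and `n`.
#' @export
fit_psychometric <- function(intensity, label = NULL, cap = 150) {
  if (is.data.frame(intensity)) {
    label <- intensity$label
    intensity <- intensity$intensity
  }
  label <- as.integer(label)
  if (!length(intensity) || length(intensity) != length(label))
    stop("need matching non-empty intensity and label vectors")
  if (!all(label %in% c(0L, 1L))) stop("labels must be binary")
  if (length(unique(label)) < 2)
    stop("labeling data must contain both classes")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(label ~ intensity, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  separated <- sep_warn && abs(b[2]) > cap
  if (separated) {
    mid <- -b[1] / b[2]
    b[2] <- sign(b[2]) * cap
    b[1] <- -mid * b[2]
  }
  out <- psychometric_curve(b[1], b[2])
  attr(out, "separation") <- separated
  attr(out, "se") <- se
  attr(out, "n") <- length(label)
  out
}

#' Average psychometric curves
#'
#' Arithmetic mean of the intercepts and of the slopes, as used to pool the
#' per-resolution fits of one rater into a single curve.
#'
#' @param curves non-empty list of [psychometric_curve()]s.
#' @return A [psychometric_curve()].
#' @export
average_curves <- function(curves) {
  if (!length(curves)) stop("empty curve list")
  stopifnot(all(vapply(curves, inherits, TRUE, "psychometric_curve")))
  psychometric_curve(mean(vapply(curves, `[[`, 0, "beta0")),
                     mean(vapply(curves, `[[`, 0, "beta1")))
}

#' Default rater psychometric curves
#'
#' Shipped placeholder curves for the liberal single rater and the more
#' conservative joint (conjunct two-rater) rater. They are calibrated only
#' qualitatively — the liberal midpoint (~0.31) is below the joint midpoint
#' (~0.46) and both are steep — and are meant to be replaced by curves
#' fitted from a user's own labeling tables with [fit_psychometric()].
#'
#' @param kind `"liberal"` or `"joint"`.
#' @return A [psychometric_curve()].
#' @export
default_curve <- function(kind = c("liberal", "joint")) {
  kind <- match.arg(kind)
  switch(kind,
         liberal = psychometric_curve(-4.0, 13.0),
         joint = psychometric_curve(-6.5, 14.0))
}

#' Rater specification
#'
#' Three rater models: `liberal` and `joint` include voxels via a logistic
#' psychometric curve on intensity (stochastically by default), `optimal`
#' thresholds at the intensity whose suprathreshold proportion matches the
#' ground-truth proportional volume (see [optimal_label()]).
#'
#' @param kind one of `"liberal"`, `"joint"`, `"optimal"`.
#' @param curve a [psychometric_curve()]; defaults to [default_curve()] for
#'   liberal/joint. Must be absent for the optimal rater.
#' @param mode `"stochastic"` (independent Bernoulli per voxel) or
#'   `"expected"` (deterministic inclusion where p >= 0.5).
#' @return An object of class `rater_spec`.
#' @export
rater_spec <- function(kind = c("liberal", "joint", "optimal"), curve = NULL,
                       mode = c("stochastic", "expected")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (kind == "optimal") {
    if (!is.null(curve)) stop("the optimal rater carries no psychometric curve")
  } else if (is.null(curve)) {
    curve <- default_curve(kind)
  } else {
    stopifnot(inherits(curve, "psychometric_curve"))
  }
  structure(list(kind = kind, curve = curve, mode = mode),
            class = "rater_spec")
}

#' @export
print.rater_spec <- function(x, ...) {
  cat(sprintf("<rater> %s%s\n", x$kind,
              if (x$kind == "optimal") ""
              else sprintf(" (beta0 = %g, beta1 = %g, %s)",
                           x$curve$beta0, x$curve$beta1, x$mode)))
  invisible(x)
}

#' Binary label mask
#'
#' @param data logical array matching the grid's matrix dims.
#' @param grid a [grid_spec()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  data <- as.logical(data)
  dim(data) <- grid$matrix_dims
  structure(list(data = data, grid = grid), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label mask> %d voxels labeled, volume %.3f mm^3\n",
              sum(x$data), mask_volume(x)))
  invisible(x)
}

#' Probabilistic labeling of an image
#'
#' Applies a psychometric curve to every voxel. In stochastic mode each
#' voxel is included by an independent Bernoulli draw with probability
#' `logistic_probability(curve, i)`; the logistic tails automatically keep
#' background (i ~ 0) out and interior voxels (i ~ 1) in, so no explicit
#' edge-voxel set is needed. Expected mode includes voxels with p >= 0.5,
#' giving a deterministic labeling surface.
#'
#' @param img an `image_volume` scaled to `[0, 1]`.
#' @param curve a [psychometric_curve()].
#' @param seed optional integer seed for the Bernoulli draws (local RNG
#'   scope; reproducible).
#' @param mode `"stochastic"` or `"expected"`.
#' @return A [label_mask()].
#' @export
probabilistic_label <- function(img, curve, seed = NULL,
                                mode = c("stochastic", "expected")) {
  stopifnot(inherits(img, "image_volume"))
  mode <- match.arg(mode)
  p <- logistic_probability(curve, img$data)
  if (mode == "expected") {
    keep <- p >= 0.5
  } else {
    draw <- function() stats::runif(length(p)) < p
    keep <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  label_mask(keep, img$grid)
}

#' Conjunct (joint) mask of two raters
#'
#' Voxelwise intersection: only voxels both raters agreed on are kept.
#'
#' @param a,b [label_mask()]s on identical grids.
#' @return A [label_mask()].
#' @export
conjunct_mask <- function(a, b) {
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  if (!.same_grid(a$grid, b$grid)) stop("grid mismatch between masks")
  label_mask(a$data & b$data, a$grid)
}

# Exact threshold on the survival function of intensities, interpolated
# linearly between *distinct* values. Returns list(threshold, proportion)
# where proportion is the piecewise-linear survival evaluated at the
# threshold (equals the target whenever it is reachable). For large volumes
# a histogram brackets the crossing and only a small value range is sorted;
# the result is identical to the full sort.
.survival_threshold <- function(v, target) {
  N <- length(v)
  if (!(target > 0 && target < 1)) stop("target proportion must be in (0, 1)")
  rng <- range(v)
  if (!all(is.finite(rng))) stop("non-finite intensities")
  if (rng[1] == rng[2])
    stop("degenerate constant image: target proportion unreachable")
  m_star <- target * N

  from_sorted <- function(vals, cum) {
    # vals strictly decreasing; cum = count of voxels >= vals[j]
    if (m_star <= cum[1]) {
      list(threshold = vals[1], proportion = cum[1] / N)
    } else if (m_star >= cum[length(cum)]) {
      list(threshold = vals[length(vals)], proportion = cum[length(cum)] / N)
    } else {
      j <- findInterval(m_star, cum)
      f <- (m_star - cum[j]) / (cum[j + 1] - cum[j])
      list(threshold = vals[j] + f * (vals[j + 1] - vals[j]),
           proportion = target)
    }
  }
  full <- function() {
    s <- sort(v, decreasing = TRUE, method = "radix")
    r <- rle(s)
    from_sorted(r$values, cumsum(r$lengths))
  }

  if (N <= 2^21) return(full())
  nb <- 65536L
  cnt <- cpp_count_hist(v, rng[1], rng[2], nb)
  ctop <- cumsum(rev(cnt)) # cumulative count from the top bin downward
  jb <- which(ctop >= m_star)[1]
  width <- (rng[2] - rng[1]) / nb
  win <- 16L
  while (win <= nb) {
    a <- rng[2] - min(jb + win, nb) * width
    b <- if (jb - win <= 1L) rng[2] else rng[2] - (jb - 1L - win) * width
    ex <- cpp_extract_range(v, a, b)
    n_above <- ex$n_above
    n_in <- length(ex$values)
    if (n_above < m_star && (n_above + n_in) >= m_star && n_in > 0) {
      s <- sort(ex$values, decreasing = TRUE, method = "radix")
      r <- rle(s)
      cum <- n_above + cumsum(r$lengths)
      # the crossing must have a distinct value on both sides inside the
      # bracket (unless it sits at the global extremes)
      if ((m_star >= cum[1] || n_above == 0) &&
          (m_star <= cum[length(cum)] || (n_above + n_in) == N))
        return(from_sorted(r$values, cum))
    }
    win <- win * 16L
  }
  full()
}

#' Optimal-rater threshold from the intensity distribution
#'
#' Computes the intensity level at which the proportion of suprathreshold
#' voxels equals `target_proportion`, by linear interpolation on the
#' empirical survival function of voxel intensities (piecewise linear
#' between distinct intensity values). When the target is below the
#' proportion of maximum-intensity voxels the maximum is returned, so the
#' mask keeps those voxels.
#'
#' @param img an `image_volume`.
#' @param target_proportion target suprathreshold proportion in (0, 1). The
#'   study sets it to the fraction of the FoV cube occupied by the ground
#'   truth ellipsoid (164.9 / 36^3 ~ 0.0035).
#' @return Threshold intensity (scalar) with attribute
#'   `achieved_proportion`, the interpolated survival at the threshold.
#' @export
optimal_threshold <- function(img, target_proportion) {
  stopifnot(inherits(img, "image_volume"))
  res <- .survival_threshold(as.vector(img$data), target_proportion)
  structure(res$threshold, achieved_proportion = res$proportion)
}

#' Optimal-rater labeling
#'
#' Thresholds the image so the labeled proportion of the FoV best matches
#' the ground-truth proportional volume, emulating a rater who includes
#' edge voxels until the labeled volume approaches the true volume. Records
#' both the discrete mask volume (voxel count x voxel volume, used for
#' overlap scores) and the proportion-matched continuous volume implied by
#' the interpolated survival function, which is free of voxel quantization
#' and therefore deviates from the truth by essentially zero.
#'
#' @param img an `image_volume`.
#' @param truth an [ellipsoid()], list of them, or a numeric ground-truth
#'   volume in mm^3.
#' @param fov FoV (mm, scalar or length 3) defining the proportional-volume
#'   target; defaults to the image grid's FoV.
#' @return A [label_mask()] with attributes `threshold` and
#'   `continuous_volume` (mm^3).
#' @export
optimal_label <- function(img, truth, fov = img$grid$fov) {
  stopifnot(inherits(img, "image_volume"))
  if (length(fov) == 1) fov <- rep(fov, 3)
  vol <- if (is.numeric(truth)) {
    sum(truth)
  } else {
    sum(vapply(.as_object_list(truth), ellipsoid_volume, 0))
  }
  if (vol <= 0) stop("ground-truth volume must be positive")
  target <- vol / prod(fov)
  if (target >= 1) stop("ground-truth volume exceeds the FoV")
  t <- optimal_threshold(img, target)
  mask <- label_mask(img$data >= as.numeric(t), img$grid)
  attr(mask, "threshold") <- as.numeric(t)
  attr(mask, "continuous_volume") <-
    attr(t, "achieved_proportion") * prod(fov)
  mask
}
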