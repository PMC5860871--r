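#' Define a region of interest on the analysis grid
#'
#' @param mask Logical 3D array on the analysis grid (non-empty).
#' @param name ROI label.
#' @param hemisphere Optional hemisphere tag (`"left"`, `"right"`, or
#'   `NA`).
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(mask, name = "roi", hemisphere = NA_character_) {
  if (length(dim(mask)) != 3L) stop("'mask' must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("ROI '", name, "' is empty")
  structure(list(mask = mask, name = name, hemisphere = hemisphere,
                 n_voxels = sum(mask)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI '%s'%s: %d voxels\n", x$name,
              if (is.na(x$hemisphere)) "" else paste0(" (", x$hemisphere, ")"),
              x$n_voxels))
  invisible(x)
}

#' Rectangular ROI, e.g. a 99-voxel box
#'
#' Geometric stand-in for an atlas-derived mask on the synthetic grid,
#' mirroring the 99-voxel primary auditory cortex ROIs.
#'
#' @param grid_dim Grid dimensions.
#' @param start Lower corner (1-based voxel index).
#' @param size Box edge lengths in voxels; the default 3 x 3 x 11 box
#'   has 99 voxels.
#' @param name,hemisphere Passed to [roi_mask()].
#' @return An `roi_mask`.
#' @export
make_box_roi <- function(grid_dim, start = c(1, 1, 1), size = c(3, 3, 11),
                         name = "box", hemisphere = NA_character_) {
  stopifnot(all(start >= 1), all(start + size - 1 <= grid_dim))
  m <- array(FALSE, dim = grid_dim)
  m[start[1]:(start[1] + size[1] - 1),
    start[2]:(start[2] + size[2] - 1),
    start[3]:(start[3] + size[3] - 1)] <- TRUE
  roi_mask(m, name = name, hemisphere = hemisphere)
}

#' Average betas over an ROI
#'
#' Per TOA condition, the arithmetic mean of the per-voxel betas over
#' the ROI; voxels with missing betas are excluded and counted.
#'
#' @param beta_map A [fit_glm()] / [combine_beta_maps()] result.
#' @param roi An [roi_mask()] on the same grid.
#' @return Named numeric vector (names = TOA values), with attribute
#'   `"n_missing"`.
#' @export
roi_mean_betas <- function(beta_map, roi) {
  stopifnot(inherits(roi, "roi_mask"))
  idx <- which(roi$mask)
  if (max(idx) > nrow(beta_map$beta)) stop("ROI exceeds the beta map grid")
  B <- beta_map$beta[idx, , drop = FALSE]
  ok <- stats::complete.cases(B)
  if (!any(ok)) stop("ROI '", roi$name, "' has no voxels with valid betas")
  out <- colMeans(B[ok, , drop = FALSE])
  names(out) <- beta_map$toas
  attr(out, "n_missing") <- sum(!ok)
  out
}

#' ROI-level decay fit and group comparison
#'
#' For every subject, averages the betas over the ROI, fits the
#' exponential decay model, and compares the two groups' time constants
#' with a Mann-Whitney test plus rank effect size.  Subjects whose ROI
#' fit leaves `tau` undefined are excluded (and listed); the comparison
#' requires at least two usable subjects per group.
#'
#' @param beta_maps List of per-subject beta maps on a common grid.
#' @param roi An [roi_mask()].
#' @param groups Factor/character of group labels, one per subject
#'   (first level = group 1).
#' @param tau_bounds,n_grid Passed to [fit_decay()].
#' @return List of class `roi_comparison`: `table` (subject, group, a,
#'   b, tau, sse, valid, reason), `U`, `z`, `p`, `r`,
#'   `median_tau` (per group), `roi`, `excluded`.
#' @export
roi_group_compare <- function(beta_maps, roi, groups,
                              tau_bounds = c(0.1, 60), n_grid = 50L) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("'groups' must have exactly two levels")
  if (length(groups) != length(beta_maps))
    stop("'groups' length must match the number of subjects")
  fits <- lapply(beta_maps, function(bm)
    fit_decay(roi_mean_betas(bm, roi), toa = bm$toas,
              tau_bounds = tau_bounds, n_grid = n_grid))
  tab <- data.frame(
    subject = if (!is.null(names(beta_maps))) names(beta_maps)
              else sprintf("sub-%02d", seq_along(beta_maps)),
    group = groups,
    t(vapply(fits, coef, numeric(3))),
    sse = vapply(fits, `[[`, numeric(1), "sse"),
    valid = vapply(fits, `[[`, logical(1), "valid"),
    reason = vapply(fits, `[[`, character(1), "reason")
  )
  usable <- is.finite(tab$tau)
  excluded <- tab$subject[!usable]
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  x <- tab$tau[usable & tab$group == g1]
  y <- tab$tau[usable & tab$group == g2]
  if (length(x) < 2 || length(y) < 2)
    stop("fewer than 2 usable subjects in a group after excluding invalid fits")
  mw <- mann_whitney_z(x, y)
  structure(
    list(table = tab, U = mw$U, z = mw$z, p = mw$p,
         r = effect_size_r(mw$z, length(x) + length(y)),
         median_tau = stats::setNames(c(stats::median(x), stats::median(y)),
                                      c(g1, g2)),
         roi = roi$name, excluded = excluded),
    class = "roi_comparison"
  )
}

#' @export
print.roi_comparison <- function(x, ...) {
  cat(sprintf("ROI '%s' group comparison of tau (Mann-Whitney)\n", x$roi))
  cat(sprintf("  median tau: %s = %.2f s, %s = %.2f s\n",
              names(x$median_tau)[1], x$median_tau[1],
              names(x$median_tau)[2], x$median_tau[2]))
  cat(sprintf("  U = %g, z = %.2f, p = %.4g, effect size r = %.2f\n",
              x$U, x$z, x$p, x$r))
  if (length(x$excluded))
    cat("  excluded subjects:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
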