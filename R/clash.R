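#' Clash-detection parameters
#'
#' Two atoms clash when their distance is smaller than the sum of their van
#' der Waals radii minus `overlap_tolerance` (the default 0.6 A mirrors the
#' default overlap criterion of interactive structure viewers). With
#' `use_vdw_radii = FALSE` a fixed `hard_cutoff` distance is used instead.
#'
#' @param overlap_tolerance allowed radius overlap, Angstrom (>= 0).
#' @param use_vdw_radii use per-atom radii (default) or the hard cutoff.
#' @param hard_cutoff fallback contact distance, Angstrom.
#' @return object of class `ClashParams`.
#' @export
clash_params <- function(overlap_tolerance = 0.6, use_vdw_radii = TRUE,
                         hard_cutoff = 3.0) {
  stopifnot(overlap_tolerance >= 0, hard_cutoff > 0)
  structure(list(overlap_tolerance = overlap_tolerance,
                 use_vdw_radii = use_vdw_radii,
                 hard_cutoff = hard_cutoff), class = "ClashParams")
}

#' Detect steric clashes between two models
#'
#' Reports every atom pair (i, j) with `dist < r_i + r_j - overlap_tolerance`
#' using a spatial grid, so the cost is near-linear in atom count. The result
#' is symmetric in the argument order up to swapping the index columns.
#'
#' @param model_a,model_b `MolecularModel`s (or n x 3 matrices with implied
#'   default radii).
#' @param params a `ClashParams`.
#' @return data frame with columns `i`, `j` (atom row indices into the two
#'   models) and `dist` (Angstrom).
#' @export
detect_clashes <- function(model_a, model_b, params = clash_params()) {
  xa <- if (inherits(model_a, "MolecularModel")) coords(model_a) else as.matrix(model_a)
  xb <- if (inherits(model_b, "MolecularModel")) coords(model_b) else as.matrix(model_b)
  ra <- if (inherits(model_a, "MolecularModel")) model_a$atoms$vdw_radius else rep(1.7, nrow(xa))
  rb <- if (inherits(model_b, "MolecularModel")) model_b$atoms$vdw_radius else rep(1.7, nrow(xb))
  res <- .cpp_clash_pairs(xa, ra, xb, rb, params$overlap_tolerance,
                          params$hard_cutoff, params$use_vdw_radii, FALSE)
  data.frame(i = res$i, j = res$j, dist = res$dist)
}

#' Fast predicate: do two coordinate sets clash at all?
#'
#' @param xa,xb n x 3 coordinate matrices.
#' @param ra,rb per-atom radii.
#' @param params a `ClashParams`.
#' @return TRUE if at least one clashing pair exists.
#' @export
has_clash <- function(xa, xb, ra = NULL, rb = NULL, params = clash_params()) {
  if (is.null(ra)) ra <- rep(1.7, nrow(xa))
  if (is.null(rb)) rb <- rep(1.7, nrow(xb))
  res <- .cpp_clash_pairs(as.matrix(xa), ra, as.matrix(xb), rb,
                          params$overlap_tolerance, params$hard_cutoff,
                          params$use_vdw_radii, TRUE)
  length(res$i) > 0
}

#' Nearest-neighbour distances from one point set to another
#'
#' For each row of `a`, the distance to the nearest row of `b`, capped: pairs
#' farther than `cap` are reported as `Inf`.
#'
#' @param a,b n x 3 matrices.
#' @param cap search radius, Angstrom.
#' @return numeric vector of length `nrow(a)`.
#' @export
nearest_dist <- function(a, b, cap = 20) {
  .cpp_nearest_dist(as.matrix(a), as.matrix(b), cap)
}
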