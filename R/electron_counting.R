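#' Counting context for absolute-scale occupancy estimation
#'
#' Collects the known quantities the electron-counting estimator needs: the
#' electron count of the fully occupied ligand region, the electrons of the
#' ordered waters the ligand displaces, and the well-ordered protein
#' envelope (a boolean voxel grid) with its known electron content, used to
#' level maps onto an absolute scale.
#'
#' @param ligand_electrons Electrons in the counted ligand region at full
#'   occupancy (after excluding any disregarded moiety).
#' @param water_electrons Electrons of the ordered waters displaced by the
#'   ligand (>= 0, strictly less than \code{ligand_electrons}).
#' @param protein_electrons Known electron content of the protein envelope.
#' @param envelope Logical 3-D array flagging the well-ordered protein
#'   voxels of the map the context will be used with.
#' @return A \code{counting_context} list.
#' @export
counting_context <- function(ligand_electrons, water_electrons,
                             protein_electrons, envelope) {
  stopifnot(is.numeric(ligand_electrons), is.numeric(water_electrons),
            is.numeric(protein_electrons), is.logical(envelope))
  if (water_electrons < 0 || ligand_electrons <= water_electrons)
    stop("need ligand_electrons > water_electrons >= 0 for usable contrast")
  if (!any(envelope)) stop("protein envelope is empty")
  structure(list(ligand_electrons = ligand_electrons,
                 water_electrons = water_electrons,
                 protein_electrons = protein_electrons,
                 envelope = envelope),
            class = "counting_context")
}

sphere_voxels <- function(dims, cell, center, radius) {
  # voxel-center membership with periodic minimum-image distances
  m <- array(FALSE, dim = dims)
  dx <- cell / dims
  d2 <- vector("list", 3L)
  for (ax in 1:3) {
    coord <- (seq_len(dims[ax]) - 1L) * dx[ax]
    d <- abs(coord - center[ax])
    d <- pmin(d, cell[ax] - d)
    d2[[ax]] <- d^2
  }
  tot <- outer(outer(d2[[1]], d2[[2]], `+`), d2[[3]], `+`)
  tot <= radius^2
}

#' Build a ligand integration mask
#'
#' The counted region is the union of spheres around the ligand atoms minus
#' the union of any exclusion spheres (disregarded moieties, heavy-atom
#' neighbourhoods). Membership is decided by voxel centres with periodic
#' distances; excluded voxels are never counted even inside an include
#' sphere.
#'
#' @param structure A [toy_structure]; its \code{ligand}-role atoms centre
#'   the include spheres.
#' @param map The \code{density_map} whose grid the mask is built on.
#' @param include_radius Include-sphere radius in Angstroms (> 0).
#' @param exclusions Optional list of exclusion spheres, each
#'   \code{list(center = c(x, y, z), radius = r)}.
#' @return A logical array of the map's dimensions with attribute
#'   \code{n_voxels}; an empty mask triggers a warning.
#' @export
build_mask <- function(structure, map, include_radius = 2.0,
                       exclusions = list()) {
  stopifnot(inherits(structure, "toy_structure"),
            inherits(map, "density_map"))
  if (include_radius <= 0) stop("`include_radius` must be positive")
  lig <- structure[structure$role == "ligand", , drop = FALSE]
  if (nrow(lig) == 0L) stop("structure has no ligand atoms")
  dims <- dim(map$grid)
  mask <- array(FALSE, dim = dims)
  for (i in seq_len(nrow(lig)))
    mask <- mask | sphere_voxels(dims, map$cell,
                                 c(lig$x[i], lig$y[i], lig$z[i]),
                                 include_radius)
  for (ex in exclusions)
    mask <- mask & !sphere_voxels(dims, map$cell, ex$center, ex$radius)
  if (!any(mask))
    warning("ligand mask is empty after exclusions")
  attr(mask, "n_voxels") <- sum(mask)
  mask
}

#' Build a well-ordered protein envelope
#'
#' Voxels within \code{radius} of any protein-role atom, minus the ligand
#' mask, defining the region whose electron content is known and trusted
#' for absolute-scale leveling.
#'
#' @param structure A [toy_structure].
#' @param map The target \code{density_map}.
#' @param radius Envelope radius in Angstroms. The default 2.5 is about
#'   four standard deviations of a B = 25 A^2 Gaussian atom, so the
#'   envelope contains essentially all of the protein's electrons — with a
#'   tighter envelope the leveling offset silently absorbs the excluded
#'   Gaussian tails and biases downstream counts.
#' @param ligand_mask Optional logical array to subtract (typically from
#'   [build_mask()]).
#' @return Logical array of envelope voxels.
#' @export
build_envelope <- function(structure, map, radius = 2.5, ligand_mask = NULL) {
  prot <- structure[structure$role == "protein", , drop = FALSE]
  if (nrow(prot) == 0L) stop("structure has no protein atoms")
  dims <- dim(map$grid)
  env <- array(FALSE, dim = dims)
  for (i in seq_len(nrow(prot)))
    env <- env | sphere_voxels(dims, map$cell,
                               c(prot$x[i], prot$y[i], prot$z[i]), radius)
  if (!is.null(ligand_mask)) env <- env & !ligand_mask
  env
}

#' Level a map onto the absolute electron scale
#'
#' Crystallographic maps lack the zero-frequency term, so their absolute
#' level is unknown. This adds the constant (an F(0,0,0) adjustment in real
#' space) that makes the electron count inside the well-ordered protein
#' envelope equal the known protein electron content. Purely additive; the
#' chosen offset is recorded in \code{f000_offset} and the operation is
#' idempotent.
#'
#' @param map A \code{density_map}.
#' @param ctx A [counting_context] whose envelope matches the map grid.
#' @return The leveled \code{density_map}, marked \code{absolute_scale}.
#' @export
level_to_absolute <- function(map, ctx) {
  stopifnot(inherits(map, "density_map"), inherits(ctx, "counting_context"))
  if (!identical(dim(ctx$envelope), dim(map$grid)))
    stop("envelope grid does not match the map grid")
  vv <- voxel_volume(map)
  env_n <- sum(ctx$envelope)
  env_e <- sum(map$grid[ctx$envelope]) * vv
  offset <- (ctx$protein_electrons - env_e) / (env_n * vv)
  out <- map
  out$grid <- map$grid + offset
  out$f000_offset <- map$f000_offset + offset
  out$absolute_scale <- TRUE
  out
}

#' Integrate electrons inside a mask
#'
#' @param map An absolute-scale \code{density_map}.
#' @param mask Logical array from [build_mask()].
#' @return Electron count (density sum times voxel volume).
#' @export
integrate_electrons <- function(map, mask) {
  stopifnot(inherits(map, "density_map"))
  if (!map$absolute_scale)
    stop("map is not on an absolute scale; apply level_to_absolute() first")
  if (!identical(dim(mask), dim(map$grid)))
    stop("mask grid does not match the map grid")
  sum(map$grid[mask]) * voxel_volume(map)
}

#' Occupancy from an integrated electron count
#'
#' Converts a masked electron count to an occupancy estimate, subtracting
#' the displaced ordered-water contribution from both the observed count
#' and the full-occupancy reference:
#' \deqn{occ = (E_{obs} - E_{water}) / (E_{ligand} - E_{water}).}
#' The raw value may fall outside [0, 1]; clamping is applied only at the
#' consensus stage.
#'
#' @param observed_e Integrated electron count in the ligand mask.
#' @param ctx A [counting_context].
#' @return Raw occupancy estimate (unclamped).
#' @export
occupancy_from_count <- function(observed_e, ctx) {
  stopifnot(inherits(ctx, "counting_context"))
  (observed_e - ctx$water_electrons) /
    (ctx$ligand_electrons - ctx$water_electrons)
}

#' Consensus of three per-model occupancy estimates
#'
#' Averages the three estimates obtained from the three map variants and
#' clamps the mean into [0.01, 0.99] (the refinement convention for
#' admissible occupancies). The spread is the population standard deviation
#' of the unclamped estimates; the \code{clamped} flag records whether
#' clamping changed the mean.
#'
#' @param estimates Numeric vector of exactly three raw estimates.
#' @return An \code{occupancy_estimate} list: \code{per_model_estimates},
#'   \code{mean_estimate}, \code{spread_sd}, \code{clamped}.
#' @export
consensus_estimate <- function(estimates) {
  if (length(estimates) != 3L || any(!is.finite(estimates)))
    stop("exactly three finite per-model estimates are required")
  raw_mean <- mean(estimates)
  clamped_mean <- min(max(raw_mean, 0.01), 0.99)
  structure(list(per_model_estimates = as.numeric(estimates),
                 mean_estimate = clamped_mean,
                 spread_sd = population_sd(estimates),
                 clamped = !identical(raw_mean, clamped_mean)),
            class = "occupancy_estimate")
}

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf(
    "Occupancy estimate: mean %.3f (models: %s; sd %.4f%s)\n",
    x$mean_estimate,
    paste(sprintf("%.3f", x$per_model_estimates), collapse = ", "),
    x$spread_sd, if (x$clamped) "; clamped" else ""))
  invisible(x)
}

#' Precision summary over a batch of occupancy estimates
#'
#' @param estimate_sets Non-empty list of \code{occupancy_estimate} objects.
#' @return Named vector with \code{max_sd}, \code{median_sd}, \code{mean_sd}
#'   of the three-model spreads.
#' @export
precision_summary <- function(estimate_sets) {
  if (length(estimate_sets) == 0L) stop("no estimates supplied")
  sds <- vapply(estimate_sets, function(e) e$spread_sd, numeric(1))
  c(max_sd = max(sds), median_sd = stats::median(sds), mean_sd = mean(sds))
}

#' Electron-counting occupancy from one map
#'
#' Single-map counting path: level the map on the protein envelope,
#' integrate electrons in the ligand mask, and convert to a raw occupancy
#' with the displaced-water correction.
#'
#' @param map A \code{density_map} (leveled internally).
#' @param mask Ligand mask from [build_mask()].
#' @param ctx A [counting_context].
#' @return Raw (unclamped) occupancy estimate.
#' @export
count_occupancy <- function(map, mask, ctx) {
  leveled <- level_to_absolute(map, ctx)
  occupancy_from_count(integrate_electrons(leveled, mask), ctx)
}

#' Three-model consensus occupancy from a reflection set
#'
#' Emulation of the three-refined-model consensus: the same diffraction data
#' are turned into three electron-density map variants — (1) the full
#' recorded resolution, (2) truncated to a common resolution limit, and (3)
#' truncated and sharpened by a reciprocal-space temperature factor — and
#' each is passed through the identical counting path (F(0,0,0) removed,
#' envelope leveling, masked integration, water correction). The three raw
#' estimates are combined by [consensus_estimate()].
#'
#' @param refl A \code{reflection_set} of the dataset (possibly with filled
#'   reflections).
#' @param structure The [toy_structure] providing ligand/protein geometry.
#' @param ctx A [counting_context] (envelope on the reflection grid).
#' @param d_trunc Common resolution limit for variants 2 and 3 (A).
#' @param b_sharpen Sharpening temperature factor for variant 3 (A^2,
#'   negative sharpens).
#' @param include_radius Ligand mask radius (A).
#' @param exclusions Exclusion spheres passed to [build_mask()].
#' @return An \code{occupancy_estimate}.
#' @export
three_model_occupancy <- function(refl, structure, ctx,
                                  d_trunc, b_sharpen = -8,
                                  include_radius = 2.0,
                                  exclusions = list()) {
  variants <- list(
    refl,
    resolution_truncate(refl, d_trunc),
    apply_reciprocal_bfactor(resolution_truncate(refl, d_trunc), b_sharpen))
  ests <- vapply(variants, function(r) {
    m <- map_from_reflections(r, zero_f000 = TRUE)
    mask <- build_mask(structure, m, include_radius, exclusions)
    count_occupancy(m, mask, ctx)
  }, numeric(1))
  consensus_estimate(ests)
}

#' Standard toy binding-site dataset
#'
#' Builds the package's reference synthetic crystal: a small protein-atom
#' cluster, a multi-atom ligand at a separate site with the requested
#' occupancy, and ordered waters occupying the same site in proportion
#' 1 - occupancy (the waters an incoming ligand displaces). Also returns
#' the ligand-free reference structure (waters at full occupancy) used to
#' fill unrecorded reflections, and the known electron counts for the
#' counting context.
#'
#' @param ligand_occupancy True ligand occupancy in [0, 1].
#' @param cell Box dimensions in A.
#' @return List with \code{structure}, \code{reference} (ligand-free),
#'   \code{ligand_electrons}, \code{water_electrons},
#'   \code{protein_electrons}.
#' @export
toy_binding_site <- function(ligand_occupancy, cell = c(16, 14, 12)) {
  stopifnot(ligand_occupancy >= 0, ligand_occupancy <= 1)
  # protein cluster near (4.5, 7, 6)
  pz <- c(6, 6, 6, 7, 8, 6, 7, 6)
  px <- c(3.5, 4.5, 5.5, 4.0, 5.0, 4.5, 3.8, 5.3)
  py <- c(6.0, 7.5, 6.5, 8.2, 5.8, 6.8, 7.0, 7.8)
  pzz <- c(5.5, 6.5, 5.0, 6.0, 6.8, 7.3, 5.2, 6.2)
  # ligand site near (11.5, 7, 6): 6 atoms, 42 electrons at full occupancy
  lz <- c(8, 8, 7, 7, 6, 6)
  lx <- c(10.8, 12.2, 11.5, 11.0, 12.0, 11.5)
  ly <- c(6.5, 7.5, 6.2, 7.9, 6.9, 7.1)
  lzz <- c(5.5, 6.5, 6.8, 5.4, 5.9, 6.9)
  # two ordered waters (10 e- each) displaced by the ligand
  wz <- c(10, 10)
  wx <- c(11.2, 11.9)
  wy <- c(7.0, 6.6)
  wzz <- c(6.2, 5.8)

  build <- function(lig_occ, wat_occ) {
    toy_structure(
      element_z = c(pz, lz, wz),
      x = c(px, lx, wx), y = c(py, ly, wy), z = c(pzz, lzz, wzz),
      b_factor = c(rep(25, length(pz)), rep(30, length(lz)),
                   rep(30, length(wz))),
      occupancy = c(rep(1, length(pz)), rep(lig_occ, length(lz)),
                    rep(wat_occ, length(wz))),
      role = c(rep("protein", length(pz)), rep("ligand", length(lz)),
               rep("water", length(wz))),
      cell = cell)
  }
  list(structure = build(ligand_occupancy, 1 - ligand_occupancy),
       reference = build(0, 1),
       ligand_electrons = sum(lz),
       water_electrons = sum(wz),
       protein_electrons = sum(pz))
}

#' End-to-end occupancy recovery on the toy binding site
#'
#' Convenience driver for validation sweeps: renders the toy dataset at the
#' requested true occupancy, computes structure factors, optionally removes
#' an overload-style fraction of reflections and fills them from the
#' ligand-free reference, inverts, and runs the three-model counting
#' consensus.
#'
#' @param ligand_occupancy True occupancy.
#' @param grid_spacing Map sampling in A.
#' @param d_trunc,b_sharpen Variant parameters for [three_model_occupancy()].
#' @param missing_fraction Fraction of reflections to remove and fill
#'   (0 disables).
#' @param include_radius Ligand mask radius (A).
#' @param seed Seed for the missingness draw.
#' @return The \code{occupancy_estimate}, with the true occupancy attached
#'   as attribute \code{truth}.
#' @export
recover_toy_occupancy <- function(ligand_occupancy, grid_spacing = 0.4,
                                  d_trunc = 1.2, b_sharpen = -8,
                                  missing_fraction = 0,
                                  include_radius = 2.5, seed = 1L) {
  site <- toy_binding_site(ligand_occupancy)
  map <- render_map(site$structure, grid_spacing)
  refl <- structure_factors(map)
  if (missing_fraction > 0) {
    ref_map <- render_map(site$reference, grid_spacing)
    ref_refl <- structure_factors(ref_map)
    refl <- fill_missing(
      simulate_incompleteness(refl, missing_fraction, seed = seed),
      ref_refl)
  }
  mask <- build_mask(site$structure, map, include_radius)
  env <- build_envelope(site$structure, map, radius = 2.5, ligand_mask = mask)
  ctx <- counting_context(site$ligand_electrons, site$water_electrons,
                          site$protein_electrons, env)
  est <- three_model_occupancy(refl, site$structure, ctx,
                               d_trunc = d_trunc, b_sharpen = b_sharpen,
                               include_radius = include_radius)
  attr(est, "truth") <- ligand_occupancy
  est
}
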