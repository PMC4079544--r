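#' Toy atomic structure in an orthogonal P1 box
#'
#' Assembles a minimal atomic model for the synthetic crystallography
#' sandbox: each atom carries an electron count (atomic number Z), a
#' position, an isotropic temperature factor B (A^2) and an occupancy, and
#' is tagged with a role (\code{protein}, \code{ligand}, \code{water} or
#' \code{heavy}). Atoms are single Gaussians whose density integrates to
#' exactly \eqn{Z \cdot occupancy}; no symmetry, orthogonal axes only.
#'
#' @param element_z Integer vector of electron counts (> 0).
#' @param x,y,z Atom coordinates in Angstroms, inside the cell.
#' @param b_factor Isotropic B in A^2 (> 0).
#' @param occupancy Fractions in [0, 1].
#' @param role Character vector of roles.
#' @param cell Length-3 vector: orthogonal box dimensions (a, b, c) in A.
#' @return A data.frame of class \code{toy_structure} with a \code{cell}
#'   attribute.
#' @export
toy_structure <- function(element_z, x, y, z, b_factor, occupancy, role,
                          cell) {
  n <- length(element_z)
  stopifnot(length(x) == n, length(y) == n, length(z) == n,
            length(b_factor) == n, length(occupancy) == n,
            length(role) == n, length(cell) == 3L, all(cell > 0))
  if (any(element_z <= 0)) stop("element_z must be positive electron counts")
  if (any(b_factor <= 0)) stop("b_factor must be positive (A^2)")
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancy must be in [0, 1]")
  if (!all(role %in% c("protein", "ligand", "water", "heavy")))
    stop("role must be one of protein, ligand, water, heavy")
  pos <- cbind(x, y, z)
  if (any(pos < 0) || any(sweep(pos, 2, cell) > 0))
    stop("atom positions must lie inside the cell box")
  if (!any(role == "protein")) stop("structure needs at least one protein atom")
  out <- data.frame(element_z = as.numeric(element_z), x = x, y = y, z = z,
                    b_factor = b_factor, occupancy = occupancy,
                    role = role, stringsAsFactors = FALSE)
  attr(out, "cell") <- as.numeric(cell)
  class(out) <- c("toy_structure", "data.frame")
  out
}

#' Total electrons contributed by a set of atoms
#'
#' @param structure A [toy_structure].
#' @param roles Optional role filter.
#' @return Sum of \eqn{Z \cdot occupancy} over the selected atoms.
#' @export
electron_content <- function(structure, roles = NULL) {
  sel <- if (is.null(roles)) rep(TRUE, nrow(structure))
         else structure$role %in% roles
  sum(structure$element_z[sel] * structure$occupancy[sel])
}

new_density_map <- function(grid, cell, absolute_scale = TRUE,
                            f000_offset = 0) {
  structure(list(grid = grid, cell = as.numeric(cell),
                 absolute_scale = isTRUE(absolute_scale),
                 f000_offset = f000_offset),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "Density map %dx%dx%d, cell %.2f x %.2f x %.2f A, %s scale, total %.2f e-\n",
    d[1], d[2], d[3], x$cell[1], x$cell[2], x$cell[3],
    if (x$absolute_scale) "absolute" else "relative", total_electrons(x)))
  invisible(x)
}

#' Voxel volume of a density map
#' @param map A \code{density_map}.
#' @return Volume of one voxel in A^3.
#' @export
voxel_volume <- function(map) prod(map$cell) / prod(dim(map$grid))

#' Total electrons represented by an absolute-scale map
#' @param map A \code{density_map}.
#' @return Integral of the density over the cell, in electrons.
#' @export
total_electrons <- function(map) sum(map$grid) * voxel_volume(map)

#' Sample a structure's electron density onto a grid
#'
#' Renders each atom as the standard isotropic B-factor Gaussian
#' \deqn{\rho(r) = Z \cdot occ \cdot (4\pi/B)^{3/2} \exp(-4\pi^2 r^2 / B),}
#' normalised so the atom integrates to \eqn{Z \cdot occ} electrons, onto a
#' periodic grid (tails wrap across the box, consistent with the Fourier
#' treatment downstream). Tails are truncated at 5 standard deviations of
#' the Gaussian, which discards well under 0.1% of each atom's electrons.
#'
#' @param structure A [toy_structure].
#' @param grid_spacing Target voxel edge in Angstroms. Must satisfy
#'   \code{grid_spacing <= sqrt(min(B))/6} for adequate sampling; grid
#'   dimensions are rounded up to even counts of at least 8 per axis.
#' @return An absolute-scale \code{density_map}.
#' @export
render_map <- function(structure, grid_spacing) {
  stopifnot(inherits(structure, "toy_structure"), grid_spacing > 0)
  cell <- attr(structure, "cell")
  if (grid_spacing > sqrt(min(structure$b_factor)) / 6)
    stop(sprintf(
      "grid_spacing %.3g too coarse for B_min = %.3g A^2: need <= %.3g A",
      grid_spacing, min(structure$b_factor),
      sqrt(min(structure$b_factor)) / 6))
  dims <- pmax(8L, 2L * as.integer(ceiling(cell / (2 * grid_spacing))))
  dx <- cell / dims
  grid <- array(0, dim = dims)
  for (i in seq_len(nrow(structure))) {
    at <- structure[i, ]
    if (at$occupancy == 0) next
    b <- at$b_factor
    sigma <- sqrt(b / (8 * pi^2))
    cutoff <- 5 * sigma
    if (2 * cutoff >= min(cell))
      stop("atom Gaussian footprint exceeds the cell; enlarge the box")
    peak <- at$element_z * at$occupancy * (4 * pi / b)^1.5
    pos <- c(at$x, at$y, at$z)
    idx <- vector("list", 3L)
    d2ax <- vector("list", 3L)
    for (ax in 1:3) {
      lo <- floor((pos[ax] - cutoff) / dx[ax])
      hi <- ceiling((pos[ax] + cutoff) / dx[ax])
      ii <- lo:hi
      d <- ii * dx[ax] - pos[ax]
      idx[[ax]] <- (ii %% dims[ax]) + 1L
      d2ax[[ax]] <- d^2
    }
    blob <- peak * exp(-(4 * pi^2 / b) *
      (outer(outer(d2ax[[1]], d2ax[[2]], `+`), d2ax[[3]], `+`)))
    grid[idx[[1]], idx[[2]], idx[[3]]] <-
      grid[idx[[1]], idx[[2]], idx[[3]]] + blob
  }
  new_density_map(grid, cell)
}

refl_s2 <- function(h, k, l, cell) {
  (h / cell[1])^2 + (k / cell[2])^2 + (l / cell[3])^2
}

signed_index <- function(n) {
  i <- 0:(n - 1L)
  ifelse(i <= n / 2, i, i - n)
}

new_reflection_set <- function(df, cell, dims, d_min) {
  structure(df, cell = as.numeric(cell), dims = as.integer(dims),
            d_min = d_min, class = c("reflection_set", "data.frame"))
}

#' Structure factors of a density map
#'
#' Discrete Fourier transform of the map,
#' \eqn{F(h) = V_{vox} \sum_x \rho(x) e^{+2\pi i h \cdot x / N}}, returning
#' the complex structure factors as a reflection table. F(0,0,0) equals the
#' total electron count in the cell; Friedel symmetry
#' \eqn{F(-h) = \overline{F(h)}} holds because the map is real.
#'
#' @param map An absolute-scale \code{density_map}.
#' @param d_min Resolution cutoff in Angstroms: only reflections with
#'   \eqn{1/d \le 1/d_{min}} are kept. \code{NULL} keeps the complete
#'   transform grid (exact inversion possible). Must not be finer than the
#'   grid Nyquist limit.
#' @return A \code{reflection_set}: data.frame with columns \code{h, k, l,
#'   f_re, f_im, source} and attributes \code{cell}, \code{dims},
#'   \code{d_min}.
#' @export
structure_factors <- function(map, d_min = NULL) {
  stopifnot(inherits(map, "density_map"))
  if (!map$absolute_scale)
    stop("map must be on an absolute scale before computing structure factors")
  dims <- dim(map$grid)
  cell <- map$cell
  fa <- stats::fft(map$grid, inverse = TRUE) * voxel_volume(map)
  hs <- signed_index(dims[1]); ks <- signed_index(dims[2])
  ls <- signed_index(dims[3])
  idx <- expand.grid(h = hs, k = ks, l = ls)
  df <- data.frame(h = idx$h, k = idx$k, l = idx$l,
                   f_re = as.vector(Re(fa)), f_im = as.vector(Im(fa)),
                   source = "observed", stringsAsFactors = FALSE)
  if (!is.null(d_min)) {
    nyq <- min((dims / 2) / cell)
    if (1 / d_min > nyq)
      stop(sprintf("d_min = %.3g A is finer than the grid Nyquist limit %.3g A",
                   d_min, 1 / nyq))
    keep <- refl_s2(df$h, df$k, df$l, cell) <= (1 / d_min)^2 + 1e-12
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  new_reflection_set(df, cell, dims, d_min)
}

#' Invert a reflection set back to a density map
#'
#' Places each structure factor on the transform grid (absent indices are
#' zero, as for unmeasured reflections) and applies the inverse discrete
#' Fourier transform. Inverting the complete set of a map's structure
#' factors reproduces that map to numerical precision.
#'
#' @param refl A \code{reflection_set}.
#' @param zero_f000 If TRUE, the F(0,0,0) term is dropped before inversion,
#'   emulating a crystallographic map whose absolute level is unknown.
#' @return A \code{density_map}; \code{absolute_scale} is FALSE when
#'   \code{zero_f000} was applied.
#' @export
map_from_reflections <- function(refl, zero_f000 = FALSE) {
  stopifnot(inherits(refl, "reflection_set"))
  dims <- attr(refl, "dims")
  cell <- attr(refl, "cell")
  fa <- array(0 + 0i, dim = dims)
  ih <- (refl$h %% dims[1]) + 1L
  ik <- (refl$k %% dims[2]) + 1L
  il <- (refl$l %% dims[3]) + 1L
  fa[cbind(ih, ik, il)] <- complex(real = refl$f_re, imaginary = refl$f_im)
  if (zero_f000) fa[1, 1, 1] <- 0 + 0i
  rho <- Re(stats::fft(fa)) / prod(cell)
  new_density_map(rho, cell, absolute_scale = !zero_f000)
}

#' Truncate a reflection set at a resolution limit
#'
#' @param refl A \code{reflection_set}.
#' @param d_min Resolution limit in Angstroms; reflections with d < d_min
#'   are discarded.
#' @return The truncated \code{reflection_set}.
#' @export
resolution_truncate <- function(refl, d_min) {
  stopifnot(inherits(refl, "reflection_set"), d_min > 0)
  cell <- attr(refl, "cell")
  keep <- refl_s2(refl$h, refl$k, refl$l, cell) <= (1 / d_min)^2 + 1e-12
  out <- refl[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_reflection_set(out, cell, attr(refl, "dims"), d_min)
}

#' Apply a reciprocal-space temperature factor
#'
#' Scales every structure factor by \eqn{\exp(-B s^2 / 4)} with
#' \eqn{s = 1/d}. Negative B sharpens, positive B blurs; B = 0 is the
#' identity, and F(0,0,0) is never changed (s = 0).
#'
#' @param refl A \code{reflection_set}.
#' @param b_sharpen Temperature factor in A^2 (may be negative).
#' @return The rescaled \code{reflection_set}.
#' @export
apply_reciprocal_bfactor <- function(refl, b_sharpen) {
  stopifnot(inherits(refl, "reflection_set"), is.finite(b_sharpen))
  cell <- attr(refl, "cell")
  scale <- exp(-b_sharpen * refl_s2(refl$h, refl$k, refl$l, cell) / 4)
  out <- refl
  out$f_re <- refl$f_re * scale
  out$f_im <- refl$f_im * scale
  out
}

#' Simulate overload-style missing reflections
#'
#' Flags a fraction of reflections as unrecorded: a small strongest-first
#' core emulating detector overloads (the brightest spots are the ones
#' lost) plus a seeded uniform random tail emulating the ordinary gaps
#' (blind regions, detector edges) that account for most incompleteness in
#' real data. Friedel mates are always removed together, so the flagged
#' count is \code{2 * round(fraction * n / 2)} — within one reflection of
#' \code{round(fraction * n)}; F(0,0,0) is never removed. Flagged
#' reflections have their amplitudes set to zero and
#' \code{source = "missing"}.
#'
#' @param refl A \code{reflection_set}.
#' @param missing_fraction Fraction in [0, 1) of reflections to flag.
#' @param seed Integer seed; the same seed flags the same set.
#' @param n_overload Number of strongest Friedel pairs lost as overloads
#'   (default 4). Overloads are the handful of spots that saturate the
#'   detector, so their number is small and does not scale with the overall
#'   missing fraction; the rest of the quota is drawn uniformly.
#' @return The degraded \code{reflection_set}.
#' @export
simulate_incompleteness <- function(refl, missing_fraction, seed = 1L,
                                    n_overload = 4L) {
  stopifnot(inherits(refl, "reflection_set"), n_overload >= 0)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("`missing_fraction` must be in [0, 1)")
  if (missing_fraction == 0) return(refl)
  n <- nrow(refl)
  m_pairs <- round(missing_fraction * n / 2)
  if (m_pairs == 0) return(refl)

  # canonical Friedel-pair key: the lexicographically larger of (h,k,l), (-h,-k,-l)
  key_fwd <- paste(refl$h, refl$k, refl$l)
  flip <- (refl$h < 0) | (refl$h == 0 & refl$k < 0) |
    (refl$h == 0 & refl$k == 0 & refl$l < 0)
  key <- ifelse(flip, paste(-refl$h, -refl$k, -refl$l), key_fwd)
  is_f000 <- refl$h == 0 & refl$k == 0 & refl$l == 0
  amp2 <- refl$f_re^2 + refl$f_im^2
  pair_amp <- tapply(amp2, key, max)
  pair_keys <- names(pair_amp)
  keep <- pair_keys != "0 0 0"
  pair_keys <- pair_keys[keep]
  pair_amp <- pair_amp[keep]
  if (m_pairs > length(pair_keys))
    stop("missing_fraction too large for the number of Friedel pairs")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  m_strong <- min(m_pairs, as.integer(n_overload))
  ord <- order(pair_amp, decreasing = TRUE)
  chosen <- pair_keys[ord[seq_len(m_strong)]]
  rest <- setdiff(pair_keys, chosen)
  if (m_pairs > m_strong)
    chosen <- c(chosen, sample(rest, m_pairs - m_strong))

  hit <- key %in% chosen & !is_f000
  out <- refl
  out$f_re[hit] <- 0
  out$f_im[hit] <- 0
  out$source[hit] <- "missing"
  out
}

#' Fill unrecorded reflections from a reference set
#'
#' Substitutes calculated structure factors from a reference model (in the
#' study design, the ligand-free starting model) for every reflection
#' flagged as missing. The filled reflections are tagged
#' \code{source = "filled"}; the fraction filled is recorded in the
#' \code{fill_fraction} attribute.
#'
#' @param observed A \code{reflection_set} possibly containing
#'   \code{source = "missing"} rows.
#' @param reference A complete \code{reflection_set} on the same cell and
#'   grid providing the substitute amplitudes.
#' @return The completed \code{reflection_set}.
#' @export
fill_missing <- function(observed, reference) {
  stopifnot(inherits(observed, "reflection_set"),
            inherits(reference, "reflection_set"))
  if (!isTRUE(all.equal(attr(observed, "cell"), attr(reference, "cell"))) ||
      !identical(attr(observed, "dims"), attr(reference, "dims")))
    stop("observed and reference reflection sets must share cell and grid")
  miss <- which(observed$source == "missing")
  out <- observed
  if (length(miss)) {
    key_obs <- paste(observed$h[miss], observed$k[miss], observed$l[miss])
    key_ref <- paste(reference$h, reference$k, reference$l)
    pos <- match(key_obs, key_ref)
    if (anyNA(pos))
      stop("reference set lacks ", sum(is.na(pos)), " required reflection(s)")
    out$f_re[miss] <- reference$f_re[pos]
    out$f_im[miss] <- reference$f_im[pos]
    out$source[miss] <- "filled"
  }
  attr(out, "fill_fraction") <- length(miss) / nrow(observed)
  out
}
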