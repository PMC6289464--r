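#' Specification of a synthetic cell-section map
#'
#' Describes a simulated EFTEM net map with known ground truth: an elliptical
#' cell section on a noisy background-subtracted field (zero-mean Gaussian
#' noise — background-subtracted counts fluctuate around zero), optionally a
#' mid-intensity structure class (emulating element-containing cell structures
#' that are not the inclusions of interest, e.g. thylakoids on a P-map), and
#' bright disk-shaped inclusions (reserve granules are roundish bodies).
#'
#' Inclusions are given either explicitly (`inclusions` data frame with
#' columns `row`, `col`, `radius` and optionally `mean`) or by count
#' (`n_inclusions` plus `radius_range`); in the latter case disk placement is
#' sampled inside the cell, deterministically per `seed`. The inclusion signal
#' is `s_inc` counts; the contrast presets `"high"` and `"low"` set it to
#' `20 * sigma_n` and `5 * sigma_n`.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param cell list with `center` (row, col) and `radii` (row, col semi-axes)
#'   of the elliptical cell mask; default: centered ellipse with semi-axes
#'   45% of the image size.
#' @param sigma_n background noise standard deviation (counts).
#' @param s_inc inclusion signal (counts); overrides `contrast`.
#' @param contrast `"high"` (`s_inc = 20 sigma_n`) or `"low"`
#'   (`s_inc = 5 sigma_n`).
#' @param inclusions optional data frame of explicit disks.
#' @param n_inclusions number of disks to place when `inclusions` is absent.
#' @param radius_range integer range (pixels) for sampled disk radii.
#' @param structure optional list `list(mean =, ellipses = list(...))`:
#'   mid-intensity class painted as ellipses (each
#'   `list(center =, radii =)`); requires `0 < mean < s_inc`.
#' @param compartments optional named list of ellipses painted (in order) as
#'   compartment labels inside the cell; remaining cell pixels are labeled
#'   `"cytosol"`.
#' @param seed integer seed controlling placement and noise.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(shape = c(256L, 256L),
                            cell = NULL,
                            sigma_n = 1,
                            s_inc = NULL,
                            contrast = c("high", "low"),
                            inclusions = NULL,
                            n_inclusions = 5L,
                            radius_range = c(4L, 10L),
                            structure = NULL,
                            compartments = NULL,
                            seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 16L))
  if (is.null(cell))
    cell <- list(center = (shape + 1) / 2, radii = 0.45 * shape)
  if (!is.numeric(sigma_n) || sigma_n < 0) stop("'sigma_n' must be >= 0")
  if (is.null(s_inc)) {
    contrast <- match.arg(contrast)
    if (sigma_n == 0)
      stop("contrast presets are defined relative to 'sigma_n'; ",
           "give 's_inc' explicitly for noiseless maps")
    s_inc <- switch(contrast, high = 20 * sigma_n, low = 5 * sigma_n)
  }
  if (s_inc <= 0) stop("'s_inc' must be positive")
  if (!is.null(structure)) {
    if (is.null(structure$mean) || is.null(structure$ellipses))
      stop("'structure' needs fields 'mean' and 'ellipses'")
    if (structure$mean <= 0 || structure$mean >= s_inc)
      stop("structure mean must satisfy 0 < s_mid < s_inc (got s_mid = ",
           structure$mean, ", s_inc = ", s_inc, ")")
  }
  if (!is.null(inclusions)) {
    inclusions <- as.data.frame(inclusions)
    stopifnot(all(c("row", "col", "radius") %in% names(inclusions)))
    if (any(inclusions$radius < 1)) stop("inclusion radii must be >= 1 pixel")
  } else {
    n_inclusions <- as.integer(n_inclusions)
    stopifnot(n_inclusions >= 0L, length(radius_range) == 2L,
              radius_range[1] >= 1L, radius_range[2] >= radius_range[1])
  }
  structure(list(shape = shape, cell = cell, sigma_n = sigma_n, s_inc = s_inc,
                 inclusions = inclusions, n_inclusions = n_inclusions,
                 radius_range = as.integer(radius_range),
                 structure = structure, compartments = compartments,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# logical ellipse mask
ellipse_mask <- function(shape, center, radii) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((c_ - center[2]) / radii[2])^2 <= 1
}

# logical disk mask
disk_mask <- function(shape, row, col, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - row)^2 + (c_ - col)^2 <= radius^2
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# resolve inclusion geometry: explicit table validated against the cell mask,
# or disks sampled (uniform center, uniform integer radius) fully inside the
# cell, with no overlap between disks
resolve_inclusions <- function(spec, cellmask) {
  shape <- spec$shape
  if (!is.null(spec$inclusions)) {
    inc <- spec$inclusions
    for (i in seq_len(nrow(inc))) {
      d <- disk_mask(shape, inc$row[i], inc$col[i], inc$radius[i])
      if (any(d & !cellmask))
        stop("inclusion ", i, " extends outside the cell mask")
    }
    if (is.null(inc$mean)) inc$mean <- spec$s_inc
    return(inc)
  }
  n <- spec$n_inclusions
  inc <- data.frame(row = numeric(0), col = numeric(0),
                    radius = integer(0), mean = numeric(0))
  if (n == 0L) return(inc)
  occupied <- matrix(FALSE, shape[1], shape[2])
  tries <- 0L
  while (nrow(inc) < n) {
    tries <- tries + 1L
    if (tries > 2000L * n)
      stop("could not place ", n, " non-overlapping inclusions inside the cell")
    rad <- sample(seq(spec$radius_range[1], spec$radius_range[2]), 1L)
    row <- sample(seq_len(shape[1]), 1L)
    col <- sample(seq_len(shape[2]), 1L)
    d <- disk_mask(shape, row, col, rad + 1)   # +1 px separation margin
    if (any(d & !cellmask) || any(d & occupied)) next
    occupied <- occupied | d
    inc <- rbind(inc, data.frame(row = row, col = col, radius = rad,
                                 mean = spec$s_inc))
  }
  inc
}

# paint compartment labels; returns list(labels, legend) or NULL
resolve_compartments <- function(spec, cellmask) {
  if (is.null(spec$compartments)) return(NULL)
  labels <- matrix(0L, spec$shape[1], spec$shape[2])
  nms <- names(spec$compartments)
  for (i in seq_along(spec$compartments)) {
    e <- spec$compartments[[i]]
    labels[ellipse_mask(spec$shape, e$center, e$radii) & cellmask] <- i
  }
  labels[cellmask & labels == 0L] <- length(spec$compartments) + 1L
  legend <- c(nms, "cytosol")
  names(legend) <- as.character(seq_along(legend))
  list(labels = labels, legend = legend)
}

#' Read a simulation specification from a JSON file
#'
#' The JSON mirrors the [simulation_spec()] arguments, e.g.
#' `{"shape": [256, 256], "sigma_n": 1, "contrast": "high",
#'   "n_inclusions": 5, "radius_range": [4, 10], "seed": 1}`;
#' `inclusions` may be an array of `{row, col, radius, mean}` objects,
#' `structure` an object `{mean, ellipses: [{center, radii}, ...]}` and
#' `compartments` a name-keyed object of `{center, radii}` ellipses.
#'
#' @param path JSON file path.
#' @return A [simulation_spec()].
#' @export
simulation_spec_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("shape", "sigma_n", "s_inc", "contrast", "n_inclusions",
               "radius_range", "seed"))
    if (!is.null(j[[nm]])) args[[nm]] <- j[[nm]]
  if (!is.null(j$cell))
    args$cell <- list(center = unlist(j$cell$center),
                      radii = unlist(j$cell$radii))
  if (!is.null(j$inclusions)) args$inclusions <- as.data.frame(j$inclusions)
  fix_ellipses <- function(e) lapply(e, function(x)
    list(center = unlist(x$center), radii = unlist(x$radii)))
  if (!is.null(j$structure))
    args$structure <- list(mean = j$structure$mean,
                           ellipses = fix_ellipses(j$structure$ellipses))
  if (!is.null(j$compartments)) args$compartments <- fix_ellipses(j$compartments)
  do.call(simulation_spec, args)
}

#' Generate a synthetic net map with ground truth
#'
#' Builds the map described by a [simulation_spec()]: zero-mean Gaussian noise
#' everywhere, plus the structure-class signal on its ellipses, plus the
#' inclusion signal on each disk. Output is bit-reproducible for a given seed
#' and leaves the caller's RNG state untouched.
#'
#' @param spec a [simulation_spec()].
#' @return A list with components `map` (a [net_map()]), `region` (a
#'   [region_mask()]) and `truth` (list: `inclusion_mask`, `structure_mask`,
#'   `true_S_TI`, `true_S_R`, `inclusions` data frame with per-disk `area` and
#'   `compartment`).
#' @export
generate_net_map <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    shape <- spec$shape
    cellmask <- ellipse_mask(shape, spec$cell$center, spec$cell$radii)
    inc <- resolve_inclusions(spec, cellmask)
    values <- matrix(rnorm(prod(shape), 0, spec$sigma_n), shape[1], shape[2])
    struct_mask <- matrix(FALSE, shape[1], shape[2])
    if (!is.null(spec$structure)) {
      for (e in spec$structure$ellipses)
        struct_mask <- struct_mask | ellipse_mask(shape, e$center, e$radii)
      struct_mask <- struct_mask & cellmask
      values[struct_mask] <- values[struct_mask] + spec$structure$mean
    }
    inc_mask <- matrix(FALSE, shape[1], shape[2])
    areas <- integer(nrow(inc))
    for (i in seq_len(nrow(inc))) {
      d <- disk_mask(shape, inc$row[i], inc$col[i], inc$radius[i])
      areas[i] <- sum(d)
      inc_mask <- inc_mask | d
      values[d] <- values[d] + inc$mean[i]
    }
    comp <- resolve_compartments(spec, cellmask)
    region <- region_mask(cellmask,
                          compartments = if (!is.null(comp)) comp$labels,
                          legend = if (!is.null(comp)) comp$legend)
    true_comp <- rep("not_determined", nrow(inc))
    if (!is.null(comp) && nrow(inc)) {
      for (i in seq_len(nrow(inc))) {
        d <- disk_mask(shape, inc$row[i], inc$col[i], inc$radius[i])
        labs <- comp$labels[d]
        counts <- table(labs[labs > 0L])
        if (length(counts) && max(counts) > sum(d) / 2)
          true_comp[i] <- comp$legend[[names(counts)[which.max(counts)]]]
      }
    }
    inc$area <- areas
    inc$compartment <- true_comp
    S_cell <- sum(cellmask)
    true_S_TI <- sum(inc_mask)
    list(map = net_map(values, provenance = "synthetic"),
         region = region,
         truth = list(inclusion_mask = inc_mask, structure_mask = struct_mask,
                      true_S_TI = true_S_TI,
                      true_S_R = 100 * true_S_TI / S_cell,
                      inclusions = inc))
  })
}

#' Generate a synthetic three-window triplet with ground truth
#'
#' Evaluates the power-law background \eqn{I(E) = A E^{-r}} per pixel at the
#' three window energies, adds the planted inclusion signal to the post-edge
#' image only, and optionally resamples all three images from Poisson
#' distributions (shot noise). Deterministic per seed.
#'
#' @param spec a [simulation_spec()] (cell/inclusion geometry, seed, `s_inc`).
#' @param A_field amplitude of the power law: scalar or matrix, must be `> 0`.
#' @param r_field exponent: scalar or matrix, must be `>= 0`.
#' @param energies three increasing energy losses in eV
#'   (default: the P-edge windows 104, 121, 144).
#' @param poisson if `TRUE`, each window image is Poisson-resampled.
#' @return A list with `pre1`, `pre2`, `post` ([window_image()]s), `region`,
#'   and `truth` (as in [generate_net_map()], plus the planted `signal`
#'   matrix).
#' @export
generate_window_triplet <- function(spec, A_field = 500, r_field = 1.5,
                                    energies = c(104, 121, 144),
                                    poisson = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"), length(energies) == 3L,
            all(diff(energies) > 0))
  shape <- spec$shape
  expand <- function(x, what) {
    if (length(x) == 1L) x <- matrix(x, shape[1], shape[2])
    if (!identical(dim(x), as.integer(shape)))
      stop("'", what, "' must be a scalar or a matrix of the map shape")
    x
  }
  A <- expand(A_field, "A_field"); r <- expand(r_field, "r_field")
  if (any(A <= 0)) stop("'A_field' must be strictly positive")
  if (any(r < 0)) stop("'r_field' must be >= 0")
  with_seed(spec$seed, {
    cellmask <- ellipse_mask(shape, spec$cell$center, spec$cell$radii)
    inc <- resolve_inclusions(spec, cellmask)
    signal <- matrix(0, shape[1], shape[2])
    inc_mask <- matrix(FALSE, shape[1], shape[2])
    areas <- integer(nrow(inc))
    for (i in seq_len(nrow(inc))) {
      d <- disk_mask(shape, inc$row[i], inc$col[i], inc$radius[i])
      areas[i] <- sum(d)
      inc_mask <- inc_mask | d
      signal[d] <- signal[d] + inc$mean[i]
    }
    imgs <- lapply(energies, function(e) A * e^(-r))
    imgs[[3]] <- imgs[[3]] + signal
    if (poisson)
      imgs <- lapply(imgs, function(m)
        matrix(rpois(length(m), m), shape[1], shape[2]))
    inc$area <- areas
    S_cell <- sum(cellmask)
    list(pre1 = window_image(imgs[[1]], energies[1], "pre1"),
         pre2 = window_image(imgs[[2]], energies[2], "pre2"),
         post = window_image(imgs[[3]], energies[3], "post"),
         region = region_mask(cellmask),
         truth = list(inclusion_mask = inc_mask, signal = signal,
                      true_S_TI = sum(inc_mask),
                      true_S_R = 100 * sum(inc_mask) / S_cell,
                      inclusions = inc))
  })
}
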