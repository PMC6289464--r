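#' Region masks for a cell section
#'
#' Geometry accompanying a map: which pixels belong to the cell section,
#' optionally an integer compartment labeling (with a legend mapping label to
#' compartment name) and an optional analyst-selected region of interest that
#' restricts inclusion counting (the programmatic equivalent of manually
#' outlining inclusion regions on the processed map).
#'
#' @param cell logical matrix; `TRUE` = pixel belongs to the cell section.
#' @param compartments optional integer matrix of compartment labels
#'   (0 = background / unlabeled).
#' @param legend named character vector or list mapping label numbers (names)
#'   to compartment names, e.g. `c("1" = "vacuole", "2" = "cytosol")`.
#'   Standard names: vacuole, cytosol, chloroplast, nucleus, PHB.
#' @param roi optional logical matrix restricting where inclusions are counted.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(cell, compartments = NULL, legend = NULL, roi = NULL) {
  if (!is.matrix(cell) || !is.logical(cell))
    stop("'cell' must be a logical matrix")
  if (!is.null(compartments)) {
    if (!is.matrix(compartments) || !identical(dim(compartments), dim(cell)))
      stop("'compartments' must be an integer matrix with the shape of 'cell'")
    storage.mode(compartments) <- "integer"
    if (is.null(legend)) stop("'compartments' requires a 'legend'")
    legend <- vapply(legend, as.character, "")
    if (is.null(names(legend)) || any(!nzchar(names(legend))))
      stop("'legend' must be named by label number")
  }
  if (!is.null(roi) && (!is.matrix(roi) || !is.logical(roi) ||
                        !identical(dim(roi), dim(cell))))
    stop("'roi' must be a logical matrix with the shape of 'cell'")
  structure(list(cell = cell, compartments = compartments,
                 legend = legend, roi = roi),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d x %d px, cell area %d px%s%s\n",
              nrow(x$cell), ncol(x$cell), sum(x$cell),
              if (!is.null(x$compartments))
                paste0(", compartments: ", paste(x$legend, collapse = "/"))
              else "",
              if (!is.null(x$roi)) paste0(", roi ", sum(x$roi), " px") else ""))
  invisible(x)
}

# Connected-component labeling of a logical mask. EBImage::bwlabel is
# 4-connected; for 8-connectivity, labels that touch diagonally are merged
# with a union-find over label pairs.
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("'connectivity' must be 4 or 8")
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (connectivity == 8L && nmax > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonal neighbor pairs with two distinct nonzero labels
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(nmax)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nmax), find, 1L)
      dense <- match(root, sort(unique(root)))
      lab[lab > 0L] <- dense[lab[lab > 0L]]
    }
  }
  lab
}

#' Label inclusions on a thresholded map
#'
#' Connected components of the white pixels, restricted to the analyst region
#' of interest if one is supplied, otherwise to the cell mask. Replaces the
#' manual selection of inclusion regions with reproducible component labeling;
#' pass a `roi` in the [region_mask()] to reproduce manual selection.
#'
#' @param mask a `binary_mask` from [binarize()] (or any logical matrix).
#' @param region a [region_mask()]; its `cell` mask must be non-empty.
#' @param min_area smallest component area (pixels) to keep. The default 1
#'   counts every white pixel, matching raw white-pixel counting.
#' @param connectivity pixel adjacency, 8 (default, diagonals connect) or 4.
#' @return An object of class `inclusion_set`: integer `labels` matrix and a
#'   data frame `records` with columns `id`, `area`, `centroid_row`,
#'   `centroid_col`, `bbox_row1`, `bbox_row2`, `bbox_col1`, `bbox_col2`,
#'   `compartment` (initialized `"not_determined"`).
#' @export
label_inclusions <- function(mask, region, min_area = 1L, connectivity = 8L) {
  stopifnot(inherits(region, "region_mask"))
  mask <- unclass(mask)
  if (!is.logical(mask)) stop("'mask' must be logical")
  if (!identical(dim(mask), dim(region$cell)))
    stop("mask and region have mismatching shapes")
  if (!any(region$cell)) stop("empty cell mask")
  keep <- if (!is.null(region$roi)) region$roi else region$cell
  lab <- label_components(mask & keep, connectivity)
  n <- max(lab)
  if (n == 0L) {
    return(structure(list(labels = lab, records = empty_records()),
                     class = "inclusion_set"))
  }
  px <- which(lab > 0L)
  id <- lab[px]
  rows <- (px - 1L) %% nrow(lab) + 1L
  cols <- (px - 1L) %/% nrow(lab) + 1L
  area <- tabulate(id, n)
  rec <- data.frame(
    id = seq_len(n),
    area = area,
    centroid_row = as.numeric(tapply(rows, id, mean)),
    centroid_col = as.numeric(tapply(cols, id, mean)),
    bbox_row1 = as.integer(tapply(rows, id, min)),
    bbox_row2 = as.integer(tapply(rows, id, max)),
    bbox_col1 = as.integer(tapply(cols, id, min)),
    bbox_col2 = as.integer(tapply(cols, id, max)),
    compartment = "not_determined",
    stringsAsFactors = FALSE)
  drop <- rec$area < min_area
  if (any(drop)) {
    lab[lab %in% rec$id[drop]] <- 0L
    rec <- rec[!drop, , drop = FALSE]
    if (nrow(rec)) {
      relab <- match(lab[lab > 0L], rec$id)
      lab[lab > 0L] <- relab
      rec$id <- seq_len(nrow(rec))
      rownames(rec) <- NULL
    }
  }
  structure(list(labels = lab, records = rec), class = "inclusion_set")
}

empty_records <- function() {
  data.frame(id = integer(), area = integer(),
             centroid_row = numeric(), centroid_col = numeric(),
             bbox_row1 = integer(), bbox_row2 = integer(),
             bbox_col1 = integer(), bbox_col2 = integer(),
             compartment = character(), stringsAsFactors = FALSE)
}

#' @export
print.inclusion_set <- function(x, ...) {
  cat(sprintf("<inclusion_set> %d inclusion(s), total area %d px\n",
              nrow(x$records), sum(x$records$area)))
  if (nrow(x$records)) print(x$records[, c("id", "area", "compartment")])
  invisible(x)
}

#' Assign inclusions to cell compartments
#'
#' Each inclusion is attributed to the compartment covering a strict majority
#' (> 50%) of its pixels; without one (including ties, unlabeled pixels in the
#' majority, or no compartment image at all) the localization is recorded as
#' `"not_determined"`.
#'
#' @param incs an `inclusion_set` from [label_inclusions()].
#' @param region a [region_mask()] with `compartments` and `legend`.
#' @return The `inclusion_set` with the `compartment` column filled in.
#' @export
assign_compartments <- function(incs, region) {
  stopifnot(inherits(incs, "inclusion_set"), inherits(region, "region_mask"))
  if (is.null(region$compartments) || nrow(incs$records) == 0L) {
    incs$records$compartment <- rep("not_determined", nrow(incs$records))
    return(incs)
  }
  if (!identical(dim(region$compartments), dim(incs$labels)))
    stop("compartment image and labels have mismatching shapes")
  rec <- incs$records
  for (i in seq_len(nrow(rec))) {
    px <- incs$labels == rec$id[i]
    labs <- region$compartments[px]
    counts <- table(labs[labs > 0L])
    rec$compartment[i] <- "not_determined"
    if (length(counts)) {
      top <- which.max(counts)
      if (counts[top] > sum(px) / 2) {
        nm <- region$legend[[names(counts)[top]]]
        rec$compartment[i] <- if (is.null(nm)) "not_determined" else nm
      }
    }
  }
  incs$records <- rec
  incs
}

#' Measure one cell section
#'
#' Aggregates the labeled inclusions of one section into the section-level
#' quantities: total inclusion area \eqn{S_{TI}} (pixels), cell-section area
#' \eqn{S_{cell}} (pixels), and the relative reserve area
#' \deqn{S_R = 100\, S_{TI} / S_{cell} \quad (\%).}
#'
#' @param incs an `inclusion_set` (after [assign_compartments()] if
#'   localization is wanted).
#' @param region a [region_mask()]; `S_cell` is the count of cell-mask pixels.
#' @param section_id identifier for the section.
#' @param workflow which workflow produced the mask (`"A"` or `"B"`).
#' @return An object of class `section_result` with fields `section_id`,
#'   `workflow`, `S_cell`, `S_TI`, `S_R`, `n_inclusions`, `inclusions`
#'   (the records data frame) and `per_compartment_S` (named numeric).
#' @export
measure_section <- function(incs, region, section_id = "section", workflow = "A") {
  stopifnot(inherits(incs, "inclusion_set"), inherits(region, "region_mask"))
  S_cell <- sum(region$cell)
  if (S_cell == 0L) stop("empty cell mask: S_cell = 0")
  rec <- incs$records
  S_TI <- sum(rec$area)
  per <- if (nrow(rec)) {
    vapply(split(rec$area, rec$compartment), sum, 0)
  } else numeric(0)
  structure(list(section_id = section_id, workflow = workflow,
                 S_cell = as.integer(S_cell), S_TI = as.integer(S_TI),
                 S_R = 100 * S_TI / S_cell,
                 n_inclusions = nrow(rec),
                 inclusions = rec,
                 per_compartment_S = per),
            class = "section_result")
}

#' @export
print.section_result <- function(x, ...) {
  cat(sprintf("<section_result> %s (workflow %s): %d inclusion(s), S_TI = %d px, S_cell = %d px, S_R = %.3f%%\n",
              x$section_id, x$workflow, x$n_inclusions, x$S_TI, x$S_cell, x$S_R))
  if (length(x$per_compartment_S)) {
    cat("  per compartment:",
        paste(names(x$per_compartment_S), x$per_compartment_S,
              sep = " = ", collapse = ", "), "px\n")
  }
  invisible(x)
}

#' Summarize a sample of cell sections
#'
#' Multi-section summary in the style of per-sample section surveys: the
#' section table sorted by decreasing \eqn{S_R}, range statistics, the number
#' of sections above a reserve-richness threshold and at zero, and, where
#' compartments were assigned, the distribution of the main-reserve
#' compartment (the compartment holding the largest inclusion area in each
#' section).
#'
#' @param results list of `section_result` objects (one per section).
#' @param threshold_pct sections with `S_R` above this percentage are counted
#'   as reserve-rich (default 8).
#' @param by_compartment if `TRUE`, sort the table by main compartment first,
#'   then by decreasing `S_R` within compartment.
#' @return An object of class `section_summary`: data frame `sections`
#'   (section_id, workflow, S_cell, S_TI, S_R, n_inclusions,
#'   main_compartment), scalars `min_S_R`, `max_S_R`, `n_above`, `n_zero`,
#'   `threshold_pct`, and `compartment_fractions` (percent of sections whose
#'   main reserve sits in each compartment).
#' @export
summarize_sections <- function(results, threshold_pct = 8, by_compartment = FALSE) {
  if (!length(results)) stop("no section results supplied")
  if (inherits(results, "section_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, TRUE, "section_result")))
  main_comp <- vapply(results, function(r) {
    if (!length(r$per_compartment_S)) return("none")
    names(r$per_compartment_S)[which.max(r$per_compartment_S)]
  }, "")
  tb <- data.frame(
    section_id = vapply(results, function(r) as.character(r$section_id), ""),
    workflow = vapply(results, function(r) r$workflow, ""),
    S_cell = vapply(results, function(r) r$S_cell, 1L),
    S_TI = vapply(results, function(r) r$S_TI, 1L),
    S_R = vapply(results, function(r) r$S_R, 1),
    n_inclusions = vapply(results, function(r) r$n_inclusions, 1L),
    main_compartment = main_comp,
    stringsAsFactors = FALSE)
  ord <- if (by_compartment) order(tb$main_compartment, -tb$S_R) else order(-tb$S_R)
  tb <- tb[ord, , drop = FALSE]
  rownames(tb) <- NULL
  with_comp <- main_comp[main_comp != "none"]
  frac <- if (length(with_comp)) {
    100 * table(with_comp) / length(with_comp)
  } else table(character(0))
  structure(list(sections = tb,
                 min_S_R = min(tb$S_R), max_S_R = max(tb$S_R),
                 n_above = sum(tb$S_R > threshold_pct),
                 n_zero = sum(tb$S_R == 0),
                 threshold_pct = threshold_pct,
                 compartment_fractions = frac),
            class = "section_summary")
}

#' @export
print.section_summary <- function(x, ...) {
  cat(sprintf("<section_summary> %d sections: S_R in [%.2f, %.2f]%%, %d above %.3g%%, %d at zero\n",
              nrow(x$sections), x$min_S_R, x$max_S_R, x$n_above,
              x$threshold_pct, x$n_zero))
  if (length(x$compartment_fractions)) {
    cat("  main-reserve compartment:",
        paste(names(x$compartment_fractions),
              sprintf("%.1f%%", x$compartment_fractions), collapse = ", "), "\n")
  }
  print(x$sections)
  invisible(x)
}

#' Choose the analysis workflow for a map
#'
#' Workflow A (threshold at `g0`, the positive-entropy onset) suits maps with
#' few inclusions; with many inclusions the element-containing structures
#' merge into the positive tail, so workflow B (zero negatives, threshold at
#' `g1`, the end of the first entropy peak) is used instead. In `"auto"` mode
#' the map is first analyzed with workflow A and the inclusion count decides:
#' up to 10 inclusions keeps A, more than 10 switches to B.
#'
#' @param mode `"A"`, `"B"` or `"auto"`.
#' @param map a [net_map()] (required for `"auto"`).
#' @param region a [region_mask()] (required for `"auto"`).
#' @param min_run,min_area,connectivity passed to the workflow-A pass in
#'   `"auto"` mode.
#' @return `"A"` or `"B"`.
#' @export
select_workflow <- function(mode = c("auto", "A", "B"), map = NULL, region = NULL,
                            min_run = 12L, min_area = 1L, connectivity = 8L) {
  mode <- match.arg(mode)
  if (mode != "auto") return(mode)
  if (is.null(map) || is.null(region))
    stop("'auto' workflow selection needs the map and region masks")
  g <- to_grey(map)
  an <- entropy_analysis(grey_histogram(g))
  g0 <- find_g0(an, min_run = min_run)
  if (is.na(g0)) return("A")   # no inclusions at all -> trivially few
  incs <- label_inclusions(binarize(g, g0), region,
                           min_area = min_area, connectivity = connectivity)
  if (nrow(incs$records) > 10L) "B" else "A"
}
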