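#' Run the full map-analysis pipeline on one cell section
#'
#' Executes the complete chain on a net map (or a three-window triplet):
#' optional background subtraction, workflow-B negative zeroing, grey
#' quantization, relative-entropy analysis, thresholding (`g0` for workflow A,
#' `g1` for workflow B), binarization, inclusion labeling, compartment
#' assignment and section measurement.
#'
#' In `workflow = "auto"` the map is analyzed with workflow A first; if more
#' than 10 inclusions are found the analysis is redone with workflow B
#' (negatives zeroed, threshold at the end of the first entropy peak). A map
#' whose entropy analysis finds no threshold (`g0` absent) is reported as a
#' section without inclusions (`S_R = 0`) with a warning — noise-only sections
#' are a meaningful biological outcome, not an error.
#'
#' @param map a [net_map()]; or `NULL` if a window triplet is given.
#' @param region a [region_mask()].
#' @param pre1,pre2,post optional [window_image()] triplet, used when `map` is
#'   `NULL`.
#' @param workflow `"auto"`, `"A"` or `"B"`.
#' @param min_run run-length guard for [find_g0()].
#' @param min_area,connectivity passed to [label_inclusions()].
#' @param smooth_window passed to [find_g1()].
#' @param threshold_override optional grey level in `[0, 255]`; bypasses the
#'   entropy thresholds (recorded in the output).
#' @param section_id identifier for the section.
#' @param out_dir optional directory: writes `entropy.csv` (g, H, G, R, RH),
#'   `record.json`, `mask.tif`, `inclusions.csv` and `section.csv`
#'   (plus `grey.tif` with `save_grey`).
#' @param save_grey also write the 8-bit grey image when `out_dir` is set.
#' @param verbose log stages to stderr.
#' @return An object of class `analysis_result`: the `section` (a
#'   `section_result`), `analysis` (the [entropy_analysis()] actually used for
#'   thresholding), `g0`, `g1`, `threshold`, `threshold_override`, `workflow`,
#'   `mask`, `grey` and `map`.
#' @export
run_analysis <- function(map = NULL, region,
                         pre1 = NULL, pre2 = NULL, post = NULL,
                         workflow = c("auto", "A", "B"),
                         min_run = 12L, min_area = 1L, connectivity = 8L,
                         smooth_window = 0L, threshold_override = NULL,
                         section_id = "section", out_dir = NULL,
                         save_grey = FALSE, verbose = FALSE) {
  workflow <- match.arg(workflow)
  stopifnot(inherits(region, "region_mask"))
  say <- function(...) if (verbose) message("[entropymap] ", ...)
  if (is.null(map)) {
    if (is.null(pre1) || is.null(pre2) || is.null(post))
      stop("give either 'map' or the full 'pre1'/'pre2'/'post' triplet")
    say("three-window: fitting power-law background")
    model <- fit_powerlaw_background(pre1, pre2)
    map <- compute_net_map(post, model)
    say("three-window: ", map$invalid_pixels, " invalid pixel(s)")
  }
  stopifnot(inherits(map, "net_map"))
  if (!identical(dim(map$values), dim(region$cell)))
    stop("map and region masks have mismatching shapes")
  if (!is.null(threshold_override) &&
      (threshold_override < 0 || threshold_override > 255))
    stop("'threshold_override' must lie in [0, 255]")

  run_pass <- function(wf) {
    m <- if (wf == "B") zero_negatives(map) else map
    grey <- to_grey(m)
    an <- entropy_analysis(grey_histogram(grey))
    g0 <- find_g0(an, min_run = min_run)
    g1 <- NA_integer_
    thr <- g0
    if (wf == "B") {
      g1 <- find_g1(an, g0, smooth_window = smooth_window)
      thr <- g1
    }
    if (!is.null(threshold_override)) thr <- as.integer(threshold_override)
    if (is.na(thr)) {
      say("workflow ", wf, ": no threshold found (noise-only map)")
      mask <- structure(matrix(FALSE, nrow(grey$levels), ncol(grey$levels)),
                        class = c("binary_mask", "matrix"))
    } else {
      say("workflow ", wf, ": threshold g = ", thr)
      mask <- binarize(grey, thr)
    }
    incs <- label_inclusions(mask, region, min_area = min_area,
                             connectivity = connectivity)
    incs <- assign_compartments(incs, region)
    list(wf = wf, grey = grey, analysis = an, g0 = g0, g1 = g1,
         threshold = thr, mask = mask, incs = incs)
  }

  pass <- run_pass(if (workflow == "B") "B" else "A")
  if (workflow == "auto" && nrow(pass$incs$records) > 10L) {
    say("auto: ", nrow(pass$incs$records),
        " inclusions under workflow A -> switching to workflow B")
    pass <- run_pass("B")
  }
  if (is.na(pass$threshold))
    warning("no inclusions: no grouped positive relative entropy above the ",
            "mean (g0 absent); reporting S_R = 0")

  section <- measure_section(pass$incs, region, section_id = section_id,
                             workflow = pass$wf)
  res <- structure(list(section = section, analysis = pass$analysis,
                        g0 = pass$g0, g1 = pass$g1,
                        threshold = pass$threshold,
                        threshold_override = threshold_override,
                        workflow = pass$wf, mask = pass$mask,
                        grey = pass$grey, map = map,
                        inclusions = pass$incs),
                   class = "analysis_result")
  if (!is.null(out_dir)) write_analysis(res, out_dir, save_grey = save_grey)
  res
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("<analysis_result> workflow %s, g0 = %s, g1 = %s, threshold = %s\n",
              x$workflow, format(x$g0), format(x$g1), format(x$threshold)))
  print(x$section)
  invisible(x)
}

#' Write the artifacts of an analysis result
#'
#' Emits, into `dir`: `entropy.csv` (the 256-row g/H/G/R/RH table, the
#' spreadsheet-equivalent of the method), `record.json` (g_mean, sigma2, q,
#' g0, g1, threshold, workflow, S values), `mask.tif` (the thresholded map),
#' `inclusions.csv` and `section.csv`.
#'
#' @param res an `analysis_result` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @param save_grey also write `grey.tif`.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(res, dir, save_grey = FALSE) {
  stopifnot(inherits(res, "analysis_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$analysis$table, file.path(dir, "entropy.csv"),
            row.names = FALSE)
  s <- res$section
  rec <- list(section_id = s$section_id, workflow = res$workflow,
              g_mean = res$analysis$g_mean, sigma2 = res$analysis$sigma2,
              q = res$analysis$q,
              g0 = if (is.na(res$g0)) NULL else res$g0,
              g1 = if (is.na(res$g1)) NULL else res$g1,
              threshold = if (is.na(res$threshold)) NULL else res$threshold,
              threshold_override = res$threshold_override,
              invalid_pixels = res$map$invalid_pixels,
              S_cell_px = s$S_cell, S_TI_px = s$S_TI, S_R_percent = s$S_R,
              n_inclusions = s$n_inclusions)
  jsonlite::write_json(rec, file.path(dir, "record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write_grey_tiff(res$mask, file.path(dir, "mask.tif"))
  if (save_grey) write_grey_tiff(res$grey, file.path(dir, "grey.tif"))
  inc <- s$inclusions
  inc <- cbind(section_id = rep(s$section_id, nrow(inc)), inc)
  write.csv(inc, file.path(dir, "inclusions.csv"), row.names = FALSE)
  sec <- data.frame(section_id = s$section_id, workflow = s$workflow,
                    S_cell_px = s$S_cell, S_TI_px = s$S_TI,
                    S_R_percent = s$S_R, n_inclusions = s$n_inclusions,
                    stringsAsFactors = FALSE)
  for (nm in names(s$per_compartment_S))
    sec[[paste0("S_", nm, "_px")]] <- s$per_compartment_S[[nm]]
  write.csv(sec, file.path(dir, "section.csv"), row.names = FALSE)
  invisible(dir)
}

#' Rebuild section results from per-section CSV files
#'
#' Reads `section.csv` files written by [write_analysis()] so that multiple
#' sections (e.g. the 18 random sections of a sample survey) can be combined
#' with [summarize_sections()].
#'
#' @param paths character vector of `section.csv` paths.
#' @return A list of `section_result` objects.
#' @export
read_sections <- function(paths) {
  lapply(paths, function(p) {
    d <- read.csv(p, stringsAsFactors = FALSE)
    if (nrow(d) != 1L) stop("expected a single-row section table: ", p)
    compcols <- grep("^S_.*_px$", names(d), value = TRUE)
    compcols <- setdiff(compcols, c("S_cell_px", "S_TI_px"))
    per <- as.numeric(d[1, compcols])
    names(per) <- sub("^S_(.*)_px$", "\\1", compcols)
    structure(list(section_id = d$section_id, workflow = d$workflow,
                   S_cell = d$S_cell_px, S_TI = d$S_TI_px,
                   S_R = d$S_R_percent, n_inclusions = d$n_inclusions,
                   inclusions = empty_records(),
                   per_compartment_S = per[!is.na(per)]),
              class = "section_result")
  })
}
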