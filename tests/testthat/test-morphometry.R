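mask_from <- function(v, nr) structure(matrix(as.logical(v), nr),
                                       class = c("binary_mask", "matrix"))

test_that("inclusion labeling finds connected components within the cell", {
  reg <- full_region(5, 5)

  # smallest possible inclusion
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  incs <- label_inclusions(mask_from(m, 5), reg)
  expect_identical(nrow(incs$records), 1L)
  expect_identical(incs$records$area, 1L)
  expect_equal(incs$records$centroid_row, 3)

  # diagonal touch: one component at 8-connectivity, two at 4
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_identical(nrow(label_inclusions(mask_from(m, 5), reg, connectivity = 8)$records), 1L)
  four <- label_inclusions(mask_from(m, 5), reg, connectivity = 4)
  expect_identical(nrow(four$records), 2L)
  # EBImage's 4-connected labeling is the independent oracle
  expect_equal(max(EBImage::bwlabel(m * 1)), 2)

  # all-black mask -> no inclusions
  empty <- label_inclusions(mask_from(matrix(FALSE, 5, 5), 5), reg)
  expect_identical(nrow(empty$records), 0L)

  # min_area filter and label consistency
  m <- matrix(FALSE, 6, 6); m[1:2, 1:2] <- TRUE; m[5, 5] <- TRUE
  kept <- label_inclusions(mask_from(m, 6), full_region(6, 6), min_area = 2)
  expect_identical(nrow(kept$records), 1L)
  expect_identical(kept$records$area, 4L)
  expect_identical(sort(unique(as.vector(kept$labels))), c(0L, 1L))

  # cell mask restricts counting; empty cell is an error
  cellonly <- region_mask(matrix(c(TRUE, FALSE)[c(1, 1, 2, 2)], 2, 2))
  m <- matrix(TRUE, 2, 2)
  expect_identical(sum(label_inclusions(mask_from(m, 2), cellonly)$records$area), 2L)
  expect_error(label_inclusions(mask_from(m, 2), region_mask(matrix(FALSE, 2, 2))),
               "empty cell")
})

test_that("roi restricts labeling like a manual selection", {
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE; m[5:6, 5:6] <- TRUE
  roi <- matrix(FALSE, 6, 6); roi[1:4, 1:4] <- TRUE
  reg <- region_mask(matrix(TRUE, 6, 6), roi = roi)
  incs <- label_inclusions(mask_from(m, 6), reg)
  expect_identical(nrow(incs$records), 1L)
  expect_identical(incs$records$area, 4L)
})

test_that("compartments are assigned by strict pixel majority", {
  cell <- matrix(TRUE, 4, 5)
  comp <- matrix(0L, 4, 5)
  comp[, 1:3] <- 1L; comp[, 4:5] <- 2L
  reg <- region_mask(cell, comp, legend = c("1" = "vacuole", "2" = "cytosol"))

  # fully inside the vacuole
  m <- matrix(FALSE, 4, 5); m[2, 1:2] <- TRUE
  incs <- assign_compartments(label_inclusions(mask_from(m, 4), reg), reg)
  expect_identical(incs$records$compartment, "vacuole")

  # 60% vacuole / 40% cytosol -> vacuole (6 px in labels 1, 4 px in label 2)
  m <- matrix(FALSE, 4, 5); m[1:2, 1:5] <- TRUE
  incs <- assign_compartments(label_inclusions(mask_from(m, 4), reg), reg)
  expect_identical(incs$records$compartment, "vacuole")

  # exact 50/50 split -> not determined
  m <- matrix(FALSE, 4, 5); m[1:2, 3:4] <- TRUE
  incs <- assign_compartments(label_inclusions(mask_from(m, 4), reg), reg)
  expect_identical(incs$records$compartment, "not_determined")

  # no compartment image at all
  incs <- assign_compartments(label_inclusions(mask_from(m, 4), full_region(4, 5)),
                              full_region(4, 5))
  expect_identical(incs$records$compartment, "not_determined")
})

test_that("section measurement implements S_R = 100 * S_TI / S_cell", {
  cell <- matrix(TRUE, 10, 10)
  reg <- region_mask(cell)

  none <- label_inclusions(mask_from(matrix(FALSE, 10, 10), 10), reg)
  s <- measure_section(none, reg)
  expect_identical(s$S_TI, 0L)
  expect_identical(s$S_R, 0)

  all_in <- label_inclusions(mask_from(matrix(TRUE, 10, 10), 10), reg)
  expect_identical(measure_section(all_in, reg)$S_R, 100)

  # direct arithmetic case
  fake <- structure(list(labels = matrix(0L, 10, 10),
                         records = data.frame(id = 1L, area = 37L,
                                              centroid_row = 1, centroid_col = 1,
                                              bbox_row1 = 1L, bbox_row2 = 1L,
                                              bbox_col1 = 1L, bbox_col2 = 1L,
                                              compartment = "vacuole")),
                    class = "inclusion_set")
  big <- region_mask(matrix(c(rep(TRUE, 5000), rep(FALSE, 200)), 100, 52))
  s <- measure_section(fake, big)
  expect_identical(s$S_cell, 5000L)
  expect_equal(s$S_R, 0.74)

  expect_error(measure_section(none, region_mask(matrix(FALSE, 2, 2))), "S_cell")
})

test_that("per-compartment areas add up to S_TI", {
  set.seed(6)
  cell <- ellipse_full <- matrix(TRUE, 30, 30)
  comp <- matrix(sample(0:3, 900, replace = TRUE), 30)
  reg <- region_mask(cell, comp,
                     legend = c("1" = "vacuole", "2" = "chloroplast", "3" = "nucleus"))
  m <- matrix(runif(900) < 0.2, 30)
  incs <- assign_compartments(label_inclusions(mask_from(m, 30), reg), reg)
  s <- measure_section(incs, reg)
  expect_identical(as.integer(sum(s$per_compartment_S)), s$S_TI)
  # min_area = 1 reproduces raw white-pixel counting
  expect_identical(s$S_TI, sum(m))
})

test_that("S_R is invariant under translation and rotation of all arrays", {
  set.seed(7)
  m <- matrix(FALSE, 20, 20); m[5:8, 5:8] <- TRUE; m[14:15, 10:12] <- TRUE
  cell <- matrix(FALSE, 20, 20); cell[3:18, 3:18] <- TRUE
  base <- measure_section(label_inclusions(mask_from(m, 20), region_mask(cell)),
                          region_mask(cell))
  rot <- function(x) t(apply(x, 2, rev))
  r90 <- measure_section(label_inclusions(mask_from(rot(m), 20), region_mask(rot(cell))),
                         region_mask(rot(cell)))
  expect_identical(base$S_R, r90$S_R)
  sh <- function(x) rbind(x[-1, ], FALSE)  # translate by one row (content clear of edge)
  tr <- measure_section(label_inclusions(mask_from(sh(m), 20), region_mask(sh(cell))),
                        region_mask(sh(cell)))
  expect_identical(base$S_R, tr$S_R)
})

test_that("section summaries sort, count and attribute main compartments", {
  mk <- function(id, sr, comp = NULL) {
    per <- if (is.null(comp)) numeric(0) else stats::setNames(100, comp)
    structure(list(section_id = id, workflow = "A", S_cell = 1000L,
                   S_TI = as.integer(10 * sr), S_R = sr,
                   n_inclusions = as.integer(sr > 0), inclusions = empty_records(),
                   per_compartment_S = per),
              class = "section_result")
  }
  sm <- summarize_sections(list(mk("a", 0), mk("b", 2), mk("c", 9), mk("d", 12)),
                           threshold_pct = 8)
  expect_equal(sm$sections$S_R, c(12, 9, 2, 0))
  expect_identical(sm$n_above, 2L)
  expect_identical(sm$n_zero, 1L)
  expect_equal(sm$min_S_R, 0)
  expect_equal(sm$max_S_R, 12)

  single <- summarize_sections(list(mk("x", 5)))
  expect_equal(single$min_S_R, 5)
  expect_equal(single$max_S_R, 5)
  expect_identical(single$n_above, 0L)

  vac <- summarize_sections(lapply(1:4, function(i) mk(i, i, "vacuole")))
  expect_equal(unname(vac$compartment_fractions["vacuole"]), 100)
  expect_error(summarize_sections(list()), "no section")
})

test_that("auto workflow selection counts inclusions under workflow A", {
  few <- generate_net_map(simulation_spec(shape = c(192, 192), n_inclusions = 5,
                                          contrast = "high", seed = 31,
                                          radius_range = c(3, 5)))
  expect_identical(select_workflow("auto", few$map, few$region), "A")

  many <- generate_net_map(simulation_spec(shape = c(256, 256), n_inclusions = 15,
                                           contrast = "high", seed = 32,
                                           radius_range = c(3, 5)))
  expect_identical(select_workflow("auto", many$map, many$region), "B")

  # exactly 10 inclusions stays with workflow A
  ten <- generate_net_map(simulation_spec(shape = c(256, 256), n_inclusions = 10,
                                          contrast = "high", seed = 33,
                                          radius_range = c(3, 5)))
  expect_identical(select_workflow("auto", ten$map, ten$region), "A")

  # explicit modes are honored as-is
  expect_identical(select_workflow("A"), "A")
  expect_identical(select_workflow("B"), "B")
})
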