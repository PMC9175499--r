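# Slide annotation geometry and foci-density quantification.

test_that("shoelace area matches hand-computed polygons", {
  expect_equal(ring_area(unit_square_ring()), 1)
  expect_equal(ring_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  # manual shoelace on the pentagon: sum of cross terms = 42, area 21
  pent <- rbind(c(0, 0), c(4, 0), c(5, 3), c(2, 5), c(-1, 3))
  expect_equal(ring_area(pent), 21)
  expect_error(ring_area(rbind(c(0, 0), c(1, 1))), "at least 3 vertices")
})

test_that("area is invariant to vertex order reversal and translation", {
  set.seed(41)
  for (i in 1:10) {
    ring <- random_simple_polygon(sample(4:12, 1))
    a <- ring_area(ring)
    expect_equal(ring_area(ring[nrow(ring):1, ]), a)
    shift <- matrix(runif(2, -100, 100), nrow(ring), 2, byrow = TRUE)
    expect_equal(ring_area(ring + shift), a, tolerance = 1e-9)
  }
})

test_that("tissue area applies hole subtraction and calibration", {
  expect_equal(tissue_area_mm2(square_slide(1000, mpp = 1)), 1)
  with_hole <- square_slide(1000, mpp = 1,
                            holes = list(unit_square_ring(500, 100, 100)))
  expect_equal(tissue_area_mm2(with_hole), 0.75)
  expect_equal(tissue_area_mm2(square_slide(1000, mpp = 0.5)), 0.25)
  expect_error(tissue_region(unit_square_ring(10),
                             holes = list(unit_square_ring(10))),
               "hole")
})

test_that("overlapping tissue regions are summed with a warning", {
  s <- calibrated_slide("s", 1,
                        list(tissue_region(unit_square_ring(100)),
                             tissue_region(unit_square_ring(100, 50, 50))))
  expect_warning(a <- tissue_area_mm2(s), "overlapping")
  expect_equal(a, 2 * 100^2 / 1e6)
})

test_that("anisotropic calibration and empty ids are rejected", {
  expect_error(calibrated_slide("s", c(0.5, 0.25)), "isotropic")
  expect_error(calibrated_slide("", 0.5), "non-empty")
  expect_error(calibrated_slide("s", -1), "positive")
})

test_that("point containment follows the even-odd rule with inclusive boundary", {
  sq <- tissue_region(unit_square_ring())
  expect_true(point_in_region(c(0.5, 0.5), sq))
  expect_false(point_in_region(c(2, 2), sq))
  expect_true(point_in_region(c(0, 0.5), sq))   # boundary counts as inside
  annulus <- tissue_region(unit_square_ring(10),
                           holes = list(unit_square_ring(4, 3, 3)))
  expect_false(point_in_region(c(5, 5), annulus))  # inside the hole
  expect_true(point_in_region(c(1, 1), annulus))
  expect_true(point_in_region(c(3, 5), annulus))   # hole boundary stays tissue
})

test_that("even-odd containment agrees with a winding-number oracle", {
  set.seed(42)
  checked <- 0
  while (checked < 1000) {
    ring <- random_simple_polygon(sample(5:15, 1))
    region <- tissue_region(ring)
    pts <- cbind(runif(50, -10, 10), runif(50, -10, 10))
    for (i in seq_len(nrow(pts))) {
      expect_identical(point_in_region(pts[i, ], region),
                       winding_inside(pts[i, ], ring))
    }
    checked <- checked + nrow(pts)
  }
})

test_that("quantification reproduces worked densities and classes", {
  set.seed(1)
  # 5 in-tissue foci over 250 mm^2 -> 2.0 per 100 mm^2, p16-low
  side <- sqrt(250 * 1e6)  # mpp 1
  marks <- lapply(1:5, function(i) {
    focus_mark(sprintf("f%d", i), runif(2, 1, side - 1))
  })
  q <- quantify_slide(square_slide(side, 1, marks))
  expect_equal(q$n_foci, 5)
  expect_equal(q$density, 2)
  expect_equal(q$p16_class, "low")
  # single focus on 75.7576 mm^2: the published single-focus density 1.32
  side2 <- sqrt(75.7576 * 1e6)
  q2 <- quantify_slide(square_slide(side2, 1,
                                    list(focus_mark("f", c(100, 100)))))
  expect_equal(round(q2$density, 2), 1.32)
  expect_equal(q2$p16_class, "low")
  # 0 foci, positive area
  q3 <- quantify_slide(square_slide(1000, 1))
  expect_equal(q3$density, 0)
  expect_equal(q3$p16_class, "low")
})

test_that("out-of-tissue marks are excluded and tallied", {
  marks <- list(focus_mark("in", c(10, 10)), focus_mark("out", c(2000, 2000)))
  expect_message(q <- quantify_slide(square_slide(1000, 1, marks)),
                 "outside annotated tissue")
  expect_equal(q$n_foci, 1)
  expect_equal(q$n_foci_excluded, 1)
})

test_that("zero tissue area errors with foci and warns without", {
  empty <- calibrated_slide("e", 1, list(),
                            list(focus_mark("f", c(0, 0))))
  expect_error(suppressMessages(quantify_slide(empty)), "zero")
  empty2 <- calibrated_slide("e", 1)
  expect_warning(q <- quantify_slide(empty2), "zero tissue area")
  expect_equal(q$density, 0)
  expect_equal(q$p16_class, "low")
})

test_that("density classification is boundary-inclusive for p16-low", {
  expect_equal(classify_density(2.1), "low")
  expect_equal(classify_density(3.82), "high")
  expect_equal(classify_density(1.08), "low")
  expect_error(classify_density(-0.1), "non-negative")
})

test_that("doubling the calibration quadruples area and quarters density", {
  set.seed(5)
  marks <- lapply(1:7, function(i) focus_mark(sprintf("f%d", i),
                                              runif(2, 1, 999)))
  q1 <- quantify_slide(square_slide(1000, 1, marks))
  q2 <- quantify_slide(square_slide(1000, 2, marks))
  expect_equal(q2$tissue_area_mm2, 4 * q1$tissue_area_mm2)
  expect_equal(q2$density, q1$density / 4)
})

test_that("known-area synthetic slides quantify to machine precision", {
  set.seed(9)
  for (i in 1:20) {
    area <- runif(1, 10, 400)
    n <- sample(0:12, 1)
    g <- gen_slide(seed = i, tissue_area_mm2 = area, n_foci_inside = n)
    q <- quantify_slide(g$slide)
    expect_equal(q$n_foci, n)
    expect_equal(q$density, 100 * n / area, tolerance = 1e-9)
  }
})

test_that("GeoJSON annotations round-trip through the reader and writer", {
  g <- gen_slide(seed = 3, tissue_area_mm2 = 120, n_foci_inside = 4,
                 n_foci_outside = 2)
  path <- tempfile(fileext = ".geojson")
  write_slide_geojson(g$slide, path)
  back <- read_slide_geojson(path)
  expect_equal(back$slide_id, g$slide$slide_id)
  expect_equal(back$microns_per_pixel, g$slide$microns_per_pixel)
  expect_equal(tissue_area_mm2(back), tissue_area_mm2(g$slide))
  q1 <- suppressMessages(quantify_slide(g$slide))
  q2 <- suppressMessages(quantify_slide(back))
  expect_equal(q2$n_foci, q1$n_foci)
  expect_equal(q2$n_foci_excluded, q1$n_foci_excluded)
  expect_equal(q2$density, q1$density)
  # calibration must come from somewhere
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$microns_per_pixel <- NULL
  path2 <- tempfile(fileext = ".geojson")
  jsonlite::write_json(doc, path2, auto_unbox = TRUE)
  expect_error(read_slide_geojson(path2), "microns_per_pixel")
  expect_s3_class(read_slide_geojson(path2, microns_per_pixel = 0.5),
                  "calibrated_slide")
})
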