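make_record <- function(w = 64, h = 48, ann = NULL, seed = 1) {
  set.seed(seed)
  px <- array(runif(h * w * 3), c(h, w, 3))
  if (is.null(ann)) {
    ann <- tibble::tibble(
      label = c("Cfb", "Rfb"), xmin = c(0, 20), ymin = c(0, 10),
      xmax = c(48, 40), ymax = c(48, 30), difficult = c(FALSE, TRUE)
    )
  }
  image_record("rec1", px, ann)
}

test_that("VOC coordinates convert between 1-based inclusive and half-open", {
  dir <- withr::local_tempdir()
  rec <- make_record(h = 64)
  write_image(rec$pixels, file.path(dir, "rec1.png"))
  write_voc_xml(rec, file.path(dir, "rec1.xml"))
  xml <- xml2::read_xml(file.path(dir, "rec1.xml"))
  bb <- xml2::xml_find_first(xml, "//object/bndbox")
  # internal (0, 0, 48, 48) -> VOC (1, 1, 48, 48)
  expect_equal(xml2::xml_text(xml2::xml_find_first(bb, "xmin")), "1")
  expect_equal(xml2::xml_text(xml2::xml_find_first(bb, "ymin")), "1")
  expect_equal(xml2::xml_text(xml2::xml_find_first(bb, "xmax")), "48")
  diff <- xml2::xml_text(xml2::xml_find_all(xml, "//object/difficult"))
  expect_equal(diff, c("0", "1"))
  back <- read_voc_xml(file.path(dir, "rec1.xml"))
  expect_equal(back$annotations$xmin[1], 0)
  expect_equal(back$annotations$xmax[1], 48)
  expect_equal(back$annotations$label, c("Cfb", "Rfb"))
})

test_that("VOC round-trip is lossless and supports empty annotation lists", {
  dir <- withr::local_tempdir()
  rec <- make_record()
  write_image(rec$pixels, file.path(dir, "rec1.png"))
  write_voc_xml(rec, file.path(dir, "rec1.xml"))
  back <- read_voc_xml(file.path(dir, "rec1.xml"))
  expect_equal(back$annotations, rec$annotations)
  expect_equal(back$width, rec$width)
  # empty case
  empty <- image_record("rec1", rec$pixels)
  write_voc_xml(empty, file.path(dir, "rec1.xml"))
  back2 <- read_voc_xml(file.path(dir, "rec1.xml"))
  expect_equal(nrow(back2$annotations), 0L)
  expect_equal(
    length(xml2::xml_find_all(xml2::read_xml(file.path(dir, "rec1.xml")),
                              "//object")), 0L)
})

test_that("malformed or inconsistent VOC input raises informative errors", {
  dir <- withr::local_tempdir()
  rec <- make_record()
  write_image(rec$pixels, file.path(dir, "rec1.png"))
  # missing bndbox element
  writeLines(c(
    "<annotation><filename>rec1.png</filename>",
    "<size><width>64</width><height>48</height><depth>3</depth></size>",
    "<object><name>Cfb</name><bndbox><xmin>1</xmin><ymin>1</ymin>",
    "<xmax>10</xmax></bndbox></object></annotation>"
  ), file.path(dir, "bad.xml"))
  expect_error(read_voc_xml(file.path(dir, "bad.xml"),
                            file.path(dir, "rec1.png")), "ymax")
  # size mismatch
  writeLines(c(
    "<annotation><filename>rec1.png</filename>",
    "<size><width>99</width><height>48</height><depth>3</depth></size>",
    "</annotation>"
  ), file.path(dir, "mismatch.xml"))
  expect_error(read_voc_xml(file.path(dir, "mismatch.xml"),
                            file.path(dir, "rec1.png")), "size")
  # refusing to write out-of-bounds boxes
  rec2 <- make_record()
  rec2$annotations$xmax[1] <- 999
  expect_error(write_voc_xml(rec2, file.path(dir, "oob.xml")), "outside")
})

test_that("tiling covers the image, shifts the last row/column inward, and
           applies the box-retention rule", {
  set.seed(5)
  px <- array(runif(720 * 1280 * 3), c(720, 1280, 3))
  ann <- tibble::tibble(
    label = c("a", "b"), difficult = FALSE,
    # box fully in tile 1; box straddling the x = 640 boundary with 30%
    # of its area in the right tile
    xmin = c(100, 610), ymin = c(100, 10), xmax = c(130, 710), ymax = c(120, 40)
  )
  rec <- image_record("big", px, ann)
  tiles <- crop_to_tiles(rec, 640, 480)
  expect_length(tiles, 4L)
  # forced origins (0,0), (640,0), (0,240), (640,240)
  expect_identical(tiles[[1]]$pixels, px[1:480, 1:640, , drop = FALSE])
  expect_identical(tiles[[2]]$pixels, px[1:480, 641:1280, , drop = FALSE])
  expect_identical(tiles[[3]]$pixels, px[241:720, 1:640, , drop = FALSE])
  expect_identical(tiles[[4]]$pixels, px[241:720, 641:1280, , drop = FALSE])
  # box b: 30/100 wide in tile 1 -> 30% < 50% retention -> dropped there;
  # 70% in tile 2 -> kept, clipped at the boundary
  expect_equal(tiles[[1]]$annotations$label, "a")
  expect_equal(tiles[[2]]$annotations$label, "b")
  expect_equal(tiles[[2]]$annotations$xmin, 0)
  expect_equal(tiles[[2]]$annotations$xmax, 70)
  # identity tiling
  one <- crop_to_tiles(tiles[[1]], 640, 480)
  expect_length(one, 1L)
  expect_identical(one[[1]]$pixels, tiles[[1]]$pixels)
  expect_error(crop_to_tiles(tiles[[1]], 1280, 480), "exceed")
})

test_that("every pixel is covered by at least one tile", {
  set.seed(6)
  px <- array(0, c(500, 700, 3))
  rec <- image_record("odd", px)
  tiles <- crop_to_tiles(rec, 640, 480)
  cover <- matrix(0L, 500, 700)
  xs <- c(0L, 60L); ys <- c(0L, 20L)
  i <- 0L
  for (y0 in ys) for (x0 in xs) {
    i <- i + 1L
    cover[(y0 + 1):(y0 + 480), (x0 + 1):(x0 + 640)] <-
      cover[(y0 + 1):(y0 + 480), (x0 + 1):(x0 + 640)] + 1L
  }
  expect_length(tiles, 4L)
  expect_true(all(cover >= 1L))
})

test_that("flips follow the half-open coordinate map and are involutions", {
  rec <- make_record(w = 100, h = 80, ann = tibble::tibble(
    label = "x", xmin = 10, ymin = 20, xmax = 30, ymax = 40, difficult = FALSE
  ))
  h <- augment_record(rec, "hflip")
  expect_equal(as.numeric(h$annotations[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(70, 20, 90, 40))
  hh <- augment_record(h, "hflip")
  expect_identical(hh$pixels, rec$pixels)
  expect_equal(hh$annotations, rec$annotations)
  vv <- augment_record(augment_record(rec, "vflip"), "vflip")
  expect_identical(vv$pixels, rec$pixels)
  expect_error(augment_record(rec, "rot180"), "unknown augmentation")
})

test_that("augmented boxes equal tight bounds of the transformed pixel mask", {
  set.seed(7)
  for (rep in 1:6) {
    w <- sample(40:100, 1); h <- sample(40:100, 1)
    box <- c(xmin = sample(0:(w - 20), 1), ymin = sample(0:(h - 20), 1))
    box <- c(box, xmax = box[[1]] + sample(5:15, 1),
             ymax = box[[2]] + sample(5:15, 1))
    rec <- image_record("r", array(0.5, c(h, w, 3)), tibble::tibble(
      label = "x", xmin = box[[1]], ymin = box[[2]], xmax = box[[3]],
      ymax = box[[4]], difficult = FALSE
    ))
    for (op in c("rot+90", "rot-90", "hflip", "vflip")) {
      got <- as.numeric(
        augment_record(rec, op)$annotations[1, c("xmin", "ymin", "xmax", "ymax")])
      want <- oracle_augmented_box(box, w, h, op)
      expect_equal(iou(got, want), 1.0, info = op)
    }
  }
})
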