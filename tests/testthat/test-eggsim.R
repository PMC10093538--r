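test_that("tray generation yields one labelled box per egg", {
  tr <- generate_tray(7, 9, seed = 4, image_size = c(218L, 216L))
  expect_equal(nrow(tr$boxes), 63)
  tr2 <- generate_tray(3, 5, seed = 4, image_size = c(218L, 216L))
  expect_equal(nrow(tr2$boxes), 15)
  expect_true(all(tr$boxes$class_id %in% 0:1))
  expect_true(all(tr$boxes$x1 < tr$boxes$x2 & tr$boxes$y1 < tr$boxes$y2))
  expect_true(all(tr$boxes$x1 >= 0 & tr$boxes$x2 <= 218 &
                  tr$boxes$y1 >= 0 & tr$boxes$y2 <= 216))
  expect_error(generate_tray(50, 50, seed = 1, image_size = c(100L, 100L)),
               "too dense")
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_tray(3, 5, seed = 99, image_size = c(128L, 128L))
  b <- generate_tray(3, 5, seed = 99, image_size = c(128L, 128L))
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  c <- generate_tray(3, 5, seed = 100, image_size = c(128L, 128L))
  expect_false(identical(a$image, c$image))
})

test_that("fertile and infertile eggs are visually distinct", {
  # fertile eggs carry a dark embryo spot + vessels: the darkest pixel
  # of a fertile interior is far darker than an infertile egg's
  # uniform glow
  tr <- generate_tray(3, 5, seed = 7, image_size = c(320L, 240L),
                      noise_sd = 0)
  interior_min <- function(b) {
    cy <- (b$y1 + b$y2) / 2; cx <- (b$x1 + b$x2) / 2
    hy <- (b$y2 - b$y1) / 4; hx <- (b$x2 - b$x1) / 4
    min(tr$image[round(cy - hy):round(cy + hy),
                 round(cx - hx):round(cx + hx), 1])
  }
  mins <- vapply(seq_len(nrow(tr$boxes)),
                 function(i) interior_min(tr$boxes[i, ]), numeric(1))
  fert <- mins[tr$boxes$class_id == 0]
  infert <- mins[tr$boxes$class_id == 1]
  if (length(fert) && length(infert)) {
    expect_lt(mean(fert), mean(infert))
  }
  # eggs are bright against the dark background
  bg <- mean(tr$image[1:5, 1:5, 1])
  b1 <- tr$boxes[1, ]
  egg <- mean(tr$image[round((b1$y1 + b1$y2) / 2) + (-1:1),
                       round((b1$x1 + b1$x2) / 2) + (-1:1), 1])
  expect_gt(egg, bg + 0.2)
})

test_that("right-angle rotations remap boxes exactly and invert", {
  tr <- generate_tray(3, 5, seed = 12, image_size = c(160L, 128L))
  s <- list(image = tr$image, boxes = tr$boxes)
  # 180 twice is the identity
  r1 <- augment(s$image, s$boxes, "rotate", list(angle = 180))
  r2 <- augment(r1$image, r1$boxes, "rotate", list(angle = 180))
  expect_equal(r2$image, s$image)
  expect_equal(r2$boxes[c("x1", "y1", "x2", "y2")],
               s$boxes[c("x1", "y1", "x2", "y2")])
  # 90 four times is the identity
  r <- s
  for (i in 1:4) r <- augment(r$image, r$boxes, "rotate", list(angle = 90))
  expect_equal(r$image, s$image)
  expect_equal(r$boxes$x1, s$boxes$x1)
  # 90 then 270 is the identity
  r <- augment(s$image, s$boxes, "rotate", list(angle = 90))
  r <- augment(r$image, r$boxes, "rotate", list(angle = 270))
  expect_equal(r$image, s$image)
  expect_equal(r$boxes$y2, s$boxes$y2)
  expect_error(augment(s$image, s$boxes, "rotate", list(angle = 45)),
               "unsupported")
})

test_that("rotation and mirror keep each box on its egg", {
  # the brightest pixel inside each remapped box must still be egg
  # material (well above background)
  tr <- generate_tray(3, 3, seed = 21, image_size = c(96L, 96L),
                      noise_sd = 0)
  for (op in list(list("rotate", list(angle = 90)),
                  list("rotate", list(angle = 270)),
                  list("mirror", list()))) {
    a <- augment(tr$image, tr$boxes, op[[1]], op[[2]])
    for (i in seq_len(nrow(a$boxes))) {
      b <- a$boxes[i, ]
      win <- a$image[(floor(b$y1) + 1):ceiling(b$y2),
                     (floor(b$x1) + 1):ceiling(b$x2), 1]
      expect_gt(max(win), 0.5)
    }
  }
})

test_that("mirror remaps x as W - x and contrast leaves boxes alone", {
  tr <- generate_tray(3, 5, seed = 13, image_size = c(160L, 128L))
  m <- augment(tr$image, tr$boxes, "mirror")
  expect_equal(m$boxes$x1, 160 - tr$boxes$x2)
  expect_equal(m$boxes$x2, 160 - tr$boxes$x1)
  expect_equal(m$boxes$y1, tr$boxes$y1)
  m2 <- augment(m$image, m$boxes, "mirror")
  expect_equal(m2$image, tr$image)

  ct <- augment(tr$image, tr$boxes, "contrast", list(gamma = 1.4))
  expect_identical(ct$boxes, tr$boxes)
  expect_false(identical(ct$image, tr$image))
})

test_that("dataset expansion is exactly fourfold and seeded", {
  samples <- lapply(1:3, function(i) small_sample(i, 2, 2, 64L))
  out <- expand_dataset(samples, seed = 8)
  expect_length(out, 12)
  out2 <- expand_dataset(samples, seed = 8)
  expect_identical(out, out2)
  # the original is retained as the first of each quadruple
  expect_identical(out[[1]]$image, samples[[1]]$image)
  expect_identical(out[[5]]$image, samples[[2]]$image)
})

test_that("VOC XML round-trips exactly and enforces the label set", {
  boxes <- data.frame(class_id = c(0L, 1L), x1 = c(10, 40.2), y1 = c(20, 50),
                      x2 = c(50, 80.7), y2 = c(80, 90))
  rec <- boxes_to_voc(boxes, "tray_0001.png", c(120L, 100L))
  # half-open 0-based -> inclusive 1-based
  expect_equal(rec$objects$xmin[[1]], 11L)
  expect_equal(rec$objects$ymin[[1]], 21L)
  expect_equal(rec$objects$xmax[[1]], 50L)
  expect_equal(rec$objects$ymax[[1]], 80L)

  path <- tempfile(fileext = ".xml")
  write_voc(rec, path)
  back <- read_voc(path)
  expect_equal(back$objects, rec$objects)
  expect_equal(back$size, rec$size)
  expect_equal(back$filename, rec$filename)

  # the conversion pair is the identity on integral boxes
  expect_equal(voc_to_boxes(back)$x1, c(10, 40))
  expect_equal(voc_to_boxes(back)$class_id, c(0L, 1L))

  # unknown class names are rejected on read
  txt <- readLines(path)
  writeLines(gsub("fertile", "duck", txt, fixed = TRUE), path)
  expect_error(read_voc(path), "unknown class")

  # degenerate boxes are rejected on write
  bad <- rec
  bad$objects$xmax[[1]] <- bad$objects$xmin[[1]]
  expect_error(write_voc(bad, tempfile(fileext = ".xml")), "degenerate")
})

test_that("the default class balance mirrors the reference stock", {
  # pooled over many eggs the infertile fraction approaches 840/2111
  trays <- lapply(1:12, function(i)
    generate_tray(5, 7, seed = 300 + i, image_size = c(160L, 128L)))
  cls <- unlist(lapply(trays, function(t) t$boxes$class_id))
  frac <- mean(cls == 1L)
  expect_gt(frac, 0.30)
  expect_lt(frac, 0.50)
})
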