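# Seeded synthetic candled-tray image generator, the x4 augmentation
# pipeline (rotation / mirror / contrast) and PASCAL VOC XML annotation
# I/O. Candling after ~5 days of incubation shows each egg as a bright
# warm ovoid on a dark tray; a fertile egg carries a dark embryo spot
# with branching blood vessels, an infertile egg a uniform translucent
# glow. Internally boxes are 0-based half-open pixel intervals; VOC
# files use 1-based inclusive integers, converted exactly at the I/O
# boundary.

.EGG_CLASSES <- c("fertile", "infertile")

with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate one synthetic candled tray
#'
#' Eggs are laid out on a `rows x cols` grid with positional jitter,
#' rendered as oriented bright ovoids over a dark noisy background.
#' A fraction `infertile_frac` of eggs (default mirroring a stock of
#' 840 infertile among 2111) are infertile and glow uniformly; fertile
#' eggs get a dark elliptical embryo spot and a branching random-walk
#' vessel tree. One tight axis-aligned box per egg is returned. The
#' output is bit-identical for identical arguments and seed.
#'
#' @param rows,cols grid layout (supported trays: 3x5, 5x7, 7x9 and
#'   anything of similar density).
#' @param seed integer seed.
#' @param image_size `c(width, height)` in pixels.
#' @param infertile_frac probability an egg is infertile.
#' @param noise_sd additive Gaussian pixel noise.
#' @return list with `image` (`H x W x 3` array in `[0,1]`), `boxes`
#'   (data.frame `class_id, x1, y1, x2, y2`, class 0 = fertile,
#'   1 = infertile, 0-based half-open pixels), `rows`, `cols`, `seed`.
#' @export
generate_tray <- function(rows, cols, seed = 1L,
                          image_size = c(1092L, 1080L),
                          infertile_frac = 840 / 2111,
                          noise_sd = 0.015) {
  W <- as.integer(image_size[[1]]); H <- as.integer(image_size[[2]])
  cw <- W / cols; ch <- H / rows
  if (cw < 10 || ch < 10) {
    stop("grid too dense for the image size", call. = FALSE)
  }
  with_seed_(seed, {
    img <- array(0, c(H, W, 3))
    base <- 0.04 + 0.02 * matrix(runif(H * W), H, W)
    img[, , 1] <- base; img[, , 2] <- base * 0.9; img[, , 3] <- base * 0.85
    boxes <- vector("list", rows * cols)
    k <- 0L
    for (r in seq_len(rows)) {
      for (cc in seq_len(cols)) {
        k <- k + 1L
        cx <- (cc - 0.5) * cw + runif(1, -0.05, 0.05) * cw
        cy <- (r - 0.5) * ch + runif(1, -0.05, 0.05) * ch
        a <- 0.36 * cw * runif(1, 0.9, 1.0)    # semi-axis across
        b <- 0.40 * ch * runif(1, 0.9, 1.0)    # semi-axis down
        th <- runif(1, -0.15, 0.15)
        infertile <- runif(1) < infertile_frac
        glow <- runif(1, 0.75, 0.95)
        img <- render_egg(img, cx, cy, a, b, th, glow, infertile)
        hw <- sqrt(a^2 * cos(th)^2 + b^2 * sin(th)^2)
        hh <- sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
        boxes[[k]] <- data.frame(
          class_id = if (infertile) 1L else 0L,
          x1 = max(cx - hw, 0), y1 = max(cy - hh, 0),
          x2 = min(cx + hw, W), y2 = min(cy + hh, H))
      }
    }
    if (noise_sd > 0) {
      img <- img + array(rnorm(length(img), sd = noise_sd), dim(img))
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, boxes = do.call(rbind, boxes),
         rows = rows, cols = cols, seed = seed)
  })
}

# paint one egg into the image; works on the egg's bounding subwindow
render_egg <- function(img, cx, cy, a, b, th, glow, infertile) {
  H <- dim(img)[[1]]; W <- dim(img)[[2]]
  ext <- max(a, b) * 1.1
  i1 <- max(1L, floor(cy - ext)); i2 <- min(H, ceiling(cy + ext))
  j1 <- max(1L, floor(cx - ext)); j2 <- min(W, ceiling(cx + ext))
  ii <- i1:i2; jj <- j1:j2
  # pixel centers at (col - 0.5, row - 0.5) in 0-based coordinates
  py <- matrix(ii - 0.5, length(ii), length(jj))
  px <- matrix(jj - 0.5, length(ii), length(jj), byrow = TRUE)
  u <- ((px - cx) * cos(th) + (py - cy) * sin(th)) / a
  v <- (-(px - cx) * sin(th) + (py - cy) * cos(th)) / b
  r2 <- u^2 + v^2
  inside <- r2 < 1
  shell <- pmax(1 - r2, 0)^0.6
  mult <- matrix(1, nrow(shell), ncol(shell))
  if (!infertile) {
    # embryo spot: dark blob offset from the egg center
    ou <- runif(1, -0.25, 0.25); ov <- runif(1, -0.3, 0.1)
    sr <- runif(1, 0.26, 0.34)
    d2 <- ((u - ou)^2 + (v - ov)^2) / sr^2
    mult <- mult * (1 - 0.8 * exp(-d2))
    # vessel tree: branching random walks from the spot, darkened thin
    n_branch <- sample(3:5, 1)
    for (bn in seq_len(n_branch)) {
      ang <- runif(1, 0, 2 * pi)
      nstep <- 60L
      dang <- cumsum(rnorm(nstep, sd = 0.22))
      pu <- ou + cumsum(cos(ang + dang)) * 0.022
      pv <- ov + cumsum(sin(ang + dang)) * 0.022
      keep <- (pu^2 + pv^2) < 0.85
      pu <- pu[keep]; pv <- pv[keep]
      if (!length(pu)) next
      # back to pixel indices in the subwindow
      vx <- cx + (pu * a * cos(th) - pv * b * sin(th))
      vy <- cy + (pu * a * sin(th) + pv * b * cos(th))
      ri <- round(vy + 0.5) - i1 + 1L
      rj <- round(vx + 0.5) - j1 + 1L
      for (off in list(c(0L, 0L), c(1L, 0L), c(0L, 1L))) {
        oi <- ri + off[[1]]; oj <- rj + off[[2]]
        ok <- oi >= 1 & oi <= nrow(mult) & oj >= 1 & oj <= ncol(mult)
        mult[cbind(oi[ok], oj[ok])] <- 0.5
      }
    }
  } else {
    glow <- glow * 1.05   # infertile eggs transmit slightly more light
  }
  val <- glow * shell * mult
  sub_r <- img[ii, jj, 1]; sub_g <- img[ii, jj, 2]; sub_b <- img[ii, jj, 3]
  sub_r[inside] <- val[inside]
  sub_g[inside] <- val[inside] * 0.55
  sub_b[inside] <- val[inside] * 0.18
  img[ii, jj, 1] <- sub_r; img[ii, jj, 2] <- sub_g; img[ii, jj, 3] <- sub_b
  img
}

#' Augment an annotated image
#'
#' Right-angle rotation, horizontal mirror or contrast change, with
#' exact box remapping (contrast leaves boxes untouched). All
#' geometric remaps are invertible.
#'
#' @param image `H x W x C` array.
#' @param boxes data.frame `class_id, x1, y1, x2, y2` (0-based
#'   half-open).
#' @param op `"rotate"`, `"mirror"` or `"contrast"`.
#' @param params list: `angle` (90, 180 or 270, counter-clockwise) for
#'   rotate; `gamma` for contrast.
#' @return list `image`, `boxes`.
#' @export
augment <- function(image, boxes, op = c("rotate", "mirror", "contrast"),
                    params = list()) {
  op <- match.arg(op)
  H <- dim(image)[[1]]; W <- dim(image)[[2]]
  if (op == "rotate") {
    angle <- params$angle %||% 90
    if (!angle %in% c(90, 180, 270)) {
      stop("unsupported rotation angle: ", angle, call. = FALSE)
    }
    if (angle == 90) {            # counter-clockwise
      image <- aperm(image, c(2, 1, 3))[W:1, , , drop = FALSE]
      boxes <- transform(boxes, x1 = y1, x2 = y2,
                         y1 = W - x2, y2 = W - x1)
    } else if (angle == 180) {
      image <- image[H:1, W:1, , drop = FALSE]
      boxes <- transform(boxes, x1 = W - x2, x2 = W - x1,
                         y1 = H - y2, y2 = H - y1)
    } else {
      image <- aperm(image, c(2, 1, 3))[, H:1, , drop = FALSE]
      boxes <- transform(boxes, x1 = H - y2, x2 = H - y1,
                         y1 = x1, y2 = x2)
    }
  } else if (op == "mirror") {
    image <- image[, W:1, , drop = FALSE]
    boxes <- transform(boxes, x1 = W - x2, x2 = W - x1)
  } else {
    gamma <- params$gamma %||% 1.3
    image <- pmin(pmax(image, 0), 1)^gamma
  }
  list(image = image, boxes = boxes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand a dataset fourfold by augmentation
#'
#' Each input sample yields itself plus exactly three augmented
#' variants: one right-angle rotation, one horizontal mirror and one
#' contrast change, with per-image seeded parameters.
#'
#' @param samples list of `list(image, boxes)` samples.
#' @param seed integer seed for the per-image augmentation draws.
#' @return list of length `4 * length(samples)`.
#' @export
expand_dataset <- function(samples, seed = 1L) {
  with_seed_(seed, {
    out <- vector("list", 4L * length(samples))
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      angle <- sample(c(90, 180, 270), 1)
      gamma <- runif(1, 0.7, 1.4)
      out[[4L * i - 3L]] <- s[c("image", "boxes")]
      out[[4L * i - 2L]] <- augment(s$image, s$boxes, "rotate",
                                    list(angle = angle))
      out[[4L * i - 1L]] <- augment(s$image, s$boxes, "mirror")
      out[[4L * i]] <- augment(s$image, s$boxes, "contrast",
                               list(gamma = gamma))
    }
    out
  })
}

#' Convert internal boxes to a VOC record
#'
#' Internal boxes are 0-based half-open; VOC uses 1-based inclusive
#' integers, so `(x1, y1, x2, y2) -> (x1 + 1, y1 + 1, x2, y2)` after
#' rounding.
#'
#' @param boxes data.frame `class_id, x1, y1, x2, y2`.
#' @param filename image file name recorded in the annotation.
#' @param size `c(width, height)` in pixels.
#' @return a `voc_record` list.
#' @export
boxes_to_voc <- function(boxes, filename, size) {
  objects <- data.frame(
    name = .EGG_CLASSES[boxes$class_id + 1L],
    xmin = as.integer(round(boxes$x1)) + 1L,
    ymin = as.integer(round(boxes$y1)) + 1L,
    xmax = as.integer(round(boxes$x2)),
    ymax = as.integer(round(boxes$y2)))
  structure(list(filename = filename,
                 size = c(width = as.integer(size[[1]]),
                          height = as.integer(size[[2]]), depth = 3L),
                 objects = objects),
            class = "voc_record")
}

#' Convert a VOC record back to internal boxes
#' @param record a `voc_record`.
#' @return data.frame `class_id, x1, y1, x2, y2` (0-based half-open).
#' @export
voc_to_boxes <- function(record) {
  o <- record$objects
  data.frame(class_id = match(o$name, .EGG_CLASSES) - 1L,
             x1 = o$xmin - 1, y1 = o$ymin - 1,
             x2 = as.numeric(o$xmax), y2 = as.numeric(o$ymax))
}

#' Write a PASCAL VOC XML annotation
#' @param record a `voc_record` from [boxes_to_voc()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_voc <- function(record, path) {
  o <- record$objects
  if (any(o$xmin >= o$xmax) || any(o$ymin >= o$ymax)) {
    stop("degenerate bounding box in record", call. = FALSE)
  }
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", record$filename)
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(record$size[["width"]]))
  xml2::xml_add_child(sz, "height", as.character(record$size[["height"]]))
  xml2::xml_add_child(sz, "depth", as.character(record$size[["depth"]]))
  for (i in seq_len(nrow(o))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", o$name[[i]])
    xml2::xml_add_child(ob, "difficult", "0")
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(o$xmin[[i]]))
    xml2::xml_add_child(bb, "ymin", as.character(o$ymin[[i]]))
    xml2::xml_add_child(bb, "xmax", as.character(o$xmax[[i]]))
    xml2::xml_add_child(bb, "ymax", as.character(o$ymax[[i]]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a PASCAL VOC XML annotation
#' @param path XML file path.
#' @return a `voc_record`.
#' @export
read_voc <- function(path) {
  doc <- xml2::read_xml(path)
  sz <- xml2::xml_find_first(doc, "size")
  num <- function(node, what) {
    v <- xml2::xml_text(xml2::xml_find_first(node, what))
    x <- suppressWarnings(as.integer(v))
    if (is.na(x)) stop("malformed VOC element <", what, ">", call. = FALSE)
    x
  }
  objs <- xml2::xml_find_all(doc, "object")
  rows <- lapply(objs, function(ob) {
    nm <- xml2::xml_text(xml2::xml_find_first(ob, "name"))
    if (!nm %in% .EGG_CLASSES) {
      stop("unknown class name in <object>: '", nm, "'", call. = FALSE)
    }
    bb <- xml2::xml_find_first(ob, "bndbox")
    r <- data.frame(name = nm, xmin = num(bb, "xmin"), ymin = num(bb, "ymin"),
                    xmax = num(bb, "xmax"), ymax = num(bb, "ymax"))
    if (r$xmin >= r$xmax || r$ymin >= r$ymax) {
      stop("degenerate <bndbox> in ", path, call. = FALSE)
    }
    r
  })
  structure(list(
    filename = xml2::xml_text(xml2::xml_find_first(doc, "filename")),
    size = c(width = num(sz, "width"), height = num(sz, "height"),
             depth = num(sz, "depth")),
    objects = do.call(rbind, rows)),
    class = "voc_record")
}

#' Nearest-neighbour resize of an annotated sample
#'
#' @param sample `list(image, boxes)`.
#' @param size target square side (or `c(width, height)`).
#' @return resized sample with rescaled boxes.
#' @export
resize_sample <- function(sample, size) {
  if (length(size) == 1) size <- c(size, size)
  W2 <- size[[1]]; H2 <- size[[2]]
  d <- dim(sample$image)
  H <- d[[1]]; W <- d[[2]]
  ri <- pmin(H, floor((seq_len(H2) - 0.5) * H / H2) + 1L)
  rj <- pmin(W, floor((seq_len(W2) - 0.5) * W / W2) + 1L)
  img <- sample$image[ri, rj, , drop = FALSE]
  boxes <- transform(sample$boxes,
                     x1 = x1 * W2 / W, x2 = x2 * W2 / W,
                     y1 = y1 * H2 / H, y2 = y2 * H2 / H)
  list(image = img, boxes = boxes)
}

#' Write a synthetic dataset in VOC directory layout
#'
#' Produces `JPEGImages/` (PNG rasters), `Annotations/` (VOC XML) and
#' `ImageSets/Main/trainval.txt`.
#'
#' @param out_dir output directory.
#' @param n_trays number of trays.
#' @param rows,cols tray grid.
#' @param seed base seed; tray `i` uses `seed + i - 1`.
#' @param image_size `c(width, height)`.
#' @param infertile_frac infertile probability per egg.
#' @return character vector of image ids, invisibly.
#' @export
generate_voc_dataset <- function(out_dir, n_trays = 1L, rows = 7L, cols = 9L,
                                 seed = 1L, image_size = c(1092L, 1080L),
                                 infertile_frac = 840 / 2111) {
  for (d in c("JPEGImages", "Annotations", file.path("ImageSets", "Main"))) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  ids <- sprintf("tray_%04d", seq_len(n_trays))
  for (i in seq_len(n_trays)) {
    tr <- generate_tray(rows, cols, seed = seed + i - 1L,
                        image_size = image_size,
                        infertile_frac = infertile_frac)
    png::writePNG(tr$image,
                  file.path(out_dir, "JPEGImages", paste0(ids[[i]], ".png")))
    rec <- boxes_to_voc(tr$boxes, paste0(ids[[i]], ".png"), image_size)
    write_voc(rec, file.path(out_dir, "Annotations", paste0(ids[[i]], ".xml")))
  }
  writeLines(ids, file.path(out_dir, "ImageSets", "Main", "trainval.txt"))
  invisible(ids)
}
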