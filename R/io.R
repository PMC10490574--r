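# Image and manifest I/O. The DICOM reader is a deliberately minimal
# single-frame parser (little-endian explicit or implicit VR, uncompressed
# monochrome pixel data) covering the tags the pipeline needs; anything
# else raises a format error naming the file.

dcm_u16 <- function(raw2) sum(as.integer(raw2) * c(1L, 256L))
dcm_u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

#' Read a single-frame DICOM image
#'
#' Parses an uncompressed, little-endian, monochrome single-frame DICOM
#' file. Pixel values are rescaled by RescaleSlope/RescaleIntercept when
#' those tags are present; TR (0018,0080), TE (0018,0081) and flip angle
#' (0018,1314) are copied into the image's `protocol`.
#'
#' @param path Path to the DICOM file.
#' @param side,subject_id,t_score,label Metadata passed to [pfb_image()];
#'   `subject_id` defaults to the file name.
#' @return A [pfb_image].
#' @export
read_dicom <- function(path, side = "left", subject_id = NULL,
                       t_score = NULL, label = NULL) {
  if (!file.exists(path)) {
    stop_pfb(sprintf("cannot read DICOM file '%s': no such file", path),
             "pfbmri_format_error")
  }
  bytes <- readBin(path, "raw", file.size(path))
  fail <- function(why) {
    stop_pfb(sprintf("cannot read DICOM file '%s': %s", path, why),
             "pfbmri_format_error")
  }
  pos <- 1L
  if (length(bytes) >= 132 &&
      rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
  }
  if (length(bytes) < pos + 8) fail("file truncated")

  explicit <- NULL # decided from the first element
  elems <- list()
  n <- length(bytes)
  while (pos + 7 <= n) {
    group <- dcm_u16(bytes[pos:(pos + 1)])
    elem <- dcm_u16(bytes[(pos + 2):(pos + 3)])
    pos <- pos + 4L
    if (is.null(explicit)) {
      vr_try <- rawToChar(bytes[pos:(pos + 1)])
      explicit <- grepl("^[A-Z]{2}$", vr_try)
    }
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        if (pos + 7 > n) fail("file truncated")
        len <- dcm_u32(bytes[(pos + 4):(pos + 7)])
        pos <- pos + 8L
      } else {
        len <- dcm_u16(bytes[(pos + 2):(pos + 3)])
        pos <- pos + 4L
        vr_len_ok <- TRUE
      }
      if (vr == "SQ" || len == 4294967295) fail("sequences are not supported")
    } else {
      vr <- NA_character_
      if (pos + 3 > n) fail("file truncated")
      len <- dcm_u32(bytes[pos:(pos + 3)])
      pos <- pos + 4L
      if (len == 4294967295) fail("sequences are not supported")
    }
    if (pos + len - 1 > n) fail("file truncated")
    key <- sprintf("%04x%04x", group, elem)
    elems[[key]] <- bytes[seq.int(pos, length.out = len)]
    pos <- pos + as.integer(len)
    if (key == "7fe00010") break
  }

  get_num <- function(key) {
    v <- elems[[key]]
    if (is.null(v)) return(NULL)
    suppressWarnings(as.numeric(trimws(rawToChar(v))))
  }
  get_u16val <- function(key) {
    v <- elems[[key]]
    if (is.null(v) || length(v) < 2) return(NULL)
    dcm_u16(v[1:2])
  }

  rows <- get_u16val("00280010")
  cols <- get_u16val("00280011")
  bits <- get_u16val("00280100") %||% 16
  signed <- (get_u16val("00280103") %||% 0) == 1
  pix <- elems[["7fe00010"]]
  if (is.null(pix) || is.null(rows) || is.null(cols)) {
    fail("missing pixel data or image dimensions")
  }
  n_px <- rows * cols
  vals <- if (bits == 8) {
    as.numeric(pix[seq_len(n_px)])
  } else {
    if (length(pix) < 2 * n_px) fail("pixel data shorter than Rows x Columns")
    v <- readBin(pix, "integer", n = n_px, size = 2, signed = signed,
                 endian = "little")
    as.numeric(v)
  }
  if (length(vals) < n_px) fail("pixel data shorter than Rows x Columns")

  slope <- get_num("00281053") %||% 1
  intercept <- get_num("00281052") %||% 0
  vals <- vals * slope + intercept
  # DICOM pixel data is row-major (first row first)
  m <- matrix(pmax(vals, 0), nrow = rows, ncol = cols, byrow = TRUE)

  tr <- get_num("00180080")
  te <- get_num("00180081")
  fa <- get_num("00181314")
  protocol <- if (!is.null(tr) || !is.null(te) || !is.null(fa)) {
    list(TR = tr, TE = te, flip_angle = fa)
  } else {
    NULL
  }
  pfb_image(m, side = side, protocol = protocol,
            subject_id = subject_id %||% basename(path),
            t_score = t_score, label = label)
}

#' Read a grayscale image from PNG
#'
#' 8- or 16-bit grayscale PNGs; values are returned on the 0-255 (or
#' 0-65535) integer scale.
#'
#' @param path PNG file path.
#' @param ... Metadata passed to [pfb_image()].
#' @return A [pfb_image].
#' @export
read_image_png <- function(path, ...) {
  a <- png::readPNG(path, info = TRUE)
  info <- attr(a, "info")
  if (length(dim(a)) == 3) a <- a[, , 1]
  depth <- if (!is.null(info) && identical(info$bit.depth, 16L)) 65535 else 255
  pfb_image(round(a * depth), subject_id = basename(path), ...)
}

#' Read / write a binary mask as PNG
#'
#' Masks use the 0 (background) / 255 (bone) PNG convention.
#'
#' @param path PNG file path.
#' @param method Provenance recorded on the returned mask.
#' @return [read_mask_png()] returns a [pfb_mask].
#' @export
read_mask_png <- function(path, method = "manual_file") {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  pfb_mask(a > 0.5, method = method)
}

#' @rdname read_mask_png
#' @param mask A [pfb_mask] or logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_matrix(mask)
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `subject_id`, `image_path`, optional
#' `mask_path`, `side`, and optional `t_score`, `label`, `TR`, `TE`,
#' `flip_angle`. Image paths ending in `.png` are read with
#' [read_image_png()], everything else with [read_dicom()]. Relative paths
#' resolve against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A [pfb_dataset].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_pfb(sprintf("manifest '%s' does not exist", path),
             "pfbmri_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "image_path", "side")
  if (!all(need %in% names(df))) {
    stop_pfb(sprintf("manifest must have columns: %s",
                     paste(need, collapse = ", ")), "pfbmri_format_error")
  }
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  images <- vector("list", nrow(df))
  masks <- if ("mask_path" %in% names(df) && any(nzchar(df$mask_path))) {
    vector("list", nrow(df))
  } else {
    NULL
  }
  for (i in seq_len(nrow(df))) {
    ip <- resolve(df$image_path[i])
    t_sc <- if ("t_score" %in% names(df) && is.finite(df$t_score[i])) df$t_score[i]
    lab <- if ("label" %in% names(df) && is.finite(df$label[i])) df$label[i]
    im <- if (grepl("\\.png$", ip, ignore.case = TRUE)) {
      read_image_png(ip, side = df$side[i], t_score = t_sc, label = lab)
    } else {
      read_dicom(ip, side = df$side[i], t_score = t_sc, label = lab)
    }
    im$subject_id <- as.character(df$subject_id[i])
    if (all(c("TR", "TE", "flip_angle") %in% names(df)) &&
        is.finite(df$TR[i])) {
      im$protocol <- list(TR = df$TR[i], TE = df$TE[i],
                          flip_angle = df$flip_angle[i])
    }
    images[[i]] <- im
    if (!is.null(masks) && nzchar(df$mask_path[i])) {
      masks[[i]] <- read_mask_png(resolve(df$mask_path[i]))
    }
  }
  pfb_dataset(images, masks)
}

#' Write a feature table to CSV (full precision)
#'
#' Values are serialized with 17 significant digits so a write/read round
#' trip is lossless.
#'
#' @param features Feature tibble from [build_feature_table()].
#' @param path Output CSV path.
#' @export
write_feature_csv <- function(features, path) {
  df <- as.data.frame(features)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @return [read_feature_csv()] returns the feature tibble.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in setdiff(names(df), "subject_id")) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  tibble::as_tibble(df)
}
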