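# Shared fixtures, all built in code at test time.

# Byte-level DICOM writer, independent of the package's parser (explicit
# VR little endian, preamble + DICM, US/DS/OW elements only).
write_fixture_dicom <- function(path, pixels, slope = NULL, intercept = NULL,
                                tr = NULL, te = NULL, flip = NULL) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  elem_str <- function(g, e, vr, s) {
    u16(g); u16(e); writeChar(vr, con, eos = NULL)
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    u16(nchar(s)); writeChar(s, con, eos = NULL)
  }
  elem_us <- function(g, e, val) {
    u16(g); u16(e); writeChar("US", con, eos = NULL); u16(2); u16(val)
  }
  if (!is.null(tr)) elem_str(0x0018, 0x0080, "DS", as.character(tr))
  if (!is.null(te)) elem_str(0x0018, 0x0081, "DS", as.character(te))
  if (!is.null(flip)) elem_str(0x0018, 0x1314, "DS", as.character(flip))
  elem_us(0x0028, 0x0010, nrow(pixels))
  elem_us(0x0028, 0x0011, ncol(pixels))
  elem_us(0x0028, 0x0100, 16)
  elem_us(0x0028, 0x0103, 0)
  if (!is.null(intercept)) elem_str(0x0028, 0x1052, "DS", as.character(intercept))
  if (!is.null(slope)) elem_str(0x0028, 0x1053, "DS", as.character(slope))
  px <- as.integer(t(pixels)) # row-major
  u16(0x7fe0); u16(0x0010)
  writeChar("OW", con, eos = NULL); u16(0)
  writeBin(length(px) * 2L, con, size = 4, endian = "little")
  writeBin(px, con, size = 2, endian = "little")
  invisible(path)
}

# Feature table with one perfectly predictive column among noise columns.
planted_feature_table <- function(n = 200, noise_features = 20, seed = 9,
                                  signal_sd = 0.05) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(rnorm(n * (noise_features + 1)), n, noise_features + 1)
    X[, 1] <- y + rnorm(n, 0, signal_sd)
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    dplyr::bind_cols(tibble::tibble(label = y), tibble::as_tibble(X))
  })
}

# Random single-component rectangular masks on a common grid, for
# DSC/IoU identity checks.
random_mask_pair <- function(n = 32) {
  rect <- function() {
    m <- matrix(FALSE, n, n)
    r0 <- sample.int(n - 4, 1); c0 <- sample.int(n - 4, 1)
    m[r0:min(n, r0 + sample.int(10, 1)),
      c0:min(n, c0 + sample.int(10, 1))] <- TRUE
    m
  }
  list(S = rect(), T_ = rect())
}

# One default phantom pair, cached across tests in a session.
.fixture_env <- new.env(parent = emptyenv())
default_phantom <- function() {
  if (is.null(.fixture_env$phantom)) {
    .fixture_env$phantom <- generate_phantom(phantom_spec(rng_seed = 7))
  }
  .fixture_env$phantom
}
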