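# Small shared fixtures, built in code at test time.

# A tiny, fast phantom spec for unit tests (not the study conditions).
tiny_spec <- function(seed = 1, ...) {
  phantom_spec(image_size = 64, n_control = 3, n_diseased = 3,
               lesion_centers = c(27, 37), seed = seed, ...)
}

# A smooth low-amplitude full-resolution field for warp/feature tests.
toy_field <- function(n = 24, amp = 0.5, seed = 1) {
  withr::with_seed(seed, {
    ur <- amp * outer(sin(seq(0, pi, length.out = n)),
                      cos(seq(0, pi, length.out = n)))
    uc <- amp * outer(cos(seq(0, pi, length.out = n)),
                      sin(seq(0, pi, length.out = n)))
    deformation_field(ur, uc)
  })
}

# Deterministic gradient image for registration tests.
toy_image <- function(n = 48) {
  r <- matrix(rep(seq_len(n) - 1, n), n, n)
  cc <- matrix(rep(seq_len(n) - 1, each = n), n, n)
  ctr <- (n - 1) / 2
  g <- exp(-((r - ctr)^2 + (cc - ctr)^2) / (2 * (n / 5)^2))
  gray_image(g / max(g))
}

# Minimal explicit-VR little-endian single-frame monochrome DICOM writer,
# used only to build test fixtures in code (the reader under test is
# independent of this byte assembly).
write_test_dicom <- function(path, pixels, spacing = c(0.5, 0.5),
                             bits = 16L) {
  stopifnot(bits == 16L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  elem_short <- function(group, elem, vr, value_raw) {
    writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
    writeChar(vr, con, eos = NULL)
    writeBin(length(value_raw), con, size = 2, endian = "little")
    writeBin(value_raw, con)
  }
  us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  str_even <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
    r
  }
  elem_short(0x0028, 0x0008, "IS", str_even("1"))        # NumberOfFrames
  elem_short(0x0028, 0x0010, "US", us(nrow(pixels)))      # Rows
  elem_short(0x0028, 0x0011, "US", us(ncol(pixels)))      # Columns
  elem_short(0x0028, 0x0030, "DS",                        # PixelSpacing
             str_even(paste(spacing, collapse = "\\")))
  elem_short(0x0028, 0x0100, "US", us(bits))              # BitsAllocated
  elem_short(0x0028, 0x0103, "US", us(0))                 # PixelRepresentation
  vals <- round(pixels * 65535)
  pix <- writeBin(as.integer(t(vals)), raw(), size = 2, endian = "little")
  # PixelData: OW uses the 12-byte header with 32-bit length
  writeBin(as.integer(c(0x7fe0, 0x0010)), con, size = 2, endian = "little")
  writeChar("OW", con, eos = NULL)
  writeBin(as.integer(0), con, size = 2, endian = "little")
  writeBin(length(pix), con, size = 4, endian = "little")
  writeBin(pix, con)
  invisible(path)
}
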