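# Minimal deterministic ZIP container (stored entries, no compression).
#
# Export bundles must be byte-reproducible given identical content and an
# injected timestamp, which rules out compressors and filesystem mtimes.
# Entries are therefore stored uncompressed with the single injected DOS
# timestamp; readers use the standard central directory. Archives are read
# back with utils::unzip(unzip = "internal").

u16 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256))
}

u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

crc32_num <- function(bytes) {
  if (length(bytes) == 0) return(0)
  hx <- digest::digest(bytes, algo = "crc32", serialize = FALSE)
  if (nchar(hx) < 8) hx <- paste0(strrep("0", 8 - nchar(hx)), hx)
  sum(strtoi(substring(hx, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L) *
        c(16777216, 65536, 256, 1))
}

dos_datetime <- function(iso_ts) {
  y <- as.integer(substr(iso_ts, 1, 4))
  mo <- as.integer(substr(iso_ts, 6, 7))
  d <- as.integer(substr(iso_ts, 9, 10))
  h <- as.integer(substr(iso_ts, 12, 13))
  mi <- as.integer(substr(iso_ts, 15, 16))
  s <- as.integer(substr(iso_ts, 18, 19))
  list(time = h * 2048 + mi * 32 + s %/% 2,
       date = max(y - 1980, 0) * 512 + mo * 32 + d)
}

as_member_bytes <- function(x) {
  if (is.raw(x)) x else charToRaw(enc2utf8(paste(x, collapse = "")))
}

# members: named list (entry name -> raw vector or character scalar).
# Entry order is the list order; callers sort names for determinism.
zip_build <- function(members, timestamp) {
  stopifnot(is_iso_ts(timestamp), length(members) > 0,
            !is.null(names(members)), all(nzchar(names(members))))
  dt <- dos_datetime(timestamp)
  locals <- list()
  centrals <- list()
  offset <- 0
  for (i in seq_along(members)) {
    name_raw <- charToRaw(enc2utf8(names(members)[i]))
    data <- as_member_bytes(members[[i]])
    crc <- crc32_num(data)
    common <- c(u16(20),           # version needed to extract
                u16(0x0800),       # general purpose flag: UTF-8 names
                u16(0),            # method: stored
                u16(dt$time), u16(dt$date),
                u32(crc), u32(length(data)), u32(length(data)),
                u16(length(name_raw)), u16(0))
    local <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), common, name_raw, data)
    central <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16(20), common,
                 u16(0),            # comment length
                 u16(0),            # disk number
                 u16(0),            # internal attributes
                 u32(0),            # external attributes
                 u32(offset), name_raw)
    locals[[i]] <- local
    centrals[[i]] <- central
    offset <- offset + length(local)
  }
  cd <- do.call(c, centrals)
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16(0), u16(0),
            u16(length(members)), u16(length(members)),
            u32(length(cd)), u32(offset), u16(0))
  c(do.call(c, locals), cd, eocd)
}

zip_write <- function(path, members, timestamp) {
  bytes <- zip_build(members, timestamp)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

zip_extract <- function(path, exdir) {
  dir.create(exdir, recursive = TRUE, showWarnings = FALSE)
  utils::unzip(path, exdir = exdir, unzip = "internal")
  invisible(exdir)
}

zip_list_names <- function(path) {
  info <- utils::unzip(path, list = TRUE, unzip = "internal")
  info$Name
}
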