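# Minimal ZIP writer. Each member is deflate-compressed by writing it
# through a gzfile() connection: the resulting gzip container is a 10-byte
# header (flags zero), the raw deflate stream, and an 8-byte trailer whose
# first word is the CRC32 of the uncompressed data -- exactly the two
# pieces a zip local header needs, both produced by zlib itself. Reading
# back goes through utils::unzip (an independent implementation), which is
# also what the audit uses.

.u16 <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
.u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.dos_datetime <- function(mtime) {
  lt <- as.POSIXlt(mtime)
  year <- max(lt$year + 1900L, 1980L)
  time <- bitwShiftL(lt$hour, 11L) + bitwShiftL(lt$min, 5L) +
    (lt$sec %/% 2L)
  date <- bitwShiftL(year - 1980L, 9L) + bitwShiftL(lt$mon + 1L, 5L) +
    lt$mday
  list(time = as.integer(time), date = as.integer(date))
}

.deflate_member <- function(path) {
  size <- file.info(path)$size
  data <- readBin(path, "raw", n = size)
  tmp <- tempfile("provtrack-gz-")
  on.exit(unlink(tmp))
  con <- gzfile(tmp, "wb", compression = 6L)
  writeBin(data, con)
  close(con)
  gz <- readBin(tmp, "raw", n = file.info(tmp)$size)
  n <- length(gz)
  if (n < 18L || gz[1L] != as.raw(0x1f) || gz[2L] != as.raw(0x8b) ||
      gz[4L] != as.raw(0x00))
    stop("unexpected gzip framing while packing '", path, "'",
         call. = FALSE)
  crc <- gz[(n - 7L):(n - 4L)]                 # CRC32, little-endian
  list(deflate = gz[11L:(n - 8L)], crc = crc, size = length(data))
}

.zip_write <- function(files, names, zipfile) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- integer(length(files))
  members <- vector("list", length(files))
  pos <- 0L
  for (i in seq_along(files)) {
    m <- .deflate_member(files[[i]])
    dt <- .dos_datetime(file.info(files[[i]])$mtime)
    name_raw <- charToRaw(names[[i]])
    header <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)),
                .u16(20L), .u16(0L), .u16(8L),
                .u16(dt$time), .u16(dt$date),
                m$crc, .u32(length(m$deflate)), .u32(m$size),
                .u16(length(name_raw)), .u16(0L), name_raw)
    writeBin(header, con)
    writeBin(m$deflate, con)
    offsets[i] <- pos
    pos <- pos + length(header) + length(m$deflate)
    members[[i]] <- list(crc = m$crc, csize = length(m$deflate),
                         size = m$size, name_raw = name_raw, dt = dt)
  }
  cd_start <- pos
  for (i in seq_along(members)) {
    m <- members[[i]]
    entry <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)),
               .u16(20L), .u16(20L), .u16(0L), .u16(8L),
               .u16(m$dt$time), .u16(m$dt$date),
               m$crc, .u32(m$csize), .u32(m$size),
               .u16(length(m$name_raw)), .u16(0L), .u16(0L),
               .u16(0L), .u16(0L), .u32(0L), .u32(offsets[i]),
               m$name_raw)
    writeBin(entry, con)
    pos <- pos + length(entry)
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            .u16(0L), .u16(0L),
            .u16(length(members)), .u16(length(members)),
            .u32(pos - cd_start), .u32(cd_start), .u16(0L))
  writeBin(eocd, con)
  invisible(zipfile)
}

# Central-directory reader: member names, sizes and exact DOS (2-second
# resolution) modification times. utils::unzip's listing truncates member
# times to the minute, which is too coarse for the audit's mtime check.
.read_zip_directory <- function(zip_path) {
  size <- file.info(zip_path)$size
  raw <- readBin(zip_path, "raw", n = size)
  le <- function(bytes) sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1L))
  # locate end-of-central-directory record (no comment in our writer, but
  # scan backwards anyway to accept third-party zips)
  eocd <- NA_integer_
  for (i in seq(from = length(raw) - 21L, to = max(1L, length(raw) - 65557L))) {
    if (raw[i] == as.raw(0x50) && raw[i + 1L] == as.raw(0x4b) &&
        raw[i + 2L] == as.raw(0x05) && raw[i + 3L] == as.raw(0x06)) {
      eocd <- i
      break
    }
  }
  if (is.na(eocd))
    stop("not a zip file (no end-of-central-directory): ", zip_path,
         call. = FALSE)
  n_entries <- le(raw[(eocd + 10L):(eocd + 11L)])
  offset <- le(raw[(eocd + 16L):(eocd + 19L)]) + 1L
  names <- character(n_entries)
  sizes <- numeric(n_entries)
  mtimes <- numeric(n_entries)
  p <- offset
  for (k in seq_len(n_entries)) {
    if (!(raw[p] == as.raw(0x50) && raw[p + 1L] == as.raw(0x4b) &&
          raw[p + 2L] == as.raw(0x01) && raw[p + 3L] == as.raw(0x02)))
      stop("corrupt zip central directory: ", zip_path, call. = FALSE)
    dtime <- le(raw[(p + 12L):(p + 13L)])
    ddate <- le(raw[(p + 14L):(p + 15L)])
    sizes[k] <- le(raw[(p + 24L):(p + 27L)])
    name_len <- le(raw[(p + 28L):(p + 29L)])
    extra_len <- le(raw[(p + 30L):(p + 31L)])
    comment_len <- le(raw[(p + 32L):(p + 33L)])
    names[k] <- rawToChar(raw[(p + 46L):(p + 45L + name_len)])
    mtimes[k] <- as.numeric(ISOdatetime(
      1980L + ddate %/% 512L,
      (ddate %/% 32L) %% 16L, ddate %% 32L,
      dtime %/% 2048L, (dtime %/% 32L) %% 64L, (dtime %% 32L) * 2L))
    p <- p + 46L + name_len + extra_len + comment_len
  }
  data.frame(name = names, size = sizes,
             mtime = as.POSIXct(mtimes, origin = "1970-01-01"),
             stringsAsFactors = FALSE)
}

#' Pack an archive directory into a single zip file
#'
#' Writes every file of the archive — copies, detail tables, appendix,
#' manifest and the serialized details document — into one zip file next
#' to the archive directory. The embedded details document carries the
#' manifest recorded at archiving time, so the zip can later be audited
#' on its own with [check_zipfile()].
#'
#' @param archive_path Path to an archive directory built by
#'   [build_archive()].
#' @param zipfile Output path; default `<archive_path>.zip`.
#' @return The zip file path, invisibly.
#' @export
create_zip_archive <- function(archive_path,
                               zipfile = paste0(archive_path, ".zip")) {
  if (!dir.exists(archive_path))
    stop("no such archive directory: ", archive_path, call. = FALSE)
  members <- list.files(archive_path, full.names = TRUE)
  members <- members[!file.info(members)$isdir]
  if (!length(members))
    stop("archive directory is empty: ", archive_path, call. = FALSE)
  .zip_write(members, basename(members), zipfile)
  invisible(zipfile)
}
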