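## Minimal text dialect of the Standard DNA Damage (SDD) interchange format:
## a "Key, value;" header block terminated by a line "***", then one
## comma-separated record per DSB site. Only the fields the repair simulator
## consumes are modelled; unrecognised header keys are accepted with a warning.

.SDD_RECORD_FIELDS <- 9L  # site_id, x, y, z, chromatin, 4 lesion counts

#' Write a damage set as a minimal SDD file
#'
#' @param damage a \linkS4class{DamageSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @examples
#' f <- tempfile(fileext = ".sdd")
#' writeSDD(generatePhotonDamage(0.5, seed = 1), f)
#' @export
writeSDD <- function(damage, path) {
  stopifnot(is(damage, "DamageSet"))
  s <- damage@sites
  hdr <- c(
    "SDD version, minimal-dialect-1;",
    sprintf("Dose or fluence, %.6g;", damage@dose),
    sprintf("Quality, %s;", damage@quality),
    sprintf("LET (keV/um), %s;",
            if (is.na(damage@let)) "NA" else sprintf("%.6g", damage@let)),
    sprintf("Nucleus radius (nm), %.6g;", damage@nucleus@radius),
    sprintf("Seed, %s;",
            if (is.na(damage@seed)) "NA" else as.character(damage@seed)),
    sprintf("Record count, %d;", nrow(s)),
    "***"
  )
  rec <- if (nrow(s) == 0L) character(0) else
    sprintf("%d,%.3f,%.3f,%.3f,%s,%d,%d,%d,%d",
            s$site_id, s$x, s$y, s$z,
            ifelse(s$chromatin == "heterochromatin", "H", "E"),
            s$lesions_a_base, s$lesions_a_ssb,
            s$lesions_b_base, s$lesions_b_ssb)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

.sddParseError <- function(line, msg) {
  stop(sprintf("SDD parse error at line %d: %s", line, msg), call. = FALSE)
}

#' Read a minimal SDD file
#'
#' Parses the dialect written by \code{\link{writeSDD}}. Header keys beyond
#' the minimal set are ignored with a warning; malformed records (wrong field
#' count, non-numeric fields) raise a parse error naming the offending line.
#'
#' @param path path to an SDD file.
#' @return A \linkS4class{DamageSet}.
#' @export
readSDD <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  sep <- which(lines == "***")[1]
  if (is.na(sep)) stop("SDD parse error: no '***' header terminator found",
                       call. = FALSE)
  known <- c("SDD version", "Dose or fluence", "Quality", "LET (keV/um)",
             "Nucleus radius (nm)", "Seed", "Record count")
  hdr <- list()
  for (i in seq_len(sep - 1L)) {
    ln <- sub(";\\s*$", "", lines[i])
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L) .sddParseError(i, "header line is not 'Key, value;'")
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = ","))
    if (!key %in% known) {
      warning(sprintf("SDD header key '%s' (line %d) ignored", key, i))
      next
    }
    hdr[[key]] <- val
  }
  num <- function(key, default = NA_real_) {
    v <- hdr[[key]]
    if (is.null(v) || identical(v, "NA")) return(default)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop(sprintf("SDD parse error: non-numeric header '%s'", key),
                       call. = FALSE)
    x
  }
  recLines <- lines[seq.int(sep + 1L, length.out = length(lines) - sep)]
  recLines <- recLines[nzchar(trimws(recLines))]
  n <- length(recLines)
  cols <- matrix(NA_character_, nrow = n, ncol = .SDD_RECORD_FIELDS)
  for (k in seq_len(n)) {
    parts <- strsplit(recLines[k], ",", fixed = TRUE)[[1]]
    if (length(parts) != .SDD_RECORD_FIELDS) {
      .sddParseError(sep + k, sprintf("expected %d fields, found %d",
                                      .SDD_RECORD_FIELDS, length(parts)))
    }
    cols[k, ] <- trimws(parts)
  }
  asNum <- function(j, what) {
    x <- suppressWarnings(as.numeric(cols[, j]))
    bad <- which(is.na(x))
    if (length(bad)) .sddParseError(sep + bad[1], paste("non-numeric", what))
    x
  }
  if (n > 0L) {
    chrom <- cols[, 5]
    bad <- which(!chrom %in% c("H", "E"))
    if (length(bad)) .sddParseError(sep + bad[1], "chromatin flag must be H or E")
    sitesDf <- data.frame(
      site_id = as.integer(asNum(1, "site_id")),
      x = asNum(2, "x"), y = asNum(3, "y"), z = asNum(4, "z"),
      chromatin = ifelse(chrom == "H", "heterochromatin", "euchromatin"),
      lesions_a_base = as.integer(asNum(6, "lesion count")),
      lesions_a_ssb = as.integer(asNum(7, "lesion count")),
      lesions_b_base = as.integer(asNum(8, "lesion count")),
      lesions_b_ssb = as.integer(asNum(9, "lesion count")),
      stringsAsFactors = FALSE
    )
  } else {
    sitesDf <- generatePhotonDamage(0)@sites
  }
  declared <- num("Record count", NA_real_)
  if (!is.na(declared) && declared != n) {
    stop(sprintf("SDD parse error: header declares %d records, found %d",
                 as.integer(declared), n), call. = FALSE)
  }
  seedVal <- hdr[["Seed"]]
  new("DamageSet",
      sites = sitesDf,
      dose = num("Dose or fluence", 0),
      quality = if (is.null(hdr[["Quality"]])) "photon" else hdr[["Quality"]],
      let = num("LET (keV/um)"),
      seed = if (is.null(seedVal) || identical(seedVal, "NA")) NA_integer_
             else as.integer(seedVal),
      nucleus = nucleus(radius = num("Nucleus radius (nm)", 5000)))
}

#' Export a damage set as CSV
#'
#' Plain CSV with one row per DSB site (site_id, x, y, z, chromatin and the
#' four per-end lesion counts), for use outside the package.
#'
#' @param damage a \linkS4class{DamageSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportDamageCSV <- function(damage, path) {
  stopifnot(is(damage, "DamageSet"))
  utils::write.csv(damage@sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
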