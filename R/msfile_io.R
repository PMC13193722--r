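## Peak-list I/O: MGF read/write (canonical text format here) and optional
## read-only mzML support through mzR.

#' Write spectra to an MGF file
#'
#' Standard Mascot generic format: BEGIN IONS / TITLE / PEPMASS / CHARGE /
#' RTINSECONDS / peak lines / END IONS. Retention times are stored in
#' seconds (internal unit is minutes).
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      sprintf("CHARGE=%d+", s$precursor_charge),
      sprintf("RTINSECONDS=%.4f", s$rt * 60)
    ), con)
    if (length(s$mz) > 0) {
      writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' @param path MGF file path.
#' @return List of [spectrum()] objects (RT converted to minutes).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) {
    stop("malformed MGF '", path, "': ", length(begins), " BEGIN IONS vs ",
         length(ends), " END IONS")
  }
  lapply(seq_along(begins), function(k) {
    block <- lines[(begins[k] + 1):(ends[k] - 1)]
    is_kv <- grepl("^[A-Z]+=", block)
    kv <- block[is_kv]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[A-Z]+=", "", kv)
    get <- function(key, default = NA_character_) {
      i <- match(key, keys)
      if (is.na(i)) default else vals[i]
    }
    peak_lines <- block[!is_kv & nzchar(block)]
    pk <- if (length(peak_lines) > 0) {
      m <- do.call(rbind, strsplit(trimws(peak_lines), "[ \t]+"))
      if (ncol(m) < 2) {
        stop("malformed MGF peak line near line ", begins[k], " in '", path, "'")
      }
      list(mz = as.numeric(m[, 1]), int = as.numeric(m[, 2]))
    } else list(mz = numeric(0), int = numeric(0))
    spectrum(
      id = get("TITLE", paste0("spectrum_", k)),
      precursor_mz = as.numeric(get("PEPMASS")),
      precursor_charge = as.integer(sub("[+-]$", "", get("CHARGE", "1+"))),
      rt = as.numeric(get("RTINSECONDS", "0")) / 60,
      mz = pk$mz, intensity = pk$int
    )
  })
}

#' Read MS2 spectra from an mzML file (requires mzR)
#'
#' @param path mzML file path.
#' @return List of [spectrum()] objects.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package")
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  sel <- which(hdr$msLevel == 2)
  lapply(sel, function(i) {
    pk <- mzR::peaks(fh, i)
    spectrum(
      id = as.character(hdr$seqNum[i]),
      precursor_mz = hdr$precursorMZ[i],
      precursor_charge = max(1L, hdr$precursorCharge[i]),
      rt = hdr$retentionTime[i] / 60,
      mz = pk[, 1], intensity = pk[, 2]
    )
  })
}
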