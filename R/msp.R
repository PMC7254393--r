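# NIST-style MSP text format: records separated by blank lines, "Key: value"
# headers, then "Num Peaks:" and whitespace- or semicolon-separated
# mz/intensity pairs. Both the line-per-pair and "m i; m i;" dialects are
# accepted on read; writing always uses the canonical line-per-pair form.

#' Read a NIST-style MSP spectral file
#'
#' Parses `Name:`, and optional `Formula:`, `RI:`, `RT:`, `Comments:` and
#' `Num Peaks:` headers. Package-written files carry `id=`, `mode=` and
#' `resolution=` keys inside `Comments:`, which are recovered on read;
#' foreign files default to mode `"EI"` and resolution `"unit"`. The
#' declared `Num Peaks` must equal the number of parsed pairs.
#'
#' @param path Path to an MSP text file.
#' @return Spectra tibble (see [msp_spectrum()]); zero rows for an empty
#'   file.
#' @export
read_msp <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  blank <- grepl("^\\s*$", lines)
  if (!length(lines) || all(blank)) {
    return(msp_spectrum(1, 1, id = "x")[0, ])
  }
  rec_id <- cumsum(c(TRUE, blank[-length(blank)])) * !blank
  recs <- split(seq_along(lines)[!blank], rec_id[!blank])

  out <- lapply(recs, function(idx) parse_msp_record(lines, idx))
  res <- dplyr::bind_rows(out)
  validate_library(res)
  res
}

parse_msp_record <- function(lines, idx) {
  txt <- lines[idx]
  header <- grepl("^[A-Za-z][A-Za-z ]*:", txt)
  get <- function(key) {
    hit <- grep(paste0("^", key, ":"), txt[header], value = TRUE)
    if (!length(hit)) {
      return(NA_character_)
    }
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  name <- get("Name")
  np_line <- grep("^Num Peaks:", txt)
  if (!length(np_line)) {
    stop("record '", name, "' (line ", idx[1], "): missing 'Num Peaks:'",
      call. = FALSE
    )
  }
  n_declared <- as.integer(trimws(sub("^Num Peaks:", "", txt[np_line[1]])))
  peak_txt <- txt[seq.int(np_line[1] + 1L, length.out = length(txt) - np_line[1])]
  tokens <- unlist(strsplit(paste(peak_txt, collapse = " "), "[;,]"))
  tokens <- unlist(strsplit(trimws(tokens), "\\s+"))
  tokens <- tokens[tokens != ""]
  vals <- suppressWarnings(as.numeric(tokens))
  if (any(is.na(vals)) || length(vals) %% 2 != 0) {
    stop("record '", name, "' (line ", idx[1], "): unparseable peak pair",
      call. = FALSE
    )
  }
  mz <- vals[seq(1, length(vals), by = 2)]
  intensity <- vals[seq(2, length(vals), by = 2)]
  if (length(mz) != n_declared) {
    stop(
      "record '", name, "' (line ", idx[1], "): Num Peaks is ", n_declared,
      " but ", length(mz), " pairs were parsed",
      call. = FALSE
    )
  }
  comments <- get("Comments")
  ckey <- function(key, default = NA_character_) {
    if (is.na(comments)) {
      return(default)
    }
    m <- regmatches(
      comments,
      regexec(paste0("\\b", key, "=([^ ]+)"), comments)
    )[[1]]
    if (length(m) < 2) default else m[2]
  }
  ri <- suppressWarnings(as.numeric(get("RI")))
  rt <- suppressWarnings(as.numeric(get("RT")))
  msp_spectrum(
    mz = mz, intensity = intensity,
    id = ckey("id", default = name),
    name = name,
    formula = get("Formula"),
    mode = ckey("mode", default = "EI"),
    resolution = ckey("resolution", default = "unit"),
    rt = rt, ri = ri
  )
}

#' Write spectra to a NIST-style MSP file
#'
#' Emits `Name:`, `Formula:` (when present), `RI:`/`RT:` (when present), a
#' `Comments:` line carrying the id, mode and resolution class,
#' `Num Peaks:` and one mz/intensity pair per line with fixed formatting
#' (m/z to 5 decimal places, intensity to 2), preserving library order.
#'
#' @param spectra Spectra tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  validate_library(spectra)
  blocks <- vapply(seq_len(nrow(spectra)), function(i) {
    s <- spectra[i, ]
    p <- s$peaks[[1]]
    hdr <- c(
      paste0("Name: ", if (is.na(s$name)) s$id else s$name),
      if (!is.na(s$formula)) paste0("Formula: ", s$formula),
      if (!is.na(s$ri)) paste0("RI: ", format(s$ri, digits = 10)),
      if (!is.na(s$rt)) paste0("RT: ", format(s$rt, digits = 10)),
      paste0(
        "Comments: id=", s$id, " mode=", s$mode,
        " resolution=", s$resolution
      ),
      paste0("Num Peaks: ", nrow(p))
    )
    pairs <- sprintf("%.5f %.2f", p$mz, p$intensity)
    paste(c(hdr, pairs), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}
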