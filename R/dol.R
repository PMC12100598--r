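#' Write / read dol pose files
#'
#' The dol file is a plain-text pose list: one whitespace-delimited row per
#' subunit copy with columns `x y z alpha beta gamma` (positions in nm,
#' Tait-Bryan angles in degrees), preceded by `#` comment lines carrying the
#' model provenance. Values round-trip to at least 12 significant digits and
#' the reader tolerates blank lines.
#'
#' @param assembly an `assembly`.
#' @param path output file path.
#' @return `write_dol` returns `path` invisibly; `read_dol` returns the pose
#'   data frame (possibly empty for a header-only file).
#' @export
write_dol <- function(assembly, path) {
  stopifnot(inherits(assembly, "assembly"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# dol pose file -- kind:", assembly$kind),
    paste("# subunits:", nrow(assembly$poses)),
    if (length(assembly$spec)) {
      scal <- assembly$spec[vapply(assembly$spec,
                                   function(v) is.numeric(v) && length(v) == 1,
                                   logical(1))]
      if (length(scal)) paste("#", paste(names(scal), unlist(scal), sep = "=",
                                         collapse = " "))
    },
    "# x y z alpha beta gamma"
  ), con)
  m <- as.matrix(assembly$poses)
  writeLines(apply(format(m, digits = 15, trim = TRUE, scientific = TRUE),
                   1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_dol
#' @export
read_dol <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    alpha = numeric(0), beta = numeric(0), gamma = numeric(0))
  if (length(body) == 0) return(out)
  lineno <- which(keep)
  rows <- strsplit(trimws(body), "\\s+")
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(v) != 6 || any(is.na(v))) {
      stop("read_dol: malformed row at line ", lineno[i], " of ", path,
           call. = FALSE)
    }
    out[i, ] <- v
  }
  out
}
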