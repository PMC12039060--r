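#' Parse an xyz-format block
#'
#' Reads the standard xyz layout: an atom-count header line, a comment line,
#' then one \code{element x y z} line per atom (coordinates in Angstrom).
#'
#' @param text either a path to an xyz file or the xyz content itself
#'   (a single string with newlines, or a character vector of lines).
#' @return an \linkS4class{XYZStructure}.
#' @examples
#' s <- parseXYZ("1\ncomment\nFe 0 0 0")
#' atomCount(s)
#' @export
parseXYZ <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L)
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(text) < 1L) stop("xyz parse error: empty input")
  n <- suppressWarnings(as.integer(trimws(text[1])))
  if (is.na(n) || n < 1L)
    stop("xyz parse error: malformed header line 1: ", sQuote(text[1]))
  comment <- if (length(text) >= 2L) text[2] else ""
  body <- text[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop("xyz parse error: header declares ", n, " atoms but only ",
         length(body), " atom lines found")
  body <- body[seq_len(n)]
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    if (length(parts) < 4L)
      stop("xyz parse error: atom line ", i + 2L, " has fewer than 4 fields")
    el <- parts[1]
    if (!el %in% names(.covalentRadii))
      stop("xyz parse error: unknown element ", sQuote(el), " on line ", i + 2L)
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(xyz))
      stop("xyz parse error: non-numeric coordinate on line ", i + 2L)
    elements[i] <- el
    coords[i, ] <- xyz
  }
  new("XYZStructure", elements = elements, coords = coords, comment = comment)
}

#' Format an XYZStructure as xyz text
#'
#' Deterministic fixed-decimal formatting (6 decimals) so fixture output is
#' bit-stable across platforms.
#'
#' @param s an \linkS4class{XYZStructure}.
#' @param comment comment line to embed.
#' @return a single string in xyz layout.
#' @export
formatXYZ <- function(s, comment = s@comment) {
  n <- length(s@elements)
  lines <- sprintf("%s %.6f %.6f %.6f", s@elements,
                   s@coords[, 1], s@coords[, 2], s@coords[, 3])
  paste(c(as.character(n), comment, lines), collapse = "\n")
}

#' @describeIn parseXYZ number of atoms in a structure.
#' @param s an \linkS4class{XYZStructure}.
#' @export
atomCount <- function(s) length(s@elements)
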