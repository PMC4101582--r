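#' Read a spectra matrix from delimited text
#'
#' The on-disk layout is one header row holding the m/z axis followed by one
#' row per sample: the first field is the sample identifier, the remaining
#' fields are channel intensities. The header's first field is the identifier
#' column name (conventionally \code{"id"}). An optional trailing column named
#' \code{"label"} carries class codes; alternatively labels can live in a
#' separate two-column file mapping sample id to class code.
#'
#' The reader rejects, and never silently repairs, any format violation:
#' non-monotone m/z headers, rows of the wrong length, non-numeric
#' intensities, and label files naming unknown sample ids are all errors.
#'
#' @param path path of the matrix file.
#' @param labelsPath optional path of a two-column (id, label) file; a header
#'   line \code{id<sep>label} is allowed and skipped.
#' @param sep field delimiter, comma (default) or tab.
#' @return A \linkS4class{SpectraMatrix}.
#' @seealso [writeSpectraMatrix()]
#' @export
readSpectraMatrix <- function(path, labelsPath = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("format error: need a header and at least one sample row",
         call. = FALSE)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  hasLabelCol <- identical(tolower(header[length(header)]), "label")
  if (hasLabelCol) header <- header[-length(header)]
  mz <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(mz))
    stop("format error: non-numeric m/z value in header", call. = FALSE)
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("format error: m/z header is not strictly increasing", call. = FALSE)
  nChan <- length(mz)

  rows <- strsplit(lines[-1], sep, fixed = TRUE)
  expected <- 1 + nChan + as.integer(hasLabelCol)
  lens <- lengths(rows)
  if (any(lens != expected))
    stop("format error: row ", which(lens != expected)[1] + 1, " has ",
         lens[lens != expected][1], " fields, expected ", expected,
         call. = FALSE)
  ids <- vapply(rows, `[`, character(1), 1)
  labels <- if (hasLabelCol)
    vapply(rows, `[`, character(1), expected) else character(0)
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[2:(nChan + 1)]), numeric(nChan)))
  if (anyNA(vals))
    stop("format error: non-numeric or missing intensity value",
         call. = FALSE)
  x <- t(matrix(vals, nrow = nChan))

  if (!is.null(labelsPath)) {
    lab <- utils::read.table(labelsPath, sep = sep, header = FALSE,
                             colClasses = "character",
                             col.names = c("id", "label"))
    if (identical(tolower(lab$id[1]), "id")) lab <- lab[-1, , drop = FALSE]
    unknown <- setdiff(lab$id, ids)
    if (length(unknown))
      stop("key error: label file names unknown sample id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    missing <- setdiff(ids, lab$id)
    if (length(missing))
      stop("key error: no label for sample id(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    labels <- lab$label[match(ids, lab$id)]
  }
  SpectraMatrix(x, mz = mz, sampleIds = ids, labels = labels)
}

# fixed interchange precision: 15 significant digits survive a print/parse
# round trip bit-for-bit at this width
.fmtNum <- function(x) sprintf("%.15g", x)

#' Write a spectra matrix as delimited text
#'
#' Writes the layout documented in [readSpectraMatrix()], at a fixed precision
#' of 15 significant digits, so that write-then-read is the identity well
#' within 1e-9 and read-then-write is byte-stable.
#'
#' @param spectra a \linkS4class{SpectraMatrix}.
#' @param path output path.
#' @param sep field delimiter, comma (default) or tab.
#' @param writeLabels include a trailing label column when labels are present
#'   (default TRUE).
#' @return The output path, invisibly.
#' @export
writeSpectraMatrix <- function(spectra, path, sep = ",", writeLabels = TRUE) {
  stopifnot(is(spectra, "SpectraMatrix"))
  x <- spectra@intensities
  withLab <- writeLabels && length(spectra@labels) > 0
  header <- paste(c("id", .fmtNum(spectra@mz), if (withLab) "label"),
                  collapse = sep)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(spectra@sampleIds[i], .fmtNum(x[i, ]),
            if (withLab) spectra@labels[i]), collapse = sep)
  }, character(1))
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("I/O error: cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
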