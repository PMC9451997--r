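# File I/O: transaction CSVs (basket and attribute-table dialects),
# grayscale images (plain PGM, PNG, whitespace-delimited matrices).

#' Read a transaction database from CSV
#'
#' Two dialects: `"basket"` has one transaction per line as comma-separated
#' item tokens (duplicates within a line are dropped); `"attribute"` is a
#' header CSV in the PN, PD, H, I, J, K, L, M, Class schema where every
#' non-PN cell `v` in {0, 1} becomes the item `"col=v"` and PN is a record
#' identifier, never an item.
#'
#' @param path File path.
#' @param dialect `"basket"` or `"attribute"`.
#' @return A [transaction_db()]; for the attribute dialect the PN column
#'   is kept as attribute `PN`.
#' @export
read_transactions <- function(path, dialect = c("basket", "attribute")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "basket") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty transaction file: ", path)
    tx <- lapply(seq_along(lines), function(i) {
      toks <- trimws(strsplit(lines[[i]], ",", fixed = TRUE)[[1L]])
      toks <- toks[nzchar(toks)]
      if (length(toks) == 0L) {
        stop("malformed basket row at line ", i, " of ", path)
      }
      toks
    })
    return(transaction_db(tx))
  }
  tab <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse attribute table ", path, ": ",
                             conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty transaction file: ", path)
  if (!"PN" %in% names(tab)) {
    stop("attribute-table dialect requires a PN column in ", path)
  }
  cols <- setdiff(names(tab), "PN")
  for (cl in cols) {
    bad <- which(!tab[[cl]] %in% c("0", "1"))
    if (length(bad) > 0L) {
      stop("malformed cell in column '", cl, "' at data line ", bad[1L],
           " of ", path, " (expected 0 or 1, got '", tab[[cl]][bad[1L]], "')")
    }
  }
  tx <- lapply(seq_len(nrow(tab)), function(i) {
    paste0(cols, "=", unlist(tab[i, cols], use.names = FALSE))
  })
  db <- transaction_db(tx)
  attr(db, "PN") <- tab$PN
  db
}

#' Read a grayscale image
#'
#' Supports plain-text PGM (P2), PNG (via the png package; values scaled
#' to 0-255 and a color image averaged to gray) and whitespace-delimited
#' numeric matrix files (any other extension).
#'
#' @param path File path.
#' @return Integer matrix of gray levels.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:3, drop = FALSE],
                                             c(1, 2), mean)
    img <- round(arr * 255)
    storage.mode(img) <- "integer"
    return(img)
  }
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  check_gray_image(m)
  storage.mode(m) <- "integer"
  m
}

read_pgm <- function(path) {
  raw <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(raw) < 4L || raw[1L] != "P2") {
    stop("only plain (P2) PGM is supported: ", path)
  }
  w <- as.integer(raw[2L]); h <- as.integer(raw[3L])
  vals <- as.integer(raw[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM payload in ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale image as plain PGM (P2)
#'
#' @param img Integer matrix with values in 0-255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  check_gray_image(img)
  stopifnot(max(img) <= 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  apply(img, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
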