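# Binarization of continuous texture features into the transactional
# attribute schema PN, PD, H, I, J, K, L, M, Class, plus the clinical
# screening rule operating on the confirmation bits.

feature_names <- c("energy", "contrast", "entropy", "mean",
                   "local_stability", "correlation")
bit_names <- c("H", "I", "J", "K", "L", "M")

#' Discretize feature records into the binary attribute table
#'
#' Each of the six texture features is mapped positionally onto the bits
#' H, I, J, K, L, M: bit = 1 iff value > threshold, with ties (value equal
#' to the threshold) mapping to 0.  Thresholds are either supplied per
#' feature or computed as the per-feature median of the input records
#' (`"median-split"`).  A constant feature under median-split yields an
#' all-zero bit column (with a warning, not an error).
#'
#' @param records Data frame with columns `PN`, `PD`, the six feature
#'   columns (`energy`, `contrast`, `entropy`, `mean`, `local_stability`,
#'   `correlation`) and optionally `Class`.
#' @param thresholds `"median-split"` or a named numeric vector of
#'   per-feature thresholds.
#' @param feature_cols Feature column names, in the order they map onto
#'   H..M.
#' @return Data frame of class `binary_table` with columns `PN`, `PD`,
#'   `H` .. `M` (and `Class` if present), all bits in {0, 1}; attribute
#'   `thresholds` records the thresholds used.
#' @export
discretize_features <- function(records, thresholds = "median-split",
                                feature_cols = feature_names) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("PN", "PD", feature_cols) %in% names(records)),
            length(feature_cols) == 6L)
  if (identical(thresholds, "median-split")) {
    thr <- vapply(records[feature_cols], stats::median, numeric(1))
  } else {
    stopifnot(is.numeric(thresholds), all(feature_cols %in% names(thresholds)))
    thr <- thresholds[feature_cols]
  }
  out <- data.frame(PN = records$PN, PD = as.integer(records$PD))
  constant <- character(0)
  for (k in seq_along(feature_cols)) {
    v <- records[[feature_cols[k]]]
    out[[bit_names[k]]] <- as.integer(v > thr[k])
    if (identical(thresholds, "median-split") && length(unique(v)) == 1L) {
      constant <- c(constant, feature_cols[k])
    }
  }
  if (length(constant) > 0L) {
    warning("constant feature(s) under median-split (bit columns all ",
            "zero): ", paste(constant, collapse = ", "))
  }
  if ("Class" %in% names(records)) out$Class <- as.integer(records$Class)
  names(thr) <- feature_cols
  attr(out, "thresholds") <- thr
  class(out) <- c("binary_table", "data.frame")
  out
}

#' Screening rule on the confirmation bits
#'
#' A record screens positive (1) iff the clinical prediagnosis bit PD is 1
#' and at least two of the confirmation bits K, L, M are 1.
#'
#' @param record A `binary_table` (or any data frame with columns `PD`,
#'   `K`, `L`, `M`); vectorized over rows.
#' @return Integer vector of 0/1 screening outcomes.
#' @export
apply_diagnostic_rule <- function(record) {
  stopifnot(all(c("PD", "K", "L", "M") %in% names(record)))
  as.integer(record$PD == 1L & (record$K + record$L + record$M) >= 2L)
}

#' The ten-row CT feature-table fragment
#'
#' The embedded reference fragment of the binarized CT screening database
#' (records PN 60-69): prediagnosis bit PD, six binarized texture bits
#' H..M and the confirmed diagnosis Class.
#'
#' @return A `binary_table` with 10 rows.
#' @export
table1_fixture <- function() {
  out <- data.frame(
    PN = 60:69,
    PD    = c(1L, 1L, 1L, 0L, 1L, 0L, 1L, 1L, 1L, 0L),
    H     = c(1L, 1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L),
    I     = c(0L, 0L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L),
    J     = c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L),
    K     = c(1L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, 0L),
    L     = c(0L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L),
    M     = c(1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L),
    Class = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 1L, 1L, 0L)
  )
  class(out) <- c("binary_table", "data.frame")
  out
}

#' Convert a binary attribute table to a transaction database
#'
#' Every non-PN cell `v` of column `col` becomes the item `"col=v"`; PN is
#' a record identifier and never an item.
#'
#' @param table A `binary_table` (or compatible data frame with a `PN`
#'   column).
#' @return A [transaction_db()] with one transaction per record.
#' @export
binary_table_to_db <- function(table) {
  stopifnot(is.data.frame(table), "PN" %in% names(table),
            nrow(table) >= 1L)
  cols <- setdiff(names(table), "PN")
  tx <- lapply(seq_len(nrow(table)), function(i) {
    paste0(cols, "=", unlist(table[i, cols], use.names = FALSE))
  })
  db <- transaction_db(tx)
  attr(db, "PN") <- table$PN
  db
}

#' Write a binary attribute table as CSV
#'
#' @param table A `binary_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binary_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
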