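# Plate-map and readout I/O for arrayed screens.
#
# Wells are named letter-row + zero-padded column ("A01"); internal
# coordinates are 0-based (row, col). The same convention is used as the
# join key across plate maps, readouts and normalized tables.

WELL_CONTENT_TYPES <- c("mock", "blank", "scrambled", "positive_control", "gene")

#' Convert well names to 0-based (row, col) coordinates
#'
#' `"A01"` maps to row 0, col 0; `"H12"` to row 7, col 11. Rows are letters
#' `A`..`P`, columns numeric; both `"A1"` and `"A01"` are accepted on input.
#'
#' @param well character vector of well names.
#' @return data.frame with columns `well`, `row`, `col` (0-based integers).
#' @examples
#' well_to_rc(c("A01", "H12", "P24"))
#' @export
well_to_rc <- function(well) {
  well <- toupper(as.character(well))
  m <- regmatches(well, regexec("^([A-P])([0-9]{1,2})$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed well name(s): ", paste(unique(well[bad]), collapse = ", "))
  }
  row <- match(vapply(m, `[`, character(1), 2L), LETTERS) - 1L
  col <- as.integer(vapply(m, `[`, character(1), 3L)) - 1L
  if (any(col < 0L)) stop("well column must be >= 1")
  data.frame(well = rc_to_well(row, col), row = row, col = col,
             stringsAsFactors = FALSE)
}

#' Convert 0-based (row, col) coordinates to well names
#'
#' @param row,col 0-based integer vectors.
#' @return character vector of well names such as `"A01"`.
#' @examples
#' rc_to_well(7, 11)  # "H12"
#' @export
rc_to_well <- function(row, col) {
  stopifnot(all(row >= 0), all(row <= 15), all(col >= 0), all(col <= 23))
  sprintf("%s%02d", LETTERS[row + 1L], col + 1L)
}

#' All well names of a plate format
#'
#' @param format plate format, 96 (8 x 12) or 384 (16 x 24).
#' @return character vector of well names in row-major order.
#' @export
plate_wells <- function(format = 96) {
  format <- match.arg(as.character(format), c("96", "384"))
  nr <- if (format == "96") 8L else 16L
  nc <- if (format == "96") 12L else 24L
  as.vector(t(outer(seq_len(nr) - 1L, seq_len(nc) - 1L, rc_to_well)))
}

#' Read a plate-map CSV
#'
#' Schema: `plate_id,well,content_type,gene_symbol,guide_id,replicate`.
#' `content_type` is one of mock, blank, scrambled, positive_control, gene.
#' Gene wells must carry a gene symbol; mock and blank wells must not.
#'
#' @param path path to a CSV file.
#' @return data.frame of well records with derived 0-based `row`/`col`.
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) stop("plate map not found: ", path)
  pm <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  validate_plate_map(pm)
}

#' Validate and complete a plate-map data.frame
#'
#' Used by [read_plate_map()] and by the simulators; enforces the schema
#' invariants and derives `row`/`col` from the well name.
#'
#' @param pm data.frame with the plate-map columns.
#' @return validated data.frame (invisibly the same rows, typed).
#' @export
validate_plate_map <- function(pm) {
  need <- c("plate_id", "well", "content_type", "gene_symbol", "guide_id",
            "replicate")
  miss <- setdiff(need, names(pm))
  if (length(miss)) stop("plate map missing column(s): ",
                         paste(miss, collapse = ", "))
  pm <- as.data.frame(pm, stringsAsFactors = FALSE)
  pm$replicate <- as.integer(pm$replicate)
  if (anyNA(pm$replicate) || any(pm$replicate < 1L)) {
    stop("replicate must be a positive integer")
  }
  bad_ct <- setdiff(unique(pm$content_type), WELL_CONTENT_TYPES)
  if (length(bad_ct)) stop("unknown content_type: ",
                           paste(bad_ct, collapse = ", "))
  rc <- well_to_rc(pm$well)
  pm$well <- rc$well
  pm$row <- rc$row
  pm$col <- rc$col
  key <- paste(pm$plate_id, pm$well)
  if (anyDuplicated(key)) {
    stop("duplicate (plate_id, well): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  is_gene <- pm$content_type == "gene"
  if (any(is_gene & (is.na(pm$gene_symbol) | pm$gene_symbol == ""))) {
    stop("gene wells must have a non-empty gene_symbol")
  }
  is_empty_type <- pm$content_type %in% c("mock", "blank")
  if (any(is_empty_type & (nzchar(pm$gene_symbol) | nzchar(pm$guide_id)),
          na.rm = TRUE)) {
    stop("mock/blank wells must have empty gene_symbol and guide_id")
  }
  pm[c("plate_id", "well", "row", "col", "content_type", "gene_symbol",
       "guide_id", "replicate")]
}

#' Read a raw luminescence readout CSV
#'
#' Schema: `plate_id,well,raw_luminescence`. One value per (plate, well);
#' luminescence must be non-negative.
#'
#' @param path path to a CSV file.
#' @return data.frame with columns `plate_id`, `well`, `raw_luminescence`.
#' @export
read_readouts <- function(path) {
  if (!file.exists(path)) stop("readout file not found: ", path)
  ro <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_readouts(ro)
}

#' Validate a readout data.frame
#' @param ro data.frame with readout columns.
#' @return validated data.frame.
#' @export
validate_readouts <- function(ro) {
  need <- c("plate_id", "well", "raw_luminescence")
  miss <- setdiff(need, names(ro))
  if (length(miss)) stop("readout table missing column(s): ",
                         paste(miss, collapse = ", "))
  ro <- as.data.frame(ro, stringsAsFactors = FALSE)
  ro$well <- well_to_rc(ro$well)$well
  ro$raw_luminescence <- as.numeric(ro$raw_luminescence)
  if (anyNA(ro$raw_luminescence)) stop("non-numeric raw_luminescence")
  if (any(ro$raw_luminescence < 0)) stop("raw_luminescence must be >= 0")
  key <- paste(ro$plate_id, ro$well)
  if (anyDuplicated(key)) {
    stop("duplicate readout for (plate_id, well): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  ro[need]
}

#' Write a hit-calling result table as CSV
#'
#' Numeric columns are written with 12 significant digits so that a
#' write/read round trip reproduces the table.
#'
#' @param results data.frame as returned by [call_hits()].
#' @param path output path.
#' @export
write_result_table <- function(results, path) {
  out <- results
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- formatC(out[[nm]], digits = 12, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hit-calling result table written by [write_result_table()]
#' @param path CSV path.
#' @return data.frame with `hit` restored as logical.
#' @export
read_result_table <- function(path) {
  res <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("hit" %in% names(res)) res$hit <- as.logical(res$hit)
  res
}
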