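# Area codebooks and bit-set ranges.
#
# A geographic range is a set of areas drawn from an ordered codebook; it is
# represented internally as an integer bitmask (bit i-1 set <=> area i in the
# range), which keeps the DEC state space and cladogenesis tables cheap.

#' Default area codebook
#'
#' The eight areas used throughout the package examples, coded `A`-`H`:
#' South America, Madagascar, sub-Saharan Africa, the Cape, the Mediterranean
#' Basin, Northern Europe, the Middle East and Asia. Any ordered character
#' vector of single-letter codes can be used instead.
#'
#' @return A named character vector; names are the one-letter codes, values
#'   the full area names.
#' @export
default_areas <- function() {
  c(A = "South America", B = "Madagascar", C = "sub-Saharan Africa",
    D = "Cape", E = "Mediterranean Basin", F = "Northern Europe",
    G = "Middle East", H = "Asia")
}

area_codes <- function(areas) {
  if (is.null(names(areas)) && is.character(areas)) return(areas)
  names(areas)
}

# vectorised popcount for small bitmasks
bit_count <- function(x) {
  x <- as.integer(x)
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

#' Convert range labels to bitmasks and back
#'
#' A range label is a string of area codes in codebook order, e.g. `"CD"`;
#' the empty (null) range is written `"0"`.
#'
#' @param label Character vector of range labels.
#' @param bits Integer vector of range bitmasks.
#' @param areas Area codebook (see [default_areas()]); only its codes are
#'   used.
#' @return `range_bits()` returns an integer vector; `range_label()` a
#'   character vector.
#' @export
range_bits <- function(label, areas = default_areas()) {
  codes <- area_codes(areas)
  vapply(label, function(lb) {
    if (is.na(lb) || lb == "" || lb == "0") return(0L)
    ch <- strsplit(lb, "")[[1]]
    idx <- match(ch, codes)
    if (anyNA(idx)) {
      stop("unknown area code(s): ", paste(ch[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    sum(bitwShiftL(1L, idx - 1L))
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname range_bits
#' @export
range_label <- function(bits, areas = default_areas()) {
  codes <- area_codes(areas)
  vapply(as.integer(bits), function(b) {
    if (b == 0L) return("0")
    idx <- which(bitwAnd(b, bitwShiftL(1L, seq_along(codes) - 1L)) > 0L)
    paste(codes[idx], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

bits_areas_idx <- function(bits, n_areas) {
  which(bitwAnd(bits, bitwShiftL(1L, seq_len(n_areas) - 1L)) > 0L)
}

#' Read and write species-by-area range tables
#'
#' The on-disk format is delimited text with a `species` column and one 0/1
#' column per area code, in codebook order.
#'
#' @param file Path to a delimited text file.
#' @param ranges A tibble with columns `species` and `range` (range labels).
#' @param areas Area codebook.
#' @param sep Field separator (default tab).
#' @return `read_range_table()` returns a tibble with columns `species` and
#'   `range`.
#' @export
read_range_table <- function(file, areas = default_areas(), sep = "\t") {
  codes <- area_codes(areas)
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species" %in% names(df)) stop("range table needs a 'species' column")
  missing <- setdiff(codes, names(df))
  if (length(missing) > 0) {
    stop("range table lacks area column(s): ", paste(missing, collapse = ", "))
  }
  mat <- as.matrix(df[, codes, drop = FALSE])
  if (!all(mat %in% c(0, 1))) stop("range table entries must be 0/1")
  bits <- as.integer(mat %*% bitwShiftL(1L, seq_along(codes) - 1L))
  if (any(bits == 0L)) {
    stop("species with empty ranges: ",
         paste(df$species[bits == 0L], collapse = ", "))
  }
  tibble::tibble(species = as.character(df$species),
                 range = range_label(bits, codes))
}

#' @rdname read_range_table
#' @export
write_range_table <- function(ranges, file, areas = default_areas(),
                              sep = "\t") {
  codes <- area_codes(areas)
  bits <- range_bits(ranges$range, codes)
  mat <- vapply(seq_along(codes), function(i) {
    as.integer(bitwAnd(bits, bitwShiftL(1L, i - 1L)) > 0L)
  }, integer(nrow(ranges)))
  out <- data.frame(species = ranges$species, mat, check.names = FALSE)
  names(out) <- c("species", codes)
  utils::write.table(out, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}
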