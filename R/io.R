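#' Read a 10x-style fragments file
#'
#' Parses a tab-separated fragments file with columns chrom, start, end,
#' barcode, count (0-based half-open coordinates). Lines starting with `#`
#' are comments. Extra columns beyond the fifth are ignored with a warning.
#' Plain and gzip-compressed files are supported.
#'
#' @param path Path to the fragments file.
#' @param genome Optional [genome_model] used to validate records.
#' @param on_unknown_chrom What to do with records on chromosomes absent
#'   from `genome`: `"skip"` drops them with a warning, `"fail"` errors.
#' @param chrom_alias Optional alias map forwarded to
#'   [normalize_chrom_names()]; `NULL` leaves names untouched.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `barcode`,
#'   `count`.
#' @export
read_fragments <- function(path, genome = NULL,
                           on_unknown_chrom = c("skip", "fail"),
                           chrom_alias = NULL) {
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  n_fields <- {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
    on.exit(close(con), add = TRUE)
    ln <- readLines(con, n = 50)
    ln <- ln[!startsWith(ln, "#")]
    if (!length(ln)) stop("fragments file has no data lines")
    length(strsplit(ln[1], "\t", fixed = TRUE)[[1]])
  }
  if (n_fields < 5)
    stop("fragments file must have at least 5 tab-separated columns")
  if (n_fields > 5)
    warning("fragments file has ", n_fields,
            " columns; columns beyond the fifth are ignored")
  what <- c(list(character(), integer(), integer(), character(),
                 integer()),
            rep(list(NULL), n_fields - 5))
  raw <- tryCatch({
    con2 <- if (grepl("\\.gz$", path)) gzfile(path, "r")
            else file(path, "r")
    on.exit(close(con2), add = TRUE)
    scan(con2, what = what, sep = "\t", quote = "", comment.char = "#",
         quiet = TRUE, multi.line = FALSE)
  }, error = function(e) NULL)
  if (is.null(raw)) {
    # slow diagnostic pass: report which data rows are malformed
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "#", quote = "",
                             colClasses = "character", fill = TRUE)
    num <- lapply(tab[c(2, 3, 5)], function(x)
      suppressWarnings(as.numeric(x)))
    bad <- which(is.na(num[[1]]) | is.na(num[[2]]) | is.na(num[[3]]) |
                   num[[1]] != floor(num[[1]]) |
                   num[[2]] != floor(num[[2]]) |
                   num[[3]] != floor(num[[3]]))
    stop("non-integer coordinates/counts at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  frags <- data.frame(chrom = raw[[1]], start = as.numeric(raw[[2]]),
                      end = as.numeric(raw[[3]]), barcode = raw[[4]],
                      count = as.numeric(raw[[5]]),
                      stringsAsFactors = FALSE)
  if (!is.null(chrom_alias))
    frags$chrom <- normalize_chrom_names(
      frags$chrom, if (is.character(chrom_alias)) chrom_alias else NULL)
  validate_fragments(frags, genome, on_unknown_chrom)
}

#' Validate fragment records
#'
#' Enforces the fragment invariants (`start < end`, `count >= 1`) and,
#' when a genome is supplied, membership and bounds of each chromosome.
#'
#' @inheritParams read_fragments
#' @param frags Fragments `data.frame`.
#' @return The validated (possibly filtered) fragments `data.frame`.
#' @export
validate_fragments <- function(frags, genome = NULL,
                               on_unknown_chrom = c("skip", "fail")) {
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  bad <- which(frags$start >= frags$end)
  if (length(bad))
    stop("start >= end at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(frags$count < 1)
  if (length(bad))
    stop("count < 1 at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (!is.null(genome)) {
    unknown <- !(frags$chrom %in% genome$chroms)
    if (any(unknown)) {
      if (on_unknown_chrom == "fail")
        stop("unknown chromosome(s): ",
             paste(unique(frags$chrom[unknown]), collapse = ", "))
      warning("skipping ", sum(unknown),
              " fragment(s) on unknown chromosome(s)")
      frags <- frags[!unknown, , drop = FALSE]
    }
    oob <- frags$end > genome$lengths[frags$chrom]
    if (any(oob))
      stop(sum(oob), " fragment(s) extend beyond chromosome ends")
  }
  rownames(frags) <- NULL
  frags
}

#' Write a fragments file
#'
#' @param frags Fragments `data.frame` (chrom, start, end, barcode, count).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fragments <- function(frags, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(
    frags[, c("chrom", "start", "end", "barcode", "count")],
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED4 file
#'
#' 0-based half-open intervals; a fourth column, when present, is kept as
#' `name`. Output is sorted by (chrom, start). Identical duplicates are
#' kept; deduplication is the caller's choice.
#'
#' @param path Path to the BED file.
#' @return `data.frame` with columns `chrom`, `start`, `end` and
#'   optionally `name`, sorted by (chrom, start).
#' @export
read_bed <- function(path) {
  n_fields <- max(utils::count.fields(path, sep = "\t",
                                      comment.char = "#"), 0)
  if (is.na(n_fields) || length(readLines(path, n = 1)) == 0 ||
      n_fields == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file must have at least 3 columns")
  out <- data.frame(chrom = as.character(bed[[1]]),
                    start = as.numeric(bed[[2]]),
                    end = as.numeric(bed[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(bed) >= 4) out$name <- as.character(bed[[4]])
  if (any(out$start >= out$end)) stop("BED intervals must have start < end")
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write regions as BED
#'
#' @param regions `data.frame` with `chrom`, `start`, `end`, optional `name`.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  cols <- c("chrom", "start", "end")
  if (!is.null(regions$name)) cols <- c(cols, "name")
  utils::write.table(regions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read profile tables
#'
#' A profile table stores per-entity, per-window values (normalized
#' coverage or log2 fold changes) as TSV with one row per entity and one
#' column per window named `chrom:start-end`. Values are written with
#' full double precision so that a write/read round trip is lossless;
#' missing windows are written as `NA`.
#'
#' @param profiles Numeric matrix, entities in rows, windows in columns.
#' @param windows `genomic_windows` the columns are aligned to.
#' @param path Output path.
#' @return `write_profile_table` returns `path` invisibly;
#'   `read_profile_table` returns a numeric matrix with window-id column
#'   names.
#' @export
write_profile_table <- function(profiles, windows, path) {
  ids <- window_id(windows)
  if (ncol(profiles) != length(ids))
    stop("profile columns are not aligned to the window set")
  vals <- matrix(sprintf("%.17g", profiles), nrow = nrow(profiles))
  vals[is.na(profiles)] <- "NA"
  out <- cbind(entity = rownames(profiles), as.data.frame(vals))
  names(out) <- c("entity", ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_profile_table
#' @export
read_profile_table <- function(path, windows = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- names(tab)[-1]
  if (!is.null(windows)) {
    expect <- window_id(windows)
    if (length(ids) != length(expect) || any(ids != expect))
      stop("profile table header does not match the given window set")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$entity
  m
}

#' Read a bedGraph track (e.g. precomputed GC fractions)
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  bg <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(bg) < 4) stop("bedGraph must have 4 columns")
  data.frame(chrom = as.character(bg[[1]]), start = as.numeric(bg[[2]]),
             end = as.numeric(bg[[3]]), value = as.numeric(bg[[4]]),
             stringsAsFactors = FALSE)
}

#' Read / write expression matrices
#'
#' TSV matrices carry genes in rows (first column = gene id) and samples
#' in columns. `read_expression_mtx` accepts MatrixMarket triplet input
#' with separate gene and sample name files. Values must be non-negative
#' and identifiers unique.
#'
#' @param path Path to the TSV matrix.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  .validate_expression(m)
}

#' @rdname read_expression
#' @param mtx_path Path to a MatrixMarket triplet file.
#' @param genes_path,samples_path One-identifier-per-line text files.
#' @export
read_expression_mtx <- function(mtx_path, genes_path, samples_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(genes_path)
  colnames(m) <- readLines(samples_path)
  .validate_expression(m)
}

#' @rdname read_expression
#' @param expr Numeric matrix, genes x samples.
#' @export
write_expression <- function(expr, path) {
  out <- cbind(gene = rownames(expr), as.data.frame(expr, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.validate_expression <- function(m) {
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  m
}
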