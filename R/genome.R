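#' Genome model
#'
#' A lightweight container for an ordered set of chromosomes and their
#' lengths. All coordinates in the package are 0-based half-open, so a
#' chromosome of length L spans positions `[0, L)`.
#'
#' @param chroms Character vector of unique chromosome names, in the order
#'   they should appear in genome-wide displays and tie-breaks.
#' @param lengths Numeric vector of chromosome lengths in bp (all > 0),
#'   either unnamed and parallel to `chroms` or named by chromosome.
#' @return An object of class `genome_model` with elements `chroms` and
#'   `lengths` (named numeric).
#' @examples
#' gm <- genome_model(c("chr1", "chr2"), c(50e6, 40e6))
#' @export
genome_model <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (!is.null(names(lengths))) {
    if (!setequal(names(lengths), chroms))
      stop("names of 'lengths' do not match 'chroms'")
    lengths <- lengths[chroms]
  } else {
    if (length(lengths) != length(chroms))
      stop("'chroms' and 'lengths' differ in length")
    names(lengths) <- chroms
  }
  lengths <- as.numeric(lengths)
  names(lengths) <- chroms
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be finite and > 0")
  structure(list(chroms = chroms, lengths = lengths),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chroms), "chromosomes,",
      format(sum(x$lengths), big.mark = ","), "bp\n")
  invisible(x)
}

#' Normalize chromosome names
#'
#' Applies an alias map once at load time so that mixed conventions
#' ("chr1" vs "1") agree with the genome model. By default names missing
#' the "chr" prefix gain it and "MT" becomes "chrM".
#'
#' @param x Character vector of chromosome names.
#' @param alias Optional named character vector mapping input names to
#'   canonical names; applied before the default prefix rule.
#' @return Character vector of normalized names.
#' @export
normalize_chrom_names <- function(x, alias = NULL) {
  x <- as.character(x)
  if (!is.null(alias)) {
    hit <- x %in% names(alias)
    x[hit] <- alias[x[hit]]
  }
  x[x == "MT"] <- "chrM"
  no_prefix <- !startsWith(x, "chr")
  x[no_prefix] <- paste0("chr", x[no_prefix])
  x
}

# Default chromosomes excluded from ploidy-sensitive baselines.
.sex_chroms <- c("chrX", "chrY", "X", "Y")

#' Tile a genome into fixed-size windows
#'
#' Each chromosome is tiled with windows of `target_size` bp. A terminal
#' remainder of at least half the target size becomes its own window;
#' a shorter remainder is merged into the previous window. A chromosome
#' shorter than the target size yields a single window. Interval sizes of
#' 1-2 Mb are the intended working range for sparse single-cell coverage.
#'
#' @param genome A [genome_model].
#' @param target_size Window size in bp (default 2e6).
#' @return A `data.frame` of class `genomic_windows` with columns `chrom`,
#'   `start`, `end`, `gc` (NA until assigned), `effective_length`
#'   (initialised to the full window length).
#' @export
make_windows <- function(genome, target_size = 2e6) {
  stopifnot(inherits(genome, "genome_model"), target_size > 0)
  per_chrom <- lapply(genome$chroms, function(ch) {
    L <- genome$lengths[[ch]]
    if (L <= target_size) {
      starts <- 0
      ends <- L
    } else {
      n <- floor(L / target_size)
      starts <- (seq_len(n) - 1) * target_size
      ends <- starts + target_size
      rem <- L - n * target_size
      if (rem >= target_size / 2) {
        starts <- c(starts, n * target_size)
        ends <- c(ends, L)
      } else {
        ends[n] <- L
      }
    }
    data.frame(chrom = ch, start = starts, end = ends)
  })
  w <- do.call(rbind, per_chrom)
  w$gc <- NA_real_
  w$effective_length <- w$end - w$start
  rownames(w) <- NULL
  class(w) <- c("genomic_windows", "data.frame")
  w
}

#' Window identifiers
#'
#' @param windows A `genomic_windows` data frame.
#' @return Character vector `"chrom:start-end"`.
#' @export
window_id <- function(windows) {
  sprintf("%s:%d-%d", windows$chrom, as.integer(windows$start),
          as.integer(windows$end))
}

# Parse "chrom:start-end" ids back into a windows data frame.
.parse_window_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed window ids: ", paste(ids[bad], collapse = ", "))
  w <- data.frame(chrom = vapply(m, `[`, "", 2L),
                  start = as.numeric(vapply(m, `[`, "", 3L)),
                  end = as.numeric(vapply(m, `[`, "", 4L)))
  w$gc <- NA_real_
  w$effective_length <- w$end - w$start
  class(w) <- c("genomic_windows", "data.frame")
  w
}

# A window is usable when it has both a defined GC fraction and
# non-peak sequence left to measure off-target coverage in.
.usable_windows <- function(windows) {
  !is.na(windows$gc) & windows$effective_length > 0
}

# GRanges helpers ------------------------------------------------------

.as_granges <- function(df, genome = NULL) {
  if (is.null(genome)) {
    GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
  } else {
    GenomicRanges::GRanges(
      seqnames = factor(df$chrom, levels = genome$chroms),
      ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
      seqlengths = genome$lengths)
  }
}

# Merge possibly-overlapping regions into a disjoint set.
.merge_regions <- function(df) {
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  gr <- GenomicRanges::reduce(.as_granges(df))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr))
}
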