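#' Describe a genome for binned analyses
#'
#' A `genome_spec` holds chromosome names and lengths plus optional centromere
#' positions used to split chromosomes into arms. It stands in for the
#' chrom.sizes / bin-table inputs that a real analysis would take from a
#' reference assembly.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp, or a
#'   data.frame with columns `name` and `length`.
#' @param arm_split Optional named numeric vector of centromere positions in
#'   bp; each must fall strictly inside its chromosome.
#' @return An object of class `genome_spec` with elements `chroms`
#'   (data.frame `name`, `length`) and `arm_split`.
#' @examples
#' g <- genome_spec(c(chrA = 5e6, chrB = 3e6))
#' genome_bins(g, 50000)
#' @export
genome_spec <- function(chromosomes, arm_split = NULL) {
  if (is.data.frame(chromosomes)) {
    check_that(all(c("name", "length") %in% names(chromosomes)),
               "chromosome data.frame needs columns `name` and `length`")
    chroms <- data.frame(name = as.character(chromosomes$name),
                         length = as.numeric(chromosomes$length))
  } else {
    check_that(!is.null(names(chromosomes)) && all(nzchar(names(chromosomes))),
               "`chromosomes` must be a named vector of lengths")
    chroms <- data.frame(name = names(chromosomes),
                         length = as.numeric(chromosomes))
  }
  check_that(all(chroms$length > 0), "chromosome lengths must be > 0")
  check_that(!anyDuplicated(chroms$name), "duplicated chromosome names")
  if (!is.null(arm_split)) {
    check_that(all(names(arm_split) %in% chroms$name),
               "arm_split names must be chromosomes")
    len <- chroms$length[match(names(arm_split), chroms$name)]
    check_that(all(arm_split > 0 & arm_split < len),
               "arm_split must lie strictly inside the chromosome")
  }
  structure(list(chroms = chroms, arm_split = arm_split),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", nrow(x$chroms), "chromosome(s),",
      format(sum(x$chroms$length), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Tile a genome into fixed-size bins
#'
#' Bins are 0-based half-open `[start, end)`; the last bin of a chromosome may
#' be shorter than `bin_size`.
#'
#' @param genome A [genome_spec()].
#' @param bin_size Bin width in bp.
#' @return data.frame with columns `chrom`, `start`, `end`, sorted by
#'   (chromosome in genome order, start).
#' @export
genome_bins <- function(genome, bin_size) {
  check_that(inherits(genome, "genome_spec"), "`genome` must be a genome_spec")
  check_that(is_count(bin_size) && bin_size > 0, "`bin_size` must be > 0")
  pieces <- lapply(seq_len(nrow(genome$chroms)), function(i) {
    len <- genome$chroms$length[i]
    start <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = genome$chroms$name[i], start = start,
               end = pmin(start + bin_size, len))
  })
  do.call(rbind, pieces)
}

#' Chromosome arms as intervals
#'
#' Returns one interval per arm; chromosomes without an `arm_split` entry are
#' treated as a single arm (the natural convention for synthetic genomes that
#' have no centromeres).
#'
#' @param genome A [genome_spec()].
#' @return data.frame with columns `chrom`, `start`, `end`, `arm`.
#' @export
genome_arms <- function(genome) {
  check_that(inherits(genome, "genome_spec"), "`genome` must be a genome_spec")
  pieces <- lapply(seq_len(nrow(genome$chroms)), function(i) {
    nm <- genome$chroms$name[i]
    len <- genome$chroms$length[i]
    split <- if (nm %in% names(genome$arm_split))
      genome$arm_split[[nm]] else NULL
    if (is.null(split) || is.na(split)) {
      data.frame(chrom = nm, start = 0, end = len, arm = paste0(nm, "_whole"))
    } else {
      data.frame(chrom = nm, start = c(0, split), end = c(split, len),
                 arm = paste0(nm, c("_p", "_q")))
    }
  })
  do.call(rbind, pieces)
}

#' Read / write UCSC-style chrom.sizes files
#'
#' Two-column tab-separated text: chromosome name, length in bp.
#'
#' @param path File path.
#' @return `read_chrom_sizes` returns a [genome_spec()].
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("name", "length"),
                    colClasses = c("character", "numeric"))
  genome_spec(stats::setNames(tab$length, tab$name))
}

#' @rdname read_chrom_sizes
#' @param genome A [genome_spec()] to serialize.
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(genome$chroms, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges view of a bin table / interval data.frame (1-based closed for IRanges)
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}
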