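# Genome = named integer vector of chromosome lengths.  All public GRanges
# carry the usual 1-based closed coordinates; files and documented contracts
# use the BED dialect (0-based half-open).  granges0()/df0() convert at the
# boundary and are used everywhere a documented coordinate appears.

#' Read a UCSC-style chrom.sizes table
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path path to a chrom.sizes file.
#' @return Named integer vector of chromosome lengths (a "genome").
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  genome(setNames(as.integer(tab$length), tab$chrom))
}

#' Construct / validate a genome
#'
#' @param lengths named vector of chromosome lengths (bp, all > 0).
#' @return The validated named integer vector.
#' @export
genome <- function(lengths) {
  if (is.null(names(lengths)) || any(names(lengths) == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names")
  lengths <- setNames(as.integer(lengths), names(lengths))
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive integers")
  lengths
}

#' Write a genome as chrom.sizes
#' @param genome named lengths vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(data.frame(names(genome), unname(genome)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_seqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome), seqlengths = unname(genome))
}

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom chromosome names.
#' @param start0,end0 0-based half-open coordinates, `start0 < end0`.
#' @param strand strand ("+", "-", "*"); recycled.
#' @param genome optional genome; when supplied, intervals are clamped to
#'   `[0, chromosome length)` and unknown chromosomes are an error.
#' @param ... further metadata columns.
#' @return GRanges (internally 1-based closed, as usual).
#' @export
granges0 <- function(chrom, start0, end0, strand = "*", genome = NULL, ...) {
  chrom <- rep_len(as.character(chrom), length(start0))
  if (any(start0 < 0)) stop("start must be >= 0")
  if (any(start0 >= end0)) stop("start must be < end")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown))
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    end0 <- pmin(end0, unname(genome[chrom]))
  }
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand, ...)
  if (!is.null(genome)) seqinfo(gr) <- as_seqinfo(genome)[seqlevels(gr)]
  gr
}

#' 0-based starts / half-open ends of a GRanges
#' @param gr a GRanges.
#' @return integer vector.
#' @export
start0 <- function(gr) start(gr) - 1L

#' @rdname start0
#' @export
end0 <- function(gr) end(gr)

#' GRanges to a 0-based data frame
#' @param gr a GRanges.
#' @return data.frame with chrom/start/end (BED convention) plus metadata.
#' @export
df0 <- function(gr) {
  cbind(data.frame(chrom = as.character(seqnames(gr)),
                   start = start0(gr), end = end0(gr)),
        as.data.frame(mcols(gr)))
}

# sort by (chrom in first-seen order, start, end); strand-agnostic
sort_regions <- function(gr) {
  gr[order(as.integer(seqnames(gr)), start(gr), end(gr))]
}
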